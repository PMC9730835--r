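#' @importFrom stats setNames
NULL

config_error <- function(msg, function_id = NULL) {
  if (!is.null(function_id) && nzchar(function_id %||% "")) {
    msg <- sprintf("[%s] %s", function_id, msg)
  }
  structure(
    class = c("soilscore_config_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
}

input_error <- function(msg) {
  structure(
    class = c("soilscore_input_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-anchor piecewise-linear evaluation curve
#'
#' Maps a measured soil property onto the unitless 0--1 indicator scale
#' through two agronomic anchors: the indicator is exactly 0.5 at `x_half`
#' (the level below which additional fertilization is recommended) and
#' exactly 1 at `x_opt` (the optimum above which yield no longer responds).
#' Below `x_zero` the indicator is 0. The curve is linear on
#' `[x_zero, x_half]` (0 to 0.5) and `[x_half, x_opt]` (0.5 to 1), and
#' clipped outside. Supplying anchors in strictly decreasing order
#' (`x_zero > x_half > x_opt`) selects the mirrored, decreasing variant
#' used for properties where "more" is worse.
#'
#' @param x numeric vector of property values; `NA` propagates.
#' @param x_zero,x_half,x_opt curve anchors, strictly ordered (either
#'   direction).
#' @param function_id optional identifier used in error messages.
#' @return numeric vector of indicator values in \[0, 1\].
#' @examples
#' eval_two_anchor(15, 0, 10, 20)   # 0.75
#' eval_two_anchor(1.6, 1.8, 1.55, 1.3)  # decreasing variant
#' @export
eval_two_anchor <- function(x, x_zero, x_half, x_opt, function_id = NULL) {
  stopifnot(is.numeric(x))
  if (anyNA(c(x_zero, x_half, x_opt))) {
    stop(config_error("two-anchor curve has missing anchors", function_id))
  }
  if (x_zero > x_half && x_half > x_opt) {
    return(eval_two_anchor(-x, -x_zero, -x_half, -x_opt, function_id))
  }
  if (!(x_zero < x_half && x_half < x_opt)) {
    stop(config_error(
      sprintf(
        "two-anchor curve needs strictly ordered anchors, got (%g, %g, %g)",
        x_zero, x_half, x_opt
      ),
      function_id
    ))
  }
  s <- ifelse(
    x <= x_half,
    0.5 * (x - x_zero) / (x_half - x_zero),
    0.5 + 0.5 * (x - x_half) / (x_opt - x_half)
  )
  pmin(pmax(s, 0), 1)
}

#' Optimum-window (trapezoid) evaluation curve
#'
#' For properties with an optimum range rather than a monotone response
#' (e.g. soil acidity): the indicator is 1 on the plateau
#' `[low1, high1]`, 0 outside `[low0, high0]`, with linear shoulders.
#'
#' @param x numeric vector of property values; `NA` propagates.
#' @param low0,low1,high1,high0 window edges, `low0 < low1 <= high1 < high0`.
#' @param function_id optional identifier used in error messages.
#' @return numeric vector of indicator values in \[0, 1\].
#' @examples
#' eval_optimum_window(5.0, 4.5, 5.5, 6.5, 7.5)  # 0.5 on the rising shoulder
#' @export
eval_optimum_window <- function(x, low0, low1, high1, high0,
                                function_id = NULL) {
  stopifnot(is.numeric(x))
  if (anyNA(c(low0, low1, high1, high0)) ||
      !(low0 < low1 && low1 <= high1 && high1 < high0)) {
    stop(config_error(
      sprintf(
        "optimum window must satisfy low0 < low1 <= high1 < high0, got (%s)",
        paste(c(low0, low1, high1, high0), collapse = ", ")
      ),
      function_id
    ))
  }
  s <- ifelse(
    x < low1,
    (x - low0) / (low1 - low0),
    ifelse(x <= high1, 1, (high0 - x) / (high0 - high1))
  )
  pmin(pmax(s, 0), 1)
}

#' Categorical lookup evaluation curve
#'
#' Scores a categorical field property (e.g. groundwater class) through a
#' key -> score table. Keys that are `NA` propagate as missing indicator
#' values; keys absent from the table return `default` when supplied and
#' raise an error otherwise (strict mode).
#'
#' @param key character vector of category keys.
#' @param table named list or named numeric vector of scores in \[0, 1\].
#' @param default optional fallback score for keys absent from the table.
#' @param function_id optional identifier used in error messages.
#' @return numeric vector of indicator values in \[0, 1\].
#' @examples
#' eval_lookup("II", c(I = 0.1, II = 0.3))
#' @export
eval_lookup <- function(key, table, default = NULL, function_id = NULL) {
  tab <- unlist(table)
  if (length(tab) == 0) {
    stop(config_error("lookup table is empty", function_id))
  }
  if (!is.numeric(tab) || anyNA(tab) || any(tab < 0 | tab > 1)) {
    stop(config_error("lookup scores must all lie in [0, 1]", function_id))
  }
  key <- as.character(key)
  out <- unname(tab[key])
  unknown <- !is.na(key) & !(key %in% names(tab))
  if (any(unknown)) {
    if (is.null(default)) {
      stop(input_error(sprintf(
        "no lookup score for key(s) %s%s",
        paste(sQuote(unique(key[unknown])), collapse = ", "),
        if (is.null(function_id)) "" else sprintf(" in %s", function_id)
      )))
    }
    out[unknown] <- default
  }
  out
}

#' Interpret a 0--1 score as good / sufficient / poor
#'
#' Applies the standard interpretation classes: good above 0.75,
#' sufficient in \[0.5, 0.75\], poor below 0.5. Both class boundaries
#' belong to "sufficient".
#'
#' @param s numeric vector of scores in \[0, 1\]; `NA` propagates.
#' @return character vector with values `"good"`, `"sufficient"`, `"poor"`.
#' @examples
#' classify_score(c(0.76, 0.75, 0.5, 0.49))
#' @export
classify_score <- function(s) {
  stopifnot(is.numeric(s))
  eps <- 1e-9  # tolerate floating-point drift from aggregation
  bad <- !is.na(s) & (s < -eps | s > 1 + eps)
  if (any(bad)) {
    stop(input_error(sprintf(
      "scores must lie in [0, 1]; got %s",
      paste(format(s[bad]), collapse = ", ")
    )))
  }
  s <- pmin(pmax(s, 0), 1)
  out <- ifelse(s > 0.75, "good", ifelse(s >= 0.5, "sufficient", "poor"))
  out[is.na(s)] <- NA_character_
  out
}
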