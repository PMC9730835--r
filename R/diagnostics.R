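# Self-audit diagnostics: indicator redundancy (Spearman correlation,
# PCA on the correlation matrix), single-property error propagation, and
# comparison of aggregation methods.

#' Build the wide indicator table for redundancy analyses
#'
#' Rows are field-years, columns are soil functions; the management
#' category is excluded (it is an external sub-score, not a measured
#' soil function).
#'
#' @param indicators long indicator table from [evaluate_battery()] /
#'   [apply_vsa()].
#' @return tibble with `field_id`, `year_age` and one column per
#'   non-management soil function.
#' @export
indicator_table <- function(indicators) {
  indicators |>
    dplyr::filter(.data$category != "management") |>
    dplyr::select("field_id", "year_age", "function_id", "value") |>
    tidyr::pivot_wider(names_from = "function_id", values_from = "value")
}

#' Spearman rank-correlation matrix of soil indicators
#'
#' Pairwise-deletion Spearman correlations between indicator columns.
#' Pairs with fewer than three complete observations, and constant
#' columns (rank correlation undefined), are reported as `NA` with a
#' warning.
#'
#' @param tbl wide indicator table ([indicator_table()] output or any
#'   numeric matrix/data frame; `field_id` / `year_age` columns are
#'   dropped automatically).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(tbl) {
  m <- as.matrix(dplyr::select(
    tibble::as_tibble(tbl),
    -dplyr::any_of(c("field_id", "year_age"))
  ))
  storage.mode(m) <- "double"
  if (ncol(m) < 2) stop(input_error("need >= 2 indicator columns"))
  constant <- apply(m, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && diff(range(x)) == 0
  })
  if (any(constant)) {
    warning(sprintf(
      "rank correlation undefined for constant column(s): %s",
      paste(colnames(m)[constant], collapse = ", ")
    ), call. = FALSE)
  }
  rho <- suppressWarnings(
    stats::cor(m, method = "spearman", use = "pairwise.complete.obs")
  )
  # insufficient support: fewer than 3 complete pairs
  ok <- !is.na(m)
  npair <- crossprod(ok)
  rho[npair < 3] <- NA
  rho[constant, ] <- NA
  rho[, constant] <- NA
  diag(rho) <- 1
  rho
}

#' PCA of the indicator correlation matrix
#'
#' Eigen-decomposition of the Pearson correlation matrix of the
#' complete-case indicator rows: per-axis fractions of total variance
#' (non-negative, descending, summing to 1) and orthonormal loadings.
#' Rank-deficient input simply yields a zero tail of fractions.
#'
#' @param tbl wide indicator table; `field_id` / `year_age` dropped.
#' @return list with `fractions`, `loadings` (columns = axes), `sdev`
#'   and `n` (complete cases used).
#' @export
pca_variance <- function(tbl) {
  m <- as.matrix(dplyr::select(
    tibble::as_tibble(tbl),
    -dplyr::any_of(c("field_id", "year_age"))
  ))
  storage.mode(m) <- "double"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) <= ncol(m)) {
    stop(input_error(sprintf(
      "PCA needs more complete rows (%d) than columns (%d)",
      nrow(m), ncol(m)
    )))
  }
  keep <- apply(m, 2, function(x) diff(range(x)) > 0)
  if (!all(keep)) {
    warning(sprintf(
      "dropping constant column(s) from PCA: %s",
      paste(colnames(m)[!keep], collapse = ", ")
    ), call. = FALSE)
    m <- m[, keep, drop = FALSE]
  }
  cm <- stats::cor(m)
  eig <- eigen(cm, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  list(
    fractions = values / sum(values),
    loadings = eig$vectors,
    sdev = sqrt(values),
    n = nrow(m)
  )
}

#' Error propagation: sensitivity of scores to one soil property
#'
#' Recomputes the full scoring pipeline with a single property perturbed
#' on every record (relative by default: scaled by `1 + delta`;
#' additive with `relative = FALSE`) and returns the change of the final
#' score and each category sub-score per field.
#'
#' @param records validated field table.
#' @param property property column to perturb.
#' @param delta perturbation size.
#' @param battery `indicator_battery`.
#' @param cfg [aggregation_config()].
#' @param relative multiplicative (`TRUE`) or additive perturbation.
#' @param use_vsa passed to [score_fields()].
#' @return tidy tibble: `field_id`, `component` (category or `"final"`),
#'   `baseline`, `perturbed`, `delta_score`.
#' @export
perturb_and_score <- function(records, property, delta,
                              battery = default_battery(),
                              cfg = aggregation_config(), relative = TRUE,
                              use_vsa = TRUE) {
  if (!property %in% soil_properties()$property) {
    stop(input_error(sprintf("unknown property '%s'", property)))
  }
  perturbed <- records
  if (property %in% names(perturbed)) {
    perturbed[[property]] <- if (relative) {
      perturbed[[property]] * (1 + delta)
    } else {
      perturbed[[property]] + delta
    }
  }
  tidy <- function(scores, name) {
    scores |>
      dplyr::select(-dplyr::any_of("class")) |>
      dplyr::rename(final = "final_score") |>
      tidyr::pivot_longer(-"field_id", names_to = "component",
                          values_to = name)
  }
  base <- tidy(score_fields(records, battery, cfg, use_vsa), "baseline")
  pert <- tidy(score_fields(perturbed, battery, cfg, use_vsa), "perturbed")
  dplyr::left_join(base, pert, by = c("field_id", "component")) |>
    dplyr::mutate(delta_score = .data$perturbed - .data$baseline)
}

#' Compare aggregation methods on an indicator table
#'
#' For every row (field-year indicator vector) computes the final score
#' under three schemes: the default nonlinear distance-to-target
#' weighting, a linear variant with equal within-category weights (same
#' category structure and indicator-count weights, only the
#' limiting-factor correction switched off), and the minimum indicator.
#' Row-wise, minimum <= nonlinear <= linear always holds.
#'
#' @param tbl wide indicator table (columns = function ids).
#' @param battery `indicator_battery` supplying the function -> category
#'   map.
#' @param cfg [aggregation_config()].
#' @return tibble with columns `minimum`, `nonlinear`, `linear` (plus
#'   `field_id` / `year_age` when present in `tbl`).
#' @export
compare_aggregations <- function(tbl, battery = default_battery(),
                                 cfg = aggregation_config()) {
  tbl <- tibble::as_tibble(tbl)
  if (nrow(tbl) == 0) stop(input_error("indicator table is empty"))
  keys <- dplyr::select(tbl, dplyr::any_of(c("field_id", "year_age")))
  m <- as.matrix(dplyr::select(
    tbl, -dplyr::any_of(c("field_id", "year_age"))
  ))
  storage.mode(m) <- "double"
  cats <- battery_categories(validate_battery(battery))
  unknown <- setdiff(colnames(m), names(cats))
  if (length(unknown) > 0) {
    stop(input_error(sprintf(
      "indicator column(s) not in battery: %s",
      paste(unknown, collapse = ", ")
    )))
  }
  col_cat <- cats[colnames(m)]
  if (!cfg$include_management) {
    keep <- col_cat != "management"
    m <- m[, keep, drop = FALSE]
    col_cat <- col_cat[keep]
  }

  # vectorized per-category step 1 + step 3 over all rows at once
  step3 <- function(weighting) {
    num <- matrix(0, nrow(m), 1)
    den <- matrix(0, nrow(m), 1)
    for (k in unique(col_cat)) {
      v <- m[, col_cat == k, drop = FALSE]
      present <- !is.na(v)
      n_k <- rowSums(present)
      if (weighting == "nonlinear") {
        w <- 1 / (v + cfg$c)
        w[!present] <- 0
      } else {
        w <- present * 1
      }
      v0 <- v
      v0[!present] <- 0
      s_k <- rowSums(w * v0) / rowSums(w)
      wk <- cfg$category_weight(n_k)
      use <- n_k >= 1
      num[use] <- num[use] + wk[use] * s_k[use]
      den[use] <- den[use] + wk[use]
    }
    as.numeric(num / den)
  }
  out <- dplyr::bind_cols(keys, tibble::tibble(
    minimum = apply(m, 1, function(x) {
      if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
    }),
    nonlinear = step3("nonlinear"),
    linear = step3("equal")
  ))
  out
}
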