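# Default illustrative indicator battery (22 soil functions).
#
# Curve parameters are plausible for Dutch-style agricultural topsoils but
# are NOT an authoritative national calibration: regional implementations
# should override this file via read_battery(). Anchor semantics:
#   two_anchor:      [x_zero, x_half, x_opt]   score 0 / 0.5 / 1
#                    (decreasing order selects the mirrored variant)
#   optimum_window:  [low0, low1, high1, high0] trapezoid, plateau = 1
#   lookup:          key -> score table for categorical properties
# Stratum keys soil_type / land_use accept "*" as a wildcard; the most
# specific match wins.

functions:
  # ---- chemical: nutrient supply, buffering, acidity -----------------
  - id: i_c_n
    category: chemical
    property: n_total
    curves:
      - land_use: grassland
        kind: two_anchor
        anchors: [200, 1200, 4000]
      - land_use: "*"
        kind: two_anchor
        anchors: [150, 900, 3000]
  - id: i_c_p
    category: chemical
    property: p_avail
    curves:
      - kind: two_anchor
        anchors: [0.5, 2.0, 5.0]
  - id: i_c_k
    category: chemical
    property: k_avail
    curves:
      - kind: two_anchor
        anchors: [20, 70, 180]
  - id: i_c_mg
    category: chemical
    property: mg_avail
    curves:
      - kind: two_anchor
        anchors: [10, 40, 120]
  - id: i_c_cu
    category: chemical
    property: cu_avail
    curves:
      - kind: two_anchor
        anchors: [0.5, 2.5, 8.0]
  - id: i_c_s
    category: chemical
    property: s_avail
    curves:
      - kind: two_anchor
        anchors: [5, 15, 40]
  - id: i_c_zn
    category: chemical
    property: zn_avail
    curves:
      - kind: two_anchor
        anchors: [0.5, 2.5, 8.0]
  - id: i_c_cec
    category: chemical
    property: cec
    curves:
      - kind: two_anchor
        anchors: [20, 60, 200]
  - id: i_c_ph
    category: chemical
    property: ph
    curves:
      - land_use: grassland
        kind: optimum_window
        anchors: [4.2, 4.8, 6.2, 7.5]
      - soil_type: clay
        land_use: arable
        kind: optimum_window
        anchors: [5.0, 6.0, 7.5, 8.3]
      - kind: optimum_window
        anchors: [4.5, 5.2, 6.8, 8.0]

  # ---- physical: structure, water, erosion, compaction, stress -------
  - id: i_p_aggstab        # aggregate stability; VSA "structure" replaces it
    category: physical
    property: organic_matter
    vsa_item: structure
    curves:
      - kind: two_anchor
        anchors: [0.5, 2.5, 6.0]
  - id: i_p_crumbability
    category: physical
    property: clay
    curves:
      - kind: two_anchor
        anchors: [60, 35, 15]     # decreasing: heavy clay crumbles poorly
  - id: i_p_water
    category: physical
    property: silt
    curves:
      - kind: optimum_window
        anchors: [5, 15, 60, 85]
  - id: i_p_winderosion
    category: physical
    property: clay
    curves:
      - kind: two_anchor
        anchors: [0, 4, 12]       # low clay = wind-erodible
  - id: i_p_sealing
    category: physical
    property: silt
    curves:
      - kind: two_anchor
        anchors: [90, 70, 40]     # decreasing: silty topsoil seals
  - id: i_p_compaction      # VSA "compaction" replaces it
    category: physical
    property: bulk_density
    vsa_item: compaction
    curves:
      - soil_type: clay
        kind: two_anchor
        anchors: [1.70, 1.45, 1.20]
      - soil_type: peat
        kind: two_anchor
        anchors: [1.30, 1.00, 0.75]
      - kind: two_anchor
        anchors: [1.80, 1.55, 1.30]
  - id: i_p_drought
    category: physical
    property: groundwater_class
    curves:
      - kind: lookup
        table: {I: 1.0, II: 1.0, III: 0.9, IV: 0.8, V: 0.7, VI: 0.5,
                VII: 0.3, VIII: 0.2}
        default: 0.5
  - id: i_p_wetness
    category: physical
    property: groundwater_class
    curves:
      - kind: lookup
        table: {I: 0.1, II: 0.3, III: 0.5, IV: 0.7, V: 0.8, VI: 0.9,
                VII: 1.0, VIII: 1.0}
        default: 0.5

  # ---- biological ----------------------------------------------------
  - id: i_b_pmn            # soil life activity via potentially mineralizable N
    category: biological
    property: pmn
    curves:
      - land_use: grassland
        kind: two_anchor
        anchors: [5, 50, 150]
      - kind: two_anchor
        anchors: [3, 30, 100]
  - id: i_b_disease        # disease resistance, organic-matter proxy
    category: biological
    property: organic_matter
    curves:
      - kind: two_anchor
        anchors: [0.5, 2.0, 5.0]

  # ---- environmental: N retention ------------------------------------
  - id: i_e_n_groundwater
    category: environmental
    property: n_total
    curves:
      - kind: two_anchor
        anchors: [12000, 6000, 2500]   # decreasing: large N pool leaches
  - id: i_e_n_surfacewater
    category: environmental
    property: n_total
    curves:
      - kind: two_anchor
        anchors: [15000, 8000, 3000]

  # ---- management (config-supplied external sub-score) ---------------
  - id: i_m_management
    category: management
    property: management_score
    curves:
      - kind: two_anchor
        anchors: [0, 0.5, 1]           # identity on [0, 1]
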