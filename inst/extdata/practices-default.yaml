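# Default farming-practice catalogue and practice x soil-function
# effectiveness matrix. Effectiveness values (0-1) are illustrative
# defaults distilled from general agronomic reasoning, NOT a calibrated
# evidence synthesis; override via read_practices(). Practices M4, M5 and
# M9 follow this package's own code assignment (tagetes/deep-rooting
# crops, leguminous crops, straw residue incorporation).

practices:
  - id: M1
    label: liming
    land_uses: ["*"]
    soil_types: ["*"]
  - id: M2
    label: compost application
    land_uses: ["*"]
    soil_types: ["*"]
  - id: M3
    label: non-till practices
    land_uses: [arable, maize]
    soil_types: ["*"]
  - id: M4
    label: tagetes or deep-rooting crops
    land_uses: [arable, maize]
    soil_types: ["*"]
  - id: M5
    label: leguminous crops
    land_uses: [arable, maize]
    soil_types: ["*"]
  - id: M6
    label: use of catch crops
    land_uses: [arable, maize]
    soil_types: ["*"]
  - id: M7
    label: increasing grassland age
    land_uses: [grassland]
    soil_types: ["*"]
  - id: M8
    label: fertilization conform maintenance and build-up approach
    land_uses: ["*"]
    soil_types: ["*"]
  - id: M9
    label: straw residue incorporation
    land_uses: [arable]
    soil_types: ["*"]
  - id: M10
    label: improve botanical composition of grassland
    land_uses: [grassland]
    soil_types: ["*"]
  - id: M11
    label: repairing subsoil compaction
    land_uses: ["*"]
    soil_types: ["*"]

effectiveness:
  - {practice: M1,  function: i_c_ph,            e: 1.0}
  - {practice: M2,  function: i_p_aggstab,       e: 0.6}
  - {practice: M2,  function: i_p_water,         e: 0.4}
  - {practice: M2,  function: i_p_crumbability,  e: 0.3}
  - {practice: M2,  function: i_c_cec,           e: 0.4}
  - {practice: M2,  function: i_b_pmn,           e: 0.5}
  - {practice: M2,  function: i_b_disease,       e: 0.5}
  - {practice: M3,  function: i_p_aggstab,       e: 0.4}
  - {practice: M3,  function: i_p_sealing,       e: 0.5}
  - {practice: M3,  function: i_p_winderosion,   e: 0.3}
  - {practice: M4,  function: i_b_disease,       e: 0.6}
  - {practice: M4,  function: i_p_compaction,    e: 0.3}
  - {practice: M5,  function: i_c_n,             e: 0.5}
  - {practice: M5,  function: i_b_pmn,           e: 0.3}
  - {practice: M6,  function: i_e_n_groundwater, e: 0.7}
  - {practice: M6,  function: i_e_n_surfacewater, e: 0.5}
  - {practice: M6,  function: i_b_pmn,           e: 0.3}
  - {practice: M6,  function: i_p_winderosion,   e: 0.3}
  - {practice: M7,  function: i_b_pmn,           e: 0.5}
  - {practice: M7,  function: i_p_aggstab,       e: 0.5}
  - {practice: M7,  function: i_c_n,             e: 0.3}
  - {practice: M8,  function: i_c_n,             e: 0.8}
  - {practice: M8,  function: i_c_p,             e: 0.8}
  - {practice: M8,  function: i_c_k,             e: 0.8}
  - {practice: M8,  function: i_c_mg,            e: 0.8}
  - {practice: M8,  function: i_c_cu,            e: 0.8}
  - {practice: M8,  function: i_c_s,             e: 0.8}
  - {practice: M8,  function: i_c_zn,            e: 0.8}
  - {practice: M9,  function: i_p_aggstab,       e: 0.3}
  - {practice: M9,  function: i_b_pmn,           e: 0.2}
  - {practice: M10, function: i_b_disease,       e: 0.4}
  - {practice: M10, function: i_b_pmn,           e: 0.3}
  - {practice: M11, function: i_p_compaction,    e: 1.0}
  - {practice: M11, function: i_p_wetness,       e: 0.2}
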