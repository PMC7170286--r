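# Default plancheckr run configuration.
#
# `checkers` lists the enabled checkers in display order; the qa_plans entry
# is a composite of 10 constituent checks, giving 34 checks in total.
# All thresholds below are illustrative departmental policy values, meant to
# be retuned per institution; they are NOT any specific clinic's settings.
checkers:
  - isocenter_consistency
  - tolerance_tables
  - drr_created
  - patient_orientation
  - image_structure_names
  - course_names
  - plan_names
  - reference_point_limits
  - bolus_linkage
  - drr_overlay
  - dose_rate
  - plan_status
  - calc_settings
  - couch_structures
  - unusual_warnings
  - invalid_characters
  - control_point_count
  - imrt_leaf_delivery
  - leaf_motion_calculator
  - density_overrides
  - bolus_hu
  - nonclinical_complete
  - couch_position
  - setup_imager_position
  - qa_plans

params:
  global:
    machines: [TB_1, TB_2]
  isocenter_consistency:
    tolerance_mm: 0.01
  tolerance_tables:
    forbidden_labels: [TEST]
  image_structure_names:
    image_regex: "^CT_[A-Z0-9_]+$"
    structure_set_regex: "^SS_[A-Z0-9_]+$"
    severity: flag
  course_names:
    regex: "^C[0-9]+$"
    severity: flag
  plan_names:
    regex: "^[A-Z][A-Z0-9_]{0,12}$"
    severity: flag
  reference_point_limits:
    limit_multiplier: 1.07
    dose_fraction_tolerance_gy: 0.05
  dose_rate:
    allowed:
      TB_1: {6X: [400, 600], 15X: [400, 600], 6X-FFF: [400, 600, 800, 1400]}
      TB_2: {6X: [400, 600], 15X: [400, 600], 6X-FFF: [400, 600, 800, 1400]}
  plan_status:
    required_status: [TREATMENT_APPROVED]
  calc_settings:
    calc_model: AAA_15.6
    max_grid_mm: 2.5
  leaf_motion_calculator:
    name: SmartLMC_15.6
  couch_structures:
    required:
      TB_1:
        - {name: COUCH_SURFACE, density: -300}
        - {name: COUCH_INTERIOR, density: -1000}
      TB_2:
        - {name: COUCH_SURFACE, density: -300}
        - {name: COUCH_INTERIOR, density: -1000}
  couch_position:
    windows:
      TB_1: {vrt: [-300, -50], lng: [200, 1500], lat: [-50, 50]}
      TB_2: {vrt: [-300, -50], lng: [200, 1500], lat: [-50, 50]}
  setup_imager_position:
    expected: {vrt: -500, lng: 0, lat: 0}
    tolerance_mm: 5
  control_point_count:
    max_imrt_cp: 400
    min_vmat_cp: 10
    max_vmat_cp: 500
  imrt_leaf_delivery:
    min_gap_mm: 0.5
    max_leaf_speed_mm_s: 25
  invalid_characters:
    allowed_chars: "A-Za-z0-9_ .:+/-"
  unusual_warnings:
    patterns: ["overrid", "unable to", "exceed", "failed"]
  bolus_hu:
    water_hu: 0
    hu_tolerance: 10
  qa_plans:
    epid_name_regex: "^QA_[A-Z0-9_]+$"
    epid_sid_mm: 1000
    sid_tolerance_mm: 1
    mu_tolerance: 0.1
    weight_tolerance: 0.0001
    gantry_tolerance_deg: 0.1
    required_status: [TREATMENT_APPROVED, PLANNING_APPROVED]
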