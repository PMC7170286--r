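# Defect catalog

Seeded, targeted mutations of the clean synthetic templates, each mapped to
the checker expected to flag it. `evaluate_detection()` sweeps this catalog
over many seeds and asserts per-checker sensitivity 1.0 (and, on the clean
templates, plan-level specificity 1.0). The catalog covers every pass/flag
checker in the default profile; report-only rows are exercised in the unit
tests instead, since a report is not a flag.

Run `plancheckr::defect_catalog()` for the authoritative list. Summary:

| defect | template | expected checker |
|---|---|---|
| isocenter_shift | STATIC_2FIELD | isocenter_consistency |
| tolerance_test_label | STATIC_2FIELD | tolerance_tables |
| drr_missing | STATIC_2FIELD | drr_created |
| drr_overlay_missing | STATIC_2FIELD | drr_overlay |
| image_name_bad | STATIC_2FIELD | image_structure_names |
| course_name_bad | STATIC_2FIELD | course_names |
| plan_name_bad | STATIC_2FIELD | plan_names |
| invalid_character | STATIC_2FIELD | invalid_characters |
| refpoint_over_limit | STATIC_2FIELD | reference_point_limits |
| refpoint_no_contribution | STATIC_2FIELD | reference_point_limits |
| bolus_unlinked | STATIC_2FIELD | bolus_linkage |
| dose_rate_invalid | STATIC_2FIELD | dose_rate |
| plan_unapproved | STATIC_2FIELD | plan_status |
| nonclinical_not_complete | STATIC_2FIELD | nonclinical_complete |
| grid_too_coarse | STATIC_2FIELD | calc_settings |
| wrong_calc_model | STATIC_2FIELD | calc_settings |
| couch_structure_missing | STATIC_2FIELD | couch_structures |
| couch_vertical_out | STATIC_2FIELD | couch_position |
| imager_position_off | STATIC_2FIELD | setup_imager_position |
| setup_fields_removed | STATIC_2FIELD | setup_imager_position |
| static_extra_cp | STATIC_2FIELD | control_point_count |
| leaf_gap_violation | IMRT_5FIELD | imrt_leaf_delivery |
| leaf_speed_violation | IMRT_5FIELD | imrt_leaf_delivery |
| wrong_lmc | IMRT_5FIELD | leaf_motion_calculator |
| qa_mu_mismatch | ONE_FX_VMAT_WITH_EPID_QA | qa_plans |
| qa_wrong_course | ONE_FX_VMAT_WITH_EPID_QA | qa_plans |
| epid_sid_wrong | ONE_FX_VMAT_WITH_EPID_QA | qa_plans |
| qa_status_wrong | ONE_FX_VMAT_WITH_EPID_QA | qa_plans |
| mapcheck_gantry_nonzero | ONE_FX_FFF_WITH_MAPCHECK_QA | qa_plans |
| mapcheck_missing | ONE_FX_FFF_WITH_MAPCHECK_QA | qa_plans |

Design notes:

- Each mutation alters exactly the intended fields and leaves the plan
  loadable; the detection sweep also asserts orthogonality (no off-target
  flags).
- The plan-name defect is a lower-case name rather than trailing whitespace:
  DICOM string encoding pads and strips trailing spaces, so a trailing-space
  plan name cannot survive an RT Plan round trip. The whitespace rule itself
  is unit-tested on in-memory contexts.
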