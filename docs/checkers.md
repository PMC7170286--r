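# Checker reference

Each checker maps a `plan_context` and a `run_config` to one `check_result`
with status `PASS`, `FLAG` or `REPORT` (the framework also supports `MANUAL`
placeholders, but the shipped profile uses none). Conventions:

- tolerance comparisons use `<=`: a value exactly at tolerance passes;
- a checker whose preconditions do not apply returns `PASS` with a
  "not applicable" message;
- a checker missing sidecar data returns `FLAG "insufficient data"`, never a
  silent pass.

All thresholds in the shipped `inst/extdata/default_config.yaml` are
illustrative departmental policy values meant to be retuned per institution.

| checker id | kind | rule | config keys |
|---|---|---|---|
| `isocenter_consistency` | P/F | all beam isocenters agree within tolerance | `tolerance_mm` (0.01) |
| `tolerance_tables` | R | flag a forbidden (non-clinical) label or a missing label; otherwise report the distinct labels in use | `forbidden_labels` ([TEST]) |
| `drr_created` | P/F | every beam has a reference DRR (sidecar) | — |
| `patient_orientation` | R | report HFS/HFP/FFS/FFP; flag if absent | — |
| `image_structure_names` | P/F | image and structure-set display names match regexes | `image_regex`, `structure_set_regex`, `severity` |
| `course_names` | P/F | course id matches the convention, non-empty, no edge whitespace | `regex`, `severity` |
| `plan_names` | P/F | plan name matches the convention | `regex`, `severity` |
| `reference_point_limits` | P/F | no reference point above `limit_multiplier x prescription`; per-fraction x fractions consistent with total; every treatment beam contributes somewhere | `limit_multiplier` (1.07), `dose_fraction_tolerance_gy` |
| `bolus_linkage` | P/F | if any bolus structure exists, every treatment beam references it | — |
| `drr_overlay` | P/F | every beam's DRR carries the overlay (sidecar) | — |
| `dose_rate` | P/F | each treatment beam's dose rate is in the allowed set for its (machine, energy) | `allowed` |
| `plan_status` | P/F | clinical plans must be in a required approval status | `required_status` |
| `calc_settings` | P/F | volume dose algorithm equals the configured name; dose grid (max axis pitch) at most the default | `calc_model`, `max_grid_mm` (2.5) |
| `couch_structures` | P/F | the couch structures configured for the machine are present with the configured densities | `required` |
| `unusual_warnings` | R | report planning warnings matching configured patterns | `patterns` |
| `invalid_characters` | P/F | identifiers contain only whitelisted characters | `allowed_chars` |
| `control_point_count` | P/F | static = 2; IMRT in [2, max]; VMAT in [min, max] | `max_imrt_cp`, `min_vmat_cp`, `max_vmat_cp` |
| `imrt_leaf_delivery` | P/F | leaf-pair gap at least the minimum (unless closed and parked outside the X jaws); required leaf speed `|d| x DR / (dMU x 60)` at most the limit | `min_gap_mm` (0.5), `max_leaf_speed_mm_s` (25) |
| `leaf_motion_calculator` | P/F | IMRT plans use the configured leaf motion calculator | `name` |
| `density_overrides` | R | report each CT density override | — |
| `bolus_hu` | R | report bolus structures whose assigned value differs from water | `water_hu`, `hu_tolerance` |
| `nonclinical_complete` | P/F | plans in non-clinical courses are COMPLETED | — |
| `couch_position` | P/F | first-control-point table top inside the per-machine window | `windows` |
| `setup_imager_position` | P/F | every setup field's imager at the configured position; a plan without setup fields flags by policy | `expected`, `tolerance_mm` |
| `qa_plans` | P/F (composite) | 10 constituent checks, flag if any fails (below) | `epid_name_regex`, `epid_sid_mm`, `sid_tolerance_mm`, `mu_tolerance`, `weight_tolerance`, `gantry_tolerance_deg`, `required_status` |

The 25 rows above carry 34 checks in total (24 standalone + the 10-part QA
composite).

## QA composite constituents

1. verification plan filed in a QA course
2. EPID plan name matches the naming convention
3. EPID reference images at the correct SID
4. EPID MU / control-point comparison against the clinical plan — applies
   only when fractions = 1, delivery IMRT/VMAT, energy 6X or 15X; fails if no
   EPID plan exists when gated
5. MapCheck plan created — applies only when fractions = 1, IMRT/VMAT,
   energy 6X-FFF
6. MapCheck beams all at gantry 0
7. EPID plan has a tolerance table and treatment time defined
8. MapCheck plan has a tolerance table and treatment time defined
9. EPID plan approval status correct
10. MapCheck plan approval status correct
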