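# Sidecar metadata schema

A single UTF-8 YAML document accompanying one exported DICOM RT Plan. It
carries treatment-planning-system database fields that standard DICOM exports
do not contain. Exactly which fields a given TPS exposes through its API
versus its database varies by vendor and version, so this schema is a
deliberately broad superset; it is documented, not asserted as faithful to
any one system.

All keys except `plan_id` are optional. A missing optional key leaves the
corresponding context field "unknown", which makes the dependent checkers
FLAG with an "insufficient data" message rather than pass silently.

| key | type | meaning |
|---|---|---|
| `plan_id` | string (required) | Must equal the RT Plan label; linkage is rejected otherwise. |
| `course_id` | string | Course identifier, checked against the course naming convention. |
| `course_intent` | `CLINICAL` \| `NON_CLINICAL` \| `QA` | Drives the plan-status and non-clinical-completion checkers. |
| `plan_status` | `UNAPPROVED` \| `PLANNING_APPROVED` \| `TREATMENT_APPROVED` \| `COMPLETED` \| `REJECTED` | Approval state in the TPS. |
| `image_id`, `structure_set_id` | string | Display names of the planning CT and structure set. |
| `calc_model` | string | Volume dose algorithm name (e.g. `AAA_15.6`). |
| `leaf_motion_calculator` | string | Leaf motion calculator name, checked on IMRT plans. |
| `drr` | map: beam name -> `{present: bool, overlay: bool}` | Whether a reference DRR exists for the beam and whether it carries the graticule/field overlay. |
| `imager_positions` | map: beam name -> `{vrt:, lng:, lat:}` (mm) | Planned imager position for each setup field. |
| `couch_structures` | list of `{name:, density:}` | Couch model structures inserted in the plan, with assigned density (HU). |
| `density_overrides` | list of `{structure:, value:}` | CT density overrides, reported by the override checker. |
| `bolus_structures` | list of `{name:, roi_number:, hu:}` | Bolus structures; `roi_number` resolves DICOM bolus references, `hu` is the assigned value checked against water. |
| `warnings` | list of strings | Planning-system warnings; those matching the configured patterns are reported as unusual. |
| `qa_plans` | list (below) | Verification plans linked to this clinical plan. |

Each `qa_plans` entry:

| key | type | meaning |
|---|---|---|
| `plan_file` | path | The QA RT Plan DICOM file, relative to the sidecar. |
| `qa_plan_id` | string | Defaults to that file's plan label. |
| `qa_kind` | `EPID` \| `MAPCHECK` | Verification modality. |
| `course_id`, `course_intent`, `plan_status` | as above | QA plans must live in a QA course with an approved status. |
| `reference_sid` | mm | SID of the EPID reference images. |
| `treatment_time_defined` | bool | Whether a treatment time is set. |
| `linked_clinical_plan_id` | string | Must match the clinical `plan_id`. |
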