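# Vendor-neutral in-memory representation of a treatment plan.
#
# Units: positions mm, doses Gy, metersets MU, angles degrees (IEC 61217).
# Coordinates: DICOM patient coordinate system.

PLAN_STATUSES <- c("UNAPPROVED", "PLANNING_APPROVED", "TREATMENT_APPROVED",
                   "COMPLETED", "REJECTED", "UNKNOWN")
COURSE_INTENTS <- c("CLINICAL", "NON_CLINICAL", "QA", "UNKNOWN")
DELIVERY_KINDS <- c("STATIC", "IMRT", "VMAT")
BEAM_ROLES <- c("TREATMENT", "SETUP")
QA_KINDS <- c("EPID", "MAPCHECK")

.norm_angle <- function(a) {
  a <- a %% 360
  a[abs(a - 360) < 1e-9] <- 0
  a
}

#' Construct a control point
#'
#' One snapshot of machine state within a beam: gantry/collimator/couch angles,
#' jaw and MLC positions, table-top position and the cumulative meterset weight
#' reached at this point of the delivery.
#'
#' @param index Zero-based control point index.
#' @param cumulative_meterset_weight Fraction of the beam meterset delivered,
#'   non-decreasing with `index`.
#' @param gantry_angle,collimator_angle,couch_angle Degrees, IEC 61217;
#'   normalised into `[0, 360)`.
#' @param jaw_positions Named numeric `c(x1, x2, y1, y2)`, mm; may be `NULL`
#'   (carried forward from the previous control point by the loader).
#' @param mlc `list(a = , b = )`: two equal-length numeric banks, mm, with
#'   `a <= b` within each leaf pair; or `NULL` for beams without MLC.
#' @param table_top Named numeric `c(vrt, lng, lat)`, mm, or `NULL`.
#' @return A `control_point` list.
#' @export
new_control_point <- function(index, cumulative_meterset_weight,
                              gantry_angle = 0, collimator_angle = 0,
                              couch_angle = 0, jaw_positions = NULL,
                              mlc = NULL, table_top = NULL) {
  stopifnot(index >= 0, cumulative_meterset_weight >= -1e-9)
  if (!is.null(mlc)) {
    if (length(mlc$a) != length(mlc$b)) {
      stop("MLC banks must have equal length", call. = FALSE)
    }
  }
  structure(list(
    index = as.integer(index),
    cumulative_meterset_weight = cumulative_meterset_weight,
    gantry_angle = .norm_angle(gantry_angle),
    collimator_angle = .norm_angle(collimator_angle),
    couch_angle = .norm_angle(couch_angle),
    jaw_positions = jaw_positions,
    mlc = mlc,
    table_top = table_top
  ), class = "control_point")
}

#' Construct a beam
#'
#' @param beam_id,beam_name Identifiers as exported.
#' @param machine_name Treatment machine name.
#' @param energy_label e.g. `"6X"`, `"15X"`, `"6X-FFF"`.
#' @param delivery_kind One of `"STATIC"`, `"IMRT"`, `"VMAT"`.
#' @param role `"TREATMENT"` or `"SETUP"`.
#' @param dose_rate MU/min.
#' @param meterset MU (0 or `NA` for setup beams).
#' @param isocenter Numeric length-3, mm, DICOM patient coordinates.
#' @param control_points List of [new_control_point()] objects.
#' @param bolus_ids Character vector of linked bolus structure names.
#' @param tolerance_table_label Record-and-verify tolerance table label.
#' @param drr_present,drr_overlay_present Logical; `NA` when the sidecar did
#'   not supply them.
#' @param imager_position Named numeric `c(vrt, lng, lat)` mm, or `NULL`.
#' @return A `beam` list.
#' @export
new_beam <- function(beam_id, beam_name = beam_id, machine_name = NA_character_,
                     energy_label = NA_character_, delivery_kind = "STATIC",
                     role = "TREATMENT", dose_rate = NA_real_,
                     meterset = NA_real_, isocenter = c(NA_real_, NA, NA),
                     control_points = list(), bolus_ids = character(0),
                     tolerance_table_label = NA_character_,
                     drr_present = NA, drr_overlay_present = NA,
                     imager_position = NULL) {
  delivery_kind <- match.arg(delivery_kind, DELIVERY_KINDS)
  role <- match.arg(role, BEAM_ROLES)
  structure(list(
    beam_id = beam_id, beam_name = beam_name, machine_name = machine_name,
    energy_label = energy_label, delivery_kind = delivery_kind, role = role,
    dose_rate = dose_rate, meterset = meterset, isocenter = isocenter,
    control_points = control_points, bolus_ids = bolus_ids,
    tolerance_table_label = tolerance_table_label,
    drr_present = drr_present, drr_overlay_present = drr_overlay_present,
    imager_position = imager_position
  ), class = "beam")
}

#' Construct a reference point
#'
#' A dose-tracking point accumulating contributions from beams, evaluated
#' against the prescription by the reference-point checker.
#'
#' @param ref_id,name Identifiers.
#' @param total_dose Total dose over the course, Gy.
#' @param dose_per_fraction Gy.
#' @param contributing_beam_ids Beams contributing dose to this point.
#' @return A `reference_point` list.
#' @export
new_reference_point <- function(ref_id, name, total_dose, dose_per_fraction,
                                contributing_beam_ids = character(0)) {
  stopifnot(total_dose >= 0)
  structure(list(
    ref_id = ref_id, name = name, total_dose = total_dose,
    dose_per_fraction = dose_per_fraction,
    contributing_beam_ids = contributing_beam_ids
  ), class = "reference_point")
}

#' Construct a plan context
#'
#' The unit a check run consumes: one treatment plan together with its
#' structure-set/dose summaries, sidecar metadata and linked QA plans.
#'
#' @param plan_id,plan_name,course_id Identifiers.
#' @param plan_status One of `r paste(PLAN_STATUSES, collapse = ", ")`.
#' @param course_intent One of `r paste(COURSE_INTENTS, collapse = ", ")`.
#' @param fractions Planned number of fractions (>= 1).
#' @param prescription_dose Gy.
#' @param beams List of [new_beam()] objects.
#' @param reference_points List of [new_reference_point()] objects.
#' @param calc_model,leaf_motion_calculator Algorithm names from the planning
#'   system (sidecar fields).
#' @param dose_grid_resolution mm (max axis pitch), or `NA`.
#' @param image_id,structure_set_id Display names of the planning image and
#'   structure set.
#' @param patient_orientation e.g. `"HFS"`.
#' @param couch_structures List of `list(name =, density =)`.
#' @param density_overrides List of `list(structure =, value =)`.
#' @param bolus_structures List of `list(name =, roi_number =, hu =)`.
#' @param qa_plans List of `qa_plan_context` objects.
#' @param warnings Character vector of planning-system warnings.
#' @param sop_instance_uid SOP instance UID of the source RT Plan, used for
#'   dose-file linkage.
#' @return A `plan_context` list.
#' @export
new_plan_context <- function(plan_id, plan_name = plan_id,
                             course_id = NA_character_,
                             plan_status = "UNKNOWN",
                             course_intent = "UNKNOWN",
                             fractions = NA_integer_,
                             prescription_dose = NA_real_,
                             beams = list(), reference_points = list(),
                             calc_model = NA_character_,
                             leaf_motion_calculator = NA_character_,
                             dose_grid_resolution = NA_real_,
                             image_id = NA_character_,
                             structure_set_id = NA_character_,
                             patient_orientation = NA_character_,
                             couch_structures = list(),
                             density_overrides = list(),
                             bolus_structures = list(),
                             qa_plans = list(), warnings = character(0),
                             sop_instance_uid = NA_character_) {
  stopifnot(plan_status %in% PLAN_STATUSES, course_intent %in% COURSE_INTENTS)
  structure(list(
    plan_id = plan_id, plan_name = plan_name, course_id = course_id,
    plan_status = plan_status, course_intent = course_intent,
    fractions = if (is.na(fractions)) NA_integer_ else as.integer(fractions),
    prescription_dose = prescription_dose, beams = beams,
    reference_points = reference_points, calc_model = calc_model,
    leaf_motion_calculator = leaf_motion_calculator,
    dose_grid_resolution = dose_grid_resolution,
    image_id = image_id, structure_set_id = structure_set_id,
    patient_orientation = patient_orientation,
    couch_structures = couch_structures,
    density_overrides = density_overrides,
    bolus_structures = bolus_structures,
    qa_plans = qa_plans, warnings = warnings,
    sop_instance_uid = sop_instance_uid
  ), class = "plan_context")
}

#' Construct a QA plan context
#'
#' @param qa_plan_id Identifier of the verification plan.
#' @param qa_kind `"EPID"` or `"MAPCHECK"`.
#' @param course_id Course holding the QA plan.
#' @param course_intent Intent of that course (should be `"QA"`).
#' @param plan_status Approval status.
#' @param beams List of beams (with per-control-point meterset weights).
#' @param reference_sid Source-to-imager distance of the reference images, mm.
#' @param linked_clinical_plan_id The clinical plan this QA plan verifies.
#' @param tolerance_table_label Label used by the QA beams.
#' @param treatment_time_defined Logical.
#' @return A `qa_plan_context` list.
#' @export
new_qa_plan_context <- function(qa_plan_id, qa_kind, course_id = NA_character_,
                                course_intent = "UNKNOWN",
                                plan_status = "UNKNOWN", beams = list(),
                                reference_sid = NA_real_,
                                linked_clinical_plan_id = NA_character_,
                                tolerance_table_label = NA_character_,
                                treatment_time_defined = NA) {
  qa_kind <- match.arg(qa_kind, QA_KINDS)
  structure(list(
    qa_plan_id = qa_plan_id, qa_kind = qa_kind, course_id = course_id,
    course_intent = course_intent, plan_status = plan_status, beams = beams,
    reference_sid = reference_sid,
    linked_clinical_plan_id = linked_clinical_plan_id,
    tolerance_table_label = tolerance_table_label,
    treatment_time_defined = treatment_time_defined
  ), class = "qa_plan_context")
}

# Validation -----------------------------------------------------------------

#' Validate a beam's internal invariants
#'
#' Hard errors: cumulative meterset weight decreasing with index; MLC bank A
#' above bank B. Soft issues (returned as character vector, surfaced in
#' `plan_context$warnings` and left for the relevant checkers to flag):
#' static beams without exactly two control points, setup beams with non-zero
#' meterset, treatment beams with a missing tolerance table label or
#' non-positive dose rate.
#'
#' @param beam A `beam` object.
#' @return Character vector of soft-issue messages (possibly empty).
#' @export
validate_beam <- function(beam) {
  cps <- beam$control_points
  w <- vapply(cps, function(cp) cp$cumulative_meterset_weight, numeric(1))
  if (length(w) > 1 && any(diff(w) < -1e-9)) {
    bad <- which(diff(w) < -1e-9)[1] + 1L
    stop(sprintf(
      "beam %s: cumulative meterset weight decreases at control point index %d",
      beam$beam_id, cps[[bad]]$index), call. = FALSE)
  }
  for (cp in cps) {
    if (!is.null(cp$mlc) && any(cp$mlc$a > cp$mlc$b + 1e-9)) {
      pair <- which(cp$mlc$a > cp$mlc$b + 1e-9)[1]
      stop(sprintf(
        "beam %s: MLC bank A above bank B at control point index %d, leaf pair %d",
        beam$beam_id, cp$index, pair), call. = FALSE)
    }
  }
  soft <- character(0)
  if (beam$delivery_kind == "STATIC" && length(cps) != 2) {
    soft <- c(soft, sprintf("beam %s: static beam has %d control points (expected 2)",
                            beam$beam_id, length(cps)))
  }
  if (beam$role == "SETUP" && isTRUE(beam$meterset > 1e-9)) {
    soft <- c(soft, sprintf("beam %s: setup beam has non-zero meterset", beam$beam_id))
  }
  if (beam$role == "TREATMENT") {
    if (is.na(beam$tolerance_table_label) || !nzchar(beam$tolerance_table_label)) {
      soft <- c(soft, sprintf("beam %s: treatment beam has no tolerance table label",
                              beam$beam_id))
    }
    if (!is.na(beam$dose_rate) && beam$dose_rate <= 0) {
      soft <- c(soft, sprintf("beam %s: non-positive dose rate", beam$beam_id))
    }
  }
  soft
}

#' Validate a plan context
#'
#' Runs [validate_beam()] on every beam (hard invariant violations error),
#' checks bolus linkage resolvability and reference-point dose consistency,
#' and appends soft issues to `ctx$warnings`.
#'
#' @param ctx A `plan_context`.
#' @param dose_fraction_tolerance Allowed absolute deviation, Gy, between
#'   `total_dose` and `dose_per_fraction * fractions`.
#' @return The validated context (with `warnings` possibly extended).
#' @export
validate_plan_context <- function(ctx, dose_fraction_tolerance = 0.05) {
  soft <- character(0)
  for (beam in ctx$beams) soft <- c(soft, validate_beam(beam))
  # resolvability is only assessable once the bolus structures are known
  # (sidecar/structure-set merge); a partial context skips this
  if (length(ctx$bolus_structures)) {
    bolus_names <- vapply(ctx$bolus_structures, function(b) b$name, character(1))
    for (beam in ctx$beams) {
      unresolved <- setdiff(beam$bolus_ids, bolus_names)
      if (length(unresolved)) {
        soft <- c(soft, sprintf("beam %s: bolus reference %s does not resolve to a bolus structure",
                                beam$beam_id, paste(unresolved, collapse = ", ")))
      }
    }
  }
  if (!is.na(ctx$fractions)) {
    for (rp in ctx$reference_points) {
      if (!is.na(rp$dose_per_fraction) &&
          abs(rp$total_dose - rp$dose_per_fraction * ctx$fractions) >
            dose_fraction_tolerance) {
        soft <- c(soft, sprintf(
          "reference point %s: total dose %.3f Gy inconsistent with %.3f Gy x %d fractions",
          rp$ref_id, rp$total_dose, rp$dose_per_fraction, ctx$fractions))
      }
    }
  }
  ctx$warnings <- unique(c(ctx$warnings, soft))
  ctx
}

#' @export
print.plan_context <- function(x, ...) {
  cat(sprintf("<plan_context> %s (course %s, %s, %s)\n", x$plan_id,
              x$course_id, x$course_intent, x$plan_status))
  cat(sprintf("  %d beams, %d reference points, %d QA plans, fractions: %s\n",
              length(x$beams), length(x$reference_points), length(x$qa_plans),
              as.character(x$fractions)))
  invisible(x)
}

#' Tabulate the beams of a plan context
#'
#' @param x A `plan_context`.
#' @param ... Unused.
#' @return A tibble with one row per beam.
#' @method tidy plan_context
#' @export
tidy.plan_context <- function(x, ...) {
  tibble::tibble(
    beam_id = vapply(x$beams, `[[`, character(1), "beam_id"),
    beam_name = vapply(x$beams, `[[`, character(1), "beam_name"),
    role = vapply(x$beams, `[[`, character(1), "role"),
    delivery_kind = vapply(x$beams, `[[`, character(1), "delivery_kind"),
    machine = vapply(x$beams, `[[`, character(1), "machine_name"),
    energy = vapply(x$beams, `[[`, character(1), "energy_label"),
    meterset = vapply(x$beams, `[[`, numeric(1), "meterset"),
    n_control_points = vapply(x$beams, function(b) length(b$control_points),
                              integer(1))
  )
}
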