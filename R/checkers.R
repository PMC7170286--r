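# The individual plan checkers. Every checker maps PlanContext x RunConfig to
# one CheckResult with status PASS / FLAG / REPORT. Conventions shared by all
# checkers:
#   - comparisons against a tolerance use <= : a value exactly at tolerance
#     passes;
#   - a checker whose preconditions do not apply returns PASS with a
#     "not applicable" message, keeping the FLAG count meaningful;
#   - a checker that needs sidecar data it cannot see returns
#     FLAG "insufficient data", never a silent PASS.

.treatment_beams <- function(ctx) {
  Filter(function(b) b$role == "TREATMENT", ctx$beams)
}
.setup_beams <- function(ctx) {
  Filter(function(b) b$role == "SETUP", ctx$beams)
}
.insufficient <- function(id, what) {
  check_result(id, "FLAG", sprintf("insufficient data: %s", what))
}

#' Check that all beams share one isocenter
#'
#' @param ctx A `plan_context`.
#' @param cfg A `run_config`; uses `isocenter_consistency.tolerance_mm`
#'   (default 0.01 mm, a float-safe equality band).
#' @return A `check_result`.
#' @export
check_isocenter_consistency <- function(ctx, cfg) {
  id <- "isocenter_consistency"
  tol <- cfg_param(cfg, id, "tolerance_mm", 0.01)
  beams <- ctx$beams
  if (length(beams) < 2) {
    return(check_result(id, "PASS", "not applicable: fewer than two beams"))
  }
  ref <- beams[[1]]$isocenter
  msgs <- character(0)
  for (b in beams[-1]) {
    d <- abs(b$isocenter - ref)
    if (any(is.na(d))) {
      return(.insufficient(id, sprintf("beam %s has no isocenter", b$beam_id)))
    }
    if (max(d) > tol) {
      msgs <- c(msgs, sprintf(
        "beam %s isocenter differs from beam %s by (%.3f, %.3f, %.3f) mm",
        b$beam_name, beams[[1]]$beam_name, d[1], d[2], d[3]))
    }
  }
  if (length(msgs)) check_result(id, "FLAG", msgs,
                                 details = list(tolerance_mm = tol))
  else check_result(id, "PASS", details = list(tolerance_mm = tol))
}

#' Check naming conventions
#'
#' Course id, plan name, and image/structure-set display names are matched
#' against configurable regexes. Each rule carries a `severity` switch
#' (`flag` or `report`) so an institution can soften a convention without
#' disabling it.
#'
#' @param ctx A `plan_context`.
#' @param cfg A `run_config`.
#' @param scope Which rule set to evaluate: `"image_structure"`, `"course"`
#'   or `"plan"`.
#' @return A `check_result`.
#' @export
check_naming_conventions <- function(ctx, cfg,
                                     scope = c("course", "plan",
                                               "image_structure")) {
  scope <- match.arg(scope)
  id <- switch(scope, course = "course_names", plan = "plan_names",
               image_structure = "image_structure_names")
  severity <- toupper(cfg_param(cfg, id, "severity", "flag"))
  if (!severity %in% c("FLAG", "REPORT")) severity <- "FLAG"
  msgs <- character(0)
  bad <- function(label, value, pattern) {
    if (is.na(value) || !nzchar(value)) {
      sprintf("%s is empty", label)
    } else if (grepl("^\\s|\\s$", value)) {
      sprintf("%s '%s' has leading/trailing whitespace", label, value)
    } else if (!grepl(pattern, value)) {
      sprintf("%s '%s' does not match convention %s", label, value, pattern)
    } else NA_character_
  }
  if (scope == "course") {
    m <- bad("course id", ctx$course_id, cfg_param(cfg, id, "regex", ".*"))
    if (!is.na(m)) msgs <- c(msgs, m)
  } else if (scope == "plan") {
    m <- bad("plan name", ctx$plan_name, cfg_param(cfg, id, "regex", ".*"))
    if (!is.na(m)) msgs <- c(msgs, m)
  } else {
    if (is.na(ctx$image_id) && is.na(ctx$structure_set_id)) {
      return(.insufficient(id, "image/structure-set names not in sidecar"))
    }
    m1 <- bad("image name", ctx$image_id,
              cfg_param(cfg, id, "image_regex", ".*"))
    m2 <- bad("structure set name", ctx$structure_set_id,
              cfg_param(cfg, id, "structure_set_regex", ".*"))
    msgs <- c(msgs, m1[!is.na(m1)], m2[!is.na(m2)])
  }
  if (length(msgs)) check_result(id, severity, msgs)
  else check_result(id, "PASS")
}

#' Check for invalid characters in identifiers
#'
#' Course id, plan id/name, beam names and image/structure-set names must
#' contain only characters from the configured whitelist.
#'
#' @param ctx A `plan_context`.
#' @param cfg A `run_config`; uses `invalid_characters.allowed_chars`, a
#'   regex character-class body.
#' @return A `check_result`.
#' @export
check_invalid_characters <- function(ctx, cfg) {
  id <- "invalid_characters"
  allowed <- cfg_param(cfg, id, "allowed_chars", "A-Za-z0-9_ .:+/-")
  pattern <- sprintf("[^%s]", allowed)
  fields <- c(course_id = ctx$course_id, plan_id = ctx$plan_id,
              plan_name = ctx$plan_name,
              image_id = ctx$image_id, structure_set_id = ctx$structure_set_id)
  for (b in ctx$beams) fields[paste0("beam ", b$beam_id, " name")] <- b$beam_name
  msgs <- character(0)
  for (nm in names(fields)) {
    val <- fields[[nm]]
    if (is.na(val)) next
    hits <- regmatches(val, gregexpr(pattern, val))[[1]]
    if (length(hits)) {
      msgs <- c(msgs, sprintf("%s '%s' contains invalid character(s): %s",
                              nm, val, paste(unique(hits), collapse = " ")))
    }
  }
  if (length(msgs)) check_result(id, "FLAG", msgs) else check_result(id, "PASS")
}

#' Check reference point dose limits and contributions
#'
#' Flags when a reference point's total dose exceeds
#' `limit_multiplier x prescription_dose`, when `dose_per_fraction x
#' fractions` deviates from `total_dose` beyond tolerance, or when a treatment
#' beam contributes to no reference point.
#'
#' @param ctx A `plan_context`.
#' @param cfg A `run_config`.
#' @return A `check_result`.
#' @export
check_reference_point_limits <- function(ctx, cfg) {
  id <- "reference_point_limits"
  mult <- cfg_param(cfg, id, "limit_multiplier", 1.07)
  ftol <- cfg_param(cfg, id, "dose_fraction_tolerance_gy", 0.05)
  if (!length(ctx$reference_points)) {
    return(check_result(id, "FLAG", "plan has no reference points"))
  }
  if (is.na(ctx$prescription_dose)) {
    return(.insufficient(id, "prescription dose unknown"))
  }
  msgs <- character(0)
  limit <- mult * ctx$prescription_dose
  for (rp in ctx$reference_points) {
    if (rp$total_dose > limit + 1e-9) {
      msgs <- c(msgs, sprintf(
        "reference point %s total dose %.2f Gy exceeds %.0f%% of prescription (%.2f Gy)",
        rp$name, rp$total_dose, 100 * mult, limit))
    }
    if (!is.na(rp$dose_per_fraction) && !is.na(ctx$fractions) &&
        abs(rp$dose_per_fraction * ctx$fractions - rp$total_dose) > ftol) {
      msgs <- c(msgs, sprintf(
        "reference point %s: %.3f Gy x %d fx inconsistent with total %.3f Gy",
        rp$name, rp$dose_per_fraction, ctx$fractions, rp$total_dose))
    }
  }
  contributing <- unique(unlist(lapply(ctx$reference_points,
                                       `[[`, "contributing_beam_ids")))
  for (b in .treatment_beams(ctx)) {
    if (!b$beam_id %in% contributing) {
      msgs <- c(msgs, sprintf("beam %s contributes to no reference point",
                              b$beam_name))
    }
  }
  if (length(msgs)) check_result(id, "FLAG", msgs) else check_result(id, "PASS")
}

#' Check bolus linkage, or report bolus override values
#'
#' With `scope = "linkage"`: if any bolus structure exists, every treatment
#' beam must reference it (flag naming the beams that do not). With
#' `scope = "hu"`: report each bolus structure whose assigned value differs
#' from water by more than `hu_tolerance`; a bolus without any evaluable
#' value is reported as "not evaluable".
#'
#' @param ctx A `plan_context`.
#' @param cfg A `run_config`.
#' @param scope `"linkage"` or `"hu"`.
#' @return A `check_result`.
#' @export
check_bolus <- function(ctx, cfg, scope = c("linkage", "hu")) {
  scope <- match.arg(scope)
  if (scope == "linkage") {
    id <- "bolus_linkage"
    if (!length(ctx$bolus_structures)) {
      return(check_result(id, "PASS", "not applicable: no bolus structures"))
    }
    bolus_names <- vapply(ctx$bolus_structures, `[[`, character(1), "name")
    msgs <- character(0)
    for (b in .treatment_beams(ctx)) {
      missing <- setdiff(bolus_names, b$bolus_ids)
      if (length(missing)) {
        msgs <- c(msgs, sprintf("bolus %s not attached to beam %s",
                                paste(missing, collapse = ", "), b$beam_name))
      }
    }
    if (length(msgs)) check_result(id, "FLAG", msgs)
    else check_result(id, "PASS")
  } else {
    id <- "bolus_hu"
    if (!length(ctx$bolus_structures)) {
      return(check_result(id, "PASS", "not applicable: no bolus structures"))
    }
    water <- cfg_param(cfg, id, "water_hu", 0)
    tol <- cfg_param(cfg, id, "hu_tolerance", 10)
    msgs <- character(0)
    for (bs in ctx$bolus_structures) {
      hu <- bs$hu %||% NA_real_
      if (is.na(hu)) {
        msgs <- c(msgs, sprintf("bolus %s: HU not evaluable", bs$name))
      } else if (abs(hu - water) > tol) {
        msgs <- c(msgs, sprintf("bolus %s has non-water value %+.0f HU",
                                bs$name, hu))
      }
    }
    if (length(msgs)) check_result(id, "REPORT", msgs)
    else check_result(id, "PASS")
  }
}

#' Check DRR presence, or DRR overlays
#'
#' Every beam needs a reference DRR; with `scope = "overlay"` the graticule /
#' field outline overlay must additionally be present. Both facts come from
#' the sidecar; missing keys flag "insufficient data".
#'
#' @param ctx A `plan_context`.
#' @param cfg A `run_config` (no parameters).
#' @param scope `"created"` or `"overlay"`.
#' @return A `check_result`.
#' @export
check_drr <- function(ctx, cfg, scope = c("created", "overlay")) {
  scope <- match.arg(scope)
  id <- if (scope == "created") "drr_created" else "drr_overlay"
  field <- if (scope == "created") "drr_present" else "drr_overlay_present"
  msgs <- character(0)
  insuff <- character(0)
  for (b in ctx$beams) {
    val <- b[[field]]
    if (is.na(val)) {
      insuff <- c(insuff, b$beam_name)
    } else if (!val) {
      msgs <- c(msgs, sprintf("beam %s has no %s", b$beam_name,
                              if (scope == "created") "DRR" else "DRR overlay"))
    }
  }
  if (length(insuff)) {
    return(.insufficient(id, sprintf("DRR %s status unknown for beam(s) %s",
                                     scope, paste(insuff, collapse = ", "))))
  }
  if (length(msgs)) check_result(id, "FLAG", msgs) else check_result(id, "PASS")
}

#' Check dose rates against the machine/energy table
#'
#' @param ctx A `plan_context`.
#' @param cfg A `run_config`; uses `dose_rate.allowed`, a nested map
#'   machine -> energy -> allowed MU/min values.
#' @return A `check_result`.
#' @export
check_dose_rate <- function(ctx, cfg) {
  id <- "dose_rate"
  allowed <- cfg_param(cfg, id, "allowed", list())
  msgs <- character(0)
  for (b in .treatment_beams(ctx)) {
    if (is.na(b$machine_name) || is.null(allowed[[b$machine_name]])) {
      msgs <- c(msgs, sprintf("beam %s: machine '%s' not in configuration",
                              b$beam_name, b$machine_name))
      next
    }
    ok <- unlist(allowed[[b$machine_name]][[b$energy_label]])
    if (is.null(ok)) {
      msgs <- c(msgs, sprintf("beam %s: energy '%s' not configured for machine %s",
                              b$beam_name, b$energy_label, b$machine_name))
    } else if (is.na(b$dose_rate) || !any(abs(ok - b$dose_rate) < 1e-6)) {
      msgs <- c(msgs, sprintf(
        "beam %s: dose rate %s MU/min not in allowed set {%s} for %s %s",
        b$beam_name, format(b$dose_rate), paste(ok, collapse = ", "),
        b$machine_name, b$energy_label))
    }
  }
  if (length(msgs)) check_result(id, "FLAG", msgs) else check_result(id, "PASS")
}

#' Check plan approval status, or completion of non-clinical courses
#'
#' With `scope = "clinical"`: a plan in a clinical course must be in one of
#' the configured required statuses. With `scope = "nonclinical"`: plans in
#' non-clinical courses must be `COMPLETED`.
#'
#' @param ctx A `plan_context`.
#' @param cfg A `run_config`.
#' @param scope `"clinical"` or `"nonclinical"`.
#' @return A `check_result`.
#' @export
check_plan_status <- function(ctx, cfg, scope = c("clinical", "nonclinical")) {
  scope <- match.arg(scope)
  id <- if (scope == "clinical") "plan_status" else "nonclinical_complete"
  if (ctx$course_intent == "UNKNOWN" || ctx$plan_status == "UNKNOWN") {
    return(.insufficient(id, "course intent / plan status not in sidecar"))
  }
  if (scope == "clinical") {
    if (ctx$course_intent != "CLINICAL") {
      return(check_result(id, "PASS", "not applicable: not a clinical course"))
    }
    req <- unlist(cfg_param(cfg, id, "required_status", "TREATMENT_APPROVED"))
    if (!ctx$plan_status %in% req) {
      return(check_result(id, "FLAG", sprintf(
        "plan status is %s; required: %s", ctx$plan_status,
        paste(req, collapse = " or "))))
    }
    check_result(id, "PASS")
  } else {
    if (ctx$course_intent != "NON_CLINICAL") {
      return(check_result(id, "PASS", "not applicable: not a non-clinical course"))
    }
    if (ctx$plan_status != "COMPLETED") {
      return(check_result(id, "FLAG", sprintf(
        "plan in non-clinical course %s has status %s (must be COMPLETED)",
        ctx$course_id, ctx$plan_status)))
    }
    check_result(id, "PASS")
  }
}

#' Check calculation settings, or the leaf motion calculator
#'
#' With `scope = "model_grid"`: the volume dose algorithm must equal the
#' configured name and the dose grid resolution must not exceed the default
#' (max-axis-pitch convention). With `scope = "lmc"`: IMRT plans must use the
#' configured leaf motion calculator.
#'
#' @param ctx A `plan_context`.
#' @param cfg A `run_config`.
#' @param scope `"model_grid"` or `"lmc"`.
#' @return A `check_result`.
#' @export
check_calc_settings <- function(ctx, cfg, scope = c("model_grid", "lmc")) {
  scope <- match.arg(scope)
  if (scope == "model_grid") {
    id <- "calc_settings"
    want <- cfg_param(cfg, id, "calc_model")
    max_grid <- cfg_param(cfg, id, "max_grid_mm", 2.5)
    msgs <- character(0)
    if (is.na(ctx$calc_model)) {
      return(.insufficient(id, "calculation model not in sidecar"))
    }
    if (!identical(ctx$calc_model, want)) {
      msgs <- c(msgs, sprintf("calculation model is '%s'; expected '%s'",
                              ctx$calc_model, want))
    }
    if (is.na(ctx$dose_grid_resolution)) {
      return(.insufficient(id, "dose grid resolution unknown (no RT Dose loaded)"))
    }
    if (ctx$dose_grid_resolution > max_grid + 1e-9) {
      msgs <- c(msgs, sprintf("dose grid %.2f mm coarser than default %.2f mm",
                              ctx$dose_grid_resolution, max_grid))
    }
    if (length(msgs)) check_result(id, "FLAG", msgs)
    else check_result(id, "PASS")
  } else {
    id <- "leaf_motion_calculator"
    has_imrt <- any(vapply(.treatment_beams(ctx),
                           function(b) b$delivery_kind == "IMRT", logical(1)))
    if (!has_imrt) {
      return(check_result(id, "PASS", "not applicable: no IMRT beams"))
    }
    if (is.na(ctx$leaf_motion_calculator)) {
      return(.insufficient(id, "leaf motion calculator not in sidecar"))
    }
    want <- cfg_param(cfg, id, "name")
    if (!identical(ctx$leaf_motion_calculator, want)) {
      return(check_result(id, "FLAG", sprintf(
        "leaf motion calculator is '%s'; expected '%s'",
        ctx$leaf_motion_calculator, want)))
    }
    check_result(id, "PASS")
  }
}

#' Check couch structures, or default couch position
#'
#' With `scope = "structures"`: the couch structures configured for the
#' beams' machine must be present with the configured density assignments.
#' With `scope = "position"`: the first control point's table-top position of
#' every treatment beam must lie within the configured per-machine window.
#'
#' @param ctx A `plan_context`.
#' @param cfg A `run_config`.
#' @param scope `"structures"` or `"position"`.
#' @return A `check_result`.
#' @export
check_couch <- function(ctx, cfg, scope = c("structures", "position")) {
  scope <- match.arg(scope)
  machines <- unique(stats::na.omit(vapply(.treatment_beams(ctx),
                                           `[[`, character(1), "machine_name")))
  if (scope == "structures") {
    id <- "couch_structures"
    req_map <- cfg_param(cfg, id, "required", list())
    if (!length(machines)) {
      return(.insufficient(id, "no treatment machine recorded"))
    }
    msgs <- character(0)
    have <- ctx$couch_structures
    have_names <- vapply(have, `[[`, character(1), "name")
    for (m in machines) {
      for (req in req_map[[m]] %||% list()) {
        k <- match(req$name, have_names)
        if (is.na(k)) {
          msgs <- c(msgs, sprintf("couch structure %s missing (machine %s)",
                                  req$name, m))
        } else {
          dens <- have[[k]]$density %||% NA_real_
          if (is.na(dens) || abs(dens - req$density) > 1e-6) {
            msgs <- c(msgs, sprintf(
              "couch structure %s density %s differs from required %s HU",
              req$name, format(dens), format(req$density)))
          }
        }
      }
    }
    if (length(msgs)) check_result(id, "FLAG", msgs)
    else check_result(id, "PASS")
  } else {
    id <- "couch_position"
    windows <- cfg_param(cfg, id, "windows", list())
    msgs <- character(0)
    for (b in .treatment_beams(ctx)) {
      win <- windows[[b$machine_name]]
      if (is.null(win)) {
        msgs <- c(msgs, sprintf("beam %s: no couch window configured for machine '%s'",
                                b$beam_name, b$machine_name))
        next
      }
      tt <- b$control_points[[1]]$table_top
      if (is.null(tt)) {
        return(.insufficient(id, sprintf("beam %s has no table-top position",
                                         b$beam_name)))
      }
      for (axis in c("vrt", "lng", "lat")) {
        rng <- unlist(win[[axis]])
        val <- unname(tt[axis])
        if (!is.null(rng) && !is.na(val) &&
            (val < rng[1] - 1e-9 || val > rng[2] + 1e-9)) {
          msgs <- c(msgs, sprintf(
            "beam %s table top %s = %.1f mm outside window [%.0f, %.0f]",
            b$beam_name, axis, val, rng[1], rng[2]))
        }
      }
    }
    if (length(msgs)) check_result(id, "FLAG", msgs)
    else check_result(id, "PASS")
  }
}

#' Check setup-field imager positions
#'
#' Every setup beam must have its imager at the configured position (within
#' tolerance). A plan with no setup fields at all flags, by policy.
#'
#' @param ctx A `plan_context`.
#' @param cfg A `run_config`.
#' @return A `check_result`.
#' @export
check_setup_fields <- function(ctx, cfg) {
  id <- "setup_imager_position"
  setup <- .setup_beams(ctx)
  if (!length(setup)) {
    return(check_result(id, "FLAG", "no setup fields found"))
  }
  expected <- cfg_param(cfg, id, "expected", list(vrt = -500, lng = 0, lat = 0))
  tol <- cfg_param(cfg, id, "tolerance_mm", 5)
  msgs <- character(0)
  for (b in setup) {
    if (is.null(b$imager_position)) {
      return(.insufficient(id, sprintf("imager position unknown for setup beam %s",
                                       b$beam_name)))
    }
    for (axis in c("vrt", "lng", "lat")) {
      want <- expected[[axis]]
      got <- unname(b$imager_position[axis])
      if (!is.null(want) && !is.na(got) && abs(got - want) > tol) {
        msgs <- c(msgs, sprintf(
          "setup beam %s imager %s = %.1f mm (expected %.1f +/- %.0f mm)",
          b$beam_name, axis, got, want, tol))
      }
    }
  }
  if (length(msgs)) check_result(id, "FLAG", msgs) else check_result(id, "PASS")
}

#' Check the number of control points per beam
#'
#' Static beams must have exactly 2; IMRT between 2 and `max_imrt_cp`; VMAT
#' between `min_vmat_cp` and `max_vmat_cp` (boundaries pass).
#'
#' @param ctx A `plan_context`.
#' @param cfg A `run_config`.
#' @return A `check_result`.
#' @export
check_control_points <- function(ctx, cfg) {
  id <- "control_point_count"
  max_imrt <- cfg_param(cfg, id, "max_imrt_cp", 400)
  min_vmat <- cfg_param(cfg, id, "min_vmat_cp", 10)
  max_vmat <- cfg_param(cfg, id, "max_vmat_cp", 500)
  msgs <- character(0)
  for (b in .treatment_beams(ctx)) {
    n <- length(b$control_points)
    bad <- switch(b$delivery_kind,
      STATIC = if (n != 2) sprintf("static beam %s has %d control points (expected 2)",
                                   b$beam_name, n),
      IMRT = if (n < 2 || n > max_imrt)
        sprintf("IMRT beam %s has %d control points (allowed 2..%d)",
                b$beam_name, n, max_imrt),
      VMAT = if (n < min_vmat || n > max_vmat)
        sprintf("VMAT beam %s has %d control points (allowed %d..%d)",
                b$beam_name, n, min_vmat, max_vmat))
    if (!is.null(bad)) msgs <- c(msgs, bad)
  }
  if (length(msgs)) check_result(id, "FLAG", msgs) else check_result(id, "PASS")
}

#' Check MLC deliverability for modulated beams
#'
#' For IMRT/VMAT beams, every leaf pair at every control point must either
#' have a gap of at least `min_gap_mm` or be fully closed parked outside the
#' X-jaw aperture; and the leaf speed each segment requires,
#' `|delta position| x dose_rate / (delta MU x 60)` mm/s, must not exceed
#' `max_leaf_speed_mm_s`.
#'
#' @param ctx A `plan_context`.
#' @param cfg A `run_config`.
#' @return A `check_result`.
#' @export
check_imrt_leaf_delivery <- function(ctx, cfg) {
  id <- "imrt_leaf_delivery"
  min_gap <- cfg_param(cfg, id, "min_gap_mm", 0.5)
  max_speed <- cfg_param(cfg, id, "max_leaf_speed_mm_s", 25)
  beams <- Filter(function(b) b$delivery_kind %in% c("IMRT", "VMAT"),
                  .treatment_beams(ctx))
  if (!length(beams)) {
    return(check_result(id, "PASS", "not applicable: no modulated beams"))
  }
  msgs <- character(0)
  for (b in beams) {
    cps <- b$control_points
    for (k in seq_along(cps)) {
      cp <- cps[[k]]
      if (is.null(cp$mlc)) next
      gap <- cp$mlc$b - cp$mlc$a
      jaws <- cp$jaw_positions
      x1 <- if (!is.null(jaws)) unname(jaws["x1"]) else -Inf
      x2 <- if (!is.null(jaws)) unname(jaws["x2"]) else Inf
      parked <- gap <= 1e-6 & (cp$mlc$b <= x1 | cp$mlc$a >= x2)
      viol <- which(gap < min_gap - 1e-9 & !parked)
      for (pair in viol) {
        msgs <- c(msgs, sprintf(
          "beam %s CP %d leaf pair %d gap %.2f mm below minimum %.2f mm",
          b$beam_name, cp$index, pair, gap[pair], min_gap))
      }
      if (k > 1 && !is.null(cps[[k - 1]]$mlc) && !is.na(b$meterset) &&
          !is.na(b$dose_rate)) {
        dmu <- (cp$cumulative_meterset_weight -
                  cps[[k - 1]]$cumulative_meterset_weight) * b$meterset
        if (dmu > 1e-9) {
          travel <- pmax(abs(cp$mlc$a - cps[[k - 1]]$mlc$a),
                         abs(cp$mlc$b - cps[[k - 1]]$mlc$b))
          speed <- travel * b$dose_rate / (dmu * 60)
          bad <- which(speed > max_speed + 1e-9)
          for (pair in bad) {
            msgs <- c(msgs, sprintf(
              "beam %s CP %d leaf pair %d requires %.1f mm/s (limit %.1f mm/s)",
              b$beam_name, cp$index, pair, speed[pair], max_speed))
          }
        }
      }
    }
  }
  if (length(msgs)) check_result(id, "FLAG", msgs) else check_result(id, "PASS")
}

#' Report the patient orientation
#'
#' @param ctx A `plan_context`.
#' @param cfg A `run_config` (no parameters).
#' @return A `check_result` with status `REPORT` carrying the orientation.
#' @export
report_patient_orientation <- function(ctx, cfg) {
  id <- "patient_orientation"
  if (is.na(ctx$patient_orientation)) {
    return(.insufficient(id, "patient orientation absent"))
  }
  check_result(id, "REPORT", sprintf("patient orientation: %s",
                                     ctx$patient_orientation))
}

#' Check and report tolerance tables
#'
#' Flags a non-clinical tolerance table (configured `forbidden_labels`, e.g.
#' "TEST") or a treatment beam without a label; otherwise reports the distinct
#' labels in use for manual inspection.
#'
#' @param ctx A `plan_context`.
#' @param cfg A `run_config`.
#' @return A `check_result`.
#' @export
check_tolerance_tables <- function(ctx, cfg) {
  id <- "tolerance_tables"
  forbidden <- unlist(cfg_param(cfg, id, "forbidden_labels", "TEST"))
  msgs <- character(0)
  labels <- character(0)
  for (b in .treatment_beams(ctx)) {
    lab <- b$tolerance_table_label
    if (is.na(lab) || !nzchar(lab)) {
      msgs <- c(msgs, sprintf("beam %s has no tolerance table", b$beam_name))
    } else if (lab %in% forbidden) {
      msgs <- c(msgs, sprintf("beam %s uses non-clinical tolerance table '%s'",
                              b$beam_name, lab))
    } else {
      labels <- c(labels, lab)
    }
  }
  if (length(msgs)) return(check_result(id, "FLAG", msgs))
  if (!length(labels)) {
    return(check_result(id, "PASS", "not applicable: no treatment beams"))
  }
  check_result(id, "REPORT", sprintf("tolerance table(s) in use: %s",
                                     paste(unique(labels), collapse = ", ")))
}

#' Report CT density overrides, or list unusual warnings
#'
#' With `scope = "overrides"`: report every structure with an assigned CT
#' density/HU override. With `scope = "warnings"`: report planning-system
#' warnings matching the configured "unusual" patterns. Nothing to report is
#' a PASS (empty-report convention).
#'
#' @param ctx A `plan_context`.
#' @param cfg A `run_config`.
#' @param scope `"overrides"` or `"warnings"`.
#' @return A `check_result`.
#' @export
report_overrides_and_warnings <- function(ctx, cfg,
                                          scope = c("overrides", "warnings")) {
  scope <- match.arg(scope)
  if (scope == "overrides") {
    id <- "density_overrides"
    if (!length(ctx$density_overrides)) return(check_result(id, "PASS"))
    msgs <- vapply(ctx$density_overrides, function(o) {
      sprintf("density override: %s = %s", o$structure, format(o$value))
    }, character(1))
    check_result(id, "REPORT", msgs)
  } else {
    id <- "unusual_warnings"
    patterns <- unlist(cfg_param(cfg, id, "patterns", character(0)))
    hits <- character(0)
    for (w in ctx$warnings) {
      if (any(vapply(patterns, function(p) grepl(p, w, ignore.case = TRUE),
                     logical(1)))) {
        hits <- c(hits, w)
      }
    }
    if (!length(hits)) return(check_result(id, "PASS"))
    check_result(id, "REPORT", sprintf("unusual warning: %s", hits))
  }
}
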