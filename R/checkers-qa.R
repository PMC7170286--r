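# The composite QA-plan checker: 10 constituent checks, flag if any one
# fails. Applicability gates: the EPID MU/control-point comparison applies
# only to single-fraction IMRT/VMAT plans at 6X or 15X; the MapCheck-required
# check only to single-fraction IMRT/VMAT plans at 6X-FFF.

.qa_sub <- function(name, status, msg) {
  list(name = name, status = status, msg = msg)
}

.qa_of_kind <- function(ctx, kind) {
  Filter(function(q) identical(q$qa_kind, kind), ctx$qa_plans)
}

#' Run the composite QA-plan checker
#'
#' Evaluates the 10 constituent verification-plan checks (QA course
#' membership, EPID naming convention, EPID reference-image SID, EPID
#' MU/control-point comparison against the clinical plan, MapCheck plan
#' presence for FFF, MapCheck gantry angles, tolerance tables and treatment
#' time for both kinds, and approval status for both kinds). The composite
#' status is FLAG if any constituent fails; the messages enumerate every
#' constituent's outcome.
#'
#' @param ctx A `plan_context`.
#' @param cfg A `run_config`.
#' @return A `check_result` whose `details$subchecks` carries per-constituent
#'   statuses.
#' @export
check_qa_plans <- function(ctx, cfg) {
  id <- "qa_plans"
  p <- function(key, default = NULL) cfg_param(cfg, id, key, default)
  epid <- .qa_of_kind(ctx, "EPID")
  mapcheck <- .qa_of_kind(ctx, "MAPCHECK")
  all_qa <- ctx$qa_plans
  subs <- list()
  add <- function(name, status, msg) {
    subs[[length(subs) + 1L]] <<- .qa_sub(name, status, msg)
  }
  na_msg <- "not applicable"

  # gates from the clinical plan
  tb <- .treatment_beams(ctx)
  modulated <- any(vapply(tb, function(b) b$delivery_kind %in% c("IMRT", "VMAT"),
                          logical(1)))
  energies <- unique(stats::na.omit(vapply(tb, `[[`, character(1),
                                           "energy_label")))
  one_fx <- !is.na(ctx$fractions) && ctx$fractions == 1
  epid_gate <- one_fx && modulated && any(energies %in% c("6X", "15X"))
  mapcheck_gate <- one_fx && modulated && any(energies == "6X-FFF")

  # 1. verification plan in QA course
  if (!length(all_qa)) {
    add("verification plan in QA course",
        if (epid_gate || mapcheck_gate) "FAIL" else "NA",
        if (epid_gate || mapcheck_gate) "no verification plan found" else na_msg)
  } else {
    bad <- Filter(function(q) !identical(q$course_intent, "QA"), all_qa)
    if (length(bad)) {
      add("verification plan in QA course", "FAIL",
          sprintf("QA plan %s is in course %s (intent %s), not a QA course",
                  bad[[1]]$qa_plan_id, bad[[1]]$course_id,
                  bad[[1]]$course_intent))
    } else add("verification plan in QA course", "OK", "ok")
  }

  # 2. EPID dosimetry plan naming convention
  if (!length(epid)) {
    add("EPID plan naming convention", "NA", na_msg)
  } else {
    rx <- p("epid_name_regex", ".*")
    bad <- Filter(function(q) !grepl(rx, q$qa_plan_id), epid)
    if (length(bad)) {
      add("EPID plan naming convention", "FAIL",
          sprintf("EPID plan name '%s' does not match %s",
                  bad[[1]]$qa_plan_id, rx))
    } else add("EPID plan naming convention", "OK", "ok")
  }

  # 3. EPID reference images at correct SID
  if (!length(epid)) {
    add("EPID reference image SID", "NA", na_msg)
  } else {
    want <- p("epid_sid_mm", 1000); tol <- p("sid_tolerance_mm", 1)
    bad <- Filter(function(q) is.na(q$reference_sid) ||
                    abs(q$reference_sid - want) > tol, epid)
    if (length(bad)) {
      add("EPID reference image SID", "FAIL",
          sprintf("EPID plan %s reference SID %s mm (expected %.0f +/- %.0f)",
                  bad[[1]]$qa_plan_id, format(bad[[1]]$reference_sid), want, tol))
    } else add("EPID reference image SID", "OK", "ok")
  }

  # 4. EPID MU / control point comparison against the clinical plan
  if (!epid_gate) {
    add("EPID MU/CP comparison", "NA", na_msg)
  } else if (!length(epid)) {
    add("EPID MU/CP comparison", "FAIL",
        "single-fraction IMRT/VMAT 6X/15X plan has no EPID verification plan")
  } else {
    mu_tol <- p("mu_tolerance", 0.1); w_tol <- p("weight_tolerance", 1e-4)
    msgs <- character(0)
    qa_beams <- .treatment_beams(list(beams = epid[[1]]$beams))
    qa_by_name <- stats::setNames(qa_beams,
                                  vapply(qa_beams, `[[`, character(1),
                                         "beam_name"))
    for (b in tb) {
      q <- qa_by_name[[b$beam_name]]
      if (is.null(q)) {
        msgs <- c(msgs, sprintf("no QA beam matches clinical beam %s",
                                b$beam_name))
        next
      }
      if (is.na(q$meterset) || abs(q$meterset - b$meterset) > mu_tol) {
        msgs <- c(msgs, sprintf("beam %s: QA MU %.2f vs clinical %.2f (tol %.2f)",
                                b$beam_name, q$meterset, b$meterset, mu_tol))
      }
      if (length(q$control_points) != length(b$control_points)) {
        msgs <- c(msgs, sprintf("beam %s: QA has %d control points vs clinical %d",
                                b$beam_name, length(q$control_points),
                                length(b$control_points)))
      } else {
        wq <- vapply(q$control_points, `[[`, numeric(1),
                     "cumulative_meterset_weight")
        wb <- vapply(b$control_points, `[[`, numeric(1),
                     "cumulative_meterset_weight")
        if (max(abs(wq - wb)) > w_tol) {
          msgs <- c(msgs, sprintf(
            "beam %s: cumulative meterset weights differ (max |d| = %.2g)",
            b$beam_name, max(abs(wq - wb))))
        }
      }
    }
    if (length(msgs)) add("EPID MU/CP comparison", "FAIL",
                          paste(msgs, collapse = "; "))
    else add("EPID MU/CP comparison", "OK", "ok")
  }

  # 5. MapCheck plan created for single-fraction FFF IMRT/VMAT
  if (!mapcheck_gate) {
    add("MapCheck plan created", "NA", na_msg)
  } else if (!length(mapcheck)) {
    add("MapCheck plan created", "FAIL",
        "single-fraction IMRT/VMAT 6X-FFF plan has no MapCheck verification plan")
  } else add("MapCheck plan created", "OK", "ok")

  # 6. MapCheck plans have all beams at gantry 0
  if (!length(mapcheck)) {
    add("MapCheck gantry angles", "NA", na_msg)
  } else {
    gtol <- p("gantry_tolerance_deg", 0.1)
    msgs <- character(0)
    for (q in mapcheck) {
      for (b in .treatment_beams(list(beams = q$beams))) {
        g <- vapply(b$control_points, `[[`, numeric(1), "gantry_angle")
        g <- pmin(g, 360 - g)  # distance from 0 across the seam
        if (any(g > gtol)) {
          msgs <- c(msgs, sprintf("MapCheck plan %s beam %s gantry %.1f deg != 0",
                                  q$qa_plan_id, b$beam_name, max(g)))
        }
      }
    }
    if (length(msgs)) add("MapCheck gantry angles", "FAIL",
                          paste(msgs, collapse = "; "))
    else add("MapCheck gantry angles", "OK", "ok")
  }

  # 7/8. tolerance tables and treatment time defined
  tol_time <- function(plans, label) {
    if (!length(plans)) return(add(label, "NA", na_msg))
    msgs <- character(0)
    for (q in plans) {
      if (is.na(q$tolerance_table_label) || !nzchar(q$tolerance_table_label)) {
        msgs <- c(msgs, sprintf("QA plan %s has no tolerance table", q$qa_plan_id))
      }
      if (!isTRUE(q$treatment_time_defined)) {
        msgs <- c(msgs, sprintf("QA plan %s has no treatment time defined",
                                q$qa_plan_id))
      }
    }
    if (length(msgs)) add(label, "FAIL", paste(msgs, collapse = "; "))
    else add(label, "OK", "ok")
  }
  tol_time(epid, "EPID tolerance table and time")
  tol_time(mapcheck, "MapCheck tolerance table and time")

  # 9/10. approval status
  status_ok <- function(plans, label) {
    if (!length(plans)) return(add(label, "NA", na_msg))
    req <- unlist(p("required_status", c("TREATMENT_APPROVED",
                                         "PLANNING_APPROVED")))
    bad <- Filter(function(q) !q$plan_status %in% req, plans)
    if (length(bad)) {
      add(label, "FAIL", sprintf("QA plan %s has status %s (required: %s)",
                                 bad[[1]]$qa_plan_id, bad[[1]]$plan_status,
                                 paste(req, collapse = " or ")))
    } else add(label, "OK", "ok")
  }
  status_ok(epid, "EPID plan status")
  status_ok(mapcheck, "MapCheck plan status")

  statuses <- vapply(subs, `[[`, character(1), "status")
  msgs <- vapply(subs, function(s) sprintf("%s: %s", s$name, s$msg),
                 character(1))
  status <- if (any(statuses == "FAIL")) "FLAG" else "PASS"
  check_result(id, status, msgs,
               details = list(subchecks = stats::setNames(as.list(statuses),
                 vapply(subs, `[[`, character(1), "name"))))
}
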