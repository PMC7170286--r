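# Checker semantics, exercised on in-memory contexts. Boundary convention
# throughout: a value exactly at tolerance passes.

cfg <- NULL
setup_cfg <- function() {
  if (is.null(cfg)) cfg <<- load_config()
  cfg
}

test_that("isocenter consistency respects the tolerance boundary", {
  cfg <- setup_cfg()
  expect_status(check_isocenter_consistency(make_ctx(), cfg), "PASS")
  shifted <- make_ctx(beams = list(
    make_beam("1", "AP"), make_beam("2", "PA", iso = c(1, 0, 0)),
    make_setup_beam()))
  res <- check_isocenter_consistency(shifted, cfg)
  expect_status(res, "FLAG")
  expect_match(res$messages, "beam PA", all = FALSE)
  at_tol <- make_ctx(beams = list(
    make_beam("1", "AP"), make_beam("2", "PA", iso = c(0.01, 0, 0)),
    make_setup_beam()))
  expect_status(check_isocenter_consistency(at_tol, cfg), "PASS")
})

test_that("naming conventions: pass, whitespace, empty", {
  cfg <- setup_cfg()
  ctx <- make_ctx()
  expect_status(check_naming_conventions(ctx, cfg, "course"), "PASS")
  expect_status(check_naming_conventions(ctx, cfg, "plan"), "PASS")
  expect_status(check_naming_conventions(ctx, cfg, "image_structure"), "PASS")
  ws <- make_ctx(plan_name = "PELV_AP ")
  res <- check_naming_conventions(ws, cfg, "plan")
  expect_status(res, "FLAG")
  expect_match(res$messages, "whitespace", all = FALSE)
  empty <- make_ctx(course_id = "")
  expect_status(check_naming_conventions(empty, cfg, "course"), "FLAG")
  # severity switch downgrades a rule to report
  p <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(checkers = list("plan_names"),
                        params = list(plan_names = list(severity = "report"))),
                   p)
  soft <- load_config(p)
  expect_status(check_naming_conventions(ws, soft, "plan"), "REPORT")
})

test_that("invalid characters are flagged with field and character", {
  cfg <- setup_cfg()
  expect_status(check_invalid_characters(make_ctx(), cfg), "PASS")
  res <- check_invalid_characters(make_ctx(plan_name = "PELV_APé"), cfg)
  expect_status(res, "FLAG")
  expect_match(res$messages, "plan_name", all = FALSE)
  expect_match(res$messages, "é", all = FALSE)
})

test_that("reference point limits: multiplier, consistency, contributions", {
  cfg <- setup_cfg()
  expect_status(check_reference_point_limits(make_ctx(), cfg), "PASS")
  over <- make_ctx(reference_points = list(
    new_reference_point("1", "PRESCRIPTION", 55, 2.2,
                        contributing_beam_ids = c("1", "2"))))
  res <- check_reference_point_limits(over, cfg)
  expect_status(res, "FLAG")
  expect_match(res$messages, "exceeds", all = FALSE)
  orphan <- make_ctx(reference_points = list(
    new_reference_point("1", "PRESCRIPTION", 50, 2,
                        contributing_beam_ids = "1")))
  res2 <- check_reference_point_limits(orphan, cfg)
  expect_status(res2, "FLAG")
  expect_match(res2$messages, "beam PA contributes to no reference point",
               all = FALSE)
  inconsistent <- make_ctx(reference_points = list(
    new_reference_point("1", "PRESCRIPTION", 50, 2.5,
                        contributing_beam_ids = c("1", "2"))))
  expect_status(check_reference_point_limits(inconsistent, cfg), "FLAG")
})

test_that("bolus linkage flags the unlinked beam; overrides are reported", {
  cfg <- setup_cfg()
  bolus <- list(list(name = "BOLUS_5MM", roi_number = 4L, hu = 0))
  all_linked <- make_ctx(beams = list(
    make_beam("1", "AP", bolus_ids = "BOLUS_5MM"),
    make_beam("2", "PA", bolus_ids = "BOLUS_5MM"),
    make_setup_beam()), bolus_structures = bolus)
  expect_status(check_bolus(all_linked, cfg, "linkage"), "PASS")
  partial <- make_ctx(beams = list(
    make_beam("1", "AP", bolus_ids = "BOLUS_5MM"),
    make_beam("2", "PA"),
    make_setup_beam()), bolus_structures = bolus)
  res <- check_bolus(partial, cfg, "linkage")
  expect_status(res, "FLAG")
  expect_match(res$messages, "beam PA", all = FALSE)
  hot <- make_ctx(bolus_structures = list(
    list(name = "BOLUS_5MM", roi_number = 4L, hu = 120)))
  res2 <- check_bolus(hot, cfg, "hu")
  expect_status(res2, "REPORT")
  expect_match(res2$messages, "\\+120 HU", all = FALSE)
  unknown <- make_ctx(bolus_structures = list(list(name = "B", hu = NULL)))
  expect_match(check_bolus(unknown, cfg, "hu")$messages, "not evaluable",
               all = FALSE)
})

test_that("DRR and overlay checks, including insufficient data", {
  cfg <- setup_cfg()
  expect_status(check_drr(make_ctx(), cfg, "created"), "PASS")
  expect_status(check_drr(make_ctx(), cfg, "overlay"), "PASS")
  no_drr <- make_ctx(beams = list(make_beam(), make_setup_beam(drr_present = FALSE)))
  res <- check_drr(no_drr, cfg, "created")
  expect_status(res, "FLAG")
  expect_match(res$messages, "SU_AP", all = FALSE)
  unknown <- make_ctx(beams = list(make_beam(drr_overlay_present = NA),
                                   make_setup_beam()))
  res2 <- check_drr(unknown, cfg, "overlay")
  expect_status(res2, "FLAG")
  expect_match(res2$messages, "insufficient data", all = FALSE)
})

test_that("dose rate checks the machine/energy table", {
  cfg <- setup_cfg()
  expect_status(check_dose_rate(make_ctx(), cfg), "PASS")
  bad <- make_ctx(beams = list(make_beam(dose_rate = 500), make_setup_beam()))
  expect_status(check_dose_rate(bad, cfg), "FLAG")
  alien <- make_ctx(beams = list(make_beam(machine = "LINAC_X"),
                                 make_setup_beam()))
  res <- check_dose_rate(alien, cfg)
  expect_status(res, "FLAG")
  expect_match(res$messages, "not in configuration", all = FALSE)
})

test_that("plan status and non-clinical completion", {
  cfg <- setup_cfg()
  expect_status(check_plan_status(make_ctx(), cfg, "clinical"), "PASS")
  expect_status(check_plan_status(make_ctx(plan_status = "PLANNING_APPROVED"),
                                  cfg, "clinical"), "FLAG")
  nc_open <- make_ctx(course_intent = "NON_CLINICAL",
                      plan_status = "UNAPPROVED")
  expect_status(check_plan_status(nc_open, cfg, "nonclinical"), "FLAG")
  nc_done <- make_ctx(course_intent = "NON_CLINICAL",
                      plan_status = "COMPLETED")
  expect_status(check_plan_status(nc_done, cfg, "nonclinical"), "PASS")
  # intent unknown (sidecar missing) cannot silently pass
  unknown <- make_ctx(course_intent = "UNKNOWN")
  expect_match(check_plan_status(unknown, cfg, "clinical")$messages,
               "insufficient data", all = FALSE)
})

test_that("calculation settings: model, grid and leaf motion calculator", {
  cfg <- setup_cfg()
  expect_status(check_calc_settings(make_ctx(), cfg, "model_grid"), "PASS")
  coarse <- make_ctx(dose_grid_resolution = 3.0)
  res <- check_calc_settings(coarse, cfg, "model_grid")
  expect_status(res, "FLAG")
  expect_match(res$messages, "3.00 mm coarser", all = FALSE)
  imrt <- make_ctx(beams = list(
    make_beam(delivery_kind = "IMRT",
              control_points = list(new_control_point(0, 0),
                                    new_control_point(1, 0.5),
                                    new_control_point(2, 1))),
    make_setup_beam()), leaf_motion_calculator = "LMC_OLD")
  expect_status(check_calc_settings(imrt, cfg, "lmc"), "FLAG")
  no_imrt <- make_ctx(leaf_motion_calculator = "LMC_OLD")
  expect_status(check_calc_settings(no_imrt, cfg, "lmc"), "PASS")
})

test_that("couch structures and couch position windows", {
  cfg <- setup_cfg()
  expect_status(check_couch(make_ctx(), cfg, "structures"), "PASS")
  expect_status(check_couch(make_ctx(), cfg, "position"), "PASS")
  missing <- make_ctx(couch_structures = list(
    list(name = "COUCH_SURFACE", density = -300)))
  res <- check_couch(missing, cfg, "structures")
  expect_status(res, "FLAG")
  expect_match(res$messages, "COUCH_INTERIOR missing", all = FALSE)
  off <- make_ctx(beams = list(
    make_beam(tt = c(vrt = -350, lng = 800, lat = 0)), make_setup_beam()))
  res2 <- check_couch(off, cfg, "position")
  expect_status(res2, "FLAG")
  expect_match(res2$messages, "-350.0 mm outside window \\[-300, -50\\]",
               all = FALSE)
})

test_that("setup-field imager positions, including the no-setup policy", {
  cfg <- setup_cfg()
  expect_status(check_setup_fields(make_ctx(), cfg), "PASS")
  off <- make_ctx(beams = list(
    make_beam(),
    make_setup_beam(imager_position = c(vrt = -500, lng = 20, lat = 0))))
  res <- check_setup_fields(off, cfg)
  expect_status(res, "FLAG")
  expect_match(res$messages, "lng", all = FALSE)
  none <- make_ctx(beams = list(make_beam()))
  expect_match(check_setup_fields(none, cfg)$messages,
               "no setup fields found", all = FALSE)
})

test_that("control point counts per delivery kind, boundaries pass", {
  cfg <- setup_cfg()
  expect_status(check_control_points(make_ctx(), cfg), "PASS")
  static3 <- make_ctx(beams = list(
    make_beam(control_points = list(new_control_point(0, 0),
                                    new_control_point(1, 0.5),
                                    new_control_point(2, 1))),
    make_setup_beam()))
  expect_status(check_control_points(static3, cfg), "FLAG")
  max_vmat <- cfg_param(cfg, "control_point_count", "max_vmat_cp")
  cps <- lapply(seq_len(max_vmat), function(k) {
    new_control_point(k - 1, (k - 1) / (max_vmat - 1),
                      gantry_angle = (k - 1) %% 360)
  })
  vmat <- make_ctx(beams = list(
    make_beam(delivery_kind = "VMAT", control_points = cps),
    make_setup_beam()))
  expect_status(check_control_points(vmat, cfg), "PASS")
})

test_that("leaf delivery: minimum gap and required leaf speed", {
  cfg <- setup_cfg()
  jaws <- c(x1 = -25, x2 = 25, y1 = -25, y2 = 25)
  mk_cp <- function(i, w, a, b) {
    new_control_point(i, w, jaw_positions = jaws,
                      mlc = list(a = a, b = b),
                      table_top = c(vrt = -150, lng = 800, lat = 0))
  }
  ok <- make_ctx(beams = list(
    make_beam(delivery_kind = "IMRT", control_points = list(
      mk_cp(0, 0, c(-10, -10), c(5, 5)),
      mk_cp(1, 0.5, c(-8, -8), c(6, 6)),
      mk_cp(2, 1, c(-6, -6), c(7, 7)))),
    make_setup_beam()))
  expect_status(check_imrt_leaf_delivery(ok, cfg), "PASS")
  narrow <- make_ctx(beams = list(
    make_beam(delivery_kind = "IMRT", control_points = list(
      mk_cp(0, 0, c(-10, -10), c(5, 5)),
      mk_cp(1, 0.5, c(-8, -0.1), c(6, 0.1)),
      mk_cp(2, 1, c(-6, -6), c(7, 7)))),
    make_setup_beam()))
  res <- check_imrt_leaf_delivery(narrow, cfg)
  expect_status(res, "FLAG")
  expect_match(res$messages, "CP 1 leaf pair 2 gap 0.20 mm", all = FALSE)
  # 30 mm over 0.5 MU at 600 MU/min: required speed 30*600/(0.5*60) = 600 mm/s
  # (hand-derived independently of the checker implementation)
  expect_equal(30 * 600 / (0.5 * 60), 600)
  fast <- make_ctx(beams = list(
    make_beam(delivery_kind = "IMRT", meterset = 100, dose_rate = 600,
              control_points = list(
      mk_cp(0, 0, c(-10, -10), c(5, 5)),
      mk_cp(1, 0.005, c(-10, 20), c(5, 35)),
      mk_cp(2, 1, c(-10, 20), c(5, 35)))),
    make_setup_beam()))
  res2 <- check_imrt_leaf_delivery(fast, cfg)
  expect_status(res2, "FLAG")
  expect_match(res2$messages, "600.0 mm/s", all = FALSE)
  # a pair fully closed behind the jaw is exempt from the gap rule
  parked <- make_ctx(beams = list(
    make_beam(delivery_kind = "IMRT", control_points = list(
      mk_cp(0, 0, c(-60, -10), c(-60, 5)),
      mk_cp(1, 1, c(-60, -8), c(-60, 6)))),
    make_setup_beam()))
  expect_status(check_imrt_leaf_delivery(parked, cfg), "PASS")
})

test_that("patient orientation is reported, or flagged when absent", {
  cfg <- setup_cfg()
  res <- report_patient_orientation(make_ctx(), cfg)
  expect_status(res, "REPORT")
  expect_match(res$messages, "HFS")
  hfp <- report_patient_orientation(make_ctx(patient_orientation = "HFP"), cfg)
  expect_match(hfp$messages, "HFP")
  absent <- report_patient_orientation(
    make_ctx(patient_orientation = NA_character_), cfg)
  expect_status(absent, "FLAG")
  expect_match(absent$messages, "insufficient data", all = FALSE)
})

test_that("tolerance tables: report clinical labels, flag forbidden/missing", {
  cfg <- setup_cfg()
  srs <- make_ctx(beams = list(make_beam(tolerance_table_label = "SRS"),
                               make_setup_beam()))
  res <- check_tolerance_tables(srs, cfg)
  expect_status(res, "REPORT")
  expect_match(res$messages, "SRS")
  test_tab <- make_ctx(beams = list(make_beam(tolerance_table_label = "TEST"),
                                    make_setup_beam()))
  expect_status(check_tolerance_tables(test_tab, cfg), "FLAG")
  missing <- make_ctx(beams = list(
    make_beam(tolerance_table_label = NA_character_), make_setup_beam()))
  expect_status(check_tolerance_tables(missing, cfg), "FLAG")
})

test_that("density overrides and unusual warnings are reported", {
  cfg <- setup_cfg()
  expect_status(report_overrides_and_warnings(make_ctx(), cfg, "overrides"),
                "PASS")
  lung <- make_ctx(density_overrides = list(
    list(structure = "LUNG_L", value = "0.3 g/cc")))
  res <- report_overrides_and_warnings(lung, cfg, "overrides")
  expect_status(res, "REPORT")
  expect_match(res$messages, "LUNG_L", all = FALSE)
  expect_status(report_overrides_and_warnings(make_ctx(), cfg, "warnings"),
                "PASS")
  warned <- make_ctx(warnings = "Dose was overridden by user at point P1")
  res2 <- report_overrides_and_warnings(warned, cfg, "warnings")
  expect_status(res2, "REPORT")
})

test_that("QA composite: clean plan passes with all 10 sub-messages", {
  cfg <- setup_cfg()
  ctx <- ctx_template("ONE_FX_VMAT_WITH_EPID_QA")
  res <- check_qa_plans(ctx, cfg)
  expect_status(res, "PASS")
  expect_length(res$messages, 10L)
  expect_length(res$details$subchecks, 10L)
})

test_that("QA composite: MU mismatch fails only the MU/CP sub-check", {
  cfg <- setup_cfg()
  ctx <- ctx_template("ONE_FX_VMAT_WITH_EPID_QA")
  qa <- ctx$qa_plans[[1]]
  qa$beams[[1]]$meterset <- qa$beams[[1]]$meterset + 5
  ctx$qa_plans[[1]] <- qa
  res <- check_qa_plans(ctx, cfg)
  expect_status(res, "FLAG")
  subs <- unlist(res$details$subchecks)
  expect_identical(unname(subs[["EPID MU/CP comparison"]]), "FAIL")
  expect_false(any(subs[names(subs) != "EPID MU/CP comparison"] == "FAIL"))
})

test_that("QA composite: missing MapCheck plan for single-fraction FFF flags", {
  cfg <- setup_cfg()
  ctx <- ctx_template("ONE_FX_FFF_WITH_MAPCHECK_QA")
  ctx$qa_plans <- list()
  res <- check_qa_plans(ctx, cfg)
  expect_status(res, "FLAG")
  expect_identical(unname(unlist(res$details$subchecks)[["MapCheck plan created"]]),
                   "FAIL")
})

test_that("QA composite: MapCheck beam off gantry zero flags", {
  cfg <- setup_cfg()
  ctx <- ctx_template("ONE_FX_FFF_WITH_MAPCHECK_QA")
  qa <- ctx$qa_plans[[1]]
  qa$beams[[1]]$control_points[[1]]$gantry_angle <- 30
  ctx$qa_plans[[1]] <- qa
  res <- check_qa_plans(ctx, cfg)
  expect_status(res, "FLAG")
  expect_identical(unname(unlist(res$details$subchecks)[["MapCheck gantry angles"]]),
                   "FAIL")
})
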