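# Loaders: RT Plan parsing, invariants, sidecar merge, dose-grid linkage,
# and deterministic assembly.

test_that("a static two-field plan loads with the expected shape", {
  ctx <- ctx_template("STATIC_2FIELD")
  tab <- tidy(ctx)
  expect_identical(nrow(tab), 4L)  # 2 treatment + 2 setup
  tx <- tab[tab$role == "TREATMENT", ]
  expect_identical(tx$n_control_points, c(2L, 2L))
  expect_identical(tx$delivery_kind, c("STATIC", "STATIC"))
  expect_identical(tx$energy, c("6X", "6X"))
  expect_equal(tx$meterset, c(100, 100))
  expect_identical(ctx$plan_id, "PELV_AP")
  expect_identical(ctx$fractions, 25L)
  expect_equal(ctx$prescription_dose, 50)
  expect_identical(ctx$patient_orientation, "HFS")
  # bolus ROI resolved to a structure name through the sidecar
  expect_identical(ctx$beams[[1]]$bolus_ids, "BOLUS_5MM")
  expect_identical(ctx$beams[[1]]$tolerance_table_label, "PHOTON")
})

test_that("decreasing cumulative meterset weights are rejected with location", {
  files <- gen_template("STATIC_2FIELD", seed = 3)
  bad_dir <- tempfile()
  dir.create(bad_dir)
  to <- file.path(bad_dir, "plan.dcm")
  file.copy(files$paths$plan, to)
  ds <- dcm_read(to)
  cps <- ds[["300A00B0"]]$value[[1]][["300A0111"]]$value
  cps[[1]][["300A0134"]] <- dcm_el("DS", 0.8)
  cps[[2]][["300A0134"]] <- dcm_el("DS", 0.3)
  ds[["300A00B0"]]$value[[1]][["300A0111"]]$value <- cps
  dcm_write(ds, to)
  expect_error(load_rtplan(to),
               "beam 1: cumulative meterset weight decreases at control point index 1")
})

test_that("MLC bank order violations are rejected", {
  cp_bad <- new_control_point(0, 0, mlc = list(a = c(5, 0), b = c(-5, 10)))
  beam <- make_beam(control_points = list(cp_bad, new_control_point(1, 1)))
  expect_error(validate_beam(beam), "MLC bank A above bank B")
})

test_that("an RT Plan without a beam sequence is a structural error", {
  ds <- list("00080016" = dcm_el("UI", SOP_RTPLAN),
             "00080018" = dcm_el("UI", "1.2.3"),
             "300A0002" = dcm_el("SH", "EMPTY"))
  p <- tempfile(fileext = ".dcm")
  dcm_write(ds, p)
  expect_error(load_rtplan(p), "BeamSequence \\(300A,00B0\\)")
})

test_that("sidecar merge updates status fields and resolves QA plans", {
  ctx <- ctx_template("ONE_FX_VMAT_WITH_EPID_QA")
  expect_identical(ctx$plan_status, "TREATMENT_APPROVED")
  expect_identical(ctx$course_id, "C1")
  expect_length(ctx$qa_plans, 1L)
  qa <- ctx$qa_plans[[1]]
  expect_identical(qa$qa_kind, "EPID")
  expect_identical(qa$linked_clinical_plan_id, ctx$plan_id)
  expect_identical(qa$tolerance_table_label, "PHOTON")
  expect_length(qa$beams, 2L)
})

test_that("sidecar mismatch and malformed sidecar are loader errors", {
  files <- gen_template("STATIC_2FIELD")
  ctx <- load_rtplan(files$paths$plan)
  wrong <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(plan_id = "OTHER"), wrong)
  expect_error(load_sidecar(wrong, ctx), "does not match")
  broken <- tempfile(fileext = ".yaml")
  writeLines(c("plan_id: [unclosed"), broken)
  expect_error(load_sidecar(broken, ctx), "malformed sidecar")
})

test_that("a sidecar omitting DRR keys degrades to FLAG, not silent pass", {
  files <- gen_template("STATIC_2FIELD", seed = 4)
  meta <- yaml::read_yaml(files$paths$sidecar)
  meta$drr <- NULL
  stripped <- tempfile(fileext = ".yaml")
  yaml::write_yaml(meta, stripped)
  ctx <- load_sidecar(stripped, load_rtplan(files$paths$plan))
  res <- check_drr(ctx, default_cfg(), "created")
  expect_status(res, "FLAG")
  expect_match(res$messages, "insufficient data", all = FALSE)
})

test_that("dose grid resolution uses the max-axis convention and checks linkage", {
  files <- gen_template("STATIC_2FIELD", seed = 5)
  ctx <- load_rtplan(files$paths$plan)
  ctx_iso <- load_dose_grid(files$paths$dose, ctx)
  expect_equal(ctx_iso$dose_grid_resolution, 2.5)
  aniso <- tempfile(fileext = ".dcm")
  ds <- dcm_read(files$paths$dose)
  ds[["00280030"]] <- dcm_el("DS", c(2.0, 2.0))
  ds[["3004000C"]] <- dcm_el("DS", c(0, 3, 6))
  dcm_write(ds, aniso)
  expect_equal(load_dose_grid(aniso, ctx)$dose_grid_resolution, 3.0)
  other <- tempfile(fileext = ".dcm")
  ds[["300C0002"]]$value[[1]][["00081155"]] <- dcm_el("UI", "1.2.3.999")
  dcm_write(ds, other)
  expect_error(load_dose_grid(other, ctx), "references plan")
})

test_that("assembly is deterministic", {
  files <- gen_template("IMRT_5FIELD", seed = 6)
  c1 <- assemble_synth(files)
  c2 <- assemble_synth(files)
  expect_identical(c1, c2)
})

test_that("soft beam invariants are recorded as warnings, not rejections", {
  static3 <- make_beam(control_points = list(
    new_control_point(0, 0), new_control_point(1, 0.5),
    new_control_point(2, 1)))
  ctx <- make_ctx(beams = list(static3, make_beam("2", "PA", gantry = 180),
                               make_setup_beam()))
  expect_match(ctx$warnings, "static beam has 3 control points", all = FALSE)
  no_tol <- make_beam(tolerance_table_label = NA_character_)
  expect_match(validate_beam(no_tol), "no tolerance table label", all = FALSE)
})

test_that("angles are normalised into [0, 360)", {
  cp <- new_control_point(0, 0, gantry_angle = 360, collimator_angle = -15)
  expect_identical(cp$gantry_angle, 0)
  expect_equal(cp$collimator_angle, 345)
})
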