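# The minimal DICOM layer: write/read round trips and an independent
# raw-tag-dump oracle (pydicom) over the same files.

test_that("datasets round-trip through write/read", {
  ds <- list(
    "00080016" = dcm_el("UI", SOP_RTPLAN),
    "00080018" = dcm_el("UI", "1.2.3.4.5"),
    "00080060" = dcm_el("CS", "RTPLAN"),
    "00100010" = dcm_el("PN", "SYNTHETIC^PHANTOM"),
    "300A0002" = dcm_el("SH", "PELV_AP"),
    "00281010" = dcm_el("US", c(16L, 4L)),
    "7FE00010" = dcm_el("OW", as.raw(0:7)),
    "300A00B0" = dcm_el("SQ", list(
      list("300A00C0" = dcm_el("IS", 1L),
           "300A0111" = dcm_el("SQ", list(
             list("300A0112" = dcm_el("IS", 0L),
                  "300A0134" = dcm_el("DS", 0.123456),
                  "300A011C" = dcm_el("DS", c(-50.5, 50.123456)))))),
      list("300A00C0" = dcm_el("IS", 2L))))
  )
  path <- tempfile(fileext = ".dcm")
  dcm_write(ds, path)
  rt <- dcm_read(path)
  expect_identical(dcm_get(rt, "300A0002"), "PELV_AP")
  expect_identical(dcm_get(rt, "00281010"), c(16L, 4L))
  expect_identical(dcm_get(rt, "7FE00010"), as.raw(0:7))
  b1 <- dcm_seq(rt, "300A00B0")[[1]]
  cp <- dcm_seq(b1, "300A0111")[[1]]
  expect_equal(dcm_get(cp, "300A0134"), 0.123456, tolerance = 1e-9)
  expect_equal(dcm_get(cp, "300A011C"), c(-50.5, 50.123456),
               tolerance = 1e-7)
  expect_identical(dcm_get(dcm_seq(rt, "300A00B0")[[2]], "300A00C0"), 2L)
})

test_that("writing is deterministic and non-DICOM input is rejected", {
  ds <- list("00080016" = dcm_el("UI", SOP_RTPLAN),
             "00080018" = dcm_el("UI", "1.2.3"),
             "300A0002" = dcm_el("SH", "X"))
  p1 <- tempfile(); p2 <- tempfile()
  dcm_write(ds, p1); dcm_write(ds, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  txt <- tempfile()
  writeLines("this is not dicom and is padded to be long enough......", txt)
  expect_error(dcm_read(txt), "not a DICOM")
})

test_that("loader agrees with an independent pydicom tag dump", {
  files <- gen_template("VMAT_2ARC", seed = 7)
  ctx <- ctx_template("VMAT_2ARC", seed = 7)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json, pydicom",
    "plan = pydicom.dcmread(sys.argv[1])",
    "dose = pydicom.dcmread(sys.argv[2])",
    "beams = plan.BeamSequence",
    "out = {",
    " 'n_beams': len(beams),",
    " 'n_cp': [len(b.ControlPointSequence) for b in beams],",
    " 'final_weights': [float(b.ControlPointSequence[-1].CumulativeMetersetWeight) for b in beams],",
    " 'gantry_first': [float(b.ControlPointSequence[0].GantryAngle) for b in beams],",
    " 'pixel_spacing': [float(v) for v in dose.PixelSpacing],",
    " 'offsets': [float(v) for v in dose.GridFrameOffsetVector],",
    "}",
    "print(json.dumps(out))"), script)
  res <- system2("python", c(script, files$paths$plan, files$paths$dose),
                 stdout = TRUE)
  dump <- jsonlite::fromJSON(res[length(res)])
  expect_identical(length(ctx$beams), as.integer(dump$n_beams))
  expect_identical(vapply(ctx$beams, function(b) length(b$control_points),
                          integer(1)),
                   as.integer(dump$n_cp))
  # arcs carry 60 control points each, 120 across the plan, weights ending at 1
  expect_identical(sum(dump$n_cp[1:2]), 120L)
  final_w <- vapply(ctx$beams, function(b) {
    b$control_points[[length(b$control_points)]]$cumulative_meterset_weight
  }, numeric(1))
  expect_equal(final_w, dump$final_weights, tolerance = 1e-9)
  gantry1 <- vapply(ctx$beams, function(b) b$control_points[[1]]$gantry_angle,
                    numeric(1))
  expect_equal(gantry1, dump$gantry_first, tolerance = 1e-9)
  expect_equal(ctx$dose_grid_resolution,
               max(c(dump$pixel_spacing, diff(dump$offsets))),
               tolerance = 1e-9)
})
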