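# Shared fixtures: quick in-memory contexts for checker unit tests, and a
# memoised cache of generated template file sets so the DICOM round trip is
# paid once per (template, seed) across the whole suite.

.template_cache <- new.env(parent = emptyenv())

gen_template <- function(template, seed = 1L) {
  key <- sprintf("%s_%d", template, seed)
  if (is.null(.template_cache[[key]])) {
    .template_cache[[key]] <- generate_clean_context(
      template, seed, out_dir = file.path(tempdir(), "plancheckr-fixtures", key))
  }
  .template_cache[[key]]
}

ctx_template <- function(template, seed = 1L) {
  key <- sprintf("ctx_%s_%d", template, seed)
  if (is.null(.template_cache[[key]])) {
    .template_cache[[key]] <- assemble_synth(gen_template(template, seed))
  }
  .template_cache[[key]]
}

default_cfg <- function() {
  if (is.null(.template_cache$cfg)) .template_cache$cfg <- load_config()
  .template_cache$cfg
}

# a minimal two-control-point treatment beam
make_beam <- function(beam_id = "1", beam_name = "AP", role = "TREATMENT",
                      delivery_kind = "STATIC", machine = "TB_1",
                      energy = "6X", dose_rate = 600, meterset = 100,
                      iso = c(0, 0, 0), gantry = 0,
                      tt = c(vrt = -150, lng = 800, lat = 0),
                      tolerance_table_label = "PHOTON",
                      control_points = NULL, bolus_ids = character(0),
                      drr_present = TRUE, drr_overlay_present = TRUE,
                      imager_position = NULL) {
  if (is.null(control_points)) {
    jaws <- c(x1 = -50, x2 = 50, y1 = -50, y2 = 50)
    control_points <- list(
      new_control_point(0, 0, gantry_angle = gantry, jaw_positions = jaws,
                        table_top = tt),
      new_control_point(1, 1, gantry_angle = gantry, jaw_positions = jaws,
                        table_top = tt))
  }
  new_beam(beam_id = beam_id, beam_name = beam_name, machine_name = machine,
           energy_label = energy, delivery_kind = delivery_kind, role = role,
           dose_rate = dose_rate,
           meterset = if (role == "SETUP") NA_real_ else meterset,
           isocenter = iso, control_points = control_points,
           bolus_ids = bolus_ids,
           tolerance_table_label = tolerance_table_label,
           drr_present = drr_present,
           drr_overlay_present = drr_overlay_present,
           imager_position = imager_position)
}

make_setup_beam <- function(beam_id = "9", beam_name = "SU_AP",
                            imager_position = c(vrt = -500, lng = 0, lat = 0),
                            ...) {
  make_beam(beam_id = beam_id, beam_name = beam_name, role = "SETUP",
            imager_position = imager_position, meterset = NA_real_, ...)
}

# a clean in-memory clinical context that passes the default battery
make_ctx <- function(beams = NULL, ...) {
  if (is.null(beams)) {
    beams <- list(make_beam("1", "AP", gantry = 0),
                  make_beam("2", "PA", gantry = 180),
                  make_setup_beam())
  }
  defaults <- list(
    plan_id = "PELV_AP", plan_name = "PELV_AP", course_id = "C1",
    plan_status = "TREATMENT_APPROVED", course_intent = "CLINICAL",
    fractions = 25L, prescription_dose = 50, beams = beams,
    reference_points = list(
      new_reference_point("1", "PRESCRIPTION", 50, 2,
                          contributing_beam_ids = c("1", "2"))),
    calc_model = "AAA_15.6", leaf_motion_calculator = "SmartLMC_15.6",
    dose_grid_resolution = 2.5, image_id = "CT_PELV_AP",
    structure_set_id = "SS_PELV_AP", patient_orientation = "HFS",
    couch_structures = list(list(name = "COUCH_SURFACE", density = -300),
                            list(name = "COUCH_INTERIOR", density = -1000)))
  override <- list(...)
  for (nm in names(override)) defaults[[nm]] <- override[[nm]]
  validate_plan_context(do.call(new_plan_context, defaults))
}

flags_of <- function(report) {
  t <- tidy(report)
  t$checker_id[t$status == "FLAG"]
}

expect_status <- function(result, status) {
  expect_s3_class(result, "check_result")
  expect_identical(result$status, status)
}
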