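# Synthetic DICOM-RT plan generator. Produces minimal-but-valid RT Plan /
# RT Dose / RT Structure Set files (required modules only, reduced 10-pair
# MLC) plus the sidecar, engineered so that every clean template passes the
# full default checker battery with zero flags. Checker inputs, not
# dosimetric truth: dose pixels are zeros.

#' The available clean plan templates
#' @format Character vector of template names.
#' @export
SYNTH_TEMPLATES <- c("STATIC_2FIELD", "IMRT_5FIELD", "VMAT_2ARC",
                     "ONE_FX_VMAT_WITH_EPID_QA", "ONE_FX_FFF_WITH_MAPCHECK_QA")

.synth_uid <- function(seed, k) {
  sprintf("1.2.826.0.1.3680043.9590.%d.%d", as.integer(seed), k)
}

.synth_iso <- c(10, -20, 55)
.synth_tt <- c(vrt = -150, lng = 800, lat = 0)
.N_LEAF_PAIRS <- 10L
.ACTIVE_PAIRS <- 3:8
.PARK_X <- -60  # closed park position, outside the x1 jaw

.mlc_banks <- function(a_active, b_active) {
  a <- rep(.PARK_X, .N_LEAF_PAIRS); b <- rep(.PARK_X, .N_LEAF_PAIRS)
  a[.ACTIVE_PAIRS] <- a_active; b[.ACTIVE_PAIRS] <- b_active
  list(a = a, b = b)
}

.cp_item <- function(index, weight, gantry = NULL, coll = NULL, couch = NULL,
                     jaws = NULL, mlc = NULL, tt = NULL, dose_rate = NULL,
                     energy = NULL, iso = NULL) {
  it <- list(
    "300A0112" = dcm_el("IS", as.integer(index)),
    "300A0134" = dcm_el("DS", weight)
  )
  if (!is.null(gantry)) it[["300A011E"]] <- dcm_el("DS", gantry)
  if (!is.null(coll)) it[["300A0120"]] <- dcm_el("DS", coll)
  if (!is.null(couch)) it[["300A0122"]] <- dcm_el("DS", couch)
  if (!is.null(dose_rate)) it[["300A0115"]] <- dcm_el("DS", dose_rate)
  if (!is.null(energy)) it[["300A0114"]] <- dcm_el("DS", energy)
  if (!is.null(iso)) it[["300A012C"]] <- dcm_el("DS", iso)
  if (!is.null(tt)) {
    it[["300A0128"]] <- dcm_el("DS", unname(tt["vrt"]))
    it[["300A0129"]] <- dcm_el("DS", unname(tt["lng"]))
    it[["300A012A"]] <- dcm_el("DS", unname(tt["lat"]))
  }
  ld <- list()
  if (!is.null(jaws)) {
    ld <- c(ld, list(
      list("300A00B8" = dcm_el("CS", "ASYMX"),
           "300A011C" = dcm_el("DS", unname(jaws[c("x1", "x2")]))),
      list("300A00B8" = dcm_el("CS", "ASYMY"),
           "300A011C" = dcm_el("DS", unname(jaws[c("y1", "y2")])))))
  }
  if (!is.null(mlc)) {
    ld <- c(ld, list(list("300A00B8" = dcm_el("CS", "MLCX"),
                          "300A011C" = dcm_el("DS", c(mlc$a, mlc$b)))))
  }
  if (length(ld)) it[["300A011A"]] <- dcm_el("SQ", ld)
  it
}

.beam_item <- function(num, name, beam_type, delivery_type, machine, cps,
                       fff = FALSE, tol_num = 1L, bolus_rois = integer(0)) {
  it <- list(
    "300A00C0" = dcm_el("IS", as.integer(num)),
    "300A00C2" = dcm_el("LO", name),
    "300A00C4" = dcm_el("CS", beam_type),
    "300A00CE" = dcm_el("CS", delivery_type),
    "300A00B2" = dcm_el("SH", machine),
    "300A0110" = dcm_el("IS", length(cps)),
    "300A0111" = dcm_el("SQ", cps),
    "300C00A0" = dcm_el("IS", as.integer(tol_num)),
    "300C006A" = dcm_el("IS", 1L)
  )
  if (fff) {
    it[["30020050"]] <- dcm_el("SQ", list(list(
      "30020051" = dcm_el("CS", "NON_STANDARD"),
      "30020052" = dcm_el("SH", "FFF"))))
  }
  if (length(bolus_rois)) {
    it[["300C00B0"]] <- dcm_el("SQ", lapply(bolus_rois, function(r) {
      list("30060084" = dcm_el("IS", as.integer(r)))
    }))
  }
  it
}

# one treatment beam description consumed by .rtplan_ds
.static_beam <- function(num, name, gantry, machine, energy = 6,
                         dose_rate = 600, meterset = 100,
                         bolus_rois = integer(0), fff = FALSE) {
  jaws <- c(x1 = -50, x2 = 50, y1 = -50, y2 = 50)
  mlc <- .mlc_banks(rep(-50, length(.ACTIVE_PAIRS)),
                    rep(50, length(.ACTIVE_PAIRS)))
  cps <- list(
    .cp_item(0L, 0, gantry = gantry, coll = 0, couch = 0, jaws = jaws,
             mlc = mlc, tt = .synth_tt, dose_rate = dose_rate,
             energy = energy, iso = .synth_iso),
    .cp_item(1L, 1))
  list(item = .beam_item(num, name, "STATIC", "TREATMENT", machine, cps,
                         fff = fff, bolus_rois = bolus_rois),
       num = num, meterset = meterset, dose_refs = c(1L, 2L))
}

.imrt_beam <- function(num, name, gantry, machine, n_cp = 20L, energy = 6,
                       dose_rate = 600, meterset = 100, fff = FALSE) {
  jaws <- c(x1 = -25, x2 = 25, y1 = -25, y2 = 25)
  k <- seq_len(n_cp) - 1L
  # sliding-window trajectory: slow leading/trailing banks, ample gap;
  # per-segment travel stays far below the configured speed limit
  a0 <- -20 + 25 * k / (n_cp - 1)
  gap <- 15 + 5 * sin(2 * pi * k / n_cp)
  jit <- stats::runif(n_cp, -0.2, 0.2)
  weights <- round(k / (n_cp - 1), 6)
  cps <- vector("list", n_cp)
  for (i in seq_len(n_cp)) {
    mlc <- .mlc_banks(rep(a0[i] + jit[i], length(.ACTIVE_PAIRS)),
                      rep(a0[i] + jit[i] + gap[i], length(.ACTIVE_PAIRS)))
    cps[[i]] <- if (i == 1) {
      .cp_item(0L, 0, gantry = gantry, coll = 10, couch = 0, jaws = jaws,
               mlc = mlc, tt = .synth_tt, dose_rate = dose_rate,
               energy = energy, iso = .synth_iso)
    } else {
      .cp_item(i - 1L, weights[i], mlc = mlc)
    }
  }
  list(item = .beam_item(num, name, "DYNAMIC", "TREATMENT", machine, cps,
                         fff = fff),
       num = num, meterset = meterset, dose_refs = c(1L, 2L))
}

.vmat_beam <- function(num, name, machine, n_cp = 60L, start = 181,
                       direction = 1, energy = 6, dose_rate = 600,
                       meterset = 200, fff = FALSE) {
  jaws <- c(x1 = -25, x2 = 25, y1 = -25, y2 = 25)
  k <- seq_len(n_cp) - 1L
  gantry <- (start + direction * 358 * k / (n_cp - 1)) %% 360
  a0 <- -15 + 5 * sin(2 * pi * k / n_cp)
  gap <- 12 + 4 * cos(2 * pi * k / n_cp)
  jit <- stats::runif(n_cp, -0.2, 0.2)
  weights <- round(k / (n_cp - 1), 6)
  cps <- vector("list", n_cp)
  for (i in seq_len(n_cp)) {
    mlc <- .mlc_banks(rep(a0[i] + jit[i], length(.ACTIVE_PAIRS)),
                      rep(a0[i] + jit[i] + gap[i], length(.ACTIVE_PAIRS)))
    cps[[i]] <- if (i == 1) {
      .cp_item(0L, 0, gantry = gantry[i], coll = 30, couch = 0, jaws = jaws,
               mlc = mlc, tt = .synth_tt, dose_rate = dose_rate,
               energy = energy, iso = .synth_iso)
    } else {
      .cp_item(i - 1L, weights[i], gantry = gantry[i], mlc = mlc)
    }
  }
  list(item = .beam_item(num, name, "DYNAMIC", "TREATMENT", machine, cps,
                         fff = fff),
       num = num, meterset = meterset, dose_refs = c(1L, 2L))
}

.setup_beam <- function(num, name, gantry, machine) {
  jaws <- c(x1 = -100, x2 = 100, y1 = -100, y2 = 100)
  cps <- list(
    .cp_item(0L, 0, gantry = gantry, coll = 0, couch = 0, jaws = jaws,
             tt = .synth_tt, energy = 6, iso = .synth_iso),
    .cp_item(1L, 0))
  list(item = .beam_item(num, name, "STATIC", "SETUP", machine, cps),
       num = num, meterset = NULL, dose_refs = integer(0))
}

.rtplan_ds <- function(plan_id, plan_name, beams, fractions, prescription,
                       check_dose, seed, uid_base, tol_label = "PHOTON") {
  ref_beams <- list()
  for (b in beams) {
    if (is.null(b$meterset)) next
    it <- list("300C0006" = dcm_el("IS", as.integer(b$num)),
               "300A0086" = dcm_el("DS", b$meterset))
    if (length(b$dose_refs)) {
      it[["300C0050"]] <- dcm_el("SQ", lapply(b$dose_refs, function(r) {
        list("300C0051" = dcm_el("IS", as.integer(r)))
      }))
    }
    ref_beams[[length(ref_beams) + 1L]] <- it
  }
  dose_refs <- list(
    list("300A0012" = dcm_el("IS", 1L),
         "300A0016" = dcm_el("LO", "PRESCRIPTION"),
         "300A0020" = dcm_el("CS", "COORDINATES"),
         "300A0026" = dcm_el("DS", prescription)),
    list("300A0012" = dcm_el("IS", 2L),
         "300A0016" = dcm_el("LO", "RP_CHECK"),
         "300A0020" = dcm_el("CS", "COORDINATES"),
         "300A0026" = dcm_el("DS", check_dose)))
  list(
    "00080005" = dcm_el("CS", "ISO_IR 192"),
    "00080016" = dcm_el("UI", SOP_RTPLAN),
    "00080018" = dcm_el("UI", uid_base),
    "00080020" = dcm_el("DA", "20240101"),
    "00080030" = dcm_el("TM", "000000"),
    "00080060" = dcm_el("CS", "RTPLAN"),
    "00100010" = dcm_el("PN", "SYNTHETIC^PHANTOM"),
    "00100020" = dcm_el("LO", sprintf("SYN%06d", seed %% 1000000L)),
    "300A0002" = dcm_el("SH", plan_id),
    "300A0003" = dcm_el("LO", plan_name),
    "300A000C" = dcm_el("CS", "PATIENT"),
    "300A0010" = dcm_el("SQ", dose_refs),
    "300A0040" = dcm_el("SQ", list(list(
      "300A0042" = dcm_el("IS", 1L),
      "300A0043" = dcm_el("SH", tol_label)))),
    "300A0070" = dcm_el("SQ", list(list(
      "300A0078" = dcm_el("IS", as.integer(fractions)),
      "300A0080" = dcm_el("IS", length(ref_beams)),
      "300C0004" = dcm_el("SQ", ref_beams)))),
    "300A0180" = dcm_el("SQ", list(list(
      "300A0182" = dcm_el("IS", 1L),
      "00185100" = dcm_el("CS", "HFS")))),
    "300A00B0" = dcm_el("SQ", lapply(beams, `[[`, "item"))
  )
}

.rtdose_ds <- function(plan_uid, uid, pitch = c(2.5, 2.5, 2.5)) {
  n_frames <- 3L
  offsets <- (seq_len(n_frames) - 1L) * pitch[3]
  list(
    "00080016" = dcm_el("UI", SOP_RTDOSE),
    "00080018" = dcm_el("UI", uid),
    "00080060" = dcm_el("CS", "RTDOSE"),
    "00280002" = dcm_el("US", 1L),
    "00280008" = dcm_el("IS", n_frames),
    "00280010" = dcm_el("US", 4L),
    "00280011" = dcm_el("US", 4L),
    "00280030" = dcm_el("DS", pitch[1:2]),
    "00280100" = dcm_el("US", 16L),
    "00280101" = dcm_el("US", 16L),
    "00280102" = dcm_el("US", 15L),
    "00280103" = dcm_el("US", 0L),
    "30040002" = dcm_el("CS", "GY"),
    "30040004" = dcm_el("CS", "PHYSICAL"),
    "3004000C" = dcm_el("DS", offsets),
    "3004000E" = dcm_el("DS", 1e-5),
    "300C0002" = dcm_el("SQ", list(list(
      "00081150" = dcm_el("UI", SOP_RTPLAN),
      "00081155" = dcm_el("UI", plan_uid)))),
    "7FE00010" = dcm_el("OW", raw(4L * 4L * n_frames * 2L))
  )
}

.rtstruct_ds <- function(uid, rois) {
  list(
    "00080016" = dcm_el("UI", SOP_RTSTRUCT),
    "00080018" = dcm_el("UI", uid),
    "00080060" = dcm_el("CS", "RTSTRUCT"),
    "30060020" = dcm_el("SQ", lapply(seq_along(rois), function(k) {
      list("30060022" = dcm_el("IS", k),
           "30060026" = dcm_el("LO", rois[k]))
    }))
  )
}

.template_spec <- function(template) {
  switch(template,
    STATIC_2FIELD = list(
      plan_id = "PELV_AP", plan_name = "PELV_AP", fractions = 25L,
      prescription = 50, check_dose = 49, energy_label = "6X",
      bolus = TRUE, qa = NULL),
    IMRT_5FIELD = list(
      plan_id = "PROS_IMRT", plan_name = "PROS_IMRT", fractions = 28L,
      prescription = 70, check_dose = 69, energy_label = "6X",
      bolus = FALSE, qa = NULL),
    VMAT_2ARC = list(
      plan_id = "PELV_VMAT", plan_name = "PELV_VMAT", fractions = 25L,
      prescription = 45, check_dose = 44.5, energy_label = "6X",
      bolus = FALSE, qa = NULL),
    ONE_FX_VMAT_WITH_EPID_QA = list(
      plan_id = "SPINE_SBRT", plan_name = "SPINE_SBRT", fractions = 1L,
      prescription = 8, check_dose = 7.9, energy_label = "6X",
      bolus = FALSE, qa = "EPID"),
    ONE_FX_FFF_WITH_MAPCHECK_QA = list(
      plan_id = "LUNG_SBRT", plan_name = "LUNG_SBRT", fractions = 1L,
      prescription = 18, check_dose = 17.8, energy_label = "6X-FFF",
      bolus = FALSE, qa = "MAPCHECK"),
    stop("unknown template '", template, "'", call. = FALSE))
}

#' Generate a clean synthetic plan file set
#'
#' Writes an RT Plan, RT Dose, RT Structure Set and sidecar (plus a QA-plan
#' RT Plan file for the QA templates) into `out_dir`. The outputs are
#' deterministic: the same template and seed yield byte-identical files.
#' Assembling and checking them under the default configuration yields zero
#' flags — this is the module's defining contract.
#'
#' @param template One of `r paste(SYNTH_TEMPLATES, collapse = ", ")`.
#' @param seed Integer seed driving UIDs and the (bounded) MLC jitter.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with `paths` (named: plan, dose, struct, sidecar,
#'   and qa_plan where applicable), `template` and `seed`.
#' @export
generate_clean_context <- function(template = SYNTH_TEMPLATES, seed = 1L,
                                   out_dir = tempfile("synth")) {
  template <- match.arg(template)
  spec <- .template_spec(template)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))
  machine <- "TB_1"
  fff <- identical(spec$energy_label, "6X-FFF")

  beams <- switch(template,
    STATIC_2FIELD = list(
      .static_beam(1L, "AP", 0, machine, bolus_rois = 4L),
      .static_beam(2L, "PA", 180, machine, bolus_rois = 4L)),
    IMRT_5FIELD = lapply(1:5, function(k) {
      .imrt_beam(k, sprintf("IMRT_%d", k), gantry = (k - 1) * 72, machine)
    }),
    VMAT_2ARC = list(
      .vmat_beam(1L, "ARC_CW", machine, start = 181, direction = 1),
      .vmat_beam(2L, "ARC_CCW", machine, start = 179, direction = -1)),
    ONE_FX_VMAT_WITH_EPID_QA = list(
      .vmat_beam(1L, "ARC_CW", machine, n_cp = 30L, start = 181,
                 direction = 1, meterset = 800),
      .vmat_beam(2L, "ARC_CCW", machine, n_cp = 30L, start = 179,
                 direction = -1, meterset = 800)),
    ONE_FX_FFF_WITH_MAPCHECK_QA = lapply(1:3, function(k) {
      .imrt_beam(k, sprintf("IMRT_%d", k), gantry = (k - 1) * 120, machine,
                 dose_rate = 800, meterset = 600, fff = TRUE)
    })
  )
  n_tx <- length(beams)
  beams <- c(beams, list(
    .setup_beam(n_tx + 1L, "SU_AP", 0, machine),
    .setup_beam(n_tx + 2L, "SU_LAT", 270, machine)))

  plan_uid <- .synth_uid(seed, 1L)
  plan_ds <- .rtplan_ds(spec$plan_id, spec$plan_name, beams, spec$fractions,
                        spec$prescription, spec$check_dose, seed, plan_uid)
  paths <- list(plan = file.path(out_dir, "plan.dcm"),
                dose = file.path(out_dir, "dose.dcm"),
                struct = file.path(out_dir, "struct.dcm"),
                sidecar = file.path(out_dir, "sidecar.yaml"))
  dcm_write(plan_ds, paths$plan)
  dcm_write(.rtdose_ds(plan_uid, .synth_uid(seed, 2L)), paths$dose)
  rois <- c("PTV", "COUCH_SURFACE", "COUCH_INTERIOR", "BOLUS_5MM")
  dcm_write(.rtstruct_ds(.synth_uid(seed, 3L), rois), paths$struct)

  beam_names <- vapply(beams, function(b) b$item[["300A00C2"]]$value,
                       character(1))
  drr <- stats::setNames(
    rep(list(list(present = TRUE, overlay = TRUE)), length(beam_names)),
    beam_names)
  sidecar <- list(
    plan_id = spec$plan_id,
    course_id = "C1",
    course_intent = "CLINICAL",
    plan_status = "TREATMENT_APPROVED",
    image_id = sprintf("CT_%s", spec$plan_id),
    structure_set_id = sprintf("SS_%s", spec$plan_id),
    calc_model = "AAA_15.6",
    leaf_motion_calculator = "SmartLMC_15.6",
    drr = drr,
    imager_positions = list(
      SU_AP = list(vrt = -500, lng = 0, lat = 0),
      SU_LAT = list(vrt = -500, lng = 0, lat = 0)),
    couch_structures = list(
      list(name = "COUCH_SURFACE", density = -300),
      list(name = "COUCH_INTERIOR", density = -1000)),
    density_overrides = list(),
    bolus_structures = if (spec$bolus) {
      list(list(name = "BOLUS_5MM", roi_number = 4L, hu = 0))
    } else list(),
    warnings = list()
  )

  if (!is.null(spec$qa)) {
    qa_id <- sprintf("QA_%s", spec$plan_id)
    qa_beams <- lapply(beams[seq_len(n_tx)], function(b) b)
    if (identical(spec$qa, "MAPCHECK")) {
      # MapCheck verification: all beams delivered at gantry 0
      qa_beams <- lapply(qa_beams, function(b) {
        cp1 <- b$item[["300A0111"]]$value[[1]]
        cp1[["300A011E"]] <- dcm_el("DS", 0)
        b$item[["300A0111"]]$value[[1]] <- cp1
        for (k in seq_along(b$item[["300A0111"]]$value)[-1]) {
          b$item[["300A0111"]]$value[[k]][["300A011E"]] <- NULL
        }
        b
      })
    }
    qa_uid <- .synth_uid(seed, 4L)
    qa_ds <- .rtplan_ds(qa_id, qa_id, qa_beams, 1L, spec$prescription,
                        spec$check_dose, seed, qa_uid)
    paths$qa_plan <- file.path(out_dir, "qa_plan.dcm")
    dcm_write(qa_ds, paths$qa_plan)
    sidecar$qa_plans <- list(list(
      qa_plan_id = qa_id,
      plan_file = "qa_plan.dcm",
      qa_kind = spec$qa,
      course_id = "QA1",
      course_intent = "QA",
      plan_status = "TREATMENT_APPROVED",
      reference_sid = 1000,
      treatment_time_defined = TRUE,
      linked_clinical_plan_id = spec$plan_id))
  }

  yaml::write_yaml(sidecar, paths$sidecar)
  invisible(structure(list(paths = paths, template = template,
                           seed = as.integer(seed)),
                      class = "synth_plan_files"))
}

#' Assemble the context from a generated file set
#'
#' @param files A `synth_plan_files` object from [generate_clean_context()]
#'   or [inject_defect()].
#' @return A validated `plan_context`.
#' @export
assemble_synth <- function(files) {
  assemble_context(files$paths$plan, dose_path = files$paths$dose,
                   struct_path = files$paths$struct,
                   sidecar_path = files$paths$sidecar)
}
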