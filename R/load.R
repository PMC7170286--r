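# Loaders: DICOM RT Plan / RT Dose / RT Structure Set plus the sidecar file
# carrying planning-system fields that DICOM exports do not contain.

.beam_ld_positions <- function(cp_ds) {
  out <- list(jaws = NULL, mlc = NULL)
  for (item in dcm_seq(cp_ds, "300A011A")) {
    kind <- dcm_get(item, "300A00B8")
    pos <- dcm_get(item, "300A011C")
    if (kind %in% c("ASYMX", "X")) {
      out$jaws <- c(out$jaws, c(x1 = pos[1], x2 = pos[2]))
    } else if (kind %in% c("ASYMY", "Y")) {
      out$jaws <- c(out$jaws, c(y1 = pos[1], y2 = pos[2]))
    } else if (kind %in% c("MLCX", "MLCY")) {
      n <- length(pos) / 2L
      out$mlc <- list(a = pos[seq_len(n)], b = pos[n + seq_len(n)])
    }
  }
  out
}

.load_beam <- function(beam_ds, meterset_info, tol_labels, setup_name_regex) {
  beam_num <- dcm_get(beam_ds, "300A00C0")
  beam_name <- dcm_get(beam_ds, "300A00C2", default = as.character(beam_num))
  beam_type <- dcm_get(beam_ds, "300A00C4", default = "STATIC")
  delivery_type <- dcm_get(beam_ds, "300A00CE", default = "TREATMENT")
  machine <- dcm_get(beam_ds, "300A00B2", default = NA_character_)

  role <- if (identical(delivery_type, "SETUP") ||
              grepl(setup_name_regex, beam_name)) "SETUP" else "TREATMENT"

  # fluence mode (FFF)
  fff <- FALSE
  for (fm in dcm_seq(beam_ds, "30020050")) {
    if (identical(dcm_get(fm, "30020051"), "NON_STANDARD") &&
        identical(dcm_get(fm, "30020052"), "FFF")) fff <- TRUE
  }

  cp_items <- dcm_seq(beam_ds, "300A0111")
  if (!length(cp_items)) {
    stop(sprintf("beam %s: RT Plan beam has no control points", beam_name),
         call. = FALSE)
  }

  # first CP carries machine state; later CPs delta-encode (carry forward)
  gantry <- NA_real_; coll <- NA_real_; couch <- NA_real_
  jaws <- NULL; mlc <- NULL; tt <- NULL
  dose_rate <- NA_real_; energy <- NA_real_; iso <- c(NA_real_, NA, NA)
  cps <- vector("list", length(cp_items))
  gantry_angles <- numeric(length(cp_items))
  for (k in seq_along(cp_items)) {
    it <- cp_items[[k]]
    gantry <- dcm_get(it, "300A011E", default = gantry)
    coll <- dcm_get(it, "300A0120", default = coll)
    couch <- dcm_get(it, "300A0122", default = couch)
    dose_rate <- dcm_get(it, "300A0115", default = dose_rate)
    energy <- dcm_get(it, "300A0114", default = energy)
    iso_k <- dcm_get(it, "300A012C")
    if (!is.null(iso_k)) iso <- iso_k
    ld <- .beam_ld_positions(it)
    if (!is.null(ld$jaws)) jaws <- ld$jaws
    if (!is.null(ld$mlc)) mlc <- ld$mlc
    vrt <- dcm_get(it, "300A0128")
    lng <- dcm_get(it, "300A0129")
    lat <- dcm_get(it, "300A012A")
    if (!is.null(vrt) || !is.null(lng) || !is.null(lat)) {
      tt <- c(vrt = vrt %||% unname(tt["vrt"]),
              lng = lng %||% unname(tt["lng"]),
              lat = lat %||% unname(tt["lat"]))
    }
    gantry_angles[k] <- if (is.na(gantry)) 0 else gantry
    cps[[k]] <- new_control_point(
      index = dcm_get(it, "300A0112", default = k - 1L),
      cumulative_meterset_weight = dcm_get(it, "300A0134", default = NA_real_),
      gantry_angle = if (is.na(gantry)) 0 else gantry,
      collimator_angle = if (is.na(coll)) 0 else coll,
      couch_angle = if (is.na(couch)) 0 else couch,
      jaw_positions = jaws, mlc = mlc, table_top = tt)
  }

  delivery_kind <- if (identical(beam_type, "DYNAMIC")) {
    span <- diff(range(.arc_unwrap(gantry_angles)))
    if (span > 1) "VMAT" else "IMRT"
  } else "STATIC"

  energy_label <- if (is.na(energy)) NA_character_ else {
    paste0(sub("\\.0*$", "", format(energy, trim = TRUE)), "X",
           if (fff) "-FFF" else "")
  }

  tol_num <- dcm_get(beam_ds, "300C00A0")
  tol_label <- if (!is.null(tol_num) && !is.null(tol_labels[[as.character(tol_num)]])) {
    tol_labels[[as.character(tol_num)]]
  } else NA_character_

  info <- meterset_info[[as.character(beam_num)]]
  bolus_rois <- vapply(dcm_seq(beam_ds, "300C00B0"),
                       function(it) dcm_get(it, "30060084"), integer(1))

  beam <- new_beam(
    beam_id = as.character(beam_num), beam_name = beam_name,
    machine_name = machine, energy_label = energy_label,
    delivery_kind = delivery_kind, role = role,
    dose_rate = dose_rate,
    meterset = if (is.null(info)) NA_real_ else info$meterset,
    isocenter = iso, control_points = cps,
    bolus_ids = as.character(bolus_rois),  # resolved to names later
    tolerance_table_label = tol_label)
  attr(beam, "dose_ref_numbers") <- if (is.null(info)) integer(0) else info$dose_refs
  beam
}

# unwrap gantry angles across the 0/360 seam so arc spans measure correctly
.arc_unwrap <- function(a) {
  if (length(a) < 2) return(a)
  out <- a
  for (k in 2:length(a)) {
    d <- a[k] - a[k - 1]
    if (d > 180) d <- d - 360
    if (d < -180) d <- d + 360
    out[k] <- out[k - 1] + d
  }
  out
}

#' Load a DICOM RT Plan into a partial plan context
#'
#' Populates beams, control points, isocenters, tolerance-table labels, bolus
#' references, reference points and fractionation from the RT Plan file.
#' Fields that DICOM exports do not carry (course, approval status, DRR and
#' imager metadata, calculation models, QA linkage) are left absent pending
#' [load_sidecar()].
#'
#' @param path Path to a DICOM RT Plan file.
#' @param setup_name_regex Beams whose delivery type does not mark them as
#'   setup are still classified `SETUP` when their name matches this regex.
#' @return A partial `plan_context` (attribute `"complete"` is `FALSE`).
#' @export
load_rtplan <- function(path, setup_name_regex = "^(SU|SETUP)") {
  ds <- dcm_read(path)
  sop_class <- dcm_get(ds, "00080016")
  if (!identical(sop_class, SOP_RTPLAN)) {
    stop("not an RT Plan object (SOP class ", sop_class %||% "missing", "): ",
         path, call. = FALSE)
  }
  beam_items <- dcm_seq(ds, "300A00B0")
  if (!length(beam_items)) {
    stop("RT Plan is missing BeamSequence (300A,00B0): ", path, call. = FALSE)
  }

  tol_labels <- list()
  for (tt in dcm_seq(ds, "300A0040")) {
    tol_labels[[as.character(dcm_get(tt, "300A0042"))]] <- dcm_get(tt, "300A0043")
  }

  fractions <- NA_integer_
  meterset_info <- list()
  fg <- dcm_seq(ds, "300A0070")
  if (length(fg)) {
    fractions <- dcm_get(fg[[1]], "300A0078", default = NA_integer_)
    for (rb in dcm_seq(fg[[1]], "300C0004")) {
      num <- dcm_get(rb, "300C0006")
      refs <- vapply(dcm_seq(rb, "300C0050"),
                     function(it) dcm_get(it, "300C0051"), integer(1))
      meterset_info[[as.character(num)]] <-
        list(meterset = dcm_get(rb, "300A0086", default = NA_real_),
             dose_refs = refs)
    }
  }

  beams <- lapply(beam_items, .load_beam, meterset_info = meterset_info,
                  tol_labels = tol_labels, setup_name_regex = setup_name_regex)

  # reference points from the dose reference sequence; contributions come from
  # the fraction-group referenced-beam items
  ref_points <- list()
  prescription <- NA_real_
  for (dr in dcm_seq(ds, "300A0010")) {
    num <- dcm_get(dr, "300A0012")
    total <- dcm_get(dr, "300A0026", default = NA_real_)
    contrib <- character(0)
    for (beam in beams) {
      if (num %in% attr(beam, "dose_ref_numbers")) {
        contrib <- c(contrib, beam$beam_id)
      }
    }
    per_fx <- if (!is.na(total) && !is.na(fractions)) total / fractions else NA_real_
    ref_points[[length(ref_points) + 1L]] <- new_reference_point(
      ref_id = as.character(num),
      name = dcm_get(dr, "300A0016", default = as.character(num)),
      total_dose = total, dose_per_fraction = per_fx,
      contributing_beam_ids = contrib)
    # the first (primary) dose reference carries the prescription
    if (is.na(prescription)) prescription <- total
  }

  orientation <- NA_character_
  ps <- dcm_seq(ds, "300A0180")
  if (length(ps)) orientation <- dcm_get(ps[[1]], "00185100", default = NA_character_)

  ctx <- new_plan_context(
    plan_id = dcm_get(ds, "300A0002", default = NA_character_),
    plan_name = dcm_get(ds, "300A0003",
                        default = dcm_get(ds, "300A0002", default = NA_character_)),
    fractions = fractions, prescription_dose = prescription,
    beams = beams, reference_points = ref_points,
    patient_orientation = orientation,
    sop_instance_uid = dcm_get(ds, "00080018", default = NA_character_))
  ctx <- validate_plan_context(ctx)
  attr(ctx, "complete") <- FALSE
  ctx
}

#' Merge a sidecar metadata file into a plan context
#'
#' The sidecar (a single UTF-8 YAML document; see the schema shipped in
#' `inst/extdata/sidecar_schema.md`) carries planning-system database fields
#' that DICOM exports do not: course name and intent, plan approval status,
#' image/structure-set display names, DRR presence and overlay status per
#' beam, calculation model names, imager positions for setup fields, couch and
#' bolus structure summaries, planning warnings and QA-plan linkage. Absent
#' optional keys stay "unknown" and cause the dependent checkers to FLAG with
#' an "insufficient data" message rather than pass silently.
#'
#' @param path Path to the sidecar file.
#' @param ctx Partial `plan_context` from [load_rtplan()].
#' @return The merged, validated `plan_context`.
#' @export
load_sidecar <- function(path, ctx) {
  meta <- tryCatch(yaml::read_yaml(path),
                   error = function(e) stop("malformed sidecar ", path, ": ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(meta$plan_id)) {
    stop("sidecar ", path, ": missing required key 'plan_id'", call. = FALSE)
  }
  if (!identical(meta$plan_id, ctx$plan_id)) {
    stop(sprintf("sidecar plan_id '%s' does not match RT Plan '%s'",
                 meta$plan_id, ctx$plan_id), call. = FALSE)
  }
  if (!is.null(meta$course_id)) ctx$course_id <- meta$course_id
  if (!is.null(meta$plan_status)) {
    if (!meta$plan_status %in% PLAN_STATUSES) {
      stop("sidecar ", path, ": unknown plan_status '", meta$plan_status, "'",
           call. = FALSE)
    }
    ctx$plan_status <- meta$plan_status
  }
  if (!is.null(meta$course_intent)) {
    if (!meta$course_intent %in% COURSE_INTENTS) {
      stop("sidecar ", path, ": unknown course_intent '", meta$course_intent,
           "'", call. = FALSE)
    }
    ctx$course_intent <- meta$course_intent
  }
  for (key in c("image_id", "structure_set_id", "calc_model",
                "leaf_motion_calculator")) {
    if (!is.null(meta[[key]])) ctx[[key]] <- meta[[key]]
  }
  if (!is.null(meta$warnings)) ctx$warnings <- c(ctx$warnings,
                                                 unlist(meta$warnings))
  if (!is.null(meta$couch_structures)) ctx$couch_structures <- meta$couch_structures
  if (!is.null(meta$density_overrides)) ctx$density_overrides <- meta$density_overrides
  if (!is.null(meta$bolus_structures)) ctx$bolus_structures <- meta$bolus_structures

  # per-beam DRR and imager metadata, keyed by beam name
  for (k in seq_along(ctx$beams)) {
    b <- ctx$beams[[k]]
    drr <- meta$drr[[b$beam_name]]
    if (!is.null(drr)) {
      if (!is.null(drr$present)) b$drr_present <- isTRUE(drr$present)
      if (!is.null(drr$overlay)) b$drr_overlay_present <- isTRUE(drr$overlay)
    }
    imp <- meta$imager_positions[[b$beam_name]]
    if (!is.null(imp)) {
      b$imager_position <- c(vrt = imp$vrt %||% NA_real_,
                             lng = imp$lng %||% NA_real_,
                             lat = imp$lat %||% NA_real_)
    }
    ctx$beams[[k]] <- b
  }

  # bolus references: map ROI numbers to names via bolus_structures
  roi_map <- list()
  for (bs in ctx$bolus_structures) {
    if (!is.null(bs$roi_number)) roi_map[[as.character(bs$roi_number)]] <- bs$name
  }
  for (k in seq_along(ctx$beams)) {
    ids <- ctx$beams[[k]]$bolus_ids
    ctx$beams[[k]]$bolus_ids <- vapply(ids, function(id) {
      roi_map[[id]] %||% id
    }, character(1), USE.NAMES = FALSE)
  }

  # QA plans: each entry may point at its own RT Plan file (relative paths are
  # resolved against the sidecar's directory)
  qa_plans <- list()
  for (q in meta$qa_plans %||% list()) {
    qa_beams <- list()
    qa_id <- q$qa_plan_id %||% NA_character_
    qa_tol <- q$tolerance_table_label %||% NA_character_
    if (!is.null(q$plan_file)) {
      qa_path <- if (file.exists(q$plan_file)) q$plan_file else
        file.path(dirname(path), q$plan_file)
      qa_ctx <- load_rtplan(qa_path)
      qa_beams <- qa_ctx$beams
      if (is.na(qa_id)) qa_id <- qa_ctx$plan_id
      if (is.na(qa_tol) && length(qa_beams)) {
        qa_tol <- qa_beams[[1]]$tolerance_table_label
      }
    }
    link <- q$linked_clinical_plan_id %||% NA_character_
    if (!is.na(link) && !identical(link, ctx$plan_id)) {
      stop(sprintf("sidecar QA plan %s links to unknown clinical plan '%s'",
                   qa_id, link), call. = FALSE)
    }
    qa_plans[[length(qa_plans) + 1L]] <- new_qa_plan_context(
      qa_plan_id = qa_id, qa_kind = q$qa_kind %||% "EPID",
      course_id = q$course_id %||% NA_character_,
      course_intent = q$course_intent %||% "UNKNOWN",
      plan_status = q$plan_status %||% "UNKNOWN",
      beams = qa_beams,
      reference_sid = q$reference_sid %||% NA_real_,
      linked_clinical_plan_id = link,
      tolerance_table_label = qa_tol,
      treatment_time_defined = q$treatment_time_defined %||% NA)
  }
  ctx$qa_plans <- qa_plans

  ctx <- validate_plan_context(ctx)
  attr(ctx, "complete") <- TRUE
  ctx
}

#' Load the dose-grid resolution from a DICOM RT Dose file
#'
#' The resolution recorded is the maximum voxel pitch across the three axes
#' (a conservative convention: any axis coarser than policy violates policy).
#'
#' @param path Path to a DICOM RT Dose file.
#' @param ctx `plan_context` the dose file must reference.
#' @return `ctx` with `dose_grid_resolution` set (mm).
#' @export
load_dose_grid <- function(path, ctx) {
  ds <- dcm_read(path)
  if (!identical(dcm_get(ds, "00080016"), SOP_RTDOSE)) {
    stop("not an RT Dose object: ", path, call. = FALSE)
  }
  ref <- dcm_seq(ds, "300C0002")
  ref_uid <- if (length(ref)) dcm_get(ref[[1]], "00081155") else NULL
  if (is.null(ref_uid) || !identical(ref_uid, ctx$sop_instance_uid)) {
    stop(sprintf("RT Dose %s references plan '%s', not '%s'", path,
                 ref_uid %||% "<none>", ctx$sop_instance_uid), call. = FALSE)
  }
  pitch <- dcm_get(ds, "00280030", default = numeric(0))  # row, col spacing
  offsets <- dcm_get(ds, "3004000C", default = numeric(0))
  if (length(offsets) > 1) pitch <- c(pitch, max(diff(offsets)))
  if (!length(pitch)) {
    stop("RT Dose ", path, " carries no grid spacing information", call. = FALSE)
  }
  ctx$dose_grid_resolution <- max(pitch)
  ctx
}

#' Load structure names from a DICOM RT Structure Set
#'
#' Records the ROI-number-to-name map (used to resolve bolus references) and
#' the list of couch structures (names matching `couch_regex`) when the
#' sidecar did not already provide them.
#'
#' @param path Path to a DICOM RT Structure Set file.
#' @param ctx `plan_context`.
#' @param couch_regex Regex identifying couch structures by name.
#' @return `ctx` with `couch_structures`/`bolus_structures` supplemented.
#' @export
load_struct <- function(path, ctx, couch_regex = "^COUCH") {
  ds <- dcm_read(path)
  if (!identical(dcm_get(ds, "00080016"), SOP_RTSTRUCT)) {
    stop("not an RT Structure Set object: ", path, call. = FALSE)
  }
  rois <- dcm_seq(ds, "30060020")
  names_by_num <- list()
  for (r in rois) {
    names_by_num[[as.character(dcm_get(r, "30060022"))]] <- dcm_get(r, "30060026")
  }
  if (!length(ctx$couch_structures)) {
    couch <- Filter(function(nm) grepl(couch_regex, nm), unlist(names_by_num))
    ctx$couch_structures <- lapply(unname(couch),
                                   function(nm) list(name = nm, density = NA_real_))
  }
  attr(ctx, "roi_names") <- names_by_num
  # resolve numeric bolus references not already resolved by the sidecar
  for (k in seq_along(ctx$beams)) {
    ids <- ctx$beams[[k]]$bolus_ids
    ctx$beams[[k]]$bolus_ids <- vapply(ids, function(id) {
      names_by_num[[id]] %||% id
    }, character(1), USE.NAMES = FALSE)
  }
  ctx
}

#' Assemble a complete plan context from its files
#'
#' Composition of [load_rtplan()], [load_struct()], [load_dose_grid()] and
#' [load_sidecar()]; runs all type invariants. Errors from the individual
#' loaders carry the offending file path.
#'
#' @param plan_path DICOM RT Plan (required).
#' @param dose_path DICOM RT Dose (optional; needed by the grid-size checker).
#' @param struct_path DICOM RT Structure Set (optional).
#' @param sidecar_path Sidecar metadata file (required for the full checker
#'   battery; without it the status/DRR/QA checkers flag "insufficient data").
#' @return A validated `plan_context`.
#' @export
assemble_context <- function(plan_path, dose_path = NULL, struct_path = NULL,
                             sidecar_path = NULL) {
  ctx <- load_rtplan(plan_path)
  if (!is.null(struct_path)) ctx <- load_struct(struct_path, ctx)
  if (!is.null(dose_path)) ctx <- load_dose_grid(dose_path, ctx)
  if (!is.null(sidecar_path)) ctx <- load_sidecar(sidecar_path, ctx)
  validate_plan_context(ctx)
}
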