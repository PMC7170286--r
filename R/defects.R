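# Named, seeded defect injection. Each defect is a targeted mutation of one
# clean synthetic file set, mapped to the checker expected to flag it; the
# catalog mirrors the recurring error classes an initial chart check guards
# against (status of non-clinical courses, DRR overlays, bolus and couch
# coordinates, imager positions, reference-point contributions, grid size,
# naming conventions, tolerance tables) plus one defect per remaining
# pass/flag checker.

# -- small mutation helpers on parsed DICOM datasets --------------------------

.mut_plan <- function(files, f) {
  ds <- dcm_read(files$paths$plan)
  ds <- f(ds)
  dcm_write(ds, files$paths$plan)
}
.mut_qa_plan <- function(files, f) {
  ds <- dcm_read(files$paths$qa_plan)
  ds <- f(ds)
  dcm_write(ds, files$paths$qa_plan)
}
.mut_dose <- function(files, f) {
  ds <- dcm_read(files$paths$dose)
  ds <- f(ds)
  dcm_write(ds, files$paths$dose)
}
.mut_sidecar <- function(files, f) {
  meta <- yaml::read_yaml(files$paths$sidecar)
  meta <- f(meta)
  yaml::write_yaml(meta, files$paths$sidecar)
}

# set an element deep inside beam b / control point k of an RT Plan dataset
.set_cp_el <- function(ds, beam, cp, tag, el) {
  ds[["300A00B0"]]$value[[beam]][["300A0111"]]$value[[cp]][[tag]] <- el
  ds
}
.get_cp <- function(ds, beam, cp) {
  ds[["300A00B0"]]$value[[beam]][["300A0111"]]$value[[cp]]
}
.set_mlc <- function(ds, beam, cp, mlc_vals) {
  items <- .get_cp(ds, beam, cp)[["300A011A"]]$value
  for (k in seq_along(items)) {
    if (identical(items[[k]][["300A00B8"]]$value, "MLCX")) {
      items[[k]][["300A011C"]] <- dcm_el("DS", mlc_vals)
    }
  }
  ds[["300A00B0"]]$value[[beam]][["300A0111"]]$value[[cp]][["300A011A"]]$value <- items
  ds
}
.get_mlc <- function(ds, beam, cp) {
  for (it in .get_cp(ds, beam, cp)[["300A011A"]]$value) {
    if (identical(it[["300A00B8"]]$value, "MLCX")) return(it[["300A011C"]]$value)
  }
  NULL
}

#' The defect catalog
#'
#' @return A tibble with one row per injectable defect: `defect_id`, the
#'   `template` it applies to, the `expected_checker` that must flag it, and
#'   a description of the mutation.
#' @export
defect_catalog <- function() {
  tibble::tibble(
    defect_id = names(.defect_mutations()),
    template = vapply(.defect_mutations(), `[[`, character(1), "template"),
    expected_checker = vapply(.defect_mutations(), `[[`, character(1),
                              "expected_checker"),
    description = vapply(.defect_mutations(), `[[`, character(1),
                         "description")
  )
}

.defect_cache <- new.env(parent = emptyenv())

.defect_mutations <- function() {
  if (!is.null(.defect_cache$defs)) return(.defect_cache$defs)
  d <- function(template, expected_checker, description, mutate) {
    list(template = template, expected_checker = expected_checker,
         description = description, mutate = mutate)
  }
  defs <- list(
    isocenter_shift = d("STATIC_2FIELD", "isocenter_consistency",
      "beam 2 isocenter shifted 1 mm in x",
      function(files) .mut_plan(files, function(ds) {
        iso <- .get_cp(ds, 2, 1)[["300A012C"]]$value
        iso[1] <- iso[1] + 1
        .set_cp_el(ds, 2, 1, "300A012C", dcm_el("DS", iso))
      })),
    tolerance_test_label = d("STATIC_2FIELD", "tolerance_tables",
      "tolerance table label set to TEST",
      function(files) .mut_plan(files, function(ds) {
        ds[["300A0040"]]$value[[1]][["300A0043"]] <- dcm_el("SH", "TEST")
        ds
      })),
    drr_missing = d("STATIC_2FIELD", "drr_created",
      "setup field SU_AP has no DRR",
      function(files) .mut_sidecar(files, function(m) {
        m$drr$SU_AP$present <- FALSE; m
      })),
    drr_overlay_missing = d("STATIC_2FIELD", "drr_overlay",
      "treatment field AP DRR lacks the overlay",
      function(files) .mut_sidecar(files, function(m) {
        m$drr$AP$overlay <- FALSE; m
      })),
    image_name_bad = d("STATIC_2FIELD", "image_structure_names",
      "planning image display name violates the convention",
      function(files) .mut_sidecar(files, function(m) {
        m$image_id <- "ct pelvis final"; m
      })),
    course_name_bad = d("STATIC_2FIELD", "course_names",
      "course id violates the course naming convention",
      function(files) .mut_sidecar(files, function(m) {
        m$course_id <- "COURSE ONE"; m
      })),
    plan_name_bad = d("STATIC_2FIELD", "plan_names",
      "plan name violates the naming convention (lower case)",
      function(files) .mut_plan(files, function(ds) {
        ds[["300A0003"]] <- dcm_el("LO", "Pelv_Ap")
        ds
      })),
    invalid_character = d("STATIC_2FIELD", "invalid_characters",
      "plan id contains a non-whitelisted character",
      function(files) {
        .mut_plan(files, function(ds) {
          ds[["300A0002"]] <- dcm_el("SH", "PELV#AP"); ds
        })
        .mut_sidecar(files, function(m) { m$plan_id <- "PELV#AP"; m })
      }),
    refpoint_over_limit = d("STATIC_2FIELD", "reference_point_limits",
      "secondary reference point raised to 110% of prescription",
      function(files) .mut_plan(files, function(ds) {
        presc <- ds[["300A0010"]]$value[[1]][["300A0026"]]$value
        ds[["300A0010"]]$value[[2]][["300A0026"]] <- dcm_el("DS", 1.10 * presc)
        ds
      })),
    refpoint_no_contribution = d("STATIC_2FIELD", "reference_point_limits",
      "beam 2 contributes to no reference point",
      function(files) .mut_plan(files, function(ds) {
        rb <- ds[["300A0070"]]$value[[1]][["300C0004"]]$value
        rb[[2]][["300C0050"]] <- NULL
        ds[["300A0070"]]$value[[1]][["300C0004"]]$value <- rb
        ds
      })),
    bolus_unlinked = d("STATIC_2FIELD", "bolus_linkage",
      "bolus detached from beam 2",
      function(files) .mut_plan(files, function(ds) {
        ds[["300A00B0"]]$value[[2]][["300C00B0"]] <- NULL
        ds
      })),
    dose_rate_invalid = d("STATIC_2FIELD", "dose_rate",
      "beam 1 dose rate set to a value outside the machine table",
      function(files) .mut_plan(files, function(ds) {
        .set_cp_el(ds, 1, 1, "300A0115", dcm_el("DS", 500))
      })),
    plan_unapproved = d("STATIC_2FIELD", "plan_status",
      "clinical plan left at planning approval",
      function(files) .mut_sidecar(files, function(m) {
        m$plan_status <- "PLANNING_APPROVED"; m
      })),
    nonclinical_not_complete = d("STATIC_2FIELD", "nonclinical_complete",
      "non-clinical course whose plan is not completed",
      function(files) .mut_sidecar(files, function(m) {
        m$course_intent <- "NON_CLINICAL"; m
      })),
    grid_too_coarse = d("STATIC_2FIELD", "calc_settings",
      "dose grid slice pitch coarsened to 3.5 mm",
      function(files) .mut_dose(files, function(ds) {
        ds[["3004000C"]] <- dcm_el("DS", c(0, 3.5, 7))
        ds
      })),
    wrong_calc_model = d("STATIC_2FIELD", "calc_settings",
      "volume dose algorithm differs from the configured default",
      function(files) .mut_sidecar(files, function(m) {
        m$calc_model <- "AAA_13.6"; m
      })),
    couch_structure_missing = d("STATIC_2FIELD", "couch_structures",
      "couch interior structure not inserted",
      function(files) .mut_sidecar(files, function(m) {
        m$couch_structures <- m$couch_structures[1]; m
      })),
    couch_vertical_out = d("STATIC_2FIELD", "couch_position",
      "table-top vertical 50 mm outside the machine window",
      function(files) .mut_plan(files, function(ds) {
        .set_cp_el(ds, 1, 1, "300A0128", dcm_el("DS", -350))
      })),
    imager_position_off = d("STATIC_2FIELD", "setup_imager_position",
      "setup-field imager longitudinal off by 20 mm",
      function(files) .mut_sidecar(files, function(m) {
        m$imager_positions$SU_AP$lng <- 20; m
      })),
    setup_fields_removed = d("STATIC_2FIELD", "setup_imager_position",
      "plan exported without setup fields",
      function(files) .mut_plan(files, function(ds) {
        beams <- ds[["300A00B0"]]$value
        keep <- vapply(beams, function(b) {
          !identical(b[["300A00CE"]]$value, "SETUP")
        }, logical(1))
        ds[["300A00B0"]]$value <- beams[keep]
        ds
      })),
    static_extra_cp = d("STATIC_2FIELD", "control_point_count",
      "static beam exported with a third control point",
      function(files) .mut_plan(files, function(ds) {
        cps <- ds[["300A00B0"]]$value[[1]][["300A0111"]]$value
        extra <- list("300A0112" = dcm_el("IS", 2L),
                      "300A0134" = dcm_el("DS", 1))
        ds[["300A00B0"]]$value[[1]][["300A0111"]]$value <- c(cps, list(extra))
        ds[["300A00B0"]]$value[[1]][["300A0110"]] <- dcm_el("IS", 3L)
        ds
      })),
    leaf_gap_violation = d("IMRT_5FIELD", "imrt_leaf_delivery",
      "one in-field leaf pair narrowed to a 0.2 mm gap",
      function(files) .mut_plan(files, function(ds) {
        mlc <- .get_mlc(ds, 1, 5)
        n <- length(mlc) / 2
        mlc[5] <- -0.1; mlc[n + 5] <- 0.1
        .set_mlc(ds, 1, 5, mlc)
      })),
    leaf_speed_violation = d("IMRT_5FIELD", "imrt_leaf_delivery",
      "one leaf asked to travel 30 mm within a single small segment",
      function(files) .mut_plan(files, function(ds) {
        mlc <- .get_mlc(ds, 1, 5)
        n <- length(mlc) / 2
        mlc[n + 4] <- mlc[n + 4] + 30
        .set_mlc(ds, 1, 5, mlc)
      })),
    wrong_lmc = d("IMRT_5FIELD", "leaf_motion_calculator",
      "leaf motion calculator differs from the configured default",
      function(files) .mut_sidecar(files, function(m) {
        m$leaf_motion_calculator <- "LMC_OLD"; m
      })),
    qa_mu_mismatch = d("ONE_FX_VMAT_WITH_EPID_QA", "qa_plans",
      "EPID verification beam meterset differs by 5 MU",
      function(files) .mut_qa_plan(files, function(ds) {
        rb <- ds[["300A0070"]]$value[[1]][["300C0004"]]$value
        rb[[1]][["300A0086"]] <- dcm_el("DS",
                                        rb[[1]][["300A0086"]]$value + 5)
        ds[["300A0070"]]$value[[1]][["300C0004"]]$value <- rb
        ds
      })),
    qa_wrong_course = d("ONE_FX_VMAT_WITH_EPID_QA", "qa_plans",
      "verification plan filed outside a QA course",
      function(files) .mut_sidecar(files, function(m) {
        m$qa_plans[[1]]$course_intent <- "CLINICAL"
        m$qa_plans[[1]]$course_id <- "C1"
        m
      })),
    epid_sid_wrong = d("ONE_FX_VMAT_WITH_EPID_QA", "qa_plans",
      "EPID reference images acquired at the wrong SID",
      function(files) .mut_sidecar(files, function(m) {
        m$qa_plans[[1]]$reference_sid <- 1200; m
      })),
    qa_status_wrong = d("ONE_FX_VMAT_WITH_EPID_QA", "qa_plans",
      "EPID verification plan left unapproved",
      function(files) .mut_sidecar(files, function(m) {
        m$qa_plans[[1]]$plan_status <- "UNAPPROVED"; m
      })),
    mapcheck_gantry_nonzero = d("ONE_FX_FFF_WITH_MAPCHECK_QA", "qa_plans",
      "MapCheck verification beam left at gantry 30",
      function(files) .mut_qa_plan(files, function(ds) {
        .set_cp_el(ds, 1, 1, "300A011E", dcm_el("DS", 30))
      })),
    mapcheck_missing = d("ONE_FX_FFF_WITH_MAPCHECK_QA", "qa_plans",
      "single-fraction FFF plan without a MapCheck verification plan",
      function(files) .mut_sidecar(files, function(m) {
        m$qa_plans <- NULL; m
      }))
  )
  .defect_cache$defs <- defs
  defs
}

#' Inject a named defect into a clean synthetic file set
#'
#' Copies the file set into `out_dir` and applies the defect's mutation;
#' exactly the intended fields are altered and the plan stays loadable.
#'
#' @param files A `synth_plan_files` object (its template must match the
#'   defect's).
#' @param defect_id A row of [defect_catalog()].
#' @param out_dir Directory for the mutated copy.
#' @return A `synth_plan_files` object pointing at the mutated copy, with a
#'   `defect_id` field.
#' @export
inject_defect <- function(files, defect_id, out_dir = tempfile("defect")) {
  defs <- .defect_mutations()
  def <- defs[[defect_id]]
  if (is.null(def)) stop("unknown defect '", defect_id, "'", call. = FALSE)
  if (!identical(def$template, files$template)) {
    stop(sprintf("defect %s applies to template %s, not %s", defect_id,
                 def$template, files$template), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  new_paths <- lapply(files$paths, function(p) {
    to <- file.path(out_dir, basename(p))
    file.copy(p, to, overwrite = TRUE)
    to
  })
  mutated <- structure(list(paths = new_paths, template = files$template,
                            seed = files$seed, defect_id = defect_id),
                       class = "synth_plan_files")
  def$mutate(mutated)
  mutated
}

#' Sensitivity/specificity of the checker battery over the defect corpus
#'
#' For every defect in the catalog and every seed, generates the clean
#' template, injects the defect, reassembles and re-checks, and records
#' whether the mapped checker flagged (sensitivity) and which other checkers
#' changed status. Clean templates are run once per seed to measure plan-level
#' specificity (a clean plan must produce zero flags).
#'
#' @param defect_ids Defects to evaluate (default: the whole catalog).
#' @param seeds Integer vector of generator seeds.
#' @param cfg A `run_config`.
#' @param templates Templates for the clean-specificity runs.
#' @return A `detection_matrix`: list with `by_defect` (per-defect sensitivity
#'   and off-target flag counts) and `clean` (per-template specificity).
#' @export
evaluate_detection <- function(defect_ids = defect_catalog()$defect_id,
                               seeds = 1:5, cfg = load_config(),
                               templates = SYNTH_TEMPLATES) {
  defs <- .defect_mutations()
  root <- tempfile("detection")
  dir.create(root, recursive = TRUE)
  on.exit(unlink(root, recursive = TRUE), add = TRUE)

  clean_cache <- new.env(parent = emptyenv())
  get_clean <- function(template, seed) {
    key <- sprintf("%s_%d", template, seed)
    if (is.null(clean_cache[[key]])) {
      clean_cache[[key]] <- generate_clean_context(
        template, seed, out_dir = file.path(root, key))
    }
    clean_cache[[key]]
  }

  clean_rows <- list()
  for (template in templates) {
    n_flag_runs <- 0L
    for (seed in seeds) {
      rep <- run_checks(assemble_synth(get_clean(template, seed)), cfg)
      if (rep$summary[["FLAG"]] > 0) n_flag_runs <- n_flag_runs + 1L
    }
    clean_rows[[template]] <- tibble::tibble(
      template = template, n = length(seeds), n_flag_runs = n_flag_runs,
      specificity = 1 - n_flag_runs / length(seeds))
  }

  defect_rows <- list()
  for (id in defect_ids) {
    def <- defs[[id]]
    n_det <- 0L; n_offtarget <- 0L
    for (seed in seeds) {
      clean <- get_clean(def$template, seed)
      mut <- inject_defect(clean, id,
                           out_dir = file.path(root, sprintf("%s_%d", id, seed)))
      rep <- run_checks(assemble_synth(mut), cfg)
      flagged <- vapply(rep$results, function(r) r$status == "FLAG", logical(1))
      flagged_ids <- vapply(rep$results, `[[`, character(1),
                            "checker_id")[flagged]
      if (def$expected_checker %in% flagged_ids) n_det <- n_det + 1L
      n_offtarget <- n_offtarget +
        length(setdiff(flagged_ids, def$expected_checker))
    }
    defect_rows[[id]] <- tibble::tibble(
      defect_id = id, template = def$template,
      expected_checker = def$expected_checker, n = length(seeds),
      n_detected = n_det, sensitivity = n_det / length(seeds),
      n_offtarget_flags = n_offtarget)
  }
  structure(list(by_defect = dplyr::bind_rows(defect_rows),
                 clean = dplyr::bind_rows(clean_rows)),
            class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat("<detection_matrix>\n")
  cat(sprintf("  defects: %d, min sensitivity %.2f, off-target flags %d\n",
              nrow(x$by_defect), min(x$by_defect$sensitivity),
              sum(x$by_defect$n_offtarget_flags)))
  cat(sprintf("  clean templates: %d, min specificity %.2f\n",
              nrow(x$clean), min(x$clean$specificity)))
  invisible(x)
}

#' Detection-matrix tile plot
#'
#' @param object A `detection_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot detection_matrix
#' @export
autoplot.detection_matrix <- function(object, ...) {
  ggplot2::ggplot(object$by_defect,
                  ggplot2::aes(x = .data$expected_checker, y = .data$defect_id,
                               fill = .data$sensitivity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#c62828", high = "#2e7d32",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "expected checker", y = "injected defect",
                  fill = "sensitivity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
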