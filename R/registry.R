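# The checker registry: one entry per displayed checker row. `kind` is "PF"
# for pass/flag checkers and "R" for report-only rows; `n_checks` counts the
# constituent checks (10 for the QA composite, 1 otherwise), giving 34 checks
# over the 25 registered rows. `origin` records which collaboration tier the
# row descends from in the shipped profile (unmodified, modified, local).

.registry_cache <- new.env(parent = emptyenv())

#' The registered checkers
#'
#' @return Named list: for each checker id, `fun(ctx, cfg)`, the display
#'   `label`, the `kind` (`"PF"` pass/flag or `"R"` report), `n_checks`
#'   (constituent checks; 10 for the QA composite) and `origin`.
#' @export
checker_registry <- function() {
  if (!is.null(.registry_cache$registry)) return(.registry_cache$registry)
  entry <- function(fun, label, kind, origin, n_checks = 1L) {
    list(fun = fun, label = label, kind = kind, origin = origin,
         n_checks = n_checks)
  }
  reg <- list(
    isocenter_consistency = entry(check_isocenter_consistency,
      "Isocenter the same for all fields", "PF", "unmodified"),
    tolerance_tables = entry(check_tolerance_tables,
      "Report tolerance tables", "R", "unmodified"),
    drr_created = entry(function(ctx, cfg) check_drr(ctx, cfg, "created"),
      "Verify DRRs created", "PF", "unmodified"),
    patient_orientation = entry(report_patient_orientation,
      "Report patient orientation", "R", "modified"),
    image_structure_names = entry(function(ctx, cfg)
        check_naming_conventions(ctx, cfg, "image_structure"),
      "Image and structure set names follow convention", "PF", "modified"),
    course_names = entry(function(ctx, cfg)
        check_naming_conventions(ctx, cfg, "course"),
      "Course names follow convention", "PF", "modified"),
    plan_names = entry(function(ctx, cfg)
        check_naming_conventions(ctx, cfg, "plan"),
      "Plan names follow convention", "PF", "modified"),
    reference_point_limits = entry(check_reference_point_limits,
      "Reference point dose limits", "PF", "modified"),
    bolus_linkage = entry(function(ctx, cfg) check_bolus(ctx, cfg, "linkage"),
      "Bolus attached to all fields", "PF", "modified"),
    drr_overlay = entry(function(ctx, cfg) check_drr(ctx, cfg, "overlay"),
      "Overlay on DRRs", "PF", "modified"),
    dose_rate = entry(check_dose_rate, "Dose rate", "PF", "modified"),
    plan_status = entry(function(ctx, cfg)
        check_plan_status(ctx, cfg, "clinical"),
      "Plan status", "PF", "modified"),
    calc_settings = entry(function(ctx, cfg)
        check_calc_settings(ctx, cfg, "model_grid"),
      "Default calculation settings and grid size", "PF", "modified"),
    couch_structures = entry(function(ctx, cfg)
        check_couch(ctx, cfg, "structures"),
      "Couch structures properly applied", "PF", "local"),
    unusual_warnings = entry(function(ctx, cfg)
        report_overrides_and_warnings(ctx, cfg, "warnings"),
      "List unusual warnings", "R", "local"),
    invalid_characters = entry(check_invalid_characters,
      "Invalid characters", "PF", "local"),
    control_point_count = entry(check_control_points,
      "Valid number of control points", "PF", "local"),
    imrt_leaf_delivery = entry(check_imrt_leaf_delivery,
      "IMRT leaf delivery", "PF", "local"),
    leaf_motion_calculator = entry(function(ctx, cfg)
        check_calc_settings(ctx, cfg, "lmc"),
      "Correct leaf motion calculator algorithm", "PF", "local"),
    density_overrides = entry(function(ctx, cfg)
        report_overrides_and_warnings(ctx, cfg, "overrides"),
      "Report CT density overrides", "R", "local"),
    bolus_hu = entry(function(ctx, cfg) check_bolus(ctx, cfg, "hu"),
      "Report bolus with non-zero HU values", "R", "local"),
    nonclinical_complete = entry(function(ctx, cfg)
        check_plan_status(ctx, cfg, "nonclinical"),
      "Non-clinical courses are set to complete", "PF", "local"),
    couch_position = entry(function(ctx, cfg)
        check_couch(ctx, cfg, "position"),
      "Default couch position", "PF", "local"),
    setup_imager_position = entry(check_setup_fields,
      "Setup fields correct imager position", "PF", "local"),
    qa_plans = entry(check_qa_plans,
      "QA plan checkers", "PF", "local", n_checks = 10L)
  )
  .registry_cache$registry <- reg
  reg
}

#' Tabulate the checker registry
#'
#' @return A tibble with one row per registered checker: id, display label,
#'   kind (pass/flag or report), constituent check count and origin tier.
#' @export
checker_table <- function() {
  reg <- checker_registry()
  tibble::tibble(
    checker_id = names(reg),
    label = vapply(reg, `[[`, character(1), "label"),
    kind = vapply(reg, `[[`, character(1), "kind"),
    n_checks = vapply(reg, `[[`, integer(1), "n_checks"),
    origin = vapply(reg, `[[`, character(1), "origin")
  )
}
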