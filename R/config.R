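# Run configuration: which checkers run, in what order, and the parameters
# that define each checker's passing criteria. One human-editable YAML
# dialect; unknown keys warn rather than fail so configs can be shared across
# institutions with locally-extended checker sets.

.default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "plancheckr",
              mustWork = TRUE)
}

.is_valid_regex <- function(pattern) {
  !inherits(tryCatch(grepl(pattern, ""), error = identity,
                     warning = identity), c("error", "warning"))
}

.validate_params <- function(params, registry, quiet) {
  known <- names(registry)
  for (id in names(params)) {
    if (!id %in% c(known, "global")) {
      warning("config parameters for unknown checker '", id, "' ignored",
              call. = FALSE)
      next
    }
    p <- params[[id]]
    for (key in names(p)) {
      val <- p[[key]]
      if (grepl("regex$", key)) {
        if (!is.character(val) || !.is_valid_regex(val)) {
          stop(sprintf("config error: %s.%s is not a valid regex", id, key),
               call. = FALSE)
        }
      }
      if (grepl("tolerance|min_gap|max_grid|max_leaf_speed", key)) {
        if (is.numeric(val) && any(val < 0)) {
          stop(sprintf("config error: %s.%s must be non-negative", id, key),
               call. = FALSE)
        }
      }
    }
  }
  if (!is.null(params$invalid_characters)) {
    wl <- params$invalid_characters$allowed_chars
    if (!is.null(wl) && (!is.character(wl) || !nzchar(wl))) {
      stop("config error: invalid_characters.allowed_chars must be a non-empty character class",
           call. = FALSE)
    }
  }
  if (!is.null(params$plan_status)) {
    req <- unlist(params$plan_status$required_status)
    bad <- setdiff(req, PLAN_STATUSES)
    if (length(bad)) {
      stop("config error: plan_status.required_status contains unknown status ",
           paste(sQuote(bad), collapse = ", "), call. = FALSE)
    }
  }
  invisible(params)
}

# deep-merge y over x (named lists); atomic values in y win
.merge_params <- function(x, y) {
  for (key in names(y)) {
    if (is.list(x[[key]]) && is.list(y[[key]]) &&
        !is.null(names(y[[key]]))) {
      x[[key]] <- .merge_params(x[[key]], y[[key]])
    } else {
      x[[key]] <- y[[key]]
    }
  }
  x
}

#' Load and validate a run configuration
#'
#' The configuration defines the checkers to run (in display order) and the
#' configurable parameters that define each checker's passing criteria
#' (naming regexes, allowed machines and dose rates, algorithm names, default
#' grid size, couch and imager windows, control-point limits, MLC
#' deliverability limits, reference-point multipliers, character whitelist,
#' forbidden tolerance-table labels). Parameters omitted from a user config
#' fall back to the shipped defaults; the fallback is reported via `message()`
#' unless `quiet = TRUE`. Unknown top-level keys and parameters for unknown
#' checkers warn but do not fail.
#'
#' @param path Path to a YAML config, or `NULL` for the shipped default
#'   configuration (which enables the full Table-style battery of 25 checkers
#'   covering 34 checks, the QA composite counting 10).
#' @param quiet Suppress the defaults-applied message.
#' @return A `run_config`: list with `enabled_checkers`, `params`, `source`.
#' @export
load_config <- function(path = NULL, quiet = TRUE) {
  registry <- checker_registry()
  defaults <- tryCatch(yaml::read_yaml(.default_config_path()),
                       error = function(e) stop("cannot read default config: ",
                                                conditionMessage(e),
                                                call. = FALSE))
  if (is.null(path)) {
    cfg_raw <- defaults
    src <- .default_config_path()
  } else {
    cfg_raw <- tryCatch(yaml::read_yaml(path),
                        error = function(e) stop("config error: malformed YAML in ",
                                                 path, ": ", conditionMessage(e),
                                                 call. = FALSE))
    src <- path
  }
  known_top <- c("checkers", "params")
  extra <- setdiff(names(cfg_raw), known_top)
  if (length(extra)) {
    warning("config ", src, ": unknown top-level keys ignored: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  enabled <- unlist(cfg_raw$checkers)
  if (!length(enabled)) {
    stop("config error: no checkers enabled in ", src, call. = FALSE)
  }
  if (anyDuplicated(enabled)) {
    stop("config error: duplicate checker id ",
         sQuote(enabled[duplicated(enabled)][1]), call. = FALSE)
  }
  unknown <- setdiff(enabled, names(registry))
  if (length(unknown)) {
    stop("config error: unknown checker id ",
         paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  }
  params <- cfg_raw$params %||% list()
  omitted <- setdiff(names(defaults$params), names(params))
  if (!is.null(path) && length(omitted) && !quiet) {
    message("config ", src, ": defaults applied for ",
            paste(omitted, collapse = ", "))
  }
  merged <- .merge_params(defaults$params, params)
  .validate_params(merged, registry, quiet)
  structure(list(enabled_checkers = enabled, params = merged, source = src),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %d checkers enabled (%s)\n",
              length(x$enabled_checkers), x$source))
  invisible(x)
}

#' Look up a checker parameter
#'
#' @param cfg A `run_config`.
#' @param checker_id Checker the parameter belongs to, or `"global"`.
#' @param key Parameter name.
#' @param default Returned when the parameter is absent.
#' @return The parameter value.
#' @export
cfg_param <- function(cfg, checker_id, key, default = NULL) {
  cfg$params[[checker_id]][[key]] %||% default
}

#' Validate a configuration file
#'
#' Convenience wrapper used by the command-line entry point: loads the config
#' and reports success or the validation error.
#'
#' @param path Path to a YAML config file.
#' @return `TRUE` (invisibly) if the config is valid; otherwise the load error
#'   propagates.
#' @export
validate_config <- function(path) {
  cfg <- load_config(path, quiet = TRUE)
  invisible(TRUE)
}
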