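# The rule engine: four compliance states, one result per enabled checker,
# rendered as text/JSON/HTML with Item/Status/Results columns.

COMPLIANCE_STATUSES <- c("PASS", "FLAG", "REPORT", "MANUAL")

#' Construct a checker result
#'
#' @param checker_id Registered checker id.
#' @param status One of `"PASS"`, `"FLAG"`, `"REPORT"`, `"MANUAL"`.
#' @param messages Character vector of human-readable findings. `FLAG` and
#'   `REPORT` results must carry at least one message; `PASS` may carry zero.
#' @param details Named list payload for machine reading.
#' @return A `check_result` object.
#' @export
check_result <- function(checker_id, status, messages = character(0),
                         details = list()) {
  status <- match.arg(status, COMPLIANCE_STATUSES)
  if (status %in% c("FLAG", "REPORT") && !length(messages)) {
    stop("a ", status, " result must carry at least one message", call. = FALSE)
  }
  structure(list(checker_id = checker_id, status = status,
                 messages = as.character(messages), details = details),
            class = "check_result")
}

#' @export
print.check_result <- function(x, ...) {
  cat(sprintf("[%s] %s", x$status, x$checker_id))
  if (length(x$messages)) cat(":", paste(x$messages, collapse = "; "))
  cat("\n")
  invisible(x)
}

#' Run the enabled checkers over a plan context
#'
#' Checkers run in the configured order, but each is independent: an exception
#' inside one checker yields a `FLAG` result carrying the error message for
#' that checker only and does not abort the run.
#'
#' @param ctx A validated `plan_context`.
#' @param cfg A `run_config` from [load_config()] (defaults to the shipped
#'   default configuration).
#' @return A `plancheck_report`: plan id, timestamp, one `check_result` per
#'   enabled checker, and summary counts per status.
#' @export
run_checks <- function(ctx, cfg = load_config()) {
  stopifnot(inherits(ctx, "plan_context"), inherits(cfg, "run_config"))
  registry <- checker_registry()
  results <- lapply(cfg$enabled_checkers, function(id) {
    fun <- registry[[id]]$fun
    tryCatch(fun(ctx, cfg), error = function(e) {
      check_result(id, "FLAG",
                   sprintf("checker error: %s", conditionMessage(e)))
    })
  })
  statuses <- vapply(results, `[[`, character(1), "status")
  summary <- vapply(COMPLIANCE_STATUSES,
                    function(s) sum(statuses == s), integer(1))
  structure(list(plan_id = ctx$plan_id,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 results = results, summary = summary),
            class = "plancheck_report")
}

#' @export
print.plancheck_report <- function(x, ...) {
  cat(render_report(x, "text"), sep = "\n")
  invisible(x)
}

#' Tabulate a check run
#'
#' @param x A `plancheck_report`.
#' @param ... Unused.
#' @return A tibble with columns `checker_id`, `item`, `status`, `messages`.
#' @method tidy plancheck_report
#' @export
tidy.plancheck_report <- function(x, ...) {
  registry <- checker_registry()
  tibble::tibble(
    checker_id = vapply(x$results, `[[`, character(1), "checker_id"),
    item = vapply(x$results, function(r) {
      registry[[r$checker_id]]$label %||% r$checker_id
    }, character(1)),
    status = vapply(x$results, `[[`, character(1), "status"),
    messages = vapply(x$results, function(r) {
      paste(r$messages, collapse = "; ")
    }, character(1))
  )
}

#' One-row summary of a check run
#'
#' @param x A `plancheck_report`.
#' @param ... Unused.
#' @return A tibble with the plan id and per-status counts.
#' @method glance plancheck_report
#' @export
glance.plancheck_report <- function(x, ...) {
  tibble::tibble(plan_id = x$plan_id, n_checkers = length(x$results),
                 n_pass = x$summary[["PASS"]], n_flag = x$summary[["FLAG"]],
                 n_report = x$summary[["REPORT"]],
                 n_manual = x$summary[["MANUAL"]])
}

.status_glyph <- c(PASS = "ok", FLAG = "FLAG", REPORT = "report",
                   MANUAL = "manual")

#' Render a check report
#'
#' @param report A `plancheck_report`.
#' @param format `"text"`, `"json"` or `"html"`. Text and HTML render an
#'   Item/Status/Results table; JSON is lossless and can be re-parsed with
#'   [report_from_json()].
#' @return A character vector (one element per line for text/html, a single
#'   JSON string for json).
#' @export
render_report <- function(report, format = c("text", "json", "html")) {
  format <- match.arg(format)
  tab <- tidy(report)
  if (format == "text") {
    w1 <- max(nchar(c("Item", tab$item)))
    w2 <- max(nchar(c("Status", tab$status)))
    header <- sprintf("Plan check report for %s (%s)", report$plan_id,
                      report$timestamp)
    rows <- sprintf("%-*s  %-*s  %s", w1, tab$item, w2, tab$status,
                    tab$messages)
    counts <- paste(sprintf("%s: %d", names(report$summary), report$summary),
                    collapse = "  ")
    c(header, strrep("-", nchar(header)),
      sprintf("%-*s  %-*s  %s", w1, "Item", w2, "Status", "Results"),
      rows, "", counts)
  } else if (format == "json") {
    jsonlite::toJSON(list(
      plan_id = report$plan_id, timestamp = report$timestamp,
      results = lapply(report$results, function(r) {
        list(checker_id = r$checker_id, status = r$status,
             messages = as.list(r$messages), details = r$details)
      }),
      summary = as.list(report$summary)
    ), auto_unbox = TRUE, null = "null")
  } else {
    esc <- function(s) {
      s <- gsub("&", "&amp;", s, fixed = TRUE)
      s <- gsub("<", "&lt;", s, fixed = TRUE)
      gsub(">", "&gt;", s, fixed = TRUE)
    }
    c("<table class=\"plancheck\">",
      "<tr><th>Item</th><th>Status</th><th>Results</th></tr>",
      sprintf("<tr class=\"%s\"><td>%s</td><td>%s</td><td>%s</td></tr>",
              tolower(tab$status), esc(tab$item), tab$status, esc(tab$messages)),
      "</table>")
  }
}

#' Re-parse a JSON report
#'
#' Inverse of `render_report(report, "json")`.
#'
#' @param json A JSON string produced by [render_report()].
#' @return A `plancheck_report`.
#' @export
report_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  results <- lapply(x$results, function(r) {
    check_result(r$checker_id, r$status, unlist(r$messages) %||% character(0),
                 r$details)
  })
  structure(list(plan_id = x$plan_id, timestamp = x$timestamp,
                 results = results,
                 summary = vapply(x$summary, as.integer, integer(1))),
            class = "plancheck_report")
}

#' Exit code for shell callers
#'
#' @param report A `plancheck_report`, or `NULL` when loading/configuration
#'   failed before any checks could run.
#' @return 0 if no checker flagged, 1 if any did, 2 on load/config error.
#' @export
exit_code <- function(report) {
  if (is.null(report)) return(2L)
  if (report$summary[["FLAG"]] > 0) 1L else 0L
}

#' Status-count bar chart for a check run
#'
#' @param object A `plancheck_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plancheck_report
#' @export
autoplot.plancheck_report <- function(object, ...) {
  tab <- tidy(object) |>
    dplyr::count(.data$status)
  tab$status <- factor(tab$status, levels = COMPLIANCE_STATUSES)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$status, y = .data$n,
                                    fill = .data$status)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(PASS = "#2e7d32", FLAG = "#c62828",
                                          REPORT = "#1565c0",
                                          MANUAL = "#6a1b9a"),
                               drop = FALSE) +
    ggplot2::labs(x = NULL, y = "checkers",
                  title = sprintf("Plan check: %s", object$plan_id)) +
    ggplot2::theme_minimal()
}
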