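# Synthetic audit logs with known statistical structure: per-category issue
# counts are Binomial(n_checks, rate) per period, per-check times are
# log-normal per person and period (strictly positive and right-skewed, like
# recorded plan-check durations). Defaults reproduce the study conditions of
# a two-period audit: 187 checks before and 186 after introduction of the
# tool, category rates equal to the empirical per-check proportions, and
# times whose mean/median match the recorded period summaries
# (49.4/45 min before, 39.3/35 min after).

.audit_default_rates <- function() {
  # empirical issues-per-check proportions by period, taxonomy order
  pre_counts <- c(21, 64, 17, 13, 11, 5, 7, 6, 6, 17, 5, 2, 2, 5, 3, 10, 6)
  with_counts <- c(7, 49, 20, 5, 9, 2, 11, 2, 9, 3, 1, 0, 1, 2, 0, 5, 1)
  list(PRE = pre_counts / 187, WITH = with_counts / 186)
}

# log-normal parameters matched to a given mean and median:
# median = exp(mu), mean = exp(mu + s^2/2)
.lnorm_from_mean_median <- function(mean, median) {
  mu <- log(median)
  s2 <- 2 * (log(mean) - mu)
  list(meanlog = mu, sdlog = sqrt(max(s2, 1e-8)))
}

#' Default audit simulation configuration
#'
#' @param n_checks Named vector `c(PRE =, WITH =)` of plan checks per period.
#' @param rates List with `PRE` and `WITH` numeric vectors of length 17:
#'   per-check issue rate per taxonomy category.
#' @param time_mean,time_median Named vectors `c(PRE =, WITH =)`: period mean
#'   and median minutes per check, converted to log-normal parameters.
#' @param n_persons Number of plan checkers to spread records over.
#' @param seed Integer seed.
#' @return An `audit_sim_config` list.
#' @export
audit_sim_config <- function(n_checks = c(PRE = 187, WITH = 186),
                             rates = .audit_default_rates(),
                             time_mean = c(PRE = 49.4, WITH = 39.3),
                             time_median = c(PRE = 45, WITH = 35),
                             n_persons = 10, seed = 1L) {
  stopifnot(all(unlist(rates) >= 0), all(unlist(rates) <= 1),
            all(n_checks >= 0))
  structure(list(n_checks = n_checks, rates = rates, time_mean = time_mean,
                 time_median = time_median, n_persons = n_persons,
                 seed = as.integer(seed)),
            class = "audit_sim_config")
}

#' Simulate audit logs
#'
#' @param cfg An [audit_sim_config()].
#' @param out_dir Optional directory; when given, `issues.csv` and
#'   `times.csv` are written there.
#' @return A list with `issues` (tibble of issue records) and `times`
#'   (tibble of time records); when `out_dir` is given, also `paths`.
#' @export
simulate_audit_logs <- function(cfg = audit_sim_config(), out_dir = NULL) {
  set.seed(cfg$seed)
  tax <- issue_taxonomy()
  persons <- sprintf("P%02d", seq_len(cfg$n_persons))
  issues <- list()
  times <- list()
  for (period in AUDIT_PERIODS) {
    n <- cfg$n_checks[[period]]
    rates <- cfg$rates[[period]]
    counts <- stats::rbinom(nrow(tax), size = n, prob = rates)
    if (sum(counts) > 0) {
      issues[[period]] <- tibble::tibble(
        period = period,
        category = rep(tax$category, counts),
        pct_related = rep(tax$pct_related, counts),
        checker_person_id = sample(persons, sum(counts), replace = TRUE))
    }
    ln <- .lnorm_from_mean_median(cfg$time_mean[[period]],
                                  cfg$time_median[[period]])
    times[[period]] <- tibble::tibble(
      period = period,
      checker_person_id = sample(persons, n, replace = TRUE),
      minutes = round(stats::rlnorm(n, ln$meanlog, ln$sdlog), 1))
  }
  out <- list(issues = dplyr::bind_rows(issues), times = dplyr::bind_rows(times))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out$paths <- list(issues = file.path(out_dir, "issues.csv"),
                      times = file.path(out_dir, "times.csv"))
    readr::write_csv(out$issues, out$paths$issues)
    readr::write_csv(out$times, out$paths$times)
  }
  out
}

#' Read an issue log
#'
#' @param path CSV with columns `period`, `category` and optionally
#'   `checker_person_id`; `pct_related` is (re)derived from the taxonomy.
#' @return A tibble of issue records.
#' @export
read_issue_log <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("period", "category") %in% names(x)))
  tax <- issue_taxonomy()
  x$pct_related <- tax$pct_related[match(x$category, tax$category)]
  if (anyNA(x$pct_related)) {
    bad <- unique(x$category[is.na(x$pct_related)])
    stop("unknown issue category: ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' Read a time log
#'
#' @param path CSV with columns `period`, `checker_person_id`, `minutes`.
#' @return A tibble of time records.
#' @export
read_time_log <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("period", "checker_person_id", "minutes") %in% names(x)))
  tibble::as_tibble(x)
}

#' Histogram of per-check times by period
#'
#' @param times A tibble of time records.
#' @param binwidth Minutes per bin.
#' @return A ggplot object.
#' @export
plot_check_times <- function(times, binwidth = 5) {
  ggplot2::ggplot(times, ggplot2::aes(x = .data$minutes,
                                      fill = .data$period)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6, boundary = 0) +
    ggplot2::labs(x = "minutes per plan check", y = "checks",
                  fill = "period") +
    ggplot2::theme_minimal()
}
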