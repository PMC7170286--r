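# Audit statistics for evaluating an automated plan check tool in clinical
# service: categorize recorded issues into the fixed 17-category taxonomy
# (9 categories un-related and 8 related to the automated checks), compare
# the related fraction between periods with an exact two-sided Fisher test,
# and compare per-check times with a tie-corrected Mann-Whitney U test.

AUDIT_PERIODS <- c("PRE", "WITH")

.unrelated_categories <- c(
  "Missing/Incorrect: contours, Booleans",
  "Missing/Incorrect: documentation, billing, database logs",
  "Prescription problems",
  "Plan quality: DVH, isodose lines unsatisfactory, beam arrangement, missing flash",
  "Aria details: treatment time, imaging templates, session scheduling, carepaths, breakpoint",
  "DRR quality, window/level",
  "Treatment field technical parameters (names, MLC, intensities, jaws, etc.)",
  "Setup field technical parameters (angles, names, etc.)",
  "Miscellaneous")

.related_categories <- c(
  "Completion status of non-clinical courses",
  "DRR overlays",
  "Treatment field technical parameters: bolus, couch coordinates",
  "Setup field technical parameters: imager position",
  "Reference Points: missing or incorrect contributions",
  "Incorrect grid size",
  "Course/plan not follow naming conventions",
  "Incorrect tolerance tables")

#' The fixed issue-category taxonomy
#'
#' @return A tibble with columns `category` and `pct_related` (whether the
#'   category is one of the 8 covered by the automated checker battery).
#' @export
issue_taxonomy <- function() {
  tibble::tibble(
    category = c(.unrelated_categories, .related_categories),
    pct_related = rep(c(FALSE, TRUE),
                      c(length(.unrelated_categories),
                        length(.related_categories))))
}

#' Round half away from zero at a fixed number of decimals
#'
#' Matches the rounding used in printed percentage tables (R's `round()`
#' rounds half to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build issue records from per-category counts
#'
#' Convenience for analysing published per-category counts: expands counts in
#' taxonomy order into one record per issue.
#'
#' @param pre,with_pct Integer vectors of length 17 (taxonomy order:
#'   9 un-related then 8 related categories).
#' @return A tibble of issue records (`period`, `category`, `pct_related`).
#' @export
issue_records_from_counts <- function(pre, with_pct) {
  tax <- issue_taxonomy()
  stopifnot(length(pre) == nrow(tax), length(with_pct) == nrow(tax))
  build <- function(counts, period) {
    tibble::tibble(
      period = period,
      category = rep(tax$category, counts),
      pct_related = rep(tax$pct_related, counts))
  }
  dplyr::bind_rows(build(pre, "PRE"), build(with_pct, "WITH"))
}

#' Categorize recorded issues
#'
#' Counts issues per category and period and computes percentages of the
#' period grand total: category percentages at 1 decimal, related/un-related
#' subtotal percentages at 2 decimals (half-up rounding, as in printed audit
#' tables). Empty periods render percentages as `NA`.
#'
#' @param records A data frame with columns `period` (`"PRE"`/`"WITH"`) and
#'   `category` (taxonomy labels; unknown labels error).
#' @return An `issue_category_table`: list with `categories` (per-category
#'   tibble), `subtotals`, and `grand_total` per period.
#' @export
categorize <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("period", "category") %in% names(records)))
  tax <- issue_taxonomy()
  bad_period <- setdiff(unique(records$period), AUDIT_PERIODS)
  if (length(bad_period)) {
    stop("unknown period label(s): ", paste(bad_period, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(records$category), tax$category)
  if (length(bad)) {
    stop("unknown issue categor", if (length(bad) > 1) "ies: " else "y: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  grand <- c(PRE = sum(records$period == "PRE"),
             WITH = sum(records$period == "WITH"))
  count_one <- function(period) {
    sub <- records[records$period == period, ]
    vapply(tax$category, function(cat) sum(sub$category == cat), integer(1))
  }
  n_pre <- count_one("PRE"); n_with <- count_one("WITH")
  pct <- function(n, total, digits) {
    if (total == 0) rep(NA_real_, length(n)) else
      round_half_up(100 * n / total, digits)
  }
  categories <- tibble::tibble(
    category = tax$category, pct_related = tax$pct_related,
    n_pre = unname(n_pre), pct_pre = pct(n_pre, grand[["PRE"]], 1),
    n_with = unname(n_with), pct_with = pct(n_with, grand[["WITH"]], 1))
  subtotals <- categories |>
    dplyr::group_by(.data$pct_related) |>
    dplyr::summarise(n_pre = sum(.data$n_pre), n_with = sum(.data$n_with),
                     .groups = "drop") |>
    dplyr::mutate(
      group = ifelse(.data$pct_related, "related", "unrelated"),
      pct_pre = pct(.data$n_pre, grand[["PRE"]], 2),
      pct_with = pct(.data$n_with, grand[["WITH"]], 2)) |>
    dplyr::select("group", "pct_related", "n_pre", "pct_pre", "n_with",
                  "pct_with") |>
    dplyr::arrange(.data$pct_related)
  structure(list(categories = categories, subtotals = subtotals,
                 grand_total = grand),
            class = "issue_category_table")
}

#' @export
print.issue_category_table <- function(x, ...) {
  cat(build_table2(x, format = "text"), sep = "\n")
  invisible(x)
}

#' @method tidy issue_category_table
#' @export
tidy.issue_category_table <- function(x, ...) x$categories

#' @method glance issue_category_table
#' @export
glance.issue_category_table <- function(x, ...) {
  s <- x$subtotals
  tibble::tibble(
    n_pre = unname(x$grand_total[["PRE"]]),
    n_with = unname(x$grand_total[["WITH"]]),
    related_pre = s$n_pre[s$pct_related],
    related_pct_pre = s$pct_pre[s$pct_related],
    related_with = s$n_with[s$pct_related],
    related_pct_with = s$pct_with[s$pct_related])
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Minimum-likelihood two-sided definition: the p-value sums the
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table (within a 1e-7
#' relative tolerance). Probabilities are computed in log space for
#' stability. A degenerate margin (a row or column of zeros) returns p = 1
#' with a warning.
#'
#' @param a,b,c_,d Cell counts: rows are periods, columns are issue classes.
#'   `a` may also be a 2x2 matrix (then `b`, `c_`, `d` are ignored).
#' @return A `fisher_2x2` list: `p_value`, `table`, `odds_ratio` (sample OR).
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c_ = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    b <- a[1, 2]; c_ <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c_, d)
  stopifnot(length(cells) == 4, all(cells >= 0), all(cells == floor(cells)))
  tab <- matrix(cells, 2, 2, byrow = TRUE)
  or <- (a * d) / (b * c_)
  row1 <- a + b; row2 <- c_ + d; col1 <- a + c_; col2 <- b + d
  n <- row1 + row2
  if (row1 == 0 || row2 == 0 || col1 == 0 || col2 == 0) {
    warning("degenerate margin: p-value defined as 1", call. = FALSE)
    return(structure(list(p_value = 1, table = tab, odds_ratio = or),
                     class = "fisher_2x2"))
  }
  lo <- max(0, row1 - col2)
  hi <- min(row1, col1)
  x <- lo:hi
  logp <- lchoose(col1, x) + lchoose(col2, row1 - x) - lchoose(n, row1)
  log_obs <- logp[x == a]
  p <- sum(exp(logp[logp <= log_obs + log(1 + 1e-7)]))
  structure(list(p_value = min(1, p), table = tab, odds_ratio = or),
            class = "fisher_2x2")
}

#' @export
print.fisher_2x2 <- function(x, ...) {
  cat("Two-sided Fisher's exact test (2x2)\n")
  print(x$table)
  cat(sprintf("p-value = %.6g, sample odds ratio = %.4g\n",
              x$p_value, x$odds_ratio))
  invisible(x)
}

#' @method tidy fisher_2x2
#' @export
tidy.fisher_2x2 <- function(x, ...) {
  tibble::tibble(p_value = x$p_value, odds_ratio = x$odds_ratio,
                 method = "Fisher exact (two-sided, minimum likelihood)")
}

#' Mann-Whitney U test with tie correction
#'
#' U is computed from rank sums with midranks for ties:
#' `U = R1 - n1 (n1 + 1) / 2`. The normal approximation uses
#' `z = (U - n1 n2 / 2 -/+ 0.5) / sigma` with the continuity correction
#' shrinking `|U - mu|` (toggleable) and the tie-corrected variance
#' `sigma^2 = (n1 n2 / 12) * ((n + 1) - sum(t^3 - t) / (n (n - 1)))`.
#' For `n1 * n2 <= exact_limit` an exact two-sided p-value
#' `P(|U - mu| >= |u_obs - mu|)` is also computed by enumerating all
#' labelings, and reported alongside. If every value is tied across both
#' samples (`sigma = 0`), the defined result is `U = n1 n2 / 2`, `p = 1`,
#' with a warning.
#'
#' @param x,y Numeric samples (e.g. minutes per check in two periods).
#' @param continuity Apply the 0.5 continuity correction (default `TRUE`).
#' @param exact_limit Enumerate the exact p-value when `n1 * n2` does not
#'   exceed this.
#' @return An `mwu_test` list: `U`, `U_prime`, `z`, `p_value` (normal
#'   approximation), `p_exact` (or `NA`), `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y, continuity = TRUE, exact_limit = 400) {
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  ranks <- rank(c(x, y))
  U <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  t_counts <- table(c(x, y))
  tie_term <- if (n > 1) sum(t_counts^3 - t_counts) / (n * (n - 1)) else 0
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  sigma <- sqrt(max(sigma2, 0))
  if (sigma == 0) {
    warning("all values tied across both samples: p-value defined as 1",
            call. = FALSE)
    return(structure(list(U = mu, U_prime = mu, z = 0, p_value = 1,
                          p_exact = 1, n1 = n1, n2 = n2, sigma = 0),
                     class = "mwu_test"))
  }
  d <- U - mu
  dc <- if (continuity) sign(d) * max(0, abs(d) - 0.5) else d
  z <- dc / sigma
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  p_exact <- NA_real_
  # enumeration is worthwhile (and feasible) only while the number of
  # labelings stays small; balanced samples reach C(n, n1) far faster than
  # the n1*n2 product suggests
  if (n1 * n2 <= exact_limit && choose(n, n1) <= 1e5) {
    idx <- utils::combn(n, n1)
    Uall <- colSums(matrix(ranks[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p_exact <- mean(abs(Uall - mu) >= abs(d) - 1e-9)
  }
  structure(list(U = U, U_prime = n1 * n2 - U, z = z, p_value = p,
                 p_exact = p_exact, n1 = n1, n2 = n2, sigma = sigma),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test: U = %g (U' = %g), z = %.4f, p = %.4g",
              x$U, x$U_prime, x$z, x$p_value))
  if (!is.na(x$p_exact)) cat(sprintf(" (exact p = %.4g)", x$p_exact))
  cat("\n")
  invisible(x)
}

#' @method tidy mwu_test
#' @export
tidy.mwu_test <- function(x, ...) {
  tibble::tibble(U = x$U, U_prime = x$U_prime, z = x$z, p_value = x$p_value,
                 p_exact = x$p_exact, n1 = x$n1, n2 = x$n2)
}

#' Summarize per-check times by plan checker and period
#'
#' Per person and overall: number of checks, mean and median minutes in each
#' period, the with/pre ratios of means and medians (2 decimals, half-up),
#' and a Mann-Whitney p-value where both periods hold at least 3 checks.
#' Persons present in only one period get blank (NA) ratios.
#'
#' @param records A data frame with columns `period`, `checker_person_id`,
#'   `minutes` (positive).
#' @return A tibble with one row per person plus an `"Overall"` row.
#' @export
summarize_times <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("period", "checker_person_id", "minutes") %in%
                  names(records)))
  if (any(records$minutes <= 0)) {
    stop("minutes must be positive", call. = FALSE)
  }
  one_group <- function(sub, label) {
    pre <- sub$minutes[sub$period == "PRE"]
    wit <- sub$minutes[sub$period == "WITH"]
    p <- if (length(pre) >= 3 && length(wit) >= 3) {
      mann_whitney_u(pre, wit, exact_limit = 0)$p_value
    } else NA_real_
    tibble::tibble(
      checker_person_id = label,
      n_pre = length(pre),
      mean_pre = if (length(pre)) mean(pre) else NA_real_,
      median_pre = if (length(pre)) stats::median(pre) else NA_real_,
      n_with = length(wit),
      mean_with = if (length(wit)) mean(wit) else NA_real_,
      median_with = if (length(wit)) stats::median(wit) else NA_real_,
      ratio_mean = if (length(pre) && length(wit)) {
        round_half_up(mean(wit) / mean(pre), 2)
      } else NA_real_,
      ratio_median = if (length(pre) && length(wit)) {
        round_half_up(stats::median(wit) / stats::median(pre), 2)
      } else NA_real_,
      p_value = p)
  }
  persons <- sort(unique(records$checker_person_id))
  rows <- lapply(persons, function(p) {
    one_group(records[records$checker_person_id == p, ], p)
  })
  dplyr::bind_rows(c(rows, list(one_group(records, "Overall"))))
}

#' Ratios and percent decrease from printed period summaries
#'
#' @param mean_pre,median_pre,mean_with,median_with Period summaries, minutes.
#' @return A tibble with `ratio_mean`, `ratio_median` (2 decimals) and
#'   `pct_decrease_mean` (whole percent, half-up).
#' @export
time_ratio_summary <- function(mean_pre, median_pre, mean_with, median_with) {
  tibble::tibble(
    ratio_mean = round_half_up(mean_with / mean_pre, 2),
    ratio_median = round_half_up(median_with / median_pre, 2),
    pct_decrease_mean = round_half_up((1 - mean_with / mean_pre) * 100, 0))
}

# Table renderers -------------------------------------------------------------

.fmt_pct <- function(x, digits) {
  ifelse(is.na(x), "—", sprintf(paste0("%.", digits, "f%%"), x))
}

#' Render the issue-category table
#'
#' @param x An `issue_category_table` from [categorize()], or a record data
#'   frame (then [categorize()] is applied first).
#' @param format `"tibble"`, `"text"` or `"csv"` (csv returns the lines of a
#'   comma-separated rendering).
#' @param n_checks Optional named vector `c(PRE =, WITH =)` of plan-check
#'   counts for the footer row.
#' @return A tibble, or a character vector of rendered lines.
#' @export
build_table2 <- function(x, format = c("tibble", "text", "csv"),
                         n_checks = NULL) {
  format <- match.arg(format)
  if (!inherits(x, "issue_category_table")) x <- categorize(x)
  cats <- x$categories
  subs <- x$subtotals
  rows <- tibble::tibble(
    category = character(0), n_pre = integer(0), pct_pre = character(0),
    n_with = integer(0), pct_with = character(0))
  add_block <- function(rows, related, title) {
    blk <- cats[cats$pct_related == related, ]
    sub <- subs[subs$pct_related == related, ]
    dplyr::bind_rows(
      rows,
      tibble::tibble(category = title, n_pre = NA_integer_, pct_pre = "",
                     n_with = NA_integer_, pct_with = ""),
      tibble::tibble(category = blk$category, n_pre = blk$n_pre,
                     pct_pre = .fmt_pct(blk$pct_pre, 1), n_with = blk$n_with,
                     pct_with = .fmt_pct(blk$pct_with, 1)),
      tibble::tibble(category = "Total:", n_pre = sub$n_pre,
                     pct_pre = .fmt_pct(sub$pct_pre, 2), n_with = sub$n_with,
                     pct_with = .fmt_pct(sub$pct_with, 2)))
  }
  rows <- add_block(rows, FALSE, "Un-related to automated checks:")
  rows <- add_block(rows, TRUE, "Related to automated checks:")
  gt <- x$grand_total
  rows <- dplyr::bind_rows(rows, tibble::tibble(
    category = "Grand Total:", n_pre = unname(gt[["PRE"]]),
    pct_pre = .fmt_pct(if (gt[["PRE"]] > 0) 100 else NA_real_, 2),
    n_with = unname(gt[["WITH"]]),
    pct_with = .fmt_pct(if (gt[["WITH"]] > 0) 100 else NA_real_, 2)))
  if (!is.null(n_checks)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      category = "Number of plan checks:",
      n_pre = as.integer(n_checks[["PRE"]]), pct_pre = "",
      n_with = as.integer(n_checks[["WITH"]]), pct_with = ""))
  }
  if (format == "tibble") return(rows)
  cells <- rbind(c("Category", "# Pre", "% Pre", "# With", "% With"),
                 cbind(rows$category,
                       ifelse(is.na(rows$n_pre), "", rows$n_pre), rows$pct_pre,
                       ifelse(is.na(rows$n_with), "", rows$n_with),
                       rows$pct_with))
  if (format == "csv") {
    return(apply(cells, 1, function(r) paste(sprintf("\"%s\"", r),
                                             collapse = ",")))
  }
  widths <- apply(nchar(cells), 2, max)
  apply(cells, 1, function(r) {
    paste(mapply(function(cell, w) formatC(cell, width = w, flag = "-"),
                 r, widths), collapse = "  ")
  })
}

#' Render the per-checker timing table
#'
#' @param records A data frame of time records (see [summarize_times()]), or
#'   an already-summarised tibble.
#' @param format `"tibble"`, `"text"` or `"csv"`.
#' @return A tibble, or a character vector of rendered lines.
#' @export
build_table3 <- function(records, format = c("tibble", "text", "csv")) {
  format <- match.arg(format)
  tab <- if (all(c("n_pre", "ratio_mean") %in% names(records))) {
    tibble::as_tibble(records)
  } else {
    summarize_times(records)
  }
  if (format == "tibble") return(tab)
  fmt <- function(x, digits = 1) ifelse(is.na(x), "N/A",
                                        formatC(x, digits = digits,
                                                format = "f"))
  cells <- rbind(
    c("Checker", "# Pre", "Avg", "Med", "# With", "Avg", "Med",
      "Ratio avg", "Ratio med", "P"),
    cbind(tab$checker_person_id, tab$n_pre, fmt(tab$mean_pre),
          fmt(tab$median_pre, 1), tab$n_with, fmt(tab$mean_with),
          fmt(tab$median_with, 1), fmt(tab$ratio_mean, 2),
          fmt(tab$ratio_median, 2), fmt(tab$p_value, 3)))
  if (format == "csv") {
    return(apply(cells, 1, function(r) paste(sprintf("\"%s\"", r),
                                             collapse = ",")))
  }
  widths <- apply(nchar(cells), 2, max)
  apply(cells, 1, function(r) {
    paste(mapply(function(cell, w) formatC(cell, width = w, flag = "-"),
                 r, widths), collapse = "  ")
  })
}
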