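# Audit statistics: categorization, Fisher exact, Mann-Whitney U, timing
# summaries and table rendering. Independent oracles: exact rational
# enumeration for the small Fisher table, stats::fisher.test and
# stats::wilcox.test as reference implementations, and brute-force labeling
# enumeration for the exact Mann-Whitney p.

test_that("categorize reproduces subtotals and percentages from counts", {
  pre <- c(21, 64, 17, 13, 11, 5, 7, 6, 6, 17, 5, 2, 2, 5, 3, 10, 6)
  wit <- c(7, 49, 20, 5, 9, 2, 11, 2, 9, 3, 1, 0, 1, 2, 0, 5, 1)
  tab <- categorize(issue_records_from_counts(pre, wit))
  g <- glance(tab)
  expect_identical(g$n_pre, 200L)
  expect_identical(g$n_with, 127L)
  expect_identical(g$related_pre, 50L)
  expect_identical(g$related_with, 13L)
  expect_equal(g$related_pct_pre, 25.00)
  expect_equal(g$related_pct_with, 10.24)
  expect_equal(tab$subtotals$pct_pre, c(75.00, 25.00))
  expect_equal(tab$subtotals$pct_with, c(89.76, 10.24))
  # spot-check category-level rounding at 1 decimal (half-up)
  cats <- tab$categories
  expect_equal(cats$pct_pre[cats$category == "Missing/Incorrect: contours, Booleans"],
               10.5)
  expect_equal(cats$pct_with[cats$category == "Prescription problems"], 15.7)
})

test_that("category percentages per period sum to 100 within rounding", {
  set.seed(42)
  tax <- issue_taxonomy()
  for (rep in 1:5) {
    n <- sample(50:400, 1)
    recs <- tibble::tibble(
      period = sample(c("PRE", "WITH"), n, replace = TRUE),
      category = sample(tax$category, n, replace = TRUE))
    tab <- categorize(recs)
    expect_equal(sum(tab$categories$pct_pre), 100, tolerance = 0.1)
    expect_equal(sum(tab$categories$pct_with), 100, tolerance = 0.1)
  }
})

test_that("categorize handles empty input and rejects unknown labels", {
  empty <- tibble::tibble(period = character(0), category = character(0))
  tab <- categorize(empty)
  expect_identical(unname(tab$grand_total), c(0L, 0L))
  expect_true(all(is.na(tab$categories$pct_pre)))
  rendered <- build_table2(tab, format = "text")
  expect_match(rendered, "—", all = FALSE)
  expect_error(categorize(tibble::tibble(period = "PRE", category = "Gremlins")),
               "unknown issue category")
})

test_that("fisher exact matches the rational-arithmetic enumeration oracle", {
  # margins (4,4)/(4,4): five tables, masses {1,16,36,16,1}/70; observed
  # a = 3 has mass 16/70; tables at most as probable sum to 34/70
  oracle <- local({
    masses <- sapply(0:4, function(x) choose(4, x) * choose(4, 4 - x))
    denom <- sum(masses)  # 70
    obs <- masses[4]      # a = 3
    sum(masses[masses <= obs]) / denom
  })
  expect_equal(oracle, 34 / 70)
  expect_equal(fisher_exact_2x2(3, 1, 1, 3)$p_value, 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(1, 1, 1, 1)$p_value, 1)
})

test_that("fisher exact agrees with stats::fisher.test over random tables", {
  set.seed(7)
  for (i in 1:60) {
    cells <- rpois(4, lambda = sample(c(2, 8, 40), 1))
    ours <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])$p_value
    ref <- stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-7,
                 label = paste("table", paste(cells, collapse = ",")))
  }
})

test_that("fisher p is swap-invariant, in (0, 1], and degenerate-safe", {
  set.seed(11)
  for (i in 1:30) {
    cells <- rpois(4, 6)
    p1 <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])$p_value
    # simultaneous row swap + column swap
    p2 <- fisher_exact_2x2(cells[4], cells[3], cells[2], cells[1])$p_value
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_gt(p1, 0)
    expect_lte(p1, 1)
  }
  expect_warning(res <- fisher_exact_2x2(0, 0, 3, 5), "degenerate margin")
  expect_equal(res$p_value, 1)
})

test_that("Mann-Whitney: separation, symmetry, antisymmetry, ties", {
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$p_exact, 0.1)  # 2 of the C(6,3)=20 labelings are as extreme
  same <- mann_whitney_u(c(3, 1, 2), c(2, 3, 1))
  expect_equal(same$U, 3 * 3 / 2)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  x <- c(10, 12, 19, 22); y <- c(11, 25, 30)
  fwd <- mann_whitney_u(x, y); rev <- mann_whitney_u(y, x)
  expect_equal(fwd$z, -rev$z)
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(fwd$U + fwd$U_prime, length(x) * length(y))
  expect_warning(tied <- mann_whitney_u(rep(5, 4), rep(5, 3)), "all values tied")
  expect_equal(tied$U, 6)
  expect_equal(tied$p_value, 1)
})

test_that("Mann-Whitney agrees with stats::wilcox.test", {
  set.seed(13)
  for (i in 1:40) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    x <- round(rlnorm(n1, 3.8, 0.4), sample(0:1, 1))
    y <- round(rlnorm(n2, 3.6, 0.4), sample(0:1, 1))
    ours <- mann_whitney_u(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("U + U' = n1 n2 holds across random tied samples", {
  set.seed(17)
  for (i in 1:50) {
    n1 <- sample(1:12, 1); n2 <- sample(1:12, 1)
    x <- sample(1:6, n1, replace = TRUE)
    y <- sample(1:6, n2, replace = TRUE)
    res <- suppressWarnings(mann_whitney_u(x, y))
    expect_equal(res$U + res$U_prime, n1 * n2)
  }
})

test_that("summarize_times mirrors the per-person table layout", {
  recs <- tibble::tibble(
    period = c(rep("PRE", 6), rep("WITH", 6), "PRE"),
    checker_person_id = c(rep("A", 6), rep("A", 6), "G"),
    minutes = c(40, 45, 50, 55, 48, 50, 30, 32, 35, 38, 36, 40, 39))
  tab <- summarize_times(recs)
  a <- tab[tab$checker_person_id == "A", ]
  expect_identical(a$n_pre, 6L)
  expect_equal(a$ratio_mean, round_half_up(mean(c(30, 32, 35, 38, 36, 40)) /
                                             mean(c(40, 45, 50, 55, 48, 50)), 2))
  g <- tab[tab$checker_person_id == "G", ]
  expect_true(is.na(g$ratio_mean))       # present in only one period
  expect_true(is.na(g$p_value))
  overall <- tab[tab$checker_person_id == "Overall", ]
  expect_identical(overall$n_pre, 7L)
  single <- summarize_times(tibble::tibble(
    period = c("PRE", "WITH"), checker_person_id = "A", minutes = c(42, 42)))
  expect_equal(single$ratio_mean, c(1.00, 1.00))
})

test_that("printed period summaries give the published ratios", {
  r <- time_ratio_summary(49.4, 45, 39.3, 35)
  expect_equal(r$ratio_mean, 0.80)
  expect_equal(r$ratio_median, 0.78)
  expect_equal(r$pct_decrease_mean, 20)
})

test_that("table renderers handle empty, single-category and full inputs", {
  tax <- issue_taxonomy()
  one <- tibble::tibble(period = "PRE", category = tax$category[1])
  expect_match(build_table2(one, format = "text"), "Grand Total", all = FALSE)
  expect_match(build_table2(one, format = "csv")[1], "Category")
  full <- issue_records_from_counts(rep(1L, 17), rep(1L, 17))
  txt <- build_table2(full, format = "text", n_checks = c(PRE = 10, WITH = 10))
  expect_match(txt, "Number of plan checks", all = FALSE)
  t3 <- build_table3(tibble::tibble(
    period = rep(c("PRE", "WITH"), each = 4),
    checker_person_id = "A",
    minutes = c(40, 42, 44, 46, 30, 32, 34, 36)), format = "text")
  expect_match(t3[1], "Checker")
})
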