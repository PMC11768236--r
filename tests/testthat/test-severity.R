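# Serious vs non-serious comparison: test selection, chi-square variants,
# Fisher exact, Mann-Whitney.

N_SER <- 17955
N_NON <- 10541
published_sev <- read.delim(faersignal_extdata("canakinumab_severity.tsv"),
                            stringsAsFactors = FALSE)
sev_table <- function(a, c) contab(a, N_SER - a, c, N_NON - c)

test_that("the cell-size rule selects the published test for every row", {
  picked <- vapply(seq_len(nrow(published_sev)), function(i) {
    choose_test(sev_table(published_sev$n_serious[i], published_sev$n_nonserious[i]))
  }, character(1))
  expect_equal(picked, published_sev$test)
  # spot checks of the rule itself
  expect_equal(choose_test(sev_table(330, 3)), "yates")
  expect_equal(choose_test(sev_table(40, 0)), "fisher")
  expect_equal(choose_test(sev_table(10, 33)), "pearson")
})

test_that("Pearson and Yates statistics reproduce published values", {
  mal <- pearson_chi2(contab(246, 17709, 425, 10116))
  expect_equal(mal$statistic, 204.663, tolerance = 0.01 / 204)
  agg <- pearson_chi2(contab(361, 17594, 277, 10264))
  expect_equal(agg$statistic, 11.561, tolerance = 0.01 / 11.5)
  pneu <- yates_chi2(contab(330, 17625, 3, 10538))
  expect_equal(pneu$statistic, 186.728, tolerance = 0.01 / 186)
  deaf <- yates_chi2(contab(35, 17920, 1, 10540))
  expect_equal(deaf$statistic, 16.663, tolerance = 0.01 / 16.6)
  # proportional table has statistic 0; Yates clamps small deviations to 0
  expect_equal(pearson_chi2(contab(10, 90, 100, 900))$statistic, 0)
  expect_equal(yates_chi2(contab(10, 90, 100, 900))$statistic, 0)
  expect_equal(yates_chi2(contab(3, 3, 3, 3))$statistic, 0)
})

test_that("chi-square variants agree with stats::chisq.test on random tables", {
  set.seed(17)
  for (i in 1:20) {
    cells <- sample(1:300, 4, replace = TRUE)
    m <- matrix(c(cells[1], cells[3], cells[2], cells[4]), 2, 2)
    t <- contab(cells[1], cells[2], cells[3], cells[4])
    expect_equal(pearson_chi2(t)$statistic,
                 unname(suppressWarnings(chisq.test(m, correct = FALSE))$statistic))
    expect_equal(yates_chi2(t)$statistic,
                 unname(suppressWarnings(chisq.test(m, correct = TRUE))$statistic))
    expect_lte(yates_chi2(t)$statistic, pearson_chi2(t)$statistic)
  }
})

test_that("Fisher exact matches enumeration and published extremes", {
  expect_equal(fisher_exact(contab(3, 1, 1, 3)), 0.485714, tolerance = 1e-6)
  expect_equal(fisher_exact(contab(5, 5, 5, 5)), 1)
  expect_lt(fisher_exact(contab(40, 17915, 0, 10541)), 0.001)
  set.seed(19)
  for (i in 1:50) {
    cells <- as.vector(rmultinom(1, sample(4:30, 1), runif(4, 0.05, 1)))
    expect_equal(fisher_exact(contab(cells[1], cells[2], cells[3], cells[4])),
                 fisher_brute(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }
})

test_that("Mann-Whitney U, Z and p behave as documented", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$Z, -4.5 / sqrt(5.25), tolerance = 1e-9)

  same <- mann_whitney(c(1, 2, 2, 9), c(1, 2, 2, 9))
  expect_equal(same$Z, 0)
  expect_equal(same$p, 1)

  # U agrees with the reference implementation, with and without ties
  set.seed(3)
  for (i in 1:10) {
    x <- sample(1:20, 15, replace = TRUE); y <- sample(5:25, 12, replace = TRUE)
    expect_equal(mann_whitney(x, y)$U,
                 unname(suppressWarnings(wilcox.test(x, y))$statistic))
  }

  set.seed(9)
  x <- rnorm(500); y <- rnorm(500, mean = 1)
  expect_lt(mann_whitney(x, y)$p, 1e-6)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("the cohort comparison filters by count and finds planted severity", {
  set.seed(21)
  # PT "S" 90% serious, PT "T" independent of seriousness; "R" too rare
  n <- 1500
  serious <- runif(n) < 0.5
  has_s <- runif(n) < ifelse(serious, 0.12, 0.013)
  has_t <- runif(n) < 0.10
  has_r <- seq_len(n) <= 29
  events <- lapply(seq_len(n), function(i)
    c("S", "T", "R")[c(has_s[i], has_t[i], has_r[i])])
  cases <- make_cases(rep(TRUE, n), events, serious = serious)
  res <- compare_severity(cases, cases$demo$primaryid, min_count = 30)
  expect_false("R" %in% res$variable)   # 29 reports, below the floor
  expect_lt(res$p[res$variable == "S"], 0.05)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(c("age", "weight") %in% res$variable |
                    !"age" %in% res$variable))
})

test_that("planted 90%-serious PT is detected in at least 95% of replicates", {
  set.seed(21)
  hits <- 0
  for (r in 1:100) {
    n <- 1000
    serious <- runif(n) < 0.5
    has_x <- runif(n) < ifelse(serious, 0.11, 0.012)
    events <- lapply(has_x, function(h) if (h) "X" else character(0))
    cases <- make_cases(rep(TRUE, n), events, serious = serious)
    res <- compare_severity(cases, cases$demo$primaryid, min_count = 30)
    p <- res$p[res$variable == "X"]
    if (length(p) == 1 && p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("null PT rates give approximately uniform p-values", {
  set.seed(22)
  ps <- numeric(0)
  for (r in 1:500) {
    n <- 900
    serious <- runif(n) < 0.5
    has_x <- runif(n) < 0.15
    events <- lapply(has_x, function(h) if (h) "X" else character(0))
    cases <- make_cases(rep(TRUE, n), events, serious = serious)
    res <- compare_severity(cases, cases$demo$primaryid, min_count = 30)
    ps <- c(ps, res$p[res$variable == "X" & res$test == "pearson"])
  }
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
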