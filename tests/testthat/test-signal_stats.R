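# Disproportionality statistics: point estimates, intervals, shrinkage
# estimators, screening policies.

test_that("ROR point estimate and Wald interval match hand arithmetic", {
  r <- ror_estimate(contab(25, 75, 100, 900))
  expect_equal(r$ror, 3, tolerance = 1e-12)
  expect_equal(r$lo, 1.824, tolerance = 1e-3)
  expect_equal(r$hi, 4.934, tolerance = 1e-3)

  r2 <- ror_estimate(contab(3, 27, 10, 960))
  expect_equal(r2$ror, 10.667, tolerance = 1e-3)
  expect_equal(r2$lo, 2.777, tolerance = 1e-3)
  expect_equal(r2$hi, 40.97, tolerance = 1e-3)

  expect_equal(ror_estimate(contab(10, 90, 10, 90))$ror, 1)

  expect_error(ror_estimate(contab(0, 10, 10, 10)), "zero-cell")
  rc <- ror_estimate(contab(0, 10, 10, 10), continuity = TRUE)
  expect_equal(rc$ror, 0.5 * 10.5 / (10.5 * 10.5))
})

test_that("PRR and its Pearson chi-square match hand arithmetic", {
  p <- prr_estimate(contab(25, 75, 100, 900))
  expect_equal(p$prr, 2.5)
  expect_equal(p$chi2, 20.308, tolerance = 1e-3)

  p2 <- prr_estimate(contab(3, 27, 10, 960))
  expect_equal(p2$prr, 9.70, tolerance = 1e-3)
  expect_equal(p2$chi2, 18.244, tolerance = 1e-2)

  # proportional table: independence
  p3 <- prr_estimate(contab(10, 90, 100, 900))
  expect_equal(p3$prr, 1)
  expect_equal(p3$chi2, 0)
  expect_error(prr_estimate(contab(5, 5, 0, 10)), "zero-cell")
})

test_that("IC is near zero for independence-scaled tables", {
  ic <- bcpnn_ic(contab(10, 90, 90, 810))
  expect_lt(abs(ic$ic), 0.1)
  expect_lt(ic$ic025, 0)
  # large-N limit: observed/expected = 1
  ic2 <- bcpnn_ic(contab(1000, 9000, 9000, 81000))
  expect_lt(abs(ic2$ic), 0.05)
  expect_true(ic$ic025 <= ic$ic)
})

test_that("IC and IC025 sit inside the exact posterior's 99% band", {
  set.seed(31)
  t <- contab(25, 75, 100, 900)
  cf <- bcpnn_ic(t)
  d <- mc_ic_draws(t, ndraw = 2e5)
  band <- quantile(d$ic, c(0.005, 0.995))
  expect_gt(cf$ic, band[1]); expect_lt(cf$ic, band[2])
  expect_gt(cf$ic025, band[1]); expect_lt(cf$ic025, band[2])
  # closed form equals the log-ratio of posterior means it computes
  expect_lt(abs(cf$ic - d$ratio_of_means), 0.02)
})

test_that("EBGM shrinks toward 1 for huge expected counts and below 1 at a = 0", {
  big <- mgps_ebgm(10000, E = 10000)
  expect_lt(abs(big$ebgm - 1), 0.02)
  for (E in c(1, 2, 5, 10)) expect_lt(mgps_ebgm(0, E = E)$ebgm, 1)
})

test_that("EBGM and EBGM05 match quadrature of the posterior mixture", {
  got <- mgps_ebgm(25, E = 2.84)
  or <- mgps_quad_oracle(25, 2.84)
  expect_equal(got$ebgm, unname(or["ebgm"]), tolerance = 1e-3)
  expect_equal(got$ebgm05, unname(or["ebgm05"]), tolerance = 1e-3)
  # table form computes E = (a+b)(a+c)/N itself
  tb <- mgps_ebgm(contab(25, 75, 100, 900))
  expect_equal(tb$E, 100 * 125 / 1100)
})

test_that("prior fitting recovers the mixture weight from simulated pairs", {
  set.seed(5)
  n <- 5000
  E <- runif(n, 0.5, 20)
  comp <- runif(n) < 1 / 3
  lam <- ifelse(comp, rgamma(n, 0.2, 0.1), rgamma(n, 2, 4))
  a <- rpois(n, lam * E)
  pr <- fit_mgps_prior(a, E)
  expect_true(attr(pr, "converged"))
  expect_lt(abs(pr$w - 1 / 3), 0.1)
  # refitting from the fitted prior cannot decrease the log-likelihood
  pr2 <- fit_mgps_prior(a, E, start = pr)
  expect_gte(attr(pr2, "loglik") + 1e-6, attr(pr, "loglik"))
})

test_that("single-component data drives the weight to the boundary, flagged", {
  set.seed(8)
  n <- 2000
  E <- runif(n, 1, 10)
  a <- rpois(n, rgamma(n, 2, 4) * E)   # second component only
  pr <- suppressWarnings(fit_mgps_prior(a, E))
  expect_true(attr(pr, "boundary") || pr$w < 0.05 || pr$w > 0.95)
})

test_that("monotonicity: moving a report from b to a increases every statistic", {
  set.seed(41)
  for (i in 1:25) {
    cells <- sample(5:200, 4, replace = TRUE)
    t1 <- contab(cells[1], cells[2], cells[3], cells[4])
    t2 <- contab(cells[1] + 1, cells[2] - 1, cells[3], cells[4])
    expect_gt(ror_estimate(t2)$ror, ror_estimate(t1)$ror)
    expect_gt(prr_estimate(t2)$prr, prr_estimate(t1)$prr)
    expect_gt(bcpnn_ic(t2)$ic, bcpnn_ic(t1)$ic)
    expect_gt(mgps_ebgm(t2)$ebgm, mgps_ebgm(t1)$ebgm)
    # ROR >= PRR whenever the exposed event proportion is the larger one
    if (cells[1] / (cells[1] + cells[2]) >= cells[3] / (cells[3] + cells[4])) {
      expect_gte(ror_estimate(t1)$ror, prr_estimate(t1)$prr)
    }
  }
})

test_that("signal flags implement the four-algorithm criteria and bands", {
  # a = 2 blocks the frequentist flags regardless of magnitude
  m <- evaluate_signal(contab(2, 8, 10, 2000))
  expect_false(m$flag_ror); expect_false(m$flag_prr)

  m2 <- evaluate_signal(contab(25, 75, 100, 900))
  expect_true(m2$flag_ror)   # lower CI 1.824 > 1

  expect_equal(faersignal:::ic_band(2.0), "medium")
  expect_equal(faersignal:::ic_band(3.5), "strong")
  expect_equal(faersignal:::ic_band(1.2), "none")

  # policy aggregation
  all4 <- evaluate_signal(contab(200, 800, 200, 8000), signal_config("all4"))
  any1 <- evaluate_signal(contab(200, 800, 200, 8000), signal_config("any1"))
  expect_equal(all4$signal, with(all4, flag_ror && flag_prr && flag_bcpnn && flag_mgps))
  expect_equal(any1$signal, with(any1, flag_ror || flag_prr || flag_bcpnn || flag_mgps))

  # zero-cell tables degrade to NA frequentist statistics, flags FALSE
  z <- evaluate_signal(contab(5, 5, 0, 100))
  expect_true(is.na(z$ror) && !z$flag_ror)
})

test_that("screening flags a strongly planted pair and respects min count", {
  cfg <- synth_config(
    n_reports = 20000, seed = 13,
    planted_effects = data.frame(pt = "Pneumonia", rr = 8, male_mult = 1,
                                 age60_mult = 1, wt100_mult = 1,
                                 stringsAsFactors = FALSE))
  d <- synth_draw(cfg)
  cases <- normalize_cases(faers_dedup(d$tables))
  part <- select_target_reports(cases, c("canakinumab", "ilaris"))
  cat <- synth_pt_catalog()
  ann <- structure(list(pt_to_soc = setNames(cat$soc, cat$pt),
                        dme = character(0), ime = character(0),
                        evidence = setNames(character(0), character(0))),
                   class = "faers_annotation")
  scr <- screen_signals(cases, part$exposed, ann)
  row <- scr[scr$term == "Pneumonia", ]
  expect_true(row$flag_ror && row$flag_prr && row$flag_bcpnn && row$flag_mgps)
  expect_true(row$signal)
  expect_true(all(scr$a >= 3))
  expect_true(all(scr$deaths <= scr$a))
  # sorted by SOC, descending ROR within SOC
  expect_false(is.unsorted(scr$soc))
  for (s in unique(scr$soc)) {
    expect_false(is.unsorted(-scr$ror[scr$soc == s]))
  }

  # empty exposed set: empty output
  expect_equal(nrow(screen_signals(cases, character(0))), 0)
})

test_that("SOC-level screening uses report-once counting and the any1 policy", {
  cfg <- synth_config(n_reports = 8000, seed = 14)
  d <- synth_draw(cfg)
  cases <- normalize_cases(faers_dedup(d$tables))
  part <- select_target_reports(cases, c("canakinumab", "ilaris"))
  cat <- synth_pt_catalog()
  ann <- structure(list(pt_to_soc = setNames(cat$soc, cat$pt),
                        dme = character(0), ime = character(0),
                        evidence = setNames(character(0), character(0))),
                   class = "faers_annotation")
  scr <- screen_signals(cases, part$exposed, ann, level = "soc")
  inf <- scr[scr$term == "Infections and infestations", ]
  # report counted once even with several infection PTs
  ids <- event_reports(cases, "Infections and infestations", "soc", ann)
  expect_equal(inf$a + inf$c, length(ids))
})
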