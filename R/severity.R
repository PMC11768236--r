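# Serious vs non-serious comparison: per-PT 2x2 tests with a cell-size
# driven choice of Pearson chi-square, Yates-corrected chi-square, or
# Fisher's exact test, plus Mann-Whitney U for age and body weight.

#' Choose the 2x2 test from observed PT-cell sizes
#'
#' The table compares PT occurrence between serious and non-serious reports:
#' `(a, c)` are the with-PT cells in the two groups. Any with-PT cell of 0
#' selects Fisher's exact test; any with-PT cell in 1-4 the Yates-corrected
#' chi-square; otherwise the Pearson chi-square.
#'
#' @param t A [contab()] or numeric `c(a, b, c, d)` with `a` = serious
#'   reports with the PT and `c` = non-serious reports with the PT.
#' @return `"pearson"`, `"yates"` or `"fisher"`.
#' @export
choose_test <- function(t) {
  t <- as_contab(t)
  cells <- c(t$a, t$c)
  if (any(cells == 0)) "fisher" else if (any(cells < 5)) "yates" else "pearson"
}

#' Pearson chi-square test for a 2x2 table
#'
#' Statistic `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` (shared with
#' [prr_estimate()]), p-value from the chi-square distribution on 1 df.
#'
#' @param t A [contab()] or numeric `c(a, b, c, d)`.
#' @return List with `statistic`, `p`.
#' @export
pearson_chi2 <- function(t) {
  t <- as_contab(t)
  stat <- chi2_stat(t$a, t$b, t$c, t$d, yates = FALSE)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Yates continuity-corrected chi-square test
#'
#' Statistic `N (max(|ad - bc| - N/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d))`,
#' clamped at zero, p-value on 1 df.
#'
#' @param t A [contab()] or numeric `c(a, b, c, d)`.
#' @return List with `statistic`, `p`.
#' @export
yates_chi2 <- function(t) {
  t <- as_contab(t)
  stat <- chi2_stat(t$a, t$b, t$c, t$d, yates = TRUE)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fisher's exact test (two-sided) for a 2x2 table
#'
#' Two-sided p-value summing, over the hypergeometric distribution with the
#' observed margins fixed, the probabilities of all tables no more probable
#' than the observed one.
#'
#' @param t A [contab()] or numeric `c(a, b, c, d)`.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(t) {
  t <- as_contab(t)
  m <- matrix(c(t$a, t$c, t$b, t$d), 2, 2)
  stats::fisher.test(m)$p.value
}

#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' U is computed from rank sums using midranks for ties; the two-sided
#' p-value comes from `Z = (U - n1 n2 / 2) / sigma` with the tie-corrected
#' standard deviation, without continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `U` (for the first sample), `Z`, `p`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = u, Z = 0, p = 1))
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  list(U = u, Z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare serious and non-serious reports within the exposed cohort
#'
#' Partitions the exposed reports by the serious flag and, for every PT with
#' total count at least `min_count`, tests the difference in reporting
#' proportion with the test chosen by [choose_test()]. Adds Mann-Whitney
#' rows for age and body weight (reports with the field present only) and
#' Pearson chi-square rows for each sex.
#'
#' @param cases A `faers_cases` object.
#' @param exposed_ids Exposed report ids.
#' @param min_count Minimum total PT count (default 30).
#' @return data.frame with columns `variable`, `kind`, `n_serious`,
#'   `n_nonserious`, `pct_serious`, `pct_nonserious`, `test`, `statistic`,
#'   `p`.
#' @export
compare_severity <- function(cases, exposed_ids, min_count = 30) {
  demo <- cases$demo[cases$demo$primaryid %in% exposed_ids, , drop = FALSE]
  n_ser <- sum(demo$serious)
  n_non <- sum(!demo$serious)
  if (n_ser == 0 || n_non == 0) stop("need both serious and non-serious reports")
  ser_ids <- demo$primaryid[demo$serious]
  non_ids <- demo$primaryid[!demo$serious]
  ev <- cases$events[cases$events$primaryid %in% demo$primaryid, , drop = FALSE]

  row_for <- function(variable, kind, a, c) {
    t <- contab(a, n_ser - a, c, n_non - c)
    test <- choose_test(t)
    res <- switch(test,
                  pearson = pearson_chi2(t),
                  yates = yates_chi2(t),
                  fisher = list(statistic = NA_real_, p = fisher_exact(t)))
    data.frame(variable = variable, kind = kind, n_serious = a,
               n_nonserious = c, pct_serious = 100 * a / n_ser,
               pct_nonserious = 100 * c / n_non, test = test,
               statistic = res$statistic, p = res$p, stringsAsFactors = FALSE)
  }

  out <- list()
  for (sx in c("female", "male")) {
    out[[length(out) + 1L]] <- row_for(
      sx, "sex", sum(demo$sex[demo$serious] == sx),
      sum(demo$sex[!demo$serious] == sx))
  }
  for (v in c("age_years", "weight_kg")) {
    xs <- demo[[v]][demo$serious]
    ys <- demo[[v]][!demo$serious]
    if (sum(!is.na(xs)) > 0 && sum(!is.na(ys)) > 0) {
      mw <- mann_whitney(xs, ys)
      out[[length(out) + 1L]] <- data.frame(
        variable = if (v == "age_years") "age" else "weight",
        kind = "continuous", n_serious = sum(!is.na(xs)),
        n_nonserious = sum(!is.na(ys)), pct_serious = NA_real_,
        pct_nonserious = NA_real_, test = "mann_whitney",
        statistic = mw$Z, p = mw$p, stringsAsFactors = FALSE)
    }
  }
  counts <- table(ev$pt)
  pts <- names(counts)[counts >= min_count]
  for (pt in pts) {
    ids <- ev$primaryid[ev$pt == pt]
    out[[length(out) + 1L]] <- row_for(pt, "pt", sum(ids %in% ser_ids),
                                       sum(ids %in% non_ids))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
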