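# Time-to-onset (TTO) analysis: onset day = event date minus therapy start
# date, Weibull maximum likelihood on the retained days, and failure-type
# classification from the shape parameter and its confidence interval.

#' Compute time-to-onset days for a cohort
#'
#' TTO is the event date minus the therapy start date, in days. Reports with
#' either date missing are excluded (counted in `n_excluded_missing`, which
#' also covers partial dates when `exclude_partial` is on, since a
#' year-or-month precision date cannot support day arithmetic). Input errors
#' — event date on or before the therapy start — are excluded and counted in
#' `n_excluded_negative`. Days beyond the observation window (default one
#' year) are excluded and counted in `n_excluded_window`.
#'
#' @param cases A `faers_cases` object.
#' @param exposed_ids Exposed report ids.
#' @param pts Optional PT filter: keep only reports listing at least one of
#'   these terms.
#' @param window Cap in days (`NULL` or `Inf` disables it).
#' @param exclude_partial Drop reports whose dates were completed from
#'   partial YYYYMM / YYYY values.
#' @return A `tto_sample`: list with `days`, the exclusion counters and the
#'   window.
#' @export
compute_tto <- function(cases, exposed_ids, pts = NULL, window = 365,
                        exclude_partial = TRUE) {
  demo <- cases$demo[cases$demo$primaryid %in% exposed_ids, , drop = FALSE]
  if (!is.null(pts)) {
    ev <- cases$events
    keep <- unique(ev$primaryid[ev$pt %in% pts])
    demo <- demo[demo$primaryid %in% keep, , drop = FALSE]
  }
  missing <- is.na(demo$event_date) | is.na(demo$therapy_start)
  if (exclude_partial) {
    missing <- missing | demo$event_date_partial | demo$therapy_start_partial
  }
  days <- as.numeric(demo$event_date - demo$therapy_start)
  neg <- !missing & days <= 0
  if (is.null(window) || !is.finite(window)) window <- Inf
  over <- !missing & !neg & days > window
  keep <- !missing & !neg & !over
  structure(list(days = days[keep],
                 n_excluded_missing = sum(missing),
                 n_excluded_negative = sum(neg),
                 n_excluded_window = sum(over),
                 window = window),
            class = "tto_sample")
}

as_tto_days <- function(x) {
  if (inherits(x, "tto_sample")) x$days else as.numeric(x)
}

#' Weibull maximum likelihood fit of a TTO sample
#'
#' The shape beta solves the profile likelihood equation
#' `sum(t^b log t) / sum(t^b) - 1/b - mean(log t) = 0` by safeguarded
#' Newton iteration (bisection fallback) on the bracket `[0.01, 50]` to
#' tolerance 1e-8; the scale is then `alpha = (sum(t^b)/n)^(1/b)`. 95%
#' confidence intervals come from the observed information matrix on the
#' `(log alpha, log beta)` scale (normal approximation), and the fit is
#' classified with [classify_failure()].
#'
#' @param sample A `tto_sample` from [compute_tto()] or a numeric vector of
#'   positive days.
#' @param min_distinct Minimum number of distinct values required.
#' @return A `weibull_fit`: `alpha`, `alpha_ci`, `beta`, `beta_ci`,
#'   `loglik`, `n`, `failure_type`.
#' @export
weibull_mle <- function(sample, min_distinct = 10) {
  t <- as_tto_days(sample)
  t <- t[!is.na(t)]
  if (any(t <= 0)) stop("TTO days must be positive")
  n <- length(t)
  if (length(unique(t)) < min_distinct) {
    if (length(unique(t)) == 1L) stop("degenerate sample: all values identical")
    stop("need at least ", min_distinct, " distinct TTO values")
  }
  lt <- log(t)
  mlt <- mean(lt)
  g <- function(b) {
    w <- t^b
    sum(w * lt) / sum(w) - 1 / b - mlt
  }
  lo <- 0.01; hi <- 50
  glo <- g(lo); ghi <- g(hi)
  if (is.na(glo) || is.na(ghi) || glo * ghi > 0) {
    stop("shape root not bracketed in [0.01, 50]")
  }
  b <- 1.2825 / sqrt(max(sum(lt^2) / n - mlt^2, 1e-12))  # moment start
  b <- min(max(b, lo), hi)
  for (i in 1:100) {
    gb <- g(b)
    if (abs(gb) < 1e-12) break
    if (gb > 0) hi <- b else lo <- b  # g is increasing in b
    eps <- 1e-6 * max(b, 1)
    deriv <- (g(b + eps) - gb) / eps
    b_new <- if (is.finite(deriv) && deriv != 0) b - gb / deriv else NA
    if (is.na(b_new) || b_new <= lo || b_new >= hi) b_new <- (lo + hi) / 2
    if (abs(b_new - b) < 1e-8) { b <- b_new; break }
    b <- b_new
  }
  beta <- b
  alpha <- (sum(t^beta) / n)^(1 / beta)

  loglik_fn <- function(par) {
    al <- exp(par[1]); be <- exp(par[2])
    sum(stats::dweibull(t, shape = be, scale = al, log = TRUE))
  }
  par <- c(log(alpha), log(beta))
  ll <- loglik_fn(par)
  h <- stats::optimHess(par, function(p) -loglik_fn(p))
  cov <- tryCatch(solve(h), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(cov), 0))
  alpha_ci <- alpha * exp(c(-1, 1) * 1.96 * se[1])
  beta_ci <- beta * exp(c(-1, 1) * 1.96 * se[2])
  structure(list(alpha = alpha, alpha_ci = alpha_ci, beta = beta,
                 beta_ci = beta_ci, loglik = ll, n = n,
                 failure_type = classify_failure(beta, beta_ci[1], beta_ci[2])),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull fit (n = %d): alpha %.2f (%.2f-%.2f), beta %.3f (%.3f-%.3f), %s\n",
              x$n, x$alpha, x$alpha_ci[1], x$alpha_ci[2],
              x$beta, x$beta_ci[1], x$beta_ci[2], x$failure_type))
  invisible(x)
}

#' Classify the Weibull failure profile
#'
#' Early failure (risk decreasing over time) when the shape and its entire
#' 95% CI lie below 1; wear-out (risk increasing) when both lie above 1;
#' random failure otherwise.
#'
#' @param beta Shape estimate, or a `weibull_fit`.
#' @param lo,hi CI bounds (ignored when `beta` is a fit).
#' @return `"early"`, `"random"` or `"wear_out"`.
#' @export
classify_failure <- function(beta, lo = NULL, hi = NULL) {
  if (inherits(beta, "weibull_fit")) {
    lo <- beta$beta_ci[1]; hi <- beta$beta_ci[2]; beta <- beta$beta
  }
  if (beta < 1 && hi < 1) "early"
  else if (beta > 1 && lo > 1) "wear_out"
  else "random"
}

#' Median and interquartile range of a TTO sample
#'
#' Quantiles use linear interpolation (type 7), the convention the IQR
#' values depend on.
#'
#' @param sample A `tto_sample` or numeric vector.
#' @return List with `median`, `q1`, `q3`, `n`.
#' @export
tto_summary <- function(sample) {
  t <- as_tto_days(sample)
  t <- t[!is.na(t)]
  if (length(t) == 0) stop("empty TTO sample")
  q <- stats::quantile(t, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], n = length(t))
}
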