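# Four-algorithm disproportionality statistics for 2x2 report tables:
# reporting odds ratio (ROR), proportional reporting ratio (PRR) with a
# Pearson chi-square, the BCPNN information component (IC), and the
# multi-item gamma Poisson shrinker (MGPS) EBGM.

# Single source of truth for the 2x2 chi-square statistic; also used by the
# serious-vs-non-serious comparison. `yates` applies the continuity
# correction max(|ad - bc| - N/2, 0).
chi2_stat <- function(a, b, c, d, yates = FALSE) {
  n <- a + b + c + d
  m <- c(a + b, c + d, a + c, b + d)
  if (any(m == 0)) stop("chi-square undefined: zero margin")
  dev <- abs(a * d - b * c)
  if (yates) dev <- max(dev - n / 2, 0)
  n * dev^2 / prod(m)
}

#' Reporting odds ratio with 95% Wald interval
#'
#' `ROR = ad / bc`, with the confidence interval
#' `exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))` on the log scale.
#' Any zero cell makes the estimate undefined; the default is to refuse,
#' with an optional Haldane–Anscombe continuity correction adding 0.5 to
#' every cell.
#'
#' @param t A [contab()] or numeric `c(a, b, c, d)`.
#' @param continuity Apply the +0.5 correction to zero-cell tables.
#' @return List with `ror`, `lo`, `hi`.
#' @examples
#' ror_estimate(contab(25, 75, 100, 900))
#' @export
ror_estimate <- function(t, continuity = FALSE) {
  t <- as_contab(t)
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) {
    if (!continuity) stop("zero-cell: ROR undefined (set continuity = TRUE for +0.5 correction)")
    cells <- cells + 0.5
  }
  ror <- cells[1] * cells[4] / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  list(ror = ror, lo = ror * exp(-1.96 * se), hi = ror * exp(1.96 * se))
}

#' Proportional reporting ratio with Pearson chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the accompanying statistic is the Pearson
#' chi-square `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` without continuity
#' correction.
#'
#' @param t A [contab()] or numeric `c(a, b, c, d)`.
#' @return List with `prr`, `chi2`.
#' @export
prr_estimate <- function(t) {
  t <- as_contab(t)
  if ((t$a + t$b) == 0 || (t$c + t$d) == 0 || t$c == 0) {
    stop("zero-cell: PRR undefined")
  }
  prr <- (t$a / (t$a + t$b)) / (t$c / (t$c + t$d))
  list(prr = prr, chi2 = chi2_stat(t$a, t$b, t$c, t$d))
}

#' BCPNN prior pseudo-counts
#'
#' Defaults follow the original Bayesian confidence propagation neural
#' network specification: uniform Beta(1, 1) priors on the drug and event
#' margins (`alpha1 = beta1 = 1`, totals `alpha = beta = 2`) and a joint
#' pseudo-count `gamma11 = 1`, with the joint total `gamma` tied to the data
#' so that the prior IC expectation is zero.
#'
#' @param alpha1,alpha,beta1,beta,gamma11 Positive pseudo-counts.
#' @return A `bcpnn_priors` list.
#' @export
bcpnn_priors <- function(alpha1 = 1, alpha = 2, beta1 = 1, beta = 2, gamma11 = 1) {
  p <- list(alpha1 = alpha1, alpha = alpha, beta1 = beta1, beta = beta,
            gamma11 = gamma11)
  stopifnot(all(unlist(p) > 0))
  structure(p, class = "bcpnn_priors")
}

#' BCPNN information component
#'
#' Closed-form posterior expectation and variance of the information
#' component `IC = log2 p11 / (p1. p.1)` under the BCPNN Beta model. With
#' `gamma = gamma11 (N+alpha)(N+beta) / ((a+b+alpha1)(a+c+beta1))`:
#'
#' `E(IC) = log2[(a+gamma11)(N+alpha)(N+beta) / ((N+gamma)(a+b+alpha1)(a+c+beta1))]`
#'
#' and `V(IC)` is the standard three-term expression on the log-2 scale. The
#' lower credibility bound is `ic025 = E(IC) - z sqrt(V(IC))` with
#' `z = 1.96` by default (a 2.0 variant is available).
#'
#' @param t A [contab()] or numeric `c(a, b, c, d)`.
#' @param priors A [bcpnn_priors()].
#' @param z Multiplier for the lower bound.
#' @return List with `ic`, `ic025`, `var`.
#' @export
bcpnn_ic <- function(t, priors = bcpnn_priors(), z = 1.96) {
  t <- as_contab(t)
  if (t$n <= 0) stop("empty table")
  a <- t$a; n <- t$n
  row1 <- t$a + t$b; col1 <- t$a + t$c
  p <- priors
  gamma <- p$gamma11 * (n + p$alpha) * (n + p$beta) /
    ((row1 + p$alpha1) * (col1 + p$beta1))
  ic <- log2((a + p$gamma11) * (n + p$alpha) * (n + p$beta) /
               ((n + gamma) * (row1 + p$alpha1) * (col1 + p$beta1)))
  v <- ((n - a + gamma - p$gamma11) / ((a + p$gamma11) * (1 + n + gamma)) +
          (n - row1 + p$alpha - p$alpha1) / ((row1 + p$alpha1) * (1 + n + p$alpha)) +
          (n - col1 + p$beta - p$beta1) / ((col1 + p$beta1) * (1 + n + p$beta))) /
    log(2)^2
  list(ic = ic, ic025 = ic - z * sqrt(v), var = v)
}

#' MGPS gamma-mixture prior
#'
#' Two-component gamma prior on the relative reporting rate lambda, with
#' shape/rate pairs `(a1, b1)` and `(a2, b2)` and mixture weight `w` on the
#' first component. The defaults are the classic gamma Poisson shrinker
#' values `a1 = 0.2, b1 = 0.1, a2 = 2, b2 = 4, w = 1/3`.
#'
#' @param a1,b1,a2,b2 Positive shape/rate parameters.
#' @param w Mixture weight in (0, 1).
#' @return An `mgps_prior` list.
#' @export
mgps_prior <- function(a1 = 0.2, b1 = 0.1, a2 = 2, b2 = 4, w = 1 / 3) {
  stopifnot(a1 > 0, b1 > 0, a2 > 0, b2 > 0, w > 0, w < 1)
  structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, w = w),
            class = "mgps_prior")
}

# Posterior mixture for lambda given observed count a and expected count E:
# components Gamma(a1 + a, b1 + E) and Gamma(a2 + a, b2 + E), with weight
# Q = w f1 / (w f1 + (1 - w) f2) where f_k is the negative-binomial marginal.
mgps_posterior <- function(a, E, prior) {
  lf1 <- stats::dnbinom(a, size = prior$a1, prob = prior$b1 / (prior$b1 + E), log = TRUE)
  lf2 <- stats::dnbinom(a, size = prior$a2, prob = prior$b2 / (prior$b2 + E), log = TRUE)
  lw <- c(log(prior$w) + lf1, log(1 - prior$w) + lf2)
  q <- exp(lw[1] - max(lw)) / sum(exp(lw - max(lw)))
  list(q = q, shape = c(prior$a1 + a, prior$a2 + a), rate = c(prior$b1 + E, prior$b2 + E))
}

#' Empirical Bayes geometric mean (MGPS)
#'
#' Given an observed count `a` and expected count `E = (a+b)(a+c)/N`, the
#' posterior over the relative reporting rate is a two-component gamma
#' mixture. `EBGM = exp(E[log lambda])` uses the digamma closed form for
#' each component; `EBGM05` is the posterior 5th percentile, solved by
#' bisection on the mixture CDF to absolute tolerance 1e-6.
#'
#' @param t A [contab()], numeric `c(a, b, c, d)`, or the observed count `a`
#'   (then `E` must be supplied).
#' @param E Expected count (ignored when `t` is a table).
#' @param prior An [mgps_prior()].
#' @return List with `ebgm`, `ebgm05`, `q` (posterior weight of the first
#'   component) and `E`.
#' @export
mgps_ebgm <- function(t, E = NULL, prior = mgps_prior()) {
  if (is.numeric(t) && length(t) == 1L) {
    a <- t
    if (is.null(E)) stop("E required when passing a bare count")
  } else {
    t <- as_contab(t)
    if (t$n <= 0) stop("empty table")
    a <- t$a
    E <- (t$a + t$b) * (t$a + t$c) / t$n
  }
  if (!is.finite(E) || E <= 0) stop("expected count must be positive")
  post <- mgps_posterior(a, E, prior)
  elog <- post$q * (digamma(post$shape[1]) - log(post$rate[1])) +
    (1 - post$q) * (digamma(post$shape[2]) - log(post$rate[2]))
  ebgm <- exp(elog)
  cdf <- function(x) {
    post$q * stats::pgamma(x, post$shape[1], post$rate[1]) +
      (1 - post$q) * stats::pgamma(x, post$shape[2], post$rate[2])
  }
  lo <- 0; hi <- max(ebgm, 1)
  while (cdf(hi) < 0.05) {
    hi <- hi * 2
    if (hi > 1e12) stop("bisection failed to bracket the 5th percentile")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < 0.05) lo <- mid else hi <- mid
    if (hi - lo < 1e-6) break
  }
  if (hi - lo >= 1e-6) stop("bisection did not converge")
  list(ebgm = ebgm, ebgm05 = (lo + hi) / 2, q = post$q, E = E)
}

#' Fit the MGPS prior by marginal maximum likelihood
#'
#' Maximizes the negative-binomial-mixture marginal likelihood of observed
#' counts given their expected counts over `(a1, b1, a2, b2, w)`, using
#' box-constrained quasi-Newton (`L-BFGS-B`) on log / logit transformed
#' parameters from the default start. On optimizer failure the default prior
#' is returned with `converged = FALSE`.
#'
#' @param a Observed counts.
#' @param E Expected counts (same length).
#' @param start Starting [mgps_prior()].
#' @return An [mgps_prior()] with attributes `loglik`, `converged`, and
#'   `boundary` (TRUE when the fitted weight sits at the 0/1 edge).
#' @export
fit_mgps_prior <- function(a, E, start = mgps_prior()) {
  stopifnot(length(a) == length(E), all(E > 0))
  if (length(a) < 50) warning("fewer than 50 pairs: prior fit may be unstable")
  negll <- function(par) {
    a1 <- exp(par[1]); b1 <- exp(par[2]); a2 <- exp(par[3]); b2 <- exp(par[4])
    w <- stats::plogis(par[5])
    lf1 <- stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE)
    lf2 <- stats::dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE)
    m <- pmax(lf1, lf2)
    -sum(m + log(w * exp(lf1 - m) + (1 - w) * exp(lf2 - m)))
  }
  par0 <- c(log(start$a1), log(start$b1), log(start$a2), log(start$b2),
            stats::qlogis(start$w))
  fit <- tryCatch(
    stats::optim(par0, negll, method = "L-BFGS-B",
                 lower = c(rep(log(1e-4), 4), stats::qlogis(1e-4)),
                 upper = c(rep(log(1e4), 4), stats::qlogis(1 - 1e-4)),
                 control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) {
    out <- start
    attr(out, "loglik") <- -negll(par0)
    attr(out, "converged") <- FALSE
    attr(out, "boundary") <- FALSE
    warning("MGPS prior fit failed; returning the starting prior")
    return(out)
  }
  w <- stats::plogis(fit$par[5])
  out <- mgps_prior(exp(fit$par[1]), exp(fit$par[2]), exp(fit$par[3]),
                    exp(fit$par[4]), w)
  attr(out, "loglik") <- -fit$value
  attr(out, "converged") <- fit$convergence == 0
  attr(out, "boundary") <- w < 0.01 || w > 0.99
  out
}

#' Signal-evaluation configuration
#'
#' Thresholds and policies for the four-algorithm screen. The per-algorithm
#' criteria are: ROR, `a >= min_a` and lower CI > 1; PRR, `a >= min_a`,
#' `PRR >= 2` and chi-square >= 4; BCPNN, `IC025 > 0`; MGPS, `EBGM05 > 2`.
#' Policy `"all4"` (PT-level screening) requires every criterion; `"any1"`
#' (SOC-level screening) any one.
#'
#' @param policy `"all4"` or `"any1"`.
#' @param min_a Minimum observed count for the frequentist criteria.
#' @param prr_min,chi2_min,ebgm05_min,ic025_min Thresholds.
#' @param continuity Apply +0.5 correction to zero-cell tables instead of
#'   returning `NA` for ROR/PRR.
#' @param bcpnn A [bcpnn_priors()].
#' @param mgps An [mgps_prior()].
#' @param z_ic Multiplier for the IC lower bound.
#' @return A `signal_config` list.
#' @export
signal_config <- function(policy = c("all4", "any1"), min_a = 3,
                          prr_min = 2, chi2_min = 4, ebgm05_min = 2,
                          ic025_min = 0, continuity = FALSE,
                          bcpnn = bcpnn_priors(), mgps = mgps_prior(),
                          z_ic = 1.96) {
  policy <- match.arg(policy)
  structure(list(policy = policy, min_a = min_a, prr_min = prr_min,
                 chi2_min = chi2_min, ebgm05_min = ebgm05_min,
                 ic025_min = ic025_min, continuity = continuity,
                 bcpnn = bcpnn, mgps = mgps, z_ic = z_ic),
            class = "signal_config")
}

# IC strength band: strong above 3.0, medium in (1.5, 3.0], otherwise none.
ic_band <- function(ic025) {
  if (is.na(ic025)) return(NA_character_)
  if (ic025 > 3.0) "strong" else if (ic025 > 1.5) "medium" else "none"
}

#' Evaluate all four algorithms on one table
#'
#' Computes ROR (with CI), PRR (with chi-square), IC (with IC025) and EBGM
#' (with EBGM05), the per-algorithm signal flags, the aggregate signal under
#' the configured policy, and the IC strength band. Zero-cell tables yield
#' `NA` for the undefined frequentist statistics (flags FALSE) unless the
#' continuity option is on.
#'
#' @param t A [contab()] or numeric `c(a, b, c, d)`.
#' @param config A [signal_config()].
#' @return A one-row data.frame of metrics and flags.
#' @export
evaluate_signal <- function(t, config = signal_config()) {
  t <- as_contab(t)
  ror <- tryCatch(ror_estimate(t, continuity = config$continuity),
                  error = function(e) list(ror = NA_real_, lo = NA_real_, hi = NA_real_))
  prr <- tryCatch(prr_estimate(t),
                  error = function(e) list(prr = NA_real_, chi2 = NA_real_))
  ic <- tryCatch(bcpnn_ic(t, config$bcpnn, z = config$z_ic),
                 error = function(e) list(ic = NA_real_, ic025 = NA_real_))
  eb <- tryCatch(mgps_ebgm(t, prior = config$mgps),
                 error = function(e) list(ebgm = NA_real_, ebgm05 = NA_real_))
  f_ror <- isTRUE(t$a >= config$min_a && !is.na(ror$lo) && ror$lo > 1)
  f_prr <- isTRUE(t$a >= config$min_a && !is.na(prr$prr) &&
                    prr$prr >= config$prr_min && prr$chi2 >= config$chi2_min)
  f_bcpnn <- isTRUE(!is.na(ic$ic025) && ic$ic025 > config$ic025_min)
  f_mgps <- isTRUE(!is.na(eb$ebgm05) && eb$ebgm05 > config$ebgm05_min)
  flags <- c(f_ror, f_prr, f_bcpnn, f_mgps)
  data.frame(a = t$a, b = t$b, c = t$c, d = t$d,
             ror = ror$ror, ror_lo = ror$lo, ror_hi = ror$hi,
             prr = prr$prr, chi2 = prr$chi2,
             ic = ic$ic, ic025 = ic$ic025,
             ebgm = eb$ebgm, ebgm05 = eb$ebgm05,
             flag_ror = f_ror, flag_prr = f_prr,
             flag_bcpnn = f_bcpnn, flag_mgps = f_mgps,
             signal = if (config$policy == "all4") all(flags) else any(flags),
             ic_band = ic_band(ic$ic025),
             stringsAsFactors = FALSE)
}

#' Screen all PT or SOC terms for disproportionality signals
#'
#' Builds the 2x2 table of every term with at least `config$min_a` exposed
#' reports and evaluates the four algorithms. PT-level screening defaults to
#' the `"all4"` policy, SOC-level to `"any1"`. Death counts among the `a`
#' exposed reports are included (input to clinical-priority scoring). Rows
#' are sorted by SOC then descending ROR.
#'
#' @param cases A `faers_cases` object.
#' @param exposed_ids Exposed report ids.
#' @param annotation Optional `faers_annotation` (required for SOC level;
#'   at PT level adds `soc` columns).
#' @param level `"pt"` or `"soc"`.
#' @param config A [signal_config()]; when omitted, the level's default
#'   policy is used.
#' @return data.frame, one row per screened term.
#' @export
screen_signals <- function(cases, exposed_ids, annotation = NULL,
                           level = c("pt", "soc"), config = NULL) {
  level <- match.arg(level)
  if (is.null(config)) {
    config <- signal_config(policy = if (level == "pt") "all4" else "any1")
  }
  demo <- cases$demo
  ev <- cases$events
  if (level == "soc") {
    if (is.null(annotation)) stop("SOC-level screening needs an annotation")
    soc <- annotation$pt_to_soc[ev$pt]
    soc[is.na(soc)] <- "UNMAPPED"
    ev <- unique(data.frame(primaryid = ev$primaryid, pt = soc,
                            stringsAsFactors = FALSE))
  }
  is_exp <- demo$primaryid %in% exposed_ids
  n_exp <- sum(is_exp)
  n_tot <- nrow(demo)
  if (n_exp == 0 || nrow(ev) == 0) {
    return(data.frame(level = character(0), soc = character(0),
                      term = character(0)))
  }
  ev_exp <- ev$primaryid %in% demo$primaryid[is_exp]
  a_tab <- table(ev$pt[ev_exp])
  tot_tab <- table(ev$pt)
  terms <- names(a_tab)[a_tab >= config$min_a]
  if (length(terms) == 0) {
    return(data.frame(level = character(0), soc = character(0),
                      term = character(0)))
  }
  death_ids <- demo$primaryid[demo$death & is_exp]
  rows <- lapply(terms, function(tm) {
    a <- as.integer(a_tab[[tm]])
    ac <- as.integer(tot_tab[[tm]])
    t <- contab(a, n_exp - a, ac - a, n_tot - n_exp - (ac - a))
    m <- evaluate_signal(t, config)
    m$term <- tm
    m$deaths <- sum(ev$primaryid[ev_exp & ev$pt == tm] %in% death_ids)
    m
  })
  out <- do.call(rbind, rows)
  out$level <- level
  if (level == "soc") {
    out$soc <- out$term
  } else if (!is.null(annotation)) {
    out$soc <- unname(annotation$pt_to_soc[out$term])
    out$soc[is.na(out$soc)] <- "UNMAPPED"
  } else {
    out$soc <- NA_character_
  }
  out <- out[order(out$soc, -out$ror), c("level", "soc", "term",
                                         setdiff(names(out), c("level", "soc", "term")))]
  rownames(out) <- NULL
  out
}
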