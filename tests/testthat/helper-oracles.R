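# Independent oracles used by the property and acceptance tests.

# Monte-Carlo draws from the exact conjugate Beta posterior of the BCPNN
# model (joint cell probability and the two margins), returning the IC draw
# vector. Defaults mirror bcpnn_priors().
mc_ic_draws <- function(t, ndraw = 1e6) {
  a <- t$a; n <- t$n; r <- t$a + t$b; cc <- t$a + t$c
  gamma <- (n + 2) * (n + 2) / ((r + 1) * (cc + 1))
  p11 <- rbeta(ndraw, a + 1, n - a + gamma - 1)
  p1 <- rbeta(ndraw, r + 1, n - r + 1)
  p2 <- rbeta(ndraw, cc + 1, n - cc + 1)
  list(ic = log2(p11 / (p1 * p2)),
       ratio_of_means = log2(mean(p11) / (mean(p1) * mean(p2))))
}

# Trapezoid quadrature (on the log scale) of the gamma-mixture posterior:
# EBGM from the integral of log(lambda), EBGM05 from the integrated CDF.
# Independent of the digamma/pgamma closed forms used by mgps_ebgm().
mgps_quad_oracle <- function(a, E, prior = mgps_prior(), npts = 4e5) {
  lf1 <- dnbinom(a, size = prior$a1, prob = prior$b1 / (prior$b1 + E), log = TRUE)
  lf2 <- dnbinom(a, size = prior$a2, prob = prior$b2 / (prior$b2 + E), log = TRUE)
  q <- 1 / (1 + exp(log(1 - prior$w) + lf2 - log(prior$w) - lf1))
  sh <- c(prior$a1 + a, prior$a2 + a); rt <- c(prior$b1 + E, prior$b2 + E)
  dens <- function(x) q * dgamma(x, sh[1], rt[1]) + (1 - q) * dgamma(x, sh[2], rt[2])
  u_lo <- log(min(qgamma(1e-12, sh, rt))) - 1
  u_hi <- log(max(qgamma(1 - 1e-12, sh, rt))) + 1
  u <- seq(u_lo, u_hi, length.out = npts)
  x <- exp(u)
  w <- dens(x) * x            # density in u-space
  du <- u[2] - u[1]
  mass <- sum(w) * du
  ebgm <- exp(sum(u * w) * du / mass)
  cdf <- cumsum(w) * du / mass
  ebgm05 <- x[which(cdf >= 0.05)[1]]
  c(ebgm = ebgm, ebgm05 = ebgm05)
}

# Full hypergeometric enumeration of the two-sided Fisher p-value.
fisher_brute <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  k <- max(0, c1 - r2):min(r1, c1)
  p <- choose(r1, k) * choose(r2, c1 - k) / choose(n, c1)
  sum(p[p <= p[k == a] * (1 + 1e-7)])
}

# Weibull profile log-likelihood over a shape grid (brute-force oracle).
weibull_grid_fit <- function(t, grid = seq(0.05, 10, by = 0.01)) {
  ll <- sapply(grid, function(b) {
    al <- (sum(t^b) / length(t))^(1 / b)
    sum(dweibull(t, shape = b, scale = al, log = TRUE))
  })
  list(beta = grid[which.max(ll)], loglik = max(ll), grid = grid, ll = ll)
}
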