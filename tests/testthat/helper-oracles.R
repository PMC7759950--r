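# Independent oracles used to cross-check the package's estimators.
# These deliberately use different algorithms than the implementation.

# Nonlinear fit of A_star(t) = Amax * (1 - c * exp(-k t)) by grid search
# over k; for fixed k the model is linear in (Amax, Amax*c), solved by OLS.
# Returns the k minimizing the residual sum of squares.
grid_fit_rate <- function(t, a_star, k_grid = seq(0.02, 1.5, by = 0.001)) {
  best_k <- NA_real_
  best_rss <- Inf
  for (k in k_grid) {
    z <- exp(-k * t)
    fit <- stats::lm.fit(cbind(1, z), a_star)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      best_k <- k
    }
  }
  best_k
}

# Conditional P(QTL = 1 | flanks) by exhaustive enumeration of the eight
# (xL, x, xR) gamete classes under the Markov chain with recombination
# fractions rL (left interval) and rR (right interval).
enum_cond_prob <- function(xL, xR, rL, rR) {
  step_p <- function(a, b, r) if (a == b) 1 - r else r
  num <- den <- 0
  for (x0 in 0:1) for (x in 0:1) for (x1 in 0:1) {
    p <- 0.5 * step_p(x0, x, rL) * step_p(x, x1, rR)
    if (x0 == xL && x1 == xR) {
      den <- den + p
      if (x == 1) num <- num + p
    }
  }
  num / den
}

# a minimal valid three-point curve for I/O tests
make_tiny_curve_csv <- function(path, times = c(0, 1, 2)) {
  writeLines(c(
    "genotype,replicate,time_min,A,gs,ci,ca,ppfd,tleaf",
    sprintf("G1,r1,%g,%g,%g,%g,400,1300,25",
            times, c(5, 10, 15), c(0.1, 0.15, 0.2), c(350, 330, 310))),
    path)
  path
}

# deterministic noiseless curve list for pipeline-level tests
make_noiseless_kin <- function(rate, ...) {
  kinetic_params(one_over_tau = rate, duration_min = 300, ...)
}
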