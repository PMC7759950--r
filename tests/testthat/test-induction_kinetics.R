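test_that("normalization to ci = 300 scales A pointwise", {
  cv <- induction_curve("g", "r", time_min = 0:9,
                        A = c(20, 30, 15, rep(20, 7)),
                        gs = rep(0.3, 10),
                        ci = c(300, 450, 200, rep(300, 7)), ca = 500)
  norm <- normalize_to_ci300(cv)
  expect_equal(norm$A_star[1:3], c(20, 20, 22.5))
  cv_bad <- cv
  cv_bad$ci[4] <- -5
  expect_error(normalize_to_ci300(cv_bad), "time 3")
})

test_that("steady-state detection finds the asymptote of a saturating trace", {
  t <- 0:40
  a <- 25 * (1 - 0.6 * exp(-0.4 * t))
  ss <- detect_steady_state(t, a)
  expect_equal(ss$status, "ok")
  # the detected onset is the first window satisfying the 1 %/min
  # criterion (monotone trace, so qualification is monotone in time)
  win_rel <- function(s) {
    idx <- t >= s & t <= s + 5
    f <- lm(a[idx] ~ t[idx])
    abs(coef(f)[2]) / mean(a[idx])
  }
  expect_lt(win_rel(ss$steady_time), 0.01)
  if (ss$steady_time > 0) expect_gt(win_rel(ss$steady_time - 1), 0.01)
  expect_equal(ss$level, 25, tolerance = 0.01)

  flat <- detect_steady_state(t, rep(7, 41))
  expect_equal(flat$steady_index, 1L)
  expect_equal(flat$level, 7)

  rising <- detect_steady_state(t, 1 + 0.5 * t)
  expect_equal(rising$status, "not_steady")
  expect_true(is.na(rising$steady_index))
})

test_that("activation rate is exact on an analytic exponential", {
  t <- 0:20
  a_star <- 25 * (1 - exp(-0.5 * t))
  fit <- estimate_activation_rate(
    list(time_min = t, A_star = a_star, A_star_max = 25))
  expect_equal(fit$one_over_tau, 0.5, tolerance = 1e-12)
  expect_equal(fit$status, "ok")
  expect_gt(fit$r_squared, 0.999)
  expect_true(all(fit$window_times >= 2))
})

test_that("noiseless simulator curves are recovered to 1e-6 relative", {
  for (k in c(0.1, 0.31, 0.5, 0.74)) {
    cv <- simulate_induction_curve(make_noiseless_kin(k))
    fit <- estimate_activation_rate(normalize_to_ci300(cv))
    expect_equal(fit$status, "ok")
    expect_lt(abs(fit$one_over_tau - k) / k, 1e-6)
  }
})

test_that("too few base points or a poor base fit are flagged", {
  t <- c(0, 1, 2, 6, 7, 8, 9, 10, 11, 12)
  a_star <- 20 * (1 - 0.7 * exp(-0.4 * t))
  fit <- estimate_activation_rate(
    list(time_min = t, A_star = a_star, A_star_max = 20))
  expect_equal(fit$status, "insufficient_points")

  set.seed(4)
  t2 <- 0:30
  noisy <- list(time_min = t2, A_star = 15 + rnorm(31, 0, 2), A_star_max = 21)
  fit2 <- estimate_activation_rate(noisy)
  expect_true(fit2$status %in% c("poor_fit", "insufficient_points"))
})

test_that("window extension keeps R2 above the retention threshold", {
  set.seed(7)
  kin <- kinetic_params(one_over_tau = 0.3, noise_sd_A = 0.3,
                        noise_sd_gs = 0.01, duration_min = 45)
  for (i in 1:20) {
    fit <- estimate_activation_rate(
      normalize_to_ci300(simulate_induction_curve(kin)))
    if (fit$status == "ok") {
      expect_gt(fit$r_squared, 0.9)
      expect_gte(fit$n_points, 3)
      expect_true(all(diff(fit$window_times) > 0))
    }
  }
})

test_that("snapshots take the nearest record, earlier on ties, NA beyond", {
  cv <- induction_curve("g", "r", time_min = 0:20, A = 10 + (0:20),
                        gs = 0.2 + 0.01 * (0:20), ci = rep(280, 21))
  s <- snapshot_phenotypes(cv, c(5, 10, 15))
  expect_equal(unname(s["A_5"]), 15)
  expect_equal(unname(s["gs_10"]), 0.3)
  expect_true(is.na(snapshot_phenotypes(cv, 30)[["A_30"]]))

  cv2 <- induction_curve("g", "r", time_min = c(0, 4, 5, 8),
                         A = c(1, 2, 3, 4), gs = rep(0.2, 4),
                         ci = rep(280, 4))
  expect_equal(unname(snapshot_phenotypes(cv2, 4.6)["A_4.6"]), 3)   # nearest
  expect_equal(unname(snapshot_phenotypes(cv2, 4.5)["A_4.5"]), 2)   # tie -> earlier
})

test_that("genotype medians follow the midpoint rule", {
  df <- data.frame(genotype = c("a", "a", "a", "b", "b", "c"),
                   one_over_tau = c(0.2, 0.3, 0.4, 0.2, 0.4, 0.5))
  med <- genotype_median(df, "one_over_tau")
  expect_equal(med$one_over_tau, c(0.3, 0.3, 0.5))
})

test_that("population summaries use linear-interpolation quantiles", {
  tab <- data.frame(line_id = letters[1:5], A_ss = c(1, 2, 3, 4, 5))
  s <- population_summary(tab, "A_ss")
  expect_equal(c(s$min, s$median, s$mean, s$max), c(1, 3, 3, 5))
  expect_equal(s$q25, 2)  # type-7 on 1..5

  # snapshot-vs-steady underestimation arithmetic
  expect_equal(pct_underestimation(20.4, 25.823), 21.0, tolerance = 0.005)
  expect_equal(pct_underestimation(25, 25), 0)
})

test_that("trait correlation matches the direct formula", {
  tab <- data.frame(line_id = letters[1:4], a = c(1, 2, 3, 4),
                    b = c(1, 2, 3, 4), c = c(1, -1, 1, -1),
                    d = c(1, 1, -1, -1))
  expect_equal(trait_correlation(tab, "a", "b")$r, 1)
  expect_equal(trait_correlation(tab, "c", "d")$r, 0)
  set.seed(2)
  x <- rnorm(5); y <- rnorm(5)
  tab2 <- data.frame(line_id = letters[1:5], x = x, y = y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(trait_correlation(tab2, "x", "y")$r, r_hand)
})

test_that("noisy estimates agree with the grid-search oracle and planted rate", {
  set.seed(11)
  kin <- kinetic_params(one_over_tau = 0.3, noise_sd_A = 0.3,
                        duration_min = 45)
  est <- oracle <- numeric(200)
  for (i in 1:200) {
    cv <- simulate_induction_curve(kin)
    norm <- normalize_to_ci300(cv)
    est[i] <- estimate_activation_rate(norm)$one_over_tau
    oracle[i] <- grid_fit_rate(norm$time_min, norm$A_star)
  }
  expect_lt(abs(mean(est, na.rm = TRUE) - 0.3) / 0.3, 0.10)
  expect_lt(abs(median(est, na.rm = TRUE) - median(oracle)) /
              median(oracle), 0.10)
})
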