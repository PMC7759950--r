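test_that("map construction hits the requested dimensions", {
  map <- build_map()
  expect_equal(length(unique(map$chromosome)), 7)
  total <- sum(tapply(map$pos_cM, map$chromosome, max))
  expect_equal(total, 7 * 161)        # 1127 cM
  expect_true(nrow(map) >= 520 && nrow(map) <= 540)

  expect_equal(build_map(1, 10, 10)$pos_cM, c(0, 10))   # two markers
  expect_equal(nrow(build_map(1, 0, 10)), 1)            # degenerate chromosome
})

test_that("Haldane map function matches its closed form and inverts", {
  expect_equal(haldane_r(0), 0)
  expect_equal(haldane_r(10), 0.090635, tolerance = 1e-5)
  expect_lt(0.5 - haldane_r(1e5), 1e-12)
  d <- c(0, 1, 5, 10, 50, 120)
  expect_equal(haldane_d(haldane_r(d)), d)
})

test_that("DH genotypes follow the Markov recombination model", {
  # coincident markers are perfectly correlated
  map0 <- sunqtl:::as_genetic_map(
    data.frame(chromosome = "1H", marker = c("a", "b"), pos_cM = c(5, 5)))
  g0 <- simulate_dh_genotypes(map0, 200, seed = 1)
  expect_identical(g0$calls[, "a"], g0$calls[, "b"])

  # switch frequency over 10 cM within 3 binomial SE of haldane_r(10)
  map1 <- sunqtl:::as_genetic_map(
    data.frame(chromosome = "1H", marker = c("a", "b", "c"),
               pos_cM = c(0, 10, 20)))
  g1 <- simulate_dh_genotypes(map1, 2000, seed = 2)
  r_hat <- mean(g1$calls[, "a"] != g1$calls[, "b"])
  r_exp <- haldane_r(10)
  se <- sqrt(r_exp * (1 - r_exp) / 2000)
  expect_lt(abs(r_hat - r_exp), 3 * se)

  # no-interference composition: switches over 0-20 cM behave like one
  # 20 cM interval
  r2_hat <- mean(g1$calls[, "a"] != g1$calls[, "c"])
  r2_exp <- haldane_r(20)
  expect_lt(abs(r2_hat - r2_exp), 3 * sqrt(r2_exp * (1 - r2_exp) / 2000))

  # allele frequency ~ 0.5 per marker
  freqs <- colMeans(g1$calls)
  expect_true(all(abs(freqs - 0.5) < 3 * sqrt(0.25 / 2000)))
})

test_that("QTL-driven phenotypes follow the additive +/-1 model", {
  map <- build_map(1, 30, 10, chr_names = "1H")
  geno <- simulate_dh_genotypes(map, 40, seed = 3)
  spec <- data.frame(chromosome = "1H", pos_cM = 10, a = 0.7)
  ph <- simulate_phenotypes(geno, map, spec, noise_sd = 0, seed = 4)
  vals <- sort(unique(ph$y))
  expect_equal(vals, c(-0.7, 0.7))    # two classes 2a apart
  x <- geno$calls[, "1Hm002"]
  expect_equal(ph$y, unname(0.7 * (2 * x - 1)))

  # a = 0 gives pure noise at the requested sd
  ph0 <- simulate_phenotypes(geno, map, transform(spec, a = 0),
                             noise_sd = 2, seed = 5)
  expect_gt(sd(ph0$y), 1)

  # QTL off-marker is refused
  expect_error(simulate_phenotypes(geno, map, transform(spec, pos_cM = 12),
                                   noise_sd = 1), "not at a map marker")
})

test_that("realized variance explained matches a^2/(a^2+sd^2)", {
  map <- build_map(1, 30, 10, chr_names = "1H")
  a <- 1
  sd_e <- a * sqrt((1 - 0.1) / 0.1)
  set.seed(6)
  r2 <- replicate(200, {
    geno <- simulate_dh_genotypes(map, 127)
    ph <- simulate_phenotypes(geno, map,
                              data.frame(chromosome = "1H", pos_cM = 10, a = a),
                              noise_sd = sd_e)
    attr(ph, "truth")$marginal_r2
  })
  expect_lt(abs(mean(r2) - 0.1), 0.015)
})

test_that("the induction model satisfies the supply-demand closed form", {
  kin <- kinetic_params(one_over_tau = 50, S0 = 0.5, k = 0.1, gs0 = 0.32,
                        gs_ss = 0.32, tau_g = 1, dip_amp = 0,
                        duration_min = 10)
  cv <- simulate_induction_curve(kin)
  i <- length(cv$time_min)           # S has saturated to 1
  expect_equal(cv$ci[i], 400 / 1.5, tolerance = 1e-9)
  expect_equal(cv$A[i], 0.1 * 400 / 1.5, tolerance = 1e-9)
  # supply equals demand everywhere on the noiseless trace
  expect_equal(cv$A, (cv$gs / 1.6) * (cv$ca - cv$ci), tolerance = 1e-12)
})

test_that("noiseless A* depends only on activation state, not stomata", {
  kin <- kinetic_params(one_over_tau = 0.4, S0 = 0.3, k = 0.07,
                        duration_min = 30)
  cv <- simulate_induction_curve(kin)
  a_star <- cv$A * 300 / cv$ci
  S <- 1 - (1 - 0.3) * exp(-cv$time_min * 0.4)
  expect_equal(a_star, 300 * 0.07 * S, tolerance = 1e-12)
})

test_that("impossible stomatal parameters are refused", {
  kin <- kinetic_params(one_over_tau = 0.3, gs0 = 0.05, gs_ss = 0.05,
                        dip_amp = 0.1, tau_dip = 2)
  expect_error(simulate_induction_curve(kin), "gs <= 0")
})

test_that("identical config and seed reproduce the study bit for bit", {
  cfg <- sim_config(seed = 9, n_lines = 12, n_reps = 2,
                    map_spec = list(n_chr = 2, chr_len = 50, spacing_cM = 5),
                    qtl_spec = data.frame(trait = "gs_ss", chromosome = "2H",
                                          pos_cM = 20, a = 0.03),
                    duration_min = 20)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  expect_identical(s1$curves[["DH001:1"]]$A, s2$curves[["DH001:1"]]$A)
})

test_that("the default study population spans the expected rate range", {
  st <- simulate_study(sim_config(seed = 31))
  expect_true(all(st$truth$one_over_tau >= 0.08 &
                    st$truth$one_over_tau <= 0.85))
  expect_gt(diff(range(st$truth$one_over_tau)), 0.4)
  expect_false(any(is.na(st$genotypes$calls)))
  expect_equal(nrow(st$genotypes$calls), 127)
})
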