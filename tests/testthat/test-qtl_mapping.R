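make_test_map <- function(pos, chr = "1H") {
  sunqtl:::as_genetic_map(
    data.frame(chromosome = chr, marker = sprintf("%s_m%02d", chr, seq_along(pos)),
               pos_cM = pos))
}

test_that("marker thinning keeps a 10 cM grid and chromosome ends", {
  map <- make_test_map(seq(0, 20, by = 2))
  thin <- thin_markers(map, spacing_cM = 10)$map
  expect_equal(thin$pos_cM, c(0, 10, 20))

  wide <- thin_markers(make_test_map(c(0, 7, 20)), spacing_cM = 25)$map
  expect_equal(wide$pos_cM, c(0, 20))      # both ends of a short chromosome

  again <- thin_markers(thin, spacing_cM = 10)$map
  expect_equal(again$pos_cM, thin$pos_cM)  # idempotent
})

test_that("marker LOD matches hand-computed residual sums of squares", {
  x <- c(0, 0, 0, 0, 1, 1, 1, 1)
  y <- c(1, 2, 1, 2, 3, 4, 3, 4)
  # RSS0 = 10 (grand mean 2.5), RSS1 = 2 (class means 1.5/3.5)
  expect_equal(marker_lod(x, y), 4 * log10(5), tolerance = 1e-12)
  expect_equal(marker_lod(x, y), 2.796, tolerance = 5e-4)

  # equal class means: no association
  expect_equal(marker_lod(c(0, 0, 1, 1), c(1, 2, 1, 2)), 0)

  # exact fit is capped at the documented value
  expect_equal(marker_lod(x, c(1, 1, 1, 1, 2, 2, 2, 2)), 300)

  expect_warning(lod0 <- marker_lod(rep(0, 6), rnorm(6)), "monomorphic")
  expect_equal(lod0, 0)
})

test_that("interval-mapping LOD collapses to marker regression at typed markers", {
  map <- thin_markers(build_map(2, 60, 2.15))$map
  geno <- simulate_dh_genotypes(map, 80, seed = 21)
  set.seed(22)
  y <- rnorm(80) + geno$calls[, 5]
  sc <- im_scan(map, geno, y)
  key <- paste(sc$profile$chromosome, round(sc$profile$pos_cM, 6))
  at <- match(paste(map$chromosome, round(map$pos_cM, 6)), key)
  expect_false(anyNA(at))
  for (i in seq_len(nrow(map)))
    expect_lt(abs(sc$profile$lod[at[i]] - marker_lod(geno$calls[, i], y)),
              1e-9)
})

test_that("expected genotypes match the enumeration oracle between flanks", {
  map <- make_test_map(c(0, 20))
  calls <- matrix(c(0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L), 4, 2,
                  dimnames = list(NULL, map$marker))
  geno <- dh_genotypes(paste0("L", 1:4), calls)
  eg <- expected_genotypes(map, geno, step_cM = 10)
  mid <- which(abs(eg$grid$pos_cM - 10) < 1e-9)
  r <- haldane_r(10)
  for (l in 1:4) {
    expect_equal(eg$X[l, mid],
                 enum_cond_prob(calls[l, 1], calls[l, 2], r, r),
                 tolerance = 1e-12)
  }
  # both flanks 0 leaves the midpoint expectation below one half
  expect_lt(eg$X[1, mid], 0.5)
  # typed positions reproduce the calls exactly
  ends <- match(c(0, 20), eg$grid$pos_cM)
  expect_equal(unname(eg$X[, ends[1]]), as.numeric(calls[, 1]))
  expect_equal(unname(eg$X[, ends[2]]), as.numeric(calls[, 2]))
})

test_that("missing flanks fall back to the nearest typed markers", {
  map <- make_test_map(c(0, 10, 20))
  calls <- matrix(c(1L, NA, 1L,   # line 1: middle marker missing
                    NA, NA, NA),  # line 2: nothing typed
                  2, 3, byrow = TRUE, dimnames = list(NULL, map$marker))
  geno <- dh_genotypes(c("L1", "L2"), calls)
  eg <- expected_genotypes(map, geno, step_cM = 5)
  expect_false(anyNA(eg$X))
  expect_true(all(eg$X >= 0 & eg$X <= 1))
  expect_equal(unname(eg$X[2, ]), rep(0.5, ncol(eg$X)))  # uninformative line
  # line 1: at the missing middle marker, conditioning on the typed ends
  mid <- which(abs(eg$grid$pos_cM - 10) < 1e-9)
  r <- haldane_r(10)
  expect_equal(eg$X[1, mid], enum_cond_prob(1, 1, r, r), tolerance = 1e-12)
})

test_that("LOD profiles are invariant under affine phenotype transforms", {
  map <- thin_markers(build_map(2, 60, 2.15))$map
  geno <- simulate_dh_genotypes(map, 60, seed = 23)
  set.seed(24)
  y <- rnorm(60)
  s1 <- im_scan(map, geno, y)
  s2 <- im_scan(map, geno, 3.7 * y - 11)
  expect_lt(max(abs(s1$profile$lod - s2$profile$lod)), 1e-9)
})

test_that("CIM with no cofactors is exactly interval mapping", {
  map <- thin_markers(build_map(2, 60, 2.15))$map
  geno <- simulate_dh_genotypes(map, 60, seed = 25)
  set.seed(26)
  y <- rnorm(60) + geno$calls[, 3]
  im <- im_scan(map, geno, y)
  cim <- cim_scan(map, geno, y, cofactors = character(0))
  expect_identical(im$profile$lod, cim$profile$lod)
})

test_that("cofactors absorbing a background QTL raise the focal peak", {
  map <- sunqtl:::as_genetic_map(rbind(
    as.data.frame(make_test_map(seq(0, 60, by = 10), "1H")),
    as.data.frame(make_test_map(seq(0, 60, by = 10), "2H"))))
  set.seed(27)
  wins <- replicate(100, {
    geno <- simulate_dh_genotypes(map, 127)
    x1 <- 2 * geno$calls[, "1H_m04"] - 1   # focal QTL, 30 cM on 1H
    x2 <- 2 * geno$calls[, "2H_m04"] - 1   # background QTL on 2H
    y <- 0.9 * x1 + 1.4 * x2 + rnorm(127, 0, 2.4)
    foc <- function(scan) {
      pr <- scan$profile
      max(pr$lod[pr$chromosome == "1H" & abs(pr$pos_cM - 30) <= 5])
    }
    im <- im_scan(map, geno, y, step_cM = 5)
    cim <- cim_scan(map, geno, y, step_cM = 5, cofactors = "2H_m04")
    foc(cim) > foc(im)
  })
  expect_gte(mean(wins), 0.8)
})

test_that("permutation thresholds are the stated order statistics", {
  map <- make_test_map(seq(0, 40, by = 10))
  geno <- simulate_dh_genotypes(map, 40, seed = 28)
  set.seed(29)
  y <- rnorm(40)
  thr_min <- permutation_threshold(map, geno, y, n_perm = 10, alpha = 1,
                                   seed = 1)
  expect_equal(as.numeric(thr_min), min(attr(thr_min, "max_lods")))

  thr_mid <- permutation_threshold(map, geno, y, n_perm = 2, alpha = 0.5,
                                   seed = 2)
  expect_equal(as.numeric(thr_mid), mean(attr(thr_mid, "max_lods")))
})

test_that("QTL summaries recover a planted effect exactly in the noiseless case", {
  map <- make_test_map(seq(0, 60, by = 10))
  geno <- simulate_dh_genotypes(map, 50, seed = 30)
  a <- 0.8
  y <- a * (2 * geno$calls[, "1H_m03"] - 1)   # QTL exactly at 20 cM, sd = 0
  sc <- im_scan(map, geno, y, threshold = 3)
  # linked flanking regions also clear a LOD-3 bar in the noiseless case;
  # the causal peak is the top-LOD row and is recovered exactly
  top <- sc$qtl[which.max(sc$qtl$lod), ]
  expect_equal(top$pos_cM, 20)
  expect_equal(top$nearest_marker, "1H_m03")
  expect_equal(top$lod, 300)                  # capped exact fit
  expect_equal(top$additivity, a, tolerance = 1e-9)
  expect_equal(top$pct_variance, 100, tolerance = 1e-9)

  # a null trait yields an empty table
  set.seed(31)
  sc0 <- im_scan(map, geno, rnorm(50), threshold = 1e6)
  expect_equal(nrow(sc0$qtl), 0)
})

test_that("forward selection stops at non-significant cofactors", {
  map <- make_test_map(seq(0, 90, by = 10))
  geno <- simulate_dh_genotypes(map, 150, seed = 32)
  set.seed(33)
  y <- 2 * (2 * geno$calls[, 3] - 1) + rnorm(150)
  cof <- select_cofactors(map, geno, y)
  expect_true(map$marker[3] %in% cof || map$marker[2] %in% cof ||
                map$marker[4] %in% cof)
  expect_lte(length(cof), 5)

  set.seed(34)
  cof0 <- select_cofactors(map, geno, rnorm(150), p_enter = 1e-6)
  expect_length(cof0, 0)
})
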