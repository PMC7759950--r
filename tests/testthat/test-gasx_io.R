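test_that("a minimal valid file yields one curve with validated fields", {
  f <- make_tiny_curve_csv(withr::local_tempfile(fileext = ".csv"))
  curves <- read_curves(f)
  expect_length(curves, 1)
  cv <- curves[["G1:r1"]]
  expect_s3_class(cv, "induction_curve")
  expect_equal(cv$time_min, c(0, 1, 2))
  expect_equal(cv$A, c(5, 10, 15))
  expect_equal(cv$ca, 400)
})

test_that("non-monotone time within a group is rejected, naming the group", {
  f <- make_tiny_curve_csv(withr::local_tempfile(fileext = ".csv"),
                           times = c(0, 2, 1))
  expect_error(read_curves(f), "G1:r1")
})

test_that("missing required columns raise a format error naming them", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("genotype,replicate,time_min,A,gs", "G1,r1,0,5,0.1"), f)
  expect_error(read_curves(f), "ci")
})

test_that("curve invariants reject bad traces", {
  ok <- list(time_min = 0:3, A = c(1, 2, 3, 4), gs = rep(0.2, 4),
             ci = rep(300, 4))
  expect_error(do.call(induction_curve,
                       c(list("g", "r"), modifyList(ok, list(ci = c(300, -1, 300, 300))))),
               "ci must be positive")
  expect_error(do.call(induction_curve,
                       c(list("g", "r"), modifyList(ok, list(gs = c(0.2, 0, 0.2, 0.2))))),
               "gs must be positive")
  expect_error(do.call(induction_curve,
                       c(list("g", "r"), modifyList(ok, list(ci = c(300, 450, 300, 300))))),
               "ci >= ca")
  expect_error(induction_curve("g", "r", time_min = 0:1, A = 1:2,
                               gs = c(0.1, 0.1), ci = c(300, 300)),
               "length >= 3")
})

test_that("write/read round trip is lossless at full double precision", {
  set.seed(1)
  kin <- kinetic_params(one_over_tau = 0.31, noise_sd_A = 0.3,
                        noise_sd_gs = 0.01)
  curves <- list(simulate_induction_curve(kin, "G1", "1"),
                 simulate_induction_curve(kin, "G2", "1"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_curves(curves, f)
  back <- read_curves(f)
  expect_identical(back[["G1:1"]]$A, curves[[1]]$A)
  expect_identical(back[["G2:1"]]$gs, curves[[2]]$gs)
  expect_identical(back[["G1:1"]]$ci, curves[[1]]$ci)

  tab <- data.frame(line_id = c("L1", "L2"),
                    one_over_tau = c(0.1234567890123456, NA),
                    A_ss = c(25.00000000000001, 17.3))
  g <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(tab, g)
  back <- read_phenotypes(g)
  expect_identical(back$one_over_tau, tab$one_over_tau)
  expect_identical(back$A_ss, tab$A_ss)
})

test_that("map and genotype files round trip and are validated", {
  map <- build_map(2, c(30, 20), spacing_cM = 10)
  geno <- simulate_dh_genotypes(map, 8, seed = 3, missing_rate = 0.1)
  fm <- withr::local_tempfile(fileext = ".csv")
  fg <- withr::local_tempfile(fileext = ".csv")
  write_map(map, fm)
  write_genotypes(geno, fg)
  expect_equal(as.data.frame(read_map(fm)), as.data.frame(map))
  back <- read_genotypes(fg)
  expect_identical(back$calls, geno$calls)

  dup <- data.frame(line_id = c("a", "a"), y = 1:2)
  fp <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(dup, fp)
  expect_error(read_phenotypes(fp), "duplicated")
})
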