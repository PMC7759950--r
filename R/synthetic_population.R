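# Synthetic DH study generator: genetic map, doubled-haploid genotypes
# (two-state Markov chain under the Haldane model), QTL-driven trait
# architectures, and mechanistic induction curves coupling first-order
# Rubisco activation with stomatal opening dynamics.
#
# Defaults emulate the dimensions of a barley DH mapping study: 127 lines,
# 7 chromosomes totalling 1127 cM with ~530 markers, single-QTL effects
# explaining ~6-14 % of trait variance, and genotype median activation
# rates spanning roughly 0.1-0.75 min-1.

#' Haldane map function
#'
#' Converts map distance to recombination fraction under no interference,
#' `r = (1 - exp(-2 d / 100)) / 2`, and back.
#'
#' @param d_cM map distance, centiMorgans (>= 0).
#' @return recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cM) {
  stopifnot(all(d_cM >= 0))
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' @rdname haldane_r
#' @param r recombination fraction in `[0, 0.5)`.
#' @return `haldane_d`: map distance in cM.
#' @export
haldane_d <- function(r) {
  stopifnot(all(r >= 0), all(r < 0.5))
  -50 * log(1 - 2 * r)
}

#' Build an evenly spaced genetic map
#'
#' Markers are placed every `spacing_cM` from 0 along each chromosome, with
#' the chromosome end always included, so the total map length equals the
#' requested lengths.  Defaults give 7 chromosomes of 161 cM (1127 cM
#' total) at 2.15 cM spacing, ~530 markers.
#'
#' @param n_chr number of chromosomes.
#' @param chr_len chromosome length(s), cM (recycled).
#' @param spacing_cM marker spacing, cM.
#' @param chr_names chromosome labels; default `"1H" ... "7H"`.
#' @return a `genetic_map` data.frame (`chromosome, marker, pos_cM`).
#' @export
build_map <- function(n_chr = 7, chr_len = 161, spacing_cM = 2.15,
                      chr_names = NULL) {
  stopifnot(n_chr >= 1, all(chr_len >= 0), spacing_cM > 0)
  chr_len <- rep_len(chr_len, n_chr)
  chr_names <- chr_names %||% paste0(seq_len(n_chr), "H")
  rows <- lapply(seq_len(n_chr), function(i) {
    p <- seq(0, chr_len[i], by = spacing_cM)
    if (chr_len[i] - p[length(p)] > 1e-8) p <- c(p, chr_len[i])
    data.frame(chromosome = chr_names[i],
               marker = sprintf("%sm%03d", chr_names[i], seq_along(p)),
               pos_cM = p, stringsAsFactors = FALSE)
  })
  as_genetic_map(do.call(rbind, rows))
}

#' Simulate doubled-haploid genotypes along a map
#'
#' One meiosis per line: the first marker of each chromosome is
#' Bernoulli(1/2); along ordered markers the parental origin switches
#' between adjacent markers with probability `haldane_r` of the interval
#' (a two-state Markov chain, i.e. no interference).  Chromosome doubling
#' fixes the single simulated gamete, so every call is homozygous.
#'
#' @param map a `genetic_map`.
#' @param n_lines number of DH lines.
#' @param seed optional integer seed (`set.seed`); `NULL` uses the current
#'   RNG stream.
#' @param missing_rate fraction of calls set to missing at random.
#' @return a [dh_genotypes()] object.
#' @export
simulate_dh_genotypes <- function(map, n_lines, seed = NULL,
                                  missing_rate = 0) {
  if (!is.null(seed)) set.seed(seed)
  calls <- matrix(NA_integer_, n_lines, nrow(map),
                  dimnames = list(NULL, map$marker))
  for (chr in unique(map$chromosome)) {
    j <- which(map$chromosome == chr)
    r <- haldane_r(diff(map$pos_cM[j]))
    g <- matrix(0L, n_lines, length(j))
    g[, 1] <- stats::rbinom(n_lines, 1L, 0.5)
    if (length(j) > 1) {
      for (k in 2:length(j)) {
        sw <- stats::rbinom(n_lines, 1L, r[k - 1])
        g[, k] <- (g[, k - 1] + sw) %% 2L
      }
    }
    calls[, j] <- g
  }
  if (missing_rate > 0)
    calls[stats::runif(length(calls)) < missing_rate] <- NA_integer_
  dh_genotypes(sprintf("DH%03d", seq_len(n_lines)), calls)
}

#' Simulate QTL-driven phenotypes
#'
#' Additive model `y = mu + sum_k a_k x_k + e`, with `x` coded -1/+1 from
#' the 0/1 parental-origin call at each QTL marker (so `a` is the
#' half-difference between class means, the "additivity" convention) and
#' `e ~ Normal(0, noise_sd)`.  For balanced DH coding a single QTL explains
#' `a^2 / (a^2 + sd^2)` of the variance in expectation.
#'
#' @param genotypes a [dh_genotypes()] object.
#' @param map the matching `genetic_map`.
#' @param qtl_spec data.frame with `chromosome`, `pos_cM`, `a` (and
#'   optionally `trait`); each position must coincide with a map marker
#'   (use [simulate_study()] to plant QTL between markers — it augments the
#'   map with pseudo-markers before simulating).
#' @param noise_sd residual standard deviation, trait units.
#' @param mu trait mean.
#' @param seed optional integer seed.
#' @param trait_name output column name.
#' @return data.frame `line_id`, `<trait_name>`; attribute `"truth"` holds
#'   the planted QTL table, their marker names and per-QTL marginal
#'   r-squared.
#' @export
simulate_phenotypes <- function(genotypes, map, qtl_spec, noise_sd,
                                mu = 0, seed = NULL, trait_name = "y") {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes$calls)
  y <- rep(mu, n)
  qmarkers <- character(nrow(qtl_spec))
  for (i in seq_len(nrow(qtl_spec))) {
    on_chr <- map$chromosome == qtl_spec$chromosome[i]
    hit <- which(on_chr & abs(map$pos_cM - qtl_spec$pos_cM[i]) < 1e-6)
    if (!length(hit))
      stop("QTL at ", qtl_spec$chromosome[i], ":", qtl_spec$pos_cM[i],
           " cM is not at a map marker; plant it via simulate_study()",
           call. = FALSE)
    qmarkers[i] <- map$marker[hit[1]]
    x <- 2 * genotypes$calls[, qmarkers[i]] - 1
    y <- y + qtl_spec$a[i] * x
  }
  y <- y + stats::rnorm(n, 0, noise_sd)
  r2 <- vapply(qmarkers, function(m) {
    stats::cor(y, genotypes$calls[, m], use = "complete.obs")^2
  }, numeric(1))
  out <- data.frame(line_id = genotypes$line_id, stringsAsFactors = FALSE)
  out[[trait_name]] <- y
  attr(out, "truth") <- list(qtl_spec = qtl_spec, qtl_markers = qmarkers,
                             marginal_r2 = r2, noise_sd = noise_sd)
  out
}

#' Kinetic parameters for one simulated leaf
#'
#' Defaults describe a typical barley leaf at 400 umol mol-1 cuvette CO2:
#' carboxylation efficiency `k` (umol m-2 s-1 per umol mol-1) on the
#' Rubisco-limited A-ci line, initial activation fraction `S0` carried over
#' from moderate light, and a stomatal trajectory rising from `gs0` to
#' `gs_ss` with time constant `tau_g` plus a transient closing dip
#' (gamma-pulse of amplitude `dip_amp`, timescale `tau_dip`).
#'
#' @param one_over_tau Rubisco activation rate, min-1.
#' @param S0 initial activation fraction, in (0, 1).
#' @param k carboxylation efficiency, (umol m-2 s-1)/(umol mol-1).
#' @param gs0,gs_ss initial and steady stomatal conductance, mol m-2 s-1.
#' @param tau_g stomatal opening time constant, min.
#' @param dip_amp,tau_dip amplitude (mol m-2 s-1) and timescale (min) of
#'   the post-step closing transient.
#' @param ca cuvette CO2, umol mol-1.
#' @param duration_min,log_interval_min trace length and logging interval.
#' @param noise_sd_A,noise_sd_gs Gaussian measurement noise on A
#'   (umol m-2 s-1) and gs (mol m-2 s-1).
#' @param ppfd,tleaf chamber light and leaf temperature (metadata).
#' @return named list of parameters.
#' @export
kinetic_params <- function(one_over_tau = 0.31, S0 = 0.4, k = 0.065,
                           gs0 = 0.23, gs_ss = 0.42, tau_g = 6,
                           dip_amp = 0.04, tau_dip = 2.5, ca = 400,
                           duration_min = 45, log_interval_min = 1,
                           noise_sd_A = 0, noise_sd_gs = 0,
                           ppfd = 1300, tleaf = 25) {
  stopifnot(one_over_tau > 0, S0 > 0, S0 < 1, k > 0, gs0 > 0, gs_ss > 0,
            tau_g > 0, tau_dip > 0, dip_amp >= 0, ca > 0,
            duration_min >= log_interval_min)
  as.list(environment())
}

#' Simulate one induction curve
#'
#' Mechanistic forward model of the post-step transient:
#' * activation state `S(t) = 1 - (1 - S0) exp(-t / tau)`;
#' * stomata `gs(t) = gs_ss + (gs0 - gs_ss) exp(-t / tau_g)
#'   - dip_amp (t / tau_dip) exp(1 - t / tau_dip)` (the gamma pulse is the
#'   transient closing dip seen after a light step);
#' * CO2 supply `(gs / 1.6)(ca - ci)` and Rubisco-limited demand
#'   `k S(t) ci` solved jointly:
#'   `ci = ca / (1 + 1.6 k S / gs)`, `A = k S ci`.
#'
#' The ci-normalized rate is therefore exactly `A* = 300 k S(t)` whatever
#' the stomata do — the identity that makes 1/tau estimable from A*.
#' Gaussian noise is added to A and gs; ci is then recomputed from the
#' noisy A and gs (`ci = ca - 1.6 A / gs`), as a gas analyser would derive
#' it.
#'
#' @param kin a [kinetic_params()] list.
#' @param genotype_id,replicate_id identifiers for the output curve.
#' @param seed optional integer seed.
#' @return an [induction_curve()].
#' @export
simulate_induction_curve <- function(kin, genotype_id = "sim",
                                     replicate_id = "1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, kin$duration_min, by = kin$log_interval_min)
  S <- 1 - (1 - kin$S0) * exp(-t * kin$one_over_tau)
  gs <- kin$gs_ss + (kin$gs0 - kin$gs_ss) * exp(-t / kin$tau_g) -
    kin$dip_amp * (t / kin$tau_dip) * exp(1 - t / kin$tau_dip)
  if (any(gs <= 0))
    stop("kinetic parameters yield gs <= 0 (dip too deep?)", call. = FALSE)
  ci <- kin$ca / (1 + 1.6 * kin$k * S / gs)
  A <- kin$k * S * ci
  if (kin$noise_sd_A > 0) A <- A + stats::rnorm(length(t), 0, kin$noise_sd_A)
  if (kin$noise_sd_gs > 0) {
    gs <- gs + stats::rnorm(length(t), 0, kin$noise_sd_gs)
    gs <- pmax(gs, 1e-4)
  }
  if (kin$noise_sd_A > 0 || kin$noise_sd_gs > 0) {
    ci <- kin$ca - 1.6 * A / gs          # as derived by the analyser
    ci <- pmax(ci, 1)
  }
  induction_curve(genotype_id, replicate_id, time_min = t, A = A, gs = gs,
                  ci = ci, ca = kin$ca, ppfd_high = kin$ppfd,
                  tleaf_C = kin$tleaf)
}

#' Default planted QTL architecture
#'
#' Seven QTL on the kinetic-parameter scale: one for the activation rate
#' (7H), three for carboxylation efficiency `k` (which drives steady-state
#' A; 2H/4H/7H) and three for `gs_ss` (2H/5H/7H), each sized to explain
#' roughly 6-14 % of the line-level variance of its trait.
#'
#' @return data.frame `trait, chromosome, pos_cM, a`.
#' @export
default_qtl_spec <- function() {
  data.frame(
    trait = c("one_over_tau", "k", "k", "k", "gs_ss", "gs_ss", "gs_ss"),
    chromosome = c("7H", "2H", "4H", "7H", "2H", "5H", "7H"),
    pos_cM = c(41.67, 27.03, 66.68, 41.67, 35.91, 53.39, 41.28),
    a = c(0.05, 0.0040, -0.0032, 0.0043, 0.030, -0.022, 0.032),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles every tunable of [simulate_study()] with defaults at the target
#' study's scale.  Line-level kinetic parameters are drawn as
#' `mu + sum(a x) + Normal(0, sd)` (QTL terms only for the traits in
#' `qtl_spec`), truncated to the stated physiological ranges.
#'
#' @param seed integer seed; mandatory for reproducible studies.
#' @param n_lines number of DH lines (127).
#' @param n_reps replicate leaves per line.
#' @param map_spec list(n_chr, chr_len, spacing_cM) for [build_map()].
#' @param qtl_spec planted QTL data.frame; see [default_qtl_spec()].
#' @param kinetics list of per-parameter `mu`, `sd`, `lo`, `hi` for
#'   `one_over_tau`, `k`, `gs_ss`, plus nuisance parameters `S0`, `tau_g`,
#'   `dip_amp`, `tau_dip`, `gs0_frac` (gs0 as a fraction of gs_ss).
#' @param noise_sd_A,noise_sd_gs measurement noise per logged record.
#' @param duration_min,log_interval_min trace length and logging interval.
#' @param ca cuvette CO2, umol mol-1.
#' @return config list (class `sim_config`).
#' @export
sim_config <- function(seed = 1, n_lines = 127, n_reps = 3,
                       map_spec = list(n_chr = 7, chr_len = 161,
                                       spacing_cM = 2.15),
                       qtl_spec = default_qtl_spec(),
                       kinetics = list(
                         one_over_tau = list(mu = 0.36, sd = 0.145,
                                             lo = 0.08, hi = 0.85),
                         k = list(mu = 0.065, sd = 0.010,
                                  lo = 0.030, hi = 0.120),
                         gs_ss = list(mu = 0.42, sd = 0.075,
                                      lo = 0.10, hi = 0.95),
                         S0 = list(mu = 0.40, sd = 0.05, lo = 0.15, hi = 0.70),
                         tau_g = list(mu = 6, sd = 1.5, lo = 2, hi = 15),
                         dip_amp = list(mu = 0.04, sd = 0.02, lo = 0, hi = 0.12),
                         tau_dip = list(mu = 2.5, sd = 0.5, lo = 1, hi = 5),
                         gs0_frac = list(mu = 0.55, sd = 0.05,
                                         lo = 0.30, hi = 0.80)),
                       noise_sd_A = 0.3, noise_sd_gs = 0.01,
                       duration_min = 45, log_interval_min = 1, ca = 400) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a complete mapping study
#'
#' End-to-end generator: builds the map, augments it with pseudo-markers at
#' planted QTL positions, simulates DH genotypes along the augmented map,
#' draws line-level kinetic parameters with QTL effects, and generates
#' replicate induction curves per line with measurement noise.  The
#' released genotype matrix excludes the QTL pseudo-markers (the analyst
#' never sees the causal locus directly); a truth ledger retains every
#' planted parameter for recovery tests.
#'
#' @param config a [sim_config()].
#' @return list (class `sim_study`) with `map`, `genotypes`, `curves`
#'   (list of [induction_curve()], `n_reps` per line), `truth` (per-line
#'   kinetic parameters and QTL codes), `qtl` (the planted spec with
#'   pseudo-marker names), and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config") || is.list(config))
  set.seed(config$seed)
  ms <- config$map_spec
  map <- build_map(ms$n_chr, ms$chr_len, ms$spacing_cM)

  # augment with pseudo-markers at planted QTL positions
  qtl <- config$qtl_spec
  qtl$marker <- NA_character_
  aug <- map
  for (i in seq_len(nrow(qtl))) {
    on_chr <- aug$chromosome == qtl$chromosome[i]
    hit <- which(on_chr & abs(aug$pos_cM - qtl$pos_cM[i]) < 1e-6)
    if (length(hit)) {
      qtl$marker[i] <- aug$marker[hit[1]]
    } else {
      qtl$marker[i] <- sprintf("QTL_%s_%s", qtl$trait[i], qtl$chromosome[i])
      add <- data.frame(chromosome = qtl$chromosome[i],
                        marker = qtl$marker[i], pos_cM = qtl$pos_cM[i],
                        stringsAsFactors = FALSE)
      aug <- rbind(as.data.frame(aug), add)
      aug <- aug[order(match(aug$chromosome, unique(map$chromosome)),
                       aug$pos_cM), ]
      aug <- as_genetic_map(aug)
    }
  }
  geno_aug <- simulate_dh_genotypes(aug, config$n_lines)

  draw <- function(par, n) {
    p <- config$kinetics[[par]]
    clip(stats::rnorm(n, p$mu, p$sd), p$lo, p$hi)
  }
  n <- config$n_lines
  truth <- data.frame(line_id = geno_aug$line_id, stringsAsFactors = FALSE)
  for (par in c("one_over_tau", "k", "gs_ss")) {
    v <- draw(par, n)
    rows <- which(qtl$trait == par)
    for (i in rows) {
      x <- 2 * geno_aug$calls[, qtl$marker[i]] - 1
      v <- v + qtl$a[i] * x
      truth[[paste0("x_", qtl$marker[i])]] <- x
    }
    p <- config$kinetics[[par]]
    truth[[par]] <- clip(v, p$lo, p$hi)
  }
  for (par in c("S0", "tau_g", "dip_amp", "tau_dip", "gs0_frac"))
    truth[[par]] <- draw(par, n)
  # keep the closing dip shallower than the initial conductance so gs > 0
  truth$dip_amp <- pmin(truth$dip_amp, 0.6 * truth$gs0_frac * truth$gs_ss)

  curves <- vector("list", n * config$n_reps)
  ci <- 1L
  for (l in seq_len(n)) {
    kin <- kinetic_params(
      one_over_tau = truth$one_over_tau[l], S0 = truth$S0[l],
      k = truth$k[l], gs0 = truth$gs0_frac[l] * truth$gs_ss[l],
      gs_ss = truth$gs_ss[l], tau_g = truth$tau_g[l],
      dip_amp = truth$dip_amp[l], tau_dip = truth$tau_dip[l],
      ca = config$ca, duration_min = config$duration_min,
      log_interval_min = config$log_interval_min,
      noise_sd_A = config$noise_sd_A, noise_sd_gs = config$noise_sd_gs)
    for (r in seq_len(config$n_reps)) {
      curves[[ci]] <- simulate_induction_curve(
        kin, genotype_id = truth$line_id[l], replicate_id = as.character(r))
      ci <- ci + 1L
    }
  }
  names(curves) <- vapply(curves, function(x)
    paste0(x$genotype_id, ":", x$replicate_id), character(1))

  geno <- dh_genotypes(geno_aug$line_id,
                       geno_aug$calls[, map$marker, drop = FALSE])
  structure(list(map = map, genotypes = geno, curves = curves,
                 truth = truth, qtl = qtl, config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> %d lines x %d markers, %d curves, %d planted QTL (seed %d)\n",
              nrow(x$genotypes$calls), ncol(x$genotypes$calls),
              length(x$curves), nrow(x$qtl), x$config$seed))
  invisible(x)
}
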