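# Monte-Carlo validation experiments for the scan engine: empirical type-I
# control, power and parameter recovery at study scale, and replicate
# equilibration experiments.  These share the per-dataset preparation
# across replicates so that hundreds of scans with permutation thresholds
# stay cheap.

#' Empirical type-I rate of the permutation threshold
#'
#' Simulates `n_sim` null phenotypes (standard normal, no QTL) on a fixed
#' genotype dataset, computes each replicate's own `n_perm`-permutation
#' genome-wide threshold at level `alpha`, and reports the fraction of
#' replicates whose genome-wide maximum LOD exceeds it.  Thresholds are
#' conditional on the genotypes, so the genotypes are held fixed; the
#' scan is plain interval mapping (the degenerate zero-cofactor CIM).
#'
#' @param map,genotypes the dataset to scan (e.g. a thinned simulated map).
#' @param n_sim number of null replicates.
#' @param n_perm permutations per replicate threshold.
#' @param alpha genome-wide level.
#' @param step_cM scan step.
#' @param seed integer seed.
#' @return list with `rate` (empirical exceedance fraction), `n_sim`,
#'   `exceeded` (logical per replicate), `thresholds` and `max_lods`.
#' @export
null_scan_rate <- function(map, genotypes, n_sim = 200, n_perm = 200,
                           alpha = 0.05, step_cM = 1, seed = 1) {
  set.seed(seed)
  eg <- expected_genotypes(map, genotypes, step_cM)
  n <- nrow(eg$X)
  M0 <- matrix(0, n, 0)
  keys <- rep("", nrow(eg$grid))
  exceeded <- logical(n_sim)
  thresholds <- numeric(n_sim)
  max_lods <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    y <- stats::rnorm(n)
    Y <- cbind(y, vapply(seq_len(n_perm), function(j) sample(y), numeric(n)))
    lod <- .scan_lod(eg$X, eg$grid, Y, M0, keys)
    mx <- apply(lod, 2, max)
    thresholds[i] <- stats::quantile(mx[-1], 1 - alpha, type = 7)
    max_lods[i] <- mx[1]
    exceeded[i] <- mx[1] > thresholds[i]
  }
  list(rate = mean(exceeded), n_sim = n_sim, exceeded = exceeded,
       thresholds = thresholds, max_lods = max_lods)
}

#' Power and recovery for a single planted QTL at study scale
#'
#' For each replicate: simulates DH genotypes along `map` augmented with a
#' QTL locus at (`chromosome`, `pos_cM`), draws the phenotype
#' `y = a x + Normal(0, sd)` with `x` coded -1/+1 and `sd` set from
#' `r2_target` (`r2 = a^2 / (a^2 + sd^2)` for balanced coding), scans with
#' an `n_perm`-permutation threshold, and records whether a QTL is called
#' on the planted chromosome, the peak position error, and the estimated
#' additivity and percent variance at the peak.  The QTL locus itself is
#' never given to the scan.
#'
#' @param map the scan map (e.g. a 10 cM-thinned map); the planted
#'   position need not be a marker.
#' @param n_sim replicates.
#' @param n_lines DH lines per replicate.
#' @param chromosome,pos_cM planted QTL location.
#' @param a additive effect (trait units; half class-mean difference).
#' @param r2_target variance fraction the QTL should explain.
#' @param n_perm,alpha,step_cM scan settings.
#' @param seed integer seed.
#' @return list with `detection_rate`, `position_errors` (cM, detected
#'   replicates), `additivity`, `pct_variance` (detected replicates, hence
#'   subject to winner's-curse inflation), `additivity_at_truth` and
#'   `pct_variance_at_truth` (every replicate, evaluated at the grid
#'   position nearest the planted locus), `planted` (a, sd, r2), `n_sim`.
#' @export
qtl_power_experiment <- function(map, n_sim = 200, n_lines = 127,
                                 chromosome = "7H", pos_cM = 41.67,
                                 a = 1, r2_target = 0.105, n_perm = 200,
                                 alpha = 0.05, step_cM = 1, seed = 1) {
  set.seed(seed)
  sd_e <- a * sqrt((1 - r2_target) / r2_target)
  qname <- "QTL_planted"
  aug <- rbind(as.data.frame(map),
               data.frame(chromosome = chromosome, marker = qname,
                          pos_cM = pos_cM, stringsAsFactors = FALSE))
  aug <- aug[order(match(aug$chromosome, unique(map$chromosome)),
                   aug$pos_cM), ]
  aug <- as_genetic_map(aug)
  detected <- logical(n_sim)
  pos_err <- add_est <- pct_est <- rep(NA_real_, n_sim)
  add_truth <- pct_truth <- rep(NA_real_, n_sim)
  for (i in seq_len(n_sim)) {
    g_aug <- simulate_dh_genotypes(aug, n_lines)
    x <- 2 * g_aug$calls[, qname] - 1
    y <- a * x + stats::rnorm(n_lines, 0, sd_e)
    geno <- dh_genotypes(g_aug$line_id,
                         g_aug$calls[, map$marker, drop = FALSE])
    eg <- expected_genotypes(map, geno, step_cM)
    Y <- cbind(y, vapply(seq_len(n_perm), function(j) sample(y),
                         numeric(n_lines)))
    M0 <- matrix(0, n_lines, 0)
    keys <- rep("", nrow(eg$grid))
    lod <- .scan_lod(eg$X, eg$grid, Y, M0, keys)
    thr <- stats::quantile(apply(lod[, -1, drop = FALSE], 2, max),
                           1 - alpha, type = 7)
    prep <- list(y = y, grid = eg$grid, X = eg$X, M = M0, keys = keys,
                 map = map, trait = "y", n = n_lines)
    qtl <- .call_qtl(prep, lod[, 1], thr, merge_cM = 20)
    # unconditional estimates at the grid position nearest the planted
    # locus (free of the selection bias that detection imposes on peaks)
    on_chr <- eg$grid$chromosome == chromosome
    p_true <- which(on_chr)[which.min(abs(eg$grid$pos_cM[on_chr] - pos_cM))]
    xr <- eg$X[, p_true] - mean(eg$X[, p_true])
    yr <- y - mean(y)
    b <- sum(xr * yr) / sum(xr^2)
    add_truth[i] <- b / 2
    pct_truth[i] <- 100 * b^2 * sum(xr^2) / sum(yr^2)
    hit <- qtl[qtl$chromosome == chromosome, , drop = FALSE]
    if (nrow(hit)) {
      detected[i] <- TRUE
      best <- hit[which.max(hit$lod), ]
      pos_err[i] <- abs(best$pos_cM - pos_cM)
      add_est[i] <- best$additivity
      pct_est[i] <- best$pct_variance
    }
  }
  list(detection_rate = mean(detected),
       position_errors = pos_err[detected],
       additivity = add_est[detected], pct_variance = pct_est[detected],
       additivity_at_truth = add_truth, pct_variance_at_truth = pct_truth,
       planted = list(a = a, sd = sd_e, r2 = r2_target), n_sim = n_sim)
}

#' Replicate equilibration experiments
#'
#' Runs [run_equilibration_experiment()] `n_sim` times with consecutive
#' seeds and collects the LOD at the planted focal QTL per snapshot time,
#' to assess how equilibration time orders QTL detectability on average.
#'
#' @param n_sim replicate simulations.
#' @param config base [sim_config()]; replicate `i` uses `config$seed + i`.
#' @param ... passed to [run_equilibration_experiment()].
#' @return list with `lod` (matrix, replicates x snapshot labels),
#'   `mean_lod` (named vector, in snapshot order ending at `steady`) and
#'   `n_sim`.
#' @export
equilibration_replicates <- function(n_sim = 50, config = sim_config(),
                                     ...) {
  lods <- NULL
  for (i in seq_len(n_sim)) {
    rep_i <- run_equilibration_experiment(config, seed = config$seed + i, ...)
    v <- stats::setNames(rep_i$summary$lod_at_qtl, rep_i$summary$snapshot)
    lods <- rbind(lods, v)
  }
  rownames(lods) <- NULL
  list(lod = lods, mean_lod = colMeans(lods), n_sim = n_sim)
}
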