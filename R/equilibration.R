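# In-silico equilibration-time experiment: how does insufficient chamber
# equilibration (phenotyping at 5, 10 or 15 min into induction instead of
# at steady state) degrade QTL detection for steady-state traits?
#
# The mechanism is planted, not assumed: line-to-line variation in
# stomatal opening kinetics (tau_g, the closing dip, the starting
# conductance) is statistically independent of the steady-state QTL, so an
# early snapshot reads the steady-state trait through a genotype-
# structured, kinetics-dependent attenuation - exactly the nuisance that
# should weaken (and can displace) steady-state QTL.

#' Run the equilibration-time experiment
#'
#' Simulates a full study ([simulate_study()]), extracts per-line snapshot
#' phenotypes at `snapshot_minutes` and at steady state, scans each with
#' the same engine and settings, and tabulates, per snapshot time: the
#' population distribution, the LOD at the planted focal QTL, the
#' genome-wide threshold (if permutations requested), the mean and maximum
#' percent underestimation versus steady state, and the number of lines
#' whose snapshot falls inside the simulated stomatal closing dip.
#'
#' @param config a [sim_config()]; must plant a QTL for the focal trait.
#' @param seed optional seed overriding `config$seed`.
#' @param trait `"gs"` (default) or `"A"`: which steady-state trait to
#'   scan (`gs_ss`/`A_ss` and their snapshots).
#' @param focal_chromosome chromosome of the planted QTL whose LOD is
#'   tracked; default `"7H"`.
#' @param snapshot_minutes snapshot times, minutes; default `c(5, 10, 15)`.
#' @param method `"cim"` or `"im"` scan.
#' @param step_cM,thin_cM scan step and marker-thinning spacing.
#' @param n_perm,alpha permutations per scan (0 = no thresholds).
#' @return An `equilibration_report`: list with `summary` (one row per
#'   snapshot time, steady state last), `scans` (the `qtl_scan` objects),
#'   `trait`, `focal` (chromosome/position of the tracked QTL) and
#'   `study`.
#' @export
run_equilibration_experiment <- function(config = sim_config(), seed = NULL,
                                         trait = c("gs", "A"),
                                         focal_chromosome = "7H",
                                         snapshot_minutes = c(5, 10, 15),
                                         method = c("cim", "im"),
                                         step_cM = 1, thin_cM = 10,
                                         n_perm = 0, alpha = 0.05) {
  trait <- match.arg(trait)
  method <- match.arg(method)
  if (!is.null(seed)) config$seed <- seed
  kin_par <- if (trait == "gs") "gs_ss" else "k"
  focal <- config$qtl_spec[config$qtl_spec$trait == kin_par &
                             config$qtl_spec$chromosome == focal_chromosome, ]
  if (!nrow(focal))
    stop("config plants no ", kin_par, " QTL on ", focal_chromosome,
         call. = FALSE)
  study <- simulate_study(config)
  pt <- phenotype_table(study$curves, snapshot_minutes = snapshot_minutes,
                        fit_activation = FALSE)
  phen <- pt$phenotypes

  thin <- thin_markers(study$map, study$genotypes, spacing_cM = thin_cM)
  ss_trait <- paste0(trait, "_ss")
  snap_traits <- c(paste0(trait, "_", snapshot_minutes), ss_trait)
  labels <- c(as.character(snapshot_minutes), "steady")

  # one background model for all snapshot times: cofactors are selected on
  # the steady-state trait and reused, so LOD differences across snapshots
  # reflect the phenotype, never a change of model
  cof <- if (method == "cim")
    select_cofactors(thin$map, thin$genotypes, phen, trait = ss_trait)
  else character(0)
  scan_one <- function(tr, sd_seed) {
    cim_scan(thin$map, thin$genotypes, phen, trait = tr, step_cM = step_cM,
             cofactors = cof, n_perm = n_perm, alpha = alpha, seed = sd_seed)
  }
  lod_at <- function(scan, chr, pos) {
    pr <- scan$profile[scan$profile$chromosome == chr, ]
    pr$lod[which.min(abs(pr$pos_cM - pos))]
  }

  # lines whose snapshot sits inside the simulated closing dip
  dip_at <- function(m) {
    with(study$truth,
         dip_amp * (m / tau_dip) * exp(1 - m / tau_dip) > 0.02 * gs_ss)
  }

  scans <- list()
  rows <- list()
  ss_vals <- phen[[ss_trait]]
  for (i in seq_along(snap_traits)) {
    tr <- snap_traits[i]
    scans[[labels[i]]] <- scan_one(tr, if (n_perm > 0) config$seed + i else NULL)
    vals <- phen[[tr]]
    und <- pct_underestimation(vals, ss_vals)
    smry <- population_summary(phen, tr)
    rows[[i]] <- data.frame(
      snapshot = labels[i], trait = tr, n = smry$n, min = smry$min,
      q25 = smry$q25, median = smry$median, q75 = smry$q75, max = smry$max,
      mean = smry$mean,
      lod_at_qtl = lod_at(scans[[labels[i]]], focal$chromosome[1],
                          focal$pos_cM[1]),
      threshold = scans[[labels[i]]]$threshold,
      mean_underestimation_pct = mean(und, na.rm = TRUE),
      max_underestimation_pct = max(und, na.rm = TRUE),
      n_dip_flagged = if (labels[i] == "steady") 0L
                      else sum(dip_at(snapshot_minutes[i])),
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(summary = summary, scans = scans, trait = trait,
                 focal = list(chromosome = focal$chromosome[1],
                              pos_cM = focal$pos_cM[1], a = focal$a[1]),
                 study = study),
            class = "equilibration_report")
}

#' @export
print.equilibration_report <- function(x, ...) {
  cat(sprintf("<equilibration_report> trait %s, focal QTL %s @ %.2f cM\n",
              x$trait, x$focal$chromosome, x$focal$pos_cM))
  print(x$summary[, c("snapshot", "median", "mean", "lod_at_qtl",
                      "mean_underestimation_pct", "n_dip_flagged")],
        digits = 4, row.names = FALSE)
  invisible(x)
}
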