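# Reproducible pipeline stages.  Each run_* function wraps one analysis
# stage, writes its outputs as the package's CSV dialects under a run
# directory, and finishes with a manifest (seed, config hash, file
# inventory with md5 checksums) so that two runs with identical config and
# seed are verifiably identical.

.write_manifest <- function(out_dir, seed, config = NULL, stage = "run") {
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  cfg_hash <- NA_character_
  if (!is.null(config)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(config, tmp)
    cfg_hash <- unname(tools::md5sum(tmp))
  }
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("sunqtl")),
    seed = seed, config_hash = cfg_hash,
    files = as.list(stats::setNames(unname(sums), files)),
    created_utc = format(Sys.time(), tz = "UTC", "%Y-%m-%dT%H:%M:%SZ"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a pipeline run manifest
#'
#' @param out_dir a run directory written by a `run_*` function.
#' @return the manifest as a list.
#' @export
read_manifest <- function(out_dir) {
  jsonlite::read_json(file.path(out_dir, "manifest.json"))
}

#' Simulate a study and write the dataset
#'
#' Wraps [simulate_study()]: writes `map.csv`, `genotypes.csv`,
#' `curves.csv`, `truth.csv` (the planted-parameter ledger),
#' `config.yaml` and `manifest.json` under `out_dir`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return the `sim_study`, invisibly.
#' @export
run_simulation <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(config)
  write_map(study$map, file.path(out_dir, "map.csv"))
  write_genotypes(study$genotypes, file.path(out_dir, "genotypes.csv"))
  write_curves(study$curves, file.path(out_dir, "curves.csv"))
  .write_csv_precise(study$truth, file.path(out_dir, "truth.csv"))
  .write_csv_precise(study$qtl, file.path(out_dir, "planted_qtl.csv"))
  cfg <- config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  .write_manifest(out_dir, config$seed, cfg, "simulate")
  invisible(study)
}

#' Phenotype a directory or file of curves
#'
#' Wraps [phenotype_table()]: reads `curves.csv` (or the given file),
#' writes `phenotypes.csv` (per-line medians) and `diagnostics.csv`
#' (per-leaf fits: window, R2, status) plus a manifest.
#'
#' @param curves_path a curves CSV file, or a directory containing
#'   `curves.csv`.
#' @param out_dir output directory.
#' @param ... passed to [phenotype_table()].
#' @return list with `phenotypes` and `diagnostics`, invisibly.
#' @export
run_phenotyping <- function(curves_path, out_dir, ...) {
  f <- if (dir.exists(curves_path))
    file.path(curves_path, "curves.csv") else curves_path
  if (!file.exists(f))
    stop("no curves file found at '", f, "'", call. = FALSE)
  curves <- read_curves(f)
  res <- phenotype_table(curves, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_phenotypes(res$phenotypes, file.path(out_dir, "phenotypes.csv"))
  .write_csv_precise(res$diagnostics, file.path(out_dir, "diagnostics.csv"))
  .write_manifest(out_dir, NA_integer_, NULL, "phenotype")
  invisible(res)
}

#' Scan one trait and write the results
#'
#' Wraps [cim_scan()] / [im_scan()]: thins the map to `thin_cM`, scans
#' `trait`, and writes `lod_profile.csv`, `qtl_table.csv` and
#' `run_meta.json` (threshold and settings) plus a manifest.
#'
#' @param map a `genetic_map` or path to a map CSV.
#' @param genotypes a [dh_genotypes()] or path to a genotype CSV.
#' @param phenotypes a phenotype data.frame or path to a phenotype CSV.
#' @param trait trait column name.
#' @param out_dir output directory.
#' @param method `"cim"` (default) or `"im"`.
#' @param thin_cM marker-thinning spacing, cM (default 10).
#' @param step_cM scan step (default 1 cM).
#' @param n_perm,alpha,seed permutation settings (default 1000, 0.05).
#' @param ... further arguments to the scan function.
#' @return the `qtl_scan`, invisibly.
#' @export
run_scan <- function(map, genotypes, phenotypes, trait, out_dir,
                     method = c("cim", "im"), thin_cM = 10, step_cM = 1,
                     n_perm = 1000, alpha = 0.05, seed = 1, ...) {
  method <- match.arg(method)
  if (is.character(map)) map <- read_map(map)
  if (is.character(genotypes)) genotypes <- read_genotypes(genotypes)
  if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)
  thin <- thin_markers(map, genotypes, spacing_cM = thin_cM)
  scan <- if (method == "cim")
    cim_scan(thin$map, thin$genotypes, phenotypes, trait = trait,
             step_cM = step_cM, n_perm = n_perm, alpha = alpha,
             seed = seed, ...)
  else
    im_scan(thin$map, thin$genotypes, phenotypes, trait = trait,
            step_cM = step_cM, n_perm = n_perm, alpha = alpha,
            seed = seed, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_csv_precise(scan$profile, file.path(out_dir, "lod_profile.csv"))
  .write_csv_precise(scan$qtl, file.path(out_dir, "qtl_table.csv"))
  meta <- scan$settings
  meta$threshold <- scan$threshold
  meta$method <- method
  jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_manifest(out_dir, seed, NULL, "scan")
  invisible(scan)
}

#' Run the equilibration experiment and write the report
#'
#' Wraps [run_equilibration_experiment()]: writes
#' `equilibration_report.csv` (one row per snapshot time) and per-snapshot
#' LOD profiles, plus a manifest.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param seed optional seed overriding `config$seed`.
#' @param ... passed to [run_equilibration_experiment()].
#' @return the `equilibration_report`, invisibly.
#' @export
run_equilibration <- function(config = sim_config(), out_dir, seed = NULL,
                              ...) {
  rep <- run_equilibration_experiment(config, seed = seed, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_csv_precise(rep$summary, file.path(out_dir, "equilibration_report.csv"))
  for (nm in names(rep$scans))
    .write_csv_precise(rep$scans[[nm]]$profile,
                       file.path(out_dir, sprintf("lod_profile_%s.csv", nm)))
  .write_manifest(out_dir, seed %||% config$seed, NULL, "equilibration")
  invisible(rep)
}

#' End-to-end demonstration run at study scale
#'
#' Simulates the default 127-line study (7 chromosomes, 1127 cM), extracts
#' phenotypes from the curves, scans the activation rate and the
#' steady-state traits with permutation thresholds, and runs one
#' equilibration experiment.  Outputs (per-genotype phenotype
#' distributions, LOD profiles, QTL tables, equilibration report) land in
#' subdirectories of `out_dir`, each with its own manifest.
#'
#' @param out_dir output directory.
#' @param seed integer seed for the whole demo.
#' @param n_perm permutations per scan (default 1000).
#' @return list with `study`, `phenotypes`, `scans`, `equilibration`,
#'   invisibly.
#' @export
run_demo <- function(out_dir, seed = 1, n_perm = 1000) {
  cfg <- sim_config(seed = seed)
  study <- run_simulation(cfg, file.path(out_dir, "dataset"))
  phen <- run_phenotyping(file.path(out_dir, "dataset"),
                          file.path(out_dir, "phenotypes"))
  scans <- list()
  for (tr in c("one_over_tau", "A_ss", "gs_ss"))
    scans[[tr]] <- run_scan(study$map, study$genotypes, phen$phenotypes,
                            trait = tr, out_dir = file.path(out_dir, paste0("scan_", tr)),
                            n_perm = n_perm, seed = seed + match(tr, c("one_over_tau", "A_ss", "gs_ss")))
  eq <- run_equilibration(cfg, file.path(out_dir, "equilibration"),
                          n_perm = 0)
  invisible(list(study = study, phenotypes = phen, scans = scans,
                 equilibration = eq))
}
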