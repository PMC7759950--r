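# Delimited-text I/O for induction curves, phenotype tables, genetic maps
# and DH genotype matrices.  All files are plain UTF-8 CSV with one header
# row; numeric fields are written with 17 significant digits so that a
# write/read round trip is lossless at double precision.  Missing values are
# empty fields, never zeros.

CURVE_COLUMNS <- c("genotype", "replicate", "time_min", "A", "gs", "ci",
                   "ca", "ppfd", "tleaf")

#' Construct an induction curve
#'
#' One leaf's minute-by-minute gas-exchange record after the step from
#' moderate (600) to saturating (1300 umol m-2 s-1) light.  Trace vectors
#' run in time order; chamber conditions (`ca`, `ppfd_high`, `tleaf_C`) are
#' scalars for the whole trace.
#'
#' @param genotype_id,replicate_id identifiers for the line and the leaf.
#' @param time_min minutes since chamber enclosure; strictly increasing,
#'   first value >= 0.
#' @param A net photosynthesis, umol m-2 s-1.
#' @param gs stomatal conductance to water vapour, mol m-2 s-1; positive.
#' @param ci intercellular CO2, umol mol-1; positive, and below `ca`
#'   wherever `A > 0`.
#' @param ca cuvette CO2, umol mol-1 (nominal 400).
#' @param ppfd_high saturating light level, umol m-2 s-1 (nominal 1300).
#' @param tleaf_C leaf temperature, degrees C (nominal 25).
#'
#' @return An object of class `induction_curve`.
#' @export
induction_curve <- function(genotype_id, replicate_id, time_min, A, gs, ci,
                            ca = 400, ppfd_high = 1300, tleaf_C = 25) {
  x <- structure(
    list(genotype_id = as.character(genotype_id),
         replicate_id = as.character(replicate_id),
         time_min = as.numeric(time_min),
         A = as.numeric(A), gs = as.numeric(gs), ci = as.numeric(ci),
         ca = as.numeric(ca)[1], ppfd_high = as.numeric(ppfd_high)[1],
         tleaf_C = as.numeric(tleaf_C)[1]),
    class = "induction_curve")
  validate_curve(x)
  x
}

#' Validate an induction curve's invariants
#'
#' Checks trace lengths, time monotonicity, positivity of `ci` and `gs`, and
#' the supply constraint `ci < ca` wherever `A > 0`.  Missing values in the
#' traces are tolerated (they propagate through downstream arithmetic);
#' missing times are not.
#'
#' @param x an `induction_curve`.
#' @return `x`, invisibly; otherwise an error naming the offending group.
#' @export
validate_curve <- function(x) {
  grp <- paste0(x$genotype_id, ":", x$replicate_id)
  n <- length(x$time_min)
  lens <- c(length(x$A), length(x$gs), length(x$ci))
  if (n < 3 || any(lens != n))
    stop("curve [", grp, "]: trace sequences must have equal length >= 3",
         call. = FALSE)
  if (anyNA(x$time_min) || x$time_min[1] < 0 || any(diff(x$time_min) <= 0))
    stop("curve [", grp, "]: time_min must be strictly increasing and start >= 0",
         call. = FALSE)
  bad_ci <- which(x$ci <= 0)
  if (length(bad_ci))
    stop("curve [", grp, "]: ci must be positive at every record (time ",
         paste(x$time_min[bad_ci], collapse = ", "), ")", call. = FALSE)
  bad_gs <- which(x$gs <= 0)
  if (length(bad_gs))
    stop("curve [", grp, "]: gs must be positive at every record (time ",
         paste(x$time_min[bad_gs], collapse = ", "), ")", call. = FALSE)
  bad <- which(x$A > 0 & x$ci >= x$ca)
  if (length(bad))
    stop("curve [", grp, "]: ci >= ca at record(s) with A > 0 (time ",
         paste(x$time_min[bad], collapse = ", "), ")", call. = FALSE)
  invisible(x)
}

#' @export
print.induction_curve <- function(x, ...) {
  cat(sprintf("<induction_curve> %s:%s, %d records, %.0f-%.0f min, ca=%g\n",
              x$genotype_id, x$replicate_id, length(x$time_min),
              min(x$time_min), max(x$time_min), x$ca))
  invisible(x)
}

# format doubles at 17 significant digits (lossless), NA -> empty field
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

.write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
    if (is.logical(out[[j]])) out[[j]] <- as.character(out[[j]])
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write '", path, "': ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

.read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " file '", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Read induction curves from CSV
#'
#' Long-format dialect: one row per logged minute per leaf, columns
#' `genotype,replicate,time_min,A,gs,ci,ca,ppfd,tleaf`.  Rows belonging to
#' one `(genotype, replicate)` group must appear in strictly increasing time
#' order; violations raise a validation error naming the group.
#'
#' @param path CSV file path.
#' @return A named list of [induction_curve()] objects
#'   (names `"genotype:replicate"`), in file order.
#' @seealso [write_curves()]
#' @export
read_curves <- function(path) {
  df <- .read_csv_checked(path, CURVE_COLUMNS, "curve")
  key <- paste0(df$genotype, ":", df$replicate)
  out <- list()
  for (k in unique(key)) {
    g <- df[key == k, , drop = FALSE]
    if (any(diff(g$time_min) <= 0))
      stop("curve [", k, "]: time_min not strictly increasing in file '",
           path, "'", call. = FALSE)
    out[[k]] <- induction_curve(
      genotype_id = g$genotype[1], replicate_id = g$replicate[1],
      time_min = g$time_min, A = g$A, gs = g$gs, ci = g$ci,
      ca = g$ca[1], ppfd_high = g$ppfd[1], tleaf_C = g$tleaf[1])
  }
  out
}

#' Write induction curves to CSV
#'
#' Inverse of [read_curves()]; numeric round trip is lossless.
#'
#' @param curves a list of `induction_curve` objects (or a single one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "induction_curve")) curves <- list(curves)
  rows <- lapply(curves, function(x) {
    n <- length(x$time_min)
    data.frame(genotype = rep(x$genotype_id, n),
               replicate = rep(x$replicate_id, n),
               time_min = x$time_min, A = x$A, gs = x$gs, ci = x$ci,
               ca = rep(x$ca, n), ppfd = rep(x$ppfd_high, n),
               tleaf = rep(x$tleaf_C, n), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  .write_csv_precise(df[, CURVE_COLUMNS], path)
}

#' Read or write a phenotype table
#'
#' Phenotype CSV dialect: `line_id` plus one numeric column per trait
#' (canonical traits: `one_over_tau`, `A_ss`, `gs_ss`, `A_5`, `A_10`,
#' `A_15`, `gs_5`, `gs_10`, `gs_15`).  Missing values are empty fields.
#' Line ids must be unique.
#'
#' @param path CSV file path.
#' @return `read_phenotypes`: a data.frame with `line_id` first.
#' @export
read_phenotypes <- function(path) {
  df <- .read_csv_checked(path, "line_id", "phenotype")
  df$line_id <- as.character(df$line_id)
  if (anyDuplicated(df$line_id))
    stop("phenotype file '", path, "': duplicated line_id(s): ",
         paste(unique(df$line_id[duplicated(df$line_id)]), collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_phenotypes
#' @param table a phenotype data.frame (`line_id` plus trait columns).
#' @export
write_phenotypes <- function(table, path) {
  stopifnot(is.data.frame(table), "line_id" %in% names(table))
  cols <- c("line_id", setdiff(names(table), "line_id"))
  .write_csv_precise(table[, cols, drop = FALSE], path)
}

#' Read or write a genetic map
#'
#' Map CSV dialect: `chromosome,marker,pos_cM`.  Positions must be
#' non-negative and non-decreasing within a chromosome; marker names unique.
#'
#' @param path CSV file path.
#' @return `read_map`: a `genetic_map` data.frame.
#' @export
read_map <- function(path) {
  df <- .read_csv_checked(path, c("chromosome", "marker", "pos_cM"), "map")
  as_genetic_map(df)
}

#' @rdname read_map
#' @param map a `genetic_map` (or compatible data.frame).
#' @export
write_map <- function(map, path) {
  .write_csv_precise(as.data.frame(map)[, c("chromosome", "marker", "pos_cM")],
                     path)
}

# validate + class-tag a map data.frame
as_genetic_map <- function(df) {
  df$chromosome <- as.character(df$chromosome)
  df$marker <- as.character(df$marker)
  if (anyDuplicated(df$marker))
    stop("map: duplicated marker name(s)", call. = FALSE)
  for (chr in unique(df$chromosome)) {
    p <- df$pos_cM[df$chromosome == chr]
    if (any(p < 0) || any(diff(p) < 0))
      stop("map: positions on chromosome ", chr,
           " must be non-negative and non-decreasing", call. = FALSE)
  }
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Read or write DH genotypes
#'
#' Genotype CSV dialect: `line_id` plus one column per marker holding the
#' parental-origin code (0 = parent A, 1 = parent B, empty = missing).  DH
#' lines are homozygous, so a single code per line/marker is the complete
#' genotype.
#'
#' @param path CSV file path.
#' @return `read_genotypes`: a `dh_genotypes` object: list with `line_id`
#'   (character) and `calls` (integer matrix, lines x markers, dimnames
#'   set).
#' @export
read_genotypes <- function(path) {
  df <- .read_csv_checked(path, "line_id", "genotype")
  ids <- as.character(df$line_id)
  if (anyDuplicated(ids)) stop("genotypes: duplicated line_id(s)", call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "line_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  bad <- !(m %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("genotypes: calls must be 0, 1 or missing", call. = FALSE)
  rownames(m) <- ids
  dh_genotypes(ids, m)
}

#' @rdname read_genotypes
#' @param genotypes a `dh_genotypes` object.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(line_id = genotypes$line_id, stringsAsFactors = FALSE)
  calls <- as.data.frame(genotypes$calls)
  df <- cbind(df, calls)
  .write_csv_precise(df, path)
}

#' @rdname read_genotypes
#' @param line_id character vector of line identifiers.
#' @param calls integer matrix of 0/1/NA parental-origin codes,
#'   lines x markers, with marker column names.
#' @export
dh_genotypes <- function(line_id, calls) {
  stopifnot(length(line_id) == nrow(calls), !is.null(colnames(calls)))
  rownames(calls) <- line_id
  structure(list(line_id = as.character(line_id), calls = calls),
            class = "dh_genotypes")
}

#' @export
print.dh_genotypes <- function(x, ...) {
  cat(sprintf("<dh_genotypes> %d lines x %d markers (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}
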