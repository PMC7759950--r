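# From-scratch genome scan for DH populations: marker thinning, single-
# marker regression, Haley-Knott interval mapping, composite interval
# mapping (CIM) with forward-selected cofactors and a map-distance
# exclusion window, permutation thresholds and QTL summarization.
#
# Everything reduces to least squares on two genotype classes: for DH lines
# the QTL genotype is 0/1, and at an untyped position Haley-Knott replaces
# it by its conditional expectation given the flanking markers under the
# Haldane (Markov, no-interference) model.  LOD = (n/2) log10(RSS0/RSS1)
# with RSS0 from the model without the position term.  This keeps every
# scan deterministic and verifiable against closed forms, and for balanced
# two-class data is near-identical to the full ML mixture.

LOD_CAP <- 300  # reported LOD when the full model fits exactly (RSS1 = 0)

#' Thin markers to a target spacing
#'
#' Greedy left-to-right selection per chromosome: keep the first marker,
#' then the next marker at least `spacing_cM` away, and always retain the
#' chromosome end.  Idempotent on already-sparse maps.
#'
#' @param map a `genetic_map`.
#' @param genotypes optional [dh_genotypes()] to subset alongside.
#' @param spacing_cM target spacing, cM (default 10, even genome coverage).
#' @return list with `map` and `genotypes` (NULL if not supplied).
#' @export
thin_markers <- function(map, genotypes = NULL, spacing_cM = 10) {
  stopifnot(spacing_cM > 0)
  keep <- logical(nrow(map))
  for (chr in unique(map$chromosome)) {
    j <- which(map$chromosome == chr)
    last <- -Inf
    for (i in j) {
      if (map$pos_cM[i] >= last + spacing_cM - 1e-9) {
        keep[i] <- TRUE
        last <- map$pos_cM[i]
      }
    }
    keep[j[length(j)]] <- TRUE  # chromosome end always retained
  }
  m <- as_genetic_map(as.data.frame(map)[keep, , drop = FALSE])
  g <- if (!is.null(genotypes))
    dh_genotypes(genotypes$line_id,
                 genotypes$calls[, m$marker, drop = FALSE]) else NULL
  list(map = m, genotypes = g)
}

#' Single-marker LOD score
#'
#' `LOD = (n/2) log10(RSS0 / RSS1)` where RSS0 is the residual sum of
#' squares of the intercept-only model and RSS1 adds the 0/1 marker term
#' (equivalently, within-class RSS).  Lines missing either value are
#' dropped pairwise.  A monomorphic marker gives LOD 0 with a warning; an
#' exact fit is capped at `r LOD_CAP`.
#'
#' @param x marker calls, 0/1 (NA allowed).
#' @param y phenotype values.
#' @return LOD score (scalar).
#' @export
marker_lod <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(y)
  if (n < 3) stop("need >= 3 lines with non-missing marker and phenotype",
                  call. = FALSE)
  if (length(unique(x)) < 2) {
    warning("monomorphic marker: LOD = 0")
    return(0)
  }
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum((y - stats::ave(y, x))^2)
  if (rss0 == 0) return(0)
  if (rss1 <= rss0 * 1e-290) return(LOD_CAP)
  min((n / 2) * log10(rss0 / rss1), LOD_CAP)
}

# conditional P(x = 1 | flanks) for a DH gamete under the Markov model;
# p(a -> b over recombination fraction r) = r if a != b else 1 - r.
.cond_prob <- function(xL, xR, rL, rR) {
  num1 <- (xL * (1 - rL) + (1 - xL) * rL) * (xR * (1 - rR) + (1 - xR) * rR)
  num0 <- ((1 - xL) * (1 - rL) + xL * rL) * ((1 - xR) * (1 - rR) + xR * rR)
  num1 / (num1 + num0)
}

#' Expected QTL genotypes on a scan grid
#'
#' For every grid position (a `step_cM` lattice per chromosome, with all
#' marker positions included so the scan collapses exactly onto marker
#' regressions there) computes `E[x | flanking markers]` for each line
#' under the Haldane model: at a typed marker the expectation is the
#' observed call; between markers it is the Markov conditional probability;
#' where a flank call is missing, conditioning falls back to the nearest
#' typed marker on each side (single-sided at chromosome ends; 0.5 when a
#' line has no typed marker on the chromosome).
#'
#' @param map a `genetic_map`.
#' @param genotypes a [dh_genotypes()] aligned to `map`.
#' @param step_cM grid step, cM.
#' @return list with `grid` (data.frame `chromosome, pos_cM`) and `X`
#'   (lines x positions matrix of expectations in `[0, 1]`).
#' @export
expected_genotypes <- function(map, genotypes, step_cM = 1) {
  calls <- genotypes$calls[, map$marker, drop = FALSE]
  n <- nrow(calls)
  grid_list <- list(); X_list <- list()
  for (chr in unique(map$chromosome)) {
    j <- which(map$chromosome == chr)
    pos <- map$pos_cM[j]
    C <- calls[, j, drop = FALSE]
    g <- sort(unique(round(c(seq(min(pos), max(pos), by = step_cM), pos), 9)))
    P <- length(g)
    Lix <- findInterval(g, pos)            # last marker with pos <= g
    Rix <- pmin(Lix + 1, length(pos))
    at_marker <- abs(g - pos[Lix]) < 1e-8
    Rix[at_marker] <- Lix[at_marker]
    dL <- g - pos[Lix]
    dR <- pos[Rix] - g
    rL <- haldane_r(pmax(dL, 0)); rR <- haldane_r(pmax(dR, 0))
    # coefficient vectors of E[x] = c00 (1-xL)(1-xR) + c10 xL (1-xR)
    #                              + c01 (1-xL) xR + c11 xL xR
    c11 <- ifelse(at_marker, 1, .cond_prob(1, 1, rL, rR))
    c10 <- ifelse(at_marker, 1, .cond_prob(1, 0, rL, rR))
    c01 <- ifelse(at_marker, 0, .cond_prob(0, 1, rL, rR))
    c00 <- ifelse(at_marker, 0, .cond_prob(0, 0, rL, rR))
    XL <- C[, Lix, drop = FALSE]; XR <- C[, Rix, drop = FALSE]
    Xe <- t(t((1 - XL) * (1 - XR)) * c00 + t(XL * (1 - XR)) * c10 +
              t((1 - XL) * XR) * c01 + t(XL * XR) * c11)
    if (anyNA(Xe)) Xe <- .fix_missing_flanks(Xe, C, pos, g)
    grid_list[[chr]] <- data.frame(chromosome = chr, pos_cM = g,
                                   stringsAsFactors = FALSE)
    X_list[[chr]] <- Xe
  }
  list(grid = do.call(rbind, grid_list), X = do.call(cbind, X_list))
}

# slow path: recompute E[x] for (line, position) cells whose default flank
# call is missing, conditioning on the nearest typed markers instead
.fix_missing_flanks <- function(Xe, C, pos, g) {
  bad <- which(is.na(Xe), arr.ind = TRUE)
  for (b in seq_len(nrow(bad))) {
    i <- bad[b, 1]; p <- bad[b, 2]
    typed <- which(!is.na(C[i, ]))
    if (!length(typed)) { Xe[i, p] <- 0.5; next }
    left <- typed[pos[typed] <= g[p] + 1e-9]
    right <- typed[pos[typed] >= g[p] - 1e-9]
    L <- if (length(left)) left[length(left)] else NA
    R <- if (length(right)) right[1] else NA
    if (!is.na(L) && abs(pos[L] - g[p]) < 1e-8) {
      Xe[i, p] <- C[i, L]
    } else if (!is.na(L) && !is.na(R)) {
      Xe[i, p] <- .cond_prob(C[i, L], C[i, R],
                             haldane_r(g[p] - pos[L]),
                             haldane_r(pos[R] - g[p]))
    } else if (!is.na(L)) {
      r <- haldane_r(g[p] - pos[L])
      Xe[i, p] <- if (C[i, L] == 1) 1 - r else r
    } else {
      r <- haldane_r(pos[R] - g[p])
      Xe[i, p] <- if (C[i, R] == 1) 1 - r else r
    }
  }
  Xe
}

# ---- internal scan machinery ---------------------------------------------

# normalize phenotype input to a vector aligned with genotype lines
.align_phenotype <- function(genotypes, phenotype, trait = NULL) {
  if (is.data.frame(phenotype)) {
    if (is.null(trait)) {
      num <- names(phenotype)[vapply(phenotype, is.numeric, logical(1))]
      trait <- setdiff(num, "line_id")[1]
    }
    if (!trait %in% names(phenotype))
      stop("trait '", trait, "' not found in phenotype table", call. = FALSE)
    idx <- match(genotypes$line_id, phenotype$line_id)
    y <- phenotype[[trait]][idx]
  } else {
    if (length(phenotype) != length(genotypes$line_id))
      stop("phenotype vector length must match the number of lines",
           call. = FALSE)
    y <- as.numeric(phenotype)
  }
  list(y = y, trait = trait %||% "trait")
}

# mean-imputed 0/1 cofactor matrix (imputation only affects the background
# adjustment, never the tested position)
.cofactor_matrix <- function(genotypes, map, markers) {
  if (!length(markers)) {
    return(list(M = matrix(0, nrow(genotypes$calls), 0),
                pos = map[0, , drop = FALSE]))
  }
  M <- genotypes$calls[, markers, drop = FALSE]
  storage.mode(M) <- "double"
  for (j in seq_len(ncol(M))) {
    na <- is.na(M[, j])
    if (any(na)) M[na, j] <- mean(M[!na, j])
  }
  list(M = M, pos = as.data.frame(map)[match(markers, map$marker), ,
                                       drop = FALSE])
}

# active-cofactor key per grid position: cofactors on the same chromosome
# within window_cM of the tested position are excluded from the model
.active_keys <- function(grid, cof_pos, window_cM) {
  if (!nrow(cof_pos)) return(rep("", nrow(grid)))
  vapply(seq_len(nrow(grid)), function(p) {
    excl <- cof_pos$chromosome == grid$chromosome[p] &
      abs(cof_pos$pos_cM - grid$pos_cM[p]) < window_cM
    paste(which(!excl), collapse = ",")
  }, character(1))
}

# LOD matrix (positions x phenotype columns) for expected genotypes X,
# phenotype matrix Y, cofactor matrix M with per-position active sets
.scan_lod <- function(X, grid, Y, M, keys) {
  n <- nrow(X)
  LOD <- matrix(0, ncol(X), ncol(Y))
  for (key in unique(keys)) {
    cols <- which(keys == key)
    act <- if (nzchar(key)) as.integer(strsplit(key, ",")[[1]]) else integer(0)
    C <- cbind(1, M[, act, drop = FALSE])
    qrC <- qr(C)
    Yr <- qr.resid(qrC, Y)
    Xr <- qr.resid(qrC, X[, cols, drop = FALSE])
    rss0 <- colSums(Yr^2)
    sxx <- colSums(Xr^2)
    sxy <- crossprod(Xr, Yr)                    # |cols| x K
    rss1 <- sweep(-sxy^2 / pmax(sxx, 1e-300), 2, rss0, "+")
    ratio <- sweep(rss1, 2, pmax(rss0, 1e-300), "/")
    lod <- -(n / 2) * log10(pmax(ratio, 10^(-2 * LOD_CAP / n)))
    lod[sxx < 1e-10, ] <- 0                     # no genotype information
    lod[lod < 0] <- 0
    LOD[cols, ] <- lod
  }
  LOD
}

# shared preparation for im_scan / cim_scan / permutation_threshold
.prepare_scan <- function(map, genotypes, phenotype, trait, step_cM,
                          cofactors, window_cM, n_cofactors) {
  ph <- .align_phenotype(genotypes, phenotype, trait)
  ok <- !is.na(ph$y)
  geno <- dh_genotypes(genotypes$line_id[ok],
                       genotypes$calls[ok, , drop = FALSE])
  y <- ph$y[ok]
  if (is.null(cofactors) && n_cofactors > 0)
    cofactors <- select_cofactors(map, geno, y, n_cofactors = n_cofactors)
  cofactors <- cofactors %||% character(0)
  eg <- expected_genotypes(map, geno, step_cM)
  cf <- .cofactor_matrix(geno, map, cofactors)
  keys <- .active_keys(eg$grid, cf$pos, window_cM)
  list(map = map, geno = geno, y = y, trait = ph$trait, grid = eg$grid,
       X = eg$X, M = cf$M, cof_pos = cf$pos, cofactors = cofactors,
       keys = keys, n = length(y))
}

.perm_threshold <- function(prep, n_perm, alpha, seed) {
  if (!is.null(seed)) set.seed(seed)
  Yp <- vapply(seq_len(n_perm), function(i) sample(prep$y),
               numeric(prep$n))
  maxl <- apply(.scan_lod(prep$X, prep$grid, Yp, prep$M, prep$keys), 2, max)
  list(threshold = unname(stats::quantile(maxl, 1 - alpha, type = 7)),
       max_lods = maxl)
}

# peak finding: local maxima >= threshold, leftmost point of plateaus,
# merged within merge_cM (higher peak wins; ties resolved leftmost)
.find_peaks <- function(pos, lod, threshold, merge_cM) {
  cand <- integer(0)
  n <- length(lod)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && lod[j + 1] == lod[i]) j <- j + 1
    left_ok <- i == 1 || lod[i - 1] < lod[i]
    right_ok <- j == n || lod[j + 1] < lod[i]
    if (left_ok && right_ok && lod[i] >= threshold) cand <- c(cand, i)
    i <- j + 1
  }
  if (!length(cand)) return(integer(0))
  ord <- cand[order(-lod[cand], pos[cand])]
  kept <- integer(0)
  for (p in ord)
    if (!length(kept) || all(abs(pos[kept] - pos[p]) >= merge_cM))
      kept <- c(kept, p)
  sort(kept)
}

.call_qtl <- function(prep, lod, threshold, merge_cM) {
  empty <- data.frame(name = character(0), chromosome = character(0),
                      pos_cM = numeric(0), nearest_marker = character(0),
                      lod = numeric(0), additivity = numeric(0),
                      pct_variance = numeric(0), stringsAsFactors = FALSE)
  if (is.na(threshold)) return(empty)
  y <- prep$y
  tss <- sum((y - mean(y))^2)
  rows <- list()
  for (chr in unique(prep$grid$chromosome)) {
    sel <- which(prep$grid$chromosome == chr)
    pk <- .find_peaks(prep$grid$pos_cM[sel], lod[sel], threshold, merge_cM)
    for (p in sel[pk]) {
      act <- if (nzchar(prep$keys[p]))
        as.integer(strsplit(prep$keys[p], ",")[[1]]) else integer(0)
      C <- cbind(1, prep$M[, act, drop = FALSE])
      qrC <- qr(C)
      yr <- qr.resid(qrC, y)
      xr <- qr.resid(qrC, prep$X[, p])
      sxx <- sum(xr^2)
      b <- if (sxx > 1e-10) sum(xr * yr) / sxx else 0
      rss0 <- sum(yr^2)
      rss1 <- rss0 - b^2 * sxx
      mk <- prep$map[prep$map$chromosome == chr, , drop = FALSE]
      nearest <- mk$marker[which.min(abs(mk$pos_cM - prep$grid$pos_cM[p]))]
      rows[[length(rows) + 1]] <- data.frame(
        name = sprintf("Q%s.%s", prep$trait, chr), chromosome = chr,
        pos_cM = prep$grid$pos_cM[p], nearest_marker = nearest,
        lod = lod[p], additivity = b / 2,
        pct_variance = 100 * (rss0 - rss1) / tss, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # disambiguate names when a chromosome carries several peaks
  dup <- duplicated(out$name) | duplicated(out$name, fromLast = TRUE)
  out$name[dup] <- sprintf("%s@%.1f", out$name[dup], out$pos_cM[dup])
  rownames(out) <- NULL
  out
}

# ---- user-facing scans ----------------------------------------------------

#' Composite interval mapping scan
#'
#' Haley-Knott regression on expected QTL genotypes along a `step_cM` grid,
#' with background marker cofactors in both the null and full models.
#' Cofactors within `window_cM` (map distance, same chromosome) of the
#' tested position are excluded so the background never absorbs the local
#' signal.  With `cofactors = character(0)` (or `n_cofactors = 0`) the scan
#' reduces exactly to plain interval mapping ([im_scan()]).
#'
#' When `n_perm > 0` a genome-wide significance threshold is computed by
#' permuting the phenotype over lines (genotypes and cofactor set fixed)
#' and taking the `1 - alpha` empirical quantile of the per-permutation
#' maximum LOD; QTL are then called at local maxima at or above the
#' threshold, merged within `merge_cM`.
#'
#' @param map a `genetic_map` (typically thinned, see [thin_markers()]).
#' @param genotypes a [dh_genotypes()].
#' @param phenotype phenotype data.frame (`line_id` + traits) or a numeric
#'   vector aligned to `genotypes$line_id`; missing lines are dropped.
#' @param trait trait column to scan (default: first trait column).
#' @param step_cM scan step, cM.
#' @param window_cM cofactor exclusion window, cM.
#' @param cofactors character vector of cofactor marker names; `NULL`
#'   selects up to `n_cofactors` by forward stepwise regression
#'   ([select_cofactors()]).
#' @param n_cofactors maximum number of auto-selected cofactors.
#' @param n_perm number of permutations (0 = no threshold, no QTL calls).
#' @param alpha genome-wide significance level.
#' @param seed seed for the permutation stream (recorded in the result).
#' @param threshold externally supplied LOD threshold (e.g. 2.5); overrides
#'   permutation.
#' @param merge_cM peak merging radius, cM.
#' @return A `qtl_scan`: list with `profile` (`chromosome, pos_cM, lod`),
#'   `threshold`, `qtl` (one row per detected QTL: name, chromosome,
#'   position, nearest marker, LOD, additivity = half the fitted class-mean
#'   difference signed by the parent-B allele, percent variance explained),
#'   and `settings`.
#' @export
cim_scan <- function(map, genotypes, phenotype, trait = NULL, step_cM = 1,
                     window_cM = 10, cofactors = NULL, n_cofactors = 5,
                     n_perm = 0, alpha = 0.05, seed = NULL, threshold = NULL,
                     merge_cM = 20) {
  prep <- .prepare_scan(map, genotypes, phenotype, trait, step_cM,
                        cofactors, window_cM, n_cofactors)
  lod <- .scan_lod(prep$X, prep$grid, matrix(prep$y), prep$M, prep$keys)[, 1]
  thr <- threshold
  max_lods <- NULL
  if (is.null(thr) && n_perm > 0) {
    pt <- .perm_threshold(prep, n_perm, alpha, seed)
    thr <- pt$threshold
    max_lods <- pt$max_lods
  }
  thr <- thr %||% NA_real_
  qtl <- .call_qtl(prep, lod, thr, merge_cM)
  structure(list(
    profile = cbind(prep$grid, lod = lod),
    threshold = thr, qtl = qtl, perm_max_lods = max_lods, map = map,
    settings = list(trait = prep$trait, step_cM = step_cM,
                    window_cM = window_cM, cofactors = prep$cofactors,
                    n_perm = n_perm, alpha = alpha, seed = seed,
                    merge_cM = merge_cM, n_lines = prep$n)),
    class = "qtl_scan")
}

#' Interval mapping scan (no cofactors)
#'
#' Plain Haley-Knott regression scan; the degenerate case of [cim_scan()]
#' with an empty cofactor set.  Arguments and value as there.
#'
#' @inheritParams cim_scan
#' @export
im_scan <- function(map, genotypes, phenotype, trait = NULL, step_cM = 1,
                    n_perm = 0, alpha = 0.05, seed = NULL, threshold = NULL,
                    merge_cM = 20) {
  cim_scan(map, genotypes, phenotype, trait = trait, step_cM = step_cM,
           cofactors = character(0), n_cofactors = 0, n_perm = n_perm,
           alpha = alpha, seed = seed, threshold = threshold,
           merge_cM = merge_cM)
}

#' Forward stepwise cofactor selection
#'
#' Adds, among all map markers, the marker giving the largest residual
#' sum-of-squares reduction, as long as its partial F test is significant
#' at `p_enter`, up to `n_cofactors` markers.  Missing calls are
#' mean-imputed for the selection regression.
#'
#' @param map a `genetic_map`.
#' @param genotypes a [dh_genotypes()].
#' @param phenotype phenotype vector or data.frame (see [cim_scan()]).
#' @param trait trait column when `phenotype` is a data.frame.
#' @param n_cofactors maximum cofactors (default 5).
#' @param p_enter partial-F entry threshold (default 0.05).
#' @return character vector of selected marker names (possibly empty).
#' @export
select_cofactors <- function(map, genotypes, phenotype, trait = NULL,
                             n_cofactors = 5, p_enter = 0.05) {
  ph <- .align_phenotype(genotypes, phenotype, trait)
  ok <- !is.na(ph$y)
  y <- ph$y[ok]
  M <- .cofactor_matrix(
    dh_genotypes(genotypes$line_id[ok], genotypes$calls[ok, , drop = FALSE]),
    map, map$marker)$M
  n <- length(y)
  chosen <- integer(0)
  repeat {
    if (length(chosen) >= n_cofactors) break
    C <- cbind(1, M[, chosen, drop = FALSE])
    qrC <- qr(C)
    yr <- qr.resid(qrC, y)
    Mr <- qr.resid(qrC, M)
    rss_cur <- sum(yr^2)
    sxx <- colSums(Mr^2)
    sxy <- as.numeric(crossprod(Mr, yr))
    red <- ifelse(sxx > 1e-10, sxy^2 / sxx, 0)
    red[chosen] <- 0
    best <- which.max(red)
    rss_new <- rss_cur - red[best]
    df2 <- n - length(chosen) - 2
    if (df2 <= 0 || rss_new <= 0) break
    f <- red[best] / (rss_new / df2)
    if (stats::pf(f, 1, df2, lower.tail = FALSE) >= p_enter) break
    chosen <- c(chosen, best)
  }
  colnames(M)[chosen]
}

#' Permutation-based genome-wide LOD threshold
#'
#' Shuffles the phenotype over lines (genotypes fixed), rescans, records
#' the genome-wide maximum LOD of each permutation and returns the
#' `1 - alpha` empirical quantile (order statistic, linear interpolation).
#'
#' @inheritParams cim_scan
#' @param n_perm number of permutations (default 1000).
#' @return LOD threshold (scalar) with attribute `"max_lods"` holding the
#'   permutation maxima.
#' @export
permutation_threshold <- function(map, genotypes, phenotype, trait = NULL,
                                  step_cM = 1, window_cM = 10,
                                  cofactors = character(0), n_perm = 1000,
                                  alpha = 0.05, seed = NULL) {
  prep <- .prepare_scan(map, genotypes, phenotype, trait, step_cM,
                        cofactors, window_cM, n_cofactors = 0)
  pt <- .perm_threshold(prep, n_perm, alpha, seed)
  structure(pt$threshold, max_lods = pt$max_lods)
}

#' Summarize detected QTL
#'
#' Returns the QTL table of a scan: per detected peak the nearest map
#' marker, the LOD, the additivity (half the difference of the fitted
#' genotype-class means, signed by the parent-B allele) and the percent
#' phenotypic variance explained by the peak term given the active
#' cofactors.  Supply `genotypes` and `phenotype` (plus `threshold`) to
#' re-call QTL at a different threshold.
#'
#' @param scan a `qtl_scan`.
#' @param genotypes,phenotype,trait inputs of the original scan (only
#'   needed to re-call at a new `threshold`).
#' @param threshold LOD threshold; default the scan's own.
#' @return data.frame of detected QTL (possibly empty).
#' @export
summarize_qtl <- function(scan, genotypes = NULL, phenotype = NULL,
                          trait = NULL, threshold = NULL) {
  stopifnot(inherits(scan, "qtl_scan"))
  if (is.null(threshold) || identical(threshold, scan$threshold))
    return(scan$qtl)
  if (is.null(genotypes) || is.null(phenotype))
    stop("re-calling at a new threshold needs genotypes and phenotype",
         call. = FALSE)
  s <- scan$settings
  rescanned <- cim_scan(scan$map, genotypes, phenotype,
                        trait = trait %||% s$trait, step_cM = s$step_cM,
                        window_cM = s$window_cM, cofactors = s$cofactors,
                        threshold = threshold, merge_cM = s$merge_cM)
  rescanned$qtl
}

#' @export
print.qtl_scan <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<qtl_scan> trait '%s': %d positions, max LOD %.2f, threshold %s, %d QTL, %d cofactor(s)\n",
              s$trait, nrow(x$profile), max(x$profile$lod),
              ifelse(is.na(x$threshold), "none", sprintf("%.2f", x$threshold)),
              nrow(x$qtl), length(s$cofactors)))
  if (nrow(x$qtl)) print(x$qtl, digits = 4)
  invisible(x)
}
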