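# Induction-curve phenotyping: ci-normalization, steady-state detection,
# the 1/tau activation-rate regression, snapshot phenotypes and population
# summaries.
#
# The estimator follows the windowed log-linear procedure: A is first
# normalized to ci = 300 umol mol-1 (A* = A * 300 / ci, a straight
# A-ci line through the origin), which removes the stomatal signal from the
# induction transient; ln(A*max - A*) is then regressed on time over the
# 2-5 min base window, extended point by point while cumulative R2 stays
# above 0.9.  1/tau is minus the slope.

#' Normalize an induction curve to ci = 300
#'
#' Computes `A_star = A * 300 / ci` pointwise (assuming a Rubisco-limited
#' A-ci relation through the origin, valid below ~300 umol mol-1), then
#' locates the steady-state window (see [detect_steady_state()]) to fix
#' `A_star_max`, the fully induced normalized rate, and the steady-state
#' values `A_ss` and `gs_ss`.
#'
#' @param curve an [induction_curve()].
#' @param window_min width of the rolling steady-state window, minutes.
#' @param slope_tol relative slope tolerance (fraction per minute) below
#'   which a window counts as steady; applied to both `A_star` and `gs`.
#' @return A `normalized_curve`: list with `time_min`, `A_star`,
#'   `A_star_max`, `steady_index`, `steady_time`, `steady_status`
#'   (`"ok"`/`"not_steady"`), `A_ss`, `gs_ss`, and the parent identifiers.
#' @export
normalize_to_ci300 <- function(curve, window_min = 5, slope_tol = 0.01) {
  validate_curve(curve)
  bad <- which(!is.na(curve$ci) & curve$ci <= 0)
  if (length(bad))
    stop("ci <= 0 at time ", paste(curve$time_min[bad], collapse = ", "),
         call. = FALSE)
  A_star <- curve$A * 300 / curve$ci
  ss <- detect_steady_state(curve$time_min, A_star, aux = curve$gs,
                            window_min = window_min, slope_tol = slope_tol)
  win <- ss$final_window
  structure(list(
    genotype_id = curve$genotype_id, replicate_id = curve$replicate_id,
    time_min = curve$time_min, A_star = A_star,
    A_star_max = ss$level, steady_index = ss$steady_index,
    steady_time = ss$steady_time, steady_status = ss$status,
    A_ss = mean(curve$A[win]), gs_ss = mean(curve$gs[win])),
    class = "normalized_curve")
}

#' Detect steady state in a trace
#'
#' Rolling-window criterion: a window of `window_min` minutes is "steady"
#' when the absolute OLS slope of the trace within it, relative to the
#' window mean, is below `slope_tol` (default 1 % per minute).  Steady
#' state is declared at the first window start from which every later
#' window also qualifies; the reported level is the mean of the trace over
#' the final qualifying window (the most relaxed data available), which is
#' deliberately robust to noise-inflated raw maxima.
#'
#' @param time time stamps, minutes.
#' @param values trace to assess (typically `A_star`).
#' @param aux optional second trace (typically `gs`) that must satisfy the
#'   same criterion for a window to qualify.
#' @param window_min,slope_tol window width (minutes) and relative slope
#'   tolerance (fraction per minute).
#' @return list with `level` (mean over the final qualifying window; falls
#'   back to `max(values)` when no window qualifies), `steady_index` /
#'   `steady_time` (first steady record; `NA` if none), `status`
#'   (`"ok"`/`"not_steady"`) and `final_window` (indices used for `level`
#'   and for steady-state means).
#' @export
detect_steady_state <- function(time, values, aux = NULL, window_min = 5,
                                slope_tol = 0.01) {
  n <- length(time)
  if (n < window_min + 1 || (time[n] - time[1]) < window_min)
    stop("trace too short for a ", window_min, "-min steady-state window",
         call. = FALSE)
  rel_slope <- function(t, v) {
    if (anyNA(v)) return(Inf)  # missing data cannot certify steadiness
    f <- .ols(t, v)
    m <- abs(mean(v))
    if (m == 0) if (f$slope == 0) 0 else Inf else abs(f$slope) / m
  }
  starts <- which(time <= time[n] - window_min + 1e-9)
  qual <- logical(length(starts))
  windows <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    idx <- which(time >= time[s] - 1e-9 & time <= time[s] + window_min + 1e-9)
    windows[[i]] <- idx
    ok <- rel_slope(time[idx], values[idx]) < slope_tol
    if (ok && !is.null(aux)) ok <- rel_slope(time[idx], aux[idx]) < slope_tol
    qual[i] <- ok
  }
  # first start from which the criterion holds for every later window
  tail_ok <- rev(cumprod(rev(qual))) > 0
  if (any(tail_ok)) {
    first <- starts[which(tail_ok)[1]]
    final_window <- windows[[max(which(qual))]]
    list(level = mean(values[final_window]), steady_index = first,
         steady_time = time[first], status = "ok",
         final_window = final_window)
  } else {
    list(level = max(values, na.rm = TRUE), steady_index = NA_integer_,
         steady_time = NA_real_, status = "not_steady",
         final_window = windows[[length(windows)]])
  }
}

#' Estimate the apparent Rubisco activation rate (1/tau)
#'
#' Fits ordinary least squares to `ln(A_star_max - A_star)` against time
#' over the base window 2-5 min after the light step (the first two
#' minutes are excluded: that phase is dominated by processes other than
#' Rubisco activation).  The window is then extended strictly in time
#' order, one later point at a time, keeping a point only while the
#' cumulative regression retains R2 > `r2_min`; the extension stops at the
#' first failing point and never considers records after the detected
#' steady-state onset.  Points with `A_star >= A_star_max` are dropped
#' before the logarithm.  `one_over_tau` is minus the fitted slope, in
#' min-1.
#'
#' @param norm a `normalized_curve` from [normalize_to_ci300()], or any
#'   list with `time_min`, `A_star` and `A_star_max` (steady-state fields
#'   are recomputed from `A_star` if absent).
#' @param r2_min cumulative R-squared retention threshold (default 0.9).
#' @param base_window numeric length-2, minutes; default `c(2, 5)`.
#' @return An `activation_fit`: list with `one_over_tau` (min-1),
#'   `intercept` (ln units), `window_times`, `r_squared`, `n_points`, and
#'   `status` (`"ok"`, `"insufficient_points"` or `"poor_fit"`).  With
#'   status `"ok"`, `r_squared > r2_min`, `n_points >= 3` and
#'   `one_over_tau > 0`.
#' @export
estimate_activation_rate <- function(norm, r2_min = 0.9,
                                     base_window = c(2, 5)) {
  t <- norm$time_min
  As <- norm$A_star
  Amax <- norm$A_star_max
  if (is.null(Amax)) stop("norm must carry A_star_max", call. = FALSE)
  t_end <- norm$steady_time
  if (is.null(t_end)) {
    ss <- tryCatch(detect_steady_state(t, As), error = function(e) NULL)
    t_end <- if (!is.null(ss) && ss$status == "ok") ss$steady_time else NA_real_
  }
  if (is.na(t_end)) t_end <- max(t)  # not steady: use the full trace, flagged

  empty_fit <- function(status) {
    structure(list(one_over_tau = NA_real_, intercept = NA_real_,
                   window_times = numeric(0), r_squared = NA_real_,
                   n_points = 0L, status = status),
              class = "activation_fit")
  }
  usable <- !is.na(As) & As < Amax & t >= base_window[1] - 1e-9 &
    t <= t_end + 1e-9
  base <- usable & t <= base_window[2] + 1e-9
  if (sum(base) < 3) return(empty_fit("insufficient_points"))

  idx <- which(base)
  y <- rep(NA_real_, length(As))
  y[usable] <- log(Amax - As[usable])
  fit <- .ols(t[idx], y[idx])
  if (is.na(fit$r2) || fit$r2 <= r2_min) {
    return(structure(list(one_over_tau = -fit$slope, intercept = fit$intercept,
                          window_times = t[idx], r_squared = fit$r2,
                          n_points = length(idx), status = "poor_fit"),
                     class = "activation_fit"))
  }
  for (j in which(usable & t > base_window[2] + 1e-9)) {
    trial <- .ols(t[c(idx, j)], y[c(idx, j)])
    if (is.na(trial$r2) || trial$r2 <= r2_min) break
    idx <- c(idx, j)
    fit <- trial
  }
  status <- if (fit$r2 > r2_min && length(idx) >= 3 && -fit$slope > 0)
    "ok" else "poor_fit"
  structure(list(one_over_tau = -fit$slope, intercept = fit$intercept,
                 window_times = t[idx], r_squared = fit$r2,
                 n_points = length(idx), status = status),
            class = "activation_fit")
}

#' @export
print.activation_fit <- function(x, ...) {
  cat(sprintf("<activation_fit> 1/tau = %.4g min-1  (R2 = %.4f, n = %d, window %.4g-%.4g min, %s)\n",
              x$one_over_tau, x$r_squared, x$n_points,
              if (x$n_points) min(x$window_times) else NA,
              if (x$n_points) max(x$window_times) else NA, x$status))
  invisible(x)
}

#' Snapshot phenotypes at requested minutes
#'
#' Returns `A` and `gs` at the record nearest each requested minute (ties
#' resolved to the earlier record).  Minutes beyond the recorded range give
#' missing values.
#'
#' @param curve an [induction_curve()].
#' @param minutes minutes into induction, default `c(5, 10, 15)`.
#' @return named numeric vector `A_<m>`, `gs_<m>` for each requested `m`.
#' @export
snapshot_phenotypes <- function(curve, minutes = c(5, 10, 15)) {
  out <- numeric(0)
  for (m in minutes) {
    if (m < min(curve$time_min) || m > max(curve$time_min)) {
      a <- NA_real_; g <- NA_real_
    } else {
      i <- which.min(abs(curve$time_min - m))  # ties -> earlier record
      a <- curve$A[i]; g <- curve$gs[i]
    }
    out[paste0("A_", m)] <- a
    out[paste0("gs_", m)] <- g
  }
  out
}

#' Per-leaf phenotype record
#'
#' Runs the full per-leaf pipeline (normalization, steady-state detection,
#' activation-rate regression, snapshots) and returns a one-row data.frame
#' with trait values and fit diagnostics.
#'
#' @param curve an [induction_curve()].
#' @param snapshot_minutes minutes for snapshot traits.
#' @param fit_activation if `FALSE`, skip the 1/tau regression (faster when
#'   only steady/snapshot traits are needed).
#' @param ... passed to [normalize_to_ci300()].
#' @return data.frame with columns `genotype`, `replicate`, `one_over_tau`,
#'   `A_ss`, `gs_ss`, snapshot traits, and diagnostics (`r_squared`,
#'   `n_points`, `fit_status`, `steady_status`).
#' @export
curve_phenotypes <- function(curve, snapshot_minutes = c(5, 10, 15),
                             fit_activation = TRUE, ...) {
  norm <- normalize_to_ci300(curve, ...)
  snap <- snapshot_phenotypes(curve, snapshot_minutes)
  if (fit_activation) {
    fit <- estimate_activation_rate(norm)
  } else {
    fit <- list(one_over_tau = NA_real_, r_squared = NA_real_, n_points = NA_integer_,
                status = "not_fitted")
  }
  df <- data.frame(genotype = curve$genotype_id, replicate = curve$replicate_id,
                   one_over_tau = fit$one_over_tau, A_ss = norm$A_ss,
                   gs_ss = norm$gs_ss, stringsAsFactors = FALSE)
  for (nm in names(snap)) df[[nm]] <- snap[[nm]]
  df$r_squared <- fit$r_squared
  df$n_points <- fit$n_points
  df$fit_status <- fit$status
  df$steady_status <- norm$steady_status
  df
}

#' Phenotype a collection of curves
#'
#' Applies [curve_phenotypes()] to every curve and aggregates replicate
#' leaves into per-genotype medians ([genotype_median()]).
#'
#' @param curves list of [induction_curve()] objects (as from
#'   [read_curves()]).
#' @param ... passed to [curve_phenotypes()].
#' @return list with `phenotypes` (per-line medians, `line_id` + trait
#'   columns) and `diagnostics` (per-leaf data.frame).
#' @export
phenotype_table <- function(curves, ...) {
  diag <- do.call(rbind, lapply(curves, curve_phenotypes, ...))
  rownames(diag) <- NULL
  traits <- setdiff(names(diag),
                    c("genotype", "replicate", "r_squared", "n_points",
                      "fit_status", "steady_status"))
  list(phenotypes = genotype_median(diag, traits), diagnostics = diag)
}

#' Per-genotype medians over replicates
#'
#' Standard midpoint rule for even replicate counts; missing replicate
#' values are dropped per trait (all-missing gives a missing median).
#'
#' @param estimates data.frame with a `genotype` column and trait columns.
#' @param traits trait column names to aggregate; default all numeric.
#' @return data.frame with `line_id` and one column per trait.
#' @export
genotype_median <- function(estimates, traits = NULL) {
  if (is.null(traits))
    traits <- names(estimates)[vapply(estimates, is.numeric, logical(1))]
  ids <- unique(estimates$genotype)
  out <- data.frame(line_id = ids, stringsAsFactors = FALSE)
  for (tr in traits) {
    out[[tr]] <- vapply(ids, function(g) {
      v <- estimates[[tr]][estimates$genotype == g]
      v <- v[!is.na(v)]
      if (length(v)) stats::median(v) else NA_real_
    }, numeric(1))
  }
  out
}

#' Population distribution summary for a trait
#'
#' Minimum, quartiles (linear-interpolation convention, quantile type 7),
#' median, maximum and mean over non-missing lines.
#'
#' @param table phenotype data.frame (`line_id` + trait columns).
#' @param trait trait column name.
#' @return one-row data.frame: `trait, n, min, q25, median, q75, max, mean`.
#' @export
population_summary <- function(table, trait) {
  v <- table[[trait]]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no non-missing values for trait '", trait, "'",
                       call. = FALSE)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(trait = trait, n = length(v), min = min(v), q25 = q[1],
             median = q[2], q75 = q[3], max = max(v), mean = mean(v),
             stringsAsFactors = FALSE)
}

#' Percent underestimation relative to steady state
#'
#' `100 * (1 - value_m / value_ss)`: by how much a snapshot taken `m`
#' minutes into induction under-reads the steady-state value.
#'
#' @param value_m snapshot value(s).
#' @param value_ss steady-state reference value(s).
#' @return percentage(s); positive when the snapshot under-reads.
#' @export
pct_underestimation <- function(value_m, value_ss) {
  100 * (1 - value_m / value_ss)
}

#' Pearson correlation between two traits
#'
#' Product-moment correlation on per-line values (pairwise complete), with
#' the two-sided test p-value.
#'
#' @param table phenotype data.frame.
#' @param trait_a,trait_b trait column names.
#' @return list with `r`, `p`, `n`.
#' @export
trait_correlation <- function(table, trait_a, trait_b) {
  a <- table[[trait_a]]; b <- table[[trait_b]]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) stop("need >= 3 paired non-missing values", call. = FALSE)
  ct <- stats::cor.test(a[ok], b[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
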