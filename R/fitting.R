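#' Default voxel-fitting options
#'
#' Bounds, starting values and tolerances for the voxel-wise
#' Levenberg-Marquardt fit of the Brix model. The bounds
#' (A in \[0, 50\], kep in \[0, 30\] /min, kel in \[0, 5\] /min) bracket
#' the physiologically plausible range with generous headroom; the
#' default start (1, 1, 0.1) sits in the interior, with two further
#' multi-start points covering fast-in-wash and slow-enhancement curves.
#'
#' @param lower,upper named numeric bounds for `A`, `kep`, `kel`.
#' @param starts list of starting triples tried in order; the best
#'   objective wins, so the result is deterministic.
#' @param ftol relative objective-convergence tolerance.
#' @param maxit maximum Levenberg-Marquardt iterations per start.
#' @param r2_min voxels with fit r-squared below this are excluded.
#' @param kep_qc_threshold ROI-level fraction of kep-unreliable voxels
#'   above which kep is dropped from ROI summaries (see [qc_kep()]).
#' @param bound_tol relative closeness to an upper bound that counts as
#'   bound saturation.
#' @return list of fitting options.
#' @export
fit_options <- function(lower = c(A = 0, kep = 0, kel = 0),
                        upper = c(A = 50, kep = 30, kel = 5),
                        starts = list(c(A = 1, kep = 1, kel = 0.1),
                                      c(A = 0.5, kep = 5, kel = 0.5),
                                      c(A = 2, kep = 0.5, kel = 0.05)),
                        ftol = 1e-8, maxit = 500L,
                        r2_min = 0.5, kep_qc_threshold = 0.25,
                        bound_tol = 1e-3) {
  list(lower = lower, upper = upper, starts = starts, ftol = ftol,
       maxit = as.integer(maxit), r2_min = r2_min,
       kep_qc_threshold = kep_qc_threshold, bound_tol = bound_tol)
}

#' Fit the Brix model to one voxel's enhancement curve
#'
#' Levenberg-Marquardt least squares (via [minpack.lm::nls.lm()]) of the
#' Brix enhancement model to a single relative-signal-intensity curve,
#' from several fixed starting points; the solution with the lowest sum
#' of squared residuals is kept, then mapped to the canonical
#' `kep >= kel` branch of the model's swap symmetry. The fit is a
#' deterministic function of the curve and options.
#'
#' @param curve list with `times` (minutes, > 0) and `rsi`
#'   (dimensionless), at least 10 post-contrast points.
#' @param init optional extra starting triple `c(A, kep, kel)` tried
#'   first.
#' @param options a [fit_options()] list.
#' @return a `brix_fit`: `A`, `kep`, `kel`, `sse`, `residual_norm`,
#'   `r_squared` (NA for a degenerate flat curve), `converged`,
#'   `at_bound` (named logical per parameter, upper bound).
#' @export
fit_voxel <- function(curve, init = NULL, options = fit_options()) {
  t <- curve$times; y <- curve$rsi
  if (length(t) < 10L) stopf("fit_voxel: need >= 10 post-contrast points")
  resid_fn <- function(p) {
    brix_model_vec(t, p[1], p[2], p[3]) - y
  }
  starts <- options$starts
  if (!is.null(init)) starts <- c(list(init), starts)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(as.numeric(s), options$lower),
                                    options$upper),
                         lower = as.numeric(options$lower),
                         upper = as.numeric(options$upper),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = options$ftol, ptol = options$ftol,
                           maxiter = options$maxit)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    conv <- fit$info %in% 1:4
    if (is.null(best) || sse < best$sse - 1e-15 ||
        (sse <= best$sse + 1e-15 && conv && !best$converged)) {
      best <- list(par = fit$par, sse = sse, converged = conv)
    }
  }
  if (is.null(best)) {
    return(structure(list(A = NA_real_, kep = NA_real_, kel = NA_real_,
                          sse = NA_real_, residual_norm = NA_real_,
                          r_squared = NA_real_, converged = FALSE,
                          at_bound = c(A = FALSE, kep = FALSE, kel = FALSE)),
                     class = "brix_fit"))
  }
  p <- canonicalize_brix(best$par[1], best$par[2], best$par[3],
                         A_max = options$upper[["A"]])
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - best$sse / sst else NA_real_
  at_bound <- abs(p - options$upper) <=
    options$bound_tol * pmax(options$upper, 1)
  names(at_bound) <- c("A", "kep", "kel")
  structure(list(A = unname(p[1]), kep = unname(p[2]), kel = unname(p[3]),
                 sse = best$sse, residual_norm = sqrt(best$sse),
                 r_squared = r2, converged = best$converged,
                 at_bound = at_bound),
            class = "brix_fit")
}

# Vectorized-over-t Brix evaluation without input checks, for the
# optimizer's inner loop (bounds guarantee non-negative parameters).
brix_model_vec <- function(t, A, kep, kel) {
  if (abs(kel - kep) <= 1e-8 * max(kep, kel, .Machine$double.eps)) {
    A * kep * t * exp(-kep * t)
  } else {
    A * kep / (kel - kep) * (exp(-kep * t) - exp(-kel * t))
  }
}

#' @export
print.brix_fit <- function(x, ...) {
  cat(sprintf("<brix_fit> A=%.4g kep=%.4g/min kel=%.4g/min  r2=%.4f %s\n",
              x$A, x$kep, x$kel, x$r_squared,
              if (x$converged) "(converged)" else "(NOT converged)"))
  invisible(x)
}

#' Fit the Brix model over every ROI voxel of a series
#'
#' The full voxel-wise pipeline for one acquisition: time-axis
#' correction, relative-signal-intensity computation, and a bounded
#' Levenberg-Marquardt Brix fit per in-ROI voxel, with quality-based
#' exclusion. Voxels are excluded (with a reason code) when the
#' baseline signal is non-positive (`"nonpositive-baseline"`), no start
#' converges (`"fit-failed"`), the amplitude or elimination rate
#' saturates its upper bound (`"bound-saturated"`), or the fit explains
#' too little variance (`"low-r2"`, including degenerate flat curves).
#' kep hitting its bound does not by itself exclude a voxel: it feeds
#' the ROI-level kep reliability flag instead (see [qc_kep()]).
#'
#' @param series a [dce_series] with a non-empty ROI.
#' @param options a [fit_options()] list.
#' @return a `parametric_map`: data.frame of per-voxel fits
#'   (`row`, `col`, `A`, `kep`, `kel`, `r_squared`, `converged`,
#'   `kep_at_bound`, `excluded`, `reason`) with attributes
#'   `kep_reliable`, `evaluable` and `grid`.
#' @export
fit_roi <- function(series, options = fit_options()) {
  stopifnot(inherits(series, "dce_series"))
  if (!any(series$roi_mask)) stopf("fit_roi: ROI mask is empty")
  series <- correct_time_axis(series)
  stack <- compute_rsi(series)
  vox <- which(series$roi_mask, arr.ind = TRUE)
  n <- nrow(vox)
  res <- data.frame(row = vox[, 1], col = vox[, 2],
                    A = NA_real_, kep = NA_real_, kel = NA_real_,
                    r_squared = NA_real_, residual_norm = NA_real_,
                    converged = FALSE, kep_at_bound = FALSE,
                    few_prepeak_samples = FALSE,
                    excluded = TRUE, reason = NA_character_)
  for (i in seq_len(n)) {
    r <- vox[i, 1]; c_ <- vox[i, 2]
    if (!stack$evaluable[r, c_]) {
      res$reason[i] <- "nonpositive-baseline"
      next
    }
    fit <- fit_voxel(list(times = stack$times, rsi = stack$rsi[r, c_, ]),
                     options = options)
    res$A[i] <- fit$A; res$kep[i] <- fit$kep; res$kel[i] <- fit$kel
    res$r_squared[i] <- fit$r_squared
    res$residual_norm[i] <- fit$residual_norm
    res$converged[i] <- fit$converged
    res$kep_at_bound[i] <- fit$at_bound[["kep"]]
    if (!is.na(fit$kep) && fit$kep > 0 && fit$kel > 0) {
      tpk <- brix_peak_time(fit$kep, fit$kel)
      res$few_prepeak_samples[i] <- sum(stack$times < tpk) < 3L
    }
    if (!fit$converged) {
      res$reason[i] <- "fit-failed"
    } else if (fit$at_bound[["A"]] || fit$at_bound[["kel"]]) {
      res$reason[i] <- "bound-saturated"
    } else if (is.na(fit$r_squared) || fit$r_squared < options$r2_min) {
      res$reason[i] <- "low-r2"
    } else {
      res$excluded[i] <- FALSE
    }
  }
  map <- structure(res, class = c("parametric_map", "data.frame"))
  attr(map, "grid") <- dim(series$roi_mask)
  attr(map, "evaluable") <- any(!res$excluded)
  attr(map, "kep_reliable") <- qc_kep(map, series,
                                      threshold = options$kep_qc_threshold)
  map
}

#' ROI-level reliability check for the exchange-rate parameter
#'
#' The in-wash rate kep is estimated from the initial rise of the
#' enhancement curve; when that rise is steep relative to the temporal
#' resolution the estimate is unstable. A fitted map's kep values are
#' declared unreliable for ROI summaries when the fraction of fitted
#' in-ROI voxels whose kep sits at the upper fitting bound, or whose
#' fitted peak time leaves fewer than 3 post-contrast samples before
#' it, exceeds `threshold`. A and kel summaries are unaffected.
#'
#' @param map a `parametric_map` from [fit_roi()].
#' @param series the originating [dce_series] (unused beyond interface
#'   symmetry; the sampling information is already in the map).
#' @param threshold maximum tolerated unreliable fraction (default 0.25;
#'   0 means a single flagged voxel marks the ROI unreliable).
#' @return logical: TRUE when kep summaries are trustworthy.
#' @export
qc_kep <- function(map, series = NULL, threshold = 0.25) {
  fitted <- !is.na(map$kep)
  if (!any(fitted)) return(FALSE)
  flagged <- map$kep_at_bound[fitted] | map$few_prepeak_samples[fitted]
  mean(flagged) <= threshold
}

#' Summarize a parametric map over its usable voxels
#'
#' Arithmetic mean and standard error of each Brix parameter over the
#' non-excluded ROI voxels. kep is reported only when the map's
#' ROI-level kep reliability flag is set; otherwise its entries are NA
#' and only A and kel are summarized, mirroring the practice of
#' excluding kep from tumor-level comparisons when the in-wash is
#' under-sampled.
#'
#' @param map a `parametric_map`.
#' @return one-row data.frame: means, SEMs, voxel counts and the
#'   `kep_reliable` flag.
#' @export
summarize_roi <- function(map) {
  ok <- !map$excluded
  if (!any(ok)) stopf("summarize_roi: no usable voxels in the map")
  kep_rel <- isTRUE(attr(map, "kep_reliable"))
  data.frame(
    n_voxels = sum(ok), n_excluded = sum(!ok),
    A_mean = mean(map$A[ok]), A_sem = sem(map$A[ok]),
    kel_mean = mean(map$kel[ok]), kel_sem = sem(map$kel[ok]),
    kep_mean = if (kep_rel) mean(map$kep[ok]) else NA_real_,
    kep_sem = if (kep_rel) sem(map$kep[ok]) else NA_real_,
    kep_reliable = kep_rel)
}
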