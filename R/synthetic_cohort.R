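#' Generate ground-truth parameter maps for one tumor and session
#'
#' Draws spatially smooth, strictly positive fields of the Brix
#' parameters A, kep and kel over an elliptical single-slice ROI.
#' Log-normal marginals are smoothed with a fixed-width Gaussian kernel
#' on the log scale, which guarantees positivity while keeping
#' heterogeneity. The spatial field is a pure function of
#' (design, group, tumor): the post-treatment session reuses the same
#' field and applies the group's effect multipliers exactly, so the
#' in-ROI mean post/pre ratio of each parameter equals the configured
#' multiplier by construction.
#'
#' @param design a [cohort_design].
#' @param group group name or index.
#' @param tumor_index tumor number within the group (1-based).
#' @param session `"pre"` or `"post"`.
#' @return a `ground_truth` object: matrices `A`, `kep`, `kel`, the
#'   logical `roi` mask, and bookkeeping fields.
#' @export
generate_parameter_maps <- function(design, group, tumor_index,
                                    session = c("pre", "post")) {
  session <- match.arg(session)
  validate_design(design)
  gi <- group_index(design, group)
  grp <- design$groups[[gi]]
  roi <- roi_mask_for(design)
  if (!any(roi)) stopf("generate_parameter_maps: ROI contains no voxels")

  shp <- design$roi$shape
  sig <- design$fields$smooth_sigma
  draw <- function(spec) {
    z <- matrix(stats::rnorm(prod(shp)), shp[1], shp[2])
    z <- smooth_field(z, sig)
    # restore unit variance lost to smoothing before applying the marginal
    s <- stats::sd(as.numeric(z))
    if (s > 0) z <- z / s
    exp(spec$meanlog + spec$sdlog * z)
  }
  maps <- with_seed(derive_seed(design$seed, gi, tumor_index, "maps"), {
    list(A = draw(design$fields$A), kep = draw(design$fields$kep),
         kel = draw(design$fields$kel))
  })
  if (session == "post") {
    maps$A <- maps$A * grp$a_mult
    maps$kel <- maps$kel * grp$kel_mult
  }
  structure(list(A = maps$A, kep = maps$kep, kel = maps$kel, roi = roi,
                 group = grp$name, tumor_index = as.integer(tumor_index),
                 session = session),
            class = "ground_truth")
}

#' Simulate a dynamic contrast-enhanced acquisition from ground truth
#'
#' Forward-simulates the 4D signal time course of one tumor slice: five
#' (by default) pre-contrast baseline frames, then post-contrast frames
#' at the design's temporal resolution, with per-voxel enhancement
#' following the Brix model at the voxel's ground-truth parameters and
#' additive zero-mean Gaussian noise of standard deviation
#' `noise_sd * baseline_signal` on every frame.
#'
#' @param truth a `ground_truth` object from [generate_parameter_maps()].
#' @param design the [cohort_design] (acquisition grid and noise level).
#' @param seed integer seed; identical seeds give bit-identical series.
#' @param baseline_signal pre-contrast signal level, arbitrary units.
#' @param actual_injection_duration realized bolus duration in seconds
#'   (defaults to the nominal duration); deviations displace the
#'   recorded frame times relative to the effective bolus midpoint and
#'   are undone by [correct_time_axis()].
#' @return a [dce_series] object.
#' @export
simulate_dce <- function(truth, design, seed = design$seed,
                         baseline_signal = 100,
                         actual_injection_duration =
                           design$acquisition$injection_duration) {
  validate_design(design)
  acq <- design$acquisition
  dt <- acq$frame_interval / 60
  n_post <- as.integer(round(acq$post_contrast_duration / dt))
  t_base <- seq.int(-(acq$n_baseline_frames - 1L), 0L) * dt
  t_post <- seq_len(n_post) * dt
  # effective bolus-midpoint offset encoded in the recorded times
  delta <- (actual_injection_duration - acq$injection_duration) / 2 / 60

  shp <- dim(truth$A)
  nf <- length(t_base) + n_post
  signal <- array(baseline_signal, dim = c(shp[1], shp[2], nf))
  for (v in which(truth$roi)) {
    rc <- arrayInd(v, shp)
    enh <- brix_model(t_post + delta, truth$A[v], truth$kep[v], truth$kel[v])
    signal[rc[1], rc[2], -seq_along(t_base)] <- baseline_signal * (1 + enh)
  }
  if (design$noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(length(signal),
                                          sd = design$noise_sd * baseline_signal))
    signal <- pmax(signal + array(noise, dim = dim(signal)), 0)
  }
  dce_series(signal = signal, frame_times = c(t_base, t_post),
             n_baseline_frames = acq$n_baseline_frames,
             nominal_injection_duration = acq$injection_duration,
             actual_injection_duration = actual_injection_duration,
             roi_mask = truth$roi)
}

#' Simulate caliper growth trajectories for a cohort
#'
#' Each tumor follows the saturating exponential law
#' \eqn{V(t) = V_0 \exp\{g\,t\,(1 - t / (2 t_{sat}))\}} with the group's
#' growth modifier scaling the specific rate \eqn{g}, per-tumor
#' log-normal spread on \eqn{g} and on the starting volume, and
#' multiplicative caliper measurement noise on the two diameters.
#' Diameters are reported so that length >= width (aspect ratio from the
#' design), at 4-day intervals with a terminal measurement closing the
#' 29-day observation window.
#'
#' @param design a [cohort_design].
#' @param seed integer seed (defaults to the design seed).
#' @return data.frame with columns `tumor_id`, `group`, `day`,
#'   `length_mm`, `width_mm`.
#' @export
simulate_growth <- function(design, seed = design$seed) {
  validate_design(design)
  gr <- design$growth
  days <- gr$days
  out <- vector("list", 0L)
  for (gi in seq_along(design$groups)) {
    grp <- design$groups[[gi]]
    for (ti in seq_len(grp$n_tumors)) {
      rec <- with_seed(derive_seed(seed, gi, ti, "growth"), {
        v0 <- gr$v0_mean * exp(stats::rnorm(1, 0, gr$v0_sdlog))
        g <- gr$rate * grp$growth_mult * exp(stats::rnorm(1, 0, gr$rate_sdlog))
        vol <- v0 * exp(g * days * (1 - days / (2 * gr$t_sat)))
        # invert V = (pi/6) L^2 W with L = aspect * W
        w <- (6 * vol / (pi * gr$aspect^2))^(1 / 3)
        l <- gr$aspect * w
        if (gr$caliper_noise_sd > 0) {
          l <- l * exp(stats::rnorm(length(l), 0, gr$caliper_noise_sd))
          w <- w * exp(stats::rnorm(length(w), 0, gr$caliper_noise_sd))
        }
        data.frame(tumor_id = sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "_", grp$name), ti),
                   group = grp$name, day = days,
                   length_mm = pmax(l, w), width_mm = pmin(l, w))
      })
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate a pimonidazole hypoxic fraction from the amplitude change
#'
#' Hypoxic fractions enter the pipeline as per-tumor scalars linearly
#' and negatively coupled to the relative change in the amplitude
#' parameter A (treatments that expand the contrast-accessible space
#' tend to leave less hypoxic tissue), plus Gaussian noise, clipped to
#' the unit interval.
#'
#' @param relative_A_change pre-to-post relative change of the in-ROI
#'   mean A, as a fraction (0.29 for +29\%).
#' @param design a [cohort_design] (supplies the coupling parameters).
#' @param seed integer seed.
#' @return hypoxic fraction in `[0, 1]`.
#' @export
simulate_hypoxic_fraction <- function(relative_A_change, design,
                                      seed = design$seed) {
  hc <- design$hypoxia_coupling
  if (hc$slope > 0) stopf("hypoxia_coupling slope must be <= 0")
  hf <- hc$intercept + hc$slope * relative_A_change
  if (hc$noise_sd > 0) {
    hf <- hf + with_seed(seed, stats::rnorm(length(relative_A_change),
                                            0, hc$noise_sd))
  }
  pmin(pmax(hf, 0), 1)
}

#' Ground-truth endpoint table for a whole cohort
#'
#' Generates, per tumor, the pre- and post-treatment in-ROI mean of the
#' ground-truth A and kel fields, the implied relative changes, and a
#' coupled hypoxic fraction. This is the generator-side view of the
#' cohort (no imaging noise, no fitting); [run_pipeline()] produces the
#' measured counterpart by simulating and fitting every acquisition, and
#' merges volume changes from the simulated caliper records.
#'
#' @param design a [cohort_design].
#' @param seed integer seed (defaults to the design seed).
#' @return data.frame, one row per tumor.
#' @export
simulate_cohort_truth <- function(design, seed = design$seed) {
  rows <- list()
  for (gi in seq_along(design$groups)) {
    grp <- design$groups[[gi]]
    for (ti in seq_len(grp$n_tumors)) {
      pre <- generate_parameter_maps(design, gi, ti, "pre")
      post <- generate_parameter_maps(design, gi, ti, "post")
      roi <- pre$roi
      A0 <- mean(pre$A[roi]); A1 <- mean(post$A[roi])
      k0 <- mean(pre$kel[roi]); k1 <- mean(post$kel[roi])
      dA <- (A1 - A0) / A0
      hf <- simulate_hypoxic_fraction(dA, design,
                                      derive_seed(seed, gi, ti, "hypoxia"))
      rows[[length(rows) + 1L]] <- data.frame(
        tumor_id = sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "_", grp$name), ti),
        group = grp$name,
        A_pre = A0, A_post = A1, kel_pre = k0, kel_post = k1,
        dA_pct = 100 * dA, dkel_pct = 100 * (k1 - k0) / k0,
        hypoxic_fraction_pct = 100 * hf)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
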