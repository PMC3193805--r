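#' Describe one experimental arm of a virtual xenograft cohort
#'
#' @param name group label.
#' @param n_tumors number of tumors in the arm (>= 1).
#' @param a_mult multiplicative pre-to-post treatment effect on the
#'   amplitude parameter A (> 0; e.g. 1.29 for a +29\% shift).
#' @param kel_mult multiplicative pre-to-post effect on the plasma
#'   elimination rate k_el (> 0).
#' @param growth_mult growth-rate modifier scaling the baseline
#'   exponential growth rate (>= 0; 1 = control growth).
#' @return a `cohort_group` list.
#' @export
cohort_group <- function(name, n_tumors = 9L, a_mult = 1, kel_mult = 1,
                         growth_mult = 1) {
  g <- list(name = as.character(name), n_tumors = as.integer(n_tumors),
            a_mult = a_mult, kel_mult = kel_mult, growth_mult = growth_mult)
  class(g) <- "cohort_group"
  g
}

#' Default five-arm treatment design
#'
#' The default arms mirror a five-group chemoradiotherapy xenograft
#' experiment: untreated control, liposomal doxorubicin alone (PL-DXR),
#' PL-DXR combined with radiotherapy under induced hypoxia, radiotherapy
#' under hypoxia alone, and normoxic radiotherapy. The amplitude and
#' elimination-rate multipliers encode the group-mean pre-to-post shifts
#' the pipeline is designed to detect (A falls in the non-irradiated
#' arms and rises in all irradiated arms; k_el falls in the two
#' radiotherapy-only arms), and the growth modifiers order the arms from
#' fastest (control) to slowest (normoxic radiotherapy) growth.
#'
#' @param n_tumors tumors per arm.
#' @return list of [cohort_group] objects.
#' @export
default_groups <- function(n_tumors = 9L) {
  list(
    cohort_group("control",             n_tumors, a_mult = 0.82, kel_mult = 1.45, growth_mult = 1.00),
    cohort_group("PL-DXR",              n_tumors, a_mult = 0.74, kel_mult = 1.85, growth_mult = 0.65),
    cohort_group("PL-DXR+hypoxic RT",   n_tumors, a_mult = 1.04, kel_mult = 1.47, growth_mult = 0.35),
    cohort_group("hypoxic RT",          n_tumors, a_mult = 1.20, kel_mult = 0.73, growth_mult = 0.50),
    cohort_group("RT",                  n_tumors, a_mult = 1.29, kel_mult = 0.73, growth_mult = 0.22)
  )
}

#' Specify a virtual cohort: arms, acquisition, noise and coupling
#'
#' A `cohort_design` is the single source of truth for the synthetic
#' cohort generator: the treatment arms and their effect sizes, the
#' dynamic acquisition grid, the image noise level, the tumor growth
#' law, and the coupling between hypoxic fraction and amplitude change.
#'
#' @param groups list of [cohort_group] descriptors.
#' @param acquisition list with `n_baseline_frames` (pre-contrast frames,
#'   default 5), `frame_interval` (seconds, default 12),
#'   `post_contrast_duration` (minutes, default 20) and
#'   `injection_duration` (nominal bolus duration, seconds, default 3).
#' @param noise_sd additive Gaussian image noise, as a fraction of the
#'   baseline signal (default 0.05).
#' @param roi list with `shape` (grid rows, cols) and `semiaxes` of the
#'   elliptical single-slice tumor ROI, in voxels.
#' @param fields marginal log-normal parameters (`meanlog`, `sdlog`) of
#'   the spatial A, kep and kel ground-truth fields plus the Gaussian
#'   `smooth_sigma` (voxels) applied to the log-fields.
#' @param growth growth-law settings: day-0 volume distribution
#'   (`v0_mean` mm^3, `v0_sdlog`), baseline specific growth `rate`
#'   (per day), saturation time `t_sat` (days), per-tumor log-rate
#'   spread `rate_sdlog`, caliper aspect ratio `aspect` (length/width),
#'   multiplicative caliper measurement noise `caliper_noise_sd`, and
#'   the measurement `days`.
#' @param hypoxia_coupling linear link from per-tumor relative A-change
#'   (fraction) to hypoxic fraction: `intercept`, `slope` (<= 0) and
#'   Gaussian `noise_sd`, all on the fraction scale.
#' @param seed master seed for the whole cohort.
#' @return validated `cohort_design` object.
#' @export
cohort_design <- function(groups = default_groups(),
                          acquisition = list(),
                          noise_sd = 0.05,
                          roi = list(),
                          fields = list(),
                          growth = list(),
                          hypoxia_coupling = list(),
                          seed = 1L) {
  d <- list(
    groups = groups,
    acquisition = utils::modifyList(list(
      n_baseline_frames = 5L, frame_interval = 12,
      post_contrast_duration = 20, injection_duration = 3), acquisition),
    noise_sd = noise_sd,
    roi = utils::modifyList(list(shape = c(24L, 24L),
                                 semiaxes = c(11.3, 11.3)), roi),
    fields = utils::modifyList(list(
      A   = list(meanlog = log(1.2), sdlog = 0.25),
      kep = list(meanlog = log(3.0), sdlog = 0.30),
      kel = list(meanlog = log(0.3), sdlog = 0.20),
      smooth_sigma = 2), fields),
    growth = utils::modifyList(list(
      v0_mean = 200, v0_sdlog = 0.3, rate = 0.14, t_sat = 40,
      rate_sdlog = 0.15, aspect = 1.2, caliper_noise_sd = 0.03,
      days = c(seq(0, 28, by = 4), 29)), growth),
    hypoxia_coupling = utils::modifyList(list(
      intercept = 0.17, slope = -0.21, noise_sd = 0.02), hypoxia_coupling),
    seed = as.integer(seed)
  )
  class(d) <- "cohort_design"
  validate_design(d)
  d
}

validate_design <- function(d) {
  if (!length(d$groups)) stopf("cohort_design: at least one group required")
  for (g in d$groups) {
    if (g$n_tumors < 1L) stopf("group '%s': n_tumors must be >= 1", g$name)
    if (g$a_mult <= 0 || g$kel_mult <= 0) {
      stopf("group '%s': effect multipliers must be > 0", g$name)
    }
    if (g$growth_mult < 0) stopf("group '%s': growth_mult must be >= 0", g$name)
  }
  a <- d$acquisition
  if (a$frame_interval <= 0) stopf("acquisition: frame_interval must be > 0")
  if (a$n_baseline_frames < 1L) stopf("acquisition: need >= 1 baseline frame")
  if (a$injection_duration <= 0) stopf("acquisition: injection_duration must be > 0")
  if (d$noise_sd < 0) stopf("noise_sd must be >= 0")
  if (d$hypoxia_coupling$slope > 0) {
    stopf("hypoxia_coupling: slope must be <= 0 (hypoxia falls as A rises)")
  }
  invisible(d)
}

group_index <- function(design, group) {
  nms <- vapply(design$groups, `[[`, "", "name")
  if (is.numeric(group)) {
    i <- as.integer(group)
    if (i < 1L || i > length(nms)) stopf("group index %d out of range", i)
    return(i)
  }
  i <- match(group, nms)
  if (is.na(i)) stopf("unknown group '%s'", group)
  i
}

# Boolean elliptical ROI mask on the design's single-slice grid.
roi_mask_for <- function(design) {
  shp <- design$roi$shape
  ax <- design$roi$semiaxes
  ctr <- (shp + 1) / 2
  r <- matrix(seq_len(shp[1]), shp[1], shp[2])
  c_ <- matrix(seq_len(shp[2]), shp[1], shp[2], byrow = TRUE)
  ((r - ctr[1]) / ax[1])^2 + ((c_ - ctr[2]) / ax[2])^2 <= 1
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("<cohort_design> %d groups, seed %d\n", length(x$groups), x$seed))
  for (g in x$groups) {
    cat(sprintf("  %-20s n=%d  A x%.2f  kel x%.2f  growth x%.2f\n",
                g$name, g$n_tumors, g$a_mult, g$kel_mult, g$growth_mult))
  }
  a <- x$acquisition
  cat(sprintf("  acquisition: %d baseline frames, %.0f s interval, %.0f min post-contrast\n",
              a$n_baseline_frames, a$frame_interval, a$post_contrast_duration))
  cat(sprintf("  ROI %dx%d grid, ~%d voxels; noise_sd %.3f\n",
              x$roi$shape[1], x$roi$shape[2], sum(roi_mask_for(x)), x$noise_sd))
  invisible(x)
}
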