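# Shared fixtures: small designs, synthetic curves and the independent
# grid-search fitting oracle. All fixtures are built in code at test time.

# A compact design: full default acquisition grid, small ROI, noise off
# unless asked for.
tiny_design <- function(noise_sd = 0, seed = 1L, ...) {
  cohort_design(noise_sd = noise_sd, seed = seed,
                roi = list(shape = c(8L, 8L), semiaxes = c(3.2, 3.2)), ...)
}

# Default post-contrast time grid (minutes): 12 s resolution, 20 min.
default_times <- function() seq_len(100L) * 0.2

# Noiseless Brix curve on the default grid.
make_curve <- function(A, kep, kel, times = default_times()) {
  list(times = times, rsi = brix_model(times, A, kep, kel))
}

# Independent fitting oracle: coarse 40^3 grid over the fitting bounds,
# then local refinement of the sum of squared residuals with
# optim(L-BFGS-B). Shares no code with the nls.lm fitter.
grid_fit_oracle <- function(curve, n_grid = 40L, options = fit_options(),
                            n_refine = 10L) {
  t <- curve$times; y <- curve$rsi
  gA <- seq(options$lower[["A"]], options$upper[["A"]], length.out = n_grid)
  gep <- seq(options$lower[["kep"]], options$upper[["kep"]], length.out = n_grid)
  gel <- seq(options$lower[["kel"]], options$upper[["kel"]], length.out = n_grid)
  syy <- sum(y * y)
  cand <- matrix(NA_real_, n_grid^2, 4L)   # sse, A, kep, kel per rate cell
  k <- 0L
  for (kep in gep) {
    for (kel in gel) {
      m0 <- if (abs(kel - kep) <= 1e-8 * max(kep, kel, 1e-300)) {
        kep * t * exp(-kep * t)
      } else {
        kep / (kel - kep) * (exp(-kep * t) - exp(-kel * t))
      }
      smm <- sum(m0 * m0); smy <- sum(m0 * y)
      sse <- gA^2 * smm - 2 * gA * smy + syy   # model linear in A
      i <- which.min(sse)
      k <- k + 1L
      cand[k, ] <- c(sse[i], gA[i], kep, kel)
    }
  }
  # local refinement (PORT routine) from the best grid cells; the model
  # has a swap-symmetric twin basin, so several starts are refined and
  # the best kept
  obj <- function(p) sum((brix_model(t, p[1], p[2], p[3]) - y)^2)
  top <- cand[order(cand[, 1])[seq_len(n_refine)], , drop = FALSE]
  # each candidate also seeds its swap-symmetric twin, clamped to bounds
  twins <- cbind(top[, 1],
                 pmin(ifelse(top[, 4] > 0, top[, 2] * top[, 3] / top[, 4],
                             top[, 2]), options$upper[["A"]]),
                 pmin(top[, 4], options$upper[["kep"]]),
                 pmin(top[, 3], options$upper[["kel"]]))
  top <- rbind(top, twins)
  best <- list(value = Inf, par = top[1, 2:4])
  for (j in seq_len(nrow(top))) {
    ref <- stats::nlminb(top[j, 2:4], obj,
                         lower = as.numeric(options$lower),
                         upper = as.numeric(options$upper),
                         control = list(abs.tol = 0, rel.tol = 1e-15,
                                        x.tol = 1e-12, iter.max = 1000,
                                        eval.max = 2000))
    if (ref$objective < best$value) {
      best <- list(value = ref$objective, par = ref$par)
    }
  }
  p <- brixflow:::canonicalize_brix(best$par[1], best$par[2], best$par[3],
                                    A_max = options$upper[["A"]])
  list(A = unname(p[1]), kep = unname(p[2]), kel = unname(p[3]),
       sse = best$value)
}

# Deterministic caliper table: one tumor from explicit relative volumes,
# converted back to diameters (aspect 1) so the volume round-trip is exact.
caliper_from_rel <- function(rel, days, tumor_id = "t1", group = "g",
                             v0 = 100) {
  vol <- v0 * rel
  d <- (6 * vol / pi)^(1 / 3)
  data.frame(tumor_id = tumor_id, group = group, day = days,
             length_mm = d, width_mm = d)
}

# Random draws of plausible Brix parameters on the canonical branch
# (kep > kel), used by the property tests.
draw_brix_params <- function(n) {
  data.frame(A = stats::runif(n, 0.3, 3),
             kep = stats::runif(n, 0.8, 8),
             kel = stats::runif(n, 0.05, 1))
}
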