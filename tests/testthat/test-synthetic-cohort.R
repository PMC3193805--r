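test_that("treatment multipliers act exactly on the ground-truth fields", {
  # identity effect with zero spatial variance: identical pre and post
  d <- tiny_design(fields = list(A = list(meanlog = log(1.2), sdlog = 0),
                                 kep = list(meanlog = log(3), sdlog = 0),
                                 kel = list(meanlog = log(0.3), sdlog = 0)))
  d$groups[[1]]$a_mult <- 1; d$groups[[1]]$kel_mult <- 1
  pre <- generate_parameter_maps(d, 1, 1, "pre")
  post <- generate_parameter_maps(d, 1, 1, "post")
  expect_identical(pre$A, post$A)
  expect_identical(pre$kel, post$kel)

  # the configured multiplier is recovered exactly from in-ROI means
  d2 <- cohort_design(seed = 3)
  pre <- generate_parameter_maps(d2, "RT", 2, "pre")
  post <- generate_parameter_maps(d2, "RT", 2, "post")
  ratio <- mean(post$A[pre$roi]) / mean(pre$A[pre$roi])
  expect_equal(ratio, 1.29, tolerance = 1e-12)
  expect_equal(mean(post$kel[pre$roi]) / mean(pre$kel[pre$roi]), 0.73,
               tolerance = 1e-12)
  # fields are positive and the two rates never coincide in the ROI
  expect_true(all(pre$A[pre$roi] > 0 & pre$kep[pre$roi] > 0 &
                    pre$kel[pre$roi] > 0))
  expect_true(all(pre$kep[pre$roi] != pre$kel[pre$roi]))
})

test_that("degenerate designs are rejected", {
  expect_error(cohort_design(roi = list(semiaxes = c(0.2, 0.2)),
                             seed = 1) |>
                 generate_parameter_maps(1, 1, "pre"),
               "no voxels")
  expect_error(cohort_design(groups = list(cohort_group("g", a_mult = 0))),
               "multipliers must be > 0")
  expect_error(cohort_design(groups = list(cohort_group("g", n_tumors = 0))),
               "n_tumors")
  expect_error(cohort_design(acquisition = list(frame_interval = 0)),
               "frame_interval")
  expect_error(cohort_design(hypoxia_coupling = list(slope = 0.5)),
               "slope")
})

test_that("simulated series follow the forward model and are seeded", {
  d <- tiny_design(noise_sd = 0)
  truth <- generate_parameter_maps(d, 1, 1, "pre")
  s <- simulate_dce(truth, d, seed = 5)
  # baseline frames carry no enhancement; frame at t = 0 equals baseline
  nb <- s$n_baseline_frames
  expect_equal(s$frame_times[nb], 0)
  expect_true(all(s$signal[, , seq_len(nb)] == 100))
  # post-contrast signal equals baseline * (1 + Brix enhancement)
  v <- which(truth$roi)[1]
  rc <- arrayInd(v, dim(truth$A))
  expect_equal(s$signal[rc[1], rc[2], nb + 7],
               100 * (1 + brix_model(s$frame_times[nb + 7], truth$A[v],
                                     truth$kep[v], truth$kel[v])),
               tolerance = 1e-12)
  # determinism: same seed bit-identical, different seed differs
  d5 <- tiny_design(noise_sd = 0.05)
  s1 <- simulate_dce(truth, d5, seed = 42)
  s2 <- simulate_dce(truth, d5, seed = 42)
  s3 <- simulate_dce(truth, d5, seed = 43)
  expect_identical(s1$signal, s2$signal)
  expect_false(identical(s1$signal, s3$signal))
})

test_that("noiseless acquisitions are recovered voxel-exactly by fitting", {
  d <- tiny_design(noise_sd = 0, seed = 2)
  truth <- generate_parameter_maps(d, "hypoxic RT", 1, "post")
  map <- fit_roi(simulate_dce(truth, d, seed = 2))
  idx <- cbind(map$row, map$col)
  expect_equal(sum(map$excluded), 0)
  expect_lt(max(abs(map$A - truth$A[idx]) / truth$A[idx]), 1e-4)
  expect_lt(max(abs(map$kep - truth$kep[idx]) / truth$kep[idx]), 1e-4)
  expect_lt(max(abs(map$kel - truth$kel[idx]) / truth$kel[idx]), 1e-4)
})

test_that("growth trajectories respect the modifier ordering", {
  # zero modifier freezes the underlying volume
  d <- cohort_design(groups = list(cohort_group("frozen", n_tumors = 2,
                                                growth_mult = 0)),
                     growth = list(caliper_noise_sd = 0))
  g <- relative_volume(simulate_growth(d, seed = 1))
  expect_equal(g$rel_volume, rep(1, nrow(g)), tolerance = 1e-12)

  # control grows at least as fast as a treated arm at every day
  d2 <- cohort_design(groups = list(
    cohort_group("control", n_tumors = 6, growth_mult = 1),
    cohort_group("treated", n_tumors = 6, growth_mult = 0.4)))
  rv <- relative_volume(simulate_growth(d2, seed = 9))
  m <- aggregate(rel_volume ~ group + day, rv, mean)
  wide <- reshape(m, idvar = "day", timevar = "group", direction = "wide")
  expect_true(all(wide$rel_volume.control >= wide$rel_volume.treated))
})

test_that("day-29 group ordering matches the intended treatment ranking", {
  ranks_ok <- vapply(1:20, function(s) {
    d <- cohort_design(seed = s)
    rv <- relative_volume(simulate_growth(d, seed = s))
    m <- aggregate(rel_volume ~ group, rv[rv$day == 29, ], mean)
    ord <- m$group[order(-m$rel_volume)]
    identical(ord, c("control", "PL-DXR", "hypoxic RT",
                     "PL-DXR+hypoxic RT", "RT"))
  }, logical(1))
  expect_true(all(ranks_ok))
})

test_that("hypoxic fractions follow the coupling and stay in [0, 1]", {
  d <- cohort_design(hypoxia_coupling = list(noise_sd = 0))
  expect_equal(simulate_hypoxic_fraction(0, d), 0.17)
  # intercept + slope * change, clipped at zero
  expect_equal(simulate_hypoxic_fraction(0.29, d), 0.17 - 0.21 * 0.29)
  expect_equal(simulate_hypoxic_fraction(5, d), 0)   # below 0 pre-clip
  expect_error(simulate_hypoxic_fraction(0, cohort_design(
    hypoxia_coupling = list(slope = 0.1))), "slope")
  # perfect linear coupling across group means at zero noise
  dA <- c(-0.18, -0.26, 0.04, 0.20, 0.29)
  hf <- vapply(dA, simulate_hypoxic_fraction, numeric(1), design = d)
  expect_equal(cor(hf, dA), -1)
  # noisy draws stay in the unit interval
  d2 <- cohort_design(hypoxia_coupling = list(noise_sd = 0.5))
  hf2 <- vapply(1:50, function(s)
    simulate_hypoxic_fraction(0.1, d2, seed = s), numeric(1))
  expect_true(all(hf2 >= 0 & hf2 <= 1))
})

test_that("the truth-level cohort table reproduces the design exactly", {
  d <- cohort_design(seed = 4,
                     roi = list(shape = c(8L, 8L), semiaxes = c(3.2, 3.2)))
  tab <- simulate_cohort_truth(d)
  expect_equal(nrow(tab), sum(vapply(d$groups, `[[`, 1L, "n_tumors")))
  agg <- aggregate(dA_pct ~ group, tab, mean)
  mults <- setNames(vapply(d$groups, `[[`, 1, "a_mult"),
                    vapply(d$groups, `[[`, "", "name"))
  expect_equal(agg$dA_pct, 100 * (mults[agg$group] - 1),
               tolerance = 1e-10, ignore_attr = TRUE)
})
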