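make_series <- function(signal_curve, n_baseline = 5L, baseline_level = 100) {
  # one-voxel series from an explicit post-contrast signal vector
  nf <- n_baseline + length(signal_curve)
  sig <- array(0, dim = c(1, 1, nf))
  sig[1, 1, ] <- c(rep(baseline_level, n_baseline), signal_curve)
  dt <- 0.2
  dce_series(sig, frame_times = c(seq.int(-(n_baseline - 1L), 0L) * dt,
                                  seq_along(signal_curve) * dt),
             n_baseline_frames = n_baseline)
}

test_that("relative signal intensity normalizes by the baseline mean", {
  # flat series: rsi identically zero
  s <- make_series(rep(100, 20))
  r <- compute_rsi(s)
  expect_equal(as.numeric(r$rsi[1, 1, ]), rep(0, 20))
  # SI(0) = 100, SI(t) = 150 -> rsi = 0.5
  s2 <- make_series(rep(150, 20))
  expect_equal(as.numeric(compute_rsi(s2)$rsi[1, 1, ]), rep(0.5, 20))
  # baseline (98, 102, 100, 99, 101) averages to 100
  s3 <- make_series(rep(150, 20))
  s3$signal[1, 1, 1:5] <- c(98, 102, 100, 99, 101)
  expect_equal(as.numeric(compute_rsi(s3)$rsi[1, 1, ]), rep(0.5, 20))
  # only post-contrast frames are retained
  expect_equal(length(r$times), 20L)
  expect_true(all(r$times > 0))
})

test_that("zero baseline flags the voxel instead of raising", {
  s <- make_series(rep(150, 20))
  s$signal[1, 1, 1:5] <- 0
  r <- compute_rsi(s)
  expect_false(r$evaluable[1, 1])
  expect_true(all(is.na(r$rsi[1, 1, ])))
})

test_that("time-axis correction centers the bolus midpoint", {
  s <- make_series(rep(150, 20))
  expect_equal(correct_time_axis(s)$frame_times, s$frame_times)  # 3 s nominal
  s9 <- make_series(rep(150, 20)); s9$actual_injection_duration <- 9
  post <- 6:25
  expect_equal(correct_time_axis(s9)$frame_times[post],
               s$frame_times[post] + 0.05)
  expect_equal(correct_time_axis(s9)$frame_times[1:5], s$frame_times[1:5])
  s1 <- make_series(rep(150, 20)); s1$actual_injection_duration <- 1
  expect_equal(correct_time_axis(s1)$frame_times[post],
               s$frame_times[post] - 1 / 60)
})

test_that("voxel fits recover noiseless parameters and handle degeneracy", {
  fit <- fit_voxel(make_curve(1.5, 2.0, 0.2))
  expect_true(fit$converged)
  expect_equal(fit$A, 1.5, tolerance = 1e-4)
  expect_equal(fit$kep, 2.0, tolerance = 1e-4)
  expect_equal(fit$kel, 0.2, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # constant-zero curve: amplitude zero, undefined r2
  fit0 <- fit_voxel(list(times = default_times(),
                         rsi = rep(0, 100)))
  expect_equal(fit0$A, 0, tolerance = 1e-8)
  expect_true(is.na(fit0$r_squared))

  expect_error(fit_voxel(list(times = 1:5 * 0.2, rsi = rep(1, 5))),
               ">= 10")
})

test_that("fitting is scale-consistent in the amplitude", {
  set.seed(21)
  pars <- draw_brix_params(8)
  for (i in seq_len(nrow(pars))) {
    cv <- make_curve(pars$A[i], pars$kep[i], pars$kel[i])
    f1 <- fit_voxel(cv)
    f2 <- fit_voxel(list(times = cv$times, rsi = 3 * cv$rsi))
    expect_equal(f2$A, 3 * f1$A, tolerance = 1e-5)
    expect_equal(f2$kep, f1$kep, tolerance = 1e-5)
    expect_equal(f2$kel, f1$kel, tolerance = 1e-5)
  }
})

test_that("ROI fitting tracks exclusions voxel by voxel", {
  d <- tiny_design(noise_sd = 0)
  truth <- generate_parameter_maps(d, 1, 1, "pre")
  s <- simulate_dce(truth, d, seed = 1)

  empty <- s; empty$roi_mask[] <- FALSE
  expect_error(fit_roi(empty), "empty")

  # noiseless ROI: nothing excluded
  map <- fit_roi(s)
  expect_equal(sum(map$excluded), 0L)
  expect_true(attr(map, "evaluable"))

  # poison one voxel's baseline: exactly that voxel excluded, with reason
  v <- which(truth$roi)[3]
  rc <- arrayInd(v, dim(truth$A))
  s$signal[rc[1], rc[2], 1:5] <- 0
  map2 <- fit_roi(s)
  bad <- map2$row == rc[1] & map2$col == rc[2]
  expect_true(map2$excluded[bad])
  expect_equal(map2$reason[bad], "nonpositive-baseline")
  expect_equal(sum(map2$excluded), 1L)
})

test_that("kep reliability reflects bound saturation and peak sampling", {
  # slow in-wash (kep = 0.5/min): peak far beyond the third sample
  d <- tiny_design(fields = list(A = list(meanlog = log(1), sdlog = 0.1),
                                 kep = list(meanlog = log(0.5), sdlog = 0),
                                 kel = list(meanlog = log(0.1), sdlog = 0)))
  truth <- generate_parameter_maps(d, 1, 1, "pre")
  map <- fit_roi(simulate_dce(truth, d, seed = 1))
  expect_true(all(!map$few_prepeak_samples))
  expect_true(attr(map, "kep_reliable"))

  # constructed map: every voxel saturated at the kep bound
  fake <- data.frame(kep = rep(30, 10), kep_at_bound = TRUE,
                     few_prepeak_samples = FALSE)
  expect_false(qc_kep(fake))
  # threshold 0: a single flagged voxel is enough
  fake2 <- data.frame(kep = c(rep(3, 9), 30),
                      kep_at_bound = c(rep(FALSE, 9), TRUE),
                      few_prepeak_samples = FALSE)
  expect_true(qc_kep(fake2, threshold = 0.25))
  expect_false(qc_kep(fake2, threshold = 0))
})

test_that("ROI summaries use exactly the non-excluded voxels", {
  d <- tiny_design(noise_sd = 0.05, seed = 8)
  truth <- generate_parameter_maps(d, 1, 1, "pre")
  map <- fit_roi(simulate_dce(truth, d, seed = 8))
  sm <- summarize_roi(map)
  expect_equal(sm$A_mean, mean(map$A[!map$excluded]))
  expect_equal(sm$A_sem, sd(map$A[!map$excluded]) /
                 sqrt(sum(!map$excluded)))

  # masking half the voxels changes the mean to the remaining half
  half <- map
  half$excluded[seq_len(nrow(half)) %% 2 == 0] <- TRUE
  expect_equal(summarize_roi(half)$A_mean,
               mean(half$A[!half$excluded]))

  # independent tabulation through the CSV export
  csv <- file.path(tempdir(), "fits.csv")
  write_parametric_csv(map, csv)
  tab <- read.csv(csv)
  expect_equal(mean(tab$A[!tab$excluded]), sm$A_mean)
  unlink(csv)

  all_excluded <- map; all_excluded$excluded <- TRUE
  expect_error(summarize_roi(all_excluded), "no usable voxels")
})
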