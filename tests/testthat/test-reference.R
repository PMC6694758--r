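# Helper: wrap a bare eccentricity-per-position table into a right-bend
# gaze log covering contiguous bins.
log_from_positions <- function(s, gaze) {
  tibble::tibble(participant_id = "P01", bend_id = 1L, mode = "active",
                 speed_kmh = 75, bend_direction = "right",
                 t_s = seq_along(s) / 20, s_m = s, gaze_h_deg = gaze,
                 gaze_v_deg = 0)
}

test_that("pooled median is computed per bin and robust to outliers", {
  trk <- default_track()
  s <- rep(seq(0.1, 9.9, by = 0.1), 3)
  gaze <- rep(3, length(s))
  raw <- pooled_median_by_position(log_from_positions(s, gaze), trk)
  expect_true(all(raw$raw_median_deg == 3))
  expect_equal(raw$s_bin_m, seq(0.25, 9.75, by = 0.5))

  # one bin holding {1, 2, 100}: the median ignores the LAF outlier
  lg <- log_from_positions(c(0.1, 0.2, 0.3, 0.6, 0.8),
                           c(1, 2, 100, 5, 5))
  raw2 <- pooled_median_by_position(lg, trk)
  expect_equal(raw2$raw_median_deg[1], 2)
  expect_equal(raw2$n, c(3L, 2L))
})

test_that("median breakdown: 40% contamination cannot drag the bin", {
  trk <- default_track()
  set.seed(31)
  clean <- stats::rnorm(60, 0, 1)
  contaminated <- c(clean, rep(25, 40))  # 40% of 100 samples
  s <- rep(0.25, 100)
  raw <- pooled_median_by_position(log_from_positions(s, contaminated),
                                   trk)
  expect_lt(abs(raw$raw_median_deg[1] - stats::median(clean)), 1)
})

test_that("left-bend traversals are mirrored before pooling", {
  trk <- default_track()
  right <- log_from_positions(seq(0.1, 4.9, by = 0.2), 4)
  left <- right
  left$bend_direction <- "left"
  left$gaze_h_deg <- -4
  raw <- pooled_median_by_position(rbind(right, left), trk)
  expect_true(all(raw$raw_median_deg == 4))
})

test_that("an empty bin raises a coverage error naming the bin", {
  trk <- default_track()
  lg <- log_from_positions(c(0.2, 0.4, 1.7), c(0, 0, 0)) # skips [0.5,1)
  expect_error(pooled_median_by_position(lg, trk), "\\[0.5, 1\\)")
})

test_that("Savitzky-Golay smoothing preserves constants and cubics", {
  s <- seq(0.25, 119.75, by = 0.5)
  const <- tibble::tibble(s_bin_m = s, raw_median_deg = 2.5,
                          n = 10L)
  sm <- smooth_reference(const)
  expect_equal(sm$curve$smoothed_deg, rep(2.5, length(s)),
               tolerance = 1e-10)
  # order-3 filter reproduces any cubic exactly, edges included
  cubic <- 1e-4 * s^3 - 0.02 * s^2 + 0.3 * s - 2
  sm3 <- smooth_reference(tibble::tibble(s_bin_m = s,
                                         raw_median_deg = cubic,
                                         n = 10L))
  expect_equal(sm3$curve$smoothed_deg, cubic, tolerance = 1e-8)
})

test_that("smoothing parameters are validated", {
  s <- seq(0.25, 9.75, by = 0.5)
  raw <- tibble::tibble(s_bin_m = s, raw_median_deg = 0, n = 1L)
  expect_error(smooth_reference(raw, window_bins = 63), "window")
  expect_error(smooth_reference(raw, window_bins = 10, order = 3),
               "odd")
  expect_error(smooth_reference(raw, window_bins = 3, order = 3),
               "odd|order")
})

test_that("estimated reference converges to the generator truth", {
  trk <- default_track()
  gen <- quiet_gen(n_participants = 6, n_bends = 2,
                   laf_base_rate_hz = no_laf_rates(),
                   gf_sigma_deg = 0.02)
  sim <- simulate_gaze(gen, trk, seed = 8)
  ref <- estimate_gf_reference(sim$log, trk)
  truth <- guiding_azimuth(ref$curve$s_bin_m, trk, 75, gen$headway_s,
                           blend_m = gen$blend_m)
  expect_lt(max(abs(ref$curve$smoothed_deg - truth)), 0.2)
})

test_that("eccentricities are zero on-reference and sign follows the bend", {
  trk <- default_track()
  gen <- quiet_gen(laf_base_rate_hz = no_laf_rates(), gf_sigma_deg = 0)
  sim <- simulate_gaze(gen, trk, seed = 4)
  ref <- estimate_gf_reference(sim$log, trk)
  ecc <- eccentricity_series(sim$log, ref)
  # noise-free, no-LAF data: residual is only the nearest-bin lookup error
  expect_lt(max(abs(ecc$ecc_deg)), 0.1)
  # +10 deg toward the bend exit on either bend direction
  shifted <- sim$log
  sgn <- ifelse(shifted$bend_direction == "right", 1, -1)
  shifted$gaze_h_deg <- shifted$gaze_h_deg + sgn * 10
  ecc10 <- eccentricity_series(shifted, ref)
  expect_equal(mean(ecc10$ecc_deg), 10, tolerance = 0.01)
  expect_lt(max(abs(ecc10$ecc_deg - 10)), 0.1)
})

test_that("positions outside the reference extent raise a coverage error", {
  trk <- default_track()
  gen <- quiet_gen(laf_base_rate_hz = no_laf_rates(), gf_sigma_deg = 0)
  sim <- simulate_gaze(gen, trk, seed = 4)
  ref <- estimate_gf_reference(sim$log, trk)
  outside <- sim$log[1, ]
  outside$s_m <- 1000
  expect_error(eccentricity_series(outside, ref), "extent")
})

test_that("restricting one whole-track reference equals per-section use", {
  trk <- default_track()
  sim <- simulate_gaze(quiet_gen(n_participants = 3), trk, seed = 6)
  ref <- estimate_gf_reference(sim$log, trk)
  full <- eccentricity_series(sim$log, ref)
  for (sec in c("A", "C1")) {
    sub <- sim$log[sim$log$section == sec, ]
    expect_equal(eccentricity_series(sub, ref)$ecc_deg,
                 full$ecc_deg[full$section == sec])
  }
})

test_that("reference round-trips to CSV", {
  trk <- default_track()
  sim <- simulate_gaze(quiet_gen(), trk, seed = 2)
  ref <- estimate_gf_reference(sim$log, trk)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gf_reference(ref, path)
  back <- utils::read.csv(path)
  expect_equal(back$smoothed_deg, ref$curve$smoothed_deg)
  expect_equal(back$n, ref$curve$n)
})
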