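test_that("eccentricity binning uses 31 half-open bins with extremes", {
  expect_length(ecc_bin_labels(), 31)
  p <- bin_distribution(rep(0.5, 10))
  expect_equal(unname(p["[0,1)"]), 1)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # hand binning: one count in lower extreme, [0,1), upper extreme
  p2 <- bin_distribution(c(-12, 0, 19))
  expect_equal(unname(p2[c("lt_-11", "[0,1)", "ge_18")]), rep(1 / 3, 3))
  # boundary membership: left-closed interior bins, extremes beyond
  p3 <- bin_distribution(c(-11, 17.999, 18))
  expect_equal(unname(p3["[-11,-10)"]), 1 / 3)
  expect_equal(unname(p3["[17,18)"]), 1 / 3)
  expect_equal(unname(p3["ge_18"]), 1 / 3)
  set.seed(1)
  expect_equal(sum(bin_distribution(stats::rnorm(500, 0, 15))), 1,
               tolerance = 1e-9)
  expect_error(bin_distribution(numeric(0)), "no samples")
})

test_that("paired t matches the hand formula and flags degeneracy", {
  # differences {1, 2, 3}: mean 2, sd 1, t = 2 / (1 / sqrt(3))
  res <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_equal(res$df, 2)
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_raw, 1)
  expect_equal(same$r2, 0)
  expect_true(same$degenerate)
  const <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_true(const$degenerate)
  expect_true(is.na(const$t))
})

test_that("r-squared satisfies its identity with t and df", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    res <- paired_t(stats::rnorm(n), stats::rnorm(n))
    if (is.na(res$t) || res$t == 0) next
    expect_equal(res$r2 / (1 - res$r2), res$t^2 / res$df,
                 tolerance = 1e-9)
    expect_true(res$r2 >= 0 && res$r2 <= 1)
  }
})

test_that("Holm adjustment is the step-down procedure", {
  out <- holm_adjust(c(0.01, 0.04, 0.03))
  expect_equal(out$p_holm, c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.03)$p_holm, 0.03)
  all1 <- holm_adjust(rep(1, 5))
  expect_true(all(all1$p_holm == 1) && !any(all1$significant))
  # brute-force step-down oracle on random families
  set.seed(9)
  for (i in 1:10) {
    p <- stats::runif(sample(2:31, 1))^2
    expect_equal(holm_adjust(p)$p_holm, holm_brute(p), tolerance = 1e-12)
  }
  # NA entries shrink the family
  mixed <- holm_adjust(c(0.01, NA, 0.04))
  expect_equal(mixed$p_holm, c(0.02, NA, 0.04))
  expect_true(all(holm_adjust(stats::runif(10))$p_holm >=
                    holm_adjust(stats::runif(10))$p_raw))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

make_cells <- function(values) {
  grid <- expand.grid(participant_id = sprintf("P%02d", 1:6),
                      mode = c("active", "passive"),
                      speed_kmh = c(60, 75, 90),
                      stringsAsFactors = FALSE)
  grid$value <- values
  grid
}

test_that("repeated-measures ANOVA handles null and additive tables", {
  flat <- make_cells(rep(4, 36))
  res <- rm_anova_2x3(flat)
  expect_equal(res$F, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
  # additive mode + speed effects: interaction SS exactly zero
  grid <- make_cells(0)
  a <- ifelse(grid$mode == "active", 1, 3)
  b <- c(`60` = 0, `75` = 2, `90` = 5)[as.character(grid$speed_kmh)]
  peff <- stats::setNames(seq(0, 2.5, by = 0.5),
                          sprintf("P%02d", 1:6))[grid$participant_id]
  grid$value <- a + b + peff
  res2 <- rm_anova_2x3(grid)
  expect_equal(res2$ss[res2$effect == "mode:speed"], 0,
               tolerance = 1e-12)
  expect_gt(res2$F[res2$effect == "mode"], 1e6) # no residual noise
})

test_that("ANOVA F statistics match the definitional SS oracle", {
  set.seed(404)
  grid <- make_cells(stats::rnorm(36, 10, 2))
  res <- rm_anova_2x3(grid)
  oracle <- rm_anova_brute(data.frame(p = grid$participant_id,
                                      i = grid$mode,
                                      j = factor(grid$speed_kmh),
                                      y = grid$value))
  expect_equal(res$F[res$effect == "mode"], unname(oracle$mode["F"]),
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "speed"], unname(oracle$speed["F"]),
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "mode:speed"],
               unname(oracle$interaction["F"]), tolerance = 1e-8)
  expect_equal(res$ss, unname(c(oracle$mode["ss"], oracle$speed["ss"],
                                oracle$interaction["ss"])),
               tolerance = 1e-8)
  # degrees of freedom of the fully-within design
  expect_equal(res$df_num, c(1, 2, 2))
  expect_equal(res$df_den, c(5, 10, 10))
  # partial eta squared definition
  expect_equal(res$pes, res$ss / (res$ss + res$ss_err), tolerance = 1e-12)
})

test_that("ANOVA drops incomplete participants listwise", {
  grid <- make_cells(stats::rnorm(36))
  grid$value[grid$participant_id == "P01" & grid$mode == "active" &
               grid$speed_kmh == 75] <- NA
  res <- rm_anova_2x3(grid)
  expect_equal(attr(res, "n_used"), 5)
  expect_equal(attr(res, "n_dropped"), 1)
  expect_equal(res$df_den, c(4, 8, 8))
  small <- grid[grid$participant_id %in% c("P01", "P02", "P03"), ]
  small$value[small$participant_id != "P01"] <- NA
  expect_error(rm_anova_2x3(small), "fewer than 3")
})

test_that("threshold-exceedance percentages split mid and far shares", {
  log <- tibble::tibble(
    participant_id = "P01", mode = "active",
    section = rep(c("A", "C1"), each = 4),
    ecc_deg = c(0, 7, 12, 25, 0, 1, 2, 3)
  )
  thr <- structure(list(t_A = 6, t_C1 = 6), class = "threshold_set")
  res <- proportion_above_threshold(log, thr)
  a <- res[res$section == "A", ]
  expect_equal(a$pct_above, 75)
  expect_equal(a$pct_mid, 50)  # 7 and 12 lie in (t, 18]
  expect_equal(a$pct_far, 25)  # 25 exceeds 18
  expect_equal(res$pct_above[res$section == "C1"], 0)
})

test_that("active vs passive exceedance difference is detected reliably", {
  # passive arrival rate doubled relative to active: the paired test on
  # the percentage above a fixed threshold should reject in >= 80% of
  # replicates with the study's 18 participants
  trk <- default_track()
  rej <- logical(200)
  for (r in seq_len(200)) {
    gen <- gaze_gen_spec(
      n_participants = 18, n_bends = 2, speeds = 75,
      laf_base_rate_hz = list(active = c(A = 0.11, C1 = 0.04),
                              passive = c(A = 0.22, C1 = 0.08)))
    sim <- simulate_gaze(gen, trk, seed = 50000 + r)
    ref <- estimate_gf_reference(sim$log, trk)
    ecc <- eccentricity_series(sim$log, ref)
    thr <- structure(list(t_A = stats::qnorm(0.9995) * 1.8,
                          t_C1 = stats::qnorm(0.9995) * 1.8),
                     class = "threshold_set")
    pct <- proportion_above_threshold(ecc, thr)
    a <- pct[pct$section == "A", ]
    act <- a[a$mode == "active", ]
    pas <- a[a$mode == "passive", ]
    act <- act[order(act$participant_id), ]
    pas <- pas[order(pas$participant_id), ]
    rej[r] <- paired_t(pas$pct_above, act$pct_above)$p_raw < 0.05
  }
  expect_gte(mean(rej), 0.8)
})

test_that("report bundle is complete and byte-reproducible", {
  trk <- default_track()
  sim <- simulate_gaze(quiet_gen(n_participants = 4), trk, seed = 77)
  res <- run_gaze_analysis(sim$log, trk, k_range = 1:3,
                           run_anova = FALSE)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  build_report(res, dir1, seed = 77)
  build_report(res, dir2, seed = 77)
  expected <- c("reference.csv", "distributions.csv", "bin_tests.csv",
                "outcomes.csv", "events.csv", "strategy_tallies.csv",
                "thresholds.json", "report.json")
  expect_true(all(file.exists(file.path(dir1, expected))))
  for (f in expected) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  # a missing upstream artifact names the stage
  broken <- res
  broken$thresholds <- NULL
  expect_error(build_report(broken, withr::local_tempdir()),
               "thresholds")
})
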