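test_that("BIC selects one component for a pure Gaussian and recovers it", {
  set.seed(101)
  x <- stats::rnorm(10000)
  m <- fit_mixture(x, "A", k_range = 1:8, seed = 1)
  expect_equal(m$k, 1)
  expect_lt(abs(m$means[1]), 0.05)
  expect_lt(abs(m$sds[1] - 1), 0.05)
  expect_equal(sum(m$weights), 1, tolerance = 1e-9)
})

test_that("two-component mixture parameters are recovered within 3 SE", {
  set.seed(202)
  n <- 10000
  x <- c(stats::rnorm(0.8 * n, 0, 2), stats::rnorm(0.2 * n, 12, 4))
  m <- fit_mixture(x, "A", k_range = 1:8, seed = 2)
  expect_equal(m$k, 2)
  ord <- order(m$means)
  w <- m$weights[ord]; mu <- m$means[ord]; sds <- m$sds[ord]
  # asymptotic standard errors for near-separated components
  se_mu <- c(2, 4) / sqrt(n * c(0.8, 0.2))
  se_sd <- c(2, 4) / sqrt(2 * n * c(0.8, 0.2))
  se_w <- sqrt(0.8 * 0.2 / n)
  expect_lt(abs(mu[1] - 0), 3 * se_mu[1])
  expect_lt(abs(mu[2] - 12), 3 * se_mu[2])
  expect_lt(abs(sds[1] - 2), 3 * se_sd[1])
  expect_lt(abs(sds[2] - 4), 3 * se_sd[2])
  expect_lt(abs(w[1] - 0.8), 3 * se_w)

  # independent cross-check against a reference EM implementation
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(mu), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
  expect_equal(sort(sds), sort(sqrt(as.numeric(
    mc$parameters$variance$sigmasq))), tolerance = 0.05)
})

test_that("fit is deterministic given a seed and validates input size", {
  set.seed(5)
  x <- stats::rnorm(600)
  a <- fit_mixture(x, "A", k_range = 1:2, seed = 7)
  b <- fit_mixture(x, "A", k_range = 1:2, seed = 7)
  expect_identical(a[c("k", "weights", "means", "sds", "bic")],
                   b[c("k", "weights", "means", "sds", "bic")])
  expect_error(fit_mixture(stats::rnorm(100), "A", k_range = 1:8),
               "at least")
})

test_that("the GF component is the central one, ties broken by weight", {
  base <- structure(list(k = 1, weights = 1, means = 0.2, sds = 1,
                         section = "A", gf_index = NA_integer_),
                    class = "gaze_mixture")
  expect_equal(identify_gf_component(base), 1)
  m3 <- base
  m3$k <- 3; m3$weights <- c(0.7, 0.2, 0.1)
  m3$means <- c(-0.3, 11, 24); m3$sds <- c(1, 3, 4)
  expect_equal(identify_gf_component(m3), 1)
  tie <- base
  tie$k <- 2; tie$weights <- c(0.3, 0.7)
  tie$means <- c(-1, 1); tie$sds <- c(1, 1)
  expect_equal(identify_gf_component(tie), 2)
})

test_that("threshold is the upper GF quantile at the requested coverage", {
  m <- structure(list(k = 1, weights = 1, means = 0, sds = 1,
                      section = "A", gf_index = 1L),
                 class = "gaze_mixture")
  # numeric inversion of the normal CDF as an independent oracle
  z_oracle <- stats::uniroot(function(z) stats::pnorm(z) - 0.9995,
                             c(0, 10), tol = 1e-12)$root
  expect_equal(derive_threshold(m, 0.9995), z_oracle, tolerance = 1e-9)
  expect_equal(round(derive_threshold(m, 0.9995), 5), 3.29053)
  expect_equal(derive_threshold(m, 0.5 + 1e-12), m$means[1],
               tolerance = 1e-6)
  expect_error(derive_threshold(m, 0.4), "coverage")
  expect_error(derive_threshold(m, 1), "coverage")
})

test_that("threshold CDF round-trips and is monotone in coverage and sd", {
  set.seed(33)
  x <- c(stats::rnorm(3000, 0, 1.5), stats::rnorm(500, 10, 3))
  m <- fit_mixture(x, "C1", k_range = 1:3, seed = 3)
  for (cov in c(0.9, 0.99, 0.9995)) {
    t_cov <- derive_threshold(m, cov)
    expect_equal(gf_component_cdf(m, t_cov), cov, tolerance = 1e-9)
  }
  expect_true(derive_threshold(m, 0.999) > derive_threshold(m, 0.99))
  wider <- m
  wider$sds[wider$gf_index] <- wider$sds[wider$gf_index] * 2
  expect_gt(derive_threshold(wider, 0.9995), derive_threshold(m, 0.9995))
})

test_that("area labels use a strict threshold on the positive side", {
  expect_identical(label_area(c(7, 7.01, -20, 0), t = 7),
                   c("GF", "LAF", "GF", "GF"))
  expect_error(label_area(1, t = -1), "t > 0")
})

test_that("derived thresholds are stable and track the true GF quantile", {
  # replicated full-design runs; the GF-state quantile of measured
  # eccentricities is the generator-truth yardstick
  trk <- default_track()
  n_rep <- 20
  t_a <- numeric(n_rep)
  q_true <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sim <- simulate_gaze(gaze_gen_spec(), trk, seed = 3000 + r)
    ref <- estimate_gf_reference(sim$log, trk)
    ecc <- eccentricity_series(sim$log, ref)
    act_a <- ecc$mode == "active" & ecc$section == "A"
    m <- fit_mixture(ecc$ecc_deg[act_a], "A", seed = r,
                     k_range = 1:6)
    t_a[r] <- derive_threshold(m)
    # latent states concatenate in log order (traversals are contiguous)
    states_all <- unlist(sim$truth$states[unique(ecc$traversal)],
                         use.names = FALSE)
    gf_mask <- states_all[act_a] == "GF"
    q_true[r] <- stats::quantile(ecc$ecc_deg[act_a][gf_mask], 0.9995)
  }
  expect_lt(stats::sd(t_a), 0.5)
  expect_lt(abs(mean(t_a) - mean(q_true)), 0.5)
})

test_that("threshold sets are fitted per section and serialize to JSON", {
  pipe <- default_pipeline()
  thr <- pipe$thr
  expect_s3_class(thr, "threshold_set")
  expect_true(thr$t_A > 0 && thr$t_C1 > 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_thresholds(thr, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$A$t, thr$t_A, tolerance = 1e-12)
  expect_equal(back$C1$k, thr$models$C1$k)
})
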