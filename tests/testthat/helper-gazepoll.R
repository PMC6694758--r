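# Shared fixtures and independent oracles for the test suite.

default_track <- function() track_spec()

# Small generator configs used across tests.
quiet_gen <- function(...) {
  args <- list(...)
  base <- list(n_participants = 2, n_bends = 2, speeds = 75,
               rate_sdlog = 0, gaze_v_sd_deg = 0)
  do.call(gaze_gen_spec, utils::modifyList(base, args))
}

# Zero-excursion rates for null configurations.
no_laf_rates <- function() {
  list(active = c(A = 0, C1 = 0), passive = c(A = 0, C1 = 0))
}

# Cache expensive shared fixtures (built once per test run).
.gp_cache <- new.env(parent = emptyenv())

# Full-design simulation and pipeline at generator defaults; shared by
# the acceptance checks that probe the study-scale conditions.
default_pipeline <- function() {
  if (is.null(.gp_cache$pipeline)) {
    trk <- default_track()
    sim <- simulate_gaze(gaze_gen_spec(), trk, seed = 424242)
    ref <- estimate_gf_reference(sim$log, trk)
    ecc <- eccentricity_series(sim$log, ref)
    thr <- fit_thresholds(ecc)
    segs <- segment_traversals(ecc)
    pol <- analyze_polling(ecc, segs, thr, trk)
    .gp_cache$pipeline <- list(track = trk, sim = sim, ref = ref,
                               ecc = ecc, thr = thr, segs = segs,
                               pol = pol)
  }
  .gp_cache$pipeline
}

# Step-down Holm adjustment written from the definition, as an
# independent check on the package's wrapper.
holm_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[ord[i]]))
    adj[ord[i]] <- running
  }
  adj
}

# Two-way fully-within ANOVA from the definitional sums of squares,
# independent of stats::aov. y indexed by participant p, factor i
# (a levels), factor j (b levels); data frame with columns p, i, j, y.
rm_anova_brute <- function(d) {
  gm <- mean(d$y)
  n <- length(unique(d$p))
  a <- length(unique(d$i))
  b <- length(unique(d$j))
  m_i <- tapply(d$y, d$i, mean)
  m_j <- tapply(d$y, d$j, mean)
  m_p <- tapply(d$y, d$p, mean)
  m_pi <- tapply(d$y, list(d$p, d$i), mean)
  m_pj <- tapply(d$y, list(d$p, d$j), mean)
  m_ij <- tapply(d$y, list(d$i, d$j), mean)

  ss_a <- n * b * sum((m_i - gm)^2)
  ss_err_a <- b * sum((sweep(sweep(m_pi, 1, m_p), 2, m_i) + gm)^2)
  ss_b <- n * a * sum((m_j - gm)^2)
  ss_err_b <- a * sum((sweep(sweep(m_pj, 1, m_p), 2, m_j) + gm)^2)

  ss_ab <- n * sum((sweep(sweep(m_ij, 1, m_i), 2, m_j) + gm)^2)
  resid <- numeric(nrow(d))
  for (r in seq_len(nrow(d))) {
    p <- as.character(d$p[r]); i <- as.character(d$i[r])
    j <- as.character(d$j[r])
    resid[r] <- d$y[r] - m_pi[p, i] - m_pj[p, j] + m_p[p] -
      m_ij[i, j] + m_i[i] + m_j[j] - gm
  }
  ss_err_ab <- sum(resid^2)

  f <- function(ss_e, df_e, ss_r, df_r) (ss_e / df_e) / (ss_r / df_r)
  list(
    mode = c(F = f(ss_a, a - 1, ss_err_a, (a - 1) * (n - 1)),
             ss = ss_a, ss_err = ss_err_a),
    speed = c(F = f(ss_b, b - 1, ss_err_b, (b - 1) * (n - 1)),
              ss = ss_b, ss_err = ss_err_b),
    interaction = c(F = f(ss_ab, (a - 1) * (b - 1), ss_err_ab,
                          (a - 1) * (b - 1) * (n - 1)),
                    ss = ss_ab, ss_err = ss_err_ab)
  )
}

# Hand-built eccentricity trace sampled at 20 Hz: a sequence of
# (value, n_samples) pairs with instantaneous level changes.
build_trace <- function(...) {
  pieces <- list(...)
  ecc <- unlist(lapply(pieces, function(p) rep(p[1], p[2])))
  tibble::tibble(t_s = (seq_along(ecc) - 1) / 20, ecc_deg = ecc)
}
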