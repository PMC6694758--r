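#' Synthetic gaze-log generator specification
#'
#' Parameters of the synthetic study: a grid of participants x driving
#' modes x speeds x bends, sampled at `hz`, in which gaze tracks the
#' guiding preview point with Gaussian noise and intermittently jumps to
#' an eccentric look-ahead target (Poisson arrivals, exponential dwells,
#' linear saccade ramps). Excursion amplitudes come from a mid/far
#' two-component mixture aimed toward the bend exit, with a small
#' proportion of opposite-direction scenery glances. Per-participant
#' lognormal rate multipliers create individual variation in polling
#' propensity.
#'
#' @param n_participants Number of participants.
#' @param n_bends Bends per condition (directions alternate right/left).
#' @param modes Driving modes simulated.
#' @param speeds Speed conditions (km/h).
#' @param hz Sampling rate (Hz).
#' @param gf_sigma_deg SD of guiding-fixation tracking noise (deg).
#' @param laf_base_rate_hz Named list (`active`, `passive`) of named
#'   vectors (`A`, `C1`) of excursion arrival rates (events/s) at the
#'   reference speed; positions beyond C1 use the `C1` rate.
#' @param speed_ref_kmh,speed_power Rates scale as
#'   `(speed / speed_ref_kmh)^speed_power`.
#' @param laf_dwell_s Named vector of mean dwell durations (s) per mode;
#'   dwells are exponential.
#' @param mid_laf_ecc_deg,mid_laf_sd_deg Mean/SD of mid-eccentric
#'   excursion amplitude (deg).
#' @param far_laf_ecc_deg,far_laf_sd_deg Mean/SD of far-eccentric
#'   excursion amplitude (deg).
#' @param p_far Named vector per mode: probability an excursion is
#'   far-eccentric.
#' @param p_opposite Probability an excursion targets the opposite
#'   (scenery) side, with negated amplitude.
#' @param saccade_duration_s Duration of the linear saccade ramp (s).
#' @param headway_s Preview time headway of the guiding target (s).
#' @param blend_m Arc-length SD (m) of the Gaussian anticipation blend
#'   applied to the preview azimuth (see [guiding_azimuth()]).
#' @param rate_sdlog SD (log scale) of the per-participant lognormal rate
#'   multiplier; 0 disables heterogeneity.
#' @param gaze_v_sd_deg SD of the (carried, unanalyzed) vertical channel.
#' @return An object of class `gaze_gen_spec`.
#' @export
gaze_gen_spec <- function(n_participants = 18, n_bends = 6,
                          modes = c("active", "passive"),
                          speeds = c(60, 75, 90), hz = 20,
                          gf_sigma_deg = 1.8,
                          laf_base_rate_hz = list(
                            active = c(A = 0.11, C1 = 0.04),
                            passive = c(A = 0.16, C1 = 0.28)),
                          speed_ref_kmh = 75, speed_power = 1,
                          laf_dwell_s = c(active = 0.4, passive = 0.7),
                          mid_laf_ecc_deg = 11, mid_laf_sd_deg = 2,
                          far_laf_ecc_deg = 24, far_laf_sd_deg = 3,
                          p_far = c(active = 0.55, passive = 0.45),
                          p_opposite = 0.02,
                          saccade_duration_s = 0.05, headway_s = 1.5,
                          blend_m = 10, rate_sdlog = 0.5,
                          gaze_v_sd_deg = 0.5) {
  stopifnot(n_participants >= 1, n_bends >= 1, hz > 0,
            gf_sigma_deg >= 0, all(speeds > 0),
            all(modes %in% c("active", "passive")))
  rates <- unlist(laf_base_rate_hz)
  if (any(rates < 0)) stop("excursion rates must be >= 0", call. = FALSE)
  if (any(laf_dwell_s[modes] <= 0)) {
    stop("mean dwell durations must be > 0", call. = FALSE)
  }
  probs <- c(p_far[modes], p_opposite)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_participants = n_participants, n_bends = n_bends, modes = modes,
         speeds = speeds, hz = hz, gf_sigma_deg = gf_sigma_deg,
         laf_base_rate_hz = laf_base_rate_hz,
         speed_ref_kmh = speed_ref_kmh, speed_power = speed_power,
         laf_dwell_s = laf_dwell_s, mid_laf_ecc_deg = mid_laf_ecc_deg,
         mid_laf_sd_deg = mid_laf_sd_deg,
         far_laf_ecc_deg = far_laf_ecc_deg,
         far_laf_sd_deg = far_laf_sd_deg, p_far = p_far,
         p_opposite = p_opposite, saccade_duration_s = saccade_duration_s,
         headway_s = headway_s, blend_m = blend_m, rate_sdlog = rate_sdlog,
         gaze_v_sd_deg = gaze_v_sd_deg),
    class = "gaze_gen_spec"
  )
}

#' Excursion arrival rate for a condition and section
#'
#' @param gen A [gaze_gen_spec()].
#' @param mode `"active"` or `"passive"`.
#' @param speed_kmh Speed (km/h).
#' @param section `"A"` or `"C1"` (positions beyond C1 use the C1 rate).
#' @return Rate in events/s.
#' @export
laf_rate <- function(gen, mode, speed_kmh, section) {
  sec <- ifelse(section == "A", "A", "C1")
  base <- gen$laf_base_rate_hz[[mode]][sec]
  unname(base * (speed_kmh / gen$speed_ref_kmh)^gen$speed_power)
}

# Deterministic 31-bit substream seed from a top-level seed and a counter,
# so per-traversal streams are independent of which other traversals run.
substream_seed <- function(seed, counter) {
  as.integer((abs(seed) * 7919 + counter * 1299709) %% 2147483587) + 1L
}

# Simulate one traversal; returns sample vectors and ground-truth events.
simulate_traversal <- function(gen, track, mode, speed, direction, mult,
                               tr_seed, ref_curve) {
  set.seed(tr_seed)
  v <- speed / 3.6
  dt <- 1 / gen$hz
  s_end <- track$approach_length_m + track$arc_length_m
  s0 <- stats::runif(1) * v * dt
  n <- floor((s_end - s0) / (v * dt)) + 1L
  t <- (seq_len(n) - 1L) * dt
  s <- s0 + v * t
  T_end <- t[n]

  la <- track$approach_length_m
  rate_a <- laf_rate(gen, mode, speed, "A") * mult
  rate_c <- laf_rate(gen, mode, speed, "C1") * mult
  rmax <- max(rate_a, rate_c)
  sacc <- gen$saccade_duration_s
  dwell_mean <- unname(gen$laf_dwell_s[mode])

  ev <- list()
  tau <- 0
  while (rmax > 0) {
    tau <- tau + stats::rexp(1, rmax)
    if (tau >= T_end) break
    rate_here <- if (s0 + v * tau < la) rate_a else rate_c
    if (stats::runif(1) > rate_here / rmax) next
    far <- stats::runif(1) < unname(gen$p_far[mode])
    amp <- if (far) {
      stats::rnorm(1, gen$far_laf_ecc_deg, gen$far_laf_sd_deg)
    } else {
      stats::rnorm(1, gen$mid_laf_ecc_deg, gen$mid_laf_sd_deg)
    }
    if (stats::runif(1) < gen$p_opposite) amp <- -abs(amp)
    dwell <- stats::rexp(1, 1 / dwell_mean)
    t_out <- tau
    d_start <- t_out + sacc
    d_end <- d_start + dwell
    t_back <- d_end + sacc
    ev[[length(ev) + 1L]] <- c(t_out, d_start, d_end, t_back,
                               amp, as.numeric(t_back <= T_end))
    tau <- t_back
  }

  ecc <- numeric(n)
  state <- rep("GF", n)
  for (e in ev) {
    i_out <- which(t >= e[1] & t < e[2])
    i_dw <- which(t >= e[2] & t < e[3])
    i_bk <- which(t >= e[3] & t < e[4])
    ecc[i_out] <- e[5] * (t[i_out] - e[1]) / sacc
    state[i_out] <- "saccade_out"
    ecc[i_dw] <- e[5]
    state[i_dw] <- "LAF"
    ecc[i_bk] <- e[5] * (1 - (t[i_bk] - e[3]) / sacc)
    state[i_bk] <- "saccade_back"
  }

  ref <- stats::approx(ref_curve$s, ref_curve$az, xout = s, rule = 2)$y
  sgn <- if (direction == "right") 1 else -1
  gaze_h <- sgn * (ref + ecc)
  if (gen$gf_sigma_deg > 0) {
    gaze_h <- gaze_h + stats::rnorm(n, 0, gen$gf_sigma_deg)
  }
  gaze_v <- if (gen$gaze_v_sd_deg > 0) {
    stats::rnorm(n, 0, gen$gaze_v_sd_deg)
  } else {
    numeric(n)
  }

  events <- if (length(ev)) {
    m <- do.call(rbind, ev)
    tibble::tibble(t_out_s = m[, 1], dwell_start_s = m[, 2],
                   dwell_end_s = m[, 3], t_back_end_s = m[, 4],
                   amplitude_deg = m[, 5], complete = m[, 6] > 0)
  } else {
    tibble::tibble(t_out_s = numeric(), dwell_start_s = numeric(),
                   dwell_end_s = numeric(), t_back_end_s = numeric(),
                   amplitude_deg = numeric(), complete = logical())
  }
  list(t = t, s = s, gaze_h = gaze_h, gaze_v = gaze_v, state = state,
       events = events)
}

#' Simulate a synthetic gaze-log dataset with ground truth
#'
#' Generates one traversal per participant x mode x speed x bend cell of
#' the design in [gaze_gen_spec()]. Each traversal covers the approach
#' and the full arc, entering the track at a uniformly random sub-sample
#' arc-length phase (real section entries are not aligned to the sampling
#' clock). The output is byte-reproducible from `seed`; each traversal
#' uses a counter-derived substream, so shrinking `n_participants` leaves
#' the remaining participants' data unchanged.
#'
#' @param gen A [gaze_gen_spec()].
#' @param track A [track_spec()].
#' @param seed Integer seed for all randomness.
#' @return A list with `log` (gaze-log tibble, see [read_gaze_log()] for
#'   columns, plus `traversal` and `section`), and `truth`: `events` (one
#'   row per latent excursion, with traversal keys and `complete` flag),
#'   `states` (named list of per-sample latent states), `rate_multiplier`
#'   (per participant), and `reference` (true preview curves per speed).
#' @examples
#' sim <- simulate_gaze(gaze_gen_spec(n_participants = 2, n_bends = 1,
#'                                    speeds = 75), track_spec(), seed = 1)
#' table(sim$log$section)
#' @export
simulate_gaze <- function(gen, track, seed = 1) {
  stopifnot(inherits(gen, "gaze_gen_spec"), inherits(track, "track_spec"))
  mult <- numeric(gen$n_participants)
  for (p in seq_len(gen$n_participants)) {
    set.seed(substream_seed(seed, 1000000 + p))
    mult[p] <- if (gen$rate_sdlog > 0) {
      stats::rlnorm(1, 0, gen$rate_sdlog)
    } else {
      1
    }
  }

  n_modes <- length(gen$modes)
  n_speeds <- length(gen$speeds)
  curves <- lapply(stats::setNames(gen$speeds, gen$speeds), function(v) {
    if (gen$blend_m > 0) {
      guiding_curve(track, v, gen$headway_s, "right", gen$blend_m)
    } else {
      s_end <- track$approach_length_m + track$arc_length_m
      grid <- seq(0, s_end, by = 0.1)
      list(s = grid, az = preview_azimuth(grid, track, v, gen$headway_s))
    }
  })
  logs <- list()
  states <- list()
  events <- list()
  k <- 0L
  for (p in seq_len(gen$n_participants)) {
    pid <- sprintf("P%02d", p)
    for (mi in seq_len(n_modes)) {
      for (si in seq_len(n_speeds)) {
        for (b in seq_len(gen$n_bends)) {
          mode <- gen$modes[mi]
          speed <- gen$speeds[si]
          direction <- if (b %% 2 == 1) "right" else "left"
          counter <- (((p - 1) * 2 + (mi - 1)) * 3 + (si - 1)) *
            gen$n_bends + b
          tr <- simulate_traversal(gen, track, mode, speed, direction,
                                   mult[p], substream_seed(seed, counter),
                                   curves[[as.character(speed)]])
          key <- paste(pid, mode, speed, b, sep = "|")
          k <- k + 1L
          logs[[k]] <- tibble::tibble(
            participant_id = pid, bend_id = b, mode = mode,
            speed_kmh = speed, bend_direction = direction,
            t_s = tr$t, s_m = tr$s, gaze_h_deg = tr$gaze_h,
            gaze_v_deg = tr$gaze_v, traversal = key
          )
          states[[key]] <- tr$state
          if (nrow(tr$events)) {
            tr$events$traversal <- key
            tr$events$participant_id <- pid
            tr$events$mode <- mode
            tr$events$speed_kmh <- speed
            tr$events$bend_id <- b
            events[[length(events) + 1L]] <- tr$events
          }
        }
      }
    }
  }
  log <- do.call(rbind, logs)
  log$section <- assign_section(log$s_m, track)
  truth_events <- if (length(events)) {
    do.call(rbind, events)
  } else {
    tibble::tibble(t_out_s = numeric(), dwell_start_s = numeric(),
                   dwell_end_s = numeric(), t_back_end_s = numeric(),
                   amplitude_deg = numeric(), complete = logical(),
                   traversal = character(), participant_id = character(),
                   mode = character(), speed_kmh = numeric(),
                   bend_id = integer())
  }
  reference <- lapply(stats::setNames(gen$speeds, gen$speeds), function(v) {
    true_gf_reference(track, v, gen$headway_s, blend_m = gen$blend_m)
  })
  list(log = log,
       truth = list(events = truth_events, states = states,
                    rate_multiplier = stats::setNames(
                      mult, sprintf("P%02d", seq_along(mult))),
                    reference = reference))
}

#' Serialize ground truth to JSON
#'
#' Writes the latent excursion intervals (seconds) and per-sample states
#' (strings) of a [simulate_gaze()] run to a JSON file.
#'
#' @param truth The `truth` element of a [simulate_gaze()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  payload <- list(
    events = truth$events,
    states = truth$states,
    rate_multiplier = as.list(truth$rate_multiplier)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
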