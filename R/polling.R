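# Gaze-polling event detection: a state machine over classified segments
# and per-sample GF/LAF area labels. An event is the complete cycle
# GF area -> saccade -> dwell in the LAF area -> saccade -> GF area;
# everything inside the dwell is merged into a single LAF regardless of
# its internal segment structure.

#' Detect gaze-polling events in one traversal
#'
#' An event opens at a saccade segment launched from a GF-area sample
#' that lands on a LAF-area sample, and closes at the first subsequent
#' saccade segment landing on a GF-area sample. The launch sample is the
#' one preceding the saccade segment; the landing sample is the
#' segment's last. The LAF dwell is the set of LAF-area samples between
#' the outbound and return saccades; its internal saccades, fixations,
#' or pursuits are merged. An excursion still open at the end of the
#' series is not an event.
#'
#' @param t Sample times (s).
#' @param ecc Eccentricities (deg).
#' @param area Per-sample area labels from [label_area()].
#' @param segments Classified segments of this traversal
#'   ([classify_segments()]).
#' @param section Per-sample section labels (event section = section of
#'   the launch sample).
#' @return A tibble with one row per event: `section`, `t_out_s`
#'   (outbound saccade start), `laf_start_s`, `laf_end_s`,
#'   `laf_duration_s`, `max_ecc_deg`, `t_back_s` (return saccade start).
#'   Attribute `n_incomplete` counts excursions open at the data end.
#' @export
detect_events <- function(t, ecc, area, segments, section) {
  n <- length(t)
  stopifnot(length(ecc) == n, length(area) == n, length(section) == n)
  dt <- if (n > 1) (t[n] - t[1]) / (n - 1) else 0
  sac <- segments[segments$klass == "saccade", , drop = FALSE]
  events <- list()
  open <- FALSE
  out_i <- NA_integer_
  out_t <- NA_real_
  out_sec <- NA_character_
  n_incomplete <- 0L
  if (nrow(sac)) {
    for (j in seq_len(nrow(sac))) {
      i_start <- sac$i_start[j]
      launch <- if (i_start > 1) i_start - 1L else i_start
      land <- sac$i_end[j] - 1L
      if (!open && area[launch] == "GF" && area[land] == "LAF") {
        open <- TRUE
        out_i <- i_start
        out_t <- t[i_start]
        out_sec <- section[launch]
      } else if (open && area[land] == "GF") {
        dwell <- which(area == "LAF")
        dwell <- dwell[dwell >= out_i & dwell < i_start]
        if (length(dwell)) {
          events[[length(events) + 1L]] <- tibble::tibble(
            section = out_sec,
            t_out_s = out_t,
            laf_start_s = t[dwell[1]],
            laf_end_s = t[dwell[length(dwell)]] + dt,
            laf_duration_s = length(dwell) * dt,
            max_ecc_deg = max(ecc[dwell]),
            t_back_s = t[i_start]
          )
        }
        open <- FALSE
      }
    }
  }
  if (open) n_incomplete <- 1L
  out <- if (length(events)) {
    do.call(rbind, events)
  } else {
    tibble::tibble(section = character(), t_out_s = numeric(),
                   laf_start_s = numeric(), laf_end_s = numeric(),
                   laf_duration_s = numeric(), max_ecc_deg = numeric(),
                   t_back_s = numeric())
  }
  attr(out, "n_incomplete") <- n_incomplete
  out
}

#' Classify a bend section's gaze strategy
#'
#' `polling` if at least one completed event; otherwise `gf_only` /
#' `laf_only` if every sample of the section sits in that area; and
#' `mixed_incomplete` for one-way crossings that never completed a
#' polling cycle (reported separately, excluded from polling counts).
#'
#' @param area Area labels of the section's samples.
#' @param n_events Number of completed events attributed to the section.
#' @return One of `"polling"`, `"gf_only"`, `"laf_only"`,
#'   `"mixed_incomplete"`.
#' @export
classify_bend <- function(area, n_events) {
  if (!length(area)) stop("empty section traversal", call. = FALSE)
  if (n_events >= 1) return("polling")
  if (all(area == "GF")) return("gf_only")
  if (all(area == "LAF")) return("laf_only")
  "mixed_incomplete"
}

#' Polling metrics for a bend section
#'
#' Defined only when at least one event occurred: polling frequency
#' (events per second of section time), mean LAF duration, and the
#' cumulative LAF duration as a percentage of section duration.
#'
#' @param laf_durations Durations (s) of the section's events' LAFs.
#' @param section_duration Duration of the section (s), `> 0`.
#' @return Named list `frequency_hz`, `mean_laf_s`, `cumulative_pct`.
#' @export
polling_metrics <- function(laf_durations, section_duration) {
  stopifnot(section_duration > 0)
  if (!length(laf_durations)) {
    stop("polling metrics are undefined without events", call. = FALSE)
  }
  list(frequency_hz = length(laf_durations) / section_duration,
       mean_laf_s = mean(laf_durations),
       cumulative_pct = min(100,
                            100 * sum(laf_durations) / section_duration))
}

#' Detect events and classify strategies for every traversal
#'
#' Runs [label_area()] (with the section-specific threshold; positions
#' beyond C1 use the C1 threshold), [detect_events()], [classify_bend()]
#' and [polling_metrics()] per traversal, for both analysis sections.
#'
#' @param ecc_log Output of [eccentricity_series()].
#' @param segments Output of [segment_traversals()].
#' @param thresholds A `threshold_set` from [fit_thresholds()].
#' @param track A [track_spec()].
#' @return A list with `events` (one row per polling event launched in A
#'   or C1) and `outcomes` (one row per traversal x section with
#'   `category`, `n_events`, `frequency_hz`, `mean_laf_s`,
#'   `cumulative_pct`; metrics are `NA` when no event occurred).
#' @export
analyze_polling <- function(ecc_log, segments, thresholds, track) {
  stopifnot(inherits(thresholds, "threshold_set"),
            inherits(track, "track_spec"))
  idx <- split(seq_len(nrow(ecc_log)), ecc_log$traversal)
  seg_idx <- split(seq_len(nrow(segments)), segments$traversal)
  ev_list <- list()
  oc_list <- list()
  for (key in names(idx)) {
    tr <- ecc_log[idx[[key]], ]
    segs <- segments[seg_idx[[key]], ]
    thr <- ifelse(tr$section == "A", thresholds$t_A, thresholds$t_C1)
    area <- ifelse(tr$ecc_deg > thr, "LAF", "GF")
    ev <- detect_events(tr$t_s, tr$ecc_deg, area, segs, tr$section)
    ev <- ev[ev$section %in% c("A", "C1"), , drop = FALSE]
    meta <- tr[1, c("participant_id", "bend_id", "mode", "speed_kmh")]
    for (sec in c("A", "C1")) {
      in_sec <- tr$section == sec
      if (!any(in_sec)) next
      ev_sec <- ev[ev$section == sec, , drop = FALSE]
      n_ev <- nrow(ev_sec)
      cat_ <- classify_bend(area[in_sec], n_ev)
      T_sec <- section_duration(track, meta$speed_kmh, sec)
      met <- if (n_ev >= 1) {
        polling_metrics(ev_sec$laf_duration_s, T_sec)
      } else {
        list(frequency_hz = NA_real_, mean_laf_s = NA_real_,
             cumulative_pct = NA_real_)
      }
      oc_list[[length(oc_list) + 1L]] <- tibble::tibble(
        traversal = key, participant_id = meta$participant_id,
        bend_id = meta$bend_id, mode = meta$mode,
        speed_kmh = meta$speed_kmh, section = sec, category = cat_,
        n_events = n_ev, frequency_hz = met$frequency_hz,
        mean_laf_s = met$mean_laf_s, cumulative_pct = met$cumulative_pct
      )
    }
    if (nrow(ev)) {
      ev$traversal <- key
      ev$participant_id <- meta$participant_id
      ev$mode <- meta$mode
      ev$speed_kmh <- meta$speed_kmh
      ev$bend_id <- meta$bend_id
      ev_list[[length(ev_list) + 1L]] <- ev
    }
  }
  events <- if (length(ev_list)) {
    do.call(rbind, ev_list)
  } else {
    tibble::tibble(section = character(), t_out_s = numeric(),
                   laf_start_s = numeric(), laf_end_s = numeric(),
                   laf_duration_s = numeric(), max_ecc_deg = numeric(),
                   t_back_s = numeric(), traversal = character(),
                   participant_id = character(), mode = character(),
                   speed_kmh = numeric(), bend_id = integer())
  }
  list(events = events, outcomes = do.call(rbind, oc_list))
}

#' Tally gaze strategies by section, mode, and category
#'
#' @param outcomes The `outcomes` tibble of [analyze_polling()].
#' @return A list with `counts` (section x mode x category with `n` and
#'   within-section-and-mode `prop`), `totals` (bends per section), and
#'   `participant_order` (participants ordered by decreasing share of
#'   polling bends, for strategy-map displays).
#' @export
tally_strategies <- function(outcomes) {
  cats <- c("gf_only", "laf_only", "polling", "mixed_incomplete")
  grid <- expand.grid(section = unique(outcomes$section),
                      mode = unique(outcomes$mode), category = cats,
                      stringsAsFactors = FALSE)
  grid$n <- mapply(function(sec, mo, ca) {
    sum(outcomes$section == sec & outcomes$mode == mo &
          outcomes$category == ca)
  }, grid$section, grid$mode, grid$category)
  cell_total <- mapply(function(sec, mo) {
    sum(outcomes$section == sec & outcomes$mode == mo)
  }, grid$section, grid$mode)
  grid$prop <- ifelse(cell_total > 0, grid$n / cell_total, NA_real_)
  totals <- vapply(unique(outcomes$section), function(sec) {
    sum(outcomes$section == sec)
  }, numeric(1))
  poll_share <- vapply(split(outcomes$category == "polling",
                             outcomes$participant_id), mean, numeric(1))
  list(counts = tibble::as_tibble(grid),
       totals = totals,
       participant_order = names(sort(poll_share, decreasing = TRUE)))
}

#' Write polling events and outcomes to CSV
#'
#' @param polling Result of [analyze_polling()].
#' @param events_path,outcomes_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_polling <- function(polling, events_path, outcomes_path) {
  utils::write.csv(as.data.frame(polling$events), events_path,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(polling$outcomes), outcomes_path,
                   row.names = FALSE, quote = FALSE)
  invisible(c(events_path, outcomes_path))
}
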