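#' Track geometry specification
#'
#' Describes the bend layout used throughout the analysis: a straight
#' approach, a constant-radius arc, and an exit straight. Arc length `s` is
#' measured in meters from the start of the approach and is continuous
#' across sections. The analysis sections are A (the whole approach,
#' `[0, approach_length_m)`) and C1 (the first `c1_length_m` of the arc,
#' half-open).
#'
#' @param approach_length_m Length of the approach straight (m).
#' @param arc_length_m Length of the circular arc (m).
#' @param radius_m Radius of the arc (m).
#' @param c1_length_m Length of the analyzed first part of the arc (m).
#' @param exit_length_m Length of the exit straight (m).
#' @param bend_direction Default bend direction, `"left"` or `"right"`.
#'   Individual traversals may override it via their own
#'   `bend_direction` column.
#' @return An object of class `track_spec`.
#' @examples
#' trk <- track_spec()
#' assign_section(c(0, 119.9, 120, 169.9, 170), trk)
#' @export
track_spec <- function(approach_length_m = 120, arc_length_m = 100,
                       radius_m = 100, c1_length_m = 50,
                       exit_length_m = 100, bend_direction = "right") {
  lens <- c(approach_length_m, arc_length_m, radius_m, c1_length_m,
            exit_length_m)
  if (!all(is.finite(lens)) || any(lens <= 0)) {
    stop("all track lengths must be finite and > 0", call. = FALSE)
  }
  if (c1_length_m > arc_length_m) {
    stop("c1_length_m must not exceed arc_length_m", call. = FALSE)
  }
  bend_direction <- match.arg(bend_direction, c("left", "right"))
  structure(
    list(approach_length_m = approach_length_m,
         arc_length_m = arc_length_m,
         radius_m = radius_m,
         c1_length_m = c1_length_m,
         exit_length_m = exit_length_m,
         bend_direction = bend_direction),
    class = "track_spec"
  )
}

#' @export
print.track_spec <- function(x, ...) {
  cat("<track_spec>\n")
  cat(sprintf("  approach %g m | arc %g m (R = %g m) | exit %g m\n",
              x$approach_length_m, x$arc_length_m, x$radius_m,
              x$exit_length_m))
  cat(sprintf("  analyzed: A = [0, %g), C1 = [%g, %g)\n",
              x$approach_length_m, x$approach_length_m,
              x$approach_length_m + x$c1_length_m))
  invisible(x)
}

#' Total track length in meters
#' @param track A [track_spec()].
#' @return Numeric scalar (m).
#' @export
track_length <- function(track) {
  track$approach_length_m + track$arc_length_m + track$exit_length_m
}

#' Assign analysis sections to track positions
#'
#' Maps arc-length positions to the analysis sections: `A` (approach
#' straight, `[0, approach_length_m)`), `C1` (first `c1_length_m` of the
#' arc, half-open), or `other` (everything beyond). The intervals are
#' half-open so the mapping partitions `[0, Inf)`.
#'
#' @param s Numeric vector of positions (m), all `>= 0`.
#' @param track A [track_spec()].
#' @return Character vector in `{"A", "C1", "other"}`.
#' @export
assign_section <- function(s, track) {
  stopifnot(inherits(track, "track_spec"))
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("track positions must be finite and >= 0", call. = FALSE)
  }
  a_end <- track$approach_length_m
  c1_end <- a_end + track$c1_length_m
  out <- rep("other", length(s))
  out[s < a_end] <- "A"
  out[s >= a_end & s < c1_end] <- "C1"
  out
}

#' Signed gaze eccentricity relative to a reference
#'
#' Converts a raw horizontal gaze angle (screen azimuth, rightward
#' positive) into a signed eccentricity relative to the guiding-fixation
#' reference, with positive values toward the bend exit. Left-bend
#' traversals are mirrored by this sign convention, so eccentricities from
#' left and right bends can be pooled.
#'
#' @param gaze_h Horizontal gaze angle (deg, rightward positive).
#' @param reference_h Reference gaze angle at the same position (deg, same
#'   frame as `gaze_h`).
#' @param direction Bend direction, `"left"` or `"right"` (recycled).
#' @return Numeric vector of eccentricities (deg, bend-exit positive).
#' @export
signed_eccentricity <- function(gaze_h, reference_h, direction) {
  if (any(!is.finite(gaze_h)) || any(!is.finite(reference_h))) {
    stop("gaze and reference angles must be finite", call. = FALSE)
  }
  if (!all(direction %in% c("left", "right"))) {
    stop("direction must be 'left' or 'right'", call. = FALSE)
  }
  sgn <- ifelse(direction == "right", 1, -1)
  sgn * (gaze_h - reference_h)
}

#' Duration of an analysis section at a given speed
#'
#' @param track A [track_spec()].
#' @param speed_kmh Vehicle speed (km/h).
#' @param section `"A"` or `"C1"`.
#' @return Duration in seconds.
#' @export
section_duration <- function(track, speed_kmh, section = c("A", "C1")) {
  section <- match.arg(section)
  stopifnot(speed_kmh > 0)
  len <- if (section == "A") track$approach_length_m else track$c1_length_m
  len / (speed_kmh / 3.6)
}

# Required gaze-log columns, in canonical order.
gaze_log_columns <- function() {
  c("participant_id", "bend_id", "mode", "speed_kmh", "bend_direction",
    "t_s", "s_m", "gaze_h_deg", "gaze_v_deg")
}

traversal_key <- function(df) {
  paste(df$participant_id, df$mode, df$speed_kmh, df$bend_id, sep = "|")
}

#' Read a gaze log from CSV
#'
#' Reads a comma-separated gaze log (UTF-8, one header row, `.` decimal,
#' angles in degrees) with the columns
#' `participant_id, bend_id, mode, speed_kmh, bend_direction, t_s, s_m,
#' gaze_h_deg, gaze_v_deg`, validates it, and returns one row per sample
#' grouped into traversals (participant x mode x speed x bend). Rows with
#' non-finite time, position, or horizontal gaze (e.g. blink dropouts) are
#' rejected; their row indices are kept in the `"dropped_rows"` attribute.
#'
#' @param path Path to the CSV file.
#' @param track A [track_spec()] used for section labeling.
#' @param hz Nominal sampling rate (Hz) used for the timestamp-jitter
#'   check; intervals deviating more than `jitter_tol` from `1/hz` trigger
#'   a warning naming the traversal.
#' @param jitter_tol Allowed relative jitter of the sampling interval.
#' @return A tibble of samples with added `traversal` and `section`
#'   columns; attribute `dropped_rows` lists rejected input rows.
#' @export
read_gaze_log <- function(path, track, hz = 20, jitter_tol = 0.2) {
  stopifnot(inherits(track, "track_spec"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  validate_gaze_log(raw, track, hz = hz, jitter_tol = jitter_tol)
}

#' Validate an in-memory gaze log
#'
#' Applies the same schema and monotonicity checks as [read_gaze_log()]
#' to a data frame already in memory.
#'
#' @inheritParams read_gaze_log
#' @param df Data frame with the gaze-log columns.
#' @return See [read_gaze_log()].
#' @export
validate_gaze_log <- function(df, track, hz = 20, jitter_tol = 0.2) {
  need <- gaze_log_columns()
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("gaze log is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[need]
  bad_dir <- !df$bend_direction %in% c("left", "right")
  bad_num <- !is.finite(df$t_s) | !is.finite(df$s_m) |
    !is.finite(df$gaze_h_deg)
  bad <- bad_dir | bad_num
  dropped <- which(bad)
  if (length(dropped)) {
    warning(sprintf("dropped %d malformed row(s): %s", length(dropped),
                    paste(utils::head(dropped, 10), collapse = ", ")),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  if (!nrow(df)) stop("gaze log contains no valid rows", call. = FALSE)
  df$traversal <- traversal_key(df)
  for (key in unique(df$traversal)) {
    tt <- df$t_s[df$traversal == key]
    if (any(diff(tt) <= 0)) {
      stop("non-monotone timestamps within traversal ", key, call. = FALSE)
    }
    jit <- abs(diff(tt) - 1 / hz) > jitter_tol / hz
    if (any(jit)) {
      warning("irregular sampling interval in traversal ", key,
              call. = FALSE)
    }
  }
  df$section <- assign_section(df$s_m, track)
  out <- tibble::as_tibble(df)
  attr(out, "dropped_rows") <- dropped
  out
}

#' Write a gaze log to CSV
#'
#' Inverse of [read_gaze_log()] on the defined columns.
#'
#' @param df Gaze-log tibble (must contain the canonical columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze_log <- function(df, path) {
  need <- gaze_log_columns()
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("cannot write gaze log; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(as.data.frame(df)[need], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' Reads a YAML configuration with optional `track`, `generator`, and
#' `analysis` sections and returns constructed specification objects.
#' Unknown keys raise an error so typos do not silently fall back to
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `track` ([track_spec()]), `generator`
#'   ([gaze_gen_spec()]), and `analysis` (named list of analysis
#'   parameters).
#' @examples
#' cfg <- read_gazepoll_config(
#'   system.file("extdata", "example-config.yaml", package = "gazepoll"))
#' cfg$track
#' @export
read_gazepoll_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("track", "generator", "analysis")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown config section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  track <- do.call(track_spec, as.list(cfg$track))
  generator <- do.call(gaze_gen_spec, as.list(cfg$generator))
  list(track = track, generator = generator,
       analysis = if (is.null(cfg$analysis)) list() else cfg$analysis)
}
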