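#' Pooled per-position median gaze curve
#'
#' Pools the horizontal gaze of all participants and conditions, mirrors
#' left-bend traversals onto the right-bend frame (so all bends
#' contribute to one curve per bend-relative position), and takes the
#' median in contiguous `bin_m` arc-length bins. The median makes the
#' curve robust to the minority of look-ahead samples; the per-bin sample
#' count is kept so the coverage of each bin can be audited.
#'
#' @param log Gaze-log tibble (from [read_gaze_log()] or
#'   [simulate_gaze()]).
#' @param track A [track_spec()].
#' @param bin_m Bin width (m).
#' @return A tibble `s_bin_m, raw_median_deg, n` covering every bin from
#'   0 to the largest observed position; attribute `min_n` holds the
#'   minimum per-bin count.
#' @export
pooled_median_by_position <- function(log, track, bin_m = 0.5) {
  stopifnot(inherits(track, "track_spec"), nrow(log) > 0)
  mirrored <- ifelse(log$bend_direction == "left", -log$gaze_h_deg,
                     log$gaze_h_deg)
  idx <- floor(log$s_m / bin_m)
  n_bins <- max(idx) + 1L
  counts <- tabulate(idx + 1L, nbins = n_bins)
  if (any(counts == 0)) {
    b <- which(counts == 0)[1] - 1L
    stop(sprintf("no gaze samples in bin [%g, %g) m; cannot form reference",
                 b * bin_m, (b + 1) * bin_m), call. = FALSE)
  }
  med <- vapply(split(mirrored, idx), stats::median, numeric(1))
  out <- tibble::tibble(
    s_bin_m = (seq_len(n_bins) - 0.5) * bin_m,
    raw_median_deg = unname(med[order(as.integer(names(med)))]),
    n = counts
  )
  attr(out, "min_n") <- min(counts)
  attr(out, "bin_m") <- bin_m
  out
}

#' Smooth the median curve into the guiding-fixation reference
#'
#' Applies a Savitzky-Golay least-squares polynomial filter to the raw
#' per-bin median curve. The default window of 63 bins spans 31.5 m at
#' 0.5 m bins (the nearest odd bin count covering at least 31 m); near
#' the curve ends the filter falls back to the polynomial fitted on the
#' first/last full window, so the reference stays defined over the full
#' extent. A Savitzky-Golay filter of order `p` reproduces polynomials
#' up to degree `p` exactly; it can overshoot at steps, so no boundedness
#' is implied.
#'
#' @param raw Output of [pooled_median_by_position()].
#' @param window_bins Filter window length in bins (odd, `> order`).
#' @param order Polynomial order.
#' @return An object of class `gf_reference`: the input tibble with a
#'   `smoothed_deg` column, plus `bin_m`, `window_bins`, `order` fields.
#' @export
smooth_reference <- function(raw, window_bins = 63, order = 3) {
  stopifnot(is.data.frame(raw), all(c("s_bin_m", "raw_median_deg") %in%
                                      names(raw)))
  if (window_bins %% 2 != 1 || window_bins <= order) {
    stop("window_bins must be odd and greater than the polynomial order",
         call. = FALSE)
  }
  if (nrow(raw) < window_bins) {
    stop(sprintf("reference curve has %d bins but the filter window is %d",
                 nrow(raw), window_bins), call. = FALSE)
  }
  sm <- signal::sgolayfilt(raw$raw_median_deg, p = order, n = window_bins)
  out <- raw
  out$smoothed_deg <- as.numeric(sm)
  structure(
    list(curve = tibble::as_tibble(out),
         bin_m = if (is.null(attr(raw, "bin_m"))) {
           stats::median(diff(raw$s_bin_m))
         } else {
           attr(raw, "bin_m")
         },
         window_bins = window_bins, order = order,
         min_n = attr(raw, "min_n")),
    class = "gf_reference"
  )
}

#' @export
print.gf_reference <- function(x, ...) {
  cat("<gf_reference>\n")
  cat(sprintf("  %d bins of %g m, extent [%g, %g) m\n", nrow(x$curve),
              x$bin_m, min(x$curve$s_bin_m) - x$bin_m / 2,
              max(x$curve$s_bin_m) + x$bin_m / 2))
  cat(sprintf("  Savitzky-Golay order %d, window %d bins; min n per bin %s\n",
              x$order, x$window_bins,
              if (is.null(x$min_n)) "?" else x$min_n))
  invisible(x)
}

#' Estimate the guiding-fixation reference from a gaze log
#'
#' Convenience wrapper: [pooled_median_by_position()] followed by
#' [smooth_reference()].
#'
#' @inheritParams pooled_median_by_position
#' @inheritParams smooth_reference
#' @return A `gf_reference` object.
#' @export
estimate_gf_reference <- function(log, track, bin_m = 0.5,
                                  window_bins = 63, order = 3) {
  smooth_reference(pooled_median_by_position(log, track, bin_m),
                   window_bins = window_bins, order = order)
}

# Reference value (mirrored frame) at arbitrary positions, nearest bin.
reference_at <- function(ref, s) {
  stopifnot(inherits(ref, "gf_reference"))
  idx <- round((s - ref$curve$s_bin_m[1]) / ref$bin_m) + 1L
  if (any(idx < 1L | idx > nrow(ref$curve))) {
    stop("position outside the reference extent", call. = FALSE)
  }
  ref$curve$smoothed_deg[idx]
}

#' Signed eccentricity of every sample relative to the reference
#'
#' Looks up the smoothed reference at each sample's nearest 0.5 m bin
#' (un-mirroring it for left bends) and applies the bend-exit-positive
#' sign convention of [signed_eccentricity()]. All sample kinds
#' (fixations, saccades, pursuits) are retained.
#'
#' @param log Gaze-log tibble.
#' @param ref A `gf_reference` covering the log's positions.
#' @return The input tibble with an added `ecc_deg` column.
#' @export
eccentricity_series <- function(log, ref) {
  ref_mirrored <- reference_at(ref, log$s_m)
  ref_h <- ifelse(log$bend_direction == "left", -ref_mirrored,
                  ref_mirrored)
  out <- log
  out$ecc_deg <- signed_eccentricity(log$gaze_h_deg, ref_h,
                                     log$bend_direction)
  out
}

#' Write a guiding-fixation reference to CSV
#'
#' Columns: `s_bin_m, raw_median_deg, smoothed_deg, n`.
#'
#' @param ref A `gf_reference`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gf_reference <- function(ref, path) {
  utils::write.csv(
    as.data.frame(ref$curve)[c("s_bin_m", "raw_median_deg",
                               "smoothed_deg", "n")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
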