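# Sequential piecewise-linear segmentation of the eccentricity signal.
# Each incoming sample either extends the current least-squares line or
# opens a new segment; the decision is the Gaussian likelihood-ratio
# between the two, expressed through the exact increase in residual sum
# of squares r^2 / (1 + h0) that adding the sample would cause (r = the
# out-of-fit prediction residual, h0 = its leverage), compared against
# 2 * split_penalty * noise_sd^2. New segments are anchored at the
# previous sample, so a jump between consecutive samples becomes its own
# steep (saccade) segment, as in segmented-linear-regression approaches
# to gaze parsing.

ls_line <- function(tt, yy) {
  n <- length(tt)
  if (n == 1) return(c(intercept = yy, slope = 0))
  tm <- mean(tt)
  sxx <- sum((tt - tm)^2)
  slope <- if (sxx > 0) sum((tt - tm) * (yy - mean(yy))) / sxx else 0
  c(intercept = mean(yy) - slope * tm, slope = slope)
}

#' Segment an eccentricity time series into linear pieces
#'
#' @param t Sample times (s), strictly increasing.
#' @param ecc Eccentricities (deg), same length.
#' @param noise_sd Sample noise SD (deg) of the residual model. `NULL`
#'   (default) estimates it from the lower quartile of absolute second
#'   differences (`quantile(|diff(ecc, differences = 2)|, 0.25) /
#'   (qnorm(0.625) * sqrt(6))`), which is blind to linear trends, barely
#'   touched by the jump-contaminated upper tail, and keeps the
#'   segmentation scale-equivariant; pass a number to fix it.
#' @param split_penalty Log-likelihood cost of opening a new segment.
#'   The default 6 makes an isolated residual of about
#'   `sqrt(12) * noise_sd` (~3.46 sigma) open a segment, so a 3 deg
#'   inter-sample jump splits reliably at 0.8 deg noise.
#' @param sacc_speed Saccadic slope (deg/s): a two-point segment whose
#'   determined slope reaches it is closed at the next sample, since at
#'   20 Hz a saccade spans at most two samples; without this rule the
#'   following dwell can be absorbed into one sloped pseudo-pursuit
#'   line.
#' @return A tibble of segments tiling the series: `i_start`, `i_end`
#'   (1-based, half-open), `t_start`, `t_end`, `slope` (deg/s),
#'   `intercept` (deg), `klass` (`NA` until [classify_segments()]).
#'   Attribute `noise_sd` records the value used.
#' @export
segment_series <- function(t, ecc, noise_sd = NULL, split_penalty = 6,
                           sacc_speed = 40) {
  n <- length(t)
  stopifnot(length(ecc) == n)
  if (n < 2) stop("need at least 2 samples to segment", call. = FALSE)
  if (any(diff(t) <= 0)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  if (is.null(noise_sd)) {
    # |second difference| of iid N(0, s) noise is half-normal with scale
    # s * sqrt(6); its 25% quantile is qnorm(0.625) * s * sqrt(6)
    noise_sd <- if (n >= 3) {
      unname(stats::quantile(abs(diff(ecc, differences = 2)), 0.25)) /
        (stats::qnorm(0.625) * sqrt(6))
    } else {
      1.4826 * stats::median(abs(diff(ecc))) / sqrt(2)
    }
    noise_sd <- max(noise_sd, 1e-9)
  }
  stopifnot(noise_sd > 0, split_penalty > 0)
  crit <- 2 * split_penalty * noise_sd^2

  starts <- 1L          # ownership start of each segment
  anchors <- NA_integer_ # anchor sample index (previous segment's last)
  # running sums of the current segment's fit points (owned + anchor)
  cnt <- 1L
  sx <- t[1]
  sy <- ecc[1]
  sxx <- t[1]^2
  sxy <- t[1] * ecc[1]

  add_point <- function(i) {
    cnt <<- cnt + 1L
    sx <<- sx + t[i]
    sy <<- sy + ecc[i]
    sxx <<- sxx + t[i]^2
    sxy <<- sxy + t[i] * ecc[i]
  }

  owned <- 1L # samples owned by the current segment (cnt minus anchor)
  anchored <- FALSE # the series-opening segment has no boundary anchor
  for (i in 2:n) {
    split <- FALSE
    retro <- FALSE
    if (cnt >= 2L) {
      xm <- sx / cnt
      sxx_c <- sxx - cnt * xm^2
      slope <- if (sxx_c > 1e-12) (sxy - sx * sy / cnt) / sxx_c else 0
      icpt <- sy / cnt - slope * xm
      pred <- icpt + slope * t[i]
      r <- ecc[i] - pred
      if (abs(slope) >= sacc_speed) {
        # a saccade spans at most two samples at this rate: close a
        # saccadic-slope segment before it can absorb the dwell
        split <- TRUE
      } else if (cnt == 2L && anchored) {
        # a fresh post-split segment sits on a real boundary: test the
        # raw residual of its determined line, so the samples right
        # after a gaze shift are not absorbed by leverage discounting
        split <- r^2 > crit
      } else {
        h0 <- 1 / cnt + if (sxx_c > 1e-12) (t[i] - xm)^2 / sxx_c else 0
        split <- r^2 / (1 + h0) > crit
        if (split && owned >= 2L) {
          # refine the split point: if the previous sample already sat
          # off the line on the same side, the jump started there
          r_prev <- ecc[i - 1] - (icpt + slope * t[i - 1])
          retro <- abs(r_prev) > 2 * noise_sd && sign(r_prev) == sign(r)
        }
      }
    }
    if (split) {
      j <- if (retro) i - 1L else i # first owned sample of new segment
      starts <- c(starts, j)
      anchors <- c(anchors, j - 1L)
      anchored <- TRUE
      cnt <- 1L
      owned <- 0L
      sx <- t[j - 1]
      sy <- ecc[j - 1]
      sxx <- t[j - 1]^2
      sxy <- t[j - 1] * ecc[j - 1]
      if (retro) {
        cnt <- cnt + 1L
        owned <- owned + 1L
        sx <- sx + t[i - 1]
        sy <- sy + ecc[i - 1]
        sxx <- sxx + t[i - 1]^2
        sxy <- sxy + t[i - 1] * ecc[i - 1]
      }
    }
    add_point(i)
    owned <- owned + 1L
  }

  ends <- c(starts[-1], n + 1L)
  dt_last <- (t[n] - t[1]) / (n - 1)
  segs <- lapply(seq_along(starts), function(j) {
    own <- starts[j]:(ends[j] - 1L)
    fitpts <- if (is.na(anchors[j])) own else c(anchors[j], own)
    fit <- ls_line(t[fitpts], ecc[fitpts])
    tibble::tibble(
      i_start = starts[j], i_end = ends[j],
      t_start = t[starts[j]],
      t_end = if (ends[j] <= n) t[ends[j]] else t[n] + dt_last,
      slope = unname(fit["slope"]), intercept = unname(fit["intercept"]),
      klass = NA_character_
    )
  })
  out <- do.call(rbind, segs)
  attr(out, "noise_sd") <- noise_sd
  out
}

#' Classify linear segments by slope
#'
#' `|slope| >= sacc_speed` is a saccade, `|slope| <= fix_speed` a
#' fixation, anything between a smooth pursuit. The polling stage only
#' distinguishes saccade from non-saccade; at 20 Hz sampling a saccade
#' spans at most a couple of samples and its slope separates cleanly.
#'
#' @param segments Output of [segment_series()].
#' @param sacc_speed Saccade slope threshold (deg/s).
#' @param fix_speed Fixation slope threshold (deg/s).
#' @return `segments` with `klass` filled in.
#' @export
classify_segments <- function(segments, sacc_speed = 40, fix_speed = 5) {
  stopifnot(sacc_speed > fix_speed, fix_speed >= 0)
  a <- abs(segments$slope)
  segments$klass <- ifelse(a >= sacc_speed, "saccade",
                           ifelse(a <= fix_speed, "fixation", "pursuit"))
  segments
}

#' Merge adjacent saccade segments into saccadic episodes
#'
#' A single saccade can be split into more than one steep segment
#' (e.g. when a sample falls mid-flight); contiguous saccade-classified
#' segments are one gaze shift and are treated as such by the polling
#' detector. Rows must belong to one traversal and be in order.
#'
#' @param segments Classified segments of one traversal.
#' @return A tibble `i_start, i_end, t_start, t_end` with one row per
#'   saccadic episode.
#' @export
saccadic_episodes <- function(segments) {
  sac <- segments[segments$klass == "saccade", , drop = FALSE]
  if (!nrow(sac)) {
    return(tibble::tibble(i_start = integer(), i_end = integer(),
                          t_start = numeric(), t_end = numeric()))
  }
  new_run <- c(TRUE, sac$i_start[-1] != sac$i_end[-nrow(sac)])
  gid <- cumsum(new_run)
  tibble::tibble(
    i_start = tapply(sac$i_start, gid, min),
    i_end = tapply(sac$i_end, gid, max),
    t_start = tapply(sac$t_start, gid, min),
    t_end = tapply(sac$t_end, gid, max)
  )
}

#' Segment and classify every traversal of an eccentricity log
#'
#' When `noise_sd` is `NULL` a single noise estimate is pooled over the
#' second differences of all traversals (tracker noise is a device
#' property; a per-traversal estimate would be biased upward on
#' traversals dense with excursions) and used for every series.
#'
#' @param ecc_log Output of [eccentricity_series()].
#' @param noise_sd,split_penalty See [segment_series()].
#' @param sacc_speed,fix_speed See [classify_segments()].
#' @return A tibble of classified segments with a `traversal` column;
#'   attribute `noise_sd` records the value used.
#' @export
segment_traversals <- function(ecc_log, noise_sd = NULL,
                               split_penalty = 6, sacc_speed = 40,
                               fix_speed = 5) {
  stopifnot(all(c("traversal", "t_s", "ecc_deg") %in% names(ecc_log)))
  idx <- split(seq_len(nrow(ecc_log)), ecc_log$traversal)
  if (is.null(noise_sd)) {
    d2 <- unlist(lapply(idx, function(ii) {
      e <- ecc_log$ecc_deg[ii]
      if (length(e) >= 3) abs(diff(e, differences = 2))
    }), use.names = FALSE)
    noise_sd <- max(unname(stats::quantile(d2, 0.25)) /
                      (stats::qnorm(0.625) * sqrt(6)), 1e-9)
  }
  out <- lapply(names(idx), function(key) {
    tr <- ecc_log[idx[[key]], ]
    segs <- classify_segments(
      segment_series(tr$t_s, tr$ecc_deg, noise_sd = noise_sd,
                     split_penalty = split_penalty,
                     sacc_speed = sacc_speed),
      sacc_speed = sacc_speed, fix_speed = fix_speed)
    segs$traversal <- key
    segs
  })
  res <- do.call(rbind, out)
  attr(res, "noise_sd") <- noise_sd
  res
}
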