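# Distribution binning, paired comparisons with Holm adjustment, and the
# 2x3 fully-within repeated-measures ANOVA on polling metrics.

#' Bin labels of the eccentricity distribution
#'
#' The 1-degree grid from -11 to 18 degrees plus the two extreme
#' classes: 31 bins total.
#'
#' @return Character vector of length 31.
#' @export
ecc_bin_labels <- function() {
  c("lt_-11", sprintf("[%d,%d)", -11:17, -10:18), "ge_18")
}

#' Binned eccentricity distribution
#'
#' Proportions of samples in half-open 1-degree bins `[a, a + 1)` for
#' `a = -11 .. 17`, plus a lower extreme class `(-Inf, -11)` and an
#' upper extreme class `[18, Inf)`. All sample kinds are included.
#'
#' @param ecc Eccentricities (deg) of one participant x condition x
#'   section cell.
#' @return Named numeric vector of 31 proportions summing to 1.
#' @export
bin_distribution <- function(ecc) {
  ecc <- ecc[is.finite(ecc)]
  if (!length(ecc)) stop("no samples to bin", call. = FALSE)
  counts <- tabulate(findInterval(ecc, -11:18) + 1L, nbins = 31)
  stats::setNames(counts / sum(counts), ecc_bin_labels())
}

#' Per-cell binned distributions for a whole eccentricity log
#'
#' One distribution per participant x mode x section, pooling speeds
#' within participant (the active/passive per-bin comparison is not
#' stratified by speed).
#'
#' @param ecc_log Output of [eccentricity_series()], restricted rows with
#'   `section` in `{A, C1}` are used.
#' @return A tibble `participant_id, mode, section, bin, proportion`.
#' @export
bin_distributions <- function(ecc_log) {
  d <- ecc_log[ecc_log$section %in% c("A", "C1"), ]
  cells <- split(d$ecc_deg,
                 list(d$participant_id, d$mode, d$section), drop = TRUE,
                 sep = "|")
  out <- lapply(names(cells), function(nm) {
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    p <- bin_distribution(cells[[nm]])
    tibble::tibble(participant_id = parts[1], mode = parts[2],
                   section = parts[3], bin = names(p),
                   proportion = unname(p))
  })
  do.call(rbind, out)
}

#' Paired t test with r-squared effect size
#'
#' Classical two-sided paired t on participant-matched values;
#' `r2 = t^2 / (t^2 + df)`. Zero-variance differences give a degenerate
#' result: if all differences are zero the test is the null identity
#' (`t = 0, p = 1, r2 = 0`); a constant nonzero difference leaves `t`
#' undefined (`NA`). Both cases are flagged.
#'
#' @param x,y Paired value vectors (same participants, two conditions).
#' @return A one-row tibble `t, df, p_raw, r2, degenerate`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  df <- length(d) - 1
  if (isTRUE(all.equal(stats::sd(d), 0)) || stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(t = 0, df = df, p_raw = 1, r2 = 0,
                            degenerate = TRUE))
    }
    return(tibble::tibble(t = NA_real_, df = df, p_raw = NA_real_,
                          r2 = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tv <- unname(tt$statistic)
  tibble::tibble(t = tv, df = unname(tt$parameter),
                 p_raw = tt$p.value, r2 = tv^2 / (tv^2 + df),
                 degenerate = FALSE)
}

#' Holm step-down adjustment
#'
#' Wraps `stats::p.adjust(method = "holm")`; `NA` entries (degenerate
#' tests) are excluded from the family, shrinking its size.
#'
#' @param p Raw p-values in `[0, 1]` (may contain `NA`).
#' @param alpha Family-wise error level.
#' @return A tibble `p_raw, p_holm, significant`.
#' @export
holm_adjust <- function(p, alpha = 0.05) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- rep(NA_real_, length(p))
  adj[ok] <- stats::p.adjust(p[ok], method = "holm")
  tibble::tibble(p_raw = p, p_holm = adj,
                 significant = !is.na(adj) & adj <= alpha)
}

#' Per-bin active vs passive comparison of gaze distributions
#'
#' For each section and each of the 31 bins, a paired t test of the
#' per-participant bin proportions between modes, Holm-adjusted across
#' the 31 bins within a section.
#'
#' @param dists Output of [bin_distributions()].
#' @param modes The two modes to compare (first minus second).
#' @param alpha Family-wise error level.
#' @return A tibble with one row per section x bin: test statistics,
#'   raw and Holm-adjusted p, `r2`, `significant`.
#' @export
compare_distributions <- function(dists, modes = c("active", "passive"),
                                  alpha = 0.05) {
  out <- list()
  for (sec in unique(dists$section)) {
    rows <- list()
    for (b in ecc_bin_labels()) {
      d1 <- dists[dists$section == sec & dists$bin == b &
                    dists$mode == modes[1], ]
      d2 <- dists[dists$section == sec & dists$bin == b &
                    dists$mode == modes[2], ]
      d1 <- d1[order(d1$participant_id), ]
      d2 <- d2[order(d2$participant_id), ]
      stopifnot(identical(d1$participant_id, d2$participant_id))
      res <- paired_t(d1$proportion, d2$proportion)
      res$section <- sec
      res$bin <- b
      rows[[length(rows) + 1L]] <- res
    }
    tab <- do.call(rbind, rows)
    adj <- holm_adjust(tab$p_raw, alpha)
    tab$p_holm <- adj$p_holm
    tab$significant <- adj$significant
    out[[length(out) + 1L]] <- tab
  }
  res <- do.call(rbind, out)
  res[c("section", "bin", "t", "df", "p_raw", "p_holm", "r2",
        "degenerate", "significant")]
}

#' 2 x 3 repeated-measures ANOVA
#'
#' Fully-within two-way ANOVA (mode: 2 levels, speed: 3 levels) on
#' per-participant cell means, fitted with `stats::aov` using the
#' participant error strata. In this balanced within-subject design the
#' Type III decomposition coincides with the classical partitioning.
#' Participants with any missing cell are dropped listwise (their count
#' is recorded); partial eta-squared is
#' `SS_effect / (SS_effect + SS_error)`. A zero effect sum of squares is
#' reported as `F = 0, p = 1`.
#'
#' @param df Data frame with columns `participant_id, mode, speed_kmh,
#'   value` (one row per cell; replicate rows are averaged).
#' @return A tibble with one row per effect (`mode`, `speed`,
#'   `mode:speed`): `df_num, df_den, ss, ss_err, F, p, pes`. Attribute
#'   `n_used` / `n_dropped` record the listwise deletion.
#' @export
rm_anova_2x3 <- function(df) {
  stopifnot(all(c("participant_id", "mode", "speed_kmh", "value") %in%
                  names(df)))
  # cell mean over the bends where the metric is defined (a bend without
  # polling contributes no value); the cell is missing only if none is
  cell <- stats::aggregate(value ~ participant_id + mode + speed_kmh,
                           data = df,
                           FUN = function(x) {
                             m <- mean(x, na.rm = TRUE)
                             if (is.nan(m)) NA_real_ else m
                           },
                           na.action = stats::na.pass)
  n_cells_per <- table(cell$participant_id[!is.na(cell$value)])
  full <- length(unique(cell$mode)) * length(unique(cell$speed_kmh))
  keep <- names(n_cells_per)[n_cells_per == full]
  n_dropped <- length(unique(cell$participant_id)) - length(keep)
  cell <- cell[cell$participant_id %in% keep & !is.na(cell$value), ]
  if (length(keep) < 3) {
    stop("fewer than 3 participants with complete cells", call. = FALSE)
  }
  cell$participant_id <- factor(cell$participant_id)
  cell$mode <- factor(cell$mode)
  cell$speed <- factor(cell$speed_kmh)
  fit <- stats::aov(value ~ mode * speed +
                      Error(participant_id / (mode * speed)), data = cell)
  sm <- summary(fit)
  pull <- function(stratum, effect) {
    tab <- sm[[paste0("Error: participant_id:", stratum)]][[1]]
    rn <- trimws(rownames(tab))
    e <- which(rn == effect)
    r <- which(rn == "Residuals")
    ss_e <- tab[e, "Sum Sq"]
    ss_r <- tab[r, "Sum Sq"]
    df_e <- tab[e, "Df"]
    df_r <- tab[r, "Df"]
    if (ss_e <= 1e-12) {
      Fv <- 0
      pv <- 1
    } else if (ss_r <= 1e-12) {
      Fv <- Inf
      pv <- 0
    } else {
      Fv <- (ss_e / df_e) / (ss_r / df_r)
      pv <- stats::pf(Fv, df_e, df_r, lower.tail = FALSE)
    }
    tibble::tibble(effect = effect, df_num = df_e, df_den = df_r,
                   ss = ss_e, ss_err = ss_r, F = Fv, p = pv,
                   pes = if (ss_e + ss_r > 0) ss_e / (ss_e + ss_r) else 0)
  }
  out <- rbind(pull("mode", "mode"), pull("speed", "speed"),
               pull("mode:speed", "mode:speed"))
  attr(out, "n_used") <- length(keep)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Percentage of gaze above the LAF threshold
#'
#' Per participant x mode x section: the percentage of samples whose
#' eccentricity exceeds the section threshold, split further into
#' mid-eccentric (threshold to 18 deg] and far-eccentric (> 18 deg)
#' shares.
#'
#' @param ecc_log Output of [eccentricity_series()].
#' @param thresholds A `threshold_set`.
#' @param far_deg Boundary between mid- and far-eccentric gaze (deg).
#' @return A tibble `participant_id, mode, section, pct_above, pct_mid,
#'   pct_far`.
#' @export
proportion_above_threshold <- function(ecc_log, thresholds,
                                       far_deg = 18) {
  d <- ecc_log[ecc_log$section %in% c("A", "C1"), ]
  d$thr <- ifelse(d$section == "A", thresholds$t_A, thresholds$t_C1)
  cells <- split(seq_len(nrow(d)),
                 list(d$participant_id, d$mode, d$section), drop = TRUE,
                 sep = "|")
  out <- lapply(names(cells), function(nm) {
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    rows <- d[cells[[nm]], ]
    tibble::tibble(
      participant_id = parts[1], mode = parts[2], section = parts[3],
      pct_above = 100 * mean(rows$ecc_deg > rows$thr),
      pct_mid = 100 * mean(rows$ecc_deg > rows$thr &
                             rows$ecc_deg <= far_deg),
      pct_far = 100 * mean(rows$ecc_deg > far_deg)
    )
  })
  do.call(rbind, out)
}
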