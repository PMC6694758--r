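# Univariate Gaussian mixtures for the GF/LAF threshold: EM with
# k-means++-style seeding and random restarts, order selected by BIC.

# One weighted EM run from given initial parameters; v are distinct
# values with multiplicities cnt. Returns NULL on degeneracy.
em_gauss1d <- function(v, cnt, w, mu, sigma, max_iter = 500, tol = 1e-8,
                       sd_floor = 0.1) {
  n <- sum(cnt)
  m_v <- length(v)
  k <- length(mu)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j) {
      log(w[j]) + stats::dnorm(v, mu[j], sigma[j], log = TRUE)
    }, numeric(m_v))
    dim(logd) <- c(m_v, k)
    m <- logd[cbind(seq_len(m_v), max.col(logd, ties.method = "first"))]
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(cnt * lse)
    if (!is.finite(ll)) return(NULL)
    r <- exp(logd - lse) * cnt
    nk <- colSums(r)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(r * v) / nk
    sigma <- sqrt(colSums(r * (outer(v, mu, "-"))^2) / nk)
    sigma <- pmax(sigma, sd_floor)
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(weights = w, means = mu, sds = sigma, loglik = ll,
       converged = converged, iter = iter)
}

# k-means++-style seeding over the distinct values: first center drawn
# by multiplicity, later centers with probability proportional to the
# squared distance to the nearest chosen center.
seed_centers <- function(v, cnt, k) {
  centers <- v[sample.int(length(v), 1, prob = cnt)]
  d2 <- (v - centers)^2
  while (length(centers) < k) {
    p <- d2 * cnt
    nc <- if (sum(p) <= 0) {
      v[sample.int(length(v), 1, prob = cnt)]
    } else {
      v[sample.int(length(v), 1, prob = p)]
    }
    centers <- c(centers, nc)
    d2 <- pmin(d2, (v - nc)^2)
  }
  centers
}

#' Fit a Gaussian mixture to active-condition eccentricities
#'
#' Fits univariate Gaussian mixtures by EM for each candidate number of
#' components, with `n_restarts` random initializations each
#' (k-means++-style mean seeding), and selects the order with minimum
#' BIC (`-2 loglik + (3k - 1) log n`). Component SDs are floored at
#' `sd_floor` to avoid singular spikes on repeated values. The GF
#' component is then identified with [identify_gf_component()].
#'
#' @param ecc Numeric vector of eccentricities (deg); by design this is
#'   active-condition data for one section.
#' @param section Section label carried in the result (`"A"` or `"C1"`).
#' @param k_range Candidate component counts.
#' @param seed Integer seed; the fit is deterministic given it.
#' @param n_restarts Random restarts per `k`.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param sd_floor Lower bound on component SDs (deg).
#' @param grid_deg Resolution (deg) of the value grid the likelihood is
#'   evaluated on: eccentricities are rounded to this grid and the EM
#'   runs on distinct values with multiplicities, which is exact for the
#'   gridded data and keeps large samples fast. Well below tracker
#'   precision at the default 0.01 deg; set to 0 to disable.
#' @return An object of class `gaze_mixture` with fields `k`, `weights`,
#'   `means`, `sds`, `loglik`, `bic` (chosen), `bic_by_k`, `gf_index`,
#'   `section`, `n`, `converged`.
#' @export
fit_mixture <- function(ecc, section = c("A", "C1"), k_range = 1:8,
                        seed = 1, n_restarts = 10, max_iter = 500,
                        tol = 1e-8, sd_floor = 0.1, grid_deg = 0.01) {
  section <- match.arg(section)
  ecc <- ecc[is.finite(ecc)]
  n <- length(ecc)
  if (n < 50 * max(k_range)) {
    stop(sprintf("need at least %d points to consider up to %d components",
                 50 * max(k_range), max(k_range)), call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  if (grid_deg > 0) {
    tab <- table(round(ecc / grid_deg))
    v <- as.numeric(names(tab)) * grid_deg
    cnt <- as.numeric(tab)
  } else {
    v <- sort(ecc)
    cnt <- rep(1, n)
  }

  sd_all <- stats::sd(ecc)
  bic_by_k <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  best <- NULL
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    # short runs from each seeding, then polish the best to convergence
    fit_k <- NULL
    for (r in seq_len(n_restarts)) {
      mu0 <- seed_centers(v, cnt, k)
      init <- em_gauss1d(v, cnt, w = rep(1 / k, k), mu = mu0,
                         sigma = rep(max(sd_all / sqrt(k), sd_floor), k),
                         max_iter = 30, tol = tol, sd_floor = sd_floor)
      if (is.null(init)) next
      if (is.null(fit_k) || init$loglik > fit_k$loglik) fit_k <- init
    }
    if (!is.null(fit_k)) {
      fit_k <- em_gauss1d(v, cnt, w = fit_k$weights, mu = fit_k$means,
                          sigma = fit_k$sds, max_iter = max_iter,
                          tol = tol, sd_floor = sd_floor)
    }
    if (is.null(fit_k)) {
      warning(sprintf("EM did not converge for k = %d; skipped", k),
              call. = FALSE)
      next
    }
    bic <- -2 * fit_k$loglik + (3 * k - 1) * log(n)
    bic_by_k[ki] <- bic
    if (is.null(best) || bic < best$bic) {
      best <- c(fit_k, list(k = k, bic = bic))
    }
  }
  if (is.null(best)) {
    stop("mixture fit failed for every candidate number of components",
         call. = FALSE)
  }
  ord <- order(best$means)
  model <- structure(
    list(k = best$k, weights = best$weights[ord], means = best$means[ord],
         sds = best$sds[ord], loglik = best$loglik, bic = best$bic,
         bic_by_k = bic_by_k, section = section, n = n,
         converged = best$converged, gf_index = NA_integer_),
    class = "gaze_mixture"
  )
  model$gf_index <- identify_gf_component(model)
  model
}

#' @export
print.gaze_mixture <- function(x, ...) {
  cat(sprintf("<gaze_mixture> section %s: k = %d (BIC %.1f, n = %d)\n",
              x$section, x$k, x$bic, x$n))
  for (j in seq_len(x$k)) {
    cat(sprintf("  %s comp %d: w = %.3f, mean = %6.2f deg, sd = %.2f deg\n",
                if (j == x$gf_index) "*" else " ", j, x$weights[j],
                x$means[j], x$sds[j]))
  }
  invisible(x)
}

#' Identify the guiding-fixation component
#'
#' The GF component is the central one: minimum `|mean|`, ties broken by
#' larger weight (the guiding mass dominates near eccentricity zero).
#'
#' @param model A `gaze_mixture`.
#' @return Integer index of the GF component.
#' @export
identify_gf_component <- function(model) {
  stopifnot(inherits(model, "gaze_mixture"))
  ord <- order(abs(model$means), -model$weights)
  ord[1]
}

#' Derive the GF/LAF threshold from a fitted mixture
#'
#' The threshold is the upper quantile of the GF component at the given
#' coverage: `t = mu_GF + z(coverage) * sd_GF`, so that `coverage` of
#' guiding fixations lie below it under the fitted Gaussian.
#'
#' @param model A `gaze_mixture` with `gf_index` set.
#' @param coverage One-sided coverage probability, in `(0.5, 1)`;
#'   default 0.9995.
#' @return Threshold in degrees.
#' @export
derive_threshold <- function(model, coverage = 0.9995) {
  stopifnot(inherits(model, "gaze_mixture"), !is.na(model$gf_index))
  if (coverage <= 0.5 || coverage >= 1) {
    stop("coverage must lie in (0.5, 1)", call. = FALSE)
  }
  g <- model$gf_index
  model$means[g] + stats::qnorm(coverage) * model$sds[g]
}

#' GF-component cumulative probability at a value
#'
#' @param model A `gaze_mixture`.
#' @param q Quantile (deg).
#' @return `P(GF component <= q)`.
#' @export
gf_component_cdf <- function(model, q) {
  g <- model$gf_index
  stats::pnorm(q, model$means[g], model$sds[g])
}

#' Label samples as GF-area or LAF-area
#'
#' A sample belongs to the LAF area iff its eccentricity strictly
#' exceeds the threshold; everything else, including negative
#' (opposite-side) eccentricities, is GF-area for polling purposes.
#'
#' @param ecc Eccentricities (deg).
#' @param t Threshold (deg, `> 0`).
#' @return Character vector in `{"GF", "LAF"}`.
#' @export
label_area <- function(ecc, t) {
  stopifnot(is.finite(t), t > 0)
  ifelse(ecc > t, "LAF", "GF")
}

#' Fit per-section thresholds from a gaze log with eccentricities
#'
#' Fits the mixture on active-condition eccentricities of each analysis
#' section and derives the per-section GF/LAF thresholds.
#'
#' @param ecc_log Output of [eccentricity_series()] (must contain `mode`,
#'   `section`, `ecc_deg`).
#' @param coverage Threshold coverage, see [derive_threshold()].
#' @param ... Passed to [fit_mixture()].
#' @return An object of class `threshold_set`: list with `t_A`, `t_C1`,
#'   `coverage`, and the fitted `models` per section.
#' @export
fit_thresholds <- function(ecc_log, coverage = 0.9995, ...) {
  stopifnot(all(c("mode", "section", "ecc_deg") %in% names(ecc_log)))
  active <- ecc_log[ecc_log$mode == "active", ]
  models <- lapply(stats::setNames(c("A", "C1"), c("A", "C1")),
                   function(sec) {
                     fit_mixture(active$ecc_deg[active$section == sec],
                                 section = sec, ...)
                   })
  structure(
    list(t_A = derive_threshold(models$A, coverage),
         t_C1 = derive_threshold(models$C1, coverage),
         coverage = coverage, models = models),
    class = "threshold_set"
  )
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(
    "<threshold_set> t_A = %.2f deg, t_C1 = %.2f deg (coverage %.4f%%)\n",
    x$t_A, x$t_C1, 100 * x$coverage))
  invisible(x)
}

#' Write a threshold set to JSON
#'
#' Per section: `k, weights, means, sds, bic, gf_index, t`.
#'
#' @param thresholds A `threshold_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(thresholds, path) {
  per_section <- function(sec, t) {
    m <- thresholds$models[[sec]]
    list(k = m$k, weights = m$weights, means = m$means, sds = m$sds,
         bic = m$bic, gf_index = m$gf_index, t = t)
  }
  jsonlite::write_json(
    list(coverage = thresholds$coverage,
         A = per_section("A", thresholds$t_A),
         C1 = per_section("C1", thresholds$t_C1)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
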