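#' Run the full gaze-polling analysis pipeline
#'
#' Chains the five analysis stages on a gaze log: empirical GF reference
#' ([estimate_gf_reference()]), eccentricities
#' ([eccentricity_series()]), per-section mixture thresholds on the
#' active condition ([fit_thresholds()]), segmentation
#' ([segment_traversals()]), polling events and strategies
#' ([analyze_polling()], [tally_strategies()]), and the distribution and
#' metric statistics ([bin_distributions()], [compare_distributions()],
#' [proportion_above_threshold()], [rm_anova_2x3()]).
#'
#' @param log Gaze-log tibble ([read_gaze_log()] / [simulate_gaze()]).
#' @param track A [track_spec()].
#' @param coverage Threshold coverage (see [derive_threshold()]).
#' @param k_range,mixture_seed,n_restarts Passed to [fit_mixture()].
#' @param noise_sd,split_penalty,sacc_speed,fix_speed Passed to the
#'   segmentation stage.
#' @param run_anova Whether to fit the 2x3 repeated-measures ANOVAs on
#'   the polling metrics (needs a full design with enough complete
#'   participants).
#' @return A list of stage results: `reference`, `ecc_log`,
#'   `thresholds`, `segments`, `events`, `outcomes`, `tallies`,
#'   `distributions`, `bin_tests`, `above_threshold`, `anovas`.
#' @export
run_gaze_analysis <- function(log, track, coverage = 0.9995,
                              k_range = 1:8, mixture_seed = 1,
                              n_restarts = 10, noise_sd = NULL,
                              split_penalty = 6, sacc_speed = 40,
                              fix_speed = 5, run_anova = TRUE) {
  if (!"traversal" %in% names(log)) log$traversal <- traversal_key(log)
  if (!"section" %in% names(log)) {
    log$section <- assign_section(log$s_m, track)
  }
  reference <- estimate_gf_reference(log, track)
  ecc_log <- eccentricity_series(log, reference)
  thresholds <- fit_thresholds(ecc_log, coverage = coverage,
                               k_range = k_range, seed = mixture_seed,
                               n_restarts = n_restarts)
  segments <- segment_traversals(ecc_log, noise_sd = noise_sd,
                                 split_penalty = split_penalty,
                                 sacc_speed = sacc_speed,
                                 fix_speed = fix_speed)
  polling <- analyze_polling(ecc_log, segments, thresholds, track)
  tallies <- tally_strategies(polling$outcomes)
  dists <- bin_distributions(ecc_log)
  bin_tests <- if (length(unique(ecc_log$mode)) == 2 &&
                     length(unique(ecc_log$participant_id)) >= 3) {
    compare_distributions(dists)
  }
  above <- proportion_above_threshold(ecc_log, thresholds)
  anovas <- NULL
  if (run_anova) {
    anovas <- list()
    for (sec in c("A", "C1")) {
      for (metric in c("frequency_hz", "mean_laf_s", "cumulative_pct")) {
        oc <- polling$outcomes[polling$outcomes$section == sec, ]
        dd <- data.frame(participant_id = oc$participant_id,
                         mode = oc$mode, speed_kmh = oc$speed_kmh,
                         value = oc[[metric]])
        res <- tryCatch(rm_anova_2x3(dd), error = function(e) NULL)
        if (!is.null(res)) {
          res$section <- sec
          res$metric <- metric
          anovas[[paste(sec, metric, sep = ".")]] <- res
        }
      }
    }
    anovas <- if (length(anovas)) do.call(rbind, anovas)
  }
  list(reference = reference, ecc_log = ecc_log, thresholds = thresholds,
       segments = segments, events = polling$events,
       outcomes = polling$outcomes, tallies = tallies,
       distributions = dists, bin_tests = bin_tests,
       above_threshold = above, anovas = anovas)
}

#' Assemble a machine-readable report bundle
#'
#' Writes the pipeline's result surfaces to a directory: the reference
#' curve and per-bend outcomes as CSV, the distribution curves, per-bin
#' test flags, strategy tallies, metric ANOVAs, thresholds and a
#' provenance block (package version, seed, parameters) as JSON. Output
#' contains no timestamps, so a rerun with the same inputs is
#' byte-identical.
#'
#' @param results Output of [run_gaze_analysis()].
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the provenance block.
#' @param config Optional list echoed into the provenance block.
#' @return Invisibly, the paths written.
#' @export
build_report <- function(results, dir, seed = NA, config = list()) {
  needed <- c("reference", "thresholds", "outcomes", "tallies",
              "distributions")
  for (nm in needed) {
    if (is.null(results[[nm]])) {
      stop("missing upstream artifact: ", nm, call. = FALSE)
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(as.data.frame(df), p, row.names = FALSE,
                     quote = FALSE)
    paths <<- c(paths, p)
  }
  write_gf_reference(results$reference, file.path(dir, "reference.csv"))
  paths <- c(paths, file.path(dir, "reference.csv"))
  w(results$distributions, "distributions.csv")
  if (!is.null(results$bin_tests)) w(results$bin_tests, "bin_tests.csv")
  w(results$outcomes, "outcomes.csv")
  w(results$events, "events.csv")
  w(results$tallies$counts, "strategy_tallies.csv")
  if (!is.null(results$anovas)) w(results$anovas, "anova.csv")
  write_thresholds(results$thresholds, file.path(dir, "thresholds.json"))
  paths <- c(paths, file.path(dir, "thresholds.json"))

  summary_path <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(
      provenance = list(
        package = "gazepoll",
        version = as.character(utils::packageVersion("gazepoll")),
        seed = seed, config = config),
      thresholds = list(t_A = results$thresholds$t_A,
                        t_C1 = results$thresholds$t_C1,
                        coverage = results$thresholds$coverage),
      strategy_totals = as.list(results$tallies$totals),
      n_events = nrow(results$events),
      n_bends = length(unique(results$outcomes$traversal))
    ),
    summary_path, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, summary_path)
  invisible(paths)
}
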