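#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end analysis in one
#' object: the pool/simulation settings, smoothing hyperparameters,
#' pairing criteria (defaults are the standard printed values 0.7 / 1 s /
#' 0.5 pps), the ramp QC threshold (5 \% of peak torque), the responses
#' to contrast and the seed.
#'
#' @param pool A [pool_config()].
#' @param svr An [svr_control()].
#' @param criteria A [pairing_criteria()].
#' @param qc_threshold Ramp QC deviation threshold (\% of peak torque).
#' @param min_firings Minimum discharges per analysed unit.
#' @param responses Outcome columns to contrast.
#' @param seed Seed for the simulation stage (overrides `pool$seed`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(pool = pool_config(), svr = svr_control(),
                            criteria = pairing_criteria(), qc_threshold = 5,
                            min_firings = 4, responses = "delta_f",
                            seed = pool$seed) {
  stopifnot(qc_threshold >= 0, min_firings >= 2)
  pool$seed <- seed
  structure(list(pool = pool, svr = svr, criteria = criteria,
                 qc_threshold = qc_threshold, min_firings = min_firings,
                 responses = responses, seed = seed),
            class = "pipeline_config")
}

#' Run the full pipeline: simulate, analyse, contrast
#'
#' One-command end-to-end demonstration on simulated data: generates a
#' study from the pool configuration, runs the per-unit analysis
#' (filtering, QC, smoothing, pairing, delta F, geometry, thresholds) and
#' fits the before/after mixed-model contrasts for each requested
#' response. Deterministic given the seed.
#'
#' @param cfg A [pipeline_config()].
#' @return List of class `pipeline_result`: `outcomes` (per-unit table),
#'   `contrasts` (named list of [fit_contrasts()] tables), `accounting`
#'   (exclusion counts), `ground_truth`, `config`.
#' @export
run_end_to_end <- function(cfg = pipeline_config()) {
  study <- simulate_study(cfg$pool)
  outcomes <- analyze_study(study, criteria = cfg$criteria, svr = cfg$svr,
                            qc_threshold = cfg$qc_threshold,
                            min_firings = cfg$min_firings)
  if (!nrow(outcomes)) {
    stop("pipeline stage 'analyze': no trial survived quality control",
         call. = FALSE)
  }
  present <- unique(outcomes$condition[!is.na(outcomes$delta_f)])
  if (!all(pic_conditions() %in% unique(outcomes$condition))) {
    stop(sprintf("pipeline stage 'analyze': condition(s) %s have no analysable trials",
                 paste(setdiff(pic_conditions(), unique(outcomes$condition)),
                       collapse = ", ")), call. = FALSE)
  }
  contrasts <- lapply(cfg$responses, function(resp) {
    fit_contrasts(outcomes, model_spec(resp))
  })
  names(contrasts) <- cfg$responses
  structure(list(outcomes = outcomes, contrasts = contrasts,
                 accounting = attr(outcomes, "accounting"),
                 ground_truth = study$ground_truth, config = cfg),
            class = "pipeline_result")
}

#' @method print pipeline_result
#' @export
print.pipeline_result <- function(x, ...) {
  acc <- x$accounting
  cat("<pipeline_result>\n")
  cat(sprintf("  units: %d loaded, %d analysed, %d short-train\n",
              acc["units_loaded"], acc["units_analysed"],
              acc["units_short_train"]))
  cat(sprintf("  trials failing QC: %d\n", acc["trial_qc_failed"]))
  for (nm in names(x$contrasts)) {
    cat(sprintf("  %s after-before contrasts:\n", nm))
    print(as.data.frame(x$contrasts[[nm]][, c("condition", "after_minus_before",
                                              "ci95_lo", "ci95_hi", "cohens_d")]),
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}
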