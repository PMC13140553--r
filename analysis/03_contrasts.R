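#!/usr/bin/env Rscript

# Stage 3: mixed-effects before/after contrasts per condition.
#
# For each motor-unit outcome, fit the study's linear mixed-effects model
# (phase, condition, their interaction; response-specific covariates;
# participant and unit random intercepts), report the after-minus-before
# estimated marginal mean difference with 90%/95% CIs and Cohen's d, then
# compare the four candidate covariate structures for delta F by AIC/BIC
# and rerun delta F on the complete-case participant subset.

suppressMessages({
  library(picmetrics)
  library(dplyr)
})

outcomes <- read_outcomes("results/outcomes.csv")
responses <- c("delta_f", "brace_height", "attenuation_slope",
               "peak_discharge_rate", "recruitment_threshold",
               "derecruitment_threshold")

all_ctr <- lapply(responses, function(resp) {
  ctr <- suppressWarnings(fit_contrasts(outcomes, model_spec(resp)))
  ctr$response <- resp
  ctr$sigma <- attr(ctr, "sigma")
  ctr
}) |> bind_rows()

readr::write_csv(all_ctr, "results/contrasts.csv")
cat("after - before marginal differences (95% CI):\n")
for (i in seq_len(nrow(all_ctr))) {
  cat(sprintf("  %-24s %-8s %+.3f (%+.3f, %+.3f)  d = %+.2f\n",
              all_ctr$response[i], all_ctr$condition[i],
              all_ctr$after_minus_before[i], all_ctr$ci95_lo[i],
              all_ctr$ci95_hi[i], all_ctr$cohens_d[i]))
}

cmp <- suppressWarnings(compare_covariate_models(outcomes))
readr::write_csv(cmp, "results/model_comparison.csv")
cat("\ndelta F covariate-model comparison (ML):\n")
print(as.data.frame(cmp), row.names = FALSE, digits = 6)

cc <- complete_case_subset(outcomes)
ctr_cc <- suppressWarnings(fit_contrasts(cc, model_spec("delta_f")))
readr::write_csv(ctr_cc, "results/contrasts_complete_cases.csv")
cat(sprintf("\ncomplete-case sensitivity (n = %d participants): delta F contrasts\n",
            length(unique(cc$participant_id))))
print(as.data.frame(ctr_cc[, c("condition", "after_minus_before",
                               "ci95_lo", "ci95_hi")]),
      row.names = FALSE, digits = 3)
cat("\nwrote results/contrasts.csv, results/model_comparison.csv,",
    "results/contrasts_complete_cases.csv\n")
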