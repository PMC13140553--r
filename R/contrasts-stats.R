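#' Specify a mixed-effects model for one motor-unit outcome
#'
#' Fixed effects are phase (before/after), condition and their
#' interaction, plus optional covariates and extra fixed effects. Random
#' effects are an intercept per participant and an intercept per unit
#' nested in participant (and condition, since units are only tracked
#' within a condition), optionally with a per-participant random slope
#' for phase.
#'
#' Default covariates follow the study conventions: delta F adjusts for
#' both peak discharge rate and recruitment threshold (the best-fitting
#' of the four candidate covariate structures); peak discharge rate,
#' brace height and attenuation slope adjust for recruitment threshold;
#' the threshold outcomes take no covariate.
#'
#' @param response One of the outcome columns (`delta_f`, `brace_height`,
#'   `attenuation_slope`, `peak_discharge_rate`, `recruitment_threshold`,
#'   `derecruitment_threshold`).
#' @param covariates Character vector of covariate columns (`NULL` =
#'   response-specific default).
#' @param random_slope_time Add a per-participant random slope for phase.
#' @param extra_fixed Optional extra fixed-effect column names (e.g. sex).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(response,
                       covariates = NULL,
                       random_slope_time = FALSE,
                       extra_fixed = NULL) {
  response <- match.arg(response, setdiff(outcome_columns(),
                                          c("unit_id", "participant_id",
                                            "condition", "phase",
                                            "n_control_units")))
  if (is.null(covariates)) {
    covariates <- switch(response,
      delta_f = c("peak_discharge_rate", "recruitment_threshold"),
      brace_height = ,
      attenuation_slope = ,
      peak_discharge_rate = "recruitment_threshold",
      character(0))
  }
  covariates <- setdiff(covariates, response)
  structure(list(response = response, covariates = covariates,
                 random_slope_time = random_slope_time,
                 extra_fixed = extra_fixed), class = "model_spec")
}

spec_formula <- function(spec, unit_intercept = TRUE) {
  fixed <- c("phase * condition", spec$covariates, spec$extra_fixed)
  rand <- if (spec$random_slope_time) "(phase | participant_id)"
          else "(1 | participant_id)"
  if (unit_intercept) rand <- c(rand, "(1 | unit_key)")
  stats::as.formula(paste(spec$response, "~",
                          paste(c(fixed, rand), collapse = " + ")))
}

prepare_model_data <- function(rows, spec) {
  need <- c(spec$response, spec$covariates, spec$extra_fixed)
  dat <- rows[stats::complete.cases(rows[, need, drop = FALSE]), , drop = FALSE]
  dat$condition <- factor(dat$condition,
                          levels = intersect(pic_conditions(), dat$condition))
  dat$phase <- factor(dat$phase, levels = pic_phases())
  dat$unit_key <- interaction(dat$participant_id, dat$condition, dat$unit_id,
                              drop = TRUE)
  if (length(unique(dat$participant_id)) < 2) {
    stop("need at least 2 participants to fit the mixed model", call. = FALSE)
  }
  both <- tapply(as.character(dat$phase), as.character(dat$condition),
                 function(p) all(pic_phases() %in% p))
  if (!all(unlist(both))) {
    stop("every condition must contain both phases", call. = FALSE)
  }
  dat
}

fit_lmer_checked <- function(spec, dat, reml = TRUE, weights = NULL) {
  quiet_lmer <- function(unit_intercept, optimizer = NULL) {
    ctl <- if (is.null(optimizer)) lme4::lmerControl()
           else lme4::lmerControl(optimizer = optimizer)
    tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(spec_formula(spec, unit_intercept = unit_intercept),
                   data = dat, REML = reml, weights = weights, control = ctl))),
      error = function(e) e)
  }
  failed <- function(f) {
    if (inherits(f, "error")) return(TRUE)
    conv <- f@optinfo$conv$lme4
    !is.null(conv$code) && conv$code < 0
  }
  fit <- quiet_lmer(TRUE)
  if (failed(fit)) fit <- quiet_lmer(TRUE, optimizer = "bobyqa")
  if (inherits(fit, "error") ||
      (!failed(fit) && lme4::isSingular(fit, tol = 1e-4))) {
    warning("singular or failed fit with unit-level intercept; refitting without it",
            call. = FALSE)
    fit <- quiet_lmer(FALSE)
    if (failed(fit)) fit <- quiet_lmer(FALSE, optimizer = "bobyqa")
  }
  if (failed(fit)) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit)
           else paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; ")
    stop(sprintf("mixed model failed to converge: %s", msg), call. = FALSE)
  }
  fit
}

model_sigma <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  sqrt(sum(vc$vcov[is.na(vc$var2)]))  # variances only, not covariances
}

#' Before/after condition contrasts from a linear mixed-effects model
#'
#' Fits the specified model by REML (lme4), evaluates estimated marginal
#' means per phase x condition at the covariates' grand means, and
#' reports the after-minus-before marginal difference per condition with
#' Wald 95\% and 90\% confidence intervals and a standardised effect size
#' Cohen's d = difference / sigma, where sigma is the model-estimated
#' population SD (square root of the summed random-effect and residual
#' variances).
#'
#' A singular unit-level intercept triggers a refit without it (with a
#' warning); non-convergence is a fatal error. With `robust = TRUE` the
#' model is refit by iteratively-reweighted least squares with Huber
#' weights on the scaled residuals, down-weighting outlying observations.
#'
#' @param rows Per-unit outcome table ([analyze_study()] output or
#'   compatible).
#' @param spec A [model_spec()].
#' @param robust Use the Huber-weighted refit.
#' @param huber_k Huber tuning constant (default 1.345).
#' @param iterations IRLS iterations when `robust = TRUE`.
#' @return Tibble with one row per condition: `condition`,
#'   `after_minus_before`, `se`, `ci95_lo/hi`, `ci90_lo/hi`, `cohens_d`.
#'   Attributes: `"sigma"`, `"aic"`, `"bic"`, `"beta_interaction"`
#'   (interaction coefficients with SE and t), `"fit"`.
#' @export
fit_contrasts <- function(rows, spec, robust = FALSE, huber_k = 1.345,
                          iterations = 4) {
  dat <- prepare_model_data(rows, spec)
  fit <- fit_lmer_checked(spec, dat, reml = TRUE)
  if (robust) {
    for (it in seq_len(iterations)) {
      r <- residuals(fit)
      s <- mad(r, center = 0)
      if (s <= 0) break
      dat$.w <- pmin(1, huber_k / abs(r / s))
      fit <- fit_lmer_checked(spec, dat, reml = TRUE, weights = dat$.w)
    }
  }
  emm <- emmeans::emmeans(fit, ~ phase | condition, data = dat,
                          lmer.df = "asymptotic")
  ctr <- emmeans::contrast(emm, "revpairwise", by = "condition")
  ci95 <- as.data.frame(confint(ctr, level = 0.95))
  ci90 <- as.data.frame(confint(ctr, level = 0.90))
  sigma_pop <- model_sigma(fit)
  out <- tibble::tibble(
    condition = as.character(ci95$condition),
    after_minus_before = ci95$estimate,
    se = ci95$SE,
    ci95_lo = ci95$asymp.LCL, ci95_hi = ci95$asymp.UCL,
    ci90_lo = ci90$asymp.LCL, ci90_hi = ci90$asymp.UCL,
    cohens_d = ci95$estimate / sigma_pop)
  cf <- as.data.frame(summary(fit)$coefficients)
  inter <- cf[grepl("^phase.*:condition", rownames(cf)), , drop = FALSE]
  attr(out, "sigma") <- sigma_pop
  attr(out, "aic") <- AIC(fit)
  attr(out, "bic") <- BIC(fit)
  attr(out, "beta_interaction") <- inter
  attr(out, "fit") <- fit
  out
}

#' Compare candidate covariate structures by AIC/BIC
#'
#' Fits the four standard candidate models for delta F (no covariate,
#' peak discharge rate, recruitment threshold, both) - or any supplied
#' list of specs - by maximum likelihood (not REML, so likelihoods are
#' comparable across fixed-effect structures) and tabulates AIC and BIC.
#' Non-convergent specs are dropped with a warning.
#'
#' @param rows Per-unit outcome table.
#' @param specs Named list of [model_spec()]s; default the four delta F
#'   candidates.
#' @return Tibble: `model`, `aic`, `bic`, `best_aic`, `best_bic`.
#' @export
compare_covariate_models <- function(rows, specs = NULL) {
  if (is.null(specs)) {
    specs <- list(
      model1 = model_spec("delta_f", covariates = character(0)),
      model2 = model_spec("delta_f", covariates = "peak_discharge_rate"),
      model3 = model_spec("delta_f", covariates = "recruitment_threshold"),
      model4 = model_spec("delta_f", covariates = c("peak_discharge_rate",
                                                    "recruitment_threshold")))
  }
  res <- lapply(names(specs), function(nm) {
    f <- tryCatch({
      dat <- prepare_model_data(rows, specs[[nm]])
      fit_lmer_checked(specs[[nm]], dat, reml = FALSE)
    }, error = function(e) {
      warning(sprintf("model '%s' failed: %s", nm, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(f)) return(NULL)
    tibble::tibble(model = nm, aic = AIC(f), bic = BIC(f))
  })
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) stop("no candidate model converged", call. = FALSE)
  out$best_aic <- out$aic == min(out$aic)
  out$best_bic <- out$bic == min(out$bic)
  out
}

#' Restrict to participants observed in all four conditions
#'
#' Sensitivity-analysis subset: keeps only participants contributing both
#' phases of every condition.
#'
#' @param rows Per-unit outcome table.
#' @return The filtered tibble.
#' @export
complete_case_subset <- function(rows) {
  cells <- unique(rows[, c("participant_id", "condition", "phase")])
  n_cells <- tapply(paste(cells$condition, cells$phase), cells$participant_id,
                    function(x) length(unique(x)))
  complete <- names(n_cells)[n_cells == length(pic_conditions()) * 2L]
  out <- rows[rows$participant_id %in% complete, , drop = FALSE]
  if (!nrow(out)) stop("no participant completed all four conditions", call. = FALSE)
  out
}

#' Import an externally deposited per-unit results table
#'
#' Column-mapping adapter for re-analysing a deposited per-unit dataset
#' with [fit_contrasts()]: reads a delimited file, renames columns to the
#' package's canonical names and recodes condition/phase labels.
#'
#' @param path Delimited text file.
#' @param mapping Named character vector: names are canonical column
#'   names ([outcome_columns()]), values the file's column names. Columns
#'   not mapped and absent from the file are filled with `NA`.
#' @param condition_labels,phase_labels Named character vectors recoding
#'   the file's condition/phase values to the canonical labels (names =
#'   file values).
#' @return Tibble with the canonical outcome columns.
#' @export
read_deposited_table <- function(path, mapping = NULL,
                                 condition_labels = NULL,
                                 phase_labels = NULL) {
  if (!file.exists(path)) stop(sprintf("missing file: %s", path), call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out <- tibble::tibble(.rows = nrow(raw))
  for (col in outcome_columns()) {
    src <- if (!is.null(mapping) && col %in% names(mapping)) mapping[[col]] else col
    out[[col]] <- if (src %in% names(raw)) raw[[src]] else NA
  }
  out$unit_id <- as.character(out$unit_id)
  out$participant_id <- as.character(out$participant_id)
  if (!is.null(condition_labels)) {
    out$condition <- unname(condition_labels[as.character(out$condition)])
  }
  if (!is.null(phase_labels)) {
    out$phase <- unname(phase_labels[as.character(out$phase)])
  }
  bad <- setdiff(unique(out$condition), pic_conditions())
  if (length(bad)) {
    stop(sprintf("unrecognised condition label(s): %s (use condition_labels)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out
}
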