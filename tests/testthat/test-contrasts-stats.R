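test_that("balanced-design contrasts equal raw participant-mean differences", {
  set.seed(21)
  rows <- simulate_outcome_table(n_participants = 8, units_per_participant = 6,
                                 effects = c("Control" = 0, "40%15s" = 0.2,
                                             "40%30s" = 0.5, "80%15s" = -0.3))
  ctr <- fit_contrasts(rows, model_spec("delta_f", covariates = character(0)))
  raw <- sapply(pic_conditions(), function(cond) {
    sub <- rows[rows$condition == cond, ]
    pm <- tapply(sub$delta_f, list(sub$participant_id, sub$phase), mean)
    mean(pm[, "after"] - pm[, "before"])
  })
  expect_equal(ctr$after_minus_before,
               unname(raw[ctr$condition]), tolerance = 1e-6)
  # Cohen's d carries the sign of the difference
  expect_true(all(sign(ctr$cohens_d) == sign(ctr$after_minus_before)))
  # 90% CI nested inside the 95% CI
  expect_true(all(ctr$ci90_lo >= ctr$ci95_lo & ctr$ci90_hi <= ctr$ci95_hi))
})

test_that("adding a constant to one condition's after rows shifts only its contrast", {
  set.seed(31)
  rows <- simulate_outcome_table(n_participants = 8, units_per_participant = 6)
  spec <- model_spec("delta_f", covariates = character(0))
  base <- fit_contrasts(rows, spec)
  shifted <- rows
  sel <- shifted$condition == "40%30s" & shifted$phase == "after"
  shifted$delta_f[sel] <- shifted$delta_f[sel] + 0.8
  got <- fit_contrasts(shifted, spec)
  delta <- got$after_minus_before - base$after_minus_before
  expect_equal(delta[got$condition == "40%30s"], 0.8, tolerance = 1e-6)
  expect_equal(delta[got$condition != "40%30s"], rep(0, 3), tolerance = 1e-6)
})

test_that("sigma for Cohen's d pools all variance components", {
  set.seed(41)
  rows <- simulate_outcome_table(n_participants = 10, units_per_participant = 6,
                                 participant_sd = 0.5, unit_sd = 0.4,
                                 resid_sd = 0.5)
  ctr <- fit_contrasts(rows, model_spec("delta_f", covariates = character(0)))
  sig <- attr(ctr, "sigma")
  truth <- sqrt(0.5^2 + 0.4^2 + 0.5^2)
  expect_equal(sig, truth, tolerance = 0.15)
  expect_equal(ctr$cohens_d, ctr$after_minus_before / sig)
})

test_that("model comparison prefers covariate models when a covariate effect exists", {
  set.seed(51)
  rows <- simulate_outcome_table(n_participants = 10, units_per_participant = 6,
                                 covariate_effect = 0.4)
  tab <- compare_covariate_models(rows)
  expect_setequal(tab$model, paste0("model", 1:4))
  # models with the recruitment-threshold covariate dominate those without
  expect_lt(tab$aic[tab$model == "model3"], tab$aic[tab$model == "model1"])
  expect_lt(tab$aic[tab$model == "model4"], tab$aic[tab$model == "model2"])
  expect_true(tab$model[which.min(tab$aic)] %in% c("model3", "model4"))

  # duplicate specs give identical criteria
  dup <- compare_covariate_models(rows, specs = list(
    a = model_spec("delta_f"), b = model_spec("delta_f")))
  expect_equal(dup$aic[1], dup$aic[2])
  expect_equal(dup$bic[1], dup$bic[2])
})

test_that("BIC prefers the smaller model under a null covariate effect", {
  wins <- 0L
  for (s in 1:20) {
    set.seed(600 + s)
    rows <- simulate_outcome_table(n_participants = 8,
                                   units_per_participant = 4,
                                   covariate_effect = 0)
    tab <- suppressWarnings(compare_covariate_models(rows, specs = list(
      small = model_spec("delta_f", covariates = character(0)),
      big = model_spec("delta_f"))))
    if (nrow(tab) == 2 && tab$bic[tab$model == "small"] <
          tab$bic[tab$model == "big"]) wins <- wins + 1L
  }
  expect_gte(wins, 16L)  # >= 80% of replicates
})

test_that("complete-case subsetting keeps only fully-observed participants", {
  rows <- toy_outcomes(n_participants = 5, units = 2)
  expect_equal(complete_case_subset(rows), rows)  # all complete: identity
  drop1 <- rows[!(rows$participant_id == "P01" & rows$condition == "40%30s"), ]
  sub <- complete_case_subset(drop1)
  expect_false("P01" %in% sub$participant_id)
  expect_setequal(unique(sub$participant_id), sprintf("P%02d", 2:5))
  none <- rows[rows$condition == "Control", ]
  expect_error(complete_case_subset(none), "no participant")
})

test_that("the deposited-table adapter remaps columns and labels", {
  rows <- toy_outcomes(n_participants = 4, units = 3)
  alien <- data.frame(
    MU = rows$unit_id, ID = rows$participant_id,
    Cond = c("CON" = "CON", "40%15s" = "G4015", "40%30s" = "G4030",
             "80%15s" = "G8015", "Control" = "CON")[rows$condition],
    Time = ifelse(rows$phase == "before", "pre", "post"),
    DF = rows$delta_f, PDR = rows$peak_discharge_rate,
    RT = rows$recruitment_threshold)
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(alien, f)
  got <- read_deposited_table(
    f,
    mapping = c(unit_id = "MU", participant_id = "ID", condition = "Cond",
                phase = "Time", delta_f = "DF", peak_discharge_rate = "PDR",
                recruitment_threshold = "RT"),
    condition_labels = c(CON = "Control", G4015 = "40%15s", G4030 = "40%30s",
                         G8015 = "80%15s"),
    phase_labels = c(pre = "before", post = "after"))
  expect_equal(got$delta_f, rows$delta_f)
  expect_setequal(unique(got$condition), pic_conditions())
  # and it feeds straight into the contrast stage
  ctr <- suppressWarnings(fit_contrasts(got, model_spec("delta_f")))
  expect_equal(nrow(ctr), 4)

  bad <- read_deposited_table  # unmapped labels are fatal
  expect_error(bad(f, mapping = c(condition = "Cond")), "condition label")
})

test_that("the Huber-weighted refit resists outlier contamination", {
  set.seed(61)
  rows <- simulate_outcome_table(n_participants = 8, units_per_participant = 6)
  spec <- model_spec("delta_f", covariates = character(0))
  clean <- fit_contrasts(rows, spec)
  dirty <- rows
  sel <- which(dirty$condition == "Control" & dirty$phase == "after")[1:3]
  dirty$delta_f[sel] <- dirty$delta_f[sel] + 25
  plain <- suppressWarnings(fit_contrasts(dirty, spec))
  rob <- suppressWarnings(fit_contrasts(dirty, spec, robust = TRUE))
  ctrl <- function(x) x$after_minus_before[x$condition == "Control"]
  expect_lt(abs(ctrl(rob) - ctrl(clean)), abs(ctrl(plain) - ctrl(clean)))
})
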