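# Shared small fixtures, built once per test run.

fix_env <- function() {
  if (is.null(.fixtures$env))
    .fixtures$env <- generate_environment(
      42, c(14, 20), years_feb = 2009:2010, years_oct = 2011:2012)
  .fixtures$env
}

fix_truth <- function() {
  if (is.null(.fixtures$truth))
    .fixtures$truth <- truth_spec(years_feb = 2009:2010,
                                  years_oct = 2011:2012)
  .fixtures$truth
}

fix_tables <- function() {
  if (is.null(.fixtures$tables)) {
    env <- fix_env()
    truth <- fix_truth()
    hauls <- rbind(
      generate_hauls(env, c(SWC_IBTS = 30, NIGFS = 25), 2009:2010,
                     "FEB_MAR", seed = 43),
      generate_hauls(env, c(SWC_IBTS = 30, NIGFS = 25), 2011:2012,
                     "OCT_NOV", seed = 44))
    smalks <- generate_smalks(truth, 150, seed = 45)
    catches <- generate_catches(env, hauls, truth, seed = 46)
    .fixtures$tables <- survey_tables(hauls, catches, smalks)
  }
  .fixtures$tables
}

fix_stage_models <- function() {
  if (is.null(.fixtures$stage_models)) {
    tabs <- fix_tables()
    models <- list()
    for (st in stage_levels())
      for (sv in survey_levels())
        models[[paste(st, sv, sep = ".")]] <-
          suppressWarnings(fit_stage_model(tabs$smalks, st, sv))
    .fixtures$stage_models <- models
  }
  .fixtures$stage_models
}

# logistic SMALK-like records with controllable effect structure; sex/year
# effects can be switched off to test elimination of null terms
simulate_stage_records <- function(n, seed, sex_effect = 0, year_effect = 0,
                                   region_effect = 2, slope = -0.6,
                                   l50_base = 20, regions = c("N-M", "S-M"),
                                   years = 2009:2010) {
  withr::with_seed(seed, {
    region <- sample(regions, n, replace = TRUE)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    year <- sample(years, n, replace = TRUE)
    length <- pmax(runif(n, 5, 40), 1)
    l50 <- l50_base +
      region_effect * (match(region, regions) - 1) /
      max(length(regions) - 1, 1) +
      sex_effect * (sex == "F") + year_effect * (year == max(years))
    p <- plogis(slope * (length - l50))
    tibble::tibble(length = length, sex = sex,
                   age = ifelse(runif(n) < p, 0L, 1L),
                   mature = FALSE, region = region, year = year,
                   survey = "SWC_IBTS", season = "OCT_NOV")
  })
}

# glm with exactly known coefficients: weighted fit on exact logistic
# probabilities makes the MLE equal the generating parameters
exact_stage_model <- function(alpha, beta) {
  lengths <- seq(0, 60, by = 0.5)
  df <- data.frame(length = lengths, .y = plogis(alpha + beta * lengths),
                   w = 1000)
  fit <- suppressWarnings(glm(.y ~ length, family = binomial(), data = df,
                              weights = w))
  structure(list(stage = "AGE0", survey = "SWC_IBTS", fit = fit,
                 terms = "length", candidate_terms = "length",
                 alpha = 0.05, n = nrow(df),
                 elimination = tibble::tibble(),
                 dropped_levels = character(0), separation = FALSE),
            class = "stage_model")
}
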