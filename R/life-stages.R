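#' Standardise a tow count to 30 minutes
#'
#' Counts are scaled to a 30-minute tow and rounded down to the nearest
#' whole fish.
#'
#' @param count Raw count(s), >= 0.
#' @param duration Tow duration(s) in minutes, > 0.
#' @return Integer standardised count(s).
#' @export
standardise_cpue <- function(count, duration) {
  if (any(!is.finite(duration) | duration <= 0))
    stop("duration must be positive")
  if (any(count < 0, na.rm = TRUE)) stop("count must be non-negative")
  as.integer(floor(count * 30 / duration))
}

#' Candidate model terms for each life-stage logistic model
#'
#' Each survey x stage combination has its own candidate structure: the four
#' main effects plus the survey-specific set of pairwise interactions from
#' which backward elimination starts.
#'
#' @param stage `"AGE0"`, `"AGE1"` or `"MATURE"`.
#' @param survey `"SWC_IBTS"` or `"NIGFS"`.
#' @return Character vector of model terms.
#' @export
stage_candidate_terms <- function(stage, survey) {
  main <- c("sex", "region", "length", "year")
  key <- paste(stage, survey, sep = ".")
  inter <- switch(
    key,
    AGE0.SWC_IBTS = c("length:region", "length:year", "sex:year"),
    AGE0.NIGFS = c("length:region", "length:year", "sex:region",
                   "region:year"),
    AGE1.SWC_IBTS = c("length:region", "length:year", "region:year"),
    AGE1.NIGFS = c("length:year", "region:year", "sex:year"),
    MATURE.SWC_IBTS = c("length:sex", "region:year", "region:sex"),
    MATURE.NIGFS = c("length:year", "region:year", "sex:year", "sex:length"),
    stop("unknown stage/survey combination: ", key))
  c(main, inter)
}

stage_outcome <- function(smalks, stage) {
  switch(stage,
         AGE0 = list(data = smalks, y = smalks$age == 0),
         AGE1 = list(data = smalks, y = smalks$age == 1),
         MATURE = {
           keep <- smalks$age >= 1
           list(data = smalks[keep, , drop = FALSE],
                y = smalks$mature[keep])
         },
         stop("unknown stage: ", stage))
}

#' Fit a life-stage membership logistic model
#'
#' Maximum-likelihood logistic fit of stage membership probability against
#' length, sex, region and year starting from the survey-specific candidate
#' structure, followed by backward elimination: the removable term (never a
#' main effect still contained in a retained interaction) with the largest
#' likelihood-ratio-test p-value above `alpha` is dropped and the model
#' refitted until every removable term is significant. The mature-stage
#' training set is all fish of age >= 1 with the maturity flag as outcome;
#' age-0 uses autumn records and age-1/mature spring records when a
#' `season` column is present.
#'
#' @param smalks SMALK tibble.
#' @param stage Stage code.
#' @param survey Survey code.
#' @param candidate_terms Candidate terms; default
#'   [stage_candidate_terms()].
#' @param alpha LRT retention level (default 0.05).
#' @return A `stage_model` object.
#' @export
fit_stage_model <- function(smalks, stage, survey, candidate_terms = NULL,
                            alpha = 0.05) {
  stage <- match.arg(stage, stage_levels())
  survey <- match.arg(survey, survey_levels())
  if (is.null(candidate_terms))
    candidate_terms <- stage_candidate_terms(stage, survey)
  df <- dplyr::filter(tibble::as_tibble(smalks), .data$survey == !!survey)
  if ("season" %in% names(df))
    df <- dplyr::filter(df, .data$season == season_for_stage(stage))
  out <- stage_outcome(df, stage)
  df <- out$data
  df$.y <- out$y
  if (length(unique(df$.y)) < 2)
    stop("need both outcome classes to fit a stage model")
  df$sex <- factor(df$sex, levels = c("F", "M"))
  df$region <- factor(df$region)
  df$year <- factor(df$year)
  dropped_levels <- character(0)
  for (v in c("sex", "region", "year")) {
    empty <- levels(df[[v]])[table(df[[v]]) == 0]
    if (length(empty)) {
      dropped_levels <- c(dropped_levels, paste0(v, ":", empty))
      df[[v]] <- droplevels(df[[v]])
      warning("dropping empty ", v, " level(s): ",
              paste(empty, collapse = ", "))
    }
  }
  terms <- candidate_terms
  terms <- terms[!vapply(strsplit(terms, ":"), function(p)
    any(vapply(p, function(v) v %in% c("sex", "region", "year") &&
                 nlevels(df[[v]]) < 2, logical(1))), logical(1))]
  elimination <- list()
  fit <- glm(as.formula(paste(".y ~", paste(terms, collapse = " + "))),
             family = binomial(), data = df)
  repeat {
    d1 <- drop1(fit, test = "LRT")
    d1 <- d1[-1, , drop = FALSE] # remove the <none> row
    p <- d1[["Pr(>Chi)"]]
    removable <- which(!is.na(p) & p > alpha)
    if (!length(removable)) break
    worst <- removable[which.max(p[removable])]
    drop_term <- rownames(d1)[worst]
    elimination[[length(elimination) + 1]] <-
      tibble::tibble(term = drop_term, lrt_p = p[worst])
    # match order-insensitively: drop1 canonicalises interaction order
    key <- function(tm) vapply(strsplit(tm, ":"), function(p)
      paste(sort(p), collapse = ":"), character(1))
    terms <- terms[key(terms) != key(drop_term)]
    if (!length(terms)) {
      fit <- glm(.y ~ 1, family = binomial(), data = df)
      break
    }
    fit <- glm(as.formula(paste(".y ~", paste(terms, collapse = " + "))),
               family = binomial(), data = df)
  }
  separation <- any(abs(coef(fit)[is.finite(coef(fit))]) > 15) ||
    any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
  if (separation)
    warning("possible complete separation in ", stage, "/", survey,
            " stage model; coefficients may be unstable")
  structure(list(stage = stage, survey = survey, fit = fit,
                 terms = terms, candidate_terms = candidate_terms,
                 alpha = alpha, n = nrow(df),
                 elimination = dplyr::bind_rows(elimination),
                 dropped_levels = dropped_levels,
                 separation = separation),
            class = "stage_model")
}

#' @export
print.stage_model <- function(x, ...) {
  cat(sprintf("<stage_model %s/%s> n = %d, retained: %s\n", x$stage,
              x$survey, x$n,
              if (length(x$terms)) paste(x$terms, collapse = " + ")
              else "(intercept only)"))
  invisible(x)
}

#' @export
tidy.stage_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(stage = x$stage, survey = x$survey,
                 term = rownames(s), estimate = s[, 1],
                 std_error = s[, 2], statistic = s[, 3],
                 p_value = s[, 4])
}

#' @export
glance.stage_model <- function(x, ...) {
  tibble::tibble(stage = x$stage, survey = x$survey, n = x$n,
                 n_terms = length(x$terms),
                 log_lik = as.numeric(logLik(x$fit)),
                 aic = x$fit$aic,
                 deviance = x$fit$deviance,
                 separation = x$separation)
}

check_levels <- function(model, df) {
  for (v in c("sex", "region", "year")) {
    lev <- model$fit$xlevels[[v]]
    if (is.null(lev)) next
    bad <- setdiff(unique(as.character(df[[v]])), lev)
    if (length(bad))
      stop("level(s) unseen by the ", model$stage, "/", model$survey,
           " stage model: ", v, " = ", paste(bad, collapse = ", "))
  }
}

#' Predicted stage-membership probability
#'
#' @param model A `stage_model`.
#' @param length Length(s) in cm.
#' @param sex,region,year Profile covariates (recycled).
#' @return Probabilities in (0, 1).
#' @export
stage_probability <- function(model, length, sex, region, year) {
  df <- tibble::tibble(length = length, sex = as.character(sex),
                       region = as.character(region),
                       year = as.character(year))
  check_levels(model, df)
  df$sex <- factor(df$sex, levels = model$fit$xlevels$sex %||% c("F", "M"))
  df$region <- factor(df$region, levels = model$fit$xlevels$region %||%
                        unique(df$region))
  df$year <- factor(df$year, levels = model$fit$xlevels$year %||%
                      unique(df$year))
  as.numeric(predict(model$fit, newdata = df, type = "response"))
}

#' Length at 50% stage membership for fixed profiles
#'
#' The linear predictor is linear in length for any retained structure, so
#' L50 solves `eta(length) = 0` from its values at lengths 0 and 1.
#' Profiles whose effective length slope is (numerically) zero get `NA`.
#'
#' @param model A `stage_model`.
#' @param profiles Tibble with `sex`, `region`, `year` (defaults to every
#'   combination seen in training).
#' @return Tibble with the profile columns and `l50` (cm).
#' @export
compute_l50 <- function(model, profiles = NULL) {
  xl <- model$fit$xlevels
  if (is.null(profiles))
    profiles <- tidyr::expand_grid(
      sex = xl$sex %||% "F", region = xl$region %||% region_levels(),
      year = xl$year %||% "2009")
  eta_at <- function(l) {
    df <- dplyr::mutate(profiles, length = l)
    df$sex <- factor(df$sex, levels = xl$sex %||% unique(df$sex))
    df$region <- factor(df$region, levels = xl$region %||% unique(df$region))
    df$year <- factor(df$year, levels = xl$year %||% unique(df$year))
    as.numeric(predict(model$fit, newdata = df, type = "link"))
  }
  eta0 <- eta_at(0)
  eta1 <- eta_at(1)
  slope <- eta1 - eta0
  l50 <- ifelse(abs(slope) < 1e-8, NA_real_, -eta0 / slope)
  dplyr::mutate(profiles, stage = model$stage, survey = model$survey,
                l50 = l50) |>
    dplyr::relocate("stage", "survey")
}

#' SMALK sex ratio by 1-cm length bin
#'
#' Proportion of females among SMALK fish per survey and 1-cm bin, used to
#' sex-average stage probabilities for unsexed catch rows. Bins without
#' SMALK fish fall back to 0.5/0.5.
#'
#' @param smalks SMALK tibble.
#' @return Tibble with `survey`, `length_bin`, `prop_f`.
#' @export
smalk_sex_ratio <- function(smalks) {
  tibble::as_tibble(smalks) |>
    dplyr::mutate(length_bin = floor(.data$length)) |>
    dplyr::group_by(.data$survey, .data$length_bin) |>
    dplyr::summarise(prop_f = mean(.data$sex == "F"), .groups = "drop")
}

#' Decompose haul length-frequencies into life-stage CPUE
#'
#' Per haul, the stage CPUE is the sum over 1-cm length classes of the
#' 30-minute standardised count times the predicted probability of the
#' class belonging to the stage, evaluated at the class midpoint (lower
#' bound + 0.5 cm) for the haul's region/year profile. Unsexed counts use
#' the sex-averaged probability weighted by the SMALK sex ratio in that
#' length bin (0.5/0.5 where no SMALK fish exist). Only season-appropriate
#' stages are populated: age-0 for Oct-Nov hauls, age-1 and mature for
#' Feb-Mar hauls.
#'
#' @param tables A `survey_tables` list (or list with `hauls`, `lengths`,
#'   `smalks`).
#' @param models Named list of `stage_model`s keyed `"<stage>.<survey>"`.
#' @param partition Region partition for haul positions.
#' @return Stage CPUE tibble: haul metadata, `total`, `cpue_age0`,
#'   `cpue_age1`, `cpue_mature` and presence flags.
#' @export
decompose_cpue <- function(tables, models, partition = region_partition()) {
  hauls <- tables$hauls
  lens <- tables$lengths
  if (!"standardised_count" %in% names(lens))
    lens <- dplyr::left_join(lens,
                             dplyr::select(hauls, "haul_id", "duration"),
                             by = "haul_id") |>
      dplyr::mutate(standardised_count =
                      standardise_cpue(.data$count, .data$duration))
  ratio <- smalk_sex_ratio(tables$smalks)
  hauls$region <- assign_region(hauls$lon, hauls$lat, partition)
  out <- purrr::map_dfr(seq_len(nrow(hauls)), function(i) {
    h <- hauls[i, ]
    rows <- lens[lens$haul_id == h$haul_id, ]
    stages <- if (h$season == "OCT_NOV") "AGE0" else c("AGE1", "MATURE")
    res <- tibble::tibble(haul_id = h$haul_id, survey = h$survey,
                          gear = h$gear, season = h$season, year = h$year,
                          lon = h$lon, lat = h$lat, region = h$region,
                          total = sum(rows$standardised_count),
                          cpue_age0 = NA_real_, cpue_age1 = NA_real_,
                          cpue_mature = NA_real_)
    for (st in stages) {
      mod <- models[[paste(st, h$survey, sep = ".")]]
      if (is.null(mod))
        stop("missing stage model for ", st, "/", h$survey)
      col <- paste0("cpue_", tolower(sub("AGE", "age", st)))
      if (nrow(rows) == 0) {
        res[[col]] <- 0
        next
      }
      mids <- rows$length_class + 0.5
      pf <- stage_probability(mod, mids, "F", h$region, h$year)
      pm <- stage_probability(mod, mids, "M", h$region, h$year)
      bins <- floor(mids)
      rsel <- ratio[ratio$survey == h$survey, ]
      wf <- rsel$prop_f[match(bins, rsel$length_bin)]
      wf[is.na(wf)] <- 0.5
      p <- ifelse(rows$sex == "F", pf,
                  ifelse(rows$sex == "M", pm, wf * pf + (1 - wf) * pm))
      res[[col]] <- sum(rows$standardised_count * p)
    }
    res
  })
  dplyr::mutate(out,
                present_age0 = .data$cpue_age0 > 0,
                present_age1 = .data$cpue_age1 > 0,
                present_mature = .data$cpue_mature > 0)
}
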