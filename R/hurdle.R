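#' Variance-inflation-factor screen for continuous covariates
#'
#' Iteratively regresses each covariate on the others, computes
#' `VIF = 1 / (1 - R^2)`, and drops the covariate with the largest VIF
#' while any exceeds the threshold. Exactly collinear covariates (infinite
#' VIF) are dropped first and flagged.
#'
#' @param data Covariate tibble.
#' @param vars Continuous covariate names (>= 2).
#' @param threshold Removal threshold, default 3.
#' @return List with `retained` (names) and `report` (tibble of iteration,
#'   variable, vif, dropped).
#' @export
vif_screen <- function(data, vars, threshold = 3) {
  stopifnot(length(vars) >= 2, nrow(data) > length(vars))
  keep <- vars
  report <- list()
  it <- 0
  repeat {
    it <- it + 1
    vifs <- vapply(keep, function(v) {
      others <- setdiff(keep, v)
      if (!length(others)) return(1)
      fml <- as.formula(paste(v, "~", paste(others, collapse = "+")))
      # collinear fits warn about perfect R^2; that is the case being
      # screened for
      r2 <- suppressWarnings(summary(stats::lm(fml, data = data))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    worst <- which.max(vifs)
    dropped <- vifs[worst] > threshold && length(keep) > 1
    report[[it]] <- tibble::tibble(iteration = it, variable = keep,
                                   vif = unname(vifs),
                                   dropped = dropped &
                                     seq_along(keep) == worst)
    if (!dropped) break
    keep <- keep[-worst]
  }
  list(retained = keep, report = dplyr::bind_rows(report))
}

#' Fit the two-part (zero-altered Poisson) hurdle model for one life stage
#'
#' The presence component is a binomial GAM on every haul; the count
#' component a zero-truncated Poisson GAM on the positive hauls, with the
#' stage CPUE rounded to the nearest whole fish (floored at 1). Both
#' components share the covariate table and carry a gear-level random
#' intercept when `re(...)` appears in their term lists.
#'
#' @param data Covariate tibble (one row per haul).
#' @param cpue Non-negative stage CPUE per haul.
#' @param presence_terms,count_terms Term labels for the two components.
#' @param stage Stage code carried in the result.
#' @param control An [hgam_control()].
#' @param sp_presence,sp_count Optional fixed smoothing parameters.
#' @return A `hurdle_model`.
#' @export
fit_hurdle <- function(data, cpue, presence_terms, count_terms,
                       stage = "AGE0", control = hgam_control(),
                       sp_presence = NULL, sp_count = NULL) {
  stopifnot(nrow(data) == length(cpue), all(cpue >= 0))
  presence <- cpue > 0
  pres <- fit_presence_gam(data, presence, presence_terms,
                           control = control, sp = sp_presence)
  pos <- which(presence)
  if (length(pos) < 5) stop("too few positive hauls for the count component")
  counts <- pmax(1, round(cpue[pos]))
  cnt <- fit_ztp_gam(data[pos, , drop = FALSE], counts, count_terms,
                     control = control, sp = sp_count)
  structure(list(stage = stage, presence = pres, count = cnt,
                 n = nrow(data), n_positive = length(pos)),
            class = "hurdle_model")
}

#' @export
print.hurdle_model <- function(x, ...) {
  cat(sprintf("<hurdle_model %s> %d hauls (%d positive)\n", x$stage, x$n,
              x$n_positive))
  cat(sprintf("  presence: AIC %.2f, edf %.2f | count: AIC %.2f, edf %.2f\n",
              x$presence$aic, x$presence$edf, x$count$aic, x$count$edf))
  invisible(x)
}

#' @export
tidy.hurdle_model <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$presence), component = "binomial"),
    dplyr::mutate(tidy(x$count), component = "poisson")) |>
    dplyr::mutate(stage = x$stage) |>
    dplyr::relocate("stage", "component")
}

#' @export
glance.hurdle_model <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$presence), component = "binomial"),
    dplyr::mutate(glance(x$count), component = "poisson")) |>
    dplyr::mutate(stage = x$stage) |>
    dplyr::relocate("stage", "component")
}

#' Term-importance table for both hurdle components
#'
#' Single-term-deletion deviance importance ([delta_deviance()]) for the
#' binomial and truncated-Poisson components, in the layout of the model
#' summary tables (term, delta deviance, edf, chi-square, p).
#'
#' @param x A `hurdle_model`.
#' @return Tibble.
#' @export
hurdle_importance <- function(x) {
  dplyr::bind_rows(
    dplyr::mutate(delta_deviance(x$presence), component = "binomial"),
    dplyr::mutate(delta_deviance(x$count), component = "poisson")) |>
    dplyr::mutate(stage = x$stage) |>
    dplyr::relocate("stage", "component")
}

#' Expected CPUE of the hurdle model
#'
#' The zero-altered Poisson expectation
#' `p * lambda / (1 - exp(-lambda))` — presence probability times the
#' truncated-Poisson conditional mean. Set `truncated = FALSE` for the
#' plain `p * lambda` alternative.
#'
#' @param p Presence probabilities.
#' @param lambda Untruncated Poisson rates.
#' @param truncated Use the truncated conditional mean (default)?
#' @return Expected CPUE.
#' @export
combined_cpue <- function(p, lambda, truncated = TRUE) {
  if (truncated) p * lambda / (-expm1(-lambda)) else p * lambda
}

#' Predict hurdle surfaces over the environmental stack
#'
#' Cellwise presence probability, count rate and combined expected CPUE on
#' the modelling domain for one year (season implied by the stage), at the
#' population level of the gear effect (per-gear surfaces via `gear`).
#' Cells whose covariates fall outside the training envelope are flagged in
#' the `extrapolated` layer.
#'
#' @param model A `hurdle_model`.
#' @param env An `env_stack`.
#' @param year Prediction year.
#' @param gear `NULL` for population-level, else a survey code to predict
#'   at that gear's intercept.
#' @param truncated Passed to [combined_cpue()].
#' @return A `prediction_grid`: list with `p`, `lambda`, `combined`,
#'   `extrapolated` grid layers plus `stage`, `year`.
#' @export
predict_combined <- function(model, env, year, gear = NULL,
                             truncated = TRUE) {
  season <- season_for_stage(model$stage)
  cells <- grid_covariates(env, year, season)
  cells$year <- as.character(year)
  if (!is.null(gear)) cells$survey <- gear
  else cells$survey <- survey_levels()[1] # ignored at population level
  population <- is.null(gear)
  p <- predict(model$presence, cells, type = "response",
               population = population)
  lam_rate <- exp(predict(model$count, cells, type = "link",
                          population = population))
  comb <- combined_cpue(p, lam_rate, truncated = truncated)
  cont <- c("depth", "slope", "aspect", "prox_shore", "temperature",
            "salinity", "lon", "lat")
  used <- unique(unlist(lapply(c(model$presence$design$terms,
                                 model$count$design$terms),
                               `[[`, "vars")))
  used <- intersect(used, cont)
  extr <- rep(FALSE, nrow(cells))
  train <- dplyr::bind_rows(model$presence$data, model$count$data)
  for (v in used) {
    rng <- range(train[[v]], na.rm = TRUE)
    extr <- extr | cells[[v]] < rng[1] | cells[[v]] > rng[2]
  }
  mk <- function(v, nm) {
    mat <- matrix(NA_real_, nrow(env$depth), ncol(env$depth))
    mat[cbind(cells$row, cells$col)] <- v
    grid_like(env$depth, mat, name = nm)
  }
  key <- paste(model$stage, year, sep = "_")
  out <- list(p = mk(p, paste0("p_", key)),
              lambda = mk(lam_rate, paste0("lambda_", key)),
              combined = mk(comb, paste0("combined_", key)),
              extrapolated = mk(as.numeric(extr), paste0("extrap_", key)),
              stage = model$stage, year = year)
  class(out) <- "prediction_grid"
  out
}

#' @export
print.prediction_grid <- function(x, ...) {
  v <- unclass(x$combined)
  cat(sprintf("<prediction_grid %s %d> %d cells, combined CPUE range [%.3g, %.3g]\n",
              x$stage, x$year, sum(is.finite(v)),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}
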