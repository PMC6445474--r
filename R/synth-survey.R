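#' Ground-truth specification for the synthetic survey
#'
#' Fixes every parameter of the synthetic data-generating process so that
#' downstream estimates can be compared against known truth:
#'
#' * per region/sex/year logistic life-stage schedules (slope and L50,
#'   hence intercept `= -slope * L50`) for the age-0, age-1 and mature
#'   probabilities. Age-0 and age-1 slopes are negative (small fish are the
#'   young ones), the maturity slope positive;
#' * presence and count linear predictors over the environmental
#'   covariates per stage (see [truth_eta()]), plus one fixed gear-level
#'   intercept per survey in each component — with only two gear levels the
#'   random-intercept variance is unidentifiable, so truth fixes the
#'   contrast;
#' * stage length distributions (normal, truncated at 0) used to spread
#'   simulated totals over 1-cm classes.
#'
#' `null = TRUE` zeroes every covariate effect (presence probability 0.5,
#' constant count rate), the reference point for null calibration of AUC.
#'
#' @param years_feb,years_oct Study years per season.
#' @param null Build the no-signal variant?
#' @param gear_presence,gear_count Named gear intercepts (SWC_IBTS, NIGFS).
#' @return A `truth_spec` list.
#' @export
truth_spec <- function(years_feb = 2009:2015, years_oct = 2011:2014,
                       null = FALSE,
                       gear_presence = c(SWC_IBTS = 0, NIGFS = -0.5),
                       gear_count = c(SWC_IBTS = 0, NIGFS = -0.5)) {
  regions <- region_levels()
  reg_off <- setNames(seq(-2, 2, length.out = length(regions)), regions)
  stage_tab <- list(
    AGE0 = list(slope = -0.7, l50 = 19, years = years_oct),
    AGE1 = list(slope = -0.55, l50 = 24, years = years_feb),
    MATURE = list(slope = 0.5, l50 = 25, years = years_feb))
  stage_par <- purrr::map_dfr(names(stage_tab), function(st) {
    p <- stage_tab[[st]]
    tidyr::expand_grid(stage = st, region = regions, sex = c("F", "M"),
                       year = p$years) |>
      dplyr::mutate(
        slope = p$slope,
        l50 = p$l50 + reg_off[.data$region] +
          ifelse(.data$sex == "F", 0.7, -0.7) +
          0.5 * sin(2 * pi * (.data$year - min(.data$year)) / 4),
        intercept = -.data$slope * .data$l50)
  })
  hurdle <- list(
    AGE0 = list(
      presence = c(b0 = 1.2, depth = -1.8, shore = -0.5),
      count = c(c0 = 2.6, depth = -0.9, depth2 = 0, temp2 = -0.15,
                aspect = 0, shore = 0),
      d_opt = 75, t_opt = 12.5),
    AGE1 = list(
      presence = c(b0 = 0.8, depth = -1.0, shore = -0.4),
      count = c(c0 = 2.4, depth = 0, depth2 = -0.8, temp2 = -0.10,
                aspect = 0.3, shore = 0),
      d_opt = 60, t_opt = 8.3),
    MATURE = list(
      presence = c(b0 = 0.6, depth = 1.4, shore = 0),
      count = c(c0 = 2.2, depth = 0.7, depth2 = 0, temp2 = -0.08,
                aspect = 0, shore = 0),
      d_opt = 75, t_opt = 9.7))
  if (null) {
    hurdle <- purrr::map(hurdle, function(h) {
      h$presence[] <- 0
      h$count[] <- 0
      h$count["c0"] <- log(3)
      h
    })
    gear_presence[] <- 0
    gear_count[] <- 0
  }
  out <- list(
    stage_par = stage_par,
    hurdle = hurdle,
    gear_presence = gear_presence,
    gear_count = gear_count,
    length_dist = list(AGE0 = c(mean = 15, sd = 3),
                       AGE1 = c(mean = 22, sd = 4),
                       MATURE = c(mean = 30, sd = 6)),
    years_feb = years_feb, years_oct = years_oct, null = null)
  class(out) <- "truth_spec"
  out
}

#' @export
print.truth_spec <- function(x, ...) {
  cat(sprintf("<truth_spec>%s %d stage-schedule rows; seasons: Feb-Mar %s, Oct-Nov %s\n",
              if (x$null) " [null]" else "", nrow(x$stage_par),
              paste(range(x$years_feb), collapse = "-"),
              paste(range(x$years_oct), collapse = "-")))
  invisible(x)
}

#' True hurdle linear predictors at given covariates
#'
#' Presence: `b0 + b_depth * zd + b_shore * zs` with `zd = (depth - 75)/40`
#' and `zs = prox_shore_km / 30`. Count (log scale):
#' `c0 + c_depth * zd + c_depth2 * ((depth - d_opt)/50)^2 +
#'  c_temp2 * (temperature - t_opt)^2 + c_aspect * cos(aspect) +
#'  c_shore * zs`. Smooth, bounded on the covariate envelope, and strong
#' enough under the defaults for clean recovery tests.
#'
#' @param truth A `truth_spec`.
#' @param stage Stage code.
#' @param cov Tibble with `depth`, `prox_shore` (m), `temperature`,
#'   `aspect` columns.
#' @return List with vectors `presence` and `count`.
#' @export
truth_eta <- function(truth, stage, cov) {
  h <- truth$hurdle[[stage]]
  if (is.null(h)) stop("no truth parameters for stage ", stage)
  zd <- (cov$depth - 75) / 40
  zs <- (cov$prox_shore / 1000) / 30
  eta_p <- h$presence["b0"] + h$presence["depth"] * zd +
    h$presence["shore"] * zs
  eta_n <- h$count["c0"] + h$count["depth"] * zd +
    h$count["depth2"] * ((cov$depth - h$d_opt) / 50)^2 +
    h$count["temp2"] * (cov$temperature - h$t_opt)^2 +
    h$count["aspect"] * cos(cov$aspect * pi / 180) +
    h$count["shore"] * zs
  if (any(!is.finite(eta_p) | !is.finite(eta_n)))
    stop("non-finite linear predictor in truth evaluation")
  list(presence = unname(eta_p), count = unname(eta_n))
}

#' Simulate haul positions for both surveys
#'
#' SWC-IBTS hauls (GOV, 30 min) are placed uniformly over sea cells in the
#' northern two-thirds of the extent, NIGFS hauls (rockhopper, 60 min) over
#' the Irish Sea third (lat < 54 1/3). Positions are cell-uniform: a cell is
#' drawn uniformly among the sub-extent's sea cells, then jittered within
#' the cell.
#'
#' @param env An `env_stack`.
#' @param n_per_survey_year Named vector (`SWC_IBTS`, `NIGFS`) or single
#'   count used for both.
#' @param years Integer years.
#' @param season `"FEB_MAR"` or `"OCT_NOV"`.
#' @param seed Integer seed.
#' @return Haul tibble.
#' @export
generate_hauls <- function(env, n_per_survey_year, years, season, seed) {
  if (length(n_per_survey_year) == 1)
    n_per_survey_year <- c(SWC_IBTS = n_per_survey_year,
                           NIGFS = n_per_survey_year)
  stopifnot(all(n_per_survey_year >= 1))
  season <- match.arg(season, season_levels())
  cc <- cell_centres(env$depth)
  sea <- unclass(env$land) == 0
  m <- grid_meta(env$depth)
  # keep a half-cell margin so within-cell jitter cannot cross the
  # survey boundary
  lat_split <- 52 + 7 / 3
  sub <- list(SWC_IBTS = which(sea & cc$lat >= lat_split + m$dy / 2),
              NIGFS = which(sea & cc$lat < lat_split - m$dy / 2))
  withr::with_seed(as.integer(seed), {
    rows <- purrr::map_dfr(c("SWC_IBTS", "NIGFS"), function(sv) {
      cells <- sub[[sv]]
      if (!length(cells)) stop("no sea cells in sub-extent for ", sv)
      purrr::map_dfr(years, function(yr) {
        n <- n_per_survey_year[[sv]]
        pick <- cells[sample.int(length(cells), n, replace = TRUE)]
        tibble::tibble(
          haul_id = sprintf("%s_%d_%s_%03d", sv, yr, season, seq_len(n)),
          survey = sv, gear = gear_for_survey(sv), year = yr,
          season = season,
          lon = cc$lon[pick] + (runif(n) - 0.5) * m$dx * 0.98,
          lat = cc$lat[pick] + (runif(n) - 0.5) * m$dy * 0.98,
          duration = ifelse(sv == "SWC_IBTS", 30, 60))
      })
    })
    rows
  })
}

#' Simulate individual SMALK records with known stage schedules
#'
#' Oct-Nov fish carry an age-0 label drawn from the true age-0 logistic at
#' their length (the rest are assigned age 1 or 2). Feb-Mar fish are all
#' age >= 1 (matching the seasonal design in which age-0 fish have not yet
#' recruited to the spring survey): an age-1 label is drawn from the true
#' age-1 logistic and a maturity flag from the true maturity logistic. Each
#' fitted stage model is therefore exactly well-specified. Lengths come
#' from season-specific two-component normal mixtures spanning the stage
#' length distributions, truncated at 1 cm.
#'
#' @param truth A `truth_spec`.
#' @param n_per_region_year Fish per region x year (split across sexes).
#' @param seed Integer seed.
#' @param seasons Which seasons to generate (default both).
#' @return SMALK tibble with an extra `season` column.
#' @export
generate_smalks <- function(truth, n_per_region_year, seed,
                            seasons = season_levels()) {
  stopifnot(n_per_region_year >= 2)
  par <- truth$stage_par
  withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seasons, function(season) {
      years <- if (season == "FEB_MAR") truth$years_feb else truth$years_oct
      purrr::map_dfr(region_levels(), function(reg) {
        purrr::map_dfr(years, function(yr) {
          n <- n_per_region_year
          sex <- sample(c("F", "M"), n, replace = TRUE)
          if (season == "OCT_NOV") {
            comp <- runif(n) < 0.5
            len <- ifelse(comp, rnorm(n, 15, 3), rnorm(n, 28, 6))
          } else {
            comp <- runif(n) < 0.5
            len <- ifelse(comp, rnorm(n, 22, 4), rnorm(n, 30, 6))
          }
          len <- pmax(len, 1)
          get_par <- function(stage) {
            p <- par[par$stage == stage & par$region == reg &
                       par$year == yr, ]
            p[match(sex, p$sex), ]
          }
          if (season == "OCT_NOV") {
            p0 <- get_par("AGE0")
            pr0 <- plogis(p0$intercept + p0$slope * len)
            is0 <- runif(n) < pr0
            age <- ifelse(is0, 0L, 1L + rbinom(n, 1, 0.4))
            mature <- ifelse(age >= 1, runif(n) < 0.3, FALSE)
          } else {
            p1 <- get_par("AGE1")
            pm <- get_par("MATURE")
            is1 <- runif(n) < plogis(p1$intercept + p1$slope * len)
            age <- ifelse(is1, 1L, 2L + rbinom(n, 1, 0.5))
            mature <- runif(n) < plogis(pm$intercept + pm$slope * len)
          }
          tibble::tibble(length = len, sex = sex, age = as.integer(age),
                         mature = mature, region = reg, year = yr,
                         survey = survey_for_region(reg), season = season)
        })
      })
    })
  })
}

#' Draw from a zero-truncated Poisson by inversion
#' @param n Number of draws.
#' @param lambda Rate(s) of the untruncated Poisson (> 0).
#' @return Integer vector of draws >= 1.
#' @export
rztpois <- function(n, lambda) {
  lambda <- rep_len(lambda, n)
  p0 <- exp(-lambda)
  u <- runif(n, min = p0, max = 1)
  pmax(1L, qpois(u, lambda))
}

#' Simulate length-frequency catches from the zero-altered process
#'
#' Per haul and season-appropriate stage: presence is Bernoulli at
#' `plogis(eta_p + a_gear)`; conditional on presence the 30-minute
#' standardised total is zero-truncated Poisson at `exp(eta_n + a'_gear)`;
#' the total is spread over 1-cm length classes by the stage length
#' distribution. Raw counts are scaled back to the tow duration so that
#' standardisation recovers the simulated totals exactly.
#'
#' @param env An `env_stack`.
#' @param hauls Haul tibble.
#' @param truth A `truth_spec`.
#' @param seed Integer seed.
#' @return Length-frequency tibble (`haul_id`, `length_class`, `sex`,
#'   `count`), with per-haul true stage totals in the
#'   `"true_totals"` attribute.
#' @export
generate_catches <- function(env, hauls, truth, seed) {
  cov <- extract_at_hauls(env, hauls)
  if (any(!cov$valid)) {
    # hauls jittered onto land/rock carry no catch; they are dropped later
    # by the modelling stage as well
    cov <- dplyr::filter(cov, .data$valid)
    hauls <- hauls[hauls$haul_id %in% cov$haul_id, ]
  }
  withr::with_seed(as.integer(seed), {
    out <- list()
    truths <- list()
    for (i in seq_len(nrow(hauls))) {
      h <- hauls[i, ]
      cv <- cov[cov$haul_id == h$haul_id, ]
      stages <- if (h$season == "OCT_NOV") "AGE0" else c("AGE1", "MATURE")
      for (st in stages) {
        eta <- truth_eta(truth, st, cv)
        ep <- eta$presence + truth$gear_presence[[h$survey]]
        en <- eta$count + truth$gear_count[[h$survey]]
        present <- runif(1) < plogis(ep)
        total <- if (present) rztpois(1, exp(en)) else 0L
        truths[[length(truths) + 1]] <- tibble::tibble(
          haul_id = h$haul_id, stage = st, eta_presence = ep,
          eta_count = en, total = total)
        if (total > 0) {
          ld <- truth$length_dist[[st]]
          len <- pmax(1, rnorm(total, ld["mean"], ld["sd"]))
          cls <- floor(len)
          tab <- table(cls)
          out[[length(out) + 1]] <- tibble::tibble(
            haul_id = h$haul_id,
            length_class = as.numeric(names(tab)),
            sex = "U",
            count = as.numeric(tab) * h$duration / 30)
        }
      }
    }
    catches <- if (length(out)) {
      dplyr::bind_rows(out) |>
        dplyr::group_by(.data$haul_id, .data$length_class, .data$sex) |>
        dplyr::summarise(count = sum(.data$count), .groups = "drop")
    } else {
      tibble::tibble(haul_id = character(), length_class = numeric(),
                     sex = character(), count = numeric())
    }
    attr(catches, "true_totals") <- dplyr::bind_rows(truths)
    catches
  })
}

#' Export ground truth as tables and grids
#'
#' @param truth A `truth_spec`.
#' @param env An `env_stack`.
#' @param dir Output directory; when `NULL` nothing is written and the
#'   truth objects are returned invisibly.
#' @return List with `l50` (tibble of true L50 per stage/region/sex/year)
#'   and `grids`, a list keyed `"<stage>_<year>"` of lists with `p`,
#'   `lambda`, `combined` grid layers (population-level gear effect).
#' @export
export_truth <- function(truth, env, dir = NULL) {
  l50 <- dplyr::mutate(truth$stage_par,
                       l50_check = -.data$intercept / .data$slope) |>
    dplyr::select("stage", "region", "sex", "year", "slope", "intercept",
                  l50 = "l50_check")
  grids <- list()
  for (st in stage_levels()) {
    season <- season_for_stage(st)
    years <- if (season == "FEB_MAR") truth$years_feb else truth$years_oct
    for (yr in years) {
      cells <- grid_covariates(env, yr, season)
      eta <- truth_eta(truth, st, cells)
      p <- plogis(eta$presence)
      lam <- exp(eta$count)
      comb <- p * lam / (1 - exp(-lam))
      mk <- function(v, nm) {
        mat <- matrix(NA_real_, nrow(env$depth), ncol(env$depth))
        mat[cbind(cells$row, cells$col)] <- v
        grid_like(env$depth, mat, name = nm)
      }
      key <- paste(st, yr, sep = "_")
      grids[[key]] <- list(p = mk(p, paste0("true_p_", key)),
                           lambda = mk(lam, paste0("true_lambda_", key)),
                           combined = mk(comb, paste0("true_combined_", key)))
    }
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(l50, file.path(dir, "true_l50.csv"))
    for (key in names(grids))
      for (part in names(grids[[key]]))
        write_grid(grids[[key]][[part]],
                   file.path(dir, sprintf("true_%s_%s.asc", part, key)))
  }
  invisible(list(l50 = l50, grids = grids))
}
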