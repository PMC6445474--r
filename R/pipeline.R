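#' Default hurdle model structures per life stage
#'
#' Desk-scale model structures used by the pipeline: the drivers of the
#' synthetic truth plus a tensor interaction and the cyclic aspect smooth
#' where the stage's reference structure uses them, and a gear random
#' intercept in every component.
#'
#' @return Named list per stage with `presence` and `count` term vectors.
#' @export
default_structures <- function() {
  list(
    AGE0 = list(presence = c("s(depth)", "s(prox_shore)", "re(survey)"),
                count = c("s(depth)", "s(temperature)", "re(survey)")),
    AGE1 = list(presence = c("s(depth)", "s(prox_shore)", "re(survey)"),
                count = c("s(depth)", "s(aspect)", "s(temperature)",
                          "re(survey)")),
    MATURE = list(presence = c("s(depth)", "te(depth,lon)", "re(survey)"),
                  count = c("s(depth)", "s(temperature)", "re(survey)")))
}

pipeline_log <- function() {
  env <- new.env()
  env$stages <- list()
  env
}

log_stage <- function(log, stage, ...) {
  log$stages[[stage]] <- list(...)
}

#' Run the full synthetic-survey analysis pipeline
#'
#' Orchestrates every stage end to end: synthetic environment and survey
#' generation with exported truth, CTD simulation with LOOCV bandwidth
#' selection and kernel-smoothed temperature/salinity surfaces, life-stage
#' logistic models and L50 tables, stage CPUE decomposition, hurdle GAMM
#' fitting (with optional stepwise selection), cross-validation, per-year
#' prediction grids, aggregation curves with slope-1 thresholds, binary
#' classification and multi-year persistence maps. All outputs are plain
#' CSV/ASCII-grid files plus a machine-readable JSON run log; repeated runs
#' with the same configuration are byte-identical.
#'
#' @param config A [default_config()] list.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory artefacts and the log.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- pipeline_log()
  seed <- config$seed
  ctrl <- hgam_control(k_s = config$k_s, k_te = config$k_te,
                       k_cc = config$k_cc)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- simulate -------------------------------------------------------------
  artefacts <- run_stage("simulate", {
    env <- generate_environment(seed, c(config$grid_nrow, config$grid_ncol),
                                years_feb = config$years_feb,
                                years_oct = config$years_oct)
    truth <- truth_spec(years_feb = config$years_feb,
                        years_oct = config$years_oct,
                        null = isTRUE(config$null_truth))
    hauls <- dplyr::bind_rows(
      generate_hauls(env, config$hauls_per_survey_year, config$years_feb,
                     "FEB_MAR", seed = seed + 1),
      generate_hauls(env, config$hauls_per_survey_year, config$years_oct,
                     "OCT_NOV", seed = seed + 2))
    smalks <- generate_smalks(truth, config$smalk_per_region_year,
                              seed = seed + 3)
    catches <- generate_catches(env, hauls, truth, seed = seed + 4)
    tables <- survey_tables(hauls, catches, smalks)
    write_survey_tables(tables, file.path(out_dir, "input"))
    write_env_stack(env, file.path(out_dir, "input", "env"))
    truth_out <- export_truth(truth, env, file.path(out_dir, "truth"))
    log_stage(log, "simulate", seed = seed,
              n_hauls = nrow(tables$hauls),
              n_length_rows = nrow(tables$lengths),
              n_smalks = nrow(tables$smalks),
              n_rejected = nrow(tables$rejected))
    list(env = env, truth = truth, tables = tables, truth_out = truth_out)
  })
  env <- artefacts$env
  tables <- artefacts$tables

  # -- layers: CTD -> kernel-smoothed surfaces ------------------------------
  run_stage("layers", {
    casts <- simulate_ctd_casts(env, config$n_ctd_stations, seed = seed + 5)
    bottom <- select_bottom_ctd(casts)
    fits <- list()
    for (key in names(env$temperature)) {
      yr <- as.integer(sub("_.*", "", key))
      season <- sub("^[0-9]+_", "", key)
      sel <- dplyr::filter(bottom, .data$year == yr, .data$season == season)
      for (vc in c("temperature", "salinity")) {
        kf <- select_bandwidth_loocv(sel, config$theta_grid_km,
                                     value_col = vc)
        env[[vc]][[key]] <- kernel_smooth(sel, env$depth, kf$theta,
                                          value_col = vc)
        fits[[length(fits) + 1]] <- tibble::tibble(
          year = yr, season = season, variable = vc, theta_km = kf$theta,
          loocv_score = kf$score)
      }
    }
    bandwidths <- dplyr::bind_rows(fits)
    readr::write_csv(bandwidths, file.path(out_dir, "kernel_bandwidths.csv"))
    readr::write_csv(bottom, file.path(out_dir, "input", "ctd_bottom.csv"))
    log_stage(log, "layers", n_casts = nrow(casts),
              n_stations = nrow(bottom),
              mean_theta_km = mean(bandwidths$theta_km))
  })

  # -- stages: logistic life-stage models, L50, CPUE decomposition ----------
  stage_art <- run_stage("stages", {
    models <- list()
    l50 <- list()
    for (st in stage_levels()) {
      for (sv in survey_levels()) {
        m <- suppressWarnings(fit_stage_model(tables$smalks, st, sv))
        models[[paste(st, sv, sep = ".")]] <- m
        l50[[length(l50) + 1]] <- compute_l50(m)
      }
    }
    l50_tab <- dplyr::bind_rows(l50)
    readr::write_csv(l50_tab, file.path(out_dir, "l50.csv"))
    cpue <- decompose_cpue(tables, models)
    readr::write_csv(cpue, file.path(out_dir, "stage_cpue.csv"))
    readr::write_csv(
      purrr::map_dfr(models, glance),
      file.path(out_dir, "stage_model_summaries.csv"))
    log_stage(log, "stages", n_models = length(models),
              n_l50 = nrow(l50_tab), n_cpue_rows = nrow(cpue))
    list(models = models, l50 = l50_tab, cpue = cpue)
  })

  # -- fit: covariates, VIF screen, hurdle models ---------------------------
  fit_art <- run_stage("fit", {
    cov <- extract_at_hauls(env, tables$hauls)
    n_excl <- attr(cov, "n_excluded")
    cov <- dplyr::filter(cov, .data$valid)
    vif <- vif_screen(cov, c("depth", "slope", "prox_shore",
                             "temperature", "salinity", "lon"))
    readr::write_csv(vif$report, file.path(out_dir, "vif_report.csv"))
    cpue <- dplyr::inner_join(
      dplyr::select(stage_art$cpue, "haul_id", dplyr::starts_with("cpue_")),
      cov, by = "haul_id")
    structures <- default_structures()
    hurdles <- list()
    importance <- list()
    for (st in stage_levels()) {
      season <- season_for_stage(st)
      dat <- dplyr::filter(cpue, .data$season == !!season)
      yvec <- dat[[paste0("cpue_", tolower(sub("AGE", "age", st)))]]
      terms <- structures[[st]]
      if (isTRUE(config$stepwise)) {
        selp <- stepwise_aic(dat, as.numeric(yvec > 0), terms$presence,
                             family = "binomial", control = ctrl)
        pos <- yvec > 0
        selc <- stepwise_aic(dat[pos, , drop = FALSE],
                             pmax(1, round(yvec[pos])), terms$count,
                             family = "ztp", control = ctrl)
        terms <- list(presence = selp$terms, count = selc$terms)
      }
      hm <- fit_hurdle(dat, yvec, terms$presence, terms$count,
                       stage = st, control = ctrl)
      hurdles[[st]] <- hm
      importance[[st]] <- hurdle_importance(hm)
    }
    imp <- dplyr::bind_rows(importance)
    readr::write_csv(imp, file.path(out_dir, "model_importance.csv"))
    readr::write_csv(purrr::map_dfr(hurdles, glance),
                     file.path(out_dir, "hurdle_summaries.csv"))
    log_stage(log, "fit", n_hauls_used = nrow(cov),
              n_hauls_excluded = n_excl,
              vif_retained = paste(vif$retained, collapse = ","),
              stepwise = isTRUE(config$stepwise))
    list(cov = cov, cpue = cpue, hurdles = hurdles, vif = vif)
  })

  # -- validate -------------------------------------------------------------
  cv_art <- run_stage("validate", {
    if (config$cv_iterations == 0) {
      log_stage(log, "validate", skipped = TRUE, reason = "cv_iterations=0")
      NULL
    } else {
      cvs <- list()
      for (st in stage_levels()) {
        season <- season_for_stage(st)
        dat <- dplyr::filter(fit_art$cpue, .data$season == !!season)
        yvec <- dat[[paste0("cpue_", tolower(sub("AGE", "age", st)))]]
        terms <- list(presence = fit_art$hurdles[[st]]$presence$terms,
                      count = fit_art$hurdles[[st]]$count$terms)
        cvs[[st]] <- cross_validate(dat, yvec, terms$presence, terms$count,
                                    iterations = config$cv_iterations,
                                    seed = seed + 10, control = ctrl,
                                    stage = st)
      }
      cv_tab <- purrr::map_dfr(cvs, function(cv) cv$summary)
      readr::write_csv(cv_tab, file.path(out_dir, "cv_results.csv"))
      log_stage(log, "validate", iterations = config$cv_iterations,
                n_stages = length(cvs))
      cvs
    }
  })

  # -- aggregate: predictions, curves, classification, persistence ----------
  agg_art <- run_stage("aggregate", {
    grid_dir <- file.path(out_dir, "grids")
    dir.create(grid_dir, showWarnings = FALSE)
    curves <- list()
    summaries <- list()
    persist <- list()
    for (st in stage_levels()) {
      season <- season_for_stage(st)
      years <- if (season == "FEB_MAR") config$years_feb else
        config$years_oct
      classified <- list()
      for (yr in years) {
        pg <- predict_combined(fit_art$hurdles[[st]], env, yr)
        write_grid(pg$combined,
                   file.path(grid_dir, sprintf("combined_%s_%d.asc", st, yr)))
        dens <- as.vector(unclass(pg$combined))
        curve <- build_curve(dens)
        thr <- tangent_threshold(curve, mode = config$curve_mode)
        cl <- classify_cells(pg$combined, thr$z_star)
        write_grid(cl, file.path(grid_dir,
                                 sprintf("classified_%s_%d.asc", st, yr)))
        classified[[as.character(yr)]] <- cl
        curves[[paste(st, yr, sep = "_")]] <- curve
        occ <- dens[!is.na(dens) & dens > 0]
        summaries[[length(summaries) + 1]] <- tibble::tibble(
          stage = st, year = yr, x_star = thr$x_star, y_star = thr$y_star,
          z_star = thr$z_star, mode = thr$mode,
          share_in_20pct_area = abundance_share(curve, 0.2),
          precision_pct = classification_precision(
            occ, thr$z_star, band = config$precision_band))
      }
      pst <- persistence(classified)
      persist[[st]] <- pst
      write_grid(pst, file.path(grid_dir,
                                sprintf("persistence_%s.asc", st)))
      # haul-based empirical curves from the observed stage CPUE
      col <- paste0("cpue_", tolower(sub("AGE", "age", st)))
      hc <- stage_art$cpue[[col]]
      hc <- hc[!is.na(hc) & hc > 0]
      if (length(hc) >= 2) {
        hcurve <- build_curve(hc)
        readr::write_csv(tibble::as_tibble(hcurve),
                         file.path(out_dir,
                                   sprintf("haul_curve_%s.csv", st)))
      }
    }
    agg_tab <- dplyr::bind_rows(summaries)
    readr::write_csv(agg_tab, file.path(out_dir, "aggregation_summary.csv"))
    for (key in names(curves))
      readr::write_csv(tibble::as_tibble(curves[[key]]),
                       file.path(out_dir, sprintf("curve_%s.csv", key)))
    log_stage(log, "aggregate", n_curves = length(curves),
              n_persistence = length(persist))
    list(summary = agg_tab, curves = curves, persistence = persist)
  })

  jsonlite::write_json(log$stages, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_config(config, file.path(out_dir, "config.txt"))
  invisible(list(env = env, tables = tables, truth = artefacts$truth,
                 truth_out = artefacts$truth_out,
                 stage_models = stage_art$models, l50 = stage_art$l50,
                 stage_cpue = stage_art$cpue, hurdles = fit_art$hurdles,
                 vif = fit_art$vif, cv = cv_art, aggregation = agg_art,
                 log = log$stages))
}

#' Simulate CTD casts over the synthetic environment
#'
#' Stations are placed uniformly over sea cells; each records several
#' pressure levels per year/season with the deepest reading closest to the
#' (true) bottom field, so bottom-selection and kernel smoothing can be
#' exercised end to end.
#'
#' @param env An `env_stack`.
#' @param n_stations Stations per year/season.
#' @param seed Integer seed.
#' @param n_levels Pressure levels per station.
#' @return Cast tibble (`station_id`, `lon`, `lat`, `year`, `season`,
#'   `pressure`, `temperature`, `salinity`).
#' @export
simulate_ctd_casts <- function(env, n_stations, seed, n_levels = 3) {
  cc <- cell_centres(env$depth)
  sea <- which(unclass(env$land) == 0)
  withr::with_seed(as.integer(seed), {
    purrr::map_dfr(names(env$temperature), function(key) {
      yr <- as.integer(sub("_.*", "", key))
      season <- sub("^[0-9]+_", "", key)
      tg <- unclass(env$temperature[[key]])
      sg <- unclass(env$salinity[[key]])
      pick <- sea[sample.int(length(sea), n_stations, replace = FALSE)]
      purrr::map_dfr(seq_along(pick), function(i) {
        cell <- pick[i]
        depth <- unclass(env$depth)[cell]
        frac <- sort(runif(n_levels, 0.2, 1))
        frac[n_levels] <- 1
        # shallower readings are warmer and fresher than the bottom value
        tibble::tibble(
          station_id = sprintf("st_%s_%03d", key, i),
          lon = cc$lon[cell], lat = cc$lat[cell],
          year = yr, season = season,
          pressure = depth * frac,
          temperature = tg[cell] + 1.5 * (1 - frac) +
            rnorm(n_levels, 0, 0.05),
          salinity = sg[cell] - 0.3 * (1 - frac) +
            rnorm(n_levels, 0, 0.02))
      })
    })
  })
}
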