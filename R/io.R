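#' Controlled vocabularies for survey data
#'
#' The study design pairs each survey with one gear and one tow duration:
#' the Scottish west-coast IBTS tows a GOV trawl for 30 minutes and the
#' Northern Irish groundfish survey a rockhopper trawl for 60 minutes.
#' Nine named regions partition the study extent (3W-10W, 52N-59N).
#'
#' @name vocab
NULL

#' @rdname vocab
#' @export
survey_levels <- function() c("SWC_IBTS", "NIGFS")

#' @rdname vocab
#' @export
gear_levels <- function() c("GOV", "ROCKHOPPER")

#' @rdname vocab
#' @export
season_levels <- function() c("FEB_MAR", "OCT_NOV")

#' @rdname vocab
#' @export
region_levels <- function() {
  c("N-O", "S-O", "N-M", "S-M", "S-W", "Cl", "W-IS", "E-IS", "SE-IS")
}

#' @rdname vocab
#' @export
stage_levels <- function() c("AGE0", "AGE1", "MATURE")

#' @rdname vocab
#' @export
sediment_levels <- function() {
  c("mud_sandy_mud", "sand_muddy_sand", "coarse", "mixed", "rock")
}

#' @rdname vocab
#' @param survey Survey codes.
#' @export
gear_for_survey <- function(survey) {
  unname(c(SWC_IBTS = "GOV", NIGFS = "ROCKHOPPER")[survey])
}

#' @rdname vocab
#' @param stage Stage codes.
#' @export
season_for_stage <- function(stage) {
  unname(c(AGE0 = "OCT_NOV", AGE1 = "FEB_MAR", MATURE = "FEB_MAR")[stage])
}

#' Rectangular partition of the study extent into the nine named regions
#'
#' A 3 x 3 tiling standing in for the survey's region boundaries: the
#' northern and central rows cover the Scottish west-coast survey area and
#' the southern row the Irish Sea survey area.
#'
#' @return Tibble with `region`, `lon_min`, `lon_max`, `lat_min`, `lat_max`.
#' @export
region_partition <- function() {
  lon_b <- seq(-10, -3, length.out = 4)
  lat_b <- seq(52, 59, length.out = 4)
  grid <- tidyr::expand_grid(row = 1:3, col = 1:3) # row 1 = north
  labels <- matrix(c("N-O", "N-M", "Cl",
                     "S-O", "S-M", "S-W",
                     "W-IS", "E-IS", "SE-IS"), 3, 3, byrow = TRUE)
  dplyr::mutate(grid,
                region = labels[cbind(.data$row, .data$col)],
                lon_min = lon_b[.data$col], lon_max = lon_b[.data$col + 1],
                lat_min = rev(lat_b)[.data$row + 1],
                lat_max = rev(lat_b)[.data$row]) |>
    dplyr::select(-"row", -"col")
}

#' Assign positions to named regions
#'
#' Points exactly on a boundary go to the northern/western region.
#'
#' @param lon,lat Coordinates in degrees.
#' @param partition Region table as from [region_partition()].
#' @return Character vector of region labels (`NA` outside the extent).
#' @export
assign_region <- function(lon, lat, partition = region_partition()) {
  lon_b <- sort(unique(c(partition$lon_min, partition$lon_max)))
  lat_b <- sort(unique(c(partition$lat_min, partition$lat_max)))
  # lon boundary belongs to the western (lower) cell: intervals (b_i, b_{i+1}]
  ci <- findInterval(lon, lon_b, left.open = TRUE)
  ci[lon == lon_b[1]] <- 1L
  # lat boundary belongs to the northern (upper) cell: intervals [b_i, b_{i+1})
  ri_up <- findInterval(lat, lat_b)
  ri_up[lat == lat_b[length(lat_b)]] <- length(lat_b) - 1L
  nrows <- length(lat_b) - 1L
  row <- nrows - ri_up + 1L
  out <- rep(NA_character_, length(lon))
  ok <- !is.na(ci) & !is.na(row) & ci >= 1 & ci <= 3 & row >= 1 & row <= 3 &
    lon >= lon_b[1] & lon <= lon_b[4] & lat >= lat_b[1] & lat <= lat_b[4]
  labels <- matrix(c("N-O", "N-M", "Cl",
                     "S-O", "S-M", "S-W",
                     "W-IS", "E-IS", "SE-IS"), 3, 3, byrow = TRUE)
  out[ok] <- labels[cbind(row[ok], ci[ok])]
  out
}

#' @rdname vocab
#' @param region Region labels.
#' @export
survey_for_region <- function(region) {
  ifelse(region %in% c("W-IS", "E-IS", "SE-IS"), "NIGFS", "SWC_IBTS")
}

# ---- row-level validation -------------------------------------------------

validate_rows <- function(df, rules, table) {
  reason <- rep(NA_character_, nrow(df))
  for (nm in names(rules)) {
    bad <- !rules[[nm]](df)
    bad[is.na(bad)] <- TRUE
    reason[is.na(reason) & bad] <- nm
  }
  keep <- is.na(reason)
  rejected <- tibble::tibble(table = table,
                             row = which(!keep),
                             reason = reason[!keep])
  list(records = df[keep, , drop = FALSE], rejected = rejected)
}

haul_rules <- function() list(
  "missing haul_id" = function(d) !is.na(d$haul_id) & nzchar(d$haul_id),
  "unknown survey" = function(d) d$survey %in% survey_levels(),
  "gear inconsistent with survey" = function(d)
    d$gear == gear_for_survey(d$survey),
  "unknown season" = function(d) d$season %in% season_levels(),
  "bad year" = function(d) is.finite(d$year) & d$year == round(d$year),
  "lon outside extent" = function(d) d$lon >= -10 & d$lon <= -3,
  "lat outside extent" = function(d) d$lat >= 52 & d$lat <= 59,
  "nonpositive duration" = function(d) is.finite(d$duration) & d$duration > 0
)

length_rules <- function() list(
  "missing haul_id" = function(d) !is.na(d$haul_id) & nzchar(d$haul_id),
  "negative length_class" = function(d) is.finite(d$length_class) &
    d$length_class >= 0,
  "unknown sex" = function(d) d$sex %in% c("F", "M", "U"),
  "negative count" = function(d) is.finite(d$count) & d$count >= 0
)

smalk_rules <- function() list(
  "nonpositive length" = function(d) is.finite(d$length) & d$length > 0,
  "unknown sex" = function(d) d$sex %in% c("F", "M"),
  "bad age" = function(d) is.finite(d$age) & d$age >= 0 & d$age == round(d$age),
  "bad maturity flag" = function(d) d$mature %in% c(TRUE, FALSE),
  "unknown region" = function(d) d$region %in% region_levels(),
  "bad year" = function(d) is.finite(d$year) & d$year == round(d$year),
  "unknown survey" = function(d) d$survey %in% survey_levels(),
  "mature fish below age 1" = function(d) !(d$mature & d$age < 1)
)

std_cols <- function(df, wanted) {
  missing <- setdiff(wanted, names(df))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  df
}

#' Read the survey observation triplet from delimited files
#'
#' Reads headed CSV files holding haul records, 1-cm length-frequency
#' records, and individual sex-maturity-age-length key (SMALK) records.
#' Unknown columns are carried along; rows violating the type invariants
#' (and length rows referencing unknown hauls) are rejected and listed.
#'
#' @param haul_path,length_path,smalk_path CSV file paths.
#' @return A list of class `survey_tables` with elements `hauls`, `lengths`,
#'   `smalks` (tibbles) and `rejected` (table/row/reason tibble).
#' @export
read_survey_tables <- function(haul_path, length_path, smalk_path) {
  for (p in c(haul_path, length_path, smalk_path))
    if (!file.exists(p)) stop("survey table not found: ", p)
  hauls <- readr::read_csv(haul_path, show_col_types = FALSE)
  lens <- readr::read_csv(length_path, show_col_types = FALSE)
  smalks <- readr::read_csv(smalk_path, show_col_types = FALSE)
  survey_tables(hauls, lens, smalks)
}

#' Assemble and validate in-memory survey tables
#' @param hauls,lengths,smalks Data frames matching the three record types.
#' @return A `survey_tables` list; see [read_survey_tables()].
#' @export
survey_tables <- function(hauls, lengths, smalks) {
  hauls <- std_cols(tibble::as_tibble(hauls),
                    c("haul_id", "survey", "gear", "year", "season",
                      "lon", "lat", "duration"))
  lengths <- std_cols(tibble::as_tibble(lengths),
                      c("haul_id", "length_class", "sex", "count"))
  smalks <- std_cols(tibble::as_tibble(smalks),
                     c("length", "sex", "age", "mature", "region", "year",
                       "survey"))
  h <- validate_rows(hauls, haul_rules(), "hauls")
  l <- validate_rows(lengths, length_rules(), "lengths")
  s <- validate_rows(smalks, smalk_rules(), "smalks")
  orphan <- !(l$records$haul_id %in% h$records$haul_id)
  orphan_rej <- tibble::tibble(table = "lengths",
                               row = which(orphan),
                               reason = "haul_id absent from haul table")
  l$records <- l$records[!orphan, , drop = FALSE]
  l$records <- dplyr::left_join(l$records,
                                dplyr::select(h$records, "haul_id", "duration"),
                                by = "haul_id") |>
    dplyr::mutate(standardised_count =
                    standardise_cpue(.data$count, .data$duration)) |>
    dplyr::select(-"duration")
  out <- list(hauls = h$records, lengths = l$records, smalks = s$records,
              rejected = dplyr::bind_rows(h$rejected, l$rejected,
                                          orphan_rej, s$rejected))
  class(out) <- "survey_tables"
  out
}

#' @export
print.survey_tables <- function(x, ...) {
  cat(sprintf("<survey_tables> %d hauls, %d length rows, %d SMALK rows (%d rows rejected)\n",
              nrow(x$hauls), nrow(x$lengths), nrow(x$smalks), nrow(x$rejected)))
  invisible(x)
}

#' Write survey tables as headed CSV files
#' @param tables A `survey_tables` list (or list with the three tibbles).
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_survey_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(hauls = file.path(dir, "hauls.csv"),
             lengths = file.path(dir, "lengths.csv"),
             smalks = file.path(dir, "smalks.csv"))
  readr::write_csv(tables$hauls, paths["hauls"])
  readr::write_csv(dplyr::select(tables$lengths,
                                 -dplyr::any_of("standardised_count")),
                   paths["lengths"])
  readr::write_csv(tables$smalks, paths["smalks"])
  invisible(paths)
}

# ---- run configuration ----------------------------------------------------

#' Default pipeline configuration
#'
#' Scalar and short-vector settings controlling the synthetic fixture and
#' every stochastic or iterative stage of the pipeline. All random draws in a
#' run are derived from `seed`.
#'
#' @param seed Integer seed.
#' @param ... Overrides for any listed field.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    grid_nrow = 20L, grid_ncol = 30L,
    years_feb = 2009:2011, years_oct = 2011:2013,
    hauls_per_survey_year = c(SWC_IBTS = 35L, NIGFS = 30L),
    smalk_per_region_year = 120L,
    cv_iterations = 20L,
    stepwise = FALSE,
    null_truth = FALSE,
    n_ctd_stations = 50L,
    theta_grid_km = exp(seq(log(5), log(500), length.out = 8)),
    curve_mode = "cubic",
    precision_band = 0.025,
    k_s = 8L, k_te = 4L, k_cc = 6L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration as a flat key-value file
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  fmt <- function(v) {
    if (is.numeric(v)) paste(formatC(v, digits = 15, format = "g"),
                             collapse = ",")
    else paste(as.character(v), collapse = ",")
  }
  keys <- names(cfg)
  vals <- vapply(cfg, fmt, character(1))
  named <- vapply(cfg, function(v) paste(names(v), collapse = ","),
                  character(1))
  lines <- sprintf("%s = %s", keys, vals)
  lines <- c(lines, sprintf("%s.names = %s", keys[nzchar(named)],
                            named[nzchar(named)]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration written by [write_run_config()]
#' @param path File path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- grep("=", readLines(path, warn = FALSE), fixed = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  base <- default_config()
  cfg <- list()
  for (i in seq_along(keys)) {
    if (grepl("\\.names$", keys[i])) next
    parts <- strsplit(vals[i], ",")[[1]]
    num <- suppressWarnings(as.numeric(parts))
    v <- if (!anyNA(num)) num
    else if (all(parts %in% c("TRUE", "FALSE"))) as.logical(parts)
    else parts
    ref <- base[[keys[i]]]
    if (!is.null(ref) && is.integer(ref) && is.numeric(v)) v <- as.integer(v)
    cfg[[keys[i]]] <- v
  }
  for (i in grep("\\.names$", keys)) {
    key <- sub("\\.names$", "", keys[i])
    if (!is.null(cfg[[key]]))
      names(cfg[[key]]) <- strsplit(vals[i], ",")[[1]]
  }
  do.call(default_config, c(list(seed = cfg$seed %||% 1L),
                            cfg[setdiff(names(cfg), "seed")]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
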