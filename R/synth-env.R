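#' Generate a synthetic environmental stack
#'
#' Builds co-registered layers over the study extent: a smooth random
#' bathymetry deepening westward with a coastline strip on the eastern
#' edge, terrain derivatives (slope, aspect), proximity to shore, a
#' spatially autocorrelated sediment classification, and per-year/season
#' bottom temperature and salinity surfaces (smooth base field + year
#' offset + correlated noise). Random fields are a fixed low-order trend
#' plus seeded Gaussian noise passed through a Gaussian blur, so stacks are
#' cheap, smooth and exactly reproducible by seed.
#'
#' @param seed Integer seed.
#' @param shape `c(nrow, ncol)`, at least 10 x 10.
#' @param years_feb,years_oct Years for which Feb-Mar / Oct-Nov
#'   temperature and salinity surfaces are generated.
#' @param flat_depth If non-`NULL`, every sea cell takes this constant
#'   depth (m); slope is then identically zero.
#' @param monotone_lon If `TRUE`, bathymetry is the pure westward trend
#'   (no noise), so depth increases strictly with distance west in every
#'   row.
#' @return An `env_stack`: list with grid layers `depth`, `slope`,
#'   `aspect`, `prox_shore`, `sediment`, `land`, and named lists
#'   `temperature` / `salinity` keyed `"<year>_<season>"`.
#' @export
generate_environment <- function(seed, shape = c(20L, 30L),
                                 years_feb = 2009:2015,
                                 years_oct = 2011:2014,
                                 flat_depth = NULL, monotone_lon = FALSE) {
  if (any(shape < 10)) stop("shape must be at least 10 x 10")
  nr <- shape[1]; nc <- shape[2]
  withr::with_seed(as.integer(seed), {
    template <- grid_layer(matrix(0, nr, nc), name = "template")
    cc <- cell_centres(template)
    # westward-deepening trend crossing zero near the eastern edge
    trend <- 170 * (-3.55 - cc$lon) / 7
    noise <- if (monotone_lon) 0 else
      25 * blur_matrix(matrix(rnorm(nr * nc), nr, nc), sigma = 2)
    depth <- trend + noise
    land <- depth <= 0
    if (!any(land)) land[, nc] <- TRUE
    if (!any(!land)) stop("degenerate bathymetry: no sea cells")
    if (!is.null(flat_depth)) depth[] <- flat_depth
    depth[land] <- NA
    depth_g <- grid_like(template, depth, name = "depth")
    land_g <- grid_like(template, matrix(as.numeric(land), nr, nc),
                        name = "land")
    terr <- compute_slope_aspect(depth_g)
    # terrain derivatives are undefined next to land; treat as flat seabed
    terr$slope[is.na(terr$slope) & !land] <- 0
    terr$aspect[is.na(terr$aspect) & !land] <- 0
    terr$slope[land] <- NA
    terr$aspect[land] <- NA
    prox <- distance_to_shore(land_g, method = "planar")
    # sediment: blurred field cut into the five classes, rock rare
    sed_field <- blur_matrix(matrix(rnorm(nr * nc), nr, nc), sigma = 3)
    qs <- quantile(sed_field[!land], probs = c(0.30, 0.55, 0.75, 0.93))
    sed <- findInterval(sed_field, qs) + 1L
    sed_m <- matrix(sed, nr, nc)
    sed_m[land] <- NA_integer_
    sed_g <- grid_like(template, sed_m, name = "sediment")
    attr(sed_g, "levels") <- sediment_levels()
    temp_l <- list()
    sal_l <- list()
    base_t <- blur_matrix(matrix(rnorm(nr * nc), nr, nc), sigma = 3)
    base_s <- blur_matrix(matrix(rnorm(nr * nc), nr, nc), sigma = 3)
    seasons <- list(FEB_MAR = years_feb, OCT_NOV = years_oct)
    season_base <- c(FEB_MAR = 8.6, OCT_NOV = 12.4)
    for (season in names(seasons)) {
      for (yr in seasons[[season]]) {
        off_t <- 0.35 * sin(2 * pi * (yr - 2009) / 7)
        noise_t <- 0.3 * blur_matrix(matrix(rnorm(nr * nc), nr, nc), 2)
        tmp <- season_base[[season]] - 0.12 * (cc$lat - 52) +
          0.5 * base_t + off_t + noise_t
        noise_s <- 0.12 * blur_matrix(matrix(rnorm(nr * nc), nr, nc), 2)
        sal <- 34.6 - 0.1 * (cc$lon + 10) / 7 + 0.25 * base_s +
          0.05 * off_t + noise_s
        tmp[land] <- NA; sal[land] <- NA
        key <- paste(yr, season, sep = "_")
        temp_l[[key]] <- grid_like(template, tmp,
                                   name = paste0("temperature_", key))
        sal_l[[key]] <- grid_like(template, sal,
                                  name = paste0("salinity_", key))
      }
    }
    out <- list(depth = depth_g, slope = terr$slope, aspect = terr$aspect,
                prox_shore = prox, sediment = sed_g, land = land_g,
                temperature = temp_l, salinity = sal_l,
                years_feb = years_feb, years_oct = years_oct, seed = seed)
    class(out) <- "env_stack"
    out
  })
}

#' @export
print.env_stack <- function(x, ...) {
  m <- grid_meta(x$depth)
  cat(sprintf("<env_stack> %d x %d cells, %d sea / %d land; %d temperature surfaces\n",
              m$nrow, m$ncol, sum(unclass(x$land) == 0),
              sum(unclass(x$land) == 1), length(x$temperature)))
  invisible(x)
}

#' Write an environmental stack as ESRI ASCII grids
#' @param env An `env_stack`.
#' @param dir Output directory.
#' @return Vector of file paths, invisibly.
#' @export
write_env_stack <- function(env, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("depth", "slope", "aspect", "prox_shore", "sediment", "land")) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_grid(env[[nm]], p)
    paths <- c(paths, p)
  }
  for (kind in c("temperature", "salinity")) {
    for (key in names(env[[kind]])) {
      p <- file.path(dir, paste0(kind, "_", key, ".asc"))
      write_grid(env[[kind]][[key]], p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Read an environmental stack written by [write_env_stack()]
#' @param dir Directory of `.asc` files.
#' @return An `env_stack`.
#' @export
read_env_stack <- function(dir) {
  out <- list()
  for (nm in c("depth", "slope", "aspect", "prox_shore", "sediment", "land"))
    out[[nm]] <- read_grid(file.path(dir, paste0(nm, ".asc")), name = nm)
  attr(out$sediment, "levels") <- sediment_levels()
  out$temperature <- list()
  out$salinity <- list()
  for (kind in c("temperature", "salinity")) {
    files <- list.files(dir, pattern = paste0("^", kind, "_"), full.names = TRUE)
    for (f in files) {
      key <- sub(paste0("^", kind, "_"), "", sub("\\.asc$", "", basename(f)))
      out[[kind]][[key]] <- read_grid(f, name = paste0(kind, "_", key))
    }
  }
  keys <- names(out$temperature)
  out$years_feb <- sort(as.integer(sub("_.*", "", keys[grepl("FEB", keys)])))
  out$years_oct <- sort(as.integer(sub("_.*", "", keys[grepl("OCT", keys)])))
  class(out) <- "env_stack"
  out
}
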