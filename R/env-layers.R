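#' Great-circle distance in kilometres
#'
#' Haversine formula on a spherical Earth (radius 6371 km). Vectorised and
#' recycling over the longer argument pair.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in degrees.
#' @return Distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

km_per_degree <- function() 111.195 # 6371 * pi / 180

# Separable Gaussian blur with edge replication; sigma in cells.
# Used by the synthetic-environment generator to impose spatial
# autocorrelation on seeded white noise.
blur_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], half), v, rep(v[n], half))
    as.numeric(stats::filter(vp, k, sides = 2))[(half + 1):(half + n)]
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

#' Slope and aspect from a bathymetry layer
#'
#' Third-order finite differences on the 3 x 3 neighbourhood (Horn's
#' operator). Slope is `atan` of the gradient magnitude in radians; aspect
#' is the compass direction (degrees clockwise from North) towards which
#' depth increases, i.e. the downslope direction of the seabed. Flat cells
#' get aspect 0 by convention and are counted in the `n_flat` attribute.
#' Cells with any missing neighbour (incl. land) return nodata; the outer
#' ring uses edge replication.
#'
#' @param depth A `grid_layer` of depth in metres (positive down).
#' @param cell_km Optional `c(dx, dy)` cell size in km. When `NULL`, sizes
#'   are derived from the geographic cell size (dx scaled by `cos(lat)` per
#'   row).
#' @return List with `slope` (radians) and `aspect` (degrees) grid layers.
#' @export
compute_slope_aspect <- function(depth, cell_km = NULL) {
  m <- grid_meta(depth)
  z <- unclass(depth)
  nr <- m$nrow; nc <- m$ncol
  if (nr < 3 || nc < 3) stop("grid too small for terrain derivatives")
  # replicated padding
  zp <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, nc, drop = FALSE])
  sh <- function(dr, dc) zp[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  tl <- sh(0, 0); tm <- sh(0, 1); tr <- sh(0, 2)
  ml <- sh(1, 0);                 mr <- sh(1, 2)
  bl <- sh(2, 0); bm <- sh(2, 1); br <- sh(2, 2)
  if (is.null(cell_km)) {
    lat_row <- m$yll + (nr - seq_len(nr) + 0.5) * m$dy
    dx_m <- matrix(m$dx * km_per_degree() * cos(lat_row * pi / 180) * 1000,
                   nr, nc)
    dy_m <- m$dy * km_per_degree() * 1000
  } else {
    dx_m <- cell_km[1] * 1000
    dy_m <- cell_km[2] * 1000
  }
  gx <- ((tr + 2 * mr + br) - (tl + 2 * ml + bl)) / (8 * dx_m) # d depth / d east
  gy <- ((tl + 2 * tm + tr) - (bl + 2 * bm + br)) / (8 * dy_m) # d depth / d north
  slope <- atan(sqrt(gx^2 + gy^2))
  aspect <- (atan2(gx, gy) * 180 / pi) %% 360
  flat <- is.finite(slope) & slope == 0
  aspect[flat] <- 0
  out_slope <- grid_like(depth, slope, name = "slope")
  out_aspect <- grid_like(depth, aspect, name = "aspect")
  attr(out_aspect, "n_flat") <- sum(flat, na.rm = TRUE)
  list(slope = out_slope, aspect = out_aspect)
}

#' Distance from sea-cell centres to the nearest coastline
#'
#' Distance is measured to the nearest coastal land cell and reduced by half
#' a cell width, so a sea cell immediately adjacent to land is half a cell
#' width from shore. Land cells carry nodata. `planar` uses local-km
#' coordinates (adequate for the small synthetic grids); `haversine` uses
#' great-circle distances.
#'
#' @param land A `grid_layer` with 1 = land, 0 = sea.
#' @param method `"planar"` or `"haversine"`.
#' @return A `grid_layer` of distances in metres (`Inf` everywhere, flagged,
#'   when there is no land).
#' @export
distance_to_shore <- function(land, method = c("planar", "haversine")) {
  method <- match.arg(method)
  L <- unclass(land) == 1
  L[is.na(L)] <- FALSE
  m <- grid_meta(land)
  cc <- cell_centres(land)
  out <- matrix(NA_real_, m$nrow, m$ncol)
  if (!any(!L)) stop("no sea cells in land mask")
  half_w_km <- (m$dx * km_per_degree() *
                  cos(mean(range(cc$lat)) * pi / 180) +
                  m$dy * km_per_degree()) / 2 / 2
  if (!any(L)) {
    out[!L] <- Inf
    g <- grid_like(land, out, name = "prox_shore")
    attr(g, "no_land") <- TRUE
    return(g)
  }
  # coastal land cells: land with at least one 4-neighbour at sea
  sea <- !L
  nbr_sea <- matrix(FALSE, m$nrow, m$ncol)
  shift_ok <- function(mat, dr, dc) {
    res <- matrix(FALSE, nrow(mat), ncol(mat))
    rs <- seq_len(nrow(mat)); cs <- seq_len(ncol(mat))
    rfrom <- rs + dr; cfrom <- cs + dc
    okr <- rfrom >= 1 & rfrom <= nrow(mat)
    okc <- cfrom >= 1 & cfrom <= ncol(mat)
    res[rs[okr], cs[okc]] <- mat[rfrom[okr], cfrom[okc]]
    res
  }
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
    nbr_sea <- nbr_sea | shift_ok(sea, d[1], d[2])
  coast <- which(L & nbr_sea)
  if (!length(coast)) coast <- which(L)
  sea_idx <- which(sea)
  if (method == "planar") {
    lat0 <- mean(range(cc$lat))
    x <- cc$lon * km_per_degree() * cos(lat0 * pi / 180)
    y <- cc$lat * km_per_degree()
    dmin <- vapply(sea_idx, function(i)
      min(sqrt((x[i] - x[coast])^2 + (y[i] - y[coast])^2)), numeric(1))
  } else {
    dmin <- vapply(sea_idx, function(i)
      min(haversine_km(cc$lon[i], cc$lat[i], cc$lon[coast], cc$lat[coast])),
      numeric(1))
  }
  out[sea_idx] <- pmax(dmin - half_w_km, half_w_km) * 1000
  grid_like(land, out, name = "prox_shore")
}

#' Default merge of 17 substratum codes into 5 habitat-aligned classes
#'
#' Mirrors the reduction of a detailed seabed-substratum classification to
#' the five classes used for modelling (the `rock` class is excluded from
#' model domains as untrawlable).
#'
#' @return Tibble with `raw_code` (1-17) and `class`.
#' @export
default_sediment_mapping <- function() {
  tibble::tibble(
    raw_code = 1:17,
    class = c("mud_sandy_mud", "mud_sandy_mud", "mud_sandy_mud",
              "sand_muddy_sand", "sand_muddy_sand", "sand_muddy_sand",
              "sand_muddy_sand", "coarse", "coarse", "coarse", "coarse",
              "mixed", "mixed", "mixed", "rock", "rock", "rock"))
}

#' Reclassify a categorical sediment layer
#'
#' @param raw A `grid_layer` of integer substratum codes.
#' @param mapping Tibble with `raw_code` and `class` columns covering every
#'   code present.
#' @return A `grid_layer` of integer codes into [sediment_levels()], with a
#'   `levels` attribute. All-rock layers are flagged via the
#'   `empty_domain` attribute.
#' @export
reclassify_sediment <- function(raw, mapping = default_sediment_mapping()) {
  vals <- unclass(raw)
  present <- sort(unique(vals[is.finite(vals)]))
  unmapped <- setdiff(present, mapping$raw_code)
  if (length(unmapped))
    stop("unmapped sediment codes: ", paste(unmapped, collapse = ", "))
  cls <- mapping$class[match(vals, mapping$raw_code)]
  code <- match(cls, sediment_levels())
  out <- grid_like(raw, matrix(code, nrow(raw), ncol(raw)), name = "sediment")
  attr(out, "levels") <- sediment_levels()
  nonrock <- sum(code != match("rock", sediment_levels()), na.rm = TRUE)
  attr(out, "empty_domain") <- nonrock == 0
  out
}

#' Keep the closest-to-bottom CTD record per station
#'
#' For every station x year x season group, retains the record with the
#' highest pressure (deepest measurement). Ties keep the last occurrence
#' and are counted in the `n_ties` attribute.
#'
#' @param casts Tibble with `station_id`, `lon`, `lat`, `year`, `season`,
#'   `pressure`, `temperature`, `salinity`.
#' @return Tibble with one row per station group.
#' @export
select_bottom_ctd <- function(casts) {
  casts <- tibble::as_tibble(casts)
  if (any(!is.finite(casts$pressure) | casts$pressure < 0))
    stop("pressure must be finite and non-negative")
  grp <- dplyr::group_by(casts, .data$station_id, .data$year, .data$season)
  picked <- dplyr::slice(grp, {
    p <- dplyr::pick("pressure")$pressure
    max(which(p == max(p)))
  })
  n_ties <- sum(dplyr::summarise(
    grp, ties = sum(.data$pressure == max(.data$pressure)) > 1,
    .groups = "drop")$ties)
  out <- dplyr::ungroup(picked)
  attr(out, "n_ties") <- n_ties
  out
}

#' Gaussian-kernel (Nadaraya-Watson) surface from point casts
#'
#' Estimates `sum(w_i y_i) / sum(w_i)` at every grid cell with weights
#' `w_i = exp(-d_i^2 / (2 theta^2))`, distances in km (haversine). Cells
#' where the weight sum underflows take the nearest cast's value and are
#' counted in the `n_underflow` attribute.
#'
#' @param casts Tibble with `lon`, `lat` and the value column.
#' @param grid A `grid_layer` template (values ignored; nodata cells in the
#'   template stay nodata).
#' @param theta Bandwidth in km (> 0).
#' @param value_col Name of the value column, default `"temperature"`.
#' @return A `grid_layer`.
#' @export
kernel_smooth <- function(casts, grid, theta, value_col = "temperature") {
  stopifnot(theta > 0, nrow(casts) >= 1)
  y <- casts[[value_col]]
  cc <- cell_centres(grid)
  keep <- !is.na(unclass(grid))
  idx <- which(keep)
  pred <- nadaraya_watson(cc$lon[idx], cc$lat[idx],
                          casts$lon, casts$lat, y, theta)
  out <- matrix(NA_real_, nrow(grid), ncol(grid))
  out[idx] <- pred$fit
  g <- grid_like(grid, out, name = value_col)
  attr(g, "theta_km") <- theta
  attr(g, "kernel") <- "gaussian exp(-d^2/(2 theta^2)), d in km"
  attr(g, "n_underflow") <- pred$n_underflow
  g
}

nadaraya_watson <- function(lon0, lat0, lon, lat, y, theta) {
  n0 <- length(lon0)
  fit <- numeric(n0)
  n_underflow <- 0L
  for (i in seq_len(n0)) {
    d <- haversine_km(lon0[i], lat0[i], lon, lat)
    w <- exp(-d^2 / (2 * theta^2))
    sw <- sum(w)
    if (sw < 1e-300) {
      fit[i] <- y[which.min(d)]
      n_underflow <- n_underflow + 1L
    } else fit[i] <- sum(w * y) / sw
  }
  list(fit = fit, n_underflow = n_underflow)
}

#' Leave-one-out bandwidth selection for the Gaussian kernel smoother
#'
#' Computes the exact leave-one-out cross-validation score
#' `sum_i (y_i - yhat_{-i}(x_i))^2` on a bandwidth grid and returns the
#' minimiser (ties take the smaller bandwidth). Degenerate inputs with all
#' casts co-located are flagged and return the mid-grid bandwidth.
#'
#' @param casts Tibble with `lon`, `lat` and the value column.
#' @param theta_grid Candidate bandwidths in km.
#' @param value_col Value column name.
#' @return A `kernel_fit` list: `theta`, `score`, `grid` (tibble of theta
#'   and LOOCV score), `degenerate`.
#' @export
select_bandwidth_loocv <- function(casts, theta_grid,
                                   value_col = "temperature") {
  stopifnot(nrow(casts) >= 3, all(theta_grid > 0))
  theta_grid <- sort(theta_grid)
  y <- casts[[value_col]]
  n <- nrow(casts)
  dmat <- outer(seq_len(n), seq_len(n), function(i, j)
    haversine_km(casts$lon[i], casts$lat[i], casts$lon[j], casts$lat[j]))
  degenerate <- max(dmat) == 0
  scores <- vapply(theta_grid, function(th) {
    w <- exp(-dmat^2 / (2 * th^2))
    diag(w) <- 0
    sw <- rowSums(w)
    pred <- ifelse(sw < 1e-300,
                   vapply(seq_len(n), function(i) {
                     d <- dmat[i, ]; d[i] <- Inf; y[which.min(d)]
                   }, numeric(1)),
                   as.vector(w %*% y) / sw)
    sum((y - pred)^2)
  }, numeric(1))
  best <- if (degenerate) ceiling(length(theta_grid) / 2)
  else which.min(scores) # which.min takes the first (smallest theta) on ties
  out <- list(theta = theta_grid[best], score = scores[best],
              grid = tibble::tibble(theta = theta_grid, score = scores),
              degenerate = degenerate)
  class(out) <- "kernel_fit"
  out
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf("<kernel_fit> theta = %.3g km (LOOCV SSE %.4g over %d candidates)%s\n",
              x$theta, x$score, nrow(x$grid),
              if (x$degenerate) " [degenerate: co-located casts]" else ""))
  invisible(x)
}

#' Extract model covariates at haul positions
#'
#' Nearest-cell lookup of the static layers plus the year/season-matched
#' temperature and salinity surfaces. Hauls that fall off-grid, on land or
#' nodata cells, or on rock sediment are flagged invalid with a reason and
#' are excluded from modelling.
#'
#' @param env An `env_stack`.
#' @param hauls Haul tibble (`haul_id`, `survey`, `year`, `season`, `lon`,
#'   `lat`, ...).
#' @return Tibble with one row per haul: covariates, `valid`, `reason`.
#' @export
extract_at_hauls <- function(env, hauls) {
  idx <- grid_index(env$depth, hauls$lon, hauls$lat)
  n <- nrow(hauls)
  pull <- function(g, rows, cols) {
    v <- rep(NA_real_, length(rows))
    ok <- !is.na(rows)
    v[ok] <- unclass(g)[cbind(rows[ok], cols[ok])]
    v
  }
  depth <- pull(env$depth, idx$row, idx$col)
  slope <- pull(env$slope, idx$row, idx$col)
  aspect <- pull(env$aspect, idx$row, idx$col)
  prox <- pull(env$prox_shore, idx$row, idx$col)
  sed_code <- pull(env$sediment, idx$row, idx$col)
  sed <- sediment_levels()[sed_code]
  key <- paste(hauls$year, hauls$season, sep = "_")
  temp <- sal <- rep(NA_real_, n)
  for (k in unique(key)) {
    sel <- key == k
    tg <- env$temperature[[k]]
    sg <- env$salinity[[k]]
    if (!is.null(tg)) temp[sel] <- pull(tg, idx$row[sel], idx$col[sel])
    if (!is.null(sg)) sal[sel] <- pull(sg, idx$row[sel], idx$col[sel])
  }
  reason <- rep(NA_character_, n)
  reason[is.na(idx$row)] <- "off grid"
  reason[is.na(reason) & is.na(depth)] <- "land or nodata cell"
  reason[is.na(reason) & !is.na(sed) & sed == "rock"] <- "rock sediment"
  reason[is.na(reason) & (is.na(temp) | is.na(sal))] <-
    "no temperature/salinity layer for year-season"
  out <- tibble::tibble(
    haul_id = hauls$haul_id, survey = hauls$survey, gear = hauls$gear,
    year = hauls$year, season = hauls$season,
    lon = hauls$lon, lat = hauls$lat,
    depth = depth, slope = slope, aspect = aspect, prox_shore = prox,
    sediment = sed, temperature = temp, salinity = sal,
    valid = is.na(reason), reason = reason)
  attr(out, "n_excluded") <- sum(!out$valid)
  out
}

#' Build cell-level covariate table for prediction
#'
#' Companion to [extract_at_hauls()] for whole-grid prediction: one row per
#' modelling-domain cell (sea, non-rock, all covariates finite) for a given
#' year and season.
#'
#' @param env An `env_stack`.
#' @param year,season Which temperature/salinity surfaces to use.
#' @return Tibble with `row`, `col`, `lon`, `lat` and the covariates.
#' @export
grid_covariates <- function(env, year, season) {
  cc <- cell_centres(env$depth)
  key <- paste(year, season, sep = "_")
  tg <- env$temperature[[key]]
  sg <- env$salinity[[key]]
  if (is.null(tg) || is.null(sg))
    stop("no temperature/salinity layers for ", key)
  nr <- nrow(env$depth); nc <- ncol(env$depth)
  df <- tibble::tibble(
    row = rep(seq_len(nr), nc), col = rep(seq_len(nc), each = nr),
    lon = as.vector(cc$lon), lat = as.vector(cc$lat),
    depth = as.vector(unclass(env$depth)),
    slope = as.vector(unclass(env$slope)),
    aspect = as.vector(unclass(env$aspect)),
    prox_shore = as.vector(unclass(env$prox_shore)),
    sediment = sediment_levels()[as.vector(unclass(env$sediment))],
    temperature = as.vector(unclass(tg)),
    salinity = as.vector(unclass(sg)))
  dplyr::filter(df, !is.na(.data$depth), !is.na(.data$sediment),
                .data$sediment != "rock", !is.na(.data$temperature),
                !is.na(.data$salinity), !is.na(.data$slope),
                !is.na(.data$prox_shore))
}
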