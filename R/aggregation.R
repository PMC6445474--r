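#' Geostatistical aggregation curve
#'
#' Ranks occupied units (hauls or grid cells) by density from maximum to
#' minimum and accumulates the proportion of total abundance (`y`) against
#' the proportion of total occupied area (`x`), starting at (0, 0). Zeros
#' and missing densities are excluded from the occupied set. Ties rank
#' stably by unit order.
#'
#' @param densities Unit densities (CPUE per unit area).
#' @param areas Unit areas (default equal).
#' @return An `aggregation_curve`: tibble of `x`, `y`, `density` per ranked
#'   unit (with the (0,0) anchor), with the ranked densities as attributes.
#' @export
build_curve <- function(densities, areas = 1) {
  areas <- rep_len(areas, length(densities))
  keep <- !is.na(densities) & densities > 0
  if (sum(keep) < 2)
    stop("aggregation curve needs at least 2 occupied units")
  d <- densities[keep]
  a <- areas[keep]
  ord <- order(-d) # stable for ties
  d <- d[ord]; a <- a[ord]
  x <- cumsum(a) / sum(a)
  y <- cumsum(d * a) / sum(d * a)
  out <- tibble::tibble(x = c(0, x), y = c(0, y),
                        density = c(NA_real_, d))
  class(out) <- c("aggregation_curve", class(out))
  attr(out, "densities") <- d
  attr(out, "areas") <- a
  out
}

#' Least-squares cubic on the transition window of an aggregation curve
#'
#' The transition phase is taken as the curve points whose local
#' central-difference slope lies in `[1/3, 3]` (the window bracketing
#' slope 1); when fewer than 4 points qualify the window is widened
#' symmetrically until 4 are included. Returns the raw-polynomial
#' coefficients of `y = a x^3 + b x^2 + c x + d`.
#'
#' @param curve An `aggregation_curve`.
#' @return List with `coefficients` (d, c, b, a order as intercept..cubic),
#'   `window` (row indices used), `degenerate` flag.
#' @export
fit_transition_cubic <- function(curve) {
  x <- curve$x; y <- curve$y
  n <- length(x)
  if (n < 4) stop("need at least 4 curve points for the cubic")
  slope <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    slope[i] <- (y[hi] - y[lo]) / (x[hi] - x[lo])
  }
  inside <- which(is.finite(slope) & slope >= 1 / 3 & slope <= 3)
  if (length(inside) < 4) {
    centre <- if (length(inside)) round(mean(range(inside)))
    else which.min(abs(slope - 1))
    half <- 2L
    repeat {
      inside <- seq(max(1, centre - half), min(n, centre + half))
      if (length(inside) >= 4 || length(inside) == n) break
      half <- half + 1L
    }
  }
  window <- seq(min(inside), max(inside))
  xs <- x[window]; ys <- y[window]
  degenerate <- length(unique(xs)) < 4
  if (degenerate)
    return(list(coefficients = c(0, 1, 0, 0), window = window,
                degenerate = TRUE))
  fit <- stats::lm(ys ~ xs + I(xs^2) + I(xs^3))
  co <- coef(fit)
  co[is.na(co)] <- 0
  list(coefficients = unname(co), window = window, degenerate = FALSE)
}

# density of the ranked step curve at cumulative-area position x,
# linearly interpolated between the bracketing units' densities
density_at_x <- function(curve, xstar) {
  d <- attr(curve, "densities")
  a <- attr(curve, "areas")
  xk <- cumsum(a) / sum(a)
  xm <- xk - a / sum(a) / 2 # unit midpoints in cumulative-area coordinates
  if (xstar <= xm[1]) return(d[1])
  if (xstar >= xm[length(xm)]) return(d[length(d)])
  stats::approx(xm, d, xout = xstar)$y
}

#' Slope-1 tangent threshold of an aggregation curve
#'
#' Fits the transition cubic and solves `3 a x^2 + 2 b x + c = 1` for the
#' tangency point, keeping the real root in `[0, 1]` on the concave branch
#' (`6 a x + 2 b <= 0`); the threshold density `z*` is the ranked-unit
#' density at cumulative-area position `x*` (interpolated). With
#' `mode = "empirical"` (or as fallback when no valid root exists) the
#' tangency is placed where the empirical segment slope first drops below
#' 1 — for equal-area units that is exactly where density falls below the
#' mean occupied-unit density. Uniform curves (no slope-1 crossing) are
#' degenerate: everything is classified dispersed.
#'
#' @param curve An `aggregation_curve`.
#' @param mode `"cubic"` (default) or `"empirical"`.
#' @return List with `x_star`, `y_star`, `z_star`, `mode` (the mode
#'   actually used) and `degenerate`.
#' @export
tangent_threshold <- function(curve, mode = c("cubic", "empirical")) {
  mode <- match.arg(mode)
  d <- attr(curve, "densities")
  a <- attr(curve, "areas")
  seg_slope <- diff(curve$y) / diff(curve$x)
  if (max(d) / min(d) < 1 + 1e-10) {
    # uniform density: the whole curve is the diagonal, no interior tangent
    return(list(x_star = NA_real_, y_star = NA_real_, z_star = Inf,
                mode = "degenerate", degenerate = TRUE))
  }
  empirical <- function() {
    k <- which(seg_slope < 1)[1]
    if (is.na(k))
      return(list(x_star = NA_real_, y_star = NA_real_, z_star = Inf,
                  mode = "degenerate", degenerate = TRUE))
    # threshold sits at the boundary above unit k; ties never split because
    # the upper neighbour's density is used
    list(x_star = curve$x[k], y_star = curve$y[k], z_star = d[k],
         mode = "empirical", degenerate = FALSE)
  }
  if (mode == "empirical") return(empirical())
  cub <- fit_transition_cubic(curve)
  co <- cub$coefficients # intercept, x, x^2, x^3
  cc <- co[2]; bb <- co[3]; aa <- co[4]
  roots <- if (abs(aa) > 1e-12) {
    disc <- (2 * bb)^2 - 4 * (3 * aa) * (cc - 1)
    if (disc < 0) numeric(0)
    else (-2 * bb + c(-1, 1) * sqrt(disc)) / (2 * 3 * aa)
  } else if (abs(bb) > 1e-12) {
    (1 - cc) / (2 * bb)
  } else numeric(0)
  roots <- roots[roots >= 0 & roots <= 1]
  roots <- roots[6 * aa * roots + 2 * bb <= 1e-8]
  if (cub$degenerate || !length(roots)) return(empirical())
  x_star <- roots[1]
  y_star <- sum(co * x_star^(0:3))
  list(x_star = x_star, y_star = min(max(y_star, 0), 1),
       z_star = density_at_x(curve, x_star), mode = "cubic",
       degenerate = FALSE)
}

#' Classify occupied cells as aggregated or dispersed
#'
#' Occupied cells with density strictly above the threshold become 1
#' (aggregated), the rest 0 (dispersed); unoccupied/nodata cells stay
#' nodata.
#'
#' @param density A `grid_layer` of predicted densities (or numeric
#'   vector).
#' @param z_star Threshold density.
#' @return A `grid_layer` (or vector) of 0/1.
#' @export
classify_cells <- function(density, z_star) {
  if (!is.finite(z_star) && !is.infinite(z_star))
    stop("threshold must be finite or Inf (degenerate)")
  v <- unclass(density)
  occupied <- !is.na(v) & v > 0
  out <- ifelse(occupied, as.numeric(v > z_star), NA_real_)
  if (inherits(density, "grid_layer")) {
    g <- grid_like(density, matrix(out, nrow(density), ncol(density)),
                   name = "aggregated")
    attr(g, "z_star") <- z_star
    g
  } else out
}

#' Multi-year persistence of aggregations
#'
#' Cellwise sum of per-year binary aggregation maps; a cell is nodata only
#' when nodata in every year. Values are bounded by the number of years.
#'
#' @param classified List of co-registered `grid_layer`s (one per year).
#' @return A `grid_layer` of integer persistence counts.
#' @export
persistence <- function(classified) {
  stopifnot(length(classified) >= 1)
  ref <- classified[[1]]
  for (g in classified[-1])
    if (!same_extent(ref, g)) stop("classified grids are not co-registered")
  arr <- vapply(classified, function(g) unclass(g),
                matrix(0, nrow(ref), ncol(ref)))
  total <- apply(arr, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE))
  g <- grid_like(ref, total, name = "persistence")
  attr(g, "n_years") <- length(classified)
  g
}

#' Precision of the aggregated/dispersed classification
#'
#' Percentage of occupied cells whose cumulative-abundance position on the
#' ranked density distribution lies outside the error band around the
#' classification threshold (band of `2 * band`, default 0.025 above and
#' below).
#'
#' @param densities Occupied-unit densities.
#' @param z_star Threshold density.
#' @param band Half-width of the error band on the cumulative-abundance
#'   axis.
#' @return Percentage in `[0, 100]`.
#' @export
classification_precision <- function(densities, z_star, band = 0.025) {
  curve <- build_curve(densities)
  q <- curve$y[-1] # cumulative-abundance position of each ranked cell
  d <- attr(curve, "densities")
  y_star <- if (!is.finite(z_star)) 1 else {
    agg <- d > z_star
    if (!any(agg)) 0 else max(q[agg])
  }
  100 * mean(abs(q - y_star) > band)
}

#' Share of abundance in a given share of occupied area
#'
#' Reads the aggregation curve at an area proportion (e.g. 0.20 to report
#' the percentage of fish in 20% of the occupied area).
#'
#' @param curve An `aggregation_curve`.
#' @param area_prop Area proportion in (0, 1].
#' @return Abundance proportion.
#' @export
abundance_share <- function(curve, area_prop = 0.2) {
  stats::approx(curve$x, curve$y, xout = area_prop, rule = 2)$y
}

#' Plot an aggregation curve with its tangent point
#' @param object An `aggregation_curve`.
#' @param threshold Optional result of [tangent_threshold()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aggregation_curve <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Proportion of occupied area",
                  y = "Cumulative proportion of abundance") +
    ggplot2::theme_minimal()
  if (!is.null(threshold) && !threshold$degenerate)
    p <- p + ggplot2::annotate("point", x = threshold$x_star,
                               y = threshold$y_star, colour = "firebrick",
                               size = 2)
  p
}
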