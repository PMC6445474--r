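#' Rectangular raster layer on a lon/lat extent
#'
#' A `grid_layer` is a plain numeric matrix (row 1 = northernmost row,
#' column 1 = westernmost column) carrying its georeferencing as attributes:
#' lower-left corner (`xll`, `yll` in degrees), cell sizes `dx`/`dy`
#' (degrees; they may differ, as in equal-area study grids), and a name.
#' Missing values are `NA` in memory and a `NODATA_value` on disk.
#'
#' @param values Numeric matrix, row 1 = north.
#' @param xll,yll Lower-left corner of the extent (degrees).
#' @param dx,dy Cell size in degrees along longitude / latitude.
#' @param name Layer name.
#' @return A `grid_layer` object.
#' @export
grid_layer <- function(values, xll = -10, yll = 52, dx = NULL, dy = NULL,
                       name = "layer") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("grid values must be numeric")
  if (is.null(dx)) dx <- 7 / ncol(values)
  if (is.null(dy)) dy <- 7 / nrow(values)
  if (dx <= 0 || dy <= 0) stop("cell sizes must be positive")
  structure(values,
            xll = xll, yll = yll, dx = dx, dy = dy, name = name,
            class = c("grid_layer", "matrix", "array"))
}

grid_meta <- function(g) {
  list(xll = attr(g, "xll"), yll = attr(g, "yll"),
       dx = attr(g, "dx"), dy = attr(g, "dy"),
       nrow = nrow(g), ncol = ncol(g), name = attr(g, "name"))
}

#' Replace the values of a grid layer, keeping its georeferencing
#' @param g A `grid_layer` template.
#' @param values Matrix of the same shape.
#' @param name Optional new name.
#' @return A `grid_layer`.
#' @export
grid_like <- function(g, values, name = attr(g, "name")) {
  stopifnot(all(dim(values) == dim(g)))
  grid_layer(values, xll = attr(g, "xll"), yll = attr(g, "yll"),
             dx = attr(g, "dx"), dy = attr(g, "dy"), name = name)
}

same_extent <- function(a, b) {
  ma <- grid_meta(a); mb <- grid_meta(b)
  isTRUE(all.equal(unlist(ma[c("xll", "yll", "dx", "dy")]),
                   unlist(mb[c("xll", "yll", "dx", "dy")]), tolerance = 1e-9)) &&
    ma$nrow == mb$nrow && ma$ncol == mb$ncol
}

#' Longitude and latitude of every cell centre
#' @param g A `grid_layer`.
#' @return List with matrices `lon` and `lat` of the grid's shape.
#' @export
cell_centres <- function(g) {
  m <- grid_meta(g)
  lon <- m$xll + (seq_len(m$ncol) - 0.5) * m$dx
  lat <- m$yll + (m$nrow - seq_len(m$nrow) + 0.5) * m$dy
  list(lon = matrix(lon, m$nrow, m$ncol, byrow = TRUE),
       lat = matrix(lat, m$nrow, m$ncol))
}

#' Row/column index of the cell containing each point
#'
#' Points outside the extent get `NA`. Points exactly on an interior cell
#' boundary fall in the northern/western cell, matching the convention used
#' for region assignment.
#'
#' @param g A `grid_layer`.
#' @param lon,lat Point coordinates (degrees).
#' @return A tibble with columns `row`, `col`.
#' @export
grid_index <- function(g, lon, lat) {
  m <- grid_meta(g)
  xmax <- m$xll + m$ncol * m$dx
  ymax <- m$yll + m$nrow * m$dy
  col <- ceiling((lon - m$xll) / m$dx)
  col[lon == m$xll] <- 1L
  row <- ceiling((ymax - lat) / m$dy)
  row[lat == ymax] <- 1L
  bad <- lon < m$xll | lon > xmax | lat < m$yll | lat > ymax |
    !is.finite(lon) | !is.finite(lat)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' @export
print.grid_layer <- function(x, ...) {
  m <- grid_meta(x)
  cat(sprintf("<grid_layer '%s'> %d x %d cells, dx=%.5g dy=%.5g, origin (%.4g, %.4g)\n",
              m$name, m$nrow, m$ncol, m$dx, m$dy, m$xll, m$yll))
  cat(sprintf("  values: %d finite, %d nodata, range [%.4g, %.4g]\n",
              sum(is.finite(x)), sum(is.na(x)),
              suppressWarnings(min(x, na.rm = TRUE)),
              suppressWarnings(max(x, na.rm = TRUE))))
  invisible(x)
}

#' Tidy a grid layer into a lon/lat/value tibble
#' @param x A `grid_layer`.
#' @param ... Unused.
#' @return Tibble with `lon`, `lat`, `value` (nodata cells included as `NA`).
#' @export
as_tibble.grid_layer <- function(x, ...) {
  cc <- cell_centres(x)
  tibble::tibble(lon = as.vector(cc$lon), lat = as.vector(cc$lat),
                 value = as.vector(unclass(x)))
}

#' Plot a grid layer as a raster map
#' @param object A `grid_layer`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grid_layer <- function(object, ...) {
  df <- as_tibble.grid_layer(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = attr(object, "name"), x = "Longitude",
                  y = "Latitude", fill = NULL) +
    ggplot2::theme_minimal()
}

# ---- ESRI ASCII grid I/O --------------------------------------------------

#' Read an ESRI ASCII grid file
#'
#' Accepts the classic `cellsize` header and the `dx`/`dy` extension used for
#' non-square cells. `NODATA_value` cells become `NA`.
#'
#' @param path File path.
#' @param name Layer name to attach (defaults to the file stem).
#' @return A `grid_layer`.
#' @export
read_grid <- function(path, name = NULL) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                    "cellsize", "dx", "dy", "nodata_value")) break
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner")
  if (!all(need %in% names(hdr))) stop("malformed ESRI ASCII header in ", path)
  if (!is.null(hdr$cellsize)) {
    dx <- dy <- hdr$cellsize
  } else if (!is.null(hdr$dx) && !is.null(hdr$dy)) {
    dx <- hdr$dx; dy <- hdr$dy
  } else stop("header lacks cellsize (or dx/dy) in ", path)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("grid body has ", length(vals), " values; header promises ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  grid_layer(m, xll = hdr$xllcorner, yll = hdr$yllcorner, dx = dx, dy = dy,
             name = name)
}

#' Write a grid layer as an ESRI ASCII file
#' @param g A `grid_layer`.
#' @param path Output file path.
#' @param digits Significant digits kept for finite values.
#' @return `path`, invisibly.
#' @export
write_grid <- function(g, path, digits = 10) {
  m <- grid_meta(g)
  hdr <- c(sprintf("ncols %d", m$ncol), sprintf("nrows %d", m$nrow),
           sprintf("xllcorner %.10g", m$xll), sprintf("yllcorner %.10g", m$yll))
  hdr <- c(hdr, if (isTRUE(all.equal(m$dx, m$dy, tolerance = 1e-12))) {
    sprintf("cellsize %.12g", m$dx)
  } else {
    c(sprintf("dx %.12g", m$dx), sprintf("dy %.12g", m$dy))
  })
  hdr <- c(hdr, "NODATA_value -9999")
  vals <- unclass(g)
  vals[is.na(vals)] <- -9999
  body <- apply(vals, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
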