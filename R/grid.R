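#' Aligned covariate grid
#'
#' A lightweight raster stack: named layers as numeric matrices on one shared
#' WGS84 lon/lat extent.  `NA` cells are nodata and are propagated, never
#' silently zero-filled.  Row 1 is the northernmost row; column 1 the
#' westernmost column.  A point belongs to the cell whose footprint contains
#' it under half-open membership `[west, east) x (south, north]`, which makes
#' boundary behaviour exactly testable.
#'
#' @param layers named list of numeric matrices with identical dimensions.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in decimal degrees.
#' @return object of class `covariate_grid`.
#' @export
#' @examples
#' g <- covariate_grid(list(soc = matrix(1:6, 2, 3)), c(0, 3, 0, 2))
#' grid_extract(g, lon = 0.5, lat = 1.5)
covariate_grid <- function(layers, extent) {
  if (!is.list(layers) || is.null(names(layers)) || any(names(layers) == ""))
    stop("`layers` must be a named list of matrices")
  dims <- unique(lapply(layers, dim))
  if (length(dims) != 1L)
    stop("all layers must share the same dimensions")
  if (length(extent) != 4L || extent[1] >= extent[2] || extent[3] >= extent[4])
    stop("`extent` must be c(xmin, xmax, ymin, ymax) with xmin < xmax, ymin < ymax")
  structure(list(layers = lapply(layers, as.matrix),
                 extent = as.numeric(extent),
                 crs = "WGS84"),
            class = "covariate_grid")
}

#' @export
print.covariate_grid <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("covariate_grid: %d layer(s), %d x %d cells\n",
              length(x$layers), d[1], d[2]))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g] (%s)\n",
              x$extent[1], x$extent[2], x$extent[3], x$extent[4], x$crs))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

grid_dim <- function(grid) dim(grid$layers[[1]])

# Row/column of the cell containing each point; NA when outside the extent.
# Membership is [west, east) in lon and (south, north] in lat.
cell_index <- function(grid, lon, lat) {
  d <- grid_dim(grid)
  e <- grid$extent
  dx <- (e[2] - e[1]) / d[2]
  dy <- (e[4] - e[3]) / d[1]
  col <- floor((lon - e[1]) / dx) + 1
  row <- floor((e[4] - lat) / dy) + 1
  row[!is.na(lat) & lat == e[4]] <- 1          # north edge of the top row
  out <- is.na(lon) | is.na(lat) |
    col < 1 | col > d[2] | row < 1 | row > d[1]
  col[out] <- NA_integer_
  row[out] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract layer values at point locations
#'
#' Nearest-cell lookup (the value of the cell containing the point), no
#' interpolation.  Points outside the extent or over nodata yield `NA`.
#'
#' @param grid a [covariate_grid()].
#' @param lon,lat point coordinates, decimal degrees WGS84.
#' @param layers layer names to extract (default all).
#' @return data frame, one column per requested layer.
#' @export
grid_extract <- function(grid, lon, lat, layers = names(grid$layers)) {
  stopifnot(inherits(grid, "covariate_grid"))
  unknown <- setdiff(layers, names(grid$layers))
  if (length(unknown))
    stop("unknown layer(s): ", paste(unknown, collapse = ", "))
  ij <- cell_index(grid, lon, lat)
  idx <- cbind(ij$row, ij$col)
  out <- lapply(grid$layers[layers], function(m) {
    v <- rep(NA_real_, nrow(ij))
    ok <- !is.na(ij$row)
    v[ok] <- m[idx[ok, , drop = FALSE]]
    v
  })
  as.data.frame(out)
}

#' Write a covariate grid to a directory
#'
#' One tab-separated matrix per layer plus a `manifest.yaml` recording the
#' extent, dimensions and layer files.  Values round-trip exactly through
#' [read_covariate_grid()] (full double precision, `NA` for nodata).
#'
#' @param grid a [covariate_grid()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_covariate_grid <- function(grid, dir) {
  stopifnot(inherits(grid, "covariate_grid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- grid_dim(grid)
  files <- stats::setNames(paste0(names(grid$layers), ".tsv"),
                           names(grid$layers))
  for (nm in names(grid$layers)) {
    m <- format(grid$layers[[nm]], digits = 17, trim = TRUE,
                scientific = TRUE)
    utils::write.table(m, file.path(dir, files[[nm]]),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  manifest <- list(class = "covariate_grid", crs = grid$crs,
                   nrow = d[1], ncol = d[2],
                   extent = as.list(stats::setNames(grid$extent,
                     c("xmin", "xmax", "ymin", "ymax"))),
                   nodata = "NA",
                   layers = as.list(files))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a covariate grid written by [write_covariate_grid()]
#'
#' @param dir directory containing `manifest.yaml` and the layer files.
#' @return a [covariate_grid()].
#' @export
read_covariate_grid <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  layers <- lapply(manifest$layers, function(f) {
    m <- as.matrix(utils::read.table(file.path(dir, f), sep = "\t",
                                     header = FALSE,
                                     colClasses = "numeric"))
    dimnames(m) <- NULL
    stopifnot(nrow(m) == manifest$nrow, ncol(m) == manifest$ncol)
    m
  })
  covariate_grid(layers, unlist(manifest$extent[c("xmin", "xmax",
                                                  "ymin", "ymax")]))
}
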