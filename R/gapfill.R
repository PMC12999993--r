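#' Fill missing observation fields from gridded covariate layers
#'
#' Looks up, for each requested field, the value of the grid cell containing
#' each site (nearest-cell, no interpolation) and fills only values that are
#' missing; measured values are never overwritten.  Per-field provenance is
#' recorded in `<field>_src` columns with values `"measured"`,
#' `"gap_filled"` or `"missing"`, and a fill log (attribute `"gapfill_log"`)
#' codes why a missing value stayed missing (`"nodata"` for a masked cell,
#' `"out_of_extent"` for a point outside the grid).
#'
#' @param obs observation table with `latitude`/`longitude` columns
#'   (decimal degrees WGS84).
#' @param grids a [covariate_grid()] whose layers include every requested
#'   field.
#' @param fields fields to fill (default: every grid layer present in `obs`).
#' @return `obs` with filled values and `<field>_src` provenance columns;
#'   attribute `"gapfill_log"` holds the fill log.
#' @export
fill_from_grids <- function(obs, grids,
                            fields = intersect(names(grids$layers),
                                               names(obs))) {
  stopifnot(is.data.frame(obs), inherits(grids, "covariate_grid"))
  if (any(!is.na(obs$latitude) & abs(obs$latitude) > 90) ||
      any(!is.na(obs$longitude) & abs(obs$longitude) > 180))
    stop("coordinates outside WGS84 bounds")
  unknown <- setdiff(fields, names(grids$layers))
  if (length(unknown))
    stop("requested field(s) without a grid layer: ",
         paste(unknown, collapse = ", "))
  unknown <- setdiff(fields, names(obs))
  if (length(unknown))
    stop("requested field(s) not in the observation table: ",
         paste(unknown, collapse = ", "))

  vals <- grid_extract(grids, obs$longitude, obs$latitude, fields)
  in_extent <- !is.na(cell_index(grids, obs$longitude, obs$latitude)$row)
  log <- data.frame(row = integer(), field = character(), code = character(),
                    stringsAsFactors = FALSE)
  for (f in fields) {
    src <- ifelse(is.na(obs[[f]]), "missing", "measured")
    gap <- which(is.na(obs[[f]]))
    for (i in gap) {
      if (!in_extent[i]) {
        code <- "out_of_extent"
      } else if (is.na(vals[[f]][i])) {
        code <- "nodata"
      } else {
        obs[[f]][i] <- vals[[f]][i]
        src[i] <- "gap_filled"
        code <- "filled"
      }
      log <- rbind(log, data.frame(row = i, field = f, code = code,
                                   stringsAsFactors = FALSE))
    }
    obs[[paste0(f, "_src")]] <- src
  }
  attr(obs, "gapfill_log") <- log
  obs
}

#' Assign biome categories from stacked categorical layers
#'
#' The biome stack carries three source layers on one grid: a `cropland`
#' indicator, a `wetland` indicator (values 1 where the class applies, 0 or
#' nodata elsewhere) and a `vegetation` layer of integer codes for the
#' remaining nine biomes.  Where several sources claim a cell the precedence
#' is cropland > wetland > vegetation, mirroring the order in which the
#' sources are listed.  Nodata in all sources yields `NA` (unclassified),
#' excluded from biome-level summaries.
#'
#' @param lat,lon site coordinates, decimal degrees WGS84.
#' @param biome_stack a [covariate_grid()] with layers `cropland`,
#'   `wetland` and `vegetation`.
#' @param codebook named integer vector mapping vegetation codes to biome
#'   names; the default numbers the nine non-cropland/wetland categories of
#'   [biome_levels()] in order.
#' @return character vector of biome names (`NA` = unclassified).
#' @export
assign_biome <- function(lat, lon, biome_stack,
                         codebook = default_vegetation_codebook()) {
  stopifnot(inherits(biome_stack, "covariate_grid"))
  need <- c("cropland", "wetland", "vegetation")
  if (!all(need %in% names(biome_stack$layers)))
    stop("biome stack must carry layers: ", paste(need, collapse = ", "))
  v <- grid_extract(biome_stack, lon, lat, need)
  out <- rep(NA_character_, length(lat))
  veg_ok <- !is.na(v$vegetation) & v$vegetation %in% codebook
  out[veg_ok] <- names(codebook)[match(v$vegetation[veg_ok], codebook)]
  out[!is.na(v$wetland) & v$wetland == 1] <- "wetland"
  out[!is.na(v$cropland) & v$cropland == 1] <- "cropland"
  out
}

#' Default vegetation-layer codebook
#'
#' Integer codes 1..9 for the nine biomes not covered by the cropland and
#' wetland source layers, in [biome_levels()] order.
#'
#' @return named integer vector.
#' @export
default_vegetation_codebook <- function() {
  veg <- setdiff(biome_levels(), c("cropland", "wetland"))
  stats::setNames(seq_along(veg), veg)
}
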