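#' In-memory single-band rasters
#'
#' A lightweight raster container: an integer matrix of cell codes plus a
#' geotransform (lower-left corner and square cell size in meters). Row 1 of
#' the matrix is the northernmost row, matching on-disk raster conventions.
#' `loss_raster()` holds loss-year codes (0 = never cleared, k >= 1 = cleared
#' in calendar year 2000 + k); `class_raster()` holds forest-class codes.
#'
#' @param values Integer matrix of cell codes.
#' @param pixel_area_ha Area of one pixel in hectares (> 0). The cell size of
#'   the geotransform is derived as `sqrt(pixel_area_ha * 1e4)` meters unless
#'   `cellsize` is given.
#' @param xll,yll Map coordinates (meters) of the lower-left raster corner.
#' @param cellsize Optional explicit cell edge length in meters.
#' @return An object of class `loss_raster`/`class_raster` (both inherit
#'   `grid_raster`).
#' @export
loss_raster <- function(values, pixel_area_ha, xll = 0, yll = 0,
                        cellsize = NULL) {
  r <- .grid_raster(values, pixel_area_ha, xll, yll, cellsize)
  if (any(r$values < 0, na.rm = TRUE)) {
    abort("Loss-year codes must be >= 0.")
  }
  class(r) <- c("loss_raster", class(r))
  r
}

#' @rdname loss_raster
#' @export
class_raster <- function(values, pixel_area_ha, xll = 0, yll = 0,
                         cellsize = NULL) {
  r <- .grid_raster(values, pixel_area_ha, xll, yll, cellsize)
  class(r) <- c("class_raster", class(r))
  r
}

.grid_raster <- function(values, pixel_area_ha, xll, yll, cellsize) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (!is.numeric(pixel_area_ha) || pixel_area_ha <= 0) {
    abort("`pixel_area_ha` must be > 0.")
  }
  if (is.null(cellsize)) cellsize <- sqrt(pixel_area_ha * 1e4)
  structure(
    list(values = values, pixel_area_ha = pixel_area_ha,
         xll = xll, yll = yll, cellsize = cellsize),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat("<", class(x)[1], "> ", nrow(x$values), " x ", ncol(x$values),
      " cells, ", signif(x$pixel_area_ha, 4), " ha/pixel, origin (",
      x$xll, ", ", x$yll, ")\n", sep = "")
  invisible(x)
}

# Map coordinates of all pixel centers, in matrix (row-major by column) order.
.pixel_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), times = nc)
  list(
    x = r$xll + (col - 0.5) * r$cellsize,
    y = r$yll + (nr - row + 0.5) * r$cellsize,
    row = row, col = col
  )
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by one row
#' of cell values per line, north first.
#'
#' @param path File path of the `.asc` grid.
#' @param kind `"loss"` or `"class"`: which raster class to construct.
#' @return `read_ascii_grid()` returns a [loss_raster()] or [class_raster()].
#' @export
read_ascii_grid <- function(path, kind = c("loss", "class")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- val("ncols"); nr <- val("nrows")
  xll <- val("xllcorner"); yll <- val("yllcorner"); cs <- val("cellsize")
  body <- lines[-(1:6)]
  vals <- matrix(as.integer(unlist(strsplit(trimws(body), "\\s+"))),
                 nrow = nr, ncol = nc, byrow = TRUE)
  ctor <- if (kind == "loss") loss_raster else class_raster
  ctor(vals, pixel_area_ha = cs^2 / 1e4, xll = xll, yll = yll, cellsize = cs)
}

#' @rdname read_ascii_grid
#' @param raster A `grid_raster`.
#' @export
write_ascii_grid <- function(raster, path) {
  v <- raster$values
  hdr <- c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", raster$xll),
    paste("yllcorner", raster$yll),
    paste("cellsize", raster$cellsize),
    "NODATA_value -9999"
  )
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Reclassify a forest-class raster into primary/degraded masks
#'
#' Collapses raw class codes into the two natural-forest strata used for
#' class-restricted outcomes: intact primary forest and degraded primary
#' forest. Codes mapped to `"other"` (plantations, non-forest, ...) fall in
#' neither mask. The mapping must cover every code present in the grid.
#'
#' @param class_raster A [class_raster()].
#' @param mapping Named character vector from class code (name) to one of
#'   `"primary"`, `"degraded"`, `"other"`, e.g.
#'   `c("1" = "degraded", "2" = "primary", "3" = "other")`.
#' @return A list of two logical matrices, `primary` and `degraded`, the
#'   same shape as the raster; the masks are disjoint.
#' @export
reclassify_forest <- function(class_raster, mapping) {
  stopifnot(inherits(class_raster, "class_raster"))
  v <- class_raster$values
  codes <- unique(as.vector(v))
  codes <- codes[!is.na(codes)]
  unmapped <- setdiff(as.character(codes), names(mapping))
  if (length(unmapped) > 0) {
    abort(paste0("Unmapped forest-class code(s): ",
                 paste(unmapped, collapse = ", "), "."))
  }
  bad <- setdiff(unique(mapping), c("primary", "degraded", "other"))
  if (length(bad) > 0) {
    abort(paste0("Mapping targets must be primary/degraded/other, got: ",
                 paste(bad, collapse = ", "), "."))
  }
  cls <- matrix(mapping[as.character(v)], nrow = nrow(v))
  list(
    primary = !is.na(cls) & cls == "primary",
    degraded = !is.na(cls) & cls == "degraded"
  )
}

#' Per-polygon annual deforested hectares from a loss-year raster
#'
#' The outcome-extraction stage: for every polygon and year, counts the
#' pixels whose loss-year code equals that year (pixel-center containment
#' rule), optionally restricted to a forest-class mask, and converts the
#' count to hectares. Deforestation rates divide by each polygon's
#' `total_area_ha` (taken from the attribute table; computed from geometry
#' when absent).
#'
#' @param polygons Polygon tibble (see [read_polygons()]); geometries must
#'   share the raster's projected coordinate frame.
#' @param loss A [loss_raster()].
#' @param mask Optional logical matrix (same shape as the raster), e.g. one
#'   of the masks from [reclassify_forest()]; only `TRUE` pixels count.
#' @param years Calendar years to extract (default 2001-2019).
#' @param forest_class Label stored in the output's `forest_class` column.
#' @param precip Optional tibble `(area_id, year, precip_std)` merged onto
#'   the result.
#' @return A tibble with one row per polygon-year: `area_id`, `year`,
#'   `forest_class`, `loss_ha`, `rate`, `total_area_ha` (plus `precip_std`
#'   if `precip` is given).
#' @export
zonal_annual_loss <- function(polygons, loss, mask = NULL,
                              years = 2001:2019, forest_class = "all",
                              precip = NULL) {
  stopifnot(inherits(loss, "loss_raster"))
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(loss$values)))
  }
  ctr <- .pixel_centers(loss)
  codes <- as.vector(loss$values)
  keep <- if (is.null(mask)) rep(TRUE, length(codes)) else as.vector(mask)
  nr <- nrow(loss$values); nc <- ncol(loss$values)
  xmax <- loss$xll + nc * loss$cellsize
  ymax <- loss$yll + nr * loss$cellsize

  out <- purrr::pmap(polygons, function(area_id, geometry, total_area_ha, ...) {
    bb <- apply(geometry, 2, range)
    if (bb[1, 1] >= xmax || bb[2, 1] <= loss$xll ||
        bb[1, 2] >= ymax || bb[2, 2] <= loss$yll) {
      warn(paste0("Polygon ", area_id,
                  " lies outside the raster extent; recording zero loss."))
      counts <- rep(0L, length(years))
    } else {
      cand <- ctr$x >= bb[1, 1] & ctr$x <= bb[2, 1] &
        ctr$y >= bb[1, 2] & ctr$y <= bb[2, 2]
      inside <- rep(FALSE, length(codes))
      inside[cand] <- .points_in_ring(ctr$x[cand], ctr$y[cand], geometry)
      sel <- codes[inside & keep]
      tab <- table(factor(sel + 2000L, levels = years))
      counts <- as.integer(tab)
    }
    area <- if (is.na(total_area_ha)) .ring_area_ha(geometry) else total_area_ha
    tibble(
      area_id = area_id,
      year = as.integer(years),
      forest_class = forest_class,
      loss_ha = counts * loss$pixel_area_ha,
      rate = deforestation_rate(counts * loss$pixel_area_ha, area),
      total_area_ha = area
    )
  })
  out <- dplyr::bind_rows(out)
  if (!is.null(precip)) {
    out <- dplyr::left_join(out, precip, by = c("area_id", "year"))
  }
  out
}

#' Annual deforestation rate
#'
#' Deforested hectares divided by the total size of the area, clipped to
#' `[0, 1]` with a warning when clipping occurs (pixelation can push the
#' extracted loss slightly past the attribute area).
#'
#' @param loss_ha Deforested hectares (>= 0); vectorized.
#' @param total_area_ha Total polygon area in hectares (> 0).
#' @return Numeric rate(s) in `[0, 1]`.
#' @export
#' @examples
#' deforestation_rate(9, 900) # 0.01
deforestation_rate <- function(loss_ha, total_area_ha) {
  if (any(total_area_ha <= 0)) abort("`total_area_ha` must be > 0.")
  if (any(loss_ha < 0)) abort("`loss_ha` must be >= 0.")
  rate <- loss_ha / total_area_ha
  if (any(rate > 1)) {
    warn("Deforestation rate above 1 clipped to 1.")
    rate <- pmin(rate, 1)
  }
  rate
}
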