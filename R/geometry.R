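#' Polygon tables and GeoJSON input/output
#'
#' Study areas are carried as a tibble with one row per polygon: the
#' attribute columns `area_id`, `title_type`, `title_year`, `total_area_ha`
#' and a `geometry` list-column holding the outer ring of each polygon as a
#' two-column (x, y) matrix in a projected, equal-area coordinate frame in
#' meters. Interior holes are not supported; zonal statistics use the
#' pixel-center rule on the outer ring.
#'
#' @param path Path of a GeoJSON `FeatureCollection` of Polygon features
#'   with properties `area_id`, `title_type`, `title_year`, `total_area_ha`.
#' @return `read_polygons()` returns the polygon tibble described above.
#' @export
read_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) abort("Not a GeoJSON FeatureCollection.")
  rows <- purrr::map(gj$features, function(f) {
    p <- f$properties
    ring <- f$geometry$coordinates[[1]]
    coords <- do.call(rbind, purrr::map(ring, ~ as.numeric(unlist(.x))))
    scalar <- function(x, default) {
      if (is.null(x) || length(x) == 0) default else x
    }
    tibble(
      area_id = as.character(p$area_id),
      title_type = as.character(scalar(p$title_type, "candidate")),
      title_year = as.integer(scalar(p$title_year, NA_integer_)),
      total_area_ha = as.numeric(scalar(p$total_area_ha, NA_real_)),
      geometry = list(coords)
    )
  })
  out <- dplyr::bind_rows(rows)
  missing_area <- is.na(out$total_area_ha)
  if (any(missing_area)) {
    out$total_area_ha[missing_area] <-
      vapply(out$geometry[missing_area], .ring_area_ha, numeric(1))
  }
  out
}

#' @rdname read_polygons
#' @param polygons A polygon tibble as returned by [read_polygons()] or
#'   [simulate_landscape()].
#' @return `write_polygons()` invisibly returns `path`.
#' @export
write_polygons <- function(polygons, path) {
  feats <- purrr::pmap(polygons, function(area_id, title_type, title_year,
                                          total_area_ha, geometry, ...) {
    ring <- lapply(seq_len(nrow(geometry)),
                   function(i) as.numeric(geometry[i, ]))
    props <- list(area_id = area_id, title_type = title_type,
                  total_area_ha = total_area_ha)
    if (!is.na(title_year)) props$title_year <- title_year
    list(
      type = "Feature",
      properties = props,
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Shoelace area of a ring given in meters, returned in hectares.
.ring_area_ha <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2 / 1e4
}

# Even-odd ray-casting containment test, vectorized over query points.
# Points exactly on an edge are resolved by the half-open rule implicit in
# the strict/non-strict comparison pair, which keeps shared edges exclusive.
.points_in_ring <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  if (n >= 2 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  if (n < 3) abort("Invalid geometry: a polygon ring needs at least 3 vertices.")
  if (anyNA(c(x, y))) abort("Invalid geometry: NA coordinates in ring.")
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py))
    if (any(crosses)) {
      xint <- x[i] + (py[crosses] - y[i]) / (y[j] - y[i]) * (x[j] - x[i])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    j <- i
  }
  inside
}
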