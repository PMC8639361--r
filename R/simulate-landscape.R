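#' Simulate a synthetic landscape: polygons plus loss-year and class rasters
#'
#' Builds a raster landscape with the same statistical law as
#' [simulate_panel()]: each study area becomes a rectangle of pixels placed
#' without overlap on the grid, and every still-forested pixel inside a
#' polygon is cleared in year `t` with the polygon's model-implied annual
#' hazard (the conditional deforestation rate). Clearing is irreversible, so
#' each pixel carries at most one loss-year code (0 = never cleared,
#' k = cleared in 2000 + k). A forest-class raster assigns each pixel a
#' class code. The per-polygon-year loss counts actually drawn are returned
#' as a panel, so zonal extraction can be checked against the generator
#' exactly.
#'
#' Draw order within the single seeded stream: unit attributes, unit
#' effects, precipitation, pixel classes (skipped when only one class has
#' positive probability), then one clearing uniform per pixel-year, polygon
#' by polygon in unit order, years in column-major order
#' (`matrix(runif(npix * nyears), npix, nyears)`).
#'
#' @param scenario A [sim_scenario()]. Polygon pixel footprints are sized
#'   from its area distribution; `total_area_ha` is replaced by the exact
#'   rasterized footprint area.
#' @param grid_shape Integer `c(nrows, ncols)` of the raster grid.
#' @param pixel_area_ha Pixel area in hectares (default 0.09, a 30 m pixel).
#' @param hazard Optional fixed annual clearing probability (scalar or one
#'   value per panel year) overriding the model-implied hazards — useful for
#'   calibration checks.
#' @param class_probs Named probabilities over class codes used to draw the
#'   class raster; default `c("1" = 0.45, "2" = 0.45, "3" = 0.10)` (1 =
#'   degraded, 2 = primary, 3 = other in [default_class_mapping()]).
#' @param dir Optional directory; when given, writes `polygons.geojson`,
#'   `lossyear.asc`, `forestclass.asc` and `panel.csv` there.
#' @return A list: `polygons` (tibble with `geometry`), `loss`
#'   ([loss_raster()]), `classes` ([class_raster()]), `panel` (the generated
#'   per-polygon annual loss records, same columns as [simulate_panel()]'s
#'   panel), and `paths` (named file paths, or `NULL`).
#' @export
simulate_landscape <- function(scenario, grid_shape = c(120, 120),
                               pixel_area_ha = 0.09, hazard = NULL,
                               class_probs = c("1" = 0.45, "2" = 0.45,
                                               "3" = 0.10),
                               dir = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (pixel_area_ha <= 0) abort("`pixel_area_ha` must be > 0.")
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  yrs <- scenario$panel_years
  n_yr <- length(yrs)

  withr::with_seed(scenario$seed, {
    units <- .draw_units(scenario)
    pub <- units$public
    n <- nrow(pub)
    precip <- rnorm(n * n_yr)

    # Rectangle footprints sized from the drawn areas, packed row-band by
    # row-band with a one-pixel gap so polygons never overlap.
    npix <- pmax(1L, as.integer(round(pub$total_area_ha / pixel_area_ha)))
    w <- as.integer(ceiling(sqrt(npix)))
    h <- as.integer(ceiling(npix / w))
    rects <- .pack_rectangles(w, h, nr, nc)
    pub$total_area_ha <- as.numeric(w * h) * pixel_area_ha

    grid <- .log_rate_grid(scenario, pub, units$unit_fe, precip)
    grid$hazard <- pmin(exp(grid$log_rate), 1)
    if (!is.null(hazard)) {
      grid$hazard <- rep(rep(hazard, length.out = n_yr), times = n)
    }

    cellsize <- sqrt(pixel_area_ha * 1e4)
    loss_vals <- matrix(0L, nr, nc)
    class_vals <- matrix(as.integer(names(class_probs)[1]), nr, nc)
    pos <- names(class_probs)[class_probs > 0]
    if (length(pos) > 1L) {
      class_vals <- matrix(
        as.integer(sample(names(class_probs), nr * nc, replace = TRUE,
                          prob = class_probs)), nr, nc)
    } else {
      class_vals <- matrix(as.integer(pos), nr, nc)
    }

    panel_rows <- vector("list", n)
    geoms <- vector("list", n)
    for (j in seq_len(n)) {
      rc <- rects[j, ]
      rows <- rc$row0:(rc$row0 + h[j] - 1L)
      cols <- rc$col0:(rc$col0 + w[j] - 1L)
      k <- length(rows) * length(cols)
      haz <- grid$hazard[grid$area_id == pub$area_id[j]]
      u <- matrix(runif(k * n_yr), k, n_yr)
      cleared <- integer(k) # 0 = standing, else index into yrs
      for (t in seq_len(n_yr)) {
        newly <- cleared == 0L & u[, t] < haz[t]
        cleared[newly] <- t
      }
      cell_rows <- rep(rows, times = length(cols))
      cell_cols <- rep(cols, each = length(rows))
      code <- ifelse(cleared == 0L, 0L, yrs[pmax(cleared, 1L)] - 2000L)
      code[cleared == 0L] <- 0L
      loss_vals[cbind(cell_rows, cell_cols)] <- code
      counts <- tabulate(cleared, nbins = n_yr)
      panel_rows[[j]] <- tibble(
        area_id = pub$area_id[j],
        year = yrs,
        forest_class = scenario$forest_class,
        loss_ha = counts * pixel_area_ha,
        rate = counts * pixel_area_ha / pub$total_area_ha[j],
        precip_std = grid$precip_std[grid$area_id == pub$area_id[j]],
        total_area_ha = pub$total_area_ha[j]
      )
      # Rectangle ring in map coordinates, aligned on pixel edges.
      x0 <- (rc$col0 - 1L) * cellsize
      x1 <- (rc$col0 - 1L + w[j]) * cellsize
      y1 <- (nr - rc$row0 + 1L) * cellsize
      y0 <- (nr - rc$row0 + 1L - h[j]) * cellsize
      geoms[[j]] <- cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0))
    }
  })

  polygons <- pub
  polygons$geometry <- geoms
  panel <- dplyr::bind_rows(panel_rows)
  loss <- loss_raster(loss_vals, pixel_area_ha)
  classes <- class_raster(class_vals, pixel_area_ha)

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(
      polygons = file.path(dir, "polygons.geojson"),
      loss = file.path(dir, "lossyear.asc"),
      classes = file.path(dir, "forestclass.asc"),
      panel = file.path(dir, "panel.csv")
    )
    write_polygons(polygons, paths[["polygons"]])
    write_ascii_grid(loss, paths[["loss"]])
    write_ascii_grid(classes, paths[["classes"]])
    utils::write.csv(panel, paths[["panel"]], row.names = FALSE)
  }

  list(polygons = polygons, loss = loss, classes = classes,
       panel = panel, paths = paths)
}

#' Default forest-class code mapping
#'
#' The class raster ships with a user-editable mapping rather than a claimed
#' canonical encoding: code 1 is degraded primary forest, code 2 intact
#' primary forest, and code 3 everything else.
#' @return Named character vector usable as `mapping` in
#'   [reclassify_forest()].
#' @export
default_class_mapping <- function() {
  c("1" = "degraded", "2" = "primary", "3" = "other")
}

# Greedy row-band packing of w x h pixel rectangles with a 1-pixel gap.
.pack_rectangles <- function(w, h, nr, nc) {
  n <- length(w)
  row0 <- integer(n); col0 <- integer(n)
  cur_row <- 1L; cur_col <- 1L; band_h <- 0L
  for (j in seq_len(n)) {
    if (cur_col + w[j] - 1L > nc) {
      cur_row <- cur_row + band_h + 1L
      cur_col <- 1L
      band_h <- 0L
    }
    if (w[j] > nc || cur_row + h[j] - 1L > nr) {
      abort("Grid too small to host the requested polygons without overlap.")
    }
    row0[j] <- cur_row; col0[j] <- cur_col
    cur_col <- cur_col + w[j] + 1L
    band_h <- max(band_h, h[j])
  }
  tibble(row0 = row0, col0 = col0)
}
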