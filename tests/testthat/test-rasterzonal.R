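# pixel grid helpers: 0.09 ha pixels (30 m), origin at (0, 0)
px <- sqrt(0.09 * 1e4)
rect_poly <- function(id, col0, row0, w, h, nr, area = NA_real_) {
  x0 <- (col0 - 1) * px; x1 <- (col0 - 1 + w) * px
  y1 <- (nr - row0 + 1) * px; y0 <- (nr - row0 + 1 - h) * px
  tibble::tibble(
    area_id = id, title_type = "candidate", title_year = NA_integer_,
    total_area_ha = area,
    geometry = list(cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0)))
  )
}

test_that("forest reclassification handles trivial and hand-counted cases", {
  # everything-primary mapping
  r <- class_raster(matrix(c(1L, 2L, 3L, 1L), 2, 2), pixel_area_ha = 0.09)
  m <- reclassify_forest(r, c("1" = "primary", "2" = "primary",
                              "3" = "primary"))
  expect_true(all(m$primary))
  expect_false(any(m$degraded))

  # 6x6 toy raster with 4 codes, hand-counted masks
  set.seed(1)
  v <- matrix(sample(1:4, 36, replace = TRUE), 6, 6)
  r <- class_raster(v, pixel_area_ha = 0.09)
  m <- reclassify_forest(r, c("1" = "degraded", "2" = "primary",
                              "3" = "primary", "4" = "other"))
  expect_equal(sum(m$degraded), sum(v == 1))
  expect_equal(sum(m$primary), sum(v %in% c(2, 3)))
  expect_false(any(m$primary & m$degraded))

  # unmapped code is an explicit error naming the code
  err <- tryCatch(reclassify_forest(r, c("1" = "degraded", "2" = "primary")),
                  error = conditionMessage)
  expect_match(err, "Unmapped forest-class code")
  expect_match(err, "3")
  expect_match(err, "4")
  expect_error(reclassify_forest(r, c("1" = "x", "2" = "primary",
                                      "3" = "primary", "4" = "other")),
               "primary/degraded/other")

  # empty raster gives empty masks
  e <- class_raster(matrix(integer(0), 0, 0), pixel_area_ha = 0.09)
  m <- reclassify_forest(e, c("1" = "primary"))
  expect_equal(dim(m$primary), c(0L, 0L))
})

test_that("zonal loss equals brute-force pixel enumeration", {
  # 10x10 raster with hand-placed codes; polygon covers columns 3..7,
  # rows 2..9 (pixel-center rule on a pixel-aligned rectangle).
  set.seed(42)
  v <- matrix(0L, 10, 10)
  v[sample(100, 40)] <- sample(c(1L, 5L, 9L, 19L), 40, replace = TRUE)
  loss <- loss_raster(v, pixel_area_ha = 0.09)
  poly <- rect_poly("p1", col0 = 3, row0 = 2, w = 5, h = 8, nr = 10,
                    area = 5 * 8 * 0.09)
  got <- zonal_annual_loss(poly, loss, years = 2001:2019)

  # oracle: exhaustive loop over all 100 pixels
  expected <- setNames(numeric(19), 2001:2019)
  for (row in 1:10) for (col in 1:10) {
    cx <- (col - 0.5) * px; cy <- (10 - row + 0.5) * px
    in_poly <- cx > (3 - 1) * px && cx < 7 * px &&
      cy > (10 - 9) * px && cy < (10 - 1) * px
    code <- v[row, col]
    if (in_poly && code > 0) {
      expected[as.character(2000 + code)] <-
        expected[as.character(2000 + code)] + 0.09
    }
  }
  expect_equal(got$loss_ha, unname(expected))

  # whole-frame polygon equals the global code histogram
  whole <- rect_poly("all", 1, 1, 10, 10, nr = 10, area = 9)
  gw <- zonal_annual_loss(whole, loss, years = 2001:2019)
  hist <- table(factor(v[v > 0] + 2000, levels = 2001:2019))
  expect_equal(gw$loss_ha, as.numeric(hist) * 0.09)

  # all-zero raster: all-zero records
  z <- zonal_annual_loss(poly, loss_raster(matrix(0L, 10, 10), 0.09))
  expect_true(all(z$loss_ha == 0))
})

test_that("masked loss never exceeds unmasked loss and splits are additive", {
  set.seed(7)
  for (rep in 1:3) {
    v <- matrix(sample(0:10, 144, replace = TRUE, prob = c(8, rep(1, 10))),
                12, 12)
    loss <- loss_raster(v, pixel_area_ha = 0.09)
    poly <- rect_poly("p", 2, 2, 8, 9, nr = 12, area = 8 * 9 * 0.09)
    mask <- matrix(sample(c(TRUE, FALSE), 144, replace = TRUE), 12, 12)
    um <- zonal_annual_loss(poly, loss, years = 2001:2010)
    mk <- zonal_annual_loss(poly, loss, mask = mask, years = 2001:2010)
    expect_true(all(mk$loss_ha <= um$loss_ha))

    # additivity: left and right halves sum to the whole
    left <- rect_poly("l", 2, 2, 4, 9, nr = 12, area = 4 * 9 * 0.09)
    right <- rect_poly("r", 6, 2, 4, 9, nr = 12, area = 4 * 9 * 0.09)
    parts <- zonal_annual_loss(dplyr::bind_rows(left, right), loss,
                               years = 2001:2010)
    sums <- tapply(parts$loss_ha, parts$year, sum)
    expect_equal(as.numeric(sums), um$loss_ha)

    # conservation: total extracted loss bounded by polygon area
    expect_lte(sum(um$loss_ha), 8 * 9 * 0.09 + 1e-12)
  }
})

test_that("degenerate polygons and extents are handled explicitly", {
  loss <- loss_raster(matrix(1L, 4, 4), pixel_area_ha = 0.09)
  outside <- rect_poly("far", 20, 20, 2, 2, nr = 4, area = 0.36)
  expect_warning(res <- zonal_annual_loss(outside, loss, years = 2001),
                 "outside")
  expect_equal(res$loss_ha, 0)

  degenerate <- outside
  degenerate$geometry <- list(cbind(c(0, 10), c(0, 10)))
  expect_error(zonal_annual_loss(degenerate, loss, years = 2001),
               "Invalid geometry")
})

test_that("deforestation_rate computes, clips and validates", {
  expect_equal(deforestation_rate(0, 900), 0)
  expect_equal(deforestation_rate(900, 900), 1)
  expect_equal(deforestation_rate(9, 900), 0.01)
  expect_warning(r <- deforestation_rate(1000, 900), "clipped")
  expect_equal(r, 1)
  expect_error(deforestation_rate(1, 0), "> 0")
  expect_error(deforestation_rate(-1, 10), ">= 0")
})

test_that("ascii grids round-trip values and geotransform", {
  v <- matrix(sample(0:19, 30, replace = TRUE), 5, 6)
  r <- loss_raster(v, pixel_area_ha = 0.09, xll = 300, yll = -120)
  p <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, p)
  r2 <- read_ascii_grid(p, kind = "loss")
  expect_identical(r2$values, r$values)
  expect_equal(r2$xll, 300)
  expect_equal(r2$yll, -120)
  expect_equal(r2$cellsize, r$cellsize)
})
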