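test_that("calibrated images round-trip through TIFF with sidecar", {
  ph <- make_tumor_phantom(shape = c(10, 16, 16), pocket_count = 0,
                           n_cells_tumor = 2, density_ratio = 1,
                           min_cell_separation = 4, n_cells_embedded = 0,
                           n_cells_outside = 0, seed = 1)
  f <- tempfile(fileext = ".tif")
  write_image(ph$image, f)
  img2 <- read_image(f)
  expect_equal(img2$data, ph$image$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(unname(img2$spacing), c(2, 1, 1))
  expect_identical(img2$channels, c("tumor", "cells", "vessels"))
  # spacing override wins over metadata
  img3 <- read_image(f, spacing_override = c(4, 2, 2))
  expect_identical(unname(img3$spacing), c(4, 2, 2))
})

test_that("reading a TIFF without pixel-size metadata requires an override", {
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(64), 8), f)
  expect_error(read_image(f), "refusing to guess")
  img <- read_image(f, spacing_override = c(0.5, 0.5))
  expect_identical(unname(img$spacing), c(0.5, 0.5))
  expect_error(read_image(tempfile()), "not found")
})

test_that("mask sets round-trip losslessly and keep label values", {
  shp <- c(10, 12, 12)
  tum <- array(0L, shp); tum[1:6, , ] <- 1L
  cr <- array(0L, shp)
  cr[7:8, 2:4, 2:4] <- 1L       # outside tumor
  cr[7:9, 8:10, 8:10] <- 3L     # labels {1, 3}: must not be renumbered
  mk <- region_mask_set(tumor = tum, craters = cr, spacing = c(2, 1, 1))
  d <- tempfile()
  write_masks(mk, d)
  mk2 <- read_masks(d)
  expect_identical(unname(mk2$craters), unname(mk$craters))
  expect_identical(unname(mk2$tumor), unname(mk$tumor))
  expect_identical(sort(setdiff(unique(as.vector(mk2$craters)), 0L)),
                   c(1L, 3L))
  expect_equal(unname(mk2$spacing), c(2, 1, 1))
})

test_that("mask-set invariants are enforced", {
  tum <- array(1L, c(4, 4, 4))
  expect_error(region_mask_set(tumor = tum, craters = array(0L, c(4, 4, 5)),
                               spacing = c(1, 1, 1)), "shape")
  expect_error(region_mask_set(tumor = tum, margin = tum,
                               spacing = c(1, 1, 1)), "disjoint")
  expect_error(region_mask_set(tumor = tum, spacing = c(1, 1)), "spacing")
  expect_error(region_mask_set(tumor = tum,
                               craters = array(-1L, c(4, 4, 4)),
                               spacing = c(1, 1, 1)), "non-negative")
})

test_that("calibrated_image validates spacing and channels", {
  expect_error(calibrated_image(array(0, c(4, 4)), spacing = c(1, -1)),
               "positive")
  expect_error(calibrated_image(array(0, c(4, 4)), spacing = c(1, 1, 1)),
               "spatial axes")
  expect_error(calibrated_image(array(0, c(4, 4, 2)), spacing = c(1, 1),
                                channels = "one", axes = "yxc"),
               "channel count")
  img <- calibrated_image(array(1:32, c(4, 4, 2)), c(1, 1), axes = "yxc")
  expect_identical(img$channels, c("c0", "c1"))
  expect_identical(get_channel(img, "c1"), array(17:32, c(4, 4)))
})

test_that("QuPath-dialect annotations read with class, annotator and area", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  f1 <- write_geojson_fixture(tempfile(fileext = ".geojson"), list(sq),
                              "CRATER", annotator = "A")
  tri <- cbind(c(20, 30, 20), c(0, 0, 10))
  f2 <- write_geojson_fixture(tempfile(fileext = ".geojson"), list(tri),
                              "PMB", annotator = "B")
  ann <- read_annotations(c(f1, f2))
  expect_equal(nrow(ann), 2)
  expect_equal(ann$area_um2, c(100, 50))
  expect_identical(ann$class, c("CRATER", "PMB"))
  expect_identical(ann$annotator, c("A", "B"))
})

test_that("annotations without class or with self-intersection are rejected", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  f <- tempfile(fileext = ".geojson")
  ring <- lapply(seq_len(4), function(r) as.list(unname(sq[r, ])))
  feat <- list(type = "Feature", properties = list(note = "x"),
               geometry = list(type = "Polygon",
                               coordinates = list(ring)))
  jsonlite::write_json(list(type = "FeatureCollection",
                            features = list(feat)),
                       f, auto_unbox = TRUE)
  expect_error(read_annotations(f), "no class")
  bow <- cbind(c(0, 10, 10, 0), c(0, 10, 0, 10))   # bow-tie
  fb <- write_geojson_fixture(tempfile(fileext = ".geojson"), list(bow),
                              "CRATER")
  expect_error(read_annotations(fb), "self-intersecting")
})

test_that("rasterized polygons reproduce area and z-projection behaves", {
  sq <- cbind(c(2, 12, 12, 2), c(2, 2, 12, 12))
  ann <- data.frame(class = "CRATER", annotator = "A", area_um2 = 100,
                    polygon = I(list(sq)))
  lab <- rasterize_annotations(ann, c(20, 20), c(1, 1))
  expect_equal(sum(lab == 1), 100, tolerance = 0.1)
  # max projection: per-column max, exact
  arr <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  img <- calibrated_image(arr, c(2, 1, 1))
  pr <- max_project(img)
  expect_equal(pr$data, apply(arr, c(2, 3), max), ignore_attr = TRUE)
  expect_identical(unname(pr$spacing), c(1, 1))
  expect_warning(max_project(pr), "already 2D")
})
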