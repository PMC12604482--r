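slab_with_notch <- function(shape = c(40, 60, 60), z_top = 24,
                            notch = NULL) {
  m <- array(0L, shape)
  m[seq_len(z_top), , ] <- 1L
  if (!is.null(notch))
    m[(z_top - notch$depth + 1):z_top,
      notch$y[1]:notch$y[2], notch$x[1]:notch$x[2]] <- 0L
  m
}

test_that("tumor segmentation recovers a planted slab to the voxel level", {
  ph <- make_tumor_phantom(shape = c(24, 80, 80), pocket_count = 0,
                           n_cells_tumor = 4, density_ratio = 1,
                           min_cell_separation = 6, n_cells_embedded = 0,
                           n_cells_outside = 0, background = 10,
                           tumor_amp = 100, noise_sd = 2, seed = 8)
  tum <- segment_tumor(ph$image, "tumor")
  truth <- ph$truth$tumor_mask
  # mismatches confined to a <= 1-voxel boundary shell
  mism <- which(tum != truth)
  expect_lt(length(mism) / sum(truth), 0.02)
  dm <- distance_map(truth, c(1, 1, 1))          # voxel units
  dmc <- distance_map(1L - truth, c(1, 1, 1))
  shell <- pmax(dm[mism], dmc[mism])
  expect_true(all(shell <= sqrt(3) + 1e-9))
})

test_that("degenerate tumor inputs are rejected or resolved by size", {
  img <- calibrated_image(array(5, c(8, 8, 8, 1)), c(1, 1, 1),
                          channels = "tumor", axes = "zyxc")
  expect_error(segment_tumor(img, "tumor"), "constant")
  # two disjoint slabs: only the large component is kept
  arr <- array(0, c(10, 40, 40))
  arr[1:5, 1:25, ] <- 100         # 5000 voxels
  arr[8:9, 35:39, 1:2] <- 100     # 20 voxels
  img2 <- calibrated_image(arr + rnorm(length(arr), 0, 0.5), c(1, 1, 1),
                           channels = "tumor")
  tum <- segment_tumor(img2, "tumor", seg3d_params(gaussian_sigma = 0.5))
  expect_gt(sum(tum[1:5, 1:25, ]), 4000)
  expect_equal(sum(tum[8:10, 30:40, ]), 0)
})

test_that("black top-hat equals the brute-force oracle on notched slabs", {
  # rectangular notch narrower than the closing kernel: recovered exactly
  notch <- list(y = c(21, 40), x = c(21, 40), depth = 10)
  tum <- slab_with_notch(notch = notch)
  p <- seg3d_params(closing_kernel = 40, opening_kernel = 2,
                    min_crater_volume = 8)
  cr <- segment_craters(tum, p)
  truth_notch <- slab_with_notch() - tum
  expect_identical(unname(array(as.integer(cr > 0), dim(cr))),
                   unname(truth_notch))
  # notch wider than the kernel: crater strictly smaller than the notch
  wide <- list(y = c(1, 60), x = c(1, 60), depth = 10)
  tum_w <- slab_with_notch(shape = c(40, 80, 80), notch = list(
    y = c(11, 70), x = c(11, 70), depth = 10))
  cr_w <- segment_craters(tum_w, p)
  notch_vol <- 60 * 60 * 10
  expect_lt(sum(cr_w > 0), notch_vol)
})

test_that("crater segmentation matches the oracle bit-exactly on random
           small volumes", {
  for (s in 1:8) {
    shp <- craters:::with_seed(s, sample(16:32, 3, replace = TRUE))
    tum <- random_blob_mask(shp, 2, seed = s * 7)
    if (!any(tum != 0)) next
    ck <- craters:::with_seed(s + 50, sample(4:7, 1))
    p <- seg3d_params(closing_kernel = ck, opening_kernel = 2,
                      min_crater_volume = 1)
    got <- array(as.integer(segment_craters(tum, p) > 0), shp)
    expect_identical(unname(got), unname(oracle_craters(tum, ck, 2)),
                     info = paste("seed", s))
  }
})

test_that("craters are empty on convex phantoms, disjoint from tumor, and
           the filled mask yields nothing", {
  flat <- slab_with_notch()
  expect_equal(sum(segment_craters(flat) > 0), 0)
  # ellipsoidal (convex) tumor
  zc <- 1:32; yc <- 1:48; xc <- 1:48
  ell <- array(as.integer(outer(outer(((zc - 30) / 28)^2, ((yc - 24) / 20)^2,
               `+`), ((xc - 24) / 20)^2, `+`) <= 1), c(32, 48, 48))
  expect_equal(sum(segment_craters(ell) > 0), 0)
  notch <- list(y = c(21, 40), x = c(21, 40), depth = 10)
  tum <- slab_with_notch(notch = notch)
  cr <- segment_craters(tum)
  expect_equal(sum(cr > 0 & tum > 0), 0)
  filled <- array(as.integer(tum | cr > 0), dim(tum))
  expect_equal(sum(segment_craters(filled) > 0), 0)   # idempotence
  expect_error(segment_craters(array(0L, c(8, 8, 8))), "empty")
})

test_that("bright punctae are found and excluded; absent punctae give an
           empty mask", {
  ph <- make_tumor_phantom(n_bright_cells = 5, seed = 9)
  bm <- exclude_bright_cells(ph$image, "tumor")
  bl <- attr(bm, "blobs")
  expect_gte(nrow(bl), 5)
  tb <- ph$truth$bright_cells
  for (i in seq_len(nrow(tb))) {
    dd <- sqrt((bl$z - tb[i, 1])^2 + (bl$y - tb[i, 2])^2 +
               (bl$x - tb[i, 3])^2)
    expect_lt(min(dd), 2)
  }
  tum <- segment_tumor(ph$image, "tumor", exclude = bm)
  expect_lt(sum(tum != ph$truth$tumor_mask) / sum(ph$truth$tumor_mask),
            0.02)
  ph0 <- make_tumor_phantom(seed = 3)
  expect_equal(sum(exclude_bright_cells(ph0$image, "tumor")), 0)
})

test_that("cell detection reaches 0.95 recall and precision on planted
           cells and returns empty tables for empty channels", {
  ph <- make_tumor_phantom(seed = 12)
  cells <- detect_cells(ph$image, "cells")
  truth <- ph$truth$cells
  dmat <- outer(seq_len(nrow(cells)), seq_len(nrow(truth)),
                Vectorize(function(i, j)
                  sqrt((cells$z[i] - truth$z[j])^2 +
                       (cells$y[i] - truth$y[j])^2 +
                       (cells$x[i] - truth$x[j])^2)))
  matched_truth <- apply(dmat, 2, min) <= 3
  matched_det <- apply(dmat, 1, min) <= 3
  expect_gte(mean(matched_truth), 0.95)   # recall
  expect_gte(mean(matched_det), 0.95)     # precision
  empty <- calibrated_image(array(0, c(10, 20, 20, 1)), c(1, 1, 1),
                            channels = "cells", axes = "zyxc")
  expect_equal(nrow(detect_cells(empty, "cells")), 0)
})
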