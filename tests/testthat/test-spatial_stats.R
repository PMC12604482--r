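tiny_masks <- function() {
  shp <- c(12, 20, 20)
  tum <- array(0L, shp); tum[1:6, , ] <- 1L
  cr <- array(0L, shp); cr[5:6, 3:6, 3:6] <- 2L   # label 2 kept as-is
  tum[cr > 0] <- 0L
  region_mask_set(tumor = tum, craters = cr, spacing = c(2, 1, 1))
}

test_that("cells are assigned to regions with exact distances", {
  mk <- tiny_masks()
  cells <- data.frame(
    z = c(9,  9, 22),     # in crater (z index 5-6 -> 8-10 um), above tumor,
    y = c(4, 14, 16),     # far away
    x = c(4, 14, 16))
  out <- assign_cell_regions(cells, mk, contact_dist = 5)
  expect_identical(out$region, c("crater", "tumor", "outside"))
  expect_equal(out$dist_to_crater[1], 0)
  expect_equal(out$dist_to_tumor[2], 0)   # z = 9 um rounds to slab top
  # a cell 4 um above the surface counts as tumor under the 5 um rule
  cell4 <- data.frame(z = 14, y = 14, x = 14)   # slab top at z = 10 um
  expect_identical(assign_cell_regions(cell4, mk, 5)$region, "tumor")
  expect_identical(assign_cell_regions(cell4, mk, 0)$region, "outside")
  # distances agree with brute-force all-pairs search on voxel-snapped
  # centroids (distances are read from the EDT at the nearest voxel)
  pts <- as.matrix(cells)
  for (a in 1:3) pts[, a] <- round(pts[, a] / c(2, 1, 1)[a]) * c(2, 1, 1)[a]
  expect_equal(out$dist_to_crater,
               oracle_point_mask_dist(pts, mk$craters > 0, c(2, 1, 1)),
               tolerance = 1e-9)
  expect_equal(out$dist_to_tumor,
               oracle_point_mask_dist(pts, mk$tumor, c(2, 1, 1)),
               tolerance = 1e-9)
})

test_that("region assignment is a partition and densities conserve counts", {
  ph <- make_tumor_phantom(seed = 31)
  tum <- segment_tumor(ph$image, "tumor")
  cr <- segment_craters(tum)
  mk <- region_mask_set(tumor = tum, craters = cr,
                        spacing = ph$image$spacing)
  cells <- assign_cell_regions(ph$truth$cells, mk, contact_dist = 5)
  expect_true(all(cells$region %in% c("crater", "tumor", "outside")))
  rep <- region_densities(cells, mk)
  expect_equal(rep$n_crater + rep$n_tumor + rep$n_outside, nrow(cells))
  expect_equal(rep$density_crater * rep$crater_area_mm2 +
               rep$density_tumor * rep$tumor_area_mm2,
               rep$n_crater + rep$n_tumor, tolerance = 1e-9)
})

test_that("density arithmetic and degenerate cases follow the contract", {
  mk <- tiny_masks()
  # 5 crater cells on a known footprint: density = n / area
  cells <- data.frame(z = rep(9, 5), y = c(3, 3, 5, 5, 4),
                      x = c(3, 5, 3, 5, 4))
  out <- assign_cell_regions(cells, mk, contact_dist = 0)
  rep <- region_densities(out, mk)
  expect_equal(rep$crater_area_mm2, 16 / 1e6)    # 4x4 columns of 1 um^2
  expect_equal(rep$density_crater, 5 / (16 / 1e6))
  # no cells: densities 0, affinity undefined
  none <- assign_cell_regions(cells[0, ], mk)
  rep0 <- region_densities(none, mk)
  expect_equal(rep0$density_crater, 0)
  expect_true(is.na(rep0$affinity_ratio))
})

test_that("coverage and diameters come from projected footprints", {
  shp <- c(8, 40, 40)
  tum <- array(0L, shp); tum[1:4, , ] <- 1L
  cr <- array(0L, shp)
  yc <- seq_len(40) - 1; xc <- yc
  foot <- outer((yc - 20)^2, (xc - 20)^2, `+`) <= 10^2
  cr[4, , ][foot] <- 1L
  tum[cr > 0] <- 0L
  mk <- region_mask_set(tumor = tum, craters = cr, spacing = c(2, 1, 1))
  cs <- coverage_and_sizes(mk)
  expect_equal(cs$diameters_um, 2 * sqrt(sum(foot) / pi), tolerance = 1e-9)
  expect_equal(cs$diameters_um, 20, tolerance = 0.1)
  expect_equal(cs$coverage_pct, 100 * sum(foot) / 1600, tolerance = 1e-9)
  # no craters
  mk0 <- region_mask_set(tumor = array(1L, c(4, 6, 6)),
                         spacing = c(1, 1, 1))
  cs0 <- coverage_and_sizes(mk0)
  expect_equal(cs0$coverage_pct, 0)
  expect_length(cs0$diameters_um, 0)
})

test_that("coverage is invariant to translation and 90-degree rotation", {
  ph <- make_tumor_phantom(shape = c(24, 96, 96), pocket_count = 2,
                           pocket_diameter = 24, n_cells_tumor = 2,
                           density_ratio = 1, min_cell_separation = 5,
                           n_cells_embedded = 0, n_cells_outside = 0,
                           seed = 4)
  pad <- function(a) {
    out <- array(0L, dim(a) + c(0, 8, 8))
    out[, 5:(dim(a)[2] + 4), 5:(dim(a)[3] + 4)] <- a
    out
  }
  tum_p <- pad(ph$truth$tumor_mask); cr_p <- pad(ph$truth$crater_mask)
  mk <- region_mask_set(tumor = tum_p, craters = cr_p,
                        spacing = c(2, 1, 1))
  base <- coverage_and_sizes(mk)$coverage_pct
  rot <- function(a) aperm(a, c(1, 3, 2))[, , dim(a)[2]:1]
  mk_r <- region_mask_set(tumor = rot(tum_p), craters = rot(cr_p),
                          spacing = c(2, 1, 1))
  expect_equal(coverage_and_sizes(mk_r)$coverage_pct, base,
               tolerance = 1e-12)
  shift1 <- function(a) {
    out <- array(0L, dim(a)); out[, , 2:dim(a)[3]] <- a[, , 1:(dim(a)[3]-1)]
    out
  }
  mk_t <- region_mask_set(tumor = shift1(tum_p), craters = shift1(cr_p),
                          spacing = c(2, 1, 1))
  expect_equal(coverage_and_sizes(mk_t)$coverage_pct, base,
               tolerance = 1e-12)
})

test_that("distance profiles bin objects by planted distances", {
  shp <- c(10, 30, 120)
  ref <- array(0L, shp); ref[, , 1:4] <- 1L      # wall at x <= 3 um
  objs <- data.frame(z = c(10, 10, 10), y = c(10, 10, 10),
                     x = c(2, 13, 103))           # inside, 10 um, 100 um
  h <- distance_profile(objs, ref, c(2, 1, 1), bins = c(0, 5, 20, 50))
  expect_equal(h$count, c(1L, 1L, 0L, 1L))        # overflow row counts 100um
  expect_equal(h$upper[4], Inf)
  expect_error(distance_profile(objs, array(0L, shp), c(2, 1, 1)), "empty")
})

test_that("tumor area fold change is a guarded ratio", {
  expect_equal(tumor_area_foldchange(4, 6), 1.5)
  expect_equal(tumor_area_foldchange(2.5, 2.5), 1)
  expect_error(tumor_area_foldchange(0, 3), "positive")
})

test_that("Mann-Whitney branches match exact enumeration and handle ties", {
  g <- group_test(c(1, 2), c(3, 4), "mwu")
  expect_equal(unname(g$statistic), 0)
  expect_equal(g$p, 1 / 3, tolerance = 1e-12)
  expect_true(g$exact)
  # exact p equals full enumeration on several random small samples
  for (s in 1:5) {
    ab <- craters:::with_seed(s, list(a = round(rnorm(5), 3),
                                      b = round(rnorm(6) + 0.5, 3)))
    got <- group_test(ab$a, ab$b, "mwu")
    expect_equal(got$p, oracle_mwu_exact(ab$a, ab$b), tolerance = 1e-9,
                 info = paste("seed", s))
  }
  expect_warning(gt <- group_test(rep(1, 4), rep(1, 5), "mwu"), "tied")
  expect_equal(gt$p, 1)
})

test_that("t tests handle pairing and exact separation", {
  x <- c(1.1, 2.3, 2.9, 4.2)
  expect_equal(group_test(x, x, "t_paired")$statistic, 0)
  expect_equal(group_test(x, x, "t_paired")$p, 1)
  sep <- group_test(c(0, 0, 0), c(1, 1, 1), "t_unpaired")
  expect_true(sep$degenerate)
  expect_equal(sep$p, 0)
  expect_equal(sep$statistic, Inf)
  expect_error(group_test(1, c(1, 2), "mwu"), "at least 2")
  expect_error(group_test(x, x[-1], "t_paired"), "equal-length")
})
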