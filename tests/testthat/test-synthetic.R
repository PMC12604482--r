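small_phantom_args <- list(shape = c(24, 64, 64), pocket_count = 1,
                           pocket_diameter = 20, n_cells_tumor = 6,
                           density_ratio = 2, n_cells_embedded = 2,
                           n_cells_outside = 2, min_cell_separation = 6,
                           vessel_count = 1)

test_that("every generator is a pure function of its seed", {
  a <- do.call(make_tumor_phantom, c(small_phantom_args, seed = 42))
  b <- do.call(make_tumor_phantom, c(small_phantom_args, seed = 42))
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$cells, b$truth$cells)
  c2 <- do.call(make_tumor_phantom, c(small_phantom_args, seed = 43))
  expect_false(identical(a$image$data, c2$image$data))

  f1 <- make_foci_phantom(seed = 7); f2 <- make_foci_phantom(seed = 7)
  expect_identical(f1$foci, f2$foci)
  s1 <- make_surface_phantom(seed = 7); s2 <- make_surface_phantom(seed = 7)
  expect_identical(s1$centroids, s2$centroids)
  m1 <- make_annotator_masks(seed = 7); m2 <- make_annotator_masks(seed = 7)
  expect_identical(m1$mask_a, m2$mask_a)
})

test_that("tumor phantom truth is consistent with direct voxel counting", {
  ph <- do.call(make_tumor_phantom, c(small_phantom_args, seed = 5))
  tr <- ph$truth
  carved_cols <- apply(tr$crater_mask > 0, c(2, 3), any)
  all_cols <- apply(tr$tumor_mask > 0, c(2, 3), any) | carved_cols
  expect_equal(unname(tr$coverage_fraction),
               sum(carved_cols) / sum(all_cols))
  expect_equal(unname(tr$area_crater_um2), sum(carved_cols) * 1)
  # crater cells sit inside carved voxels; tumor cells just above the face
  for (i in which(tr$cells$region == "crater")) {
    vi <- round(unlist(tr$cells[i, c("z", "y", "x")]) /
                c(2, 1, 1)) + 1
    expect_gt(tr$crater_mask[vi[1], vi[2], vi[3]], 0)
  }
  expect_true(all(tr$cells$z[tr$cells$region == "tumor"] > tr$z_top_um))
  # pocket_count = 0 gives a smooth surface and zero coverage
  ph0 <- make_tumor_phantom(shape = c(20, 48, 48), pocket_count = 0,
                            n_cells_tumor = 4, density_ratio = 1,
                            min_cell_separation = 5, n_cells_embedded = 0,
                            n_cells_outside = 0, seed = 1)
  expect_equal(ph0$truth$coverage_fraction, 0)
  expect_equal(sum(ph0$truth$crater_mask), 0)
})

test_that("foci phantom plants separated clusters and labeled noise", {
  fp <- make_foci_phantom(n_clusters = 3, cluster_sigma = 2,
                          foci_per_cluster = 10, n_noise = 0, seed = 2)
  expect_equal(nrow(fp$foci), 30)
  expect_true(all(fp$truth$cluster > 0))
  ctr <- fp$truth$centers
  dd <- as.matrix(dist(ctr))
  expect_true(all(dd[upper.tri(dd)] > 100))   # far beyond the 10 um radius
  fp2 <- make_foci_phantom(n_clusters = 0, n_noise = 50, seed = 3)
  expect_equal(nrow(fp2$foci), 50)
  expect_true(all(fp2$truth$cluster == 0))
})

test_that("surface phantom satisfies its planted polynomial exactly at
           zero noise and records attrition by construction", {
  coeffs <- c(0, 0, 0, 1, 0, 1)    # z = u^2 + v^2 on scaled coords
  sp <- make_surface_phantom(degree = 2, coeffs = coeffs, noise_sd = 0,
                             occupied_fraction = 1, seed = 1)
  u <- 2 * sp$centroids$x / sp$truth$domain_size - 1
  v <- 2 * sp$centroids$y / sp$truth$domain_size - 1
  expect_equal(sp$centroids$z, u^2 + v^2, tolerance = 1e-12)
  expect_equal(sp$truth$attrition_pct, 0)
  sp6 <- make_surface_phantom(degree = 3, occupied_fraction = 0.6, seed = 2)
  expect_equal(sp6$truth$attrition_pct, 40)
  # no centroid falls inside the planted hole
  dd <- sqrt((sp6$centroids$x - sp6$truth$hole_center[1])^2 +
             (sp6$centroids$y - sp6$truth$hole_center[2])^2)
  expect_true(all(dd > sp6$truth$hole_radius_um))
  expect_error(make_surface_phantom(degree = 12, seed = 1))
})

test_that("annotator phantom achieves requested JI within tolerance,
           verified by direct JI computation", {
  am <- make_annotator_masks(planted_ji = c(1, 0.5, 0.3), extra_a = 1,
                             extra_b = 2, seed = 4)
  for (i in 1:3) {
    ji <- jaccard(am$mask_a == i, am$mask_b == i)
    expect_lt(abs(ji - am$truth$planted_ji[i]), 0.021)
    expect_equal(ji, am$truth$achieved_ji[i], tolerance = 1e-12)
  }
  expect_equal(am$truth[c("tp", "fp", "fn")], list(tp = 2L, fp = 2L,
                                                    fn = 3L))
  # identical object when planted JI is 1
  expect_identical(which(am$mask_a == 1), which(am$mask_b == 1))
  # infeasible request errors with the pair index
  expect_error(make_annotator_masks(planted_ji = 0.47,
                                    object_size = c(2L, 3L)),
               "pair 1")
})

test_that("mIF phantom plants recoverable class intensities and analytic
           boundary lengths", {
  mp <- make_mif_phantom(seed = 6)
  tr <- mp$truth
  # class intensity separation: thresholding the planted channels recovers
  # every planted class exactly
  feats <- extract_cell_features(mp$image, mp$cell_mask)
  gated <- classify_cells(feats)
  truth_cls <- tr$cells$class
  truth_cls[truth_cls == "stroma"] <- "other"
  truth_cls[truth_cls == "CD8T"] <- "CD8T"
  map <- c(CD4T = "CD4T", CD8T = "CD8T", DC = "DC", Treg = "Treg",
           tumor = "tumor", other = "other")
  expect_identical(gated$cell_type, unname(map[truth_cls]))
  # analytic PMB length: a hole with no notches has length 2*pi*r
  mp0 <- make_mif_phantom(n_craters = 0, include_decoys = FALSE, seed = 2)
  expect_equal(mp0$truth$pmb_length_um, 2 * pi * mp0$truth$holes$r,
               tolerance = 1e-12)
  expect_equal(mp0$truth$linear_density_per_cm, 0)
  # notched holes: perimeter strictly longer than the plain circle
  with_notch <- unique(tr$candidates$hole[tr$candidates$carved])
  expect_true(all(tr$pmb_length_um[with_notch] >
                  2 * pi * tr$holes$r[with_notch]))
})
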