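mif_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mp <- make_mif_phantom(seed = 3)
      reg <- segment_tumor_regions(mp$image)
      cache <<- list(mp = mp, reg = reg)
    }
    cache
  }
})

test_that("percentile normalization is exact, bounded and idempotent", {
  arr <- array(0, c(40, 40, 3))
  arr[, , 1] <- 7                               # constant channel
  arr[, , 2] <- craters:::with_seed(1, runif(1600, 0, 10))
  arr[, , 3] <- craters:::with_seed(2, runif(1600, 0, 4))
  img <- calibrated_image(arr, c(1, 1), channels = c("a", "b", "nuc"),
                          axes = "yxc")
  pp <- preprocess_channels(img, c("a", "b"), "nuc")
  expect_true(all(get_channel(pp, "a") == 1))   # constant -> all ones
  v <- quantile(arr[, , 2], 0.99)
  expect_equal(get_channel(pp, "b"),
               array(pmin(arr[, , 2] / v, 1), c(40, 40)))
  comp <- get_channel(pp, "membrane_sum")
  expect_lte(max(comp), 2)
  # idempotence: renormalizing the normalized channels is a near no-op
  # (the interpolated percentile of a clipped channel sits just under 1)
  pp2 <- preprocess_channels(pp, c("a", "b"), "nuc")
  expect_equal(get_channel(pp2, "b"), get_channel(pp, "b"),
               tolerance = 1e-4)
  zero <- calibrated_image(array(0, c(10, 10, 2)), c(1, 1),
                           channels = c("z", "nuc"), axes = "yxc")
  expect_error(preprocess_channels(zero, "z", "nuc"), "zero")
})

test_that("rolling-ball subtraction removes background, keeps peaks", {
  expect_equal(subtract_background(matrix(5, 60, 60), 10),
               array(0, c(60, 60)))
  # single narrow peak on a flat background
  img <- matrix(2, 80, 80)
  img[40:42, 40:42] <- 12
  out <- subtract_background(img, 15)
  expect_equal(out[41, 41], 10, tolerance = 0.5)      # peak within 5%
  expect_lt(max(out[1:20, 1:20]), 1e-9)               # background removed
  expect_true(all(out >= 0))
  expect_true(all(out <= img - min(img) + 1e-9))
  # low-frequency ramp is mostly removed
  ramp <- outer(seq(0, 4, length.out = 100), rep(1, 100))
  out_r <- subtract_background(ramp, 20)
  expect_lt(max(out_r), 0.4 * 4)
  expect_error(subtract_background(matrix(0, 20, 20), 30), "too large")
})

test_that("per-cell features equal direct per-label averaging", {
  arr <- array(craters:::with_seed(3, runif(30 * 30 * 2)), c(30, 30, 2))
  img <- calibrated_image(arr, c(1, 1), channels = c("m1", "m2"),
                          axes = "yxc")
  mask <- array(0L, c(30, 30))
  mask[2:5, 2:5] <- 1L
  mask[20:24, 20:29] <- 7L
  ft <- extract_cell_features(img, mask)
  expect_equal(ft$id, c(1L, 7L))
  for (ch in 1:2) {
    expect_equal(ft[[paste0("m", ch)]],
                 c(mean(arr[, , ch][mask == 1]),
                   mean(arr[, , ch][mask == 7])))
  }
  # cell straddling two intensities averages them
  arr2 <- array(0, c(10, 10, 1)); arr2[1:5, 1, 1] <- 20
  img2 <- calibrated_image(arr2, c(1, 1), channels = "m", axes = "yxc")
  m2 <- array(0L, c(10, 10)); m2[1:10, 1] <- 1L
  expect_equal(extract_cell_features(img2, m2)$m, 10)
  expect_error(extract_cell_features(img2, array(0L, c(10, 10))), "empty")
})

test_that("gating recovers planted types with documented priority", {
  fx <- mif_fixture()
  feats <- classify_cells(extract_cell_features(fx$mp$image,
                                                fx$mp$cell_mask))
  truth <- fx$mp$truth$cells$class
  truth[truth == "stroma"] <- "other"
  expect_identical(feats$cell_type, truth)
  # CD4+FOXP3+ resolves to Treg, all-zero to other
  fake <- data.frame(CD4 = c(1, 0), FOXP3 = c(1, 0), CD163 = 0, CD11c = 0,
                     CD8a = 0, SOX10 = 0)
  out <- classify_cells(fake)
  expect_identical(out$cell_type, c("Treg", "other"))
  expect_error(classify_cells(fake, gates = data.frame(
    type = "X", markers = I(list("missing_channel")))), "absent")
})

test_that("tumor-region segmentation finds PVAs and measures the PMB to
           within 3 percent of the analytic length", {
  fx <- mif_fixture()
  reg <- fx$reg
  tr <- fx$mp$truth
  expect_equal(sum(reg$holes$perivascular), nrow(tr$holes))
  expect_lt(abs(reg$pmb_total_cm / tr$pmb_cm - 1), 0.03)
  expect_equal(sum(reg$margin & reg$tumor), 0)
  # a hole without CD31 content is not perivascular: white out CD31/CD105
  img2 <- fx$mp$image
  ic <- match(c("CD31", "CD105"), img2$channels)
  img2$data[, , ic] <- 0.001 *
    array(abs(craters:::with_seed(1, rnorm(prod(dim(img2$data)[1:2]) * 2))),
          c(dim(img2$data)[1:2], 2))
  reg2 <- segment_tumor_regions(img2)
  expect_equal(sum(reg2$holes$perivascular), 0)
})

test_that("the rule classifier accepts exactly the planted CRATERs and
           rejects each decoy on its violated rule", {
  fx <- mif_fixture()
  tr <- fx$mp$truth
  feats <- crater_candidate_features(tr$candidates, fx$reg, fx$mp$image,
                                     fx$mp$cell_mask)
  cls <- classify_crater_candidates(feats, tr$perivascular_nuclear_density)
  expect_identical(cls$accepted, tr$candidates$expected_accept)
  expect_match(cls$failed_rules[cls$kind == "big"], "size")
  expect_match(cls$failed_rules[cls$kind == "vessel"], "no_vessel")
  expect_match(cls$failed_rules[cls$kind == "asma"], "no_asma")
  expect_match(cls$failed_rules[cls$kind == "nuclei"], "nuclear_density")
  expect_match(cls$failed_rules[cls$kind == "collagen"], "collagen")
  expect_match(cls$failed_rules[cls$kind == "offboundary"], "location")
})

test_that("relaxing any single rule never shrinks the accepted set", {
  fx <- mif_fixture()
  tr <- fx$mp$truth
  feats <- crater_candidate_features(tr$candidates, fx$reg, fx$mp$image,
                                     fx$mp$cell_mask)
  base <- classify_crater_candidates(feats,
                                     tr$perivascular_nuclear_density)
  relaxed <- list(
    mif_params(crater_size_range = c(10, 100)),
    mif_params(max_collagen_fibers = 10L),
    mif_params(nuclear_density_frac = 10))
  for (p in relaxed) {
    r <- classify_crater_candidates(feats, tr$perivascular_nuclear_density,
                                    params = p)
    expect_true(all(r$accepted[base$accepted]))
  }
})

test_that("cell region assignment reproduces the crater > border > tumor
           exclusion logic against direct set algebra", {
  fx <- mif_fixture()
  mp <- fx$mp; reg <- fx$reg
  crmask <- array(0L, dim(mp$cell_mask))
  for (ci in which(mp$truth$candidates$expected_accept)) {
    cc <- mp$truth$candidates[ci, ]
    ys <- seq_len(dim(crmask)[1]) - 1; xs <- seq_len(dim(crmask)[2]) - 1
    crmask[outer((ys - cc$cy)^2, (xs - cc$cx)^2, `+`) <=
           (cc$diameter / 2)^2] <- 1L
  }
  cells <- extract_cell_features(mp$image, mp$cell_mask)
  got <- assign_cells_to_regions(cells, mp$cell_mask, crmask, reg)
  for (i in seq_len(nrow(got))) {
    px <- mp$cell_mask == got$id[i]
    want <- if (any(crmask[px] != 0)) "crater"
            else if (any(reg$margin[px] != 0)) "border"
            else if (any(reg$tumor[px] != 0)) "tumor"
            else "outside"
    expect_identical(got$region[i], want)
  }
  counts <- table(got$region)
  expect_equal(sum(counts), nrow(cells))
})

test_that("linear density is count per usable centimeter", {
  expect_equal(crater_linear_density(4, 0.2), 20)
  expect_equal(crater_linear_density(0, 0.35), 0)
  expect_equal(crater_linear_density(3, c(0.1, 0.2, 0.3),
                                     fibrotic = c(FALSE, TRUE, FALSE)), 7.5)
  expect_error(crater_linear_density(2, 0.4, fibrotic = TRUE), "zero")
})

test_that("marker comparisons detect planted shifts and ignore null ones", {
  set.seed(1)
  cells <- data.frame(HLA = c(rnorm(100, 10, 1), rnorm(100, 15, 1)),
                      in_crater = rep(c(FALSE, TRUE), each = 100))
  res <- marker_region_comparison(cells, "HLA", cells$in_crater)
  expect_lt(res$test$p, 0.001)
  null <- data.frame(HLA = rep(c(2, 3, 4, 5), 10),
                     in_crater = rep(c(FALSE, TRUE), each = 20))
  res0 <- marker_region_comparison(null, "HLA", null$in_crater)
  expect_gt(res0$test$p, 0.5)
  expect_error(marker_region_comparison(cells[1:3, ], "HLA",
                                        c(TRUE, FALSE, FALSE)),
               "at least 2")
})
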