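# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's separable/transform-based implementations: morphology
# is done by explicit shift-and-combine over every structuring-element
# offset, distances by all-pairs search, neighbor counts by O(n^2) loops.

# Shift an array by integer offsets, filling with `fill`.
shift_array <- function(arr, off, fill = 0L) {
  d <- dim(arr)
  out <- array(fill, d)
  src <- dst <- vector("list", length(d))
  for (a in seq_along(d)) {
    o <- off[a]
    if (o >= 0) { dst[[a]] <- seq_len(d[a] - o) + o; src[[a]] <- seq_len(d[a] - o) }
    else { dst[[a]] <- seq_len(d[a] + o); src[[a]] <- seq_len(d[a] + o) - o }
    if (length(dst[[a]]) == 0) return(out)
  }
  do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(arr), src)))))
}

# Box-SE offsets with the package's anchor convention: window at voxel i
# covers [i - floor(k/2), i + k - 1 - floor(k/2)].
box_offsets <- function(k, nd) {
  k <- rep_len(k, nd)
  per <- lapply(k, function(kk) seq(-(kk %/% 2), kk - 1 - kk %/% 2))
  as.matrix(expand.grid(per))
}

oracle_dilate <- function(mask, k) {
  offs <- box_offsets(k, length(dim(mask)))
  out <- array(0L, dim(mask))
  for (r in seq_len(nrow(offs)))
    # dilation: union of the mask translated by each SE offset
    out <- out | shift_array(mask, as.integer(offs[r, ]))
  array(as.integer(out), dim(mask))
}

oracle_erode <- function(mask, k) {
  offs <- -box_offsets(k, length(dim(mask)))   # reflected SE
  out <- array(1L, dim(mask))
  for (r in seq_len(nrow(offs)))
    out <- out & shift_array(mask, as.integer(offs[r, ]), fill = 0L)
  array(as.integer(out), dim(mask))
}

oracle_close <- function(mask, k) {
  # pad with background by k, dilate, erode, crop (package convention)
  d <- dim(mask)
  k <- rep_len(as.integer(k), length(d))
  pad <- array(0L, d + 2L * k)
  idx <- lapply(seq_along(d), function(a) k[a] + seq_len(d[a]))
  pad <- do.call(`[<-`, c(list(pad), idx, list(mask)))
  out <- oracle_erode(oracle_dilate(pad, k), k)
  array(do.call(`[`, c(list(out), idx)), d)
}

oracle_open <- function(mask, k) oracle_dilate(oracle_erode(mask, k), k)

# Black top-hat + clean-up, mirroring segment_craters but built on the
# shift-based oracle morphology.
oracle_craters <- function(tumor, close_k, open_k) {
  th <- oracle_close(tumor, close_k)
  th[tumor != 0] <- 0L
  oracle_open(th, open_k)
}

# All-pairs nearest distance from points (um) to mask voxel centers.
oracle_point_mask_dist <- function(points, mask, spacing) {
  idx <- which(mask != 0)
  co <- arrayInd(idx, dim(mask))
  vox <- sweep(co - 1, 2, spacing, `*`)
  apply(points, 1, function(p)
    sqrt(min(colSums((t(vox) - as.numeric(p))^2))))
}

# O(n^2) neighbor-count filter oracle.
oracle_filter_foci <- function(foci, radius, min_neighbors) {
  n <- nrow(foci)
  keep <- logical(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    for (j in seq_len(n)) {
      if (i == j) next
      if (sqrt((foci$x[i] - foci$x[j])^2 + (foci$y[i] - foci$y[j])^2) <=
          radius) cnt <- cnt + 1L
    }
    keep[i] <- cnt >= min_neighbors
  }
  keep
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
oracle_mwu_exact <- function(a, b) {
  n <- length(a); m <- length(b)
  pool <- c(a, b)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - n * (n + 1) / 2)
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Brute-force grid-cell occupancy for the attrition projection.
oracle_attrition <- function(centroids, grid_cell) {
  x <- centroids$x; y <- centroids$y; r <- centroids$radius_um
  hull <- grDevices::chull(x, y)
  gx <- seq(min(x) + grid_cell / 2, max(x), by = grid_cell)
  gy <- seq(min(y) + grid_cell / 2, max(y), by = grid_cell)
  n_in <- 0L; n_unocc <- 0L
  ring <- cbind(x[hull], y[hull])
  for (cx in gx) for (cy in gy) {
    if (!craters:::points_in_polygon(cx, cy, ring)) next
    n_in <- n_in + 1L
    hit <- FALSE
    for (i in seq_along(x))
      if ((cx - x[i])^2 + (cy - y[i])^2 <= r[i]^2) { hit <- TRUE; break }
    if (!hit) n_unocc <- n_unocc + 1L
  }
  100 * n_unocc / n_in
}

# Minimal QuPath-dialect GeoJSON writer for fixtures.
write_geojson_fixture <- function(path, polys, classes, annotator = NULL) {
  feats <- lapply(seq_along(polys), function(i) {
    ring <- polys[[i]]
    ring <- rbind(ring, ring[1, ])
    props <- list(classification = list(name = classes[i]))
    if (!is.null(annotator)) props$annotator <- annotator
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(r) as.list(unname(ring[r, ]))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

# Small 3D phantom helper for oracle comparisons.
random_blob_mask <- function(shape, n_blobs, seed) {
  craters:::with_seed(seed, {
    m <- array(0L, shape)
    zc <- seq_len(shape[1]); yc <- seq_len(shape[2]); xc <- seq_len(shape[3])
    for (b in seq_len(n_blobs)) {
      c0 <- c(runif(1, 1, shape[1]), runif(1, 1, shape[2]),
              runif(1, 1, shape[3]))
      r <- runif(1, 2, min(shape) / 3)
      m[outer(outer((zc - c0[1])^2, (yc - c0[2])^2, `+`),
              (xc - c0[3])^2, `+`) <= r^2] <- 1L
    }
    m
  })
}
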