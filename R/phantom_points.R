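#' Synthetic RNAscope foci phantom
#'
#' Clustered point clouds emulating transcript foci detected in a projected
#' RNAscope image: `n_clusters` isotropic Gaussian clusters of
#' `foci_per_cluster` points each, plus `n_noise` uniform noise points.
#' Cluster centers are drawn with a minimum separation so cluster identity
#' is unambiguous. The truth manifest labels every point with its cluster id
#' (`0` = noise), by construction.
#'
#' @param n_clusters number of clusters.
#' @param cluster_sigma cluster spread (um).
#' @param foci_per_cluster points per cluster.
#' @param n_noise uniform noise points.
#' @param extent `c(width, height)` of the field (um); points are kept
#'   inside a margin so KDE mass stays in-field.
#' @param min_separation minimum distance between cluster centers (um);
#'   default keeps clusters far apart relative to the 10 um filter radius.
#' @param seed RNG seed.
#' @return list with `foci` (data.frame `x`, `y` in um) and `truth`
#'   (per-point `cluster` id, cluster centers).
#' @export
make_foci_phantom <- function(n_clusters = 3, cluster_sigma = 2,
                              foci_per_cluster = 10, n_noise = 0,
                              extent = c(500, 500),
                              min_separation = 100, seed = 1) {
  with_seed(seed, {
    margin <- max(20, 6 * cluster_sigma)
    centers <- matrix(numeric(0), 0, 2)
    att <- 0
    while (nrow(centers) < n_clusters) {
      att <- att + 1
      if (att > 5000)
        stop("cannot place ", n_clusters, " cluster centers at separation ",
             min_separation, " in the given extent")
      p <- c(runif(1, margin, extent[1] - margin),
             runif(1, margin, extent[2] - margin))
      if (nrow(centers) &&
          min(sqrt(rowSums((centers -
            matrix(p, nrow(centers), 2, byrow = TRUE))^2))) < min_separation)
        next
      centers <- rbind(centers, p)
    }
    pts <- matrix(numeric(0), 0, 2)
    cl <- integer(0)
    for (i in seq_len(n_clusters)) {
      pp <- cbind(rnorm(foci_per_cluster, centers[i, 1], cluster_sigma),
                  rnorm(foci_per_cluster, centers[i, 2], cluster_sigma))
      pp[, 1] <- pmin(pmax(pp[, 1], 1), extent[1] - 1)
      pp[, 2] <- pmin(pmax(pp[, 2], 1), extent[2] - 1)
      pts <- rbind(pts, pp)
      cl <- c(cl, rep(i, foci_per_cluster))
    }
    if (n_noise > 0) {
      pts <- rbind(pts, cbind(runif(n_noise, margin, extent[1] - margin),
                              runif(n_noise, margin, extent[2] - margin)))
      cl <- c(cl, rep(0L, n_noise))
    }
    foci <- data.frame(x = pts[, 1], y = pts[, 2])
    list(foci = foci,
         truth = list(cluster = cl,
                      centers = if (n_clusters)
                        data.frame(x = centers[, 1], y = centers[, 2])
                      else data.frame(x = numeric(0), y = numeric(0)),
                      extent = extent))
  })
}

# Bivariate monomial exponent table for total degree <= degree, ordered by
# total degree then y-exponent. Coefficient count (degree+1)(degree+2)/2.
poly_basis_exponents <- function(degree) {
  ex <- do.call(rbind, lapply(0:degree, function(tot)
    cbind(i = tot - (0:tot), j = 0:tot)))
  ex
}

poly_design <- function(u, v, degree) {
  ex <- poly_basis_exponents(degree)
  m <- matrix(0, length(u), nrow(ex))
  for (k in seq_len(nrow(ex))) m[, k] <- u^ex[k, "i"] * v^ex[k, "j"]
  m
}

#' Synthetic fragmented-tumor surface phantom
#'
#' Emulates the residual-fragment geometry of an immune-attacked mouse
#' tumor: blob centroids lying on a planted bivariate polynomial surface
#' `z = P(x, y)` (plus vertical Gaussian noise), with the (x, y) positions
#' restricted to an occupied subset of the square domain covering
#' `occupied_fraction` of its area. The unoccupied subset is a central disc
#' of area `1 - occupied_fraction`, so the convex hull of the fragment cloud
#' still spans the full domain and the planted attrition
#' (`100 * (1 - occupied_fraction)` percent) is recoverable.
#'
#' The polynomial is defined on domain coordinates scaled to `[-1, 1]`.
#' When `coeffs` is omitted, coefficients are drawn at random with
#' decreasing magnitude by total degree but a guaranteed non-degenerate
#' top-degree contribution; a flat polynomial of the stated degree is
#' flagged `degenerate` in the manifest.
#'
#' Blobs tile the occupied region on a jittered subgrid (several per coarse
#' cell) so their footprints cover it densely; each blob gets an equivalent
#' radius equal to the subgrid diagonal over two.
#'
#' @param degree planted polynomial degree (2-10).
#' @param coeffs optional coefficient vector, length
#'   `(degree+1)(degree+2)/2`, basis of [poly_basis_exponents()] on scaled
#'   coordinates, z in um.
#' @param n_blobs approximate number of fragments.
#' @param occupied_fraction fraction of the domain area bearing fragments.
#' @param noise_sd vertical noise (um).
#' @param domain_size side of the square (x, y) domain (um).
#' @param seed RNG seed.
#' @return list with `centroids` (data.frame `x`, `y`, `z` um,
#'   `radius_um`) and `truth` (degree, coeffs, true attrition percent,
#'   hole geometry, degenerate flag).
#' @export
make_surface_phantom <- function(degree = 5, coeffs = NULL, n_blobs = 500,
                                 occupied_fraction = 0.6, noise_sd = 1,
                                 domain_size = 1000, seed = 1) {
  stopifnot(degree >= 2, degree <= 10,
            occupied_fraction >= 0, occupied_fraction <= 1)
  with_seed(seed, {
    ex <- poly_basis_exponents(degree)
    if (is.null(coeffs)) {
      tot <- ex[, 1] + ex[, 2]
      coeffs <- rnorm(nrow(ex), 0, 60 / (1 + tot))
      top <- tot == degree
      coeffs[top] <- sign(coeffs[top]) * pmax(abs(coeffs[top]), 25)
    }
    if (length(coeffs) != nrow(ex))
      stop("coeffs must have length ", nrow(ex), " for degree ", degree)
    degenerate <- all(abs(coeffs[ex[, 1] + ex[, 2] == degree]) < 1e-12)

    L <- domain_size
    ncell <- max(4L, ceiling(sqrt(n_blobs / max(occupied_fraction, 1e-3))))
    step <- L / ncell
    # the fragment cloud's footprint (and hence its convex hull) is the
    # domain square inset by half a lattice step; the truth hole is sized
    # against that effective domain so planted attrition is exact
    L_eff <- L - step
    hole_r <- sqrt((1 - occupied_fraction) / pi) * L_eff
    hole_c <- c(L / 2, L / 2)
    gx <- (seq_len(ncell) - 0.5) * step
    grid <- cbind(x = rep(gx, each = ncell), y = rep(gx, ncell))
    # small jitter + footprint radius chosen so the blob discs are
    # guaranteed to tile the occupied region (max center-to-blob distance
    # sqrt(2)/2 * step + jitter < radius), with little spill into the hole
    jit <- matrix(runif(2 * nrow(grid), -0.05, 0.05) * step, ncol = 2)
    pts <- grid + jit
    keep <- sqrt((pts[, 1] - hole_c[1])^2 + (pts[, 2] - hole_c[2])^2) >
      hole_r + 0.4 * step
    pts <- pts[keep, , drop = FALSE]
    u <- 2 * pts[, 1] / L - 1
    v <- 2 * pts[, 2] / L - 1
    z <- as.vector(poly_design(u, v, degree) %*% coeffs)
    if (noise_sd > 0) z <- z + rnorm(length(z), 0, noise_sd)
    radius <- 0.8 * step
    centroids <- data.frame(x = pts[, 1], y = pts[, 2], z = z,
                            radius_um = radius)
    list(centroids = centroids,
         truth = list(degree = degree, coeffs = coeffs,
                      basis = ex, domain_size = L,
                      hole_center = hole_c, hole_radius_um = hole_r,
                      occupied_fraction = occupied_fraction,
                      attrition_pct = 100 * (1 - occupied_fraction),
                      noise_sd = noise_sd, degenerate = degenerate))
  })
}
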