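#' Centroids of labeled 3D blobs
#'
#' Per-label centroid in um (index origin at zero) and voxel count, ordered
#' by label. Matches direct averaging of voxel coordinates exactly.
#'
#' @param labels integer 3D label mask (0 background).
#' @param spacing (z, y, x) voxel size (um).
#' @return data.frame `label`, `z`, `y`, `x` (um), `voxels`,
#'   `radius_um` (equivalent-sphere radius).
#' @export
extract_centroids <- function(labels, spacing) {
  labs <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (!length(labs)) stop("empty label mask")
  idx <- which(labels > 0)
  co <- arrayInd(idx, dim(labels))
  l <- labels[idx]
  agg <- function(v) as.vector(tapply(v, l, mean))
  voxels <- as.vector(table(factor(l, levels = labs)))
  vol_um3 <- voxels * prod(spacing)
  data.frame(label = labs,
             z = (agg(co[, 1]) - 1) * spacing[1],
             y = (agg(co[, 2]) - 1) * spacing[2],
             x = (agg(co[, 3]) - 1) * spacing[3],
             voxels = voxels,
             radius_um = (3 * vol_um3 / (4 * pi))^(1 / 3))
}

#' Fit a polynomial surface z = P(x, y) with empirical degree selection
#'
#' Least-squares fit of a bivariate polynomial for each candidate degree
#' (x, y scaled to [-1, 1] for conditioning), degree chosen by k-fold
#' cross-validated RMSE with a one-standard-error tie-break toward the
#' lowest degree (plain in-sample RMSE decreases monotonically with degree
#' and cannot select). Candidate degrees needing more coefficients than
#' there are points are dropped with a message.
#'
#' @param centroids data.frame with `x`, `y`, `z` (um).
#' @param degrees candidate degrees (the published range is 2 to 10).
#' @param k_folds cross-validation folds.
#' @param seed fold-assignment seed.
#' @return object of class `surface_fit`: `degree`, `coefficients` (basis
#'   of [poly_basis_exponents()] on scaled coordinates), `rmse` (um,
#'   full-fit at the chosen degree), `selection_scores` (per-degree CV RMSE
#'   and SE), scaling, and the data.
#' @export
fit_surface <- function(centroids, degrees = 2:10, k_folds = 5, seed = 1) {
  n <- nrow(centroids)
  x <- centroids$x; y <- centroids$y; z <- centroids$z
  cx <- (max(x) + min(x)) / 2; sx <- (max(x) - min(x)) / 2
  cy <- (max(y) + min(y)) / 2; sy <- (max(y) - min(y)) / 2
  if (sx == 0 || sy == 0)
    stop("degenerate centroid cloud: x or y has zero extent (collinear)")
  u <- (x - cx) / sx; v <- (y - cy) / sy
  ncoef <- (degrees + 1) * (degrees + 2) / 2
  usable <- degrees[ncoef <= n]
  if (!length(usable))
    stop("too few centroids (", n, ") for the smallest candidate degree")
  if (length(usable) < length(degrees))
    message("degrees ", paste(setdiff(degrees, usable), collapse = ","),
            " dropped: need more coefficients than points")
  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  scores <- data.frame(degree = usable, cv_rmse = NA_real_, se = NA_real_)
  for (di in seq_along(usable)) {
    deg <- usable[di]
    fold_rmse <- numeric(k_folds)
    for (f in seq_len(k_folds)) {
      tr <- folds != f
      X <- poly_design(u[tr], v[tr], deg)
      fit <- lm.fit(X, z[tr])
      Xte <- poly_design(u[!tr], v[!tr], deg)
      pred <- Xte %*% ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      fold_rmse[f] <- sqrt(mean((z[!tr] - pred)^2))
    }
    scores$cv_rmse[di] <- mean(fold_rmse)
    scores$se[di] <- sd(fold_rmse) / sqrt(k_folds)
  }
  best <- which.min(scores$cv_rmse)
  # one-SE rule: smallest degree within one SE of the minimum
  ok <- scores$cv_rmse <= scores$cv_rmse[best] + scores$se[best]
  chosen <- scores$degree[which(ok)[1]]
  X <- poly_design(u, v, chosen)
  fit <- lm.fit(X, z)
  if (any(is.na(fit$coefficients)))
    stop("rank-deficient design at degree ", chosen,
         ": centroid (x, y) positions are degenerate")
  resid <- z - X %*% fit$coefficients
  structure(list(degree = chosen, coefficients = fit$coefficients,
                 basis = poly_basis_exponents(chosen),
                 rmse = sqrt(mean(resid^2)),
                 selection_scores = scores,
                 scaling = list(cx = cx, sx = sx, cy = cy, sy = sy),
                 centroids = centroids),
            class = "surface_fit")
}

#' @export
print.surface_fit <- function(x, ...) {
  cat("<surface_fit> degree", x$degree, " rmse(um)", signif(x$rmse, 4),
      " n", nrow(x$centroids), "\n")
  invisible(x)
}

#' Predict surface height at (x, y) in um
#' @param object a `surface_fit`.
#' @param x,y coordinates (um).
#' @param ... unused.
#' @export
predict.surface_fit <- function(object, x, y, ...) {
  s <- object$scaling
  X <- poly_design((x - s$cx) / s$sx, (y - s$cy) / s$sy, object$degree)
  as.vector(X %*% object$coefficients)
}

#' Tumor attrition from fragment projection onto the fitted surface
#'
#' The surface domain — the convex hull of the fragment (x, y) centroids —
#' is discretized into square grid cells; a cell is occupied when some
#' fragment footprint (a disc of that fragment's equivalent radius around
#' its centroid) covers the cell center. Attrition is the percentage of
#' in-domain cells left unoccupied. Footprint projection is the default;
#' `footprint = FALSE` uses bare centroids (a cell is occupied only if it
#' contains one).
#'
#' @param fit a [fit_surface()] result (used for its centroid cloud when
#'   `centroids` is missing).
#' @param centroids data.frame with `x`, `y` and `radius_um`.
#' @param grid_cell grid cell size (um).
#' @param footprint use blob footprints (default) or centroids only.
#' @return list with `attrition_pct`, `occupied_grid` (logical matrix with
#'   NA outside the hull), grid geometry.
#' @export
attrition_from_projection <- function(fit, centroids = NULL,
                                      grid_cell = 10, footprint = TRUE) {
  if (is.null(centroids)) centroids <- fit$centroids
  if (!nrow(centroids)) stop("empty centroid set")
  stopifnot(grid_cell > 0)
  x <- centroids$x; y <- centroids$y
  r <- if (footprint && !is.null(centroids$radius_um))
    centroids$radius_um else rep(0, length(x))
  hull <- chull(x, y)
  hx <- x[hull]; hy <- y[hull]
  gx <- seq(min(x) + grid_cell / 2, max(x), by = grid_cell)
  gy <- seq(min(y) + grid_cell / 2, max(y), by = grid_cell)
  cx <- rep(gx, times = length(gy))
  cy <- rep(gy, each = length(gx))
  inside <- points_in_polygon(cx, cy, cbind(hx, hy))
  occ <- rep(FALSE, length(cx))
  if (footprint) {
    for (i in seq_along(x)) {
      near <- which(abs(cx - x[i]) <= r[i] & abs(cy - y[i]) <= r[i])
      if (!length(near)) next
      hit <- (cx[near] - x[i])^2 + (cy[near] - y[i])^2 <= r[i]^2
      occ[near[hit]] <- TRUE
    }
  } else {
    half <- grid_cell / 2
    for (i in seq_along(x)) {
      near <- which(abs(cx - x[i]) <= half & abs(cy - y[i]) <= half)
      occ[near] <- TRUE
    }
  }
  n_in <- sum(inside)
  if (n_in == 0) stop("degenerate hull: no grid cells inside")
  att <- 100 * sum(inside & !occ) / n_in
  grid <- matrix(NA, length(gx), length(gy))
  grid[matrix(c(match(cx, gx), match(cy, gy)), ncol = 2)[inside, ]] <-
    occ[inside]
  list(attrition_pct = att, occupied_grid = grid, grid_x = gx, grid_y = gy,
       grid_cell = grid_cell, n_cells_domain = n_in,
       footprint = footprint)
}
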