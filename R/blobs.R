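#' Multiscale blob detection (difference-of-Gaussian)
#'
#' Detects compact bright objects (cells, foci) as scale-space maxima of a
#' difference-of-Gaussian approximation to the scale-normalized Laplacian.
#' Works on 2D and 3D arrays with anisotropic spacing: smoothing sigmas are
#' specified in micrometres and converted per axis.
#'
#' The input is range-normalized to `[0, 1]` before filtering, so
#' `threshold` is a fraction of the image dynamic range. Candidates are
#' spatial local maxima of each DoG layer that also dominate the adjacent
#' scales at the same voxel; overlapping candidates (closer than the larger
#' radius) are merged, keeping the stronger response. Detections whose
#' estimated radius extends beyond the image border are flagged
#' `truncated = TRUE` rather than dropped.
#'
#' @param arr numeric array (2D or 3D).
#' @param spacing per-axis voxel size (um).
#' @param min_sigma,max_sigma blob scale range in um (blob radius is about
#'   `sigma * sqrt(d)` for dimensionality d).
#' @param n_scales number of geometric scale steps.
#' @param threshold minimum DoG response (fraction of dynamic range when
#'   `normalize = TRUE`, absolute otherwise).
#' @param normalize range-normalize the input to `[0, 1]` first; disable
#'   when the input is already on a calibrated scale and an absolute
#'   response threshold is wanted.
#' @return data.frame with one row per blob: centroid columns (`z`, `y`,
#'   `x` in um as applicable), `sigma_um`, `radius_um`, `response`,
#'   `truncated`.
#' @export
detect_blobs <- function(arr, spacing, min_sigma = 3, max_sigma = 8,
                         n_scales = 5L, threshold = 0.05,
                         normalize = TRUE) {
  d <- dim(arr)
  nd <- length(d)
  spacing <- rep_len(spacing, nd)
  rng <- range(arr)
  v <- if (!normalize) arr
       else if (diff(rng) > 0) (arr - rng[1]) / diff(rng) else arr * 0
  sigmas <- exp(seq(log(min_sigma), log(max_sigma), length.out = n_scales + 1L))
  sm <- lapply(sigmas, function(s) gaussian_smooth(v, s, spacing))
  dog <- vector("list", n_scales)
  for (i in seq_len(n_scales))
    dog[[i]] <- (sm[[i]] - sm[[i + 1]]) * sigmas[i] / (sigmas[i + 1] - sigmas[i])
  cand <- list()
  for (i in seq_len(n_scales)) {
    mx <- cpp_local_max(as.numeric(dog[[i]]), d, threshold)
    idx <- which(mx)
    if (!length(idx)) next
    keep <- rep(TRUE, length(idx))
    if (i > 1) keep <- keep & dog[[i]][idx] >= dog[[i - 1]][idx]
    if (i < n_scales) keep <- keep & dog[[i]][idx] >= dog[[i + 1]][idx]
    idx <- idx[keep]
    if (!length(idx)) next
    co <- arrayInd(idx, d)
    cand[[length(cand) + 1L]] <- data.frame(
      co, sigma_um = sigmas[i], response = dog[[i]][idx])
  }
  cols <- if (nd == 3L) c("z", "y", "x") else c("y", "x")
  if (!length(cand)) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), nd), cols))
    out$sigma_um <- numeric(0); out$radius_um <- numeric(0)
    out$response <- numeric(0); out$truncated <- logical(0)
    out$id <- integer(0)
    return(out[c("id", cols, "sigma_um", "radius_um", "response", "truncated")])
  }
  cand <- do.call(rbind, cand)
  names(cand)[seq_len(nd)] <- cols
  # voxel indices -> um
  pos <- as.matrix(cand[cols])
  for (a in seq_len(nd)) pos[, a] <- (pos[, a] - 1) * spacing[a]
  cand[cols] <- pos
  cand$radius_um <- cand$sigma_um * sqrt(nd)
  # merge overlapping candidates, strongest first
  ord <- order(-cand$response)
  cand <- cand[ord, , drop = FALSE]
  accepted <- integer()
  for (r in seq_len(nrow(cand))) {
    if (length(accepted)) {
      dd <- sqrt(rowSums((as.matrix(cand[accepted, cols, drop = FALSE]) -
        matrix(pos[ord[r], ], length(accepted), nd, byrow = TRUE))^2))
      if (any(dd < pmax(cand$radius_um[accepted], cand$radius_um[r]))) next
    }
    accepted <- c(accepted, r)
  }
  out <- cand[accepted, , drop = FALSE]
  extent <- (d - 1) * spacing
  pm <- as.matrix(out[cols])
  out$truncated <- apply(pm - out$radius_um < 0, 1, any) |
    apply(pm + out$radius_um > matrix(extent, nrow(pm), nd, byrow = TRUE),
          1, any)
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[c("id", cols, "sigma_um", "radius_um", "response", "truncated")]
}
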