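#' @title Grid morphology and distance primitives
#'
#' @description Binary morphology with rectangular (box) structuring
#' elements in 2D/3D, exact anisotropic Euclidean distance transforms,
#' separable Gaussian smoothing and connected-component labeling. Box
#' structuring elements of even size are anchored at `floor(k/2)` (0-based),
#' a fixed, documented convention so results are bit-stable; erosion and
#' dilation share the anchor, so closing `(A %+% B) %-% B` is extensive and
#' opening anti-extensive.
#'
#' @name craters-morphology
NULL

box_k <- function(k, nd) {
  k <- as.integer(rep_len(k, nd))
  if (any(k < 1)) stop("kernel size must be >= 1")
  k
}

#' Box dilation / erosion of a binary array
#'
#' @param mask logical/0-1 array (2D or 3D).
#' @param k structuring-element size in voxels, scalar or per-axis.
#' @return integer 0/1 array of the same shape.
#' @export
box_dilate <- function(mask, k) {
  d <- dim(mask); k <- box_k(k, length(d))
  # the sliding window computes max over A[i + s]; dilation by B needs
  # max over A[i - b], so the window anchor is the mirror of the SE anchor
  out <- cpp_box_filter(as.numeric(mask != 0), d, k, k - 1L - k %/% 2L, TRUE)
  array(as.integer(out > 0), d)
}

#' @rdname box_dilate
#' @export
box_erode <- function(mask, k) {
  d <- dim(mask); k <- box_k(k, length(d))
  # pad with background so voxels whose window leaves the array erode away
  # (out-of-range counts as background, the usual binary-erosion contract)
  padded <- pad_array(array(as.integer(mask != 0), d), k)
  out <- cpp_box_filter(as.numeric(padded), dim(padded), k, k %/% 2L, FALSE)
  crop_array(array(as.integer(out >= 1), dim(padded)), k, d)
}

#' Box closing / opening with background padding
#'
#' Closing pads the volume with background (0) by the kernel size before
#' dilating, then erodes and crops, preventing phantom structures at image
#' borders. Opening needs no padding (out-of-range voxels act as background).
#'
#' @inheritParams box_dilate
#' @export
box_close <- function(mask, k) {
  d <- dim(mask); k <- box_k(k, length(d))
  padded <- pad_array(array(as.integer(mask != 0), d), k)
  out <- box_erode(box_dilate(padded, k), k)
  crop_array(out, k, d)
}

#' @rdname box_close
#' @export
box_open <- function(mask, k) {
  box_dilate(box_erode(mask, k), k)
}

pad_array <- function(arr, pad) {
  d <- dim(arr)
  nd <- length(d)
  out <- array(0L, d + 2L * pad)
  idx <- lapply(seq_len(nd), function(i) pad[i] + seq_len(d[i]))
  do.call(`[<-`, c(list(out), idx, list(arr)))
}

crop_array <- function(arr, pad, shape) {
  idx <- lapply(seq_along(shape), function(i) pad[i] + seq_len(shape[i]))
  array(do.call(`[`, c(list(arr), idx)), shape)
}

#' Exact Euclidean distance map to a mask
#'
#' Distance (um) from every voxel to the nearest voxel of `mask`, honoring
#' anisotropic spacing. Exact (Felzenszwalb-Huttenlocher transform), so it
#' agrees with brute-force nearest-voxel search to machine precision.
#'
#' @param mask logical/0-1 array (the reference set).
#' @param spacing per-axis voxel size (um).
#' @return numeric array of distances; error if `mask` is empty.
#' @export
distance_map <- function(mask, spacing) {
  if (!any(mask != 0)) stop("distance_map: reference mask is empty")
  d <- dim(mask)
  sqrt(cpp_edt_sq(as.numeric(mask != 0), d, as.numeric(rep_len(spacing,
                                                               length(d)))))
}

#' Separable Gaussian smoothing
#'
#' @param arr numeric array (2D/3D).
#' @param sigma_um smoothing sigma in um (scalar, isotropic in physical
#'   space) — converted per axis via `spacing`.
#' @param spacing per-axis voxel size (um).
#' @return smoothed array.
#' @export
gaussian_smooth <- function(arr, sigma_um, spacing) {
  d <- dim(arr)
  sig <- sigma_um / rep_len(spacing, length(d))
  cpp_gauss(as.numeric(arr), d, sig)
}

#' Connected-component labeling
#'
#' @param mask logical/0-1 array.
#' @param connectivity 4/8 in 2D, 6/26 in 3D; default full connectivity.
#' @return integer label array (0 background), labels in raster-scan order.
#' @export
label_components <- function(mask, connectivity = NULL) {
  d <- dim(mask)
  if (is.null(connectivity)) connectivity <- if (length(d) == 3L) 26L else 8L
  cpp_label(as.integer(mask != 0), d, as.integer(connectivity))
}

#' Otsu threshold of an array
#'
#' Histogram-based global threshold maximizing between-class variance
#' (delegates to EBImage's implementation on the flattened, range-normalized
#' data). Errors on constant input, where the criterion is undefined.
#'
#' @param arr numeric array.
#' @param levels histogram bin count.
#' @return threshold on the original intensity scale.
#' @export
otsu_threshold <- function(arr, levels = 256L) {
  r <- range(arr)
  if (diff(r) == 0) stop("Otsu threshold undefined on constant input (no foreground)")
  v <- (as.vector(arr) - r[1]) / diff(r)
  th <- EBImage::otsu(EBImage::Image(matrix(v, ncol = 1)), range = c(0, 1),
                      levels = levels)
  r[1] + th * diff(r)
}

#' Fill enclosed background holes in a binary mask
#'
#' Background components not connected to the array border are set to
#' foreground. Uses face connectivity for the background.
#'
#' @param mask logical/0-1 array (2D or 3D).
#' @return integer 0/1 array.
#' @export
fill_holes <- function(mask) {
  d <- dim(mask)
  bg <- array(as.integer(mask == 0), d)
  lab <- cpp_label(bg, d, if (length(d) == 3L) 6L else 4L)
  border_idx <- border_voxel_indices(d)
  keep <- unique(lab[border_idx])
  out <- array(1L, d)
  out[lab %in% keep & lab > 0] <- 0L
  out
}

border_voxel_indices <- function(d) {
  nd <- length(d)
  idx <- c()
  for (ax in seq_len(nd)) {
    sel <- lapply(d, seq_len)
    for (v in c(1L, d[ax])) {
      sel2 <- sel; sel2[[ax]] <- v
      g <- as.matrix(expand.grid(sel2))
      lin <- g[, 1]
      mult <- 1
      for (dd in 2:nd) {
        mult <- mult * d[dd - 1]
        lin <- lin + (g[, dd] - 1L) * mult
      }
      idx <- c(idx, lin)
    }
  }
  unique(idx)
}

#' Labels of components touching the array border
#' @param lab integer label array.
#' @return integer vector of labels with at least one border voxel.
#' @export
border_labels <- function(lab) {
  setdiff(unique(lab[border_voxel_indices(dim(lab))]), 0L)
}
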