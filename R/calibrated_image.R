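#' Calibrated intensity image
#'
#' An n-D intensity array (2D or 3D, with an optional trailing channel axis)
#' carrying per-spatial-axis physical voxel size in micrometres and ordered
#' channel names. Physical coordinates follow the convention that array index
#' `(1, 1, ...)` sits at the origin, i.e. `coord_um = (index - 1) * spacing`.
#'
#' Axis order is `"zyx"` for 3D and `"yx"` for 2D, with `"c"` appended when a
#' channel axis is present (always last).
#'
#' @param data numeric array, 2D or 3D spatial, optional channel axis last.
#' @param spacing numeric vector of per-spatial-axis voxel size (um),
#'   ordered like the spatial axes.
#' @param channels character vector of channel names, or `NULL` for a
#'   single-channel image with no channel axis. Defaults to `c0..cN` when a
#'   channel axis exists.
#' @param axes axis-order string, e.g. `"zyx"`, `"zyxc"`, `"yx"`, `"yxc"`.
#'   Inferred from `data` and `channels` when omitted.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(data, spacing, channels = NULL, axes = NULL) {
  if (is.null(dim(data))) stop("`data` must be an array")
  nd <- length(dim(data))
  has_ch <- (!is.null(axes) && endsWith(axes, "c")) || nd == 4L ||
    (!is.null(channels) && length(channels) > 1L)
  if (is.null(axes)) {
    nsp <- if (has_ch) nd - 1L else nd
    axes <- paste0(if (nsp == 3L) "zyx" else "yx", if (has_ch) "c" else "")
  }
  nsp <- nchar(sub("c$", "", axes))
  if (nsp < 2L || nsp > 3L) stop("only 2D or 3D spatial images are supported")
  if (length(spacing) != nsp)
    stop("`spacing` length must equal the number of spatial axes (", nsp, ")")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` values must be strictly positive")
  if (endsWith(axes, "c")) {
    ncH <- dim(data)[nd]
    if (is.null(channels)) channels <- paste0("c", seq_len(ncH) - 1L)
    if (length(channels) != ncH)
      stop("channel count (", ncH, ") != length of `channels` (",
           length(channels), ")")
  } else if (!is.null(channels) && length(channels) != 1L) {
    stop("multiple channel names given but `data` has no channel axis")
  }
  names(spacing) <- strsplit(sub("c$", "", axes), "")[[1]]
  structure(list(data = data, spacing = spacing,
                 channels = channels, axes = axes),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat("<calibrated_image> ", paste(dim(x$data), collapse = "x"),
      " axes=", x$axes,
      " spacing(um)=", paste(signif(x$spacing, 4), collapse = ","),
      if (!is.null(x$channels))
        paste0(" channels=", paste(x$channels, collapse = ",")),
      "\n", sep = "")
  invisible(x)
}

n_spatial_axes <- function(img) nchar(sub("c$", "", img$axes))

#' Extract one channel as a bare spatial array
#'
#' @param img a [calibrated_image()].
#' @param channel channel name or index; ignored for single-channel images.
#' @return numeric array with the spatial dimensions of `img`.
#' @export
get_channel <- function(img, channel = NULL) {
  if (!endsWith(img$axes, "c")) return(img$data)
  if (is.null(channel)) stop("multichannel image: `channel` is required")
  if (is.character(channel)) {
    idx <- match(channel, img$channels)
    if (is.na(idx)) stop("channel '", channel, "' not found; have: ",
                         paste(img$channels, collapse = ", "))
  } else idx <- as.integer(channel)
  nd <- length(dim(img$data))
  out <- if (nd == 3L) img$data[, , idx] else img$data[, , , idx]
  array(out, dim(img$data)[-nd])
}

#' Maximum-intensity z-projection
#'
#' Collapses a 3D stack to 2D by taking, per pixel and channel, the maximum
#' over z. Spacing is reduced to the (y, x) axes. A 2D input is returned
#' unchanged with a warning.
#'
#' @param img a 3D [calibrated_image()].
#' @return a 2D [calibrated_image()].
#' @export
max_project <- function(img) {
  stopifnot(inherits(img, "calibrated_image"))
  if (n_spatial_axes(img) == 2L) {
    warning("input is already 2D; returning unchanged")
    return(img)
  }
  d <- dim(img$data)
  if (endsWith(img$axes, "c")) {
    out <- array(NA_real_, c(d[2], d[3], d[4]))
    for (ch in seq_len(d[4]))
      out[, , ch] <- apply(img$data[, , , ch], c(2, 3), max)
    calibrated_image(out, img$spacing[c("y", "x")], img$channels, "yxc")
  } else {
    out <- apply(img$data, c(2, 3), max)
    calibrated_image(out, img$spacing[c("y", "x")], NULL, "yx")
  }
}
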