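#' @title Image and mask I/O (TIFF + JSON sidecar)
#'
#' @description Images and masks are serialized as plain TIFF with a JSON
#' sidecar (`<path>.json`) carrying calibration, axis order, channel names
#' and the intensity scaling used for storage. Label masks are written as
#' 16-bit pages (lossless for labels up to 65535); intensity data as 32-bit
#' float pages after affine rescaling to `[0, 1]` (offset/scale recorded in
#' the sidecar). Physical pixel size is never guessed: reading a file that
#' carries neither a sidecar, nor TIFF resolution metadata, nor an explicit
#' `spacing_override` is an error.
#'
#' @name craters-io
NULL

sidecar_path <- function(path) paste0(path, ".json")

split_pages <- function(arr) {
  # spatial-first array -> list of (y,x) matrices in page order
  nd <- length(dim(arr))
  if (nd == 2L) return(list(arr))
  if (nd == 3L) return(lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ]))
  stop("internal: unexpected page dimensionality")
}

join_pages <- function(pages, shape) {
  if (length(shape) == 2L) return(array(pages[[1]], shape))
  arr <- array(0, shape)
  for (z in seq_len(shape[1])) arr[z, , ] <- pages[[z]]
  arr
}

#' Write a calibrated image to TIFF with a JSON sidecar
#'
#' @param img a [calibrated_image()].
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "calibrated_image"))
  d <- img$data
  off <- min(d); rng <- max(d) - off
  if (rng == 0) rng <- 1
  scaled <- (d - off) / rng
  has_ch <- endsWith(img$axes, "c")
  pages <- list()
  if (has_ch) {
    nd <- length(dim(scaled))
    for (ch in seq_len(dim(scaled)[nd])) {
      sp <- if (nd == 3L) scaled[, , ch] else scaled[, , , ch]
      pages <- c(pages, split_pages(array(sp, dim(scaled)[-nd])))
    }
  } else pages <- split_pages(scaled)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(kind = "intensity", axes = img$axes, shape = dim(d),
               spacing = unname(img$spacing), channels = img$channels,
               offset = off, scale = rng)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a calibrated image
#'
#' Reads a TIFF written by [write_image()] (sidecar present), or a foreign
#' TIFF using its resolution metadata. When no physical pixel size can be
#' established and no `spacing_override` is supplied, reading fails rather
#' than silently assuming a unit.
#'
#' @param path TIFF file path.
#' @param spacing_override optional per-spatial-axis pixel size (um) that
#'   takes precedence over any metadata.
#' @return a [calibrated_image()].
#' @export
read_image <- function(path, spacing_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    shape <- as.integer(meta$shape)
    has_ch <- endsWith(meta$axes, "c")
    spshape <- if (has_ch) shape[-length(shape)] else shape
    if (has_ch) {
      nz <- if (length(spshape) == 3L) spshape[1] else 1L
      nch <- shape[length(shape)]
      arr <- array(0, shape)
      for (ch in seq_len(nch)) {
        blk <- join_pages(pages[(ch - 1L) * nz + seq_len(nz)], spshape)
        if (length(spshape) == 3L) arr[, , , ch] <- blk else arr[, , ch] <- blk
      }
    } else arr <- join_pages(pages, spshape)
    arr <- arr * meta$scale + meta$offset
    spacing <- if (!is.null(spacing_override)) spacing_override
               else as.numeric(meta$spacing)
    return(calibrated_image(arr, spacing,
                            channels = unlist(meta$channels),
                            axes = meta$axes))
  }
  info <- attr(tiff::readTIFF(path, info = TRUE), "info")
  arr <- tiff::readTIFF(path)
  if (length(dim(arr)) == 2L) {
    axes <- "yx"; channels <- NULL
  } else {
    axes <- "yxc"; channels <- paste0("c", seq_len(dim(arr)[3]) - 1L)
  }
  if (!is.null(spacing_override)) {
    spacing <- spacing_override
  } else {
    xres <- suppressWarnings(as.numeric(info$x.resolution))
    unit <- info$resolution.unit
    if (length(xres) == 1L && is.finite(xres) && xres > 0 &&
        !is.null(unit) && unit %in% c("cm", "inch")) {
      per_um <- if (unit == "cm") xres / 1e4 else xres / 25400
      spacing <- rep(1 / per_um, 2)
    } else {
      stop("no pixel-size metadata in '", path,
           "' and no `spacing_override` given; refusing to guess units")
    }
  }
  calibrated_image(arr, spacing, channels = channels, axes = axes)
}

write_label_tiff <- function(arr, path) {
  if (max(arr) > 65535) stop("label values above 65535 are not storable")
  tiff::writeTIFF(lapply(split_pages(arr / 65535), function(p) p),
                  path, bits.per.sample = 16L)
}

read_label_tiff <- function(path, shape) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- join_pages(pages, shape)
  array(as.integer(round(arr * 65535)), shape)
}

#' Write / read a region mask set
#'
#' Each mask becomes one integer TIFF inside `dir` (`tumor.tif`,
#' `craters.tif`, ...), with a `masks.json` sidecar recording shape, spacing
#' and which masks are present. The round trip is lossless: labels are
#' preserved exactly and never renumbered.
#'
#' @param masks a [region_mask_set()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_masks <- function(masks, dir) {
  stopifnot(inherits(masks, "region_mask_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  present <- character()
  for (nm in c("tumor", "craters", "margin", "vessels", "excluded_cells")) {
    if (is.null(masks[[nm]])) next
    write_label_tiff(masks[[nm]], file.path(dir, paste0(nm, ".tif")))
    present <- c(present, nm)
  }
  meta <- list(kind = "region_mask_set", shape = dim(masks$tumor),
               spacing = unname(masks$spacing), masks = present)
  jsonlite::write_json(meta, file.path(dir, "masks.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_masks
#' @export
read_masks <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "masks.json"),
                              simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  got <- list()
  for (nm in meta$masks)
    got[[nm]] <- read_label_tiff(file.path(dir, paste0(nm, ".tif")), shape)
  region_mask_set(tumor = got$tumor, craters = got$craters,
                  margin = got$margin, vessels = got$vessels,
                  excluded_cells = got$excluded_cells,
                  spacing = as.numeric(meta$spacing))
}

#' Write a cell/foci table as CSV with units in the header comment
#'
#' @param tab data.frame; coordinate columns are in micrometres.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(tab, path) {
  con <- file(path, "w")
  writeLines("# coordinates in um; areas in mm^2; densities in cells/mm^2",
             con)
  utils::write.csv(tab, con, row.names = FALSE)
  close(con)
  invisible(path)
}
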