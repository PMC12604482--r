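#' Co-registered region mask set
#'
#' Bundles the boolean tumor mask, the integer-labeled CRATER instance mask,
#' the margin band and optional vessel / excluded-cell masks, all sharing one
#' shape and one physical calibration. Label 0 is background in the crater
#' mask; crater labels are positive integers and are never renumbered by I/O.
#' The margin band lies outside the tumor by construction.
#'
#' @param tumor logical/0-1 array.
#' @param craters integer array of crater instance labels (0 = background).
#' @param margin logical/0-1 array, disjoint from `tumor`. Optional.
#' @param vessels,excluded_cells optional logical arrays.
#' @param spacing per-spatial-axis voxel size (um).
#' @return an object of class `region_mask_set`.
#' @export
region_mask_set <- function(tumor, craters = NULL, margin = NULL,
                            vessels = NULL, excluded_cells = NULL, spacing) {
  shp <- unname(dim(tumor))
  if (is.null(shp)) stop("`tumor` must be an array")
  if (is.null(craters)) craters <- array(0L, shp)
  for (nm in c("craters", "margin", "vessels", "excluded_cells")) {
    m <- get(nm)
    if (!is.null(m) && !identical(unname(dim(m)), shp))
      stop("mask '", nm, "' shape differs from tumor shape")
  }
  if (length(spacing) != length(shp))
    stop("`spacing` length must match mask dimensionality")
  if (any(spacing <= 0)) stop("`spacing` must be strictly positive")
  if (any(craters < 0) || any(craters != round(craters)))
    stop("crater labels must be non-negative integers")
  if (!is.null(margin) && any(margin != 0 & tumor != 0))
    stop("margin and tumor masks must be disjoint")
  names(spacing) <- if (length(shp) == 3L) c("z", "y", "x") else c("y", "x")
  structure(list(tumor = array(as.integer(tumor != 0), shp),
                 craters = array(as.integer(craters), shp),
                 margin = if (!is.null(margin))
                   array(as.integer(margin != 0), shp),
                 vessels = if (!is.null(vessels))
                   array(as.integer(vessels != 0), shp),
                 excluded_cells = if (!is.null(excluded_cells))
                   array(as.integer(excluded_cells != 0), shp),
                 spacing = spacing),
            class = "region_mask_set")
}

#' @export
print.region_mask_set <- function(x, ...) {
  cat("<region_mask_set> ", paste(dim(x$tumor), collapse = "x"),
      " spacing(um)=", paste(signif(x$spacing, 4), collapse = ","),
      " craters=", length(setdiff(unique(as.vector(x$craters)), 0L)),
      " masks=", paste(names(Filter(Negate(is.null),
        x[c("margin", "vessels", "excluded_cells")])), collapse = ","),
      "\n", sep = "")
  invisible(x)
}
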