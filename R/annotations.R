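#' Region annotations (QuPath-style GeoJSON)
#'
#' Reads polygonal region annotations from the GeoJSON dialect QuPath
#' exports: a `FeatureCollection` whose features carry
#' `properties$classification$name` (or `properties$class`) as the class
#' label. Coordinates are taken as micrometres; supply `pixel_size` to scale
#' pixel-unit files. Every feature must carry a class; self-intersecting
#' polygons are rejected with the index of the offending geometry.
#'
#' @param paths one or more GeoJSON file paths.
#' @param annotator annotator id(s), recycled over `paths`; defaults to the
#'   file's `properties$annotator` or, failing that, the file name.
#' @param pixel_size multiply coordinates by this factor (um per unit).
#' @return data.frame with one row per polygon: `class`, `annotator`,
#'   `area_um2`, and a list-column `polygon` of n x 2 matrices (x, y in um).
#' @export
read_annotations <- function(paths, annotator = NULL, pixel_size = 1) {
  if (!is.null(annotator)) annotator <- rep_len(annotator, length(paths))
  out <- list()
  for (fi in seq_along(paths)) {
    gj <- jsonlite::read_json(paths[fi])
    feats <- if (!is.null(gj$features)) gj$features else list(gj)
    for (i in seq_along(feats)) {
      f <- feats[[i]]
      cls <- f$properties$classification$name
      if (is.null(cls)) cls <- f$properties$class
      if (is.null(cls))
        stop("feature ", i, " in '", paths[fi], "' has no class property")
      ann <- if (!is.null(annotator)) annotator[fi]
             else if (!is.null(f$properties$annotator)) f$properties$annotator
             else basename(paths[fi])
      geom <- f$geometry
      polys <- switch(geom$type,
        Polygon = list(geom$coordinates),
        MultiPolygon = geom$coordinates,
        stop("feature ", i, ": unsupported geometry type ", geom$type))
      for (p in polys) {
        ring <- do.call(rbind, lapply(p[[1]], function(xy)
          c(as.numeric(xy[[1]]), as.numeric(xy[[2]])))) * pixel_size
        # drop closing vertex if repeated
        n <- nrow(ring)
        if (n > 1 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
        if (nrow(ring) < 3) stop("feature ", i, ": degenerate polygon")
        if (!polygon_is_simple(ring))
          stop("feature ", i, " in '", paths[fi],
               "' is self-intersecting; rejecting")
        out[[length(out) + 1L]] <- list(class = cls, annotator = ann,
                                        area_um2 = polygon_area(ring),
                                        polygon = ring)
      }
    }
  }
  data.frame(class = vapply(out, `[[`, "", "class"),
             annotator = vapply(out, `[[`, "", "annotator"),
             area_um2 = vapply(out, `[[`, 0, "area_um2"),
             polygon = I(lapply(out, `[[`, "polygon")))
}

#' Polygon area by the shoelace formula
#' @param ring n x 2 matrix of vertices (um), not closed.
#' @return area in um^2 (always positive).
#' @export
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(seq_len(nrow(ring))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
                         (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# Simple-polygon test: no two non-adjacent edges properly intersect.
polygon_is_simple <- function(ring) {
  n <- nrow(ring)
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (segments_intersect(ring[i, ], ring[nxt[i], ],
                             ring[j, ], ring[nxt[j], ])) return(FALSE)
    }
  }
  TRUE
}

# Even-odd point-in-polygon for a grid of pixel centers.
points_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize polygon annotations to an instance label mask
#'
#' Pixel centers at `coord_um = (index - 1) * spacing`; pixels whose center
#' falls inside a polygon (even-odd rule) get that polygon's label, later
#' polygons overwriting earlier ones.
#'
#' @param annotations data.frame from [read_annotations()] (or any frame
#'   with a `polygon` list-column).
#' @param shape (ny, nx) output dimensions.
#' @param spacing (y, x) pixel size in um.
#' @return integer (ny, nx) label mask; row i of `annotations` has label i.
#' @export
rasterize_annotations <- function(annotations, shape, spacing) {
  lab <- array(0L, shape)
  xs <- (seq_len(shape[2]) - 1) * spacing[2]
  ys <- (seq_len(shape[1]) - 1) * spacing[1]
  grid <- cbind(px = rep(xs, each = shape[1]), py = rep(ys, shape[2]))
  for (i in seq_len(nrow(annotations))) {
    ring <- annotations$polygon[[i]]
    inside <- points_in_polygon(grid[, 1], grid[, 2], ring)
    lab[inside] <- i
  }
  lab
}
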