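#' Synthetic multiplexed-immunofluorescence (mIF) phantom
#'
#' Emulates a 2D multiplexed image of a human melanoma section: an S100+
#' tumor disc containing perivascular areas (PVAs — round stromal holes with
#' a CD31+/CD105+ vessel spot and an aSMA+ pericyte ring), CRATER notches
#' carved into the tumor along the perivascular-melanocytic boundary (PMB),
#' and per-class cells (tumor, stromal, CD8 T, CD4 T, Treg, CD163+CD11c+ DC)
#' rendered into a ground-truth cell label mask and class-specific intensity
#' channels. Collagen fibers are drawn as thin lines; every true CRATER is
#' crossed by exactly one.
#'
#' Besides the true CRATERs the generator can plant one decoy candidate per
#' disqualifying rule (oversized, vessel-containing, aSMA-containing,
#' nuclei-rich, collagen-rich, off-boundary), so the rule classifier can be
#' tested candidate-by-candidate.
#'
#' The manifest records, analytically from the planted geometry: the PMB
#' length of every hole after notch carving (union-of-discs perimeter), the
#' per-candidate features and expected accept/reject, per-cell class and
#' region, and the true CRATER linear density per cm of PMB.
#'
#' @param shape (ny, nx) pixels; spacing is 1 um/px.
#' @param tumor_radius tumor disc radius (um).
#' @param n_pva number of perivascular holes.
#' @param pva_radius range of hole radii (um).
#' @param n_craters number of true CRATER notches on the PMB.
#' @param crater_diameter range of CRATER diameters (um; the human
#'   definition is 20-50 um).
#' @param include_decoys plant the six rule-violating decoy candidates.
#' @param noise_sd channel noise (fraction of the unit class intensity).
#' @param cell_radius cell disc radius (um).
#' @param seed RNG seed.
#' @return list with `image` (a [calibrated_image()]), `cell_mask`
#'   (integer label mask), and `truth` (cells, candidates, holes, PMB
#'   lengths, linear density, tumor mask).
#' @export
make_mif_phantom <- function(shape = c(700, 700), tumor_radius = 250,
                             n_pva = 3, pva_radius = c(45, 55),
                             n_craters = 4, crater_diameter = c(28, 44),
                             include_decoys = TRUE, noise_sd = 0.02,
                             cell_radius = 4, seed = 1) {
  with_seed(seed, {
    ny <- shape[1]; nx <- shape[2]
    ctr <- c(ny, nx) / 2
    ys <- seq_len(ny) - 1; xs <- seq_len(nx) - 1
    dy2 <- (ys - ctr[1])^2
    dx2 <- (xs - ctr[2])^2
    disc <- function(cy, cx, r)
      outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2
    tumor0 <- outer(dy2, dx2, `+`) <= tumor_radius^2

    # -- perivascular holes
    holes <- data.frame(cy = numeric(0), cx = numeric(0), r = numeric(0))
    att <- 0
    while (nrow(holes) < n_pva) {
      att <- att + 1
      if (att > 20000) stop("cannot place perivascular holes")
      if (att %% 1000 == 0) holes <- holes[0, ]   # restart a stuck layout
      r <- runif(1, pva_radius[1], pva_radius[2])
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0, tumor_radius - r - 60)
      cy <- ctr[1] + rad * sin(ang); cx <- ctr[2] + rad * cos(ang)
      if (nrow(holes) &&
          min(sqrt((holes$cy - cy)^2 + (holes$cx - cx)^2) -
              holes$r - r) < 85) next
      holes <- rbind(holes, data.frame(cy = cy, cx = cx, r = r))
    }

    # -- candidate plan: true craters + decoys, notches carved on the PMB
    kinds <- c(rep("crater", n_craters),
               if (include_decoys) c("big", "vessel", "asma",
                                     "nuclei", "collagen", "offboundary"))
    cand <- data.frame(kind = if (length(kinds)) kinds else character(0),
                       diameter = runif(length(kinds), crater_diameter[1],
                                        crater_diameter[2]),
                       stringsAsFactors = FALSE)
    cand$hole <- integer(nrow(cand)) * NA_integer_
    cand$angle <- numeric(nrow(cand)) * NA_real_
    cand$cy <- numeric(nrow(cand)) * NA_real_
    cand$cx <- numeric(nrow(cand)) * NA_real_
    cand$diameter[cand$kind == "big"] <- 80
    cand$diameter[cand$kind == "nuclei"] <- 44
    cand$carved <- cand$kind != "offboundary"
    # assign notch candidates to holes round-robin with angular slots
    notch_idx <- which(cand$carved)
    per_hole_used <- vector("list", n_pva)
    hi <- 0L
    for (ci in notch_idx) {
      placed <- FALSE
      for (trial in seq_len(n_pva)) {
        hi <- hi %% n_pva + 1L
        R <- holes$r[hi]; r <- cand$diameter[ci] / 2
        alpha <- acos(pmax(-1, 1 - r^2 / (2 * R^2)))
        ok <- FALSE
        for (k in seq_len(50)) {
          ang <- runif(1, 0, 2 * pi)
          used <- per_hole_used[[hi]]
          if (is.null(used) ||
              all(abs((ang - used$ang + pi) %% (2 * pi) - pi) >
                  alpha + used$alpha + 0.25)) { ok <- TRUE; break }
        }
        if (!ok) next
        # keep the notch inside the tumor disc
        ncy <- holes$cy[hi] + R * sin(ang)
        ncx <- holes$cx[hi] + R * cos(ang)
        if (sqrt((ncy - ctr[1])^2 + (ncx - ctr[2])^2) + r >
            tumor_radius - 10) next
        cand$hole[ci] <- hi; cand$angle[ci] <- ang
        per_hole_used[[hi]] <- rbind(per_hole_used[[hi]],
                                     data.frame(ang = ang, alpha = alpha))
        placed <- TRUE
        break
      }
      if (!placed) stop("cannot place candidate ", ci, " on a hole boundary")
    }
    for (ci in notch_idx) {
      hi <- cand$hole[ci]
      cand$cy[ci] <- holes$cy[hi] + holes$r[hi] * sin(cand$angle[ci])
      cand$cx[ci] <- holes$cx[hi] + holes$r[hi] * cos(cand$angle[ci])
    }
    off <- which(cand$kind == "offboundary")
    if (length(off)) {
      ang <- runif(1, 0, 2 * pi)
      rad <- tumor_radius + 80
      cand$cy[off] <- ctr[1] + rad * sin(ang)
      cand$cx[off] <- ctr[2] + rad * cos(ang)
    }

    # -- carve holes and notches out of the tumor field
    tumor <- tumor0
    for (hi in seq_len(n_pva))
      tumor <- tumor & !disc(holes$cy[hi], holes$cx[hi], holes$r[hi])
    for (ci in notch_idx)
      tumor <- tumor & !disc(cand$cy[ci], cand$cx[ci], cand$diameter[ci] / 2)

    # -- analytic PMB length per hole (union-of-discs perimeter)
    pmb_len <- numeric(n_pva)
    for (hi in seq_len(n_pva)) {
      R <- holes$r[hi]
      on_h <- notch_idx[cand$hole[notch_idx] == hi]
      a_sum <- 0; add <- 0
      for (ci in on_h) {
        r <- cand$diameter[ci] / 2
        alpha <- acos(pmax(-1, 1 - r^2 / (2 * R^2)))
        gamma <- acos(pmin(1, r / (2 * R)))
        a_sum <- a_sum + 2 * alpha
        add <- add + (2 * pi - 2 * gamma) * r
      }
      pmb_len[hi] <- (2 * pi - a_sum) * R + add
    }
    outer_len <- 2 * pi * tumor_radius

    # -- cells
    cells <- data.frame(y = numeric(0), x = numeric(0),
                        class = character(0), region = character(0))
    add_cell <- function(y, x, class, region) {
      if (nrow(cells) &&
          min(sqrt((cells$y - y)^2 + (cells$x - x)^2)) < 2.1 * cell_radius)
        return(FALSE)
      cells[nrow(cells) + 1L, ] <<- list(y, x, class, region)
      TRUE
    }
    sample_in_disc <- function(cy, cx, r) {
      th <- runif(1, 0, 2 * pi); rr <- r * sqrt(runif(1))
      c(cy + rr * sin(th), cx + rr * cos(th))
    }
    rejection_place <- function(n, class, region, gen, ok = NULL,
                                required = TRUE) {
      att <- 0
      while (n > 0) {
        att <- att + 1
        if (att > 20000) {
          if (required) stop("cell placement failed for class ", class)
          break      # best-effort fill; truth counts use placed cells
        }
        p <- gen()
        if (p[1] < 6 || p[1] > ny - 6 || p[2] < 6 || p[2] > nx - 6) next
        if (!is.null(ok) && !ok(p)) next
        if (add_cell(p[1], p[2], class, region)) n <- n - 1
      }
    }
    in_mask <- function(m) function(p)
      m[round(p[1]) + 1L, round(p[2]) + 1L]
    # tumor cells inside the (carved) tumor field, clear of its boundary
    tumor_core <- EBImage::erode(EBImage::Image(tumor * 1),
                                 EBImage::makeBrush(13, "disc")) > 0.5
    rejection_place(220, "tumor", "tumor",
                    function() sample_in_disc(ctr[1], ctr[2], tumor_radius),
                    in_mask(tumor_core))
    # dense stromal nuclei inside every hole (perivascular stroma), outside
    # the vessel/pericyte zone and clear of notches; the count scales with
    # the eligible area so heavily notched holes stay placeable
    for (hi in seq_len(n_pva)) {
      elig <- disc(holes$cy[hi], holes$cx[hi], holes$r[hi] - 5) &
        !disc(holes$cy[hi], holes$cx[hi], 18)
      for (ci in notch_idx)
        elig <- elig & !disc(cand$cy[ci], cand$cx[ci],
                             cand$diameter[ci] / 2 + 5)
      avail <- which(elig, arr.ind = TRUE)
      n_st <- min(35L, nrow(avail) %/% 90L)
      if (n_st > 0)
        rejection_place(n_st, "stroma", "pva", function() {
          rc <- avail[sample(nrow(avail), 1), ]
          c(rc[1] - 1, rc[2] - 1)
        }, required = FALSE)
    }
    # immune cells inside true craters: ~0.002 nuclei/um^2
    for (ci in which(cand$kind == "crater")) {
      r <- cand$diameter[ci] / 2
      n_in <- if (pi * r^2 * 0.0013 >= 2) 2L else 1L
      cls <- c("CD8T", "DC")
      for (k in seq_len(n_in))
        rejection_place(1, cls[k], paste0("crater", ci),
          function() sample_in_disc(cand$cy[ci], cand$cx[ci], r - 5))
    }
    # nuclei-rich decoy: many stromal nuclei inside the notch
    for (ci in which(cand$kind == "nuclei"))
      rejection_place(8, "stroma", paste0("cand", ci),
        function() sample_in_disc(cand$cy[ci], cand$cx[ci],
                                  cand$diameter[ci] / 2 - 5))
    # scattered immune cells in the outer stroma
    stroma_gen <- function() {
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, tumor_radius + 15, tumor_radius + 90)
      c(ctr[1] + rad * sin(ang), ctr[2] + rad * cos(ang))
    }
    rejection_place(10, "CD8T", "stroma", stroma_gen)
    rejection_place(10, "CD4T", "stroma", stroma_gen)
    rejection_place(5, "Treg", "stroma", stroma_gen)
    rejection_place(5, "DC", "stroma", stroma_gen)

    # -- cell label mask
    cell_mask <- array(0L, c(ny, nx))
    for (i in seq_len(nrow(cells))) {
      d <- disc(cells$y[i], cells$x[i], cell_radius)
      cell_mask[d] <- i
    }

    # -- channels
    chan_names <- c("DAPI", "S100", "SOX10", "CD8a", "CD4", "FOXP3",
                    "CD163", "CD11c", "CD31", "CD105", "aSMA", "COL")
    chans <- setNames(lapply(chan_names, function(n) array(0, c(ny, nx))),
                      chan_names)
    paint_cells <- function(chan, classes, amp = 1) {
      for (i in which(cells$class %in% classes))
        chan[disc(cells$y[i], cells$x[i], cell_radius)] <- amp
      chan
    }
    chans$DAPI <- paint_cells(chans$DAPI, unique(cells$class))
    chans$S100 <- 0.8 * tumor
    chans$S100 <- paint_cells(chans$S100, "tumor")
    chans$SOX10 <- paint_cells(chans$SOX10, "tumor")
    chans$CD8a <- paint_cells(chans$CD8a, "CD8T")
    chans$CD4 <- paint_cells(chans$CD4, c("CD4T", "Treg"))
    chans$FOXP3 <- paint_cells(chans$FOXP3, "Treg")
    chans$CD163 <- paint_cells(chans$CD163, "DC")
    chans$CD11c <- paint_cells(chans$CD11c, "DC")
    for (hi in seq_len(n_pva)) {
      vs <- disc(holes$cy[hi], holes$cx[hi], 8)
      chans$CD31[vs] <- 1; chans$CD105[vs] <- 1
      ring <- disc(holes$cy[hi], holes$cx[hi], 15) &
        !disc(holes$cy[hi], holes$cx[hi], 10)
      chans$aSMA[ring] <- 1
    }
    for (ci in which(cand$kind == "vessel")) {
      vs <- disc(cand$cy[ci], cand$cx[ci], 6)
      chans$CD31[vs] <- 1; chans$CD105[vs] <- 1
    }
    for (ci in which(cand$kind == "asma"))
      chans$aSMA[disc(cand$cy[ci], cand$cx[ci], 6)] <- 1
    # collagen fibers: one through every crater-like candidate except the
    # collagen decoy, which gets four
    draw_line <- function(chan, cy, cx, ang, len, width = 1.2) {
      t <- seq(-len / 2, len / 2, by = 0.5)
      py <- cy + t * sin(ang); px <- cx + t * cos(ang)
      for (k in seq_along(t)) {
        yy <- round(py[k]) + 1L; xx <- round(px[k]) + 1L
        if (yy < 2 || yy > ny - 1 || xx < 2 || xx > nx - 1) next
        sel_y <- max(1, yy - 1):min(ny, yy + 1)
        sel_x <- max(1, xx - 1):min(nx, xx + 1)
        chan[sel_y, sel_x][outer((sel_y - 1 - py[k])^2,
                                 (sel_x - 1 - px[k])^2, `+`) <= width^2] <- 1
      }
      chan
    }
    for (ci in seq_len(nrow(cand))) {
      if (cand$kind[ci] %in% c("vessel", "asma")) next
      nfib <- if (cand$kind[ci] == "collagen") 4L else 1L
      base <- runif(1, 0, pi)
      for (f in seq_len(nfib)) {
        off <- (f - (nfib + 1) / 2) * 7       # perpendicular spacing
        chans$COL <- draw_line(chans$COL,
                               cand$cy[ci] + off * cos(base),
                               cand$cx[ci] - off * sin(base), base,
                               cand$diameter[ci] * 1.4)
      }
    }
    img_arr <- array(0, c(ny, nx, length(chan_names)))
    for (k in seq_along(chan_names))
      img_arr[, , k] <- chans[[k]] +
        array(abs(rnorm(ny * nx, 0, noise_sd)), c(ny, nx))
    img <- calibrated_image(img_arr, c(1, 1), channels = chan_names,
                            axes = "yxc")

    # -- planted candidate features and expected classification
    cand$on_boundary <- cand$kind != "offboundary"
    cand$fibers <- ifelse(cand$kind == "collagen", 4L,
                          ifelse(cand$kind %in% c("vessel", "asma"), 0L, 1L))
    cand$vessel_overlap <- cand$kind == "vessel"
    cand$asma_overlap <- cand$kind == "asma"
    cand$expected_accept <- cand$kind == "crater"
    nd <- 64
    th <- seq(0, 2 * pi, length.out = nd + 1)[-(nd + 1)]
    cand$polygon <- I(lapply(seq_len(nrow(cand)), function(ci)
      cbind(x = cand$cx[ci] + cand$diameter[ci] / 2 * cos(th),
            y = cand$cy[ci] + cand$diameter[ci] / 2 * sin(th))))

    pmb_cm <- sum(pmb_len) / 1e4
    truth <- list(
      holes = holes, candidates = cand,
      pmb_length_um = pmb_len, pmb_cm = pmb_cm,
      outer_boundary_um = outer_len,
      n_true_craters = sum(cand$kind == "crater"),
      linear_density_per_cm = sum(cand$kind == "crater") / pmb_cm,
      cells = cells, tumor_mask = tumor * 1L,
      perivascular_nuclear_density =
        sum(cells$class == "stroma" & cells$region == "pva") /
          sum(pi * holes$r^2),
      spacing = c(1, 1))
    list(image = img, cell_mask = cell_mask, truth = truth)
  })
}
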