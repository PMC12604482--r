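#' Synthetic annotator mask pair with planted overlap structure
#'
#' Builds two instance masks emulating two annotators outlining the same
#' CRATERs: `length(planted_ji)` object pairs whose Jaccard index is planted
#' to the requested values (rectangles of fixed size shifted horizontally by
#' the distance that produces the target IoU), plus `extra_a` objects only
#' in mask A and `extra_b` only in mask B. The manifest records the achieved
#' (integer-pixel) JI of every pair — computed directly from the planted
#' geometry — and the implied TP/FP/FN at the strict `ji > 0.4` matching
#' threshold.
#'
#' For an `h x w` rectangle shifted by `d` pixels, JI = (w-d)/(w+d), so
#' `d = round(w (1-ji)/(1+ji))`; with the default 40 x 60 objects the
#' achieved JI is within 0.02 of the request, otherwise an error names the
#' offending pair.
#'
#' @param planted_ji numeric vector of target Jaccard indices in `[0, 1]`.
#' @param extra_a,extra_b unmatched object counts in A / in B.
#' @param object_size `c(h, w)` rectangle size in pixels.
#' @param threshold matching threshold used for the manifest TP/FP/FN.
#' @param seed RNG seed (slot shuffling only; geometry is deterministic).
#' @return list with `mask_a`, `mask_b` (integer instance masks) and
#'   `truth` (achieved JI per pair, tp/fp/fn, tolerance).
#' @export
make_annotator_masks <- function(planted_ji = c(0.8, 0.6, 0.5),
                                 extra_a = 0L, extra_b = 0L,
                                 object_size = c(40L, 60L),
                                 threshold = 0.4, seed = 1) {
  stopifnot(all(planted_ji >= 0), all(planted_ji <= 1))
  with_seed(seed, {
    h <- object_size[1]; w <- object_size[2]
    npair <- length(planted_ji)
    nslot <- npair + extra_a + extra_b
    d <- integer(npair); achieved <- numeric(npair)
    for (i in seq_len(npair)) {
      ji <- planted_ji[i]
      d[i] <- if (ji <= 0) w else as.integer(round(w * (1 - ji) / (1 + ji)))
      achieved[i] <- if (d[i] >= w) 0 else (w - d[i]) / (w + d[i])
      if (abs(achieved[i] - ji) > 0.02)
        stop("pair ", i, ": planted JI ", ji, " not achievable within 0.02",
             " for ", h, "x", w, " objects (achieved ",
             round(achieved[i], 4), ")")
    }
    slot_w <- 2L * w + 20L
    slot_h <- h + 20L
    ncol_s <- ceiling(sqrt(nslot))
    nrow_s <- ceiling(nslot / ncol_s)
    shape <- c(nrow_s * slot_h + 20L, ncol_s * slot_w + 20L)
    mask_a <- array(0L, shape); mask_b <- array(0L, shape)
    slot_origin <- function(s) {
      r <- (s - 1L) %/% ncol_s; cc <- (s - 1L) %% ncol_s
      c(10L + r * slot_h, 10L + cc * slot_w)
    }
    slots <- sample(nslot)
    la <- 0L; lb <- 0L
    for (i in seq_len(npair)) {
      o <- slot_origin(slots[i])
      la <- la + 1L; lb <- lb + 1L
      mask_a[o[1] + seq_len(h), o[2] + seq_len(w)] <- la
      mask_b[o[1] + seq_len(h), o[2] + d[i] + seq_len(w)] <- lb
    }
    for (e in seq_len(extra_a)) {
      o <- slot_origin(slots[npair + e])
      la <- la + 1L
      mask_a[o[1] + seq_len(h), o[2] + seq_len(w)] <- la
    }
    for (e in seq_len(extra_b)) {
      o <- slot_origin(slots[npair + extra_a + e])
      lb <- lb + 1L
      mask_b[o[1] + seq_len(h), o[2] + seq_len(w)] <- lb
    }
    tp <- as.integer(sum(achieved > threshold))
    fp <- as.integer(npair - tp + extra_a)   # A objects without a match
    fn <- as.integer(npair - tp + extra_b)   # B objects without a match
    list(mask_a = mask_a, mask_b = mask_b,
         truth = list(planted_ji = planted_ji, achieved_ji = achieved,
                      threshold = threshold, tp = tp, fp = fp, fn = fn,
                      ji_tolerance = 0.02))
  })
}
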