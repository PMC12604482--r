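#' Jaccard index (intersection over union) of two pixel sets
#'
#' @param a,b logical arrays (or 0/1) of equal shape.
#' @return |a intersect b| / |a union b|; error when both sets are empty.
#' @export
jaccard <- function(a, b) {
  a <- a != 0; b <- b != 0
  u <- sum(a | b)
  if (u == 0) stop("Jaccard undefined: both sets empty")
  sum(a & b) / u
}

#' Match object instances between two annotation masks
#'
#' Candidate pairs are objects with Jaccard index strictly greater than
#' `threshold`; a one-to-one matching is chosen greedily by descending JI
#' (the standard instance-segmentation convention; optimal assignment via
#' exhaustive search is available for small problems in
#' [match_objects_optimal()]). Unmatched objects of A are false positives,
#' unmatched objects of B false negatives.
#'
#' @param mask_a,mask_b integer instance masks (0 background), same shape.
#' @param threshold JI matching threshold (strict `>`; the published rule
#'   is "greater than 0.4").
#' @return list: `matches` (data.frame `id_a`, `id_b`, `ji`), `tp`, `fp`,
#'   `fn`, `ji_all` (every overlapping pair's JI, for the JI histogram).
#' @export
match_objects <- function(mask_a, mask_b, threshold = 0.4) {
  stopifnot(identical(dim(mask_a), dim(mask_b)))
  ids_a <- sort(setdiff(unique(as.vector(mask_a)), 0L))
  ids_b <- sort(setdiff(unique(as.vector(mask_b)), 0L))
  sz_a <- if (length(ids_a)) table(factor(mask_a[mask_a > 0], ids_a))
  sz_b <- if (length(ids_b)) table(factor(mask_b[mask_b > 0], ids_b))
  both <- mask_a > 0 & mask_b > 0
  pairs <- if (any(both)) {
    ov <- as.data.frame(table(a = mask_a[both], b = mask_b[both]),
                        stringsAsFactors = FALSE)
    ov <- ov[ov$Freq > 0, ]
    ov$a <- as.integer(ov$a); ov$b <- as.integer(ov$b)
    ov$ji <- ov$Freq / (as.numeric(sz_a[as.character(ov$a)]) +
                        as.numeric(sz_b[as.character(ov$b)]) - ov$Freq)
    ov
  } else data.frame(a = integer(0), b = integer(0), Freq = integer(0),
                    ji = numeric(0))
  cand <- pairs[pairs$ji > threshold, , drop = FALSE]
  cand <- cand[order(-cand$ji, cand$a, cand$b), , drop = FALSE]
  used_a <- integer(0); used_b <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$a[i] %in% used_a || cand$b[i] %in% used_b) next
    keep[i] <- TRUE
    used_a <- c(used_a, cand$a[i]); used_b <- c(used_b, cand$b[i])
  }
  m <- cand[keep, , drop = FALSE]
  list(matches = data.frame(id_a = m$a, id_b = m$b, ji = m$ji),
       tp = nrow(m),
       fp = length(ids_a) - nrow(m),
       fn = length(ids_b) - nrow(m),
       ji_all = pairs$ji)
}

#' Optimal one-to-one matching by exhaustive assignment (small masks)
#'
#' Maximizes matched-pair count, then total JI, over all one-to-one
#' assignments of above-threshold pairs. Exponential; intended as the
#' reference for masks with few objects.
#'
#' @inheritParams match_objects
#' @return as [match_objects()].
#' @export
match_objects_optimal <- function(mask_a, mask_b, threshold = 0.4) {
  base <- match_objects(mask_a, mask_b, threshold)
  both <- mask_a > 0 & mask_b > 0
  ids_a <- sort(setdiff(unique(as.vector(mask_a)), 0L))
  ids_b <- sort(setdiff(unique(as.vector(mask_b)), 0L))
  ov <- if (any(both)) {
    t <- as.data.frame(table(a = mask_a[both], b = mask_b[both]),
                       stringsAsFactors = FALSE)
    t <- t[t$Freq > 0, ]
    t$a <- as.integer(t$a); t$b <- as.integer(t$b)
    t
  } else NULL
  if (is.null(ov) || !nrow(ov)) return(base)
  sz_a <- table(factor(mask_a[mask_a > 0], ids_a))
  sz_b <- table(factor(mask_b[mask_b > 0], ids_b))
  ov$ji <- ov$Freq / (as.numeric(sz_a[as.character(ov$a)]) +
                      as.numeric(sz_b[as.character(ov$b)]) - ov$Freq)
  ov <- ov[ov$ji > threshold, , drop = FALSE]
  if (!nrow(ov)) return(base)
  best <- list(n = -1, ji = -Inf, rows = integer(0))
  recurse <- function(rows, i, used_a, used_b) {
    if (i > nrow(ov)) {
      n <- length(rows); tot <- sum(ov$ji[rows])
      if (n > best$n || (n == best$n && tot > best$ji))
        best <<- list(n = n, ji = tot, rows = rows)
      return(invisible())
    }
    recurse(rows, i + 1, used_a, used_b)
    if (!(ov$a[i] %in% used_a) && !(ov$b[i] %in% used_b))
      recurse(c(rows, i), i + 1, c(used_a, ov$a[i]), c(used_b, ov$b[i]))
  }
  recurse(integer(0), 1L, integer(0), integer(0))
  m <- ov[best$rows, , drop = FALSE]
  list(matches = data.frame(id_a = m$a, id_b = m$b, ji = m$ji),
       tp = nrow(m), fp = length(ids_a) - nrow(m),
       fn = length(ids_b) - nrow(m), ji_all = base$ji_all)
}

#' Pairwise F1 concordance report across annotators
#'
#' For every mask pair: TP/FP/FN at the JI threshold, precision
#' (TP/(TP+FP)), recall (TP/(TP+FN)) and their harmonic mean F1; the
#' report's `mean_f1` is the arithmetic mean over pairs. Pairs with no
#' objects on either side have undefined F1 and are excluded with a
#' warning.
#'
#' @param pairs list of `list(a = mask, b = mask)` (or a list of masks, in
#'   which case all unordered pairs are compared).
#' @param threshold JI matching threshold.
#' @return object of class `concordance_report`: per-pair table,
#'   `mean_f1`, `ji_threshold`, JI histogram values.
#' @export
f1_report <- function(pairs, threshold = 0.4) {
  if (length(pairs) && !is.list(pairs[[1]])) stop("pairs must be lists")
  if (length(pairs) && is.null(pairs[[1]]$a)) {
    masks <- pairs
    idx <- utils::combn(length(masks), 2)
    pairs <- lapply(seq_len(ncol(idx)), function(i)
      list(a = masks[[idx[1, i]]], b = masks[[idx[2, i]]],
           name = paste0(idx[1, i], "-", idx[2, i])))
  }
  rows <- list(); ji_all <- numeric(0)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    m <- match_objects(p$a, p$b, threshold)
    ji_all <- c(ji_all, m$ji_all)
    if (m$tp + m$fp + m$fn == 0) {
      warning("pair ", i, " has no objects on either side; excluded")
      next
    }
    prec <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else NA_real_
    rec <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else 0
    rows[[length(rows) + 1L]] <-
      data.frame(pair = if (!is.null(p$name)) p$name else as.character(i),
                 tp = m$tp, fp = m$fp, fn = m$fn,
                 precision = prec, recall = rec, f1 = f1)
  }
  if (!length(rows)) stop("no scorable pairs")
  tab <- do.call(rbind, rows)
  structure(list(pairs = tab, mean_f1 = mean(tab$f1),
                 ji_threshold = threshold, ji_values = ji_all),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> threshold", x$ji_threshold,
      " mean F1 =", round(x$mean_f1, 4), "\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}
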