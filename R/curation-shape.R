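#' Footprint shape metrics
#'
#' Binarizes a spatial weight map at a fraction of its maximum, traces the
#' boundary polygon at that level (marching-squares contour), and computes
#' polygon area, perimeter, the compacity `C = P^2 / (4 pi A)` (1 for a
#' perfect circle; larger for rougher or more elongated contours), and the
#' inertia ratio, the ratio of the larger to the smaller principal second
#' moment of area of the binarized region (1 for a disk, `(a/b)^2` for an
#' ellipse with axis ratio `a/b`).
#'
#' @param fp numeric matrix, a nonnegative spatial weight map.
#' @param binarize_frac binarization threshold as a fraction of the map's
#'   maximum weight (default 0.5).
#' @param min_pixels minimum binarized size below which the footprint is
#'   flagged degenerate (default 9).
#' @return A list of class `shape_metrics`: `area`, `perimeter`, `compacity`,
#'   `inertia_ratio`, `centroid` (row, col), `n_pixels`, `degenerate`
#'   (logical), `reason` (character, when degenerate).
#' @export
compute_shape_metrics <- function(fp, binarize_frac = 0.5, min_pixels = 9) {
  stopifnot(is.matrix(fp))
  degen <- function(reason) {
    structure(list(area = NA_real_, perimeter = NA_real_,
                   compacity = NA_real_, inertia_ratio = NA_real_,
                   centroid = c(NA_real_, NA_real_), n_pixels = 0L,
                   degenerate = TRUE, reason = reason),
              class = "shape_metrics")
  }
  if (!any(is.finite(fp)) || max(fp, na.rm = TRUE) <= 0) return(degen("empty map"))
  thr <- binarize_frac * max(fp)
  mask <- fp >= thr
  npx <- sum(mask)
  if (npx < min_pixels) return(degen(sprintf("only %d px above threshold", npx)))

  # sub-pixel boundary polygon at the binarization level
  cl <- grDevices::contourLines(x = seq_len(nrow(fp)), y = seq_len(ncol(fp)),
                                z = fp, levels = thr)
  if (!length(cl)) return(degen("no closed contour at threshold"))
  # use the contour enclosing the largest area (footprints can shed specks)
  polys <- lapply(cl, function(p) cbind(p$x, p$y))
  areas <- vapply(polys, polygon_area, numeric(1))
  poly <- polys[[which.max(abs(areas))]]
  A <- abs(areas[which.max(abs(areas))])
  P <- polygon_perimeter(poly)
  if (A <= 0) return(degen("zero contour area"))

  # principal second moments of area from the binarized pixel set; the 1/12
  # per-pixel self-moment keeps one-pixel-thin regions non-singular
  idx <- which(mask, arr.ind = TRUE)
  mu <- colMeans(idx)
  dc <- sweep(idx, 2, mu)
  S <- crossprod(dc) / npx + diag(1 / 12, 2)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values

  structure(list(area = A, perimeter = P,
                 compacity = P^2 / (4 * pi * A),
                 inertia_ratio = max(ev) / min(ev),
                 centroid = unname(mu), n_pixels = npx,
                 degenerate = FALSE, reason = NA_character_),
            class = "shape_metrics")
}

polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  0.5 * sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)
}

polygon_perimeter <- function(xy) {
  d <- diff(rbind(xy, xy[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

#' Shape-based footprint filter
#'
#' Rejects a neuron when its inertia ratio exceeds `ir_max` (elongated shapes
#' such as dendrites or vessels) or its compacity exceeds `compacity_max`
#' (rough contours from background fluorescence); degenerate footprints are
#' rejected with a logged reason.
#'
#' @param fps a [footprint_set()].
#' @param ir_max inertia-ratio threshold (default 5; strict `>` rejects).
#' @param compacity_max compacity threshold (default 35; strict `>` rejects).
#' @param binarize_frac passed to [compute_shape_metrics()].
#' @return A list with `kept` and `rejected` (character id vectors),
#'   `metrics` (data frame per neuron) and `report` (per-id rejection
#'   reasons).
#' @export
filter_by_shape <- function(fps, ir_max = 5, compacity_max = 35,
                            binarize_frac = 0.5) {
  stopifnot(inherits(fps, "footprint_set"))
  ids <- names(fps$maps)
  rows <- lapply(ids, function(id) {
    m <- compute_shape_metrics(fps$maps[[id]], binarize_frac)
    data.frame(neuron_id = id, area = m$area, perimeter = m$perimeter,
               compacity = m$compacity, inertia_ratio = m$inertia_ratio,
               degenerate = m$degenerate, stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  reason <- rep(NA_character_, nrow(metrics))
  reject <- metrics$degenerate
  reason[reject] <- "degenerate footprint"
  ir_bad <- !metrics$degenerate & metrics$inertia_ratio > ir_max
  reject[ir_bad] <- TRUE
  reason[ir_bad] <- sprintf("inertia ratio %.2f > %g", metrics$inertia_ratio[ir_bad], ir_max)
  c_bad <- !metrics$degenerate & !ir_bad & metrics$compacity > compacity_max
  reject[c_bad] <- TRUE
  reason[c_bad] <- sprintf("compacity %.2f > %g", metrics$compacity[c_bad], compacity_max)
  list(kept = ids[!reject], rejected = ids[reject],
       metrics = metrics,
       report = data.frame(neuron_id = ids[reject], reason = reason[reject],
                           stringsAsFactors = FALSE))
}

#' Pairwise footprint overlap
#'
#' The symmetric overlap of two binarized footprints:
#' `overlap = 1/2 (|N1 n N2| / |N1| + |N1 n N2| / |N2|)`, i.e. the mean of
#' the intersection's share of each footprint, in `[0, 1]`.
#'
#' @param f1,f2 weight-map matrices on a common grid.
#' @param binarize_frac binarization threshold fraction (default 0.5).
#' @return Overlap fraction in `[0, 1]`.
#' @export
compute_pairwise_overlap <- function(f1, f2, binarize_frac = 0.5) {
  stopifnot(identical(dim(f1), dim(f2)))
  if (max(f1) <= 0 || max(f2) <= 0) stop("empty footprint: overlap undefined")
  m1 <- f1 >= binarize_frac * max(f1)
  m2 <- f2 >= binarize_frac * max(f2)
  a1 <- sum(m1); a2 <- sum(m2)
  inter <- sum(m1 & m2)
  0.5 * (inter / a1 + inter / a2)
}

#' Resolve highly overlapping footprint pairs
#'
#' Candidate pairs are footprints whose binarized centroids lie within
#' `centroid_max_px` of each other; for every candidate pair overlapping by
#' more than `overlap_max` the member with the lower peak-to-noise ratio is
#' removed. Pairs are processed in descending-overlap order and neurons
#' already removed cannot remove others; PNR ties remove the
#' lexicographically larger neuron id (deterministic, logged).
#'
#' @param fps a [footprint_set()].
#' @param pnr named numeric vector of per-neuron peak-to-noise ratios.
#' @param centroid_max_px centroid-distance gate in pixels (default 36).
#' @param overlap_max overlap threshold (default 0.5; strict `>` removes).
#' @param binarize_frac binarization threshold fraction.
#' @return A list with `kept`, `removed` (id vectors) and `log` (data frame
#'   of processed pairs: ids, overlap, which was removed).
#' @export
resolve_overlaps <- function(fps, pnr, centroid_max_px = 36, overlap_max = 0.5,
                             binarize_frac = 0.5) {
  stopifnot(inherits(fps, "footprint_set"))
  ids <- names(fps$maps)
  if (!all(ids %in% names(pnr))) stop("PNR missing for some neurons")
  cent <- t(vapply(fps$maps, function(m) {
    idx <- which(m >= binarize_frac * max(m), arr.ind = TRUE)
    colMeans(idx)
  }, numeric(2)))

  pairs <- NULL
  n <- length(ids)
  if (n >= 2) {
    cmb <- utils::combn(n, 2)
    d <- sqrt(colSums((t(cent[cmb[1, ], , drop = FALSE]) -
                         t(cent[cmb[2, ], , drop = FALSE]))^2))
    keep <- d <= centroid_max_px
    if (any(keep)) {
      cand <- cmb[, keep, drop = FALSE]
      ov <- vapply(seq_len(ncol(cand)), function(k) {
        compute_pairwise_overlap(fps$maps[[cand[1, k]]], fps$maps[[cand[2, k]]],
                                 binarize_frac)
      }, numeric(1))
      pairs <- data.frame(i = ids[cand[1, ]], j = ids[cand[2, ]], overlap = ov,
                          stringsAsFactors = FALSE)
      pairs <- pairs[order(-pairs$overlap, pairs$i, pairs$j), , drop = FALSE]
    }
  }

  alive <- stats::setNames(rep(TRUE, n), ids)
  log_rows <- list()
  if (!is.null(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]; ov <- pairs$overlap[k]
      if (ov <= overlap_max || !alive[i] || !alive[j]) next
      loser <- if (pnr[i] < pnr[j]) i else if (pnr[j] < pnr[i]) j else max(i, j)
      alive[loser] <- FALSE
      log_rows[[length(log_rows) + 1]] <-
        data.frame(i = i, j = j, overlap = ov, removed = loser,
                   tie = pnr[i] == pnr[j], stringsAsFactors = FALSE)
    }
  }
  list(kept = ids[alive], removed = ids[!alive],
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(i = character(), j = character(), overlap = numeric(),
                    removed = character(), tie = logical()))
}
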