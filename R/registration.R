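#' Spatial correlation of two footprints
#'
#' Pearson correlation of the two weight maps over the union of their
#' binarized supports, so the shared background of zeros does not inflate the
#' estimate. Empty supports give 0 (flagged by warning).
#'
#' @param f1,f2 weight-map matrices on a common, pre-aligned grid.
#' @param binarize_frac support threshold as a fraction of each map's max.
#' @return Correlation in `[-1, 1]`.
#' @export
spatial_correlation <- function(f1, f2, binarize_frac = 0.5) {
  stopifnot(identical(dim(f1), dim(f2)))
  m1 <- max(f1); m2 <- max(f2)
  if (m1 <= 0 || m2 <= 0) {
    warning("empty footprint support; spatial correlation set to 0")
    return(0)
  }
  supp <- (f1 >= binarize_frac * m1) | (f2 >= binarize_frac * m2)
  a <- f1[supp]; b <- f2[supp]
  if (length(a) < 2 || sd(a) == 0 || sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Register neurons across sessions at a fixed spatial-correlation threshold
#'
#' All cross-session footprint pairs with spatial correlation above
#' `r_threshold` are candidate matches; candidates are resolved greedily in
#' descending-r order into one-to-one matches per session pair, and
#' multi-session identities are formed by transitive linking. A link that
#' would place two same-session neurons in one identity chain is skipped
#' (chains break at their weakest link, which the descending-r order makes
#' automatic).
#'
#' @param sets list of [footprint_set()], one per session (pre-aligned field
#'   of view).
#' @param r_threshold fixed spatial-correlation threshold (default 0.85,
#'   strict `>` accepts).
#' @param binarize_frac support threshold for [spatial_correlation()].
#' @return An object of class `registration_map`: `assignments` (data frame
#'   `session`, `neuron_id`, `global_id`), `matches` (accepted links with
#'   `r`), `r_threshold`, `n_sessions`.
#' @export
register_fixed_threshold <- function(sets, r_threshold = 0.85,
                                     binarize_frac = 0.5) {
  stopifnot(length(sets) >= 2)
  for (s in sets) stopifnot(inherits(s, "footprint_set"))
  n_per <- vapply(sets, function(s) s$n_neurons, integer(1))
  node_session <- rep(seq_along(sets), n_per)
  node_id <- unlist(lapply(sets, function(s) names(s$maps)), use.names = FALSE)
  n_nodes <- length(node_id)
  offset <- c(0, cumsum(n_per))

  edges <- list()
  for (s in seq_along(sets)) {
    for (t in seq_along(sets)) {
      if (t <= s) next
      for (i in seq_len(n_per[s])) {
        for (j in seq_len(n_per[t])) {
          r <- spatial_correlation(sets[[s]]$maps[[i]], sets[[t]]$maps[[j]],
                                   binarize_frac)
          if (r > r_threshold) {
            edges[[length(edges) + 1]] <-
              c(a = offset[s] + i, b = offset[t] + j, r = r)
          }
        }
      }
    }
  }

  parent <- seq_len(n_nodes)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  comp_sessions <- as.list(node_session)

  matches <- list()
  if (length(edges)) {
    em <- do.call(rbind, edges)
    em <- em[order(-em[, "r"]), , drop = FALSE]
    for (k in seq_len(nrow(em))) {
      a <- as.integer(em[k, "a"]); b <- as.integer(em[k, "b"])
      ra <- find(a); rb <- find(b)
      if (ra == rb) next
      if (length(intersect(comp_sessions[[ra]], comp_sessions[[rb]]))) next
      parent[rb] <- ra
      comp_sessions[[ra]] <- c(comp_sessions[[ra]], comp_sessions[[rb]])
      matches[[length(matches) + 1]] <- data.frame(
        session_a = node_session[a], id_a = node_id[a],
        session_b = node_session[b], id_b = node_id[b],
        r = em[k, "r"], stringsAsFactors = FALSE)
    }
  }

  roots <- vapply(seq_len(n_nodes), find, integer(1))
  global_id <- match(roots, unique(roots))
  structure(list(
    assignments = data.frame(session = node_session, neuron_id = node_id,
                             global_id = global_id, stringsAsFactors = FALSE),
    matches = if (length(matches)) do.call(rbind, matches) else
      data.frame(session_a = integer(), id_a = character(),
                 session_b = integer(), id_b = character(), r = numeric()),
    r_threshold = r_threshold, n_sessions = length(sets)
  ), class = "registration_map")
}

#' @export
print.registration_map <- function(x, ...) {
  cat(sprintf("<registration_map> %d sessions, %d neurons, %d cross-session links (r > %.2f)\n",
              x$n_sessions, nrow(x$assignments), nrow(x$matches), x$r_threshold))
  invisible(x)
}

# global identity of (session, neuron_id); NA when unknown
map_lookup <- function(map, session, neuron_id) {
  a <- map$assignments
  hit <- a$session == session & a$neuron_id == as.character(neuron_id)
  if (!any(hit)) return(NA_integer_)
  a$global_id[which(hit)[1]]
}

# neuron_id in `session` carrying global identity `gid`; NA when absent
map_reverse <- function(map, session, gid) {
  a <- map$assignments
  hit <- a$session == session & a$global_id == gid
  if (!any(hit)) return(NA_character_)
  a$neuron_id[which(hit)[1]]
}

#' Jaccard overlap of active populations across two sessions
#'
#' `J = |A n C| / |A u C|` over registered identities: the intersection is
#' the cells matched across the two sessions and active in both ("A&C
#' neurons"); unmatched active cells count once each in the union.
#'
#' @param active_a,active_c neuron ids active in each session.
#' @param map a [register_fixed_threshold()] map.
#' @param session_a,session_c session indices within the map.
#' @return A list: `J`, `n_intersection`, `n_union`, `ac_ids_a`,
#'   `ac_ids_c` (the A&C neurons' local ids per session). `J` is `NA`
#'   (warning) for an empty union.
#' @export
jaccard_overlap <- function(active_a, active_c, map, session_a = 1, session_c = 2) {
  active_a <- as.character(active_a); active_c <- as.character(active_c)
  if (!length(active_a) && !length(active_c)) {
    warning("empty union; Jaccard undefined")
    return(list(J = NA_real_, n_intersection = 0L, n_union = 0L,
                ac_ids_a = character(), ac_ids_c = character()))
  }
  ga <- vapply(active_a, function(id) map_lookup(map, session_a, id), integer(1))
  gc_ <- vapply(active_c, function(id) map_lookup(map, session_c, id), integer(1))
  if (any(is.na(ga)) || any(is.na(gc_))) stop("active ids missing from map")
  inter <- intersect(ga, gc_)
  uni <- union(ga, gc_)
  list(J = length(inter) / length(uni),
       n_intersection = length(inter), n_union = length(uni),
       ac_ids_a = active_a[ga %in% inter],
       ac_ids_c = active_c[gc_ %in% inter])
}

#' Shuffle-normalized Jaccard index
#'
#' Corrects the Jaccard index for session sizes: 1000 surrogate indices are
#' drawn by sampling `n_a` and `n_c` identities uniformly without replacement
#' from a pool of `pool_size`, and the observed index is z-scored against
#' that distribution. Within a declared comparison group the z-scores can be
#' min-max normalized to `[0, 1]` with [minmax_normalize()].
#'
#' @param J observed Jaccard index.
#' @param n_a,n_c numbers of active neurons in the two sessions.
#' @param pool_size size of the identity pool to draw from (at least
#'   `max(n_a, n_c)`); typically the total number of distinct registered
#'   identities.
#' @param n_shuffles number of surrogate draws (default 1000).
#' @param seed integer seed.
#' @return A list: `z_J`, `null_mean`, `null_sd`, `n_shuffles`, `seed`.
#'   `z_J` is `NA` (warning) when the null SD is 0.
#' @export
normalized_jaccard <- function(J, n_a, n_c, pool_size, n_shuffles = 1000,
                               seed = 1L) {
  if (pool_size < max(n_a, n_c)) stop("pool_size must be >= max(n_a, n_c)")
  null_J <- with_seed(seed, vapply(seq_len(n_shuffles), function(k) {
    A <- sample.int(pool_size, n_a)
    C <- sample.int(pool_size, n_c)
    length(intersect(A, C)) / length(union(A, C))
  }, numeric(1)))
  mu <- mean(null_J); sdv <- sd(null_J)
  if (!is.finite(sdv) || sdv == 0) {
    warning("degenerate Jaccard null (sd = 0); z flagged NA")
    return(list(z_J = NA_real_, null_mean = mu, null_sd = sdv,
                n_shuffles = n_shuffles, seed = seed))
  }
  list(z_J = (J - mu) / sdv, null_mean = mu, null_sd = sdv,
       n_shuffles = n_shuffles, seed = seed)
}

#' Min-max normalization within a comparison group
#'
#' @param x numeric vector (e.g. z-scored Jaccard indices of the mice in one
#'   region-by-timepoint comparison).
#' @return `(x - min) / (max - min)`, in `[0, 1]`; errors for fewer than two
#'   distinct values.
#' @export
minmax_normalize <- function(x) {
  if (length(x) < 2 || max(x) == min(x)) {
    stop("min-max normalization needs >= 2 distinct group values")
  }
  (x - min(x)) / (max(x) - min(x))
}

#' Activity contrast of A&C neurons between contexts
#'
#' Per-neuron normalized contrast `(r_C - r_A) / (r_C + r_A)` in `[-1, 1]`
#' (0 = no preference), or the plain difference `r_C - r_A`. Neurons silent
#' in both contexts are excluded (logged via the `n_excluded` element).
#'
#' @param rates_a,rates_c event rates (events/s) of the same neurons in
#'   context A and context C.
#' @param mode `"contrast"` (default) or `"difference"`.
#' @return A list: `per_neuron`, `mean`, `n_excluded`.
#' @export
ac_activity_contrast <- function(rates_a, rates_c,
                                 mode = c("contrast", "difference")) {
  mode <- match.arg(mode)
  stopifnot(length(rates_a) == length(rates_c))
  both_zero <- rates_a == 0 & rates_c == 0
  a <- rates_a[!both_zero]; c_ <- rates_c[!both_zero]
  v <- if (mode == "contrast") (c_ - a) / (c_ + a) else c_ - a
  list(per_neuron = v, mean = mean(v), n_excluded = sum(both_zero))
}

#' Share of correlated neurons that are A&C neurons
#'
#' @param ac_ids A&C neuron ids in the session.
#' @param correlated_ids ids of neurons in at least one correlated pair.
#' @return Percent; `NA` (warning) for an empty correlated set.
#' @export
ac_fraction_in_correlated <- function(ac_ids, correlated_ids) {
  if (!length(correlated_ids)) {
    warning("empty correlated set; A&C fraction undefined")
    return(NA_real_)
  }
  100 * mean(as.character(correlated_ids) %in% as.character(ac_ids))
}

#' Correlation between registration certainty and A&C counts
#'
#' Sanity check that the number of A&C neurons is not driven by how certain
#' the registration was per mouse.
#'
#' @param certainty per-mouse registration certainty scores (externally
#'   supplied).
#' @param ac_counts per-mouse A&C neuron counts.
#' @return A list: `r`, `r_squared`, `p`, `n`; all `NA` (warning) for
#'   constant input.
#' @export
registration_certainty_check <- function(certainty, ac_counts) {
  stopifnot(length(certainty) == length(ac_counts))
  if (length(certainty) < 3) stop("need at least 3 mice")
  if (sd(certainty) == 0 || sd(ac_counts) == 0) {
    warning("constant input; correlation undefined")
    return(list(r = NA_real_, r_squared = NA_real_, p = NA_real_,
                n = length(certainty)))
  }
  ct <- stats::cor.test(certainty, ac_counts)
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = length(certainty))
}
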