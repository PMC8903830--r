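# --- geometric masks built from first principles -----------------------------

disk_mask <- function(radius, size = 4 * radius + 20) {
  ctr <- size / 2
  m <- matrix(0, size, size)
  for (i in seq_len(size)) {
    for (j in seq_len(size)) {
      if ((i - ctr)^2 + (j - ctr)^2 <= radius^2) m[i, j] <- 1
    }
  }
  m
}

ellipse_mask <- function(a, b, theta = 0, size = 4 * max(a, b) + 20) {
  ctr <- size / 2
  m <- matrix(0, size, size)
  for (i in seq_len(size)) {
    for (j in seq_len(size)) {
      u <- cos(theta) * (i - ctr) + sin(theta) * (j - ctr)
      v <- -sin(theta) * (i - ctr) + cos(theta) * (j - ctr)
      if ((u / a)^2 + (v / b)^2 <= 1) m[i, j] <- 1
    }
  }
  m
}

square_mask <- function(side, size = 2 * side + 20) {
  m <- matrix(0, size, size)
  lo <- floor((size - side) / 2) + 1
  m[lo:(lo + side - 1), lo:(lo + side - 1)] <- 1
  m
}

# --- independent oracles ------------------------------------------------------

# exhaustive application of the overlap-resolution rule, mirroring the stated
# procedure literally: recompute candidate pairs by descending overlap and
# drop the lower-PNR member, never letting a removed neuron act
brute_force_overlap_resolution <- function(maps, pnr, centroid_max_px = 36,
                                           overlap_max = 0.5) {
  ids <- names(maps)
  cent <- t(sapply(maps, function(m) {
    colMeans(which(m >= 0.5 * max(m), arr.ind = TRUE))
  }))
  pairs <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      if (sqrt(sum((cent[i, ] - cent[j, ])^2)) > centroid_max_px) next
      ov <- compute_pairwise_overlap(maps[[i]], maps[[j]])
      pairs[[length(pairs) + 1]] <- list(i = ids[i], j = ids[j], ov = ov)
    }
  }
  ord <- order(-sapply(pairs, `[[`, "ov"),
               sapply(pairs, `[[`, "i"), sapply(pairs, `[[`, "j"))
  alive <- setNames(rep(TRUE, length(ids)), ids)
  for (p in pairs[ord]) {
    if (p$ov <= overlap_max || !alive[p$i] || !alive[p$j]) next
    loser <- if (pnr[p$i] < pnr[p$j]) p$i else if (pnr[p$j] < pnr[p$i]) p$j else
      max(p$i, p$j)
    alive[loser] <- FALSE
  }
  ids[!alive]
}

# maximum-weight one-to-one assignment over edges with r > threshold, by
# bitmask dynamic programming over the (smaller) second session; exact for
# instances up to ~12 x 12
optimal_assignment <- function(rmat, threshold) {
  n1 <- nrow(rmat); n2 <- ncol(rmat)
  stopifnot(n2 <= 14)
  w <- rmat
  w[w <= threshold] <- NA
  best <- new.env(hash = TRUE)
  solve <- function(i, used) {
    if (i > n1) return(list(score = 0, pairs = list()))
    key <- paste(i, used)
    if (!is.null(best[[key]])) return(best[[key]])
    res <- solve(i + 1, used)  # leave row i unmatched
    for (j in seq_len(n2)) {
      if (bitwAnd(used, bitwShiftL(1L, j - 1L)) == 0L && !is.na(w[i, j])) {
        sub <- solve(i + 1, bitwOr(used, bitwShiftL(1L, j - 1L)))
        if (sub$score + w[i, j] > res$score) {
          res <- list(score = sub$score + w[i, j],
                      pairs = c(sub$pairs, list(c(i, j))))
        }
      }
    }
    best[[key]] <- res
    res
  }
  solve(1L, 0L)
}

# --- labeled candidate builder for the event classifier ----------------------

# true events vs denoised-only artifact transients, labels from ground truth
make_labeled_candidates <- function(seed, n_neurons = 30, duration_s = 360,
                                    event_rate = 0.06, artifact_rate = 0.04,
                                    noise_sd = 0.15) {
  g <- generate_event_trains(sim_spec(n_neurons, duration_s,
                                      base_rate_hz = event_rate, seed = seed))
  tr <- render_traces(g$trains, noise_sd = noise_sd, seed = seed + 1)
  art <- inject_denoised_artifacts(tr, rate_hz = artifact_rate, seed = seed + 2)
  feats <- NULL; labs <- character(0)
  for (i in seq_len(n_neurons)) {
    cand <- detect_event_candidates(art$traces$raw[i, ], art$traces$denoised[i, ])
    if (!nrow(cand)) next
    f <- extract_candidate_features(cand, art$traces$raw[i, ],
                                    art$traces$denoised[i, ])
    truth_f <- floor(g$trains$trains[[i]] * 10) + 1
    art_f <- floor(art$artifact_times[[i]] * 10) + 1
    lab <- vapply(cand$time_frame, function(fr) {
      if (length(truth_f) && min(abs(truth_f - fr)) <= 2) "accepted"
      else if (length(art_f) && min(abs(art_f - fr)) <= 2) "rejected"
      else NA_character_
    }, character(1))
    keep <- !is.na(lab)
    feats <- rbind(feats, f[keep, , drop = FALSE])
    labs <- c(labs, lab[keep])
  }
  list(features = feats, labels = labs)
}

# two-context sessions with a planted rate gain on a neuron subset
make_context_pair <- function(n_neurons = 60, duration_s = 360, rate = 0.15,
                              gain = 2, frac_mod = 0.3, seed = 1) {
  ce <- rep(1, n_neurons)
  ce[seq_len(round(frac_mod * n_neurons))] <- gain
  a <- generate_event_trains(sim_spec(n_neurons, duration_s, base_rate_hz = rate,
                                      seed = seed))$trains
  c_ <- generate_event_trains(sim_spec(n_neurons, duration_s, base_rate_hz = rate,
                                       context_effect = ce, seed = seed + 1000))$trains
  list(a = a, c = c_, ids = as.character(seq_len(n_neurons)))
}
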