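# Peak prominence: height above the higher of the two reference valleys, each
# valley being the minimum between the peak and the nearest higher sample (or
# the trace edge) on that side.
peak_prominence <- function(x, p) {
  h <- x[p]
  left <- if (p == 1) h else {
    higher <- which(x[seq_len(p - 1)] > h)
    lo <- if (length(higher)) max(higher) + 1L else 1L
    min(x[lo:(p - 1L)], h)
  }
  right <- if (p == length(x)) h else {
    higher <- which(x[(p + 1L):length(x)] > h) + p
    hi <- if (length(higher)) min(higher) - 1L else length(x)
    min(x[(p + 1L):hi], h)
  }
  h - max(left, right)
}

# width (frames) of the contiguous run around p with x >= h - prom/2
peak_halfprom_width <- function(x, p, prom) {
  lev <- x[p] - prom / 2
  lo <- p
  while (lo > 1 && x[lo - 1] >= lev) lo <- lo - 1
  hi <- p
  while (hi < length(x) && x[hi + 1] >= lev) hi <- hi + 1
  hi - lo + 1L
}

# Peak detection on one fluorescence trace with the three curation criteria:
# amplitude >= baseline + amp_sd * noise SD, minimum peak distance, minimum
# width at half prominence.
find_trace_peaks <- function(x, amp_sd = 3, min_dist_frames = 15,
                             min_dur_frames = 3) {
  empty <- data.frame(frame = integer(), height = numeric(),
                      prominence = numeric(), width_frames = integer())
  if (length(x) < 3) return(empty)
  sd_n <- robust_noise_sd(x)
  base <- stats::median(x)
  pk <- pracma::findpeaks(x, minpeakheight = base + amp_sd * sd_n,
                          minpeakdistance = min_dist_frames, sortstr = TRUE)
  if (is.null(pk)) return(empty)
  out <- data.frame(frame = as.integer(pk[, 2]), height = pk[, 1])
  out$prominence <- vapply(out$frame, function(p) peak_prominence(x, p), numeric(1))
  out$width_frames <- mapply(peak_halfprom_width, p = out$frame,
                             prom = out$prominence, MoreArgs = list(x = x))
  out <- out[out$width_frames >= min_dur_frames, , drop = FALSE]
  out[order(out$frame), , drop = FALSE]
}

#' Detect calcium-event candidates on a raw/denoised trace pair
#'
#' Peaks are found independently on the raw and the denoised trace; a peak
#' qualifies when its amplitude is at least `amp_sd` baseline-noise SDs above
#' the trace median, it is at least `min_dist_frames` from the next peak, and
#' it lasts at least `min_dur_frames` (width at half prominence). At the
#' default 10 Hz these are 15 frames = 1.5 s and 3 frames = 300 ms.
#' Candidates are the denoised-trace peaks, each annotated with the nearest
#' raw-trace peak within 1 s, if any.
#'
#' @param raw,denoised equal-length numeric fluorescence traces.
#' @param fs_hz sampling rate (default 10).
#' @param amp_sd amplitude criterion in baseline-noise SDs (default 3).
#' @param min_dist_frames minimum peak separation (default 15).
#' @param min_dur_frames minimum peak duration (default 3).
#' @return Data frame of class `event_candidates`: one row per candidate with
#'   `time_frame`, `amplitude`, `prominence`, `width_frames` (denoised) and
#'   `raw_frame`, `raw_height`, `raw_prominence`, `raw_width_frames` (NA when
#'   no raw peak matched).
#' @export
detect_event_candidates <- function(raw, denoised, fs_hz = 10, amp_sd = 3,
                                    min_dist_frames = 15, min_dur_frames = 3) {
  stopifnot(length(raw) == length(denoised))
  if (length(raw) < 50) stop("traces must have at least 50 frames")
  pden <- find_trace_peaks(denoised, amp_sd, min_dist_frames, min_dur_frames)
  praw <- find_trace_peaks(raw, amp_sd, min_dist_frames, min_dur_frames)
  out <- data.frame(time_frame = pden$frame, amplitude = pden$height,
                    prominence = pden$prominence,
                    width_frames = pden$width_frames,
                    raw_frame = rep(NA_integer_, nrow(pden)),
                    raw_height = rep(NA_real_, nrow(pden)),
                    raw_prominence = rep(NA_real_, nrow(pden)),
                    raw_width_frames = rep(NA_integer_, nrow(pden)))
  if (nrow(pden) && nrow(praw)) {
    tol <- round(fs_hz)  # 1 s matching tolerance
    for (k in seq_len(nrow(out))) {
      d <- abs(praw$frame - out$time_frame[k])
      if (min(d) <= tol) {
        m <- which.min(d)
        out$raw_frame[k] <- praw$frame[m]
        out$raw_height[k] <- praw$height[m]
        out$raw_prominence[k] <- praw$prominence[m]
        out$raw_width_frames[k] <- praw$width_frames[m]
      }
    }
  }
  class(out) <- c("event_candidates", "data.frame")
  out
}

#' Extract the 8-feature vector of each event candidate
#'
#' Features, in order: PNR of the raw and of the denoised peak (peak height
#' above trace median, over baseline-noise SD), width-to-height ratio (width
#' at half prominence in seconds over prominence) on both traces, peak
#' prominence on both traces, the Pearson correlation between the raw and
#' denoised traces in a +/- 1 s window around the peak, and the local PNR of
#' the raw peak, whose noise SD is estimated from the raw trace within
#' +/- 2 s of the peak excluding +/- 0.3 s around it. Candidates with no
#' matching raw peak get zero raw features and zero correlation.
#'
#' @param candidates an `event_candidates` data frame.
#' @param raw,denoised the trace pair the candidates came from.
#' @param fs_hz sampling rate (default 10).
#' @return Numeric matrix, one row per candidate, 8 named columns.
#' @export
extract_candidate_features <- function(candidates, raw, denoised, fs_hz = 10) {
  sd_raw <- robust_noise_sd(raw)
  sd_den <- robust_noise_sd(denoised)
  base_raw <- stats::median(raw)
  base_den <- stats::median(denoised)
  n <- nrow(candidates)
  feats <- matrix(0, n, 8,
                  dimnames = list(NULL, c(
                    "pnr_raw", "pnr_denoised", "wh_raw", "wh_denoised",
                    "prom_raw", "prom_denoised", "raw_den_cor", "local_pnr_raw")))
  w1 <- round(fs_hz)        # 1 s
  w2 <- round(2 * fs_hz)    # 2 s
  wx <- round(0.3 * fs_hz)  # 0.3 s exclusion
  for (k in seq_len(n)) {
    p <- candidates$time_frame[k]
    feats[k, "pnr_denoised"] <- (candidates$amplitude[k] - base_den) / sd_den
    feats[k, "wh_denoised"] <- (candidates$width_frames[k] / fs_hz) /
      max(candidates$prominence[k], 1e-9)
    feats[k, "prom_denoised"] <- candidates$prominence[k]
    idx <- max(1, p - w1):min(length(raw), p + w1)
    r <- suppressWarnings(stats::cor(raw[idx], denoised[idx]))
    if (!is.na(candidates$raw_frame[k])) {
      pr <- candidates$raw_frame[k]
      feats[k, "pnr_raw"] <- (candidates$raw_height[k] - base_raw) / sd_raw
      feats[k, "wh_raw"] <- (candidates$raw_width_frames[k] / fs_hz) /
        max(candidates$raw_prominence[k], 1e-9)
      feats[k, "prom_raw"] <- candidates$raw_prominence[k]
      feats[k, "raw_den_cor"] <- if (is.finite(r)) r else 0
      nb <- setdiff(max(1, pr - w2):min(length(raw), pr + w2),
                    (pr - wx):(pr + wx))
      feats[k, "local_pnr_raw"] <-
        (candidates$raw_height[k] - stats::median(raw[nb])) /
        robust_noise_sd(raw[nb])
    }
  }
  feats
}

#' Train the event-candidate classifier (PCA + quadratic discriminant)
#'
#' Standardizes the feature matrix, projects it on the principal components
#' retaining at least `variance_retained` of the variance, and fits a
#' quadratic Bayesian (Gaussian) discriminant in that space, with per-class
#' covariances shrunk toward their diagonal (lambda = 0.01) for stability on
#' small label sets.
#'
#' @param features numeric matrix (candidates x 8 features).
#' @param labels factor/character with two levels, e.g. `"accepted"` /
#'   `"rejected"`.
#' @param variance_retained fraction of feature variance the retained
#'   components must explain (default 0.9).
#' @param shrinkage covariance shrinkage weight toward the diagonal.
#' @return An object of class `event_classifier` with the projection, the
#'   per-class Gaussian parameters and the training accuracy.
#' @export
train_event_classifier <- function(features, labels, variance_retained = 0.9,
                                   shrinkage = 0.01) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes to train")
  if (any(table(labels) < 2)) stop("each class needs at least 2 examples")
  if (any(table(labels) < 20)) {
    warning("fewer than 20 examples in some class; classifier may be unstable")
  }
  mu <- colMeans(features)
  sc <- pmax(apply(features, 2, sd), 1e-9)
  z <- sweep(sweep(features, 2, mu), 2, sc, "/")
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cumvar >= variance_retained)[1]
  k <- max(2L, min(k, ncol(features)))   # >= 2 dims keeps the QDA quadratic
  proj <- pc$rotation[, seq_len(k), drop = FALSE]
  s <- z %*% proj

  classes <- levels(labels)
  pars <- lapply(classes, function(cl) {
    sk <- s[labels == cl, , drop = FALSE]
    S <- stats::cov(sk)
    S <- (1 - shrinkage) * S + shrinkage * diag(diag(S), ncol(S))
    if (rcond(S) < 1e-10) S <- S + diag(1e-6 * mean(diag(S)) + 1e-12, ncol(S))
    list(mean = colMeans(sk), cov = S, prior = nrow(sk) / nrow(s))
  })
  names(pars) <- classes
  clf <- structure(list(center = mu, scale = sc, projection = proj,
                        k = k, classes = classes, pars = pars),
                   class = "event_classifier")
  clf$training_accuracy <- mean(predict(clf, features) == labels)
  clf
}

#' @export
predict.event_classifier <- function(object, newdata, ...) {
  z <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
  s <- z %*% object$projection
  ll <- vapply(object$classes, function(cl) {
    p <- object$pars[[cl]]
    ch <- chol(p$cov)
    d <- forwardsolve(t(ch), t(sweep(s, 2, p$mean)))
    -0.5 * colSums(d^2) - sum(log(diag(ch))) + log(p$prior)
  }, numeric(nrow(s)))
  if (nrow(s) == 1L) ll <- matrix(ll, nrow = 1)
  factor(object$classes[max.col(ll)], levels = object$classes)
}

#' Classify candidates into an accepted event train
#'
#' @param clf an [train_event_classifier()] result.
#' @param candidates `event_candidates` for one neuron.
#' @param features matching feature matrix from
#'   [extract_candidate_features()].
#' @param fs_hz sampling rate (default 10).
#' @param accept_label label treated as "accepted" (default `"accepted"`).
#' @return A list with `times_s` (sorted accepted event times), `accepted`
#'   (logical per candidate).
#' @export
classify_events <- function(clf, candidates, features, fs_hz = 10,
                            accept_label = "accepted") {
  if (!nrow(candidates)) return(list(times_s = numeric(0), accepted = logical(0)))
  pred <- predict(clf, features)
  acc <- pred == accept_label
  list(times_s = sort((candidates$time_frame[acc] - 1) / fs_hz), accepted = acc)
}

#' Low-activity neuron filter
#'
#' A neuron is kept iff `N_peaks + 2 * H_max - 3 > 0` (strict), where
#' `N_peaks` is its number of accepted calcium events in the recording and
#' `H_max` the relative height of its largest peak, in `[0, 1]`.
#'
#' @param trains an [event_train_set()] of accepted events.
#' @param h_max numeric vector in `[0, 1]`, one per neuron (in train order),
#'   e.g. from [compute_hmax()].
#' @return A list with `kept`, `removed` (id vectors) and `score` (the
#'   per-neuron discriminant value).
#' @export
filter_low_activity <- function(trains, h_max) {
  stopifnot(inherits(trains, "event_train_set"))
  if (length(h_max) != trains$n_neurons) stop("h_max length must match neurons")
  if (any(h_max < 0 | h_max > 1)) stop("h_max must lie in [0, 1]")
  n_peaks <- lengths(trains$trains)
  score <- n_peaks + 2 * h_max - 3
  ids <- names(trains$trains)
  list(kept = ids[score > 0], removed = ids[score <= 0],
       score = stats::setNames(score, ids))
}

#' Relative height of a neuron's largest peak
#'
#' `H_max` is the largest accepted-event prominence on the denoised trace,
#' min-max normalized by the session-wide denoised dynamic range, clipped to
#' `[0, 1]`.
#'
#' @param prominences accepted-event prominences for one neuron (denoised).
#' @param session_range session-wide denoised dynamic range
#'   (`max - min` over all neurons' denoised traces).
#' @return `H_max` in `[0, 1]` (0 for a neuron with no accepted events).
#' @export
compute_hmax <- function(prominences, session_range) {
  if (!length(prominences) || session_range <= 0) return(0)
  min(1, max(prominences) / session_range)
}

#' Run the full four-stage curation on one session
#'
#' Stages: (1) shape filter (inertia ratio, compacity); (2) overlap
#' resolution (centroid gate + overlap rule, lower PNR removed); (3)
#' event-candidate detection and, when a classifier is supplied, rejection of
#' noisy candidates; (4) low-activity removal by the linear rule.
#'
#' @param fps a [footprint_set()].
#' @param traces a `trace_set` (matrices `raw`, `denoised`, `fs_hz`) whose
#'   rows align with `fps`.
#' @param classifier optional [train_event_classifier()] model; when `NULL`
#'   all candidates are accepted.
#' @param ir_max,compacity_max,centroid_max_px,overlap_max stage thresholds.
#' @param amp_sd,min_dist_frames,min_dur_frames candidate-detection
#'   parameters.
#' @return A list with `trains` (curated [event_train_set()]), `kept`,
#'   `report` (class `curation_report`: per-stage removal counts and ids).
#' @export
curate_session <- function(fps, traces, classifier = NULL,
                           ir_max = 5, compacity_max = 35,
                           centroid_max_px = 36, overlap_max = 0.5,
                           amp_sd = 3, min_dist_frames = 15, min_dur_frames = 3) {
  stopifnot(inherits(fps, "footprint_set"))
  ids <- names(fps$maps)
  stopifnot(nrow(traces$raw) == length(ids))
  fs <- traces$fs_hz

  st1 <- filter_by_shape(fps, ir_max, compacity_max)
  keep1 <- st1$kept

  pnr <- vapply(seq_along(ids), function(i) {
    x <- traces$raw[i, ]
    (max(x) - stats::median(x)) / robust_noise_sd(x)
  }, numeric(1))
  names(pnr) <- ids
  st2 <- resolve_overlaps(footprint_set(fps$maps[keep1], neuron_ids = keep1),
                          pnr[keep1], centroid_max_px, overlap_max)
  keep2 <- st2$kept

  session_range <- max(traces$denoised) - min(traces$denoised)
  trains <- list(); h_max <- numeric(0)
  for (id in keep2) {
    i <- match(id, ids)
    cand <- detect_event_candidates(traces$raw[i, ], traces$denoised[i, ], fs,
                                    amp_sd, min_dist_frames, min_dur_frames)
    if (nrow(cand) && !is.null(classifier)) {
      feats <- extract_candidate_features(cand, traces$raw[i, ],
                                          traces$denoised[i, ], fs)
      res <- classify_events(classifier, cand, feats, fs)
      times <- res$times_s
      proms <- cand$prominence[res$accepted]
    } else {
      times <- (cand$time_frame - 1) / fs
      proms <- cand$prominence
    }
    trains[[id]] <- times
    h_max <- c(h_max, compute_hmax(proms, session_range))
  }
  duration_s <- ncol(traces$raw) / fs
  ets <- event_train_set(trains, duration_s, fs, neuron_ids = keep2)
  st4 <- filter_low_activity(ets, h_max)
  final <- subset_trains(ets, st4$kept)

  report <- structure(list(
    n_input = length(ids),
    n_kept = length(st4$kept),
    removed_shape = st1$rejected,
    removed_overlap = st2$removed,
    removed_low_activity = st4$removed,
    kept = st4$kept,
    shape_metrics = st1$metrics,
    overlap_log = st2$log
  ), class = "curation_report")
  list(trains = final, kept = st4$kept, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf(
    "<curation_report> %d neurons in, %d kept (shape -%d, overlap -%d, low-activity -%d)\n",
    x$n_input, x$n_kept, length(x$removed_shape), length(x$removed_overlap),
    length(x$removed_low_activity)))
  invisible(x)
}
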