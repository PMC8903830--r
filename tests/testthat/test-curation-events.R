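kernel_trace <- function(frames, at, amp = 1, fs = 10, decay = 0.5, rise = 0.05) {
  x <- numeric(frames)
  tk <- seq(0, decay * 8, by = 1 / fs)
  k <- exp(-tk / decay) - exp(-tk / rise)
  k <- k / max(k) * amp
  for (f0 in at) {
    idx <- f0:min(frames, f0 + length(k) - 1)
    x[idx] <- x[idx] + k[seq_along(idx)]
  }
  x
}

test_that("candidate detection applies the amplitude, distance and duration rules", {
  set.seed(1)
  noise <- rnorm(600, sd = 0.1)

  # one event 10x the noise SD: exactly one candidate at the event frame +/- 2
  x <- kernel_trace(600, 300, amp = 1) + noise
  d <- kernel_trace(600, 300, amp = 1)
  cand <- detect_event_candidates(x, d)
  expect_identical(nrow(cand), 1L)
  expect_lte(abs(cand$time_frame - 300), 2)
  expect_false(is.na(cand$raw_frame))

  # two events 10 frames apart: minimum-distance rule keeps one
  d2 <- kernel_trace(600, c(300, 310), amp = 1)
  cand2 <- detect_event_candidates(d2 + noise, d2)
  expect_identical(nrow(cand2), 1L)

  # two events 30 frames apart: both found
  d3 <- kernel_trace(600, c(300, 330), amp = 1)
  cand3 <- detect_event_candidates(d3 + noise, d3)
  expect_identical(nrow(cand3), 2L)

  # 2-frame spike artifact: fails the 3-frame minimum duration
  d4 <- numeric(600); d4[300:301] <- 1
  cand4 <- detect_event_candidates(d4 + noise, d4)
  expect_identical(nrow(cand4), 0L)

  # all-constant trace: zero candidates, no error (SD floor)
  expect_identical(nrow(detect_event_candidates(rep(1, 100), rep(1, 100))), 0L)

  expect_error(detect_event_candidates(rnorm(20), rnorm(20)), "50 frames")
})

test_that("candidate features match an independent recomputation", {
  set.seed(2)
  noise <- rnorm(800, sd = 0.1)
  x <- kernel_trace(800, c(200, 520), amp = c(1)) + noise
  d <- kernel_trace(800, c(200, 520), amp = 1)
  cand <- detect_event_candidates(x, d)
  expect_identical(nrow(cand), 2L)
  f <- extract_candidate_features(cand, x, d)

  # oracle recomputation from first principles for the first candidate
  sd_raw <- 1.4826 * mad(diff(x), constant = 1) / sqrt(2)
  p <- cand$time_frame[1]
  expect_equal(unname(f[1, "pnr_denoised"]),
               (cand$amplitude[1] - median(d)) / max(1.4826 * mad(diff(d), constant = 1) / sqrt(2), 1e-9),
               tolerance = 1e-10)
  pr <- cand$raw_frame[1]
  expect_equal(unname(f[1, "pnr_raw"]), (cand$raw_height[1] - median(x)) / sd_raw,
               tolerance = 1e-10)
  win <- (p - 10):(p + 10)
  expect_equal(unname(f[1, "raw_den_cor"]), cor(x[win], d[win]), tolerance = 1e-10)

  # identical raw and denoised traces: correlation feature is 1
  cand_id <- detect_event_candidates(d, d)
  f_id <- extract_candidate_features(cand_id, d, d)
  expect_true(all(abs(f_id[, "raw_den_cor"] - 1) < 1e-9))

  # all features finite
  expect_true(all(is.finite(f)))
})

test_that("PCA + quadratic discriminant separates labeled candidate classes", {
  trn <- make_labeled_candidates(1)
  tst <- make_labeled_candidates(101)
  expect_gte(min(table(trn$labels)), 20)

  clf <- train_event_classifier(trn$features, trn$labels)
  expect_lte(clf$k, 8)
  expect_gt(clf$training_accuracy, 0.9)
  # held-out accuracy on an independently generated session
  expect_gt(mean(predict(clf, tst$features) == tst$labels), 0.9)

  # true events accepted, artifacts rejected, via classify_events
  res <- classify_events(clf, data.frame(time_frame = seq_len(nrow(tst$features)),
                                         check.names = FALSE),
                         tst$features)
  acc_rate <- mean(res$accepted[tst$labels == "accepted"])
  rej_rate <- mean(res$accepted[tst$labels == "rejected"])
  expect_gte(acc_rate, 0.9)
  expect_lte(rej_rate, 0.1)

  # label shuffling destroys performance
  set.seed(3)
  sh <- sample(trn$labels)
  clf_sh <- train_event_classifier(trn$features, sh)
  expect_lt(abs(mean(predict(clf_sh, tst$features) == tst$labels) - 0.5), 0.15)

  # one class only: error
  expect_error(train_event_classifier(trn$features,
                                      rep("accepted", nrow(trn$features))),
               "2 classes")
})

test_that("quadratic discriminant agrees with an established QDA on clean data", {
  set.seed(4)
  x <- rbind(matrix(rnorm(200 * 3, mean = 0), ncol = 3),
             matrix(rnorm(200 * 3, mean = 2), ncol = 3))
  y <- rep(c("a", "b"), each = 200)
  clf <- train_event_classifier(x, y, variance_retained = 1, shrinkage = 0)
  ref <- MASS::qda(x, grouping = y)
  xnew <- matrix(rnorm(300 * 3, mean = 1), ncol = 3)
  agree <- mean(as.character(predict(clf, xnew)) ==
                  as.character(predict(ref, xnew)$class))
  expect_gt(agree, 0.97)
})

test_that("low-activity rule keeps a neuron iff N_peaks + 2 H_max - 3 > 0", {
  trains <- event_train_set(list(
    c(10),             # N=1, H=1 -> 0, removed (boundary)
    c(10, 20, 30),     # N=3, H=0 -> 0, removed
    c(10, 20, 30, 40), # N=4, H=0 -> 1, kept
    c(10, 20),         # N=2, H=0.6 -> 0.2, kept
    numeric(0)         # silent, removed
  ), duration_s = 60, fs_hz = 10, neuron_ids = letters[1:5])
  res <- filter_low_activity(trains, h_max = c(1, 0, 0, 0.6, 0))
  expect_setequal(res$kept, c("c", "d"))
  expect_setequal(res$removed, c("a", "b", "e"))
  expect_error(filter_low_activity(trains, h_max = c(2, 0, 0, 0, 0)), "0, 1")
})

test_that("full curation keeps a clean session and removes planted corruption", {
  n <- 25L
  gf <- generate_footprints(n, grid = c(200, 200), seed = 10)
  g <- generate_event_trains(sim_spec(n, 360, base_rate_hz = 0.06, seed = 11))
  tr <- render_traces(g$trains, noise_sd = 0.12, seed = 12)
  clean <- curate_session(gf$footprints, tr)
  expect_identical(clean$report$n_kept, n)

  # corrupt: 3 dendrite-like shapes, 3 artifact-only neurons, 3 silent neurons
  rf <- cofire:::render_footprint
  maps <- gf$footprints$maps
  maps[[26]] <- rf(c(200, 200), c(30, 100), 12, elongation = 7)
  maps[[27]] <- rf(c(200, 200), c(170, 40), 12, elongation = 8, theta0 = 1)
  maps[[28]] <- rf(c(200, 200), c(100, 170), 11, elongation = 7, theta0 = 2)
  spots <- list(c(20, 20), c(180, 180), c(20, 180), c(180, 20), c(100, 15), c(15, 100))
  for (k in 29:34) maps[[k]] <- rf(c(200, 200), spots[[k - 28]], 6)
  fset <- footprint_set(maps)

  ets <- event_train_set(c(g$trains$trains,
                           g$trains$trains[1:3],
                           rep(list(numeric(0)), 6)),
                         360, 10)
  tr2 <- render_traces(ets, noise_sd = 0.12, seed = 13)
  blank <- render_traces(event_train_set(rep(list(numeric(0)), 3), 360, 10),
                         noise_sd = 0, seed = 1)
  art <- inject_denoised_artifacts(blank, rate_hz = 0.03, seed = 14)
  tr2$denoised[29:31, ] <- tr2$denoised[29:31, ] + art$traces$denoised

  clf <- train_event_classifier(make_labeled_candidates(1)$features,
                                make_labeled_candidates(1)$labels)
  res <- curate_session(fset, tr2, classifier = clf)
  removed <- setdiff(as.character(1:34), res$kept)
  truth <- as.character(26:34)
  tp <- length(intersect(removed, truth))
  prec <- tp / max(1, length(removed)); rec <- tp / length(truth)
  expect_gte(2 * prec * rec / (prec + rec), 0.9)
})
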