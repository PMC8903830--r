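test_that("event-train generator respects rates, bounds and determinism", {
  # zero rate: all empty
  g0 <- generate_event_trains(sim_spec(10, 60, base_rate_hz = 0, seed = 1))
  expect_true(all(lengths(g0$trains$trains) == 0))

  # Poisson mean: 1000 neurons, 360 s at 0.1 Hz -> mean count 36; the mean of
  # 1000 iid Poisson(36) counts lies in 36 +/- 3.3 * sqrt(36/1000) w.p. ~99.9%
  g <- generate_event_trains(sim_spec(1000, 360, base_rate_hz = 0.1, seed = 2))
  cnt <- lengths(g$trains$trains)
  expect_gt(mean(cnt), 36 - 3.3 * sqrt(36 / 1000))
  expect_lt(mean(cnt), 36 + 3.3 * sqrt(36 / 1000))
  # aggregate counts inside the 99% Poisson interval
  expect_gt(mean(cnt >= qpois(0.005, 36) & cnt <= qpois(0.995, 36)), 0.95)
  expect_true(all(unlist(g$trains$trains) >= 0 & unlist(g$trains$trains) <= 360))
  expect_false(is.unsorted(g$trains$trains[[1]]))

  # determinism: same spec + seed -> bit-identical
  g2 <- generate_event_trains(sim_spec(1000, 360, base_rate_hz = 0.1, seed = 2))
  expect_identical(g$trains, g2$trains)

  # validation
  expect_error(sim_spec(10, -5), "duration_s")
  expect_error(sim_spec(10, 60, base_rate_hz = -1), "base_rate_hz")
})

test_that("assembly co-events are shared by members as injected", {
  sp <- sim_spec(12, 300, base_rate_hz = 0,
                 assembly = list(list(members = 1:10, rate_hz = 0.2, jitter_ms = 0)),
                 seed = 3)
  g <- generate_event_trains(sp)
  co <- g$truth$co_event_times[[1]]
  expect_gt(length(co), 0)
  for (m in 1:10) expect_equal(g$trains$trains[[m]], co)
  expect_length(g$trains$trains[[11]], 0)

  # with jitter, member events stay within the jitter bound of a co-event
  spj <- sim_spec(5, 300, base_rate_hz = 0,
                  assembly = list(list(members = 1:5, rate_hz = 0.2, jitter_ms = 80)),
                  seed = 4)
  gj <- generate_event_trains(spj)
  for (m in 1:5) {
    d <- vapply(gj$trains$trains[[m]],
                function(t) min(abs(gj$truth$co_event_times[[1]] - t)), numeric(1))
    expect_true(all(d <= 0.08 + 1e-12))
  }
})

test_that("FSR neurons raise their rate only inside post-shock windows", {
  sp <- sim_spec(400, 360, base_rate_hz = 0.2, fsr_fraction = 0.5, fsr_gain = 8,
                 shock_times_s = c(180, 240, 300), seed = 5)
  g <- generate_event_trains(sp)
  in_win <- function(t) any(t >= c(180, 240, 300) & t < c(180, 240, 300) + 30)
  fsr <- g$truth$fsr_ids
  n_win_fsr <- mean(vapply(fsr, function(i) {
    sum(vapply(g$trains$trains[[i]], in_win, logical(1)))
  }, numeric(1)))
  n_win_other <- mean(vapply(setdiff(1:400, fsr), function(i) {
    sum(vapply(g$trains$trains[[i]], in_win, logical(1)))
  }, numeric(1)))
  # expected window counts: 90 s * 0.2 Hz * gain vs * 1
  expect_gt(n_win_fsr, 0.8 * 90 * 0.2 * 8)
  expect_lt(n_win_other, 1.3 * 90 * 0.2)
})

test_that("rendered traces superpose kernels and obey the noise model", {
  ets <- event_train_set(list(c(10)), duration_s = 60, fs_hz = 10)
  tr0 <- render_traces(ets, noise_sd = 0, seed = 1)
  expect_equal(tr0$raw, tr0$denoised)            # zero noise: identical
  expect_equal(max(tr0$denoised), 1, tolerance = 0.05)  # single kernel peaks at 1

  tr <- render_traces(ets, noise_sd = 0.2, seed = 7)
  resid <- tr$raw - tr$denoised
  expect_equal(sd(as.numeric(resid)), 0.2, tolerance = 0.02)
  expect_identical(render_traces(ets, noise_sd = 0.2, seed = 7)$raw, tr$raw)

  # empty neuron set: zero-row matrices, no error
  e <- render_traces(event_train_set(list(), 10, 10), noise_sd = 0, seed = 1)
  expect_identical(nrow(e$raw), 0L)
})

test_that("footprint generator hits requested overlaps and validates targets", {
  gf <- generate_footprints(8, grid = c(160, 160),
                            overlap_pairs = list(list(i = 1, j = 2, target = 0.6)),
                            seed = 4)
  ov <- compute_pairwise_overlap(gf$footprints$maps[[1]], gf$footprints$maps[[2]])
  expect_gt(ov, 0.55); expect_lt(ov, 0.65)
  # unrequested pairs placed apart: overlap 0
  for (i in 3:7) {
    expect_equal(compute_pairwise_overlap(gf$footprints$maps[[i]],
                                          gf$footprints$maps[[i + 1]]), 0)
  }
  expect_error(generate_footprints(4, overlap_pairs = list(list(i = 1, j = 2, target = 1.2))),
               "target_overlap")
  # smooth disks are compact and round
  m <- compute_shape_metrics(gf$footprints$maps[[5]])
  expect_lt(m$compacity, 1.2)
  expect_lt(m$inertia_ratio, 1.5)
})

test_that("multisession generator plants identity with the requested carryover", {
  base <- sim_spec(40, 60, base_rate_hz = 0.1, seed = 1)
  ms <- generate_multisession(base, 2, carryover = 0.25, seed = 6)
  shared <- intersect(ms$sessions[[1]]$global_ids, ms$sessions[[2]]$global_ids)
  expect_length(shared, 10)  # 0.25 * 40
  # set algebra: true J = c / (2 - c) = 0.25 / 1.75
  J_true <- length(shared) / length(union(ms$sessions[[1]]$global_ids,
                                          ms$sessions[[2]]$global_ids))
  expect_equal(J_true, 0.25 / (2 - 0.25), tolerance = 1e-12)

  # jitter 0 + carryover 1: registration recovers identity exactly
  ms1 <- generate_multisession(base, 2, carryover = 1, seed = 7)
  map <- register_fixed_threshold(list(ms1$sessions[[1]]$footprints,
                                       ms1$sessions[[2]]$footprints))
  expect_identical(nrow(map$matches), 40L)
  ga <- map$assignments[map$assignments$session == 1, ]
  gb <- map$assignments[map$assignments$session == 2, ]
  expect_identical(ga$global_id[order(as.integer(ga$neuron_id))],
                   gb$global_id[order(as.integer(gb$neuron_id))])
})

test_that("match rate degrades monotonically with footprint jitter", {
  base <- sim_spec(30, 30, base_rate_hz = 0.1, seed = 1)
  rate <- vapply(c(0, 0.5, 1, 2), function(j) {
    ms <- generate_multisession(base, 2, carryover = 1, footprint_jitter_px = j,
                                seed = 11)
    map <- register_fixed_threshold(list(ms$sessions[[1]]$footprints,
                                         ms$sessions[[2]]$footprints))
    nrow(map$matches) / 30
  }, numeric(1))
  expect_true(all(diff(rate) <= 0))
  expect_identical(rate[1], 1)
})

test_that("LFP generator validates specs and builds consistent ground truth", {
  expect_error(lfp_sim_spec(60, fs_hz = 1000, ripple = list(freq_hz = 600)),
               "Nyquist")
  expect_error(lfp_sim_spec(60, coupling_prob = 1.5), "coupling_prob")

  spec <- lfp_sim_spec(300, ripple = list(count = 20, amp_sd = 8),
                       spindle = list(count = 10, amp_sd = 8),
                       coupling_prob = 1,
                       sws_intervals = list(c(20, 280)), seed = 9)
  g <- generate_lfp(spec)
  # coupling_prob 1: every true ripple center within 0.5 s of a spindle center
  for (rc in g$truth$ripple_centers) {
    expect_lte(min(abs(g$truth$spindle_centers - rc)), 0.5)
  }
  expect_true(all(g$truth$ripple_coupled))
  # all events inside SWS
  expect_true(all(g$truth$ripple_centers > 20 & g$truth$ripple_centers < 280))
  expect_true(all(g$truth$spindle_centers > 20 & g$truth$spindle_centers < 280))
  # occurrence arithmetic on ground truth
  expect_equal(length(g$truth$ripple_centers) / 260, 20 / 260)
  # determinism
  g2 <- generate_lfp(spec)
  expect_identical(g$lfp$ca1, g2$lfp$ca1)
  expect_identical(g$truth, g2$truth)
})
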