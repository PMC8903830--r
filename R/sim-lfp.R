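#' Simulation specification for dual-site LFP
#'
#' Background 1/f^alpha noise on both channels (CA1 and ACC) plus
#' Gaussian-enveloped oscillatory bursts: ripples on CA1, spindles on ACC,
#' all placed inside slow-wave-sleep (SWS) intervals. A fraction
#' `coupling_prob` of ripples is placed within `coupling_offset_s` of a
#' spindle center; the remainder is kept clear of every spindle's +/- 0.5 s
#' window so the injected coupling fraction is exact by construction.
#'
#' @param duration_s recording length (s).
#' @param fs_hz sampling rate (Hz, default 1250).
#' @param noise_alpha 1/f exponent of the background (default 1).
#' @param noise_sd background SD in signal units.
#' @param ripple list: `freq_hz` (default 150), `dur_ms` range (default
#'   `c(60, 80)`), `amp_sd` amplitude in background-SD units, `count`.
#' @param spindle list: `freq_hz` (default 13), `dur_ms` range (default
#'   `c(500, 1000)`), `amp_sd`, `count`.
#' @param coupling_prob fraction of ripples coupled to a spindle.
#' @param coupling_offset_s maximum |ripple center - spindle center| for
#'   coupled placements (must be <= 0.5 s).
#' @param sws_intervals list of `c(start_s, end_s)`; default one interval
#'   covering the whole recording.
#' @param seed integer seed.
#' @return An object of class `lfp_sim_spec`.
#' @export
lfp_sim_spec <- function(duration_s, fs_hz = 1250, noise_alpha = 1, noise_sd = 1,
                         ripple = list(), spindle = list(),
                         coupling_prob = 0, coupling_offset_s = 0.4,
                         sws_intervals = NULL, seed = 1L) {
  stopifnot_scalar_num(duration_s, "duration_s", lower = 1e-9)
  stopifnot_scalar_num(coupling_prob, "coupling_prob", lower = 0, upper = 1)
  stopifnot_scalar_num(coupling_offset_s, "coupling_offset_s", lower = 0, upper = 0.5)
  ripple <- utils::modifyList(
    list(freq_hz = 150, dur_ms = c(60, 80), amp_sd = 8, count = 0), ripple)
  spindle <- utils::modifyList(
    list(freq_hz = 13, dur_ms = c(500, 1000), amp_sd = 8, count = 0), spindle)
  if (any(c(ripple$dur_ms, spindle$dur_ms) <= 0)) stop("event durations must be positive")
  if (ripple$freq_hz >= fs_hz / 2) stop("ripple frequency at or above Nyquist")
  if (spindle$freq_hz >= fs_hz / 2) stop("spindle frequency at or above Nyquist")
  if (is.null(sws_intervals)) sws_intervals <- list(c(0, duration_s))
  for (iv in sws_intervals) {
    if (length(iv) != 2 || iv[1] >= iv[2] || iv[1] < 0 || iv[2] > duration_s) {
      stop("sws_intervals must be (start, end) pairs within the recording")
    }
  }
  structure(list(duration_s = duration_s, fs_hz = fs_hz,
                 noise_alpha = noise_alpha, noise_sd = noise_sd,
                 ripple = ripple, spindle = spindle,
                 coupling_prob = coupling_prob,
                 coupling_offset_s = coupling_offset_s,
                 sws_intervals = sws_intervals, seed = as.integer(seed)),
            class = "lfp_sim_spec")
}

# 1/f^alpha noise via spectral shaping of white Gaussian noise
pink_noise <- function(n, alpha, sd_out) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))                 # avoid the DC bin
  f <- pmin(f, n - f + 1)                   # mirror for negative frequencies
  W <- W * f^(-alpha / 2)
  x <- Re(fft(W, inverse = TRUE)) / n
  x <- x - mean(x)
  x / sd(x) * sd_out
}

# Gaussian-enveloped sinusoidal burst sampled on the signal grid; `dur_s` is
# the nominal event duration. The envelope is deliberately flat-topped
# (sigma = dur/3, truncated at +/- 0.75 dur) so the burst holds most of its
# amplitude across the nominal duration, as physiological ripples and
# spindles do, rather than spiking at the center.
burst_waveform <- function(center_s, dur_s, freq_hz, amp, fs, n) {
  half <- 0.75 * dur_s
  i0 <- max(1L, floor((center_s - half) * fs) + 1L)
  i1 <- min(n, ceiling((center_s + half) * fs) + 1L)
  t <- (seq(i0, i1) - 1) / fs - center_s
  phase <- runif(1, 0, 2 * pi)
  list(idx = i0:i1,
       y = amp * exp(-t^2 / (2 * (dur_s / 3)^2)) * sin(2 * pi * freq_hz * t + phase))
}

# sample `count` centers uniformly inside intervals, >= min_sep apart and
# >= margin from interval edges; optional predicate gates each draw
sample_centers <- function(count, intervals, margin, min_sep, accept = NULL,
                           max_tries = 5000) {
  lens <- vapply(intervals, function(iv) max(0, (iv[2] - iv[1]) - 2 * margin), numeric(1))
  if (sum(lens) <= 0) stop("SWS intervals too short for the requested events")
  centers <- numeric(0)
  tries <- 0
  while (length(centers) < count && tries < max_tries) {
    tries <- tries + 1
    k <- sample.int(length(intervals), 1, prob = lens)
    c0 <- runif(1, intervals[[k]][1] + margin, intervals[[k]][2] - margin)
    if (length(centers) && min(abs(centers - c0)) < min_sep) next
    if (!is.null(accept) && !accept(c0)) next
    centers <- c(centers, c0)
  }
  if (length(centers) < count) {
    stop("could not place all events; SWS intervals too crowded")
  }
  sort(centers)
}

#' Generate dual-site LFP with injected ripples and spindles
#'
#' @param spec an [lfp_sim_spec()].
#' @return A list with `lfp` (class `lfp_recording`: `ca1`, `acc`, `accel`,
#'   `fs_hz`, `duration_s`, `sws_intervals`) and `truth` (spindle centers and
#'   durations, ripple centers and durations, per-ripple `coupled` flags).
#' @export
generate_lfp <- function(spec) {
  stopifnot(inherits(spec, "lfp_sim_spec"))
  with_seed(spec$seed, {
    n <- round(spec$duration_s * spec$fs_hz)
    ca1 <- pink_noise(n, spec$noise_alpha, spec$noise_sd)
    acc <- pink_noise(n, spec$noise_alpha, spec$noise_sd)

    sp <- spec$spindle
    sp_dur <- runif(sp$count, sp$dur_ms[1], sp$dur_ms[2]) / 1000
    sp_centers <- if (sp$count > 0) {
      sample_centers(sp$count, spec$sws_intervals,
                     margin = max(sp_dur) / 2 + 0.1, min_sep = 3)
    } else numeric(0)
    for (k in seq_along(sp_centers)) {
      b <- burst_waveform(sp_centers[k], sp_dur[k], sp$freq_hz,
                          sp$amp_sd * spec$noise_sd, spec$fs_hz, n)
      acc[b$idx] <- acc[b$idx] + b$y
    }

    rp <- spec$ripple
    n_coupled <- if (length(sp_centers)) round(spec$coupling_prob * rp$count) else 0
    rp_dur <- runif(rp$count, rp$dur_ms[1], rp$dur_ms[2]) / 1000
    margin_r <- max(c(rp_dur, 0.05)) / 2 + 0.05

    coupled_centers <- numeric(0)
    if (n_coupled > 0) {
      tries <- 0
      while (length(coupled_centers) < n_coupled && tries < 5000) {
        tries <- tries + 1
        host <- sample(sp_centers, 1)
        c0 <- host + runif(1, -spec$coupling_offset_s, spec$coupling_offset_s)
        c0 <- min(max(c0, margin_r), spec$duration_s - margin_r)
        if (length(coupled_centers) && min(abs(coupled_centers - c0)) < 0.3) next
        coupled_centers <- c(coupled_centers, c0)
      }
      if (length(coupled_centers) < n_coupled) {
        stop("could not place coupled ripples; too few spindles for the requested count")
      }
    }
    n_free <- rp$count - n_coupled
    free_centers <- if (n_free > 0) {
      away <- function(c0) {
        (!length(sp_centers) || min(abs(sp_centers - c0)) > 0.7) &&
          (!length(coupled_centers) || min(abs(coupled_centers - c0)) >= 0.5)
      }
      sample_centers(n_free, spec$sws_intervals, margin = margin_r,
                     min_sep = 0.5, accept = away)
    } else numeric(0)

    rp_centers <- c(coupled_centers, free_centers)
    coupled_flag <- c(rep(TRUE, n_coupled), rep(FALSE, n_free))
    ord <- order(rp_centers)
    rp_centers <- rp_centers[ord]; coupled_flag <- coupled_flag[ord]
    rp_dur <- rp_dur[seq_along(rp_centers)]
    for (k in seq_along(rp_centers)) {
      b <- burst_waveform(rp_centers[k], rp_dur[k], rp$freq_hz,
                          rp$amp_sd * spec$noise_sd, spec$fs_hz, n)
      ca1[b$idx] <- ca1[b$idx] + b$y
    }

    # accelerometer magnitude: quiet (low noise) inside SWS, strong outside
    t <- (seq_len(n) - 1) / spec$fs_hz
    in_sws <- rep(FALSE, n)
    for (iv in spec$sws_intervals) in_sws <- in_sws | (t >= iv[1] & t < iv[2])
    accel <- abs(rnorm(n, sd = 0.05)) + ifelse(in_sws, 0, 1)

    list(
      lfp = structure(list(ca1 = ca1, acc = acc, accel = accel,
                           fs_hz = spec$fs_hz, duration_s = spec$duration_s,
                           sws_intervals = spec$sws_intervals),
                      class = "lfp_recording"),
      truth = list(spindle_centers = sp_centers, spindle_dur_s = sp_dur,
                   ripple_centers = rp_centers, ripple_dur_s = rp_dur,
                   ripple_coupled = coupled_flag)
    )
  })
}
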