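# total seconds covered by a list of (start, end) intervals
sws_total_s <- function(sws) sum(vapply(sws, function(iv) iv[2] - iv[1], numeric(1)))

# logical sample mask for the intervals
sws_mask <- function(sws, n, fs) {
  t <- (seq_len(n) - 1) / fs
  m <- rep(FALSE, n)
  for (iv in sws) m <- m | (t >= iv[1] & t < iv[2])
  m
}

# zero-phase Butterworth band-pass (order 4 per direction)
bandpass_filter <- function(x, fs, band, order = 4) {
  ny <- fs / 2
  if (band[2] >= ny) stop("band edge at or above Nyquist")
  bf <- signal::butter(order, band / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# analytic-signal amplitude envelope via the frequency-domain Hilbert method
analytic_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Downsample an LFP signal
#'
#' Zero-phase anti-alias low-pass at `0.4 * fs_out`, then decimation (integer
#' factors) or polyphase resampling (rational factors).
#'
#' @param x signal vector.
#' @param fs_in,fs_out input and output rates (Hz); `fs_out` must not exceed
#'   `fs_in`.
#' @return The downsampled signal.
#' @export
downsample_lfp <- function(x, fs_in = 30000, fs_out = 1250) {
  if (fs_out > fs_in) stop("fs_out must not exceed fs_in")
  if (fs_out == fs_in) return(x)
  bf <- signal::butter(6, (0.4 * fs_out) / (fs_in / 2), type = "low")
  xf <- as.numeric(signal::filtfilt(bf, x))
  ratio <- fs_in / fs_out
  if (abs(ratio - round(ratio)) < 1e-9) {
    xf[seq(1, length(xf), by = round(ratio))]
  } else {
    frac <- MASS::fractions(fs_out / fs_in)
    pq <- as.integer(strsplit(attr(frac, "fracs"), "/")[[1]])
    as.numeric(signal::resample(xf, pq[1], pq[2]))
  }
}

#' Detect immobility from accelerometer magnitude
#'
#' A crude quiet-period helper: intervals where the smoothed accelerometer
#' magnitude stays below `threshold` for at least `min_duration_s`. It is not
#' a sleep-stage scorer; slow-wave-sleep intervals should be supplied
#' directly whenever available.
#'
#' @param accel accelerometer magnitude vector.
#' @param fs sampling rate (Hz).
#' @param threshold magnitude threshold.
#' @param min_duration_s minimum quiet duration (s).
#' @param smooth_s smoothing window (s, default 1).
#' @return List of `c(start_s, end_s)` intervals.
#' @export
detect_immobility <- function(accel, fs, threshold, min_duration_s,
                              smooth_s = 1) {
  sm <- moving_avg(accel, round(smooth_s * fs))
  quiet <- sm < threshold
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] / fs >= min_duration_s) {
      out[[length(out) + 1]] <- c((starts[k] - 1) / fs, ends[k] / fs)
    }
  }
  out
}

# contiguous above-threshold regions of z restricted to a sample mask,
# returned as (start, end) sample indices
threshold_regions <- function(z, mask, thr) {
  above <- z > thr & mask
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect sharp-wave ripples in CA1 LFP
#'
#' The band-passed (100-250 Hz) trace is squared, smoothed (10 ms) and
#' z-scored over slow-wave-sleep samples. Contiguous regions above `edge_sd`
#' are candidates; candidates closer than `merge_ms` are merged; merged
#' events are kept when their peak z exceeds `peak_sd` and their duration
#' lies within `dur_ms`.
#'
#' @param ca1 CA1 LFP vector.
#' @param fs sampling rate (Hz).
#' @param sws list of `c(start_s, end_s)` SWS intervals.
#' @param band band-pass edges (Hz, default `c(100, 250)`).
#' @param edge_sd onset/offset threshold in SDs (default 3).
#' @param peak_sd peak threshold in SDs (default 5).
#' @param dur_ms duration bounds (ms, default `c(50, 100)`).
#' @param merge_ms merge gap (ms, default 20; strict `<` merges).
#' @param smooth_ms smoothing of the squared signal (ms, default 10).
#' @return Data frame: `onset_s`, `peak_s`, `offset_s`, `duration_ms`,
#'   `peak_z`, one row per ripple.
#' @export
detect_ripples <- function(ca1, fs, sws, band = c(100, 250), edge_sd = 3,
                           peak_sd = 5, dur_ms = c(50, 100), merge_ms = 20,
                           smooth_ms = 10) {
  if (sws_total_s(sws) < 10) stop("SWS total below 10 s; normalization unstable")
  xf <- bandpass_filter(ca1, fs, band)
  pw <- moving_avg(xf^2, round(smooth_ms / 1000 * fs))
  mask <- sws_mask(sws, length(ca1), fs)
  z <- (pw - mean(pw[mask])) / sd(pw[mask])
  reg <- threshold_regions(z, mask, edge_sd)
  reg <- merge_regions(reg, round(merge_ms / 1000 * fs))
  events_from_regions(reg, z, fs, dur_ms, peak_sd, peak_stat = "argmax")
}

#' Detect sleep spindles in ACC LFP
#'
#' The band-passed (12-15 Hz) trace's analytic-signal envelope is smoothed
#' (50 ms) and z-scored over SWS samples; contiguous regions above
#' `thresh_sd` lasting 200-2000 ms are spindles. The event center is the
#' onset/offset midpoint.
#'
#' @param acc_lfp ACC LFP vector.
#' @param fs sampling rate (Hz).
#' @param sws SWS intervals.
#' @param band band-pass edges (Hz, default `c(12, 15)`).
#' @param thresh_sd envelope threshold in SDs (default 2.5).
#' @param dur_ms duration bounds (ms, default `c(200, 2000)`).
#' @param smooth_ms envelope smoothing (ms, default 50).
#' @return Data frame: `onset_s`, `center_s`, `offset_s`, `duration_ms`,
#'   `peak_z`, one row per spindle.
#' @export
detect_spindles <- function(acc_lfp, fs, sws, band = c(12, 15), thresh_sd = 2.5,
                            dur_ms = c(200, 2000), smooth_ms = 50) {
  if (sws_total_s(sws) < 10) stop("SWS total below 10 s; normalization unstable")
  xf <- bandpass_filter(acc_lfp, fs, band)
  env <- moving_avg(analytic_envelope(xf), round(smooth_ms / 1000 * fs))
  mask <- sws_mask(sws, length(acc_lfp), fs)
  z <- (env - mean(env[mask])) / sd(env[mask])
  reg <- threshold_regions(z, mask, thresh_sd)
  ev <- events_from_regions(reg, z, fs, dur_ms, peak_sd = -Inf,
                            peak_stat = "midpoint")
  names(ev)[names(ev) == "peak_s"] <- "center_s"
  ev
}

# merge regions whose gap is strictly below `gap_samples`
merge_regions <- function(reg, gap_samples) {
  if (!nrow(reg)) return(reg)
  out <- reg[1, , drop = FALSE]
  for (k in seq_len(nrow(reg))[-1]) {
    if (reg[k, "start"] - out[nrow(out), "end"] - 1L < gap_samples) {
      out[nrow(out), "end"] <- reg[k, "end"]
    } else {
      out <- rbind(out, reg[k, , drop = FALSE])
    }
  }
  out
}

# apply peak and duration criteria; report times in seconds
events_from_regions <- function(reg, z, fs, dur_ms, peak_sd,
                                peak_stat = c("argmax", "midpoint")) {
  peak_stat <- match.arg(peak_stat)
  rows <- list()
  for (k in seq_len(nrow(reg))) {
    i0 <- reg[k, "start"]; i1 <- reg[k, "end"]
    dur <- (i1 - i0 + 1) / fs * 1000
    zmax <- max(z[i0:i1])
    if (zmax <= peak_sd && is.finite(peak_sd)) next
    if (dur < dur_ms[1] || dur > dur_ms[2]) next
    pk <- if (peak_stat == "argmax") i0 + which.max(z[i0:i1]) - 1L else (i0 + i1) / 2
    rows[[length(rows) + 1]] <- data.frame(
      onset_s = (i0 - 1) / fs, peak_s = (pk - 1) / fs, offset_s = (i1 - 1) / fs,
      duration_ms = dur, peak_z = zmax)
  }
  if (!length(rows)) {
    return(data.frame(onset_s = numeric(), peak_s = numeric(),
                      offset_s = numeric(), duration_ms = numeric(),
                      peak_z = numeric()))
  }
  do.call(rbind, rows)
}

#' Ripple-spindle coupling
#'
#' A ripple is coupled when its peak lies within a `window_s` window
#' (+/- `window_s / 2`) around some spindle center.
#'
#' @param ripples [detect_ripples()] output.
#' @param spindles [detect_spindles()] output.
#' @param window_s full window width (default 1.0, i.e. +/- 0.5 s).
#' @param ripple_time which ripple time point to use: `"peak"` (default),
#'   `"onset"` or `"center"`.
#' @return A list of class `coupling_summary`: `n_ripples`, `n_spindles`,
#'   `coupled` (logical per ripple), `coupled_ripple_pct` (`NA`, flagged,
#'   when there are no ripples), `window_s`.
#' @export
couple_events <- function(ripples, spindles, window_s = 1.0,
                          ripple_time = c("peak", "onset", "center")) {
  ripple_time <- match.arg(ripple_time)
  rt <- switch(ripple_time,
               peak = ripples$peak_s,
               onset = ripples$onset_s,
               center = (ripples$onset_s + ripples$offset_s) / 2)
  if (!length(rt)) {
    warning("no ripples; coupled percentage undefined")
    return(structure(list(n_ripples = 0L, n_spindles = nrow(spindles),
                          coupled = logical(0), coupled_ripple_pct = NA_real_,
                          window_s = window_s), class = "coupling_summary"))
  }
  coupled <- vapply(rt, function(t0) {
    nrow(spindles) > 0 && min(abs(spindles$center_s - t0)) <= window_s / 2
  }, logical(1))
  structure(list(n_ripples = length(rt), n_spindles = nrow(spindles),
                 coupled = coupled,
                 coupled_ripple_pct = 100 * mean(coupled),
                 window_s = window_s),
            class = "coupling_summary")
}

#' @export
print.coupling_summary <- function(x, ...) {
  cat(sprintf("<coupling_summary> %d ripples, %d spindles; %.1f%% coupled (+/- %.2f s)\n",
              x$n_ripples, x$n_spindles, x$coupled_ripple_pct, x$window_s / 2))
  invisible(x)
}

#' Occurrence rate per SWS second
#'
#' @param events event data frame (ripples or spindles).
#' @param sws SWS intervals.
#' @return Events per second of SWS.
#' @export
occurrence_rate <- function(events, sws) {
  tot <- sws_total_s(sws)
  if (tot <= 0) stop("zero SWS time; rate undefined")
  nrow(events) / tot
}
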