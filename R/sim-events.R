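#' Simulation specification for a calcium-imaging session
#'
#' Describes one synthetic session: independent Poisson background activity,
#' optional synchronous assemblies (sets of neurons sharing co-events),
#' per-context rate modulation, and a foot-shock-responsive (FSR) subset whose
#' rate is multiplied for 30 s after each shock.
#'
#' @param n_neurons number of neurons.
#' @param duration_s session length in seconds (default 360, a 6-min context
#'   exposure).
#' @param fs_trace_hz trace sampling rate (Hz, default 10).
#' @param base_rate_hz per-neuron baseline event rate (events/s).
#' @param assembly list of assemblies, each `list(members =, rate_hz =,
#'   jitter_ms =)`: `members` indexes neurons sharing Poisson co-events at
#'   `rate_hz`, each member's copy jittered uniformly by up to `jitter_ms`.
#' @param context_effect optional per-neuron rate multiplier (length
#'   `n_neurons`), e.g. to make one context drive a subset harder.
#' @param fsr_fraction fraction of neurons that respond to foot-shocks.
#' @param fsr_gain rate multiplier applied to FSR neurons for
#'   `fsr_window_s` after each shock.
#' @param fsr_window_s length of the post-shock response window (s).
#' @param shock_times_s foot-shock onset times (s).
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_neurons, duration_s = 360, fs_trace_hz = 10,
                     base_rate_hz = 0.1, assembly = list(),
                     context_effect = NULL, fsr_fraction = 0, fsr_gain = 1,
                     fsr_window_s = 30, shock_times_s = numeric(), seed = 1L) {
  stopifnot_scalar_num(n_neurons, "n_neurons", lower = 1)
  stopifnot_scalar_num(duration_s, "duration_s", lower = 1e-9)
  stopifnot_scalar_num(fs_trace_hz, "fs_trace_hz", lower = 1e-9)
  stopifnot_scalar_num(base_rate_hz, "base_rate_hz", lower = 0)
  stopifnot_scalar_num(fsr_fraction, "fsr_fraction", lower = 0, upper = 1)
  stopifnot_scalar_num(fsr_gain, "fsr_gain", lower = 0)
  if (is.null(context_effect)) context_effect <- rep(1, n_neurons)
  if (length(context_effect) != n_neurons || any(context_effect < 0)) {
    stop("context_effect must be a nonnegative vector of length n_neurons")
  }
  for (a in assembly) {
    if (!all(c("members", "rate_hz") %in% names(a))) {
      stop("each assembly needs `members` and `rate_hz`")
    }
    if (a$rate_hz < 0) stop("assembly rate must be nonnegative")
    if (any(a$members < 1 | a$members > n_neurons)) stop("assembly member out of range")
  }
  if (any(shock_times_s < 0 | shock_times_s > duration_s)) {
    stop("shock times must lie within the session")
  }
  structure(
    list(n_neurons = as.integer(n_neurons), duration_s = duration_s,
         fs_trace_hz = fs_trace_hz, base_rate_hz = base_rate_hz,
         assembly = assembly, context_effect = context_effect,
         fsr_fraction = fsr_fraction, fsr_gain = fsr_gain,
         fsr_window_s = fsr_window_s,
         shock_times_s = as.numeric(shock_times_s), seed = as.integer(seed)),
    class = "sim_spec"
  )
}

# Piecewise-constant-rate Poisson sampler on [0, duration]: per segment the
# count is Poisson(rate * len) and times are uniform within the segment.
sample_inhomogeneous <- function(breaks, rates) {
  times <- numeric(0)
  for (i in seq_along(rates)) {
    len <- breaks[i + 1] - breaks[i]
    if (len <= 0 || rates[i] <= 0) next
    k <- rpois(1, rates[i] * len)
    if (k > 0) times <- c(times, runif(k, breaks[i], breaks[i + 1]))
  }
  sort(times)
}

#' Generate per-neuron event trains with known ground truth
#'
#' Background events are Poisson at `base_rate_hz * context_effect[i]`; FSR
#' neurons multiply their rate by `fsr_gain` for `fsr_window_s` after each
#' shock; assembly co-events are drawn once per assembly and copied (with
#' jitter) into every member's train.
#'
#' @param spec a [sim_spec()].
#' @return A list with `trains` (an [event_train_set()]) and `truth`, a list
#'   holding `fsr_ids` (integer indices), `assembly_members`,
#'   `co_event_times` (one vector per assembly), and the per-neuron
#'   background/assembly decomposition.
#' @export
generate_event_trains <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_neurons
    n_fsr <- round(spec$fsr_fraction * n)
    fsr_ids <- if (n_fsr > 0) sort(sample.int(n, n_fsr)) else integer(0)

    # rate breakpoints: session start/end plus each shock response window
    brk <- sort(unique(c(0, spec$duration_s,
                         pmin(spec$shock_times_s, spec$duration_s),
                         pmin(spec$shock_times_s + spec$fsr_window_s, spec$duration_s))))
    in_window <- vapply(head(brk, -1), function(b0) {
      any(b0 >= spec$shock_times_s - 1e-12 &
            b0 < spec$shock_times_s + spec$fsr_window_s - 1e-12)
    }, logical(1))

    trains <- vector("list", n)
    for (i in seq_len(n)) {
      r0 <- spec$base_rate_hz * spec$context_effect[i]
      rates <- rep(r0, length(brk) - 1)
      if (i %in% fsr_ids) rates[in_window] <- rates[in_window] * spec$fsr_gain
      trains[[i]] <- sample_inhomogeneous(brk, rates)
    }

    co_times <- vector("list", length(spec$assembly))
    for (k in seq_along(spec$assembly)) {
      a <- spec$assembly[[k]]
      ct <- sample_inhomogeneous(c(0, spec$duration_s), a$rate_hz)
      co_times[[k]] <- ct
      jit <- if (is.null(a$jitter_ms)) 0 else a$jitter_ms / 1000
      for (m in a$members) {
        t_m <- ct
        if (jit > 0 && length(ct)) t_m <- ct + runif(length(ct), -jit, jit)
        t_m <- pmin(pmax(t_m, 0), spec$duration_s)
        trains[[m]] <- sort(c(trains[[m]], t_m))
      }
    }

    list(
      trains = event_train_set(trains, spec$duration_s, spec$fs_trace_hz),
      truth = list(
        fsr_ids = fsr_ids,
        assembly_members = lapply(spec$assembly, `[[`, "members"),
        co_event_times = co_times
      )
    )
  })
}

#' Render raw/denoised fluorescence traces from event trains
#'
#' The denoised trace is a superposition of difference-of-exponential calcium
#' kernels (GCaMP6f-like defaults: 0.05 s rise, 0.5 s decay), normalized so a
#' single event peaks at `amplitude`; the raw trace adds white Gaussian noise.
#'
#' @param events an [event_train_set()].
#' @param kernel numeric `c(rise_s, decay_s, amplitude)`.
#' @param noise_sd SD of the additive noise on the raw trace (a.u.).
#' @param seed integer seed for the noise.
#' @return A list of class `trace_set` with matrices `raw` and `denoised`
#'   (neurons x frames), `fs_hz` and `neuron_ids`. Empty input gives matrices
#'   with zero rows.
#' @export
render_traces <- function(events, kernel = c(rise_s = 0.05, decay_s = 0.5, amplitude = 1),
                          noise_sd = 0.1, seed = 1L) {
  stopifnot(inherits(events, "event_train_set"))
  rise <- kernel[[1]]; decay <- kernel[[2]]; amp <- kernel[[3]]
  if (decay <= 0 || rise <= 0) stop("kernel rise and decay must be positive")
  fs <- events$fs_hz
  n_frames <- max(1L, ceiling(events$duration_s * fs))
  n <- events$n_neurons

  # kernel sampled on the frame grid, peak-normalized to `amp`
  tk <- seq(0, decay * 8, by = 1 / fs)
  k <- exp(-tk / decay) - exp(-tk / rise)
  if (max(k) > 0) k <- k / max(k) * amp

  den <- matrix(0, n, n_frames)
  for (i in seq_len(n)) {
    for (t0 in events$trains[[i]]) {
      f0 <- floor(t0 * fs) + 1L
      idx <- f0:min(n_frames, f0 + length(k) - 1L)
      den[i, idx] <- den[i, idx] + k[seq_along(idx)]
    }
  }
  raw <- with_seed(seed, den + matrix(rnorm(n * n_frames, sd = noise_sd), n, n_frames))
  structure(list(raw = raw, denoised = den, fs_hz = fs,
                 neuron_ids = names(events$trains)),
            class = "trace_set")
}

#' Inject spurious denoised-only transients
#'
#' Emulates deconvolution artifacts: event-shaped bumps added to the
#' denoised traces only, with no counterpart in the raw fluorescence. They
#' pass candidate detection on the denoised trace but lack raw-trace support,
#' which is exactly the signature the event classifier is trained to reject.
#'
#' @param traces a `trace_set` from [render_traces()].
#' @param rate_hz artifact rate per neuron (events/s).
#' @param kernel artifact kernel `c(rise_s, decay_s, amplitude)`; defaults to
#'   the calcium-event kernel so artifacts are not trivially separable by
#'   shape on the denoised trace.
#' @param seed integer seed.
#' @return A list: `traces` (modified `trace_set`) and `artifact_times`
#'   (list of injected times per neuron).
#' @export
inject_denoised_artifacts <- function(traces, rate_hz,
                                      kernel = c(rise_s = 0.05, decay_s = 0.5,
                                                 amplitude = 1),
                                      seed = 1L) {
  stopifnot(inherits(traces, "trace_set"))
  fs <- traces$fs_hz
  n_frames <- ncol(traces$denoised)
  duration_s <- n_frames / fs
  tk <- seq(0, kernel[[2]] * 8, by = 1 / fs)
  k <- exp(-tk / kernel[[2]]) - exp(-tk / kernel[[1]])
  k <- k / max(k) * kernel[[3]]
  with_seed(seed, {
    times <- lapply(seq_len(nrow(traces$denoised)), function(i) {
      m <- rpois(1, rate_hz * duration_s)
      sort(runif(m, 0, duration_s))
    })
    for (i in seq_along(times)) {
      for (t0 in times[[i]]) {
        f0 <- floor(t0 * fs) + 1L
        idx <- f0:min(n_frames, f0 + length(k) - 1L)
        traces$denoised[i, idx] <- traces$denoised[i, idx] + k[seq_along(idx)]
      }
    }
    list(traces = traces, artifact_times = times)
  })
}
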