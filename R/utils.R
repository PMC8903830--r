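#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test mad prcomp predict rnorm runif rpois sd var fft
#' @importFrom grDevices contourLines
#' @importFrom utils head tail
NULL

# Robust baseline-noise SD of a fluorescence trace: 1.4826 * MAD of the first
# difference, divided by sqrt(2) (differencing doubles the variance of white
# noise), floored so PNR-type ratios stay finite on noiseless traces.
robust_noise_sd <- function(x, floor = 1e-9) {
  if (length(x) < 2) return(floor)
  s <- 1.4826 * stats::median(abs(diff(x) - stats::median(diff(x)))) / sqrt(2)
  max(s, floor)
}

# Seeded evaluation that restores the caller's RNG state afterwards, so
# library functions do not clobber user-level reproducibility.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of child seeds from one user-facing seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

# moving-average smoother with edge padding, window in samples (odd forced)
moving_avg <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(x)
  half <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(half + 1L):(half + length(x))]
}
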