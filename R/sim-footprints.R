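#' Footprint set
#'
#' Per-neuron 2D spatial weight maps on a common pixel grid, as produced by
#' constrained matrix-factorization source extraction.
#'
#' @param maps list of nonnegative numeric matrices, all with identical
#'   dimensions.
#' @param neuron_ids optional ids.
#' @return An object of class `footprint_set`: list with `maps` (named list),
#'   `dim` (grid size), `n_neurons`.
#' @export
footprint_set <- function(maps, neuron_ids = NULL) {
  if (!length(maps)) stop("footprint set must contain at least one map")
  d <- dim(maps[[1]])
  for (m in maps) {
    if (!is.matrix(m) || !identical(dim(m), d)) stop("all maps must share one grid")
    if (any(!is.finite(m)) || any(m < 0)) stop("maps must be finite and nonnegative")
  }
  if (is.null(neuron_ids)) neuron_ids <- seq_along(maps)
  names(maps) <- as.character(neuron_ids)
  structure(list(maps = maps, dim = d, n_neurons = length(maps)),
            class = "footprint_set")
}

#' @export
print.footprint_set <- function(x, ...) {
  cat(sprintf("<footprint_set> %d neurons on a %d x %d grid\n",
              x$n_neurons, x$dim[1], x$dim[2]))
  invisible(x)
}

# Render one soma-like footprint: Gaussian radial weight profile
# (sigma = radius/2 along each axis), truncated where it falls below ~1e-4.
#   radius_px: nominal boundary radius; elongation: major/minor axis ratio;
#   roughness: relative amplitude of an 8-lobe radial sinusoid on the boundary.
render_footprint <- function(grid, center, radius_px, elongation = 1,
                             theta0 = 0, roughness = 0, lobes = 8) {
  H <- grid[1]; W <- grid[2]
  x <- matrix(rep(seq_len(W), each = H), H, W) - center[2]
  y <- matrix(rep(seq_len(H), W), H, W) - center[1]
  # rotate into the principal frame, squeeze to an area-preserving ellipse
  u <- cos(theta0) * x + sin(theta0) * y
  v <- -sin(theta0) * x + cos(theta0) * y
  a <- radius_px * sqrt(elongation)
  b <- radius_px / sqrt(elongation)
  d <- sqrt((u / a)^2 + (v / b)^2)   # 1 on the smooth boundary
  if (roughness > 0) {
    th <- atan2(v / b, u / a)
    d <- d / pmax(1 + roughness * sin(lobes * th), 0.05)
  }
  w <- exp(-2 * d^2)
  w[w < 1e-4] <- 0
  w
}

#' Generate synthetic spatial footprints
#'
#' Footprints are linear-falloff blobs with controllable mean radius,
#' elongation (axis ratio) and boundary roughness; designated pairs are placed
#' so that their measured overlap (per [compute_pairwise_overlap()]) hits a
#' requested target within +/- 0.05.
#'
#' @param n number of footprints.
#' @param radius_px length-2 range of mean radii (pixels).
#' @param elongation length-2 range of axis ratios (1 = disk).
#' @param roughness boundary roughness amplitude (0 = smooth).
#' @param grid `c(H, W)` grid size in pixels.
#' @param overlap_pairs list of `list(i =, j =, target =)` requesting a given
#'   pairwise overlap between footprints `i` and `j`.
#' @param seed integer seed.
#' @return A list with `footprints` (a [footprint_set()]) and `truth` (data
#'   frame of centers and shape parameters).
#' @export
generate_footprints <- function(n, radius_px = c(5, 7), elongation = c(1, 1),
                                roughness = 0, grid = c(120, 120),
                                overlap_pairs = list(), seed = 1L) {
  stopifnot_scalar_num(n, "n", lower = 1)
  for (p in overlap_pairs) {
    if (p$target > 1 || p$target < 0) stop("target_overlap must lie in [0, 1]")
    if (p$i > n || p$j > n) stop("overlap pair index out of range")
  }
  rmax <- max(radius_px) * sqrt(max(elongation)) * (1 + roughness)
  if (min(grid) < 4 * rmax) stop("grid too small to hold the requested shapes")
  with_seed(seed, {
    margin <- ceiling(rmax) + 1
    # rejection-sample centers so footprints placed at random do not collide;
    # members of requested overlap pairs are re-placed afterwards anyway
    cy <- cx <- numeric(n)
    min_sep <- 1.4 * max(radius_px)
    for (i in seq_len(n)) {
      for (try in 1:2000) {
        y0 <- runif(1, margin, grid[1] - margin)
        x0 <- runif(1, margin, grid[2] - margin)
        if (i == 1 || min(sqrt((cy[1:(i - 1)] - y0)^2 +
                                 (cx[1:(i - 1)] - x0)^2)) >= min_sep) break
        if (try == 2000) stop("grid too crowded to place footprints apart")
      }
      cy[i] <- y0; cx[i] <- x0
    }
    params <- data.frame(
      cy = cy, cx = cx,
      radius = runif(n, radius_px[1], radius_px[2]),
      elong = runif(n, elongation[1], elongation[2]),
      theta = runif(n, 0, pi)
    )
    paired_j <- vapply(overlap_pairs, function(p) as.integer(p$j), integer(1))

    render_i <- function(i, center = c(params$cy[i], params$cx[i])) {
      render_footprint(grid, center, params$radius[i], params$elong[i],
                       params$theta[i], roughness)
    }
    maps <- lapply(seq_len(n), function(i) render_i(i))

    # place each requested pair's second member by bisection on center
    # distance; overlap decreases monotonically from ~1 (coincident) to 0
    for (p in overlap_pairs) {
      i <- p$i; j <- p$j
      if (p$target == 0) next   # default random placement is far apart
      dir <- runif(1, 0, 2 * pi)
      ci <- c(params$cy[i], params$cx[i])
      lo <- 0; hi <- 2 * rmax + 2
      for (iter in 1:40) {
        mid <- (lo + hi) / 2
        cj <- ci + mid * c(sin(dir), cos(dir))
        mj <- render_i(j, cj)
        ov <- compute_pairwise_overlap(maps[[i]], mj)
        if (abs(ov - p$target) < 0.005) break
        if (ov > p$target) lo <- mid else hi <- mid
      }
      params$cy[j] <- cj[1]; params$cx[j] <- cj[2]
      maps[[j]] <- mj
    }
    # neurons not in any pair must not accidentally sit on a paired one: leave
    # as drawn; random placement on a generous grid keeps spurious overlap rare

    list(footprints = footprint_set(maps), truth = params)
  })
}

#' Generate a multi-session population with known cross-session identity
#'
#' A fixed reservoir of `pool_size` candidate neurons (the field of view's
#' population) is laid out once; session 1 records `n_neurons` of them. With
#' numeric `carryover`, each later session re-records exactly
#' `round(carryover * n_neurons)` of session 1's cells plus fresh cells drawn
#' from the rest of the reservoir; with `carryover = NULL` each session is an
#' independent uniform draw from the reservoir (the chance-overlap
#' condition). Per session, footprint centroids are jittered by
#' `footprint_jitter_px`; event trains are drawn independently from `base`.
#'
#' @param base a [sim_spec()]; `n_neurons` is the per-session count.
#' @param n_sessions number of sessions.
#' @param carryover fraction of session 1's cells re-recorded in each later
#'   session (`[0, 1]`), or `NULL` for independent draws.
#' @param footprint_jitter_px SD (pixels) of the Gaussian centroid jitter
#'   applied per session.
#' @param pool_size reservoir size (default `4 * n_neurons`).
#' @param radius_px,grid footprint geometry, as in [generate_footprints()].
#' @param seed integer seed.
#' @return A list with `sessions` (each: `footprints`, `trains`,
#'   `global_ids` mapping local neuron index to reservoir identity) and
#'   `truth` (`pool_size`, the per-session identity map).
#' @export
generate_multisession <- function(base, n_sessions = 2, carryover = 0.5,
                                  footprint_jitter_px = 0, pool_size = NULL,
                                  radius_px = c(8, 12), grid = c(220, 220),
                                  seed = 1L) {
  stopifnot(inherits(base, "sim_spec"))
  if (!is.null(carryover)) {
    stopifnot_scalar_num(carryover, "carryover", lower = 0, upper = 1)
  }
  n <- base$n_neurons
  if (is.null(pool_size)) pool_size <- 4L * n
  if (pool_size < 2 * n) stop("pool_size must be at least 2 * n_neurons")
  seeds <- derive_seeds(seed, 2 + n_sessions)

  # reservoir shape parameters, fixed across sessions
  rmax <- max(radius_px) + footprint_jitter_px * 3
  if (min(grid) < 4 * rmax) stop("grid too small for jittered shapes")
  pool <- with_seed(seeds[1], {
    margin <- ceiling(rmax) + 1
    data.frame(
      cy = runif(pool_size, margin, grid[1] - margin),
      cx = runif(pool_size, margin, grid[2] - margin),
      radius = runif(pool_size, radius_px[1], radius_px[2])
    )
  })

  ids_per_session <- with_seed(seeds[2], {
    out <- vector("list", n_sessions)
    out[[1]] <- sort(sample.int(pool_size, n))
    for (s in seq_len(n_sessions)[-1]) {
      if (is.null(carryover)) {
        out[[s]] <- sort(sample.int(pool_size, n))
      } else {
        n_keep <- round(carryover * n)
        kept <- sample(out[[1]], n_keep)
        fresh <- sample(setdiff(seq_len(pool_size), out[[1]]), n - n_keep)
        out[[s]] <- sort(c(kept, fresh))
      }
    }
    out
  })

  sessions <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    gids <- ids_per_session[[s]]
    sdat <- with_seed(seeds[2 + s], {
      # session 1 is the unjittered reference field of view
      jit_sd <- if (s == 1) 0 else footprint_jitter_px
      jit_y <- rnorm(length(gids), 0, jit_sd)
      jit_x <- rnorm(length(gids), 0, jit_sd)
      maps <- lapply(seq_along(gids), function(k) {
        g <- gids[k]
        render_footprint(grid, c(pool$cy[g] + jit_y[k], pool$cx[g] + jit_x[k]),
                         pool$radius[g])
      })
      spec_s <- base
      spec_s$seed <- derive_seeds(seeds[2 + s], 1)
      list(maps = maps, trains = generate_event_trains(spec_s)$trains)
    })
    sessions[[s]] <- list(
      footprints = footprint_set(sdat$maps),
      trains = sdat$trains,
      global_ids = gids
    )
  }
  list(sessions = sessions,
       truth = list(pool_size = pool_size,
                    identity = ids_per_session))
}
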