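#' Build the context-decoding feature matrix
#'
#' Each context session is tiled with 5-s bins (half-open `[b, b+5)`;
#' a trailing partial bin is dropped with a message); each row is one bin,
#' each column one A&C neuron, each entry the neuron's mean events per frame
#' in that bin. A 360-s session yields 72 rows per context.
#'
#' @param trains_a,trains_c [event_train_set()]s of the two context sessions,
#'   sharing the A&C neurons' ids.
#' @param ac_ids A&C neuron ids (columns).
#' @param bin_s bin width (default 5).
#' @param min_neurons inclusion rule: below this many A&C neurons the result
#'   is flagged not includable (default 50; computation still runs).
#' @return A list of class `feature_matrix`: `x` (rows = bins of both
#'   contexts), `label` (factor A/C per row), `rows_per_context`,
#'   `includable`.
#' @export
build_features <- function(trains_a, trains_c, ac_ids, bin_s = 5,
                           min_neurons = 50) {
  stopifnot(inherits(trains_a, "event_train_set"),
            inherits(trains_c, "event_train_set"))
  ac_ids <- as.character(ac_ids)
  bin_one <- function(trains) {
    n_bins <- floor(trains$duration_s / bin_s)
    if (n_bins * bin_s < trains$duration_s - 1e-9) {
      message(sprintf("dropping trailing partial bin (%.1f s)",
                      trains$duration_s - n_bins * bin_s))
    }
    frames_per_bin <- bin_s * trains$fs_hz
    sub <- subset_trains(trains, ac_ids)
    x <- matrix(0, n_bins, length(ac_ids), dimnames = list(NULL, ac_ids))
    for (j in seq_along(ac_ids)) {
      t <- sub$trains[[j]]
      if (length(t)) {
        b <- floor(t / bin_s) + 1
        b <- b[b <= n_bins]
        if (length(b)) {
          tb <- table(b)
          x[as.integer(names(tb)), j] <- as.integer(tb) / frames_per_bin
        }
      }
    }
    x
  }
  xa <- bin_one(trains_a)
  xc <- bin_one(trains_c)
  structure(list(
    x = rbind(xa, xc),
    label = factor(rep(c("A", "C"), c(nrow(xa), nrow(xc)))),
    rows_per_context = c(A = nrow(xa), C = nrow(xc)),
    includable = length(ac_ids) >= min_neurons
  ), class = "feature_matrix")
}

#' Cross-validated context decoding with a linear SVM
#'
#' Stratified k-fold cross-validation of a linear-kernel support vector
#' machine (cost 1). Features are standardized per fold with statistics
#' fitted on the training folds only. Accuracy is reported both as the mean
#' of the fold accuracies and as the pooled-prediction accuracy.
#'
#' @param fm a [build_features()] result.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @param cost SVM regularization constant (default 1).
#' @param blocked when `TRUE`, folds are contiguous temporal blocks within
#'   each context instead of seeded random splits.
#' @return A list of class `decoder_result`: `cv_accuracy` (mean fold
#'   accuracy, %), `pooled_accuracy`, `fold_accuracies`, `k`, `seed`,
#'   `includable`.
#' @export
train_decode_cv <- function(fm, k = 10, seed = 1L, cost = 1, blocked = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  y <- fm$label
  if (nlevels(droplevels(y)) < 2) stop("need both context labels to decode")
  if (min(table(y)) < k) stop("need at least k rows per class")
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    ord <- if (blocked) idx else with_seed(seed, sample(idx))
    fold[ord] <- rep_len(seq_len(k), length(idx))
  }
  correct <- logical(length(y))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    mu <- colMeans(fm$x[tr, , drop = FALSE])
    sc <- pmax(apply(fm$x[tr, , drop = FALSE], 2, sd), 1e-9)
    xtr <- sweep(sweep(fm$x[tr, , drop = FALSE], 2, mu), 2, sc, "/")
    xte <- sweep(sweep(fm$x[te, , drop = FALSE], 2, mu), 2, sc, "/")
    mdl <- e1071::svm(xtr, y[tr], kernel = "linear", cost = cost, scale = FALSE)
    pred <- predict(mdl, xte)
    correct[te] <- pred == y[te]
    fold_acc[f] <- mean(pred == y[te])
  }
  structure(list(cv_accuracy = 100 * mean(fold_acc),
                 pooled_accuracy = 100 * mean(correct),
                 fold_accuracies = 100 * fold_acc, k = k, seed = seed,
                 includable = fm$includable),
            class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf("<decoder_result> %.1f%% CV accuracy (%d folds; pooled %.1f%%)%s\n",
              x$cv_accuracy, x$k, x$pooled_accuracy,
              if (!x$includable) " [below A&C inclusion rule]" else ""))
  invisible(x)
}

#' Permutation null of the decoder accuracy
#'
#' For each shuffle, every neuron's event times are redrawn uniformly over
#' the two concatenated sessions (total calcium events per neuron and the
#' number of neurons maintained), destroying any context-rate difference;
#' the feature matrix is rebuilt and the cross-validated decoder retrained
#' and scored. Over shuffles this gives the chance-level accuracy
#' distribution. Shuffling each session separately would instead fix every
#' neuron's per-context total and force held-out bins to compensate training
#' bins exactly, biasing CV accuracy far below chance.
#'
#' @param trains_a,trains_c,ac_ids,bin_s as in [build_features()].
#' @param n_shuffles number of shuffles (default 1000; fewer than 10 warns).
#' @param seed integer seed.
#' @param k CV folds (default 10).
#' @param true_accuracy optional observed accuracy; when given, its distance
#'   above the null mean in null SDs is reported.
#' @return A list: `accuracies` (%, per shuffle), `null_mean`, `null_sd`,
#'   `z_true` (or `NA`), `n_shuffles`, `seed`.
#' @export
shuffle_null_accuracy <- function(trains_a, trains_c, ac_ids, n_shuffles = 1000,
                                  seed = 1L, bin_s = 5, k = 10,
                                  true_accuracy = NULL) {
  if (n_shuffles < 10) warning("fewer than 10 shuffles; null SD is unstable")
  ac_ids <- as.character(ac_ids)
  sub_a <- subset_trains(trains_a, ac_ids)
  sub_c <- subset_trains(trains_c, ac_ids)
  d_a <- sub_a$duration_s; d_c <- sub_c$duration_s
  totals <- lengths(sub_a$trains) + lengths(sub_c$trains)
  seeds <- derive_seeds(seed, n_shuffles + 1)
  acc <- vapply(seq_len(n_shuffles), function(i) {
    sh <- with_seed(seeds[i], lapply(totals, function(m) sort(runif(m, 0, d_a + d_c))))
    ta <- lapply(sh, function(t) t[t < d_a])
    tc <- lapply(sh, function(t) t[t >= d_a] - d_a)
    sa <- event_train_set(ta, d_a, sub_a$fs_hz, neuron_ids = ac_ids)
    sc_ <- event_train_set(tc, d_c, sub_c$fs_hz, neuron_ids = ac_ids)
    fm <- build_features(sa, sc_, ac_ids, bin_s)
    train_decode_cv(fm, k = k, seed = seeds[n_shuffles + 1])$cv_accuracy
  }, numeric(1))
  mu <- mean(acc); sdv <- sd(acc)
  list(accuracies = acc, null_mean = mu, null_sd = sdv,
       z_true = if (is.null(true_accuracy)) NA_real_ else (true_accuracy - mu) / sdv,
       n_shuffles = n_shuffles, seed = seed)
}

#' Behavioral discrimination ratio
#'
#' Relative difference in freezing between the trained context A and the
#' neutral context C: `(freeze_A - freeze_C) / (freeze_A + freeze_C)`, in
#' `[-1, 1]` (1 = freezing only in A, 0 = equal). The plain difference is
#' available as an alternative.
#'
#' @param freeze_a,freeze_c freezing percentages in `[0, 100]`.
#' @param mode `"ratio"` (default) or `"difference"`.
#' @return The ratio; `NA` (warning) when both freezing values are 0.
#' @export
discrimination_ratio <- function(freeze_a, freeze_c, mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  stopifnot_scalar_num(freeze_a, "freeze_a", 0, 100)
  stopifnot_scalar_num(freeze_c, "freeze_c", 0, 100)
  if (mode == "difference") return(freeze_a - freeze_c)
  if (freeze_a + freeze_c == 0) {
    warning("0/0 discrimination ratio; flagged NA")
    return(NA_real_)
  }
  (freeze_a - freeze_c) / (freeze_a + freeze_c)
}

#' Correlation between decoder accuracy and behavioral discrimination
#'
#' @param accuracies per-mouse-day decoder accuracies (%).
#' @param ratios matching discrimination ratios.
#' @return A list: `r`, `r_squared`, `p`, `n`; `NA` (warning) for constant
#'   input.
#' @export
accuracy_behavior_correlation <- function(accuracies, ratios) {
  stopifnot(length(accuracies) == length(ratios))
  if (length(accuracies) < 3) stop("need at least 3 paired values")
  if (sd(accuracies) == 0 || sd(ratios) == 0) {
    warning("constant input; correlation undefined")
    return(list(r = NA_real_, r_squared = NA_real_, p = NA_real_,
                n = length(accuracies)))
  }
  ct <- stats::cor.test(accuracies, ratios)
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = length(accuracies))
}
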