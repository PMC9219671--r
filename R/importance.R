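#' Per-class feature importances of a discriminant model
#'
#' Expanding the nearest-centroid rule, the score of class \eqn{i} for a
#' spectrum \eqn{x} is linear in \eqn{x} with gradient \eqn{w_i = V \bar
#' z_i} (the class centroid pulled back through the projection), so
#' \eqn{w_i} measures how strongly each wavenumber pushes a spectrum toward
#' class \eqn{i}. Weights are also reported normalized to the global maximum
#' absolute value, so `normalized` lies in \eqn{[-1, 1]} with at least one
#' entry equal to \eqn{\pm 1}.
#'
#' @param model A fitted `sers_lda`.
#' @return Tibble of class `sers_importance` with columns `class`,
#'   `feature` (column index), `wavenumber`, `weight`, `normalized`.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "sers_lda")) {
    rlang::abort("`model` must be a fitted `sers_lda`.")
  }
  W <- model$centroids %*% t(model$V)   # c x p
  norm <- W / max(abs(W))
  out <- tibble::tibble(
    class = rep(model$classes, each = model$p),
    feature = rep(seq_len(model$p), times = length(model$classes)),
    wavenumber = rep(model$wavenumber, times = length(model$classes)),
    weight = as.vector(t(W)),
    normalized = as.vector(t(norm))
  )
  class(out) <- c("sers_importance", class(out))
  attr(out, "p") <- model$p
  out
}

#' Quantile filter on feature importances
#'
#' A feature is retained for a class only if its absolute weight strictly
#' exceeds that class's `q` quantile of absolute weights (linear-interpolation
#' sample quantile) and it is not within `boundary_margin` features of either
#' end of the analysed range (contributions at the range boundaries are
#' screened out as edge artifacts).
#'
#' @param imp A `sers_importance` tibble.
#' @param q Quantile level in (0, 1), default 0.95.
#' @param boundary_margin Number of features excluded at each range edge.
#' @return The tibble with a logical `retained` column added.
#' @export
filter_importance <- function(imp, q = 0.95, boundary_margin = 10) {
  if (q <= 0 || q >= 1) {
    rlang::abort("`q` must be strictly between 0 and 1.")
  }
  p <- attr(imp, "p")
  out <- imp |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(
      retained = abs(.data$weight) >
        stats::quantile(abs(.data$weight), q, type = 7) &
        .data$feature > boundary_margin &
        .data$feature <= p - boundary_margin
    ) |>
    dplyr::ungroup()
  class(out) <- c("sers_importance", class(tibble::tibble()))
  attr(out, "p") <- p
  out
}

#' Rank features by importance
#'
#' Features are ranked by their maximum absolute normalized weight over
#' classes, in descending order; ties are broken toward the lower
#' wavenumber.
#'
#' @param imp A `sers_importance` tibble.
#' @return Tibble with `feature`, `wavenumber`, `score`, `rank`.
#' @export
rank_features <- function(imp) {
  out <- imp |>
    dplyr::group_by(.data$feature, .data$wavenumber) |>
    dplyr::summarise(score = max(abs(.data$normalized)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$wavenumber)
  out$rank <- seq_len(nrow(out))
  out
}

#' Accuracy as a function of the number of top-ranked features
#'
#' For each `k`, the full split / augment / fit / nearest-centroid chain is
#' refit on the top-`k` features over `n_repeats` seeded random splits, and
#' the mean and SD of the test accuracy are recorded. Iteration stops early
#' once the mean accuracy has been at least 0.999 for 5 consecutive values
#' of `k`.
#'
#' @param df Preprocessed long spectra tibble.
#' @param imp A `sers_importance` tibble computed from a model trained on a
#'   split of `df`.
#' @param n_repeats Random splits per `k` (default 20).
#' @param k_max Largest number of features tried (default 100).
#' @param seed Integer seed.
#' @param ratio Training fraction of each split.
#' @param sigma_rel,copies Gaussian augmentation parameters.
#' @param shrinkage Ridge coefficient for each refit.
#' @return Tibble of class `sers_accuracy_curve` with `k`, `mean_accuracy`,
#'   `sd_accuracy`; attribute `k_perfect` is the smallest `k` whose mean
#'   accuracy reaches 1 (NA if never).
#' @export
accuracy_curve <- function(df, imp, n_repeats = 20, k_max = 100, seed = 1,
                           ratio = 0.5, sigma_rel = 0.05, copies = 2,
                           shrinkage = 1e-3) {
  w <- spectra_wide(df)
  p <- ncol(w$X)
  if (k_max > p) {
    rlang::abort("`k_max` cannot exceed the number of features.")
  }
  ranking <- rank_features(imp)
  order_idx <- ranking$feature
  labels <- unname(w$labels)
  classes <- sort(unique(labels))
  split_seeds <- withr::with_seed(seed, sample.int(2147483646L, n_repeats))
  class_idx <- split(seq_along(labels), labels)
  ks <- integer(0)
  means <- sds <- numeric(0)
  streak <- 0L
  for (k in seq_len(k_max)) {
    cols <- order_idx[seq_len(k)]
    Xk <- w$X[, cols, drop = FALSE]
    acc <- vapply(seq_len(n_repeats), function(r) {
      train_idx <- withr::with_seed(split_seeds[r], {
        unlist(lapply(class_idx, function(ix) {
          sample(ix, floor(length(ix) * ratio))
        }), use.names = FALSE)
      })
      test_idx <- setdiff(seq_along(labels), train_idx)
      aug <- augment_core(Xk[train_idx, , drop = FALSE], labels[train_idx],
                          sigma_rel, copies, seed = split_seeds[r])
      fit <- lda_core(aug$X, aug$labels,
                      n_components = min(2, k, length(classes) - 1),
                      shrinkage = shrinkage)
      Z <- project_core(fit, Xk[test_idx, , drop = FALSE])
      pred <- classify_core(Z, fit$centroids, fit$classes)
      mean(pred == labels[test_idx])
    }, numeric(1))
    ks <- c(ks, k)
    means <- c(means, mean(acc))
    sds <- c(sds, stats::sd(acc))
    streak <- if (mean(acc) >= 0.999) streak + 1L else 0L
    if (streak >= 5L) break
  }
  out <- tibble::tibble(k = ks, mean_accuracy = means, sd_accuracy = sds)
  class(out) <- c("sers_accuracy_curve", class(out))
  attr(out, "n_repeats") <- n_repeats
  perfect <- which(means >= 1 - 1e-12)
  attr(out, "k_perfect") <- if (length(perfect)) ks[min(perfect)] else NA_integer_
  out
}

#' @rdname accuracy_curve
#' @param x A `sers_accuracy_curve`.
#' @export
k_perfect <- function(x) {
  attr(x, "k_perfect")
}

#' Group top-ranked features into spectral intervals
#'
#' The top `k` features (by [rank_features()] order) are attributed to the
#' class with the largest absolute weight at that feature, then merged, per
#' class, into maximal runs in which consecutive selected features are at
#' most `gap_tol` grid steps apart. Interval bounds are reported in
#' cm\eqn{^{-1}} with the peak normalized importance inside each interval.
#'
#' @param imp A `sers_importance` tibble.
#' @param k Number of top-ranked features to group (default 25).
#' @param gap_tol Largest grid-step gap merged into one interval.
#' @return Tibble with `class`, `lo`, `hi`, `n_features`, `peak_importance`.
#' @export
group_intervals <- function(imp, k = 25, gap_tol = 2) {
  p <- attr(imp, "p")
  if (k > p) {
    rlang::abort("`k` cannot exceed the number of features.")
  }
  if (k == 0) {
    return(tibble::tibble(class = character(0), lo = numeric(0),
                          hi = numeric(0), n_features = integer(0),
                          peak_importance = numeric(0)))
  }
  top <- rank_features(imp)$feature[seq_len(k)]
  sub <- dplyr::filter(imp, .data$feature %in% top)
  attributed <- sub |>
    dplyr::group_by(.data$feature, .data$wavenumber) |>
    dplyr::slice_max(abs(.data$weight), n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  attributed |>
    dplyr::group_by(.data$class) |>
    dplyr::arrange(.data$feature, .by_group = TRUE) |>
    dplyr::mutate(run = cumsum(c(1, diff(.data$feature) > gap_tol))) |>
    dplyr::group_by(.data$class, .data$run) |>
    dplyr::summarise(
      lo = min(.data$wavenumber), hi = max(.data$wavenumber),
      n_features = dplyr::n(),
      peak_importance = max(abs(.data$normalized)),
      .groups = "drop"
    ) |>
    dplyr::select(-"run")
}
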