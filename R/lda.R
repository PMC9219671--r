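#' Stratified train/test split
#'
#' Randomly partitions the spectra of every class into training and test
#' subsets (default ratio 50:50), deterministically under `seed`.
#'
#' @param df Long spectra tibble; every class needs at least 2 spectra.
#' @param ratio Training fraction, strictly between 0 and 1.
#' @param seed Integer seed.
#' @return List with elements `train` and `test` (long spectra tibbles).
#' @export
split_spectra <- function(df, ratio = 0.5, seed = 1) {
  check_spectra_df(df)
  if (ratio <= 0 || ratio >= 1) {
    rlang::abort("`ratio` must be strictly between 0 and 1.")
  }
  info <- dplyr::distinct(df, .data$spectrum_id, .data$label)
  sizes <- table(info$label)
  if (any(sizes < 2)) {
    rlang::abort("every class needs at least 2 spectra to split.")
  }
  train_ids <- withr::with_seed(seed, {
    unlist(lapply(split(info$spectrum_id, info$label), function(ids) {
      n_train <- floor(length(ids) * ratio)
      if (n_train < 1 || n_train >= length(ids)) {
        rlang::abort("`ratio` leaves an empty training or test set.")
      }
      sample(ids, n_train)
    }), use.names = FALSE)
  })
  list(
    train = dplyr::filter(df, .data$spectrum_id %in% train_ids),
    test = dplyr::filter(df, !(.data$spectrum_id %in% train_ids))
  )
}

# Matrix-level augmentation core shared with accuracy_curve().
augment_core <- function(X, labels, sigma_rel, copies, seed) {
  if (copies == 0) {
    return(list(X = X, labels = labels))
  }
  feat_sd <- apply(X, 2, stats::sd)
  n <- nrow(X)
  p <- ncol(X)
  blocks <- withr::with_seed(seed, {
    lapply(seq_len(copies), function(j) {
      noise <- matrix(stats::rnorm(n * p), n, p) *
        rep(sigma_rel * feat_sd, each = n)
      Xa <- X + noise
      rownames(Xa) <- paste0(rownames(X), "_aug", j)
      Xa
    })
  })
  Xout <- do.call(rbind, c(list(X), blocks))
  list(X = Xout, labels = rep(labels, copies + 1))
}

#' Augment training spectra with Gaussian noise
#'
#' Each of `copies` augmented replicates adds zero-mean Gaussian noise with
#' per-wavenumber SD equal to `sigma_rel` times the training set's
#' per-wavenumber SD. Labels are replicated with the rows.
#'
#' @param df Long spectra tibble (the training part).
#' @param sigma_rel Relative noise level (default 0.05).
#' @param copies Number of noisy replicates per spectrum (default 2).
#' @param seed Integer seed.
#' @return Augmented spectra tibble with `nrow * (1 + copies)` spectra.
#' @export
augment_spectra <- function(df, sigma_rel = 0.05, copies = 2, seed = 1) {
  check_spectra_df(df)
  stopifnot(sigma_rel >= 0, copies >= 0)
  if (copies == 0) {
    return(df)
  }
  w <- spectra_wide(df)
  aug <- augment_core(w$X, w$labels, sigma_rel, copies, seed)
  spectra_long(aug$X, w$wavenumber, aug$labels)
}

# Scatter matrices from a samples x features matrix and labels.
scatter_core <- function(X, labels, weighted = FALSE) {
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    rlang::abort("scatter matrices need at least 2 classes.")
  }
  p <- ncol(X)
  grand_mean <- colMeans(X)
  class_means <- t(matrix(
    vapply(classes, function(cl) {
      colMeans(X[labels == cl, , drop = FALSE])
    }, numeric(p)),
    nrow = p, dimnames = list(NULL, classes)
  ))
  S_W <- matrix(0, p, p)
  for (cl in classes) {
    Xi <- X[labels == cl, , drop = FALSE]
    C <- sweep(Xi, 2, class_means[cl, ])
    S_W <- S_W + crossprod(C)
  }
  sizes <- as.vector(table(factor(labels, levels = classes)))
  names(sizes) <- classes
  D <- sweep(class_means, 2, grand_mean)
  S_B <- if (weighted) crossprod(D * sqrt(sizes)) else crossprod(D)
  S_W <- (S_W + t(S_W)) / 2
  S_B <- (S_B + t(S_B)) / 2
  list(S_W = S_W, S_B = S_B, class_means = class_means,
       grand_mean = grand_mean, class_sizes = sizes, classes = classes)
}

#' Within- and between-class scatter matrices
#'
#' Computes the within-class scatter \eqn{S_W = \sum_i \sum_{x \in D_i}
#' (x - \bar x_i)(x - \bar x_i)^T} and the between-class scatter
#' \eqn{S_B = \sum_i (\bar x_i - \bar X)(\bar x_i - \bar X)^T} (unweighted by
#' default; set `weighted = TRUE` to weight each class term by its size).
#'
#' @param df Long spectra tibble with at least 2 classes.
#' @param weighted Weight the between-class terms by class size?
#' @return List with `S_W`, `S_B`, `class_means`, `grand_mean`,
#'   `class_sizes`, `classes` and `wavenumber`.
#' @export
scatter_matrices <- function(df, weighted = FALSE) {
  w <- spectra_wide(df)
  out <- scatter_core(w$X, unname(w$labels), weighted = weighted)
  out$wavenumber <- w$wavenumber
  out
}

# Discriminant subspace from scatter matrices, solved as a symmetric
# generalized eigenproblem on the shrunken within-class scatter.
lda_core <- function(X, labels, n_components = 2, shrinkage = 1e-3,
                     weighted = FALSE) {
  sc <- scatter_core(X, labels, weighted = weighted)
  c_n <- length(sc$classes)
  p <- ncol(X)
  if (n_components > c_n - 1) {
    rlang::abort("`n_components` cannot exceed (number of classes - 1).")
  }
  S <- sc$S_W
  if (shrinkage > 0) {
    gamma_scale <- sum(diag(S)) / p
    if (gamma_scale == 0) gamma_scale <- 1
    diag(S) <- diag(S) + shrinkage * gamma_scale
  }
  R <- tryCatch(chol(S), error = function(e) {
    rlang::abort(paste0(
      "within-class scatter is singular (p > n or collinear features); ",
      "set `shrinkage` > 0."
    ))
  })
  # M = R^{-T} S_B R^{-1} is symmetric with the same spectrum as S^{-1} S_B.
  W1 <- backsolve(R, sc$S_B, transpose = TRUE)
  M <- backsolve(R, t(W1), transpose = TRUE)
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  keep <- seq_len(n_components)
  V <- backsolve(R, eig$vectors[, keep, drop = FALSE])
  # Unit-norm columns, sign fixed so the largest-magnitude entry is positive.
  for (j in seq_len(ncol(V))) {
    V[, j] <- V[, j] / sqrt(sum(V[, j]^2))
    imax <- which.max(abs(V[, j]))
    if (V[imax, j] < 0) V[, j] <- -V[, j]
  }
  centroids <- sweep(sc$class_means, 2, sc$grand_mean) %*% V
  colnames(centroids) <- paste0("LD", keep)
  list(
    V = V, eigenvalues = eig$values[keep], shrinkage = shrinkage,
    centroids = centroids, class_means = sc$class_means,
    grand_mean = sc$grand_mean, class_sizes = sc$class_sizes,
    classes = sc$classes, n = nrow(X), p = p
  )
}

#' Fit a linear discriminant model from scatter matrices
#'
#' Builds \eqn{S_W} and \eqn{S_B} from the (preprocessed) spectra, shrinks
#' the within-class scatter by a ridge term \eqn{\gamma \,
#' \mathrm{tr}(S_W)/p \, I} (required when the number of spectral features
#' exceeds the number of training spectra, as is typical here), and extracts
#' the leading eigenvectors of \eqn{S_W^{-1} S_B} as a symmetric generalized
#' eigenproblem. Scores are computed as \eqn{Z = (X - \bar X) V}, i.e. the
#' projection is anchored at the training grand mean so the class clouds are
#' centred at the origin of the discriminant plane.
#'
#' @param df Long spectra tibble (training set) with at least 2 classes.
#' @param n_components Number of discriminant components (default 2; at most
#'   number of classes minus 1).
#' @param shrinkage Ridge coefficient \eqn{\gamma \ge 0} (default `1e-3`).
#' @param weighted Weight the between-class scatter by class sizes?
#' @return An object of class `sers_lda` with elements `V` (p x k
#'   eigenvector matrix, unit-norm columns, eigenvalues descending),
#'   `eigenvalues`, `centroids` (class means in discriminant space),
#'   `grand_mean`, `classes`, `wavenumber`, `n`, `p`.
#' @examples
#' d <- generate_spectra(n_per_class = c(6, 6, 6), seed = 1)
#' m <- preprocess_spectra(d)
#' fit <- fit_sers_lda(m)
#' glance(fit)
#' @export
fit_sers_lda <- function(df, n_components = 2, shrinkage = 1e-3,
                         weighted = FALSE) {
  w <- spectra_wide(df)
  fit <- lda_core(w$X, unname(w$labels), n_components = n_components,
                  shrinkage = shrinkage, weighted = weighted)
  fit$wavenumber <- w$wavenumber
  rownames(fit$V) <- NULL
  structure(fit, class = "sers_lda")
}

#' @export
print.sers_lda <- function(x, ...) {
  cat("<sers_lda> ", length(x$classes), " classes, ", x$p, " features, ",
      ncol(x$V), " components\n", sep = "")
  cat("eigenvalues:", signif(x$eigenvalues, 4), "\n")
  cat("shrinkage gamma:", x$shrinkage, "\n")
  invisible(x)
}

# Scores for a matrix of spectra.
project_core <- function(model, X) {
  Z <- sweep(X, 2, model$grand_mean) %*% model$V
  colnames(Z) <- paste0("LD", seq_len(ncol(Z)))
  Z
}

# Nearest-centroid labels; ties go to the lexicographically smallest class
# (model$classes is sorted, so the first minimum wins).
classify_core <- function(Z, centroids, classes) {
  d2 <- outer(rowSums(Z^2), rowSums(centroids^2), `+`) -
    2 * Z %*% t(centroids)
  classes[apply(d2, 1, which.min)]
}

#' Project spectra onto the discriminant plane
#'
#' @param model A fitted `sers_lda`.
#' @param df Long spectra tibble on the same wavenumber axis as the training
#'   data.
#' @return Tibble with `spectrum_id`, `label` and one column per
#'   discriminant coordinate (`LD1`, `LD2`, ...).
#' @export
project_lda <- function(model, df) {
  stopifnot(inherits(model, "sers_lda"))
  w <- spectra_wide(df)
  if (ncol(w$X) != model$p) {
    rlang::abort("feature count does not match the fitted model.")
  }
  Z <- project_core(model, w$X)
  dplyr::bind_cols(
    tibble::tibble(spectrum_id = w$ids, label = unname(w$labels)),
    tibble::as_tibble(Z)
  )
}

#' Predict classes or discriminant scores
#'
#' Classification assigns each spectrum to the class whose discriminant-space
#' centroid is nearest (Euclidean distance, equal priors); ties are broken
#' toward the lexicographically smallest class name.
#'
#' @param object A fitted `sers_lda`.
#' @param newdata Long spectra tibble.
#' @param type `"class"` for predicted labels, `"scores"` for discriminant
#'   coordinates.
#' @param ... Unused.
#' @return A tibble: `spectrum_id`, `label`, and `pred` (for `"class"`) or
#'   `LD*` columns (for `"scores"`).
#' @export
predict.sers_lda <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  scores <- project_lda(object, newdata)
  if (type == "scores") {
    return(scores)
  }
  Z <- as.matrix(scores[, grep("^LD", names(scores)), drop = FALSE])
  scores$pred <- classify_core(Z, object$centroids, object$classes)
  scores[, c("spectrum_id", "label", "pred")]
}

#' Per-class classification metrics
#'
#' Computes, for every class, precision = TP/(TP+FP), sensitivity =
#' TP/(TP+FN) and their harmonic mean (F score), together with the class
#' support, plus the overall accuracy and the confusion matrix as
#' attributes. A class present among predictions but absent from the truth
#' gets `NA` metrics with a warning rather than a silent zero.
#'
#' @param truth True class labels.
#' @param pred Predicted class labels (same length).
#' @return Tibble with columns `class`, `precision`, `sensitivity`,
#'   `f_score`, `support`; attributes `accuracy` and `confusion`.
#' @export
classification_metrics <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    rlang::abort("`truth` and `pred` must have the same length.")
  }
  classes <- sort(union(truth, pred))
  cm <- table(factor(truth, classes), factor(pred, classes))
  res <- lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    support <- sum(cm[cl, ])
    if (support == 0) {
      rlang::warn(paste0("class '", cl, "' absent from `truth`; metrics NA."))
      return(tibble::tibble(class = cl, precision = NA_real_,
                            sensitivity = NA_real_, f_score = NA_real_,
                            support = 0L))
    }
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    sensitivity <- tp / (tp + fn)
    f <- if (!is.na(precision) && precision + sensitivity > 0) {
      2 * precision * sensitivity / (precision + sensitivity)
    } else {
      NA_real_
    }
    tibble::tibble(class = cl, precision = precision,
                   sensitivity = sensitivity, f_score = f,
                   support = as.integer(support))
  })
  out <- dplyr::bind_rows(res)
  attr(out, "accuracy") <- sum(diag(cm)) / length(truth)
  attr(out, "confusion") <- cm
  out
}

#' @rdname classification_metrics
#' @param x A tibble returned by [classification_metrics()].
#' @export
accuracy <- function(x) {
  attr(x, "accuracy")
}
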