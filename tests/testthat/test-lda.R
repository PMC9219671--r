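test_that("stratified split is exact, deterministic and validated", {
  d <- tiny_dataset(n_per_class = c(10, 10, 10))
  parts <- split_spectra(d, ratio = 0.5, seed = 3)
  tr <- dplyr::distinct(parts$train, spectrum_id, label)
  te <- dplyr::distinct(parts$test, spectrum_id, label)
  expect_equal(unname(table(tr$label)), rep(5L, 3), ignore_attr = TRUE)
  expect_equal(unname(table(te$label)), rep(5L, 3), ignore_attr = TRUE)
  expect_length(intersect(tr$spectrum_id, te$spectrum_id), 0)
  expect_setequal(c(tr$spectrum_id, te$spectrum_id), unique(d$spectrum_id))

  parts2 <- split_spectra(d, ratio = 0.5, seed = 3)
  expect_identical(parts, parts2)

  expect_error(split_spectra(d, ratio = 1.0, seed = 1), "between 0 and 1")
  single <- dplyr::filter(d, !(spectrum_id %in% sprintf("a_%03d", 2:10)))
  expect_error(split_spectra(single, seed = 1), "at least 2")
})

test_that("Gaussian augmentation stacks the declared number of copies", {
  d <- tiny_dataset(n_per_class = c(2, 2, 2))
  expect_identical(augment_spectra(d, copies = 0, seed = 1), d)

  noiseless <- augment_spectra(d, sigma_rel = 0, copies = 2, seed = 1)
  expect_equal(length(unique(noiseless$spectrum_id)), 18)  # 6 x (1 + 2)
  w0 <- serslda:::spectra_wide(d)
  w <- serslda:::spectra_wide(noiseless)
  expect_equal(w$X[7:12, ], w0$X, ignore_attr = TRUE)
  expect_equal(w$X[13:18, ], w0$X, ignore_attr = TRUE)
  expect_equal(unname(w$labels), rep(unname(w0$labels), 3))

  aug <- augment_spectra(d, sigma_rel = 0.05, copies = 2, seed = 2)
  expect_equal(length(unique(aug$spectrum_id)), 18)
  expect_gt(max(abs(serslda:::spectra_wide(aug)$X[7:12, ] - w0$X)), 0)
})

test_that("scatter matrices match the direct-summation oracle on a 2-D toy", {
  X <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  d <- toy_spectra(X, c("c1", "c1", "c2", "c2"))
  sc <- scatter_matrices(d)
  expect_equal(sc$S_W, matrix(c(4, 0, 0, 0), 2), ignore_attr = TRUE)
  expect_equal(sc$S_B, matrix(c(0, 0, 0, 2), 2), ignore_attr = TRUE)
  expect_equal(unname(sc$class_sizes), c(2L, 2L))

  # translation invariance
  sc2 <- scatter_matrices(toy_spectra(sweep(X, 2, c(-3, 11), `+`),
                                      c("c1", "c1", "c2", "c2")))
  expect_equal(sc2$S_W, sc$S_W)
  expect_equal(sc2$S_B, sc$S_B)

  # one point per class: no within-class dispersion
  sc3 <- scatter_matrices(toy_spectra(X[c(1, 3), ], c("c1", "c2")))
  expect_equal(sc3$S_W, matrix(0, 2, 2), ignore_attr = TRUE)

  expect_error(scatter_matrices(toy_spectra(X, rep("c1", 4))), "2 classes")
})

test_that("weighted between-class scatter applies class sizes", {
  X <- rbind(c(0, 0), c(2, 0), c(4, 0), c(0, 2))
  labs <- c("c1", "c1", "c1", "c2")
  sc_u <- scatter_matrices(toy_spectra(X, labs))
  sc_w <- scatter_matrices(toy_spectra(X, labs), weighted = TRUE)
  gm <- colMeans(X)
  m1 <- colMeans(X[1:3, , drop = FALSE])
  m2 <- X[4, ]
  expect_equal(sc_u$S_B, outer(m1 - gm, m1 - gm) + outer(m2 - gm, m2 - gm),
               ignore_attr = TRUE)
  expect_equal(sc_w$S_B,
               3 * outer(m1 - gm, m1 - gm) + 1 * outer(m2 - gm, m2 - gm),
               ignore_attr = TRUE)
})

test_that("two-class discriminant matches the Fisher closed form", {
  X <- withr::with_seed(5, matrix(stats::rnorm(60 * 4), 60, 4))
  X[31:60, 1] <- X[31:60, 1] + 2
  labs <- rep(c("g1", "g2"), each = 30)
  fit <- fit_sers_lda(toy_spectra(X, labs), n_components = 1, shrinkage = 0)
  sc <- scatter_matrices(toy_spectra(X, labs))
  fisher <- solve(sc$S_W, sc$class_means["g1", ] - sc$class_means["g2", ])
  expect_lt(principal_angle(fit$V, cbind(fisher)), 1e-8)
})

test_that("the discriminant plane matches a dense eigensolver on small instances", {
  for (s in 1:20) {
    n <- 30 + (s %% 4) * 10
    p <- 4 + (s %% 7)
    X <- withr::with_seed(s, matrix(stats::rnorm(n * p), n, p))
    labs <- rep(c("a", "b", "c"), length.out = n)
    shift <- withr::with_seed(1000 + s, matrix(stats::rnorm(3 * p), 3, p))
    X <- X + shift[match(labs, c("a", "b", "c")), ]
    fit <- fit_sers_lda(toy_spectra(X, labs), n_components = 2, shrinkage = 0)
    expect_lt(principal_angle(fit$V, oracle_lda_subspace(X, labs)), 1e-6)
    expect_gte(fit$eigenvalues[1], fit$eigenvalues[2])
  }
})

test_that("fitting validates components and singularity", {
  d <- tiny_dataset(n_per_class = c(4, 4, 4))
  expect_error(fit_sers_lda(d, n_components = 3), "classes - 1")

  X <- withr::with_seed(2, matrix(stats::rnorm(6 * 10), 6, 10))  # p > n
  toy <- toy_spectra(X, rep(c("a", "b", "c"), each = 2))
  expect_error(fit_sers_lda(toy, shrinkage = 0), "shrinkage")
  expect_s3_class(fit_sers_lda(toy, shrinkage = 1e-3), "sers_lda")
})

test_that("projection is centred on the training grand mean", {
  X <- withr::with_seed(3, matrix(stats::rnorm(30 * 5), 30, 5))
  labs <- rep(c("a", "b", "c"), each = 10)
  X <- X + 2 * (match(labs, c("a", "b", "c")) %o% rep(1, 5))
  d <- toy_spectra(X, labs)
  fit <- fit_sers_lda(d, shrinkage = 0)

  # projecting the class means reproduces the stored centroids
  means <- toy_spectra(fit$class_means, fit$classes)
  Z <- project_lda(fit, means)
  expect_equal(as.matrix(Z[, c("LD1", "LD2")]), unname(fit$centroids),
               ignore_attr = TRUE, tolerance = 1e-10)

  # a row at the grand mean projects to the origin
  gm <- toy_spectra(matrix(fit$grand_mean, 1), "a")
  Zg <- project_lda(fit, gm)
  expect_equal(unlist(Zg[, c("LD1", "LD2")]), c(LD1 = 0, LD2 = 0),
               tolerance = 1e-12)

  # toy hand product
  Zall <- project_lda(fit, d)
  expect_equal(as.matrix(Zall[, c("LD1", "LD2")]),
               sweep(X, 2, fit$grand_mean) %*% fit$V, ignore_attr = TRUE)

  expect_error(project_lda(fit, toy_spectra(X[, 1:3], labs)), "feature count")
})

test_that("nearest-centroid classification matches a brute-force distance oracle", {
  fit <- structure(list(
    V = diag(2), centroids = rbind(a = c(0, 0), b = c(4, 0), c = c(0, 4)),
    classes = c("a", "b", "c"), grand_mean = c(0, 0), p = 2,
    wavenumber = 1:2
  ), class = "sers_lda")
  colnames(fit$centroids) <- c("LD1", "LD2")

  Z <- withr::with_seed(9, matrix(stats::rnorm(200 * 2, sd = 3), 200, 2))
  pred <- serslda:::classify_core(Z, fit$centroids, fit$classes)
  oracle <- apply(Z, 1, function(z) {
    d <- sqrt(colSums((t(fit$centroids) - z)^2))
    fit$classes[which.min(d)]
  })
  expect_identical(pred, oracle)

  # exact centroid and equidistant tie
  at <- serslda:::classify_core(rbind(c(4, 0)), fit$centroids, fit$classes)
  expect_identical(at, "b")
  tie <- serslda:::classify_core(rbind(c(2, 0)), fit$centroids, fit$classes)
  expect_identical(tie, "a")  # lexicographically smallest wins
})

test_that("classification metrics implement the standard definitions", {
  # TP = 3, FP = 1, FN = 1 for class x
  truth <- c("x", "x", "x", "x", "y", "y", "y")
  pred <- c("x", "x", "x", "y", "x", "y", "y")
  m <- classification_metrics(truth, pred)
  mx <- dplyr::filter(m, class == "x")
  expect_equal(mx$precision, 0.75)
  expect_equal(mx$sensitivity, 0.75)
  expect_equal(mx$f_score, 0.75)
  expect_equal(accuracy(m), 5 / 7)

  # perfect prediction of 33 test spectra of one class
  truth2 <- c(rep("lung", 33), rep("heart", 20))
  m2 <- classification_metrics(truth2, truth2)
  lung <- dplyr::filter(m2, class == "lung")
  expect_equal(unlist(lung[, c("precision", "sensitivity", "f_score")]),
               c(precision = 1, sensitivity = 1, f_score = 1))
  expect_equal(lung$support, 33L)

  allwrong <- classification_metrics(c("a", "b"), c("b", "a"))
  expect_equal(accuracy(allwrong), 0)

  expect_warning(classification_metrics(c("a", "a"), c("a", "b")),
                 "absent from")
  expect_error(classification_metrics("a", c("a", "b")), "same length")
})

test_that("tidy and glance summarise the fitted model", {
  d <- tiny_dataset(n_per_class = c(5, 5, 5))
  m <- preprocess_spectra(d, lo = 450, hi = 1350)
  fit <- fit_sers_lda(m)
  td <- tidy(fit)
  expect_named(td, c("feature", "wavenumber", "LD1", "LD2"))
  expect_equal(nrow(td), fit$p)
  gl <- glance(fit)
  expect_equal(gl$n_classes, 3)
  expect_gte(gl$lambda1, gl$lambda2)
  expect_true(all(abs(colSums(fit$V^2) - 1) < 1e-9))
})

test_that("test accuracy is non-decreasing in the exclusive-band amplitude", {
  amps <- c(0, 0.05, 0.1, 0.2, 0.3)
  mean_acc <- vapply(amps, function(a) {
    accs <- vapply(1:10, function(s) {
      d <- tiny_dataset(n_per_class = c(8, 8, 8), seed = 50 + s,
                        exclusive_amplitude = a, noise_sd = 0.05)
      m <- preprocess_spectra(d, lo = 450, hi = 1350)
      parts <- split_spectra(m, seed = s)
      fit <- fit_sers_lda(augment_spectra(parts$train, seed = s))
      pred <- predict(fit, parts$test)
      mean(pred$pred == pred$label)
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  # allow sampling noise of one misclassified spectrum per 12-sample test set
  expect_true(all(diff(mean_acc) >= -1 / 12))
  expect_gt(mean_acc[5], mean_acc[1])
})
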