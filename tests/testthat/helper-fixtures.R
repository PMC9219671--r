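# Shared fixtures and independent oracles.

# Small fast generator configuration: 3 classes on a short axis, three shared
# bands and one exclusive band per class.
tiny_profiles <- function(exclusive_amplitude = 0.3, noise_sd = 0.02,
                          jitter_center = 0.5, jitter_amplitude = 0.05) {
  shared <- band_spec(c(500, 800, 1100), c(1, 0.6, 0.8), width = 10,
                      jitter_center = jitter_center,
                      jitter_amplitude = jitter_amplitude)
  excl <- list(a = 650, b = 950, c = 1250)
  profiles <- lapply(names(excl), function(cl) {
    class_profile(
      cl,
      dplyr::bind_rows(
        shared,
        band_spec(excl[[cl]], exclusive_amplitude, width = 8,
                  jitter_center = jitter_center,
                  jitter_amplitude = jitter_amplitude)
      ),
      noise_sd = noise_sd
    )
  })
  names(profiles) <- names(excl)
  profiles
}

tiny_axis <- function(n = 300) wavenumber_axis(400, 1400, n)

tiny_dataset <- function(n_per_class = c(10, 10, 10), seed = 1, ...) {
  generate_spectra(tiny_profiles(...), n_per_class = n_per_class,
                   axis = tiny_axis(), seed = seed)
}

# Long spectra tibble from a plain matrix (rows = samples), for toy LDA
# problems whose coordinates are chosen by hand.
toy_spectra <- function(X, labels, wavenumber = seq_len(ncol(X))) {
  ids <- sprintf("s%03d", seq_len(nrow(X)))
  tibble::tibble(
    spectrum_id = rep(ids, each = ncol(X)),
    label = rep(labels, each = ncol(X)),
    wavenumber = rep(wavenumber, times = nrow(X)),
    intensity = as.vector(t(X))
  )
}

# Exhaustive lower-convex-hull baseline: the pointwise maximum, over all
# point pairs whose connecting segment stays below every point, of that
# segment. O(n^3); independent of the monotone-chain implementation.
oracle_rubberband <- function(x, y) {
  n <- length(x)
  base <- rep(-Inf, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      line <- y[i] + (y[j] - y[i]) / (x[j] - x[i]) * (x - x[i])
      if (all(y - line >= -1e-9 * max(1, max(abs(y))))) {
        seg <- which(x >= x[i] & x <= x[j])
        base[seg] <- pmax(base[seg], line[seg])
      }
    }
  }
  base
}

# Dense-eigensolver discriminant oracle (no shrinkage; S_W must be
# invertible): eigenvectors of S_W^{-1} S_B.
oracle_lda_subspace <- function(X, labels, n_components = 2) {
  sc <- serslda:::scatter_core(X, labels)
  e <- eigen(solve(sc$S_W) %*% sc$S_B)
  Re(e$vectors[, seq_len(n_components), drop = FALSE])
}

# Largest principal angle (radians) between the column spaces of A and B.
principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(s))))
}

# One full default-scale classification run; returns the metrics tibble.
default_run_metrics <- function(seed) {
  run <- run_sers_pipeline(seed = seed, compute_curve = FALSE)
  run$metrics
}
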