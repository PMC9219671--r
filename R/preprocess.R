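#' Restrict spectra to a Raman-shift range
#'
#' Keeps exactly the grid points with `lo <= wavenumber <= hi` (default
#' 300--1800 cm\eqn{^{-1}}, the window that carries the protein vibrational
#' bands).
#'
#' @param df Long spectra tibble.
#' @param lo,hi Range limits in cm\eqn{^{-1}}.
#' @return The truncated spectra tibble.
#' @export
select_range <- function(df, lo = 300, hi = 1800) {
  check_spectra_df(df)
  if (lo >= hi) {
    rlang::abort("`lo` must be smaller than `hi`.")
  }
  eps <- 1e-8 * (hi - lo)
  out <- dplyr::filter(df, .data$wavenumber >= lo - eps,
                       .data$wavenumber <= hi + eps)
  if (nrow(out) == 0) {
    rlang::abort("no grid points fall inside the selected range.")
  }
  out
}

# Indices of the lower convex hull of (x, y); x strictly increasing.
# Andrew's monotone chain, lower chain only.
lower_hull <- function(x, y) {
  n <- length(x)
  hull <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    while (m >= 2L) {
      a <- hull[m - 1L]
      b <- hull[m]
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross <= 0) m <- m - 1L else break
    }
    m <- m + 1L
    hull[m] <- i
  }
  hull[seq_len(m)]
}

rubberband_one <- function(x, y) {
  if (any(!is.finite(y))) {
    rlang::abort("non-finite intensities; cannot fit a rubber-band baseline.")
  }
  if (length(x) < 3) {
    rlang::abort("rubber-band correction needs at least 3 points.")
  }
  h <- lower_hull(x, y)
  baseline <- stats::approx(x[h], y[h], xout = x)$y
  corrected <- y - baseline
  tol <- sqrt(.Machine$double.eps) * max(1, max(abs(y)))
  corrected[corrected < 0 & corrected > -tol] <- 0
  list(baseline = baseline, corrected = corrected)
}

#' Rubber-band baseline correction
#'
#' Estimates each spectrum's background as the lower convex hull of its
#' (wavenumber, intensity) points, linearly interpolated between hull
#' vertices, and subtracts it. The corrected spectrum is non-negative with
#' zeros at the hull vertices; the first and last points are always vertices.
#'
#' @param df Long spectra tibble.
#' @param keep_baseline If `TRUE`, keep the estimated background in a
#'   `baseline` column.
#' @return Tibble with the corrected `intensity` (and optionally `baseline`).
#' @export
correct_baseline <- function(df, keep_baseline = FALSE) {
  check_spectra_df(df)
  out <- df |>
    dplyr::group_by(.data$spectrum_id) |>
    dplyr::group_modify(function(d, key) {
      rb <- rubberband_one(d$wavenumber, d$intensity)
      d$intensity <- rb$corrected
      if (keep_baseline) d$baseline <- rb$baseline
      d
    }) |>
    dplyr::ungroup()
  out[, union(.spectra_cols, names(out))]
}

#' Eliminate whole spectra contaminated by cosmic-ray spikes
#'
#' At every wavenumber the median and the median absolute deviation (MAD)
#' across spectra are computed; a spectrum is dropped entirely if any of its
#' points exceeds `median + threshold * 1.4826 * MAD` at that wavenumber.
#' This targets single-channel artifacts whose signal-to-noise ratio far
#' exceeds that of the true bands at the same frequency.
#'
#' When spectra have been rubber-band corrected, the correction pins the
#' first and last points of the range to zero, so the cross-spectrum
#' dispersion of the outermost channels is degenerate and the robust
#' threshold there is meaninglessly tight; `edge_margin` channels at each
#' end are therefore excluded from the exceedance test (spikes in the
#' interior are unaffected).
#'
#' @param df Long spectra tibble (at least 3 spectra).
#' @param threshold Multiple of the robust SD (default 8).
#' @param edge_margin Channels at each range edge excluded from the
#'   exceedance test (default 5).
#' @return The retained spectra; removed ids in attribute `"removed_ids"`.
#' @export
remove_outliers <- function(df, threshold = 8, edge_margin = 5) {
  w <- spectra_wide(df)
  if (nrow(w$X) < 3) {
    rlang::abort("outlier elimination needs at least 3 spectra.")
  }
  med <- apply(w$X, 2, stats::median)
  mad_raw <- apply(w$X, 2, stats::mad, constant = 1)
  lim <- med + threshold * 1.4826 * mad_raw
  # a zero MAD leaves the signal-to-noise ratio at that frequency undefined
  # (e.g. channels pinned by the rubber-band hull across most spectra), so
  # such channels cannot contribute to the exceedance test
  lim[mad_raw == 0] <- Inf
  p <- ncol(w$X)
  if (edge_margin > 0 && p > 2 * edge_margin) {
    edge <- c(seq_len(edge_margin), (p - edge_margin + 1):p)
    lim[edge] <- Inf
  }
  bad <- which(apply(w$X, 1, function(r) any(r > lim)))
  if (length(bad) == nrow(w$X)) {
    rlang::abort("all spectra flagged as outliers; threshold too aggressive.")
  }
  removed <- w$ids[bad]
  out <- dplyr::filter(df, !(.data$spectrum_id %in% removed))
  attr(out, "removed_ids") <- sort(removed)
  out
}

#' @rdname remove_outliers
#' @param x A tibble returned by [remove_outliers()] or
#'   [preprocess_spectra()].
#' @export
removed_ids <- function(x) {
  attr(x, "removed_ids")
}

#' Standardize each spectrum to zero mean and unit variance
#'
#' Each spectrum is normalized to its own mean and standard deviation
#' (population convention, dividing by the number of points).
#'
#' @param df Long spectra tibble.
#' @return Tibble of standardized spectra.
#' @export
standardize_spectra <- function(df) {
  check_spectra_df(df)
  df |>
    dplyr::group_by(.data$spectrum_id) |>
    dplyr::group_modify(function(d, key) {
      s <- sd_pop(d$intensity)
      if (s == 0) {
        rlang::abort("constant spectrum: standard deviation is zero.")
      }
      d$intensity <- (d$intensity - mean(d$intensity)) / s
      d
    }) |>
    dplyr::ungroup() |>
    (\(out) out[, union(.spectra_cols, names(out))])()
}

# Central Savitzky-Golay coefficients for (window, order).
sg_coefficients <- function(window, order) {
  signal::sgolay(p = order, n = window)[(window + 1) / 2, ]
}

smooth_one <- function(y, h) {
  n <- length(y)
  m <- (length(h) - 1L) / 2L
  ypad <- c(y[(m + 1):2], y, y[(n - 1):(n - m)])
  out <- numeric(n)
  for (j in seq_along(h)) {
    out <- out + h[j] * ypad[j:(j + n - 1)]
  }
  out
}

#' Savitzky--Golay smoothing
#'
#' Applies the central Savitzky--Golay least-squares filter (default window
#' 11, polynomial order 2). The ends of each spectrum are mirror-padded so
#' the output length equals the input length.
#'
#' @param df Long spectra tibble.
#' @param window Odd filter window length.
#' @param order Polynomial order, less than `window`.
#' @return Tibble of smoothed spectra.
#' @export
smooth_spectra <- function(df, window = 11, order = 2) {
  check_spectra_df(df)
  if (window %% 2 == 0) {
    rlang::abort("`window` must be odd.")
  }
  if (order >= window) {
    rlang::abort("`order` must be smaller than `window`.")
  }
  n_points <- length(unique(df$wavenumber))
  if (n_points < window) {
    rlang::abort("spectra are shorter than the filter window.")
  }
  h <- sg_coefficients(window, order)
  df |>
    dplyr::group_by(.data$spectrum_id) |>
    dplyr::group_modify(function(d, key) {
      d$intensity <- smooth_one(d$intensity, h)
      d
    }) |>
    dplyr::ungroup() |>
    (\(out) out[, union(.spectra_cols, names(out))])()
}

#' Per-class spectral archetype
#'
#' The archetype of a group of (normalized) spectra is their mean spectrum
#' together with the per-wavenumber standard deviation (population
#' convention): the mean pictures the "ideal" analyte spectrum and the SD
#' band pictures its reproducibility.
#'
#' @param df Long spectra tibble (each class needs at least 2 spectra).
#' @return Tibble with columns `label`, `wavenumber`, `mean`, `sd`,
#'   `n_members`.
#' @export
compute_archetype <- function(df) {
  check_spectra_df(df)
  n_members <- dplyr::count(dplyr::distinct(df, .data$spectrum_id, .data$label),
                            .data$label)
  if (any(n_members$n < 2)) {
    rlang::abort("archetypes need at least 2 spectra per class.")
  }
  df |>
    dplyr::group_by(.data$label, .data$wavenumber) |>
    dplyr::summarise(
      mean = mean(.data$intensity),
      sd = sd_pop(.data$intensity),
      n_members = dplyr::n(),
      .groups = "drop"
    )
}

#' Full preprocessing chain
#'
#' Applies, in order: range selection, rubber-band baseline correction,
#' robust outlier elimination, per-spectrum standardization, and
#' Savitzky--Golay smoothing. The stage order is fixed; removed spectrum ids
#' and the final dimensions are recorded as attributes.
#'
#' @param df Long spectra tibble.
#' @param lo,hi Range limits, cm\eqn{^{-1}}.
#' @param outlier_threshold Robust-SD multiple for outlier elimination.
#' @param sg_window,sg_order Savitzky--Golay parameters.
#' @return The preprocessed spectra tibble with attributes `removed_ids`,
#'   `n_before`, `n_after`, `p` and `stages`.
#' @examples
#' d <- generate_spectra(n_per_class = c(4, 4, 4), seed = 1)
#' m <- preprocess_spectra(d)
#' attr(m, "p")
#' @export
preprocess_spectra <- function(df, lo = 300, hi = 1800, outlier_threshold = 8,
                               sg_window = 11, sg_order = 2) {
  check_spectra_df(df)
  n_before <- length(unique(df$spectrum_id))
  out <- df |>
    select_range(lo = lo, hi = hi) |>
    correct_baseline() |>
    remove_outliers(threshold = outlier_threshold)
  removed <- attr(out, "removed_ids")
  out <- out |>
    standardize_spectra() |>
    smooth_spectra(window = sg_window, order = sg_order)
  attr(out, "removed_ids") <- removed
  attr(out, "n_before") <- n_before
  attr(out, "n_after") <- length(unique(out$spectrum_id))
  attr(out, "p") <- length(unique(out$wavenumber))
  attr(out, "stages") <- c("select_range", "correct_baseline",
                           "remove_outliers", "standardize_spectra",
                           "smooth_spectra")
  out
}
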