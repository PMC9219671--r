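#' Wavenumber axes for synthetic SERS spectra
#'
#' `wavenumber_axis()` builds a uniformly spaced Raman-shift axis.
#' `default_wavenumber_axis()` builds the 1024-point instrument-like grid used
#' by the default synthetic data: its step is chosen so that exactly 855 grid
#' points fall inside the analysed 300--1800 cm\eqn{^{-1}} window (with 300 and
#' 1800 themselves on the grid), mirroring the dimensions of a typical
#' dispersive CCD spectrometer acquisition after range selection.
#'
#' @param from,to Axis limits in cm\eqn{^{-1}}.
#' @param n_points Number of grid points (default 1024).
#' @param window Analysis window in cm\eqn{^{-1}} for the default axis.
#' @param n_window Number of grid points inside `window`.
#' @param n_below Number of grid points below the window.
#' @return A strictly increasing numeric vector of Raman shifts.
#' @examples
#' length(default_wavenumber_axis())
#' sum(default_wavenumber_axis() >= 300 & default_wavenumber_axis() <= 1800)
#' @export
wavenumber_axis <- function(from = 250, to = 1900, n_points = 1024) {
  stopifnot(from < to, n_points >= 2)
  seq(from, to, length.out = n_points)
}

#' @rdname wavenumber_axis
#' @export
default_wavenumber_axis <- function(n_points = 1024, window = c(300, 1800),
                                    n_window = 855, n_below = 85) {
  stopifnot(n_window >= 2, n_below >= 0, n_below + n_window <= n_points)
  step <- (window[2] - window[1]) / (n_window - 1)
  window[1] + (seq_len(n_points) - 1 - n_below) * step
}

#' Describe one vibrational band of a synthetic spectrum
#'
#' @param center Band position, cm\eqn{^{-1}}.
#' @param amplitude Peak intensity (arbitrary units), non-negative.
#' @param width Half-width at half maximum, cm\eqn{^{-1}}.
#' @param jitter_center Per-spectrum SD of the band position, cm\eqn{^{-1}}.
#' @param jitter_amplitude Per-spectrum relative SD of the amplitude.
#' @return A one-row tibble.
#' @export
band_spec <- function(center, amplitude, width = 8,
                      jitter_center = 1, jitter_amplitude = 0.1) {
  stopifnot(
    all(width > 0), all(amplitude >= 0),
    all(jitter_center >= 0), all(jitter_amplitude >= 0)
  )
  tibble::tibble(
    center = center, amplitude = amplitude, width = width,
    jitter_center = jitter_center, jitter_amplitude = jitter_amplitude
  )
}

#' Define a synthetic class profile
#'
#' A class profile bundles the vibrational bands of one protein source with a
#' smooth fluorescence-like background model and an additive noise level.
#'
#' @param name Class name.
#' @param bands Tibble of band specifications (see [band_spec()]).
#' @param baseline_sd SDs of the random degree-3 polynomial baseline
#'   coefficients (constant first), drawn fresh for every spectrum.
#' @param noise_sd SD of the additive i.i.d. Gaussian noise.
#' @param shape Band line shape, `"lorentzian"` (typical for Raman bands) or
#'   `"gaussian"`.
#' @return An object of class `sers_profile`.
#' @export
class_profile <- function(name, bands,
                          baseline_sd = c(0.5, 0.3, 0.2, 0.1),
                          noise_sd = 0.02,
                          shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  stopifnot(is.character(name), length(name) == 1, noise_sd >= 0)
  structure(
    list(name = name, bands = bands, baseline_sd = baseline_sd,
         noise_sd = noise_sd, shape = shape),
    class = "sers_profile"
  )
}

#' @export
print.sers_profile <- function(x, ...) {
  cat("<sers_profile> class:", x$name, "-", nrow(x$bands), "bands,",
      x$shape, "line shape, noise sd", x$noise_sd, "\n")
  invisible(x)
}

# Shared major bands: one canonical position per assignment-table row that is
# present for all three protein sources (seminal-fluid column taken as the
# canonical position so the shared skeleton is identical across classes).
.shared_band_centers <- c(
  421, 537, 630, 652, 766, 833, 857, 885, 905, 945, 954, 963, 1011, 1041,
  1053, 1130, 1169, 1212, 1241, 1260, 1307, 1324, 1339, 1348, 1366, 1385,
  1392, 1459, 1473, 1557, 1663
)
# The five most intense bands of the measured spectra.
.major_band_centers <- c(766, 1011, 1348, 1459, 1663)

.default_exclusive <- list(
  seminal = c(453, 492, 572, 591, 683, 1069, 1095),
  lung = 1623,
  heart = c(502, 1279, 1600)
)

#' Default three-class SERS-like profiles
#'
#' The three default classes (`seminal`, `lung`, `heart`) model the same
#' glycoprotein produced by different cell types: they share an identical set
#' of 31 major vibrational bands and differ only in a small set of
#' class-exclusive minor bands whose amplitude is a fraction of the strongest
#' shared band (the tryptophan indole breathing band at 1011 cm\eqn{^{-1}}).
#'
#' @param exclusive_amplitude Amplitude of the class-exclusive bands relative
#'   to the strongest shared band (default 0.15).
#' @param exclusive Named list of class-exclusive band centers
#'   (cm\eqn{^{-1}}); one entry per class.
#' @param noise_sd Additive Gaussian noise SD.
#' @param jitter_center,jitter_amplitude Band jitters, see [band_spec()].
#' @param shape Band line shape.
#' @return Named list of three `sers_profile` objects.
#' @export
sers_profiles <- function(exclusive_amplitude = 0.15,
                          exclusive = .default_exclusive,
                          noise_sd = 0.02,
                          jitter_center = 1, jitter_amplitude = 0.1,
                          shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  if (anyDuplicated(names(exclusive))) {
    rlang::abort("duplicate class names in `exclusive`.")
  }
  amp <- ifelse(.shared_band_centers %in% .major_band_centers, 1, 0.45)
  shared <- band_spec(.shared_band_centers, amp, width = 8,
                      jitter_center = jitter_center,
                      jitter_amplitude = jitter_amplitude)
  profiles <- lapply(names(exclusive), function(cls) {
    bands <- shared
    if (length(exclusive[[cls]]) > 0) {
      excl <- band_spec(exclusive[[cls]], exclusive_amplitude, width = 6,
                        jitter_center = jitter_center,
                        jitter_amplitude = jitter_amplitude)
      bands <- dplyr::bind_rows(shared, excl)
    }
    class_profile(cls, bands, noise_sd = noise_sd, shape = shape)
  })
  names(profiles) <- names(exclusive)
  profiles
}

# Evaluate the sum of band profiles on the axis.
eval_bands <- function(axis, center, amplitude, width, shape) {
  if (length(center) == 0) {
    return(numeric(length(axis)))
  }
  y <- numeric(length(axis))
  for (b in seq_along(center)) {
    if (shape == "lorentzian") {
      y <- y + amplitude[b] * width[b]^2 / ((axis - center[b])^2 + width[b]^2)
    } else {
      s <- width[b] / sqrt(2 * log(2))
      y <- y + amplitude[b] * exp(-(axis - center[b])^2 / (2 * s^2))
    }
  }
  y
}

#' Generate one synthetic SERS spectrum
#'
#' The spectrum is the sum of a smooth random degree-3 polynomial baseline,
#' the profile's vibrational bands (position and amplitude jittered per
#' spectrum) and i.i.d. Gaussian noise. All randomness is fixed by `seed`.
#'
#' @param profile A `sers_profile`.
#' @param axis Wavenumber axis (strictly increasing numeric vector).
#' @param seed Integer seed fixing all randomness.
#' @param id Spectrum identifier.
#' @return Long tibble with columns `spectrum_id`, `label`, `wavenumber`,
#'   `intensity`.
#' @examples
#' sp <- generate_spectrum(sers_profiles()$seminal, default_wavenumber_axis(), seed = 1)
#' @export
generate_spectrum <- function(profile, axis, seed, id = profile$name) {
  stopifnot(inherits(profile, "sers_profile"))
  if (is.unsorted(axis, strictly = TRUE)) {
    rlang::abort("`axis` must be strictly increasing.")
  }
  b <- profile$bands
  if (nrow(b) > 0 &&
      (min(b$center) < min(axis) || max(b$center) > max(axis))) {
    rlang::abort(paste0(
      "profile '", profile$name, "' has band centers outside the axis span."
    ))
  }
  intensity <- withr::with_seed(seed, {
    centers <- b$center + stats::rnorm(nrow(b), 0, b$jitter_center)
    amps <- pmax(b$amplitude * (1 + stats::rnorm(nrow(b), 0, b$jitter_amplitude)), 0)
    u <- if (diff(range(axis)) > 0) {
      2 * (axis - min(axis)) / diff(range(axis)) - 1
    } else {
      axis * 0
    }
    coef <- stats::rnorm(length(profile$baseline_sd), 0, profile$baseline_sd)
    baseline <- drop(outer(u, seq_along(coef) - 1, `^`) %*% coef)
    baseline +
      eval_bands(axis, centers, amps, b$width, profile$shape) +
      stats::rnorm(length(axis), 0, profile$noise_sd)
  })
  tibble::tibble(
    spectrum_id = id, label = profile$name,
    wavenumber = axis, intensity = intensity
  )
}

#' Generate a labeled synthetic dataset
#'
#' @param profiles Named list of `sers_profile` objects (one per class).
#' @param n_per_class Number of spectra per class; defaults to 66/66/65, a
#'   total of 197 acquisitions.
#' @param axis Wavenumber axis shared by all spectra.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return Long spectra tibble.
#' @examples
#' d <- generate_spectra(n_per_class = c(2, 2, 2), seed = 1)
#' dplyr::count(dplyr::distinct(d, spectrum_id, label), label)
#' @export
generate_spectra <- function(profiles = sers_profiles(),
                             n_per_class = c(66, 66, 65),
                             axis = default_wavenumber_axis(),
                             seed = 1) {
  nms <- vapply(profiles, function(p) p$name, character(1))
  if (anyDuplicated(nms)) {
    rlang::abort("duplicate class names in `profiles`.")
  }
  n_per_class <- rep_len(n_per_class, length(profiles))
  if (any(n_per_class < 1)) {
    rlang::abort("`n_per_class` must be >= 1 for every class.")
  }
  total <- sum(n_per_class)
  seeds <- withr::with_seed(seed, sample.int(2147483646L, total))
  out <- vector("list", total)
  k <- 0L
  for (ci in seq_along(profiles)) {
    for (j in seq_len(n_per_class[ci])) {
      k <- k + 1L
      out[[k]] <- generate_spectrum(
        profiles[[ci]], axis, seed = seeds[k],
        id = sprintf("%s_%03d", nms[ci], j)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Inject cosmic-ray-like spikes into a spectra set
#'
#' Randomly chosen spectra receive 1--3 single-channel positive spikes of
#' height `spike_height` times that spectrum's intensity SD. Spike channels
#' are drawn inside `window` excluding its two edge channels (the rubber-band
#' baseline pins the window endpoints to zero, so a spike planted exactly
#' there would be erased before outlier screening and the planted ground
#' truth would be lost).
#'
#' @param df Long spectra tibble.
#' @param n_spectra Number of spectra to contaminate (default 6).
#' @param spike_height Spike height in multiples of the spectrum SD.
#' @param window Wavenumber window eligible for spikes.
#' @param seed Integer seed.
#' @return The contaminated tibble, with the affected spectrum ids in
#'   attribute `"spiked_ids"` (see [spiked_ids()]).
#' @export
inject_spikes <- function(df, n_spectra = 6, spike_height = 20,
                          window = c(300, 1800), seed = 1) {
  check_spectra_df(df)
  ids <- unique(df$spectrum_id)
  stopifnot(n_spectra <= length(ids), n_spectra >= 0, spike_height > 0)
  if (n_spectra == 0) {
    attr(df, "spiked_ids") <- character(0)
    return(df)
  }
  wn <- sort(unique(df$wavenumber))
  eligible <- wn[wn >= window[1] & wn <= window[2]]
  eligible <- eligible[-c(1, length(eligible))]
  df <- withr::with_seed(seed, {
    hit <- sample(ids, n_spectra)
    for (id in hit) {
      rows <- which(df$spectrum_id == id)
      h <- spike_height * stats::sd(df$intensity[rows])
      at <- sample(eligible, sample(1:3, 1))
      spike_rows <- rows[df$wavenumber[rows] %in% at]
      df$intensity[spike_rows] <- df$intensity[spike_rows] + h
    }
    attr(df, "spiked_ids") <- sort(hit)
    df
  })
  df
}

#' @rdname inject_spikes
#' @param x A tibble returned by [inject_spikes()].
#' @export
spiked_ids <- function(x) {
  attr(x, "spiked_ids")
}
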