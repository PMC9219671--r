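# Internal helpers shared across modules.

# Canonical long-format columns for a set of spectra.
.spectra_cols <- c("spectrum_id", "label", "wavenumber", "intensity")

check_spectra_df <- function(df, call = rlang::caller_env()) {
  if (!is.data.frame(df)) {
    rlang::abort("`df` must be a data frame of spectra.", call = call)
  }
  missing <- setdiff(.spectra_cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("`df` is missing spectra columns: ", paste(missing, collapse = ", ")),
      call = call
    )
  }
  invisible(df)
}

# Long tibble -> list(X, wavenumber, labels, ids). Row order follows first
# appearance of each spectrum_id; column order is ascending wavenumber.
spectra_wide <- function(df) {
  check_spectra_df(df)
  ids <- unique(df$spectrum_id)
  wn <- sort(unique(df$wavenumber))
  n <- length(ids)
  p <- length(wn)
  if (nrow(df) != n * p) {
    rlang::abort("spectra do not share a common wavenumber axis.")
  }
  i <- match(df$spectrum_id, ids)
  j <- match(df$wavenumber, wn)
  X <- matrix(NA_real_, n, p, dimnames = list(ids, NULL))
  X[cbind(i, j)] <- df$intensity
  if (anyNA(X)) {
    rlang::abort("spectra do not share a common wavenumber axis.")
  }
  labels <- df$label[match(ids, df$spectrum_id)]
  names(labels) <- ids
  list(X = X, wavenumber = wn, labels = labels, ids = ids)
}

# Inverse of spectra_wide().
spectra_long <- function(X, wavenumber, labels, ids = rownames(X)) {
  n <- nrow(X)
  p <- ncol(X)
  tibble::tibble(
    spectrum_id = rep(ids, each = p),
    label = rep(unname(labels), each = p),
    wavenumber = rep(wavenumber, times = n),
    intensity = as.vector(t(X))
  )
}

# Deterministic per-stage seed derived from one root seed. Kept below 2^31.
child_seed <- function(seed, stage) {
  offsets <- c(
    synth = 11L, spikes = 23L, split = 37L, augment = 47L,
    curve = 59L, misc = 71L
  )
  if (!stage %in% names(offsets)) {
    rlang::abort(paste0("unknown seed stage: ", stage))
  }
  as.integer((as.double(seed) * 7919 + offsets[[stage]]) %% 2147483646) + 1L
}

# Population standard deviation (divide by n).
sd_pop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}
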