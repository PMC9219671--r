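#' The packaged vibrational band-assignment table
#'
#' Fifty assignment rows for the SERS spectra of the glycoprotein produced
#' by three cell types (`seminal`, `lung`, `heart`): per-class band position
#' in cm\eqn{^{-1}} (NA when the band is absent from that class's spectrum),
#' the vibrational-mode assignment, the amino-acid or dipeptide carrier, the
#' literature band position and a reference tag. Some rows (e.g. the 502
#' cm\eqn{^{-1}} band) have no assignment text; they are matched by position
#' but reported as unassigned.
#'
#' Note: for a handful of rows the table's per-class presence pattern and
#' the narrative description of class-exclusive bands disagree (the table
#' additionally lists seminal-only bands at 435 and 1441 cm\eqn{^{-1}}, and
#' places 1623 cm\eqn{^{-1}} in the heart column). The packaged table is
#' treated as authoritative throughout.
#'
#' @return Tibble with columns `seminal`, `lung`, `heart`, `assignment`,
#'   `residue`, `reported_band`, `ref`.
#' @examples
#' dplyr::filter(band_table(), seminal == 766)
#' @export
band_table <- function() {
  path <- system.file("extdata", "ace_band_table.csv", package = "serslda")
  tb <- readr::read_csv(
    path,
    col_types = readr::cols(
      seminal = readr::col_double(),
      lung = readr::col_double(),
      heart = readr::col_double(),
      .default = readr::col_character()
    )
  )
  pos <- as.matrix(tb[, c("seminal", "lung", "heart")])
  if (any(rowSums(!is.na(pos)) == 0) ||
      any(pos < 300 | pos > 1800, na.rm = TRUE)) {
    rlang::abort("packaged band table is malformed.")
  }
  tb
}

#' Pick peaks from an archetype spectrum
#'
#' Local maxima of the archetype mean whose topographic prominence (height
#' above the higher of the two key saddles separating the peak from taller
#' terrain) reaches `min_prominence`.
#'
#' @param archetype Tibble with `wavenumber` and `mean` columns for one
#'   class (one row per wavenumber).
#' @param min_prominence Minimum prominence, in intensity units.
#' @return Tibble with `wavenumber`, `height`, `prominence`, sorted by
#'   position.
#' @export
pick_peaks <- function(archetype, min_prominence = 0.1) {
  x <- archetype$wavenumber
  y <- archetype$mean
  n <- length(y)
  if (n < 3) {
    return(tibble::tibble(wavenumber = numeric(0), height = numeric(0),
                          prominence = numeric(0)))
  }
  is_peak <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  prom <- vapply(is_peak, function(i) {
    higher_left <- which(y[seq_len(i - 1)] > y[i])
    lo <- if (length(higher_left)) max(higher_left) + 1L else 1L
    left_min <- min(y[lo:i])
    higher_right <- which(y[(i + 1):n] > y[i]) + i
    hi <- if (length(higher_right)) min(higher_right) - 1L else n
    right_min <- min(y[i:hi])
    y[i] - max(left_min, right_min)
  }, numeric(1))
  keep <- prom >= min_prominence
  tibble::tibble(
    wavenumber = x[is_peak[keep]],
    height = y[is_peak[keep]],
    prominence = prom[keep]
  )
}

#' Match picked peaks against the band table
#'
#' Each observed peak is matched to the nearest band position in the given
#' class's column of the table, provided the distance does not exceed `tol`;
#' when two rows are equidistant the one with the smaller row index wins.
#'
#' @param peaks Numeric vector of observed peak positions (cm\eqn{^{-1}}),
#'   or a tibble from [pick_peaks()].
#' @param table Band table, see [band_table()].
#' @param class One of `"seminal"`, `"lung"`, `"heart"` (a position column
#'   of `table`).
#' @param tol Matching tolerance in cm\eqn{^{-1}} (default 5, a typical
#'   SERS band-position variability).
#' @return Tibble with `observed`, `matched_position`, `assignment`,
#'   `residue`, `distance`, `row` (`NA`s when unmatched).
#' @export
assign_peaks <- function(peaks, table = band_table(), class, tol = 5) {
  if (is.data.frame(peaks)) {
    peaks <- peaks$wavenumber
  }
  if (!class %in% c("seminal", "lung", "heart")) {
    rlang::abort("`class` must be one of 'seminal', 'lung', 'heart'.")
  }
  pos <- table[[class]]
  out <- lapply(peaks, function(pk) {
    d <- abs(pos - pk)
    if (all(is.na(d)) || min(d, na.rm = TRUE) > tol) {
      return(tibble::tibble(observed = pk, matched_position = NA_real_,
                            assignment = NA_character_,
                            residue = NA_character_,
                            distance = NA_real_, row = NA_integer_))
    }
    i <- which.min(d)  # first minimum = smaller row index on ties
    tibble::tibble(observed = pk, matched_position = pos[i],
                   assignment = table$assignment[i],
                   residue = table$residue[i],
                   distance = d[i], row = i)
  })
  dplyr::bind_rows(out)
}

#' Class-exclusive bands from the band table
#'
#' With `versus = NULL`, returns the band positions present for `class` and
#' absent for both other classes. With `versus` set, compares only the two
#' named classes (pairwise mode) and returns positions present for `class`
#' but absent for `versus`.
#'
#' @inheritParams assign_peaks
#' @param versus Optional second class for a pairwise comparison.
#' @return Tibble with `position`, `assignment`, `residue`.
#' @examples
#' exclusive_bands(class = "seminal")$position
#' @export
exclusive_bands <- function(table = band_table(), class, versus = NULL) {
  all_cls <- c("seminal", "lung", "heart")
  if (!class %in% all_cls) {
    rlang::abort("`class` must be one of 'seminal', 'lung', 'heart'.")
  }
  others <- if (is.null(versus)) setdiff(all_cls, class) else versus
  keep <- !is.na(table[[class]])
  for (o in others) {
    keep <- keep & is.na(table[[o]])
  }
  tibble::tibble(
    position = table[[class]][keep],
    assignment = table$assignment[keep],
    residue = table$residue[keep]
  )
}
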