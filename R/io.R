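#' Read and write spectra as wide CSV with a label sidecar
#'
#' The on-disk dialect is one wide CSV whose first column `wavenumber_cm1`
#' holds the Raman-shift axis and whose remaining columns hold one spectrum
#' each (column name = spectrum id), plus a sidecar CSV with columns
#' `spectrum_id,label`.
#'
#' @param df Long spectra tibble.
#' @param spectra_path Path of the wide spectra CSV.
#' @param labels_path Path of the labels CSV.
#' @return `write_spectra()` returns `df` invisibly; `read_spectra()` returns
#'   a long spectra tibble.
#' @export
write_spectra <- function(df, spectra_path, labels_path) {
  w <- spectra_wide(df)
  wide <- tibble::as_tibble(as.data.frame(t(w$X)))
  names(wide) <- w$ids
  wide <- dplyr::bind_cols(tibble::tibble(wavenumber_cm1 = w$wavenumber), wide)
  readr::write_csv(wide, spectra_path)
  readr::write_csv(
    tibble::tibble(spectrum_id = w$ids, label = unname(w$labels)),
    labels_path
  )
  invisible(df)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(spectra_path, labels_path) {
  wide <- readr::read_csv(spectra_path, show_col_types = FALSE)
  labels <- readr::read_csv(labels_path, show_col_types = FALSE)
  ids <- setdiff(names(wide), "wavenumber_cm1")
  missing <- setdiff(ids, labels$spectrum_id)
  if (length(missing) > 0) {
    rlang::abort(paste0("labels missing for: ", paste(missing, collapse = ", ")))
  }
  df <- tidyr::pivot_longer(wide, -"wavenumber_cm1",
                            names_to = "spectrum_id", values_to = "intensity")
  df$label <- labels$label[match(df$spectrum_id, labels$spectrum_id)]
  df <- df[, c("spectrum_id", "label", "wavenumber_cm1", "intensity")]
  names(df)[3] <- "wavenumber"
  dplyr::arrange(df, match(.data$spectrum_id, ids), .data$wavenumber)
}
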