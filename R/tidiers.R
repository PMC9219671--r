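#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the discriminant loadings
#'
#' @param x A fitted `sers_lda`.
#' @param ... Unused.
#' @return Tibble with one row per spectral feature: `feature`,
#'   `wavenumber` and one column per discriminant component (`LD1`, ...).
#' @method tidy sers_lda
#' @export
tidy.sers_lda <- function(x, ...) {
  V <- x$V
  colnames(V) <- paste0("LD", seq_len(ncol(V)))
  dplyr::bind_cols(
    tibble::tibble(feature = seq_len(x$p), wavenumber = x$wavenumber),
    tibble::as_tibble(V)
  )
}

#' One-row model summary
#'
#' @param x A fitted `sers_lda`.
#' @param ... Unused.
#' @return One-row tibble with `n`, `p`, `n_classes`, `n_components`,
#'   `shrinkage` and the eigenvalues `lambda1`, `lambda2`, ...
#' @method glance sers_lda
#' @export
glance.sers_lda <- function(x, ...) {
  ev <- tibble::as_tibble(as.list(stats::setNames(
    x$eigenvalues, paste0("lambda", seq_along(x$eigenvalues))
  )))
  dplyr::bind_cols(
    tibble::tibble(n = x$n, p = x$p, n_classes = length(x$classes),
                   n_components = ncol(x$V), shrinkage = x$shrinkage),
    ev
  )
}
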