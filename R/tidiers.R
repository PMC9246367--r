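#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a rate-ratio fit
#'
#' One row per FST bin with observed and fitted rate ratios and residuals.
#'
#' @param x A `rate_fit` from [fit_r0()].
#' @param ... Unused.
#' @return Tibble with the input bins plus `fitted` and `resid`.
#' @method tidy rate_fit
#' @export
tidy.rate_fit <- function(x, ...) {
  tibble::as_tibble(x$bins)
}

#' One-row summary of a rate-ratio fit
#'
#' @inheritParams tidy.rate_fit
#' @return Tibble with `r0_hat`, `se`, `rss`, `n_bins`.
#' @method glance rate_fit
#' @export
glance.rate_fit <- function(x, ...) {
  tibble::tibble(r0_hat = x$r0_hat, se = x$se, rss = x$rss,
                 n_bins = x$n_bins)
}

#' Tidy a within-individual entropy result
#'
#' @param x A `within_entropy` result.
#' @param ... Unused.
#' @return Tibble with the folded spectrum: `n`, `zeta`.
#' @method tidy within_entropy
#' @export
tidy.within_entropy <- function(x, ...) {
  tibble::tibble(n = seq_along(x$zeta) - 1, zeta = x$zeta)
}

#' @rdname tidy.within_entropy
#' @method glance within_entropy
#' @export
glance.within_entropy <- function(x, ...) {
  tibble::tibble(sw = x$sw, n_markers = x$n_markers)
}

#' Tidy a between-individual entropy result
#'
#' @param x A `between_entropy` result.
#' @param ... Unused.
#' @return Tibble with the eigen-spectrum: `component`, `lambda`,
#'   `fraction` (`lambda / J`).
#' @method tidy between_entropy
#' @export
tidy.between_entropy <- function(x, ...) {
  tibble::tibble(component = seq_along(x$lambda), lambda = x$lambda,
                 fraction = x$lambda / x$n_individuals)
}

#' @rdname tidy.between_entropy
#' @method glance between_entropy
#' @export
glance.between_entropy <- function(x, ...) {
  tibble::tibble(sb = x$sb, sb_max = log(x$n_individuals),
                 n_individuals = x$n_individuals)
}
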