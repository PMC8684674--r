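#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a zero-inflated Poisson fit
#'
#' @param x A `zip_fit` object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @method tidy zip_fit
#' @export
tidy.zip_fit <- function(x, ...) {
  tibble(term = c("pi", "lambda"), estimate = c(x$pi, x$lambda))
}

#' One-row summary of a zero-inflated Poisson fit
#'
#' @param x A `zip_fit` object.
#' @param ... Unused.
#' @return Tibble with `n_obs`, `logLik`, `iterations`, `converged`,
#'   `degenerate`.
#' @method glance zip_fit
#' @export
glance.zip_fit <- function(x, ...) {
  tibble(n_obs = x$n_obs, logLik = x$loglik, iterations = x$iterations,
         converged = x$converged, degenerate = x$degenerate)
}
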