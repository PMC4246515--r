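#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a growth or cell-profile fit
#'
#' One row per fitted parameter, with its estimate.
#'
#' @param x A `growth_fit` or `cell_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @method tidy beta_fit
#' @export
tidy.beta_fit <- function(x, ...) {
  p <- unclass(x$params)
  tibble::tibble(term = names(p)[vapply(p, is.numeric, logical(1))],
                 estimate = unlist(p[vapply(p, is.numeric, logical(1))]))
}

#' Glance at a growth or cell-profile fit
#'
#' One-row summary of fit quality and convergence.
#'
#' @inheritParams tidy.beta_fit
#' @return A one-row tibble: `r_squared`, `sse`, `converged`,
#'   `iterations`, `restarts`, `nobs`.
#' @method glance beta_fit
#' @export
glance.beta_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared,
    sse = x$sse,
    converged = x$converged,
    iterations = x$iterations,
    restarts = x$restarts,
    nobs = length(x$residuals)
  )
}

#' Augment the data of a fit with fitted values and residuals
#'
#' @inheritParams tidy.beta_fit
#' @return The fit's data as a tibble with added `.fitted` and `.resid`
#'   columns.
#' @method augment beta_fit
#' @export
augment.beta_fit <- function(x, ...) {
  out <- tibble::as_tibble(x$data)
  out$.fitted <- x$fitted
  out$.resid <- x$residuals
  out
}
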