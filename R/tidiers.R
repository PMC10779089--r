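#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a binding fit into one row per parameter
#'
#' @param x a `binding_fit`.
#' @param ... unused.
#' @return a tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble::tibble(
    term = c("K", "logK"),
    estimate = c(x$K, x$logK),
    std.error = c(x$K_stderr, x$logK_stderr))
}

#' One-row summary of a binding fit
#'
#' @param x a `binding_fit`.
#' @param ... unused.
#' @return a one-row tibble with the constant, its log, uncertainties and
#'   fit diagnostics.
#' @export
glance.binding_fit <- function(x, ...) {
  tibble::tibble(
    K = x$K, logK = x$logK, K_stderr = x$K_stderr,
    logK_stderr = x$logK_stderr, residual_rms = x$residual_rms,
    n_points = x$n_points, converged = x$converged,
    ill_conditioned = x$ill_conditioned, method = x$method)
}
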