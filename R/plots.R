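#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#' @export
ggplot2::autoplot

#' Plot a spectrum
#'
#' @param object an `icd_spectrum`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.icd_spectrum <- function(object, ...) {
  ggplot(tibble::as_tibble(object), aes(x = .data$wavelength, y = .data$value)) +
    geom_line() +
    labs(x = "wavelength (nm)", y = spectrum_unit(object))
}

#' Plot a titration series, coloured by host concentration
#'
#' @param object an `icd_titration`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.icd_titration <- function(object, ...) {
  long <- tidyr::unnest(
    dplyr::mutate(tibble::as_tibble(object),
                  spectrum = purrr::map(.data$spectrum, tibble::as_tibble)),
    "spectrum")
  ggplot(long, aes(x = .data$wavelength, y = .data$value,
                   colour = .data$host_M, group = .data$host_M)) +
    geom_line() +
    labs(x = "wavelength (nm)", y = "signal", colour = "host (M)")
}

#' Plot the saturation curve of a binding fit
#'
#' Observed readout-wavelength intensity against host concentration with the
#' fitted 1:1 isotherm overlaid.
#'
#' @param object a `binding_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.binding_fit <- function(object, ...) {
  sat <- object$saturation
  G <- sat$guest_M[1]; l <- sat$pathlength_cm[1]
  band <- object$fitted_response
  deps <- band$delta_eps[which.min(abs(band$wavelength - sat$wavelength[1]))]
  hgrid <- seq(0, max(sat$host_M), length.out = 200)
  curve <- tibble::tibble(
    host_M = hgrid,
    value = deps * speciate(G, hgrid, object$K)$complex * l)
  ggplot(sat, aes(x = .data$host_M, y = .data$value)) +
    geom_line(data = curve, colour = "grey40") +
    geom_point() +
    labs(x = "host concentration (M)",
         y = sprintf("signal @ %.4g nm", sat$wavelength[1]),
         title = sprintf("1:1 fit: logK = %.3f", object$logK))
}

#' @importFrom rlang .data
NULL
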