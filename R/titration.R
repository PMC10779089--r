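#' Assemble a titration series
#'
#' A titration series is a tibble with one row per titration point: columns
#' `guest_M`, `host_M`, `pathlength_cm` and a `spectrum` list-column of
#' [new_spectrum()] objects. The guest concentration must be identical across
#' points (the constant-guest titration design); rows are sorted by host
#' concentration.
#'
#' @param spectra list of `icd_spectrum` objects.
#' @param guest_M,host_M,pathlength_cm numeric vectors, one entry per point.
#' @return a tibble of class `icd_titration` with attribute `common_grid`.
#' @export
titration_series <- function(spectra, guest_M, host_M, pathlength_cm = 1) {
  n <- length(spectra)
  if (n == 0) rlang::abort("a titration series needs at least one point")
  guest_M <- rep_len(as.numeric(guest_M), n)
  host_M <- rep_len(as.numeric(host_M), n)
  pathlength_cm <- rep_len(as.numeric(pathlength_cm), n)
  purrr::walk(spectra, assert_spectrum, min_points = 1L)
  if (any(guest_M <= 0)) rlang::abort("guest_M must be positive at every titration point")
  if (any(host_M < 0)) rlang::abort("host_M must be non-negative")
  if (diff(range(guest_M)) > 1e-12 * max(guest_M)) {
    rlang::abort("guest_M must be constant across the series (constant-guest titration design)")
  }
  ord <- order(host_M)
  out <- tibble::tibble(guest_M = guest_M[ord], host_M = host_M[ord],
                        pathlength_cm = pathlength_cm[ord],
                        spectrum = spectra[ord])
  grids <- purrr::map(out$spectrum, "wavelength")
  common <- all(purrr::map_lgl(grids, ~ length(.x) == length(grids[[1]]) &&
                                 all(abs(.x - grids[[1]]) < 1e-9)))
  class(out) <- c("icd_titration", class(out))
  attr(out, "common_grid") <- common
  out
}

#' @export
print.icd_titration <- function(x, ...) {
  cat(sprintf("<icd_titration: %d points, guest %.3g M, host %.3g-%.3g M, common grid: %s>\n",
              nrow(x), x$guest_M[1], min(x$host_M), max(x$host_M),
              attr(x, "common_grid")))
  NextMethod()
}

#' Read a titration series from a JSON manifest
#'
#' The manifest is a JSON document with a `points` array; each element gives
#' `file` (spectrum path, relative to the manifest), `guest_M`, `host_M` and
#' optionally `pathlength_cm`.
#'
#' @param path manifest path.
#' @param dialect spectrum file dialect passed to [read_spectrum()].
#' @return an `icd_titration`.
#' @export
read_titration_manifest <- function(path, dialect = "csv") {
  if (!file.exists(path)) rlang::abort(sprintf("manifest not found: %s", path))
  man <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  pts <- man$points
  if (is.null(pts) || NROW(pts) == 0) rlang::abort("manifest has no `points`")
  pts <- tibble::as_tibble(pts)
  files <- file.path(dirname(path), pts$file)
  spectra <- purrr::map(files, read_spectrum, dialect = dialect)
  titration_series(spectra,
                   guest_M = pts$guest_M, host_M = pts$host_M,
                   pathlength_cm = pts$pathlength_cm %||% 1)
}

#' Write a titration series as spectrum files plus a JSON manifest
#'
#' @param series an `icd_titration`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix for per-point spectra.
#' @return the manifest path, invisibly.
#' @export
write_titration_manifest <- function(series, dir, prefix = "point") {
  if (!inherits(series, "icd_titration")) rlang::abort("expected an `icd_titration`")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s_%02d.csv", prefix, seq_len(nrow(series)))
  purrr::walk2(series$spectrum, files,
               ~ write_spectrum(.x, file.path(dir, .y)))
  manifest <- list(points = data.frame(file = files,
                                       guest_M = series$guest_M,
                                       host_M = series$host_M,
                                       pathlength_cm = series$pathlength_cm))
  out <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, out, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out)
}

#' Signal at (or nearest to) a wavelength for each titration point
#'
#' @param series an `icd_titration`.
#' @param wavelength target wavelength (nm).
#' @return a tibble with `guest_M`, `host_M`, `pathlength_cm`, `wavelength`
#'   (the grid point actually used) and `value`.
#' @export
titration_at <- function(series, wavelength) {
  if (!inherits(series, "icd_titration")) rlang::abort("expected an `icd_titration`")
  rows <- purrr::map2_dfr(series$spectrum, seq_len(nrow(series)), function(s, i) {
    j <- which.min(abs(s$wavelength - wavelength))
    tibble::tibble(point = i, wavelength = s$wavelength[j], value = s$value[j])
  })
  dplyr::bind_cols(dplyr::select(tibble::as_tibble(series), -"spectrum")[rows$point, ],
                   rows[c("wavelength", "value")])
}
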