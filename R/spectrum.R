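#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Ellipticity (mdeg) per unit of differential absorbance: theta[deg] = 32.982 * dA.
#' Conversion constant between ellipticity and differential absorbance
#'
#' Millidegrees of ellipticity per unit of differential absorbance
#' (`theta[mdeg] = 32982 * dA`), the standard circular-dichroism convention.
#' @export
MDEG_PER_DELTA_ABS <- 32982

#' Signal units understood by the spectral layer
#'
#' CD-channel units: `"ellipticity_mdeg"`, `"delta_absorbance"`,
#' `"delta_epsilon"` (M^-1 cm^-1). Absorption-channel units: `"absorbance"`,
#' `"molar_absorption"` (M^-1 cm^-1). Conversions between the CD and
#' absorption families are not defined.
#' @export
spectrum_units <- function() {
  c("ellipticity_mdeg", "delta_absorbance", "delta_epsilon",
    "absorbance", "molar_absorption")
}

#' Build a spectrum
#'
#' A spectrum is a tibble with columns `wavelength` (nm, strictly ascending)
#' and `value`, carrying its signal `unit`, optional cell `pathlength_cm`
#' and free-form `meta` as attributes. Input rows may arrive in any order;
#' they are sorted by wavelength.
#'
#' @param wavelength numeric, nm.
#' @param value numeric signal, same length as `wavelength`.
#' @param unit one of [spectrum_units()].
#' @param pathlength_cm optional cell pathlength in cm.
#' @param meta named list of provenance key-values.
#' @return a tibble of class `icd_spectrum`.
#' @export
new_spectrum <- function(wavelength, value, unit = "ellipticity_mdeg",
                         pathlength_cm = NA_real_, meta = list()) {
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value)) {
    abort("`wavelength` and `value` must have equal length")
  }
  if (length(wavelength) == 0) abort("spectrum has no data rows")
  if (!all(is.finite(wavelength)) || !all(is.finite(value))) {
    abort("spectrum contains non-finite wavelengths or values")
  }
  unit <- match.arg(unit, spectrum_units())
  ord <- order(wavelength)
  wavelength <- wavelength[ord]
  value <- value[ord]
  if (anyDuplicated(wavelength)) {
    abort(sprintf("duplicate wavelengths in spectrum (e.g. %g nm)",
                  wavelength[duplicated(wavelength)][1]))
  }
  out <- tibble(wavelength = wavelength, value = value)
  class(out) <- c("icd_spectrum", class(out))
  attr(out, "unit") <- unit
  attr(out, "pathlength_cm") <- as.numeric(pathlength_cm)
  attr(out, "meta") <- meta
  out
}

#' @export
print.icd_spectrum <- function(x, ...) {
  cat(sprintf("<icd_spectrum: %d points, %.6g-%.6g nm, unit = %s>\n",
              nrow(x), min(x$wavelength), max(x$wavelength), spectrum_unit(x)))
  NextMethod()
}

#' Unit tag of a spectrum
#' @param s an `icd_spectrum`.
#' @return a string from [spectrum_units()].
#' @export
spectrum_unit <- function(s) attr(s, "unit") %||% NA_character_

#' Pathlength recorded on a spectrum
#' @param s an `icd_spectrum`.
#' @return pathlength in cm, or `NA`.
#' @export
spectrum_pathlength <- function(s) attr(s, "pathlength_cm") %||% NA_real_

assert_spectrum <- function(s, min_points = 2L) {
  if (!inherits(s, "icd_spectrum")) abort("expected an `icd_spectrum`")
  if (nrow(s) < min_points) {
    abort(sprintf("spectrum needs at least %d points, got %d", min_points, nrow(s)))
  }
  invisible(s)
}

with_spectrum_values <- function(s, value, unit = spectrum_unit(s)) {
  new_spectrum(s$wavelength, value, unit = unit,
               pathlength_cm = spectrum_pathlength(s), meta = attr(s, "meta"))
}

#' Solution composition of a titration point
#'
#' @param guest_M total guest concentration (mol/L).
#' @param host_M total host (cyclodextrin) concentration (mol/L).
#' @param pathlength_cm cell pathlength (cm).
#' @return a one-row tibble of class `solution_spec`.
#' @export
solution_spec <- function(guest_M, host_M = 0, pathlength_cm = 1) {
  guest_M <- as.numeric(guest_M); host_M <- as.numeric(host_M)
  pathlength_cm <- as.numeric(pathlength_cm)
  if (any(c(guest_M, host_M, pathlength_cm) < 0, na.rm = TRUE)) {
    abort("concentrations and pathlength must be non-negative")
  }
  out <- tibble(guest_M = guest_M, host_M = host_M, pathlength_cm = pathlength_cm)
  class(out) <- c("solution_spec", class(out))
  out
}

## ---- file I/O ---------------------------------------------------------------

parse_header_block <- function(lines) {
  hdr <- grep("^\\s*#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    h <- sub("^\\s*#\\s*", "", h)
    m <- regmatches(h, regexec("^([A-Za-z0-9_.-]+)\\s*[:=]\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- trimws(m[3])
  }
  kv
}

#' Read a CD/UV spectrum from a plain-text file
#'
#' The file format is a header block of `# key: value` lines (recognised keys:
#' `unit`, `pathlength_cm`, `guest_M`, `host_M`) followed by two numeric
#' columns, wavelength (nm) and signal. The `csv` dialect separates columns
#' with commas; `jasco_text` with tabs or whitespace. Rows may be in either
#' wavelength order; the returned spectrum is ascending.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"jasco_text"`.
#' @param default_unit unit assumed when the header names none.
#' @return an `icd_spectrum`; header keys land in `attr(, "meta")`.
#' @export
read_spectrum <- function(path, dialect = c("csv", "jasco_text"),
                          default_unit = "ellipticity_mdeg") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines_trim <- trimws(lines)
  if (length(lines) == 0 || all(lines_trim == "")) {
    abort(sprintf("parse error in %s: empty file", path))
  }
  meta <- parse_header_block(lines)
  is_data <- !grepl("^\\s*#", lines) & lines_trim != ""
  data_lines <- lines[is_data]
  data_lineno <- which(is_data)
  if (length(data_lines) == 0) abort(sprintf("parse error in %s: no data rows", path))
  sep <- if (dialect == "csv") "," else "[\t ]+"
  parts <- strsplit(trimws(data_lines), sep)
  wl <- numeric(length(parts)); val <- numeric(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]][nzchar(parts[[i]])]
    nums <- suppressWarnings(as.numeric(p))
    if (length(nums) < 2 || any(is.na(nums[1:2]))) {
      abort(sprintf("parse error in %s at line %d: non-numeric row %s",
                    path, data_lineno[i], dQuote(data_lines[i])))
    }
    wl[i] <- nums[1]; val[i] <- nums[2]
  }
  unit <- meta$unit %||% default_unit
  pl <- suppressWarnings(as.numeric(meta$pathlength_cm %||% NA))
  new_spectrum(wl, val, unit = unit, pathlength_cm = pl, meta = meta)
}

#' Write a spectrum to a plain-text file
#'
#' Inverse of [read_spectrum()]: values are serialised with 17 significant
#' digits so that a csv round-trip reproduces them bit for bit.
#'
#' @param s an `icd_spectrum`.
#' @param path output path.
#' @param dialect `"csv"` or `"jasco_text"`.
#' @export
write_spectrum <- function(s, path, dialect = c("csv", "jasco_text")) {
  dialect <- match.arg(dialect)
  assert_spectrum(s, min_points = 1L)
  hdr <- c(sprintf("# unit: %s", spectrum_unit(s)))
  if (is.finite(spectrum_pathlength(s))) {
    hdr <- c(hdr, sprintf("# pathlength_cm: %s", format(spectrum_pathlength(s), digits = 17)))
  }
  meta <- attr(s, "meta")
  for (k in setdiff(names(meta), c("unit", "pathlength_cm"))) {
    hdr <- c(hdr, sprintf("# %s: %s", k, as.character(meta[[k]])))
  }
  sep <- if (dialect == "csv") "," else "\t"
  rows <- paste(formatC(s$wavelength, digits = 17, format = "g"),
                formatC(s$value, digits = 17, format = "g"), sep = sep)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

## ---- unit conversion --------------------------------------------------------

unit_family <- function(unit) {
  switch(unit,
         ellipticity_mdeg = , delta_absorbance = , delta_epsilon = "cd",
         absorbance = , molar_absorption = "abs")
}

# factor taking a unit to its family's "absorbance-like" base
# (delta_absorbance for CD, absorbance for UV); molar units need c*l.
to_base_factor <- function(unit, cl) {
  switch(unit,
         ellipticity_mdeg = 1 / MDEG_PER_DELTA_ABS,
         delta_absorbance = 1,
         absorbance = 1,
         delta_epsilon = cl,
         molar_absorption = cl)
}

#' Convert a spectrum between signal units
#'
#' Supported conversions stay within a channel family: ellipticity (mdeg)
#' <-> differential absorbance <-> differential molar absorption
#' (Delta-epsilon) on the CD side, and absorbance <-> molar absorption on
#' the UV side. Ellipticity and differential absorbance are related by the
#' fixed constant [MDEG_PER_DELTA_ABS]; molar units apply the Beer-Lambert
#' law `dA = Delta-epsilon * c * l` with `c` the total guest concentration.
#'
#' @param s an `icd_spectrum`.
#' @param target_unit one of [spectrum_units()] in the same family as `s`.
#' @param solution a [solution_spec()]; required (with `guest_M > 0` and a
#'   positive pathlength) whenever a molar unit is involved.
#' @return the converted `icd_spectrum`.
#' @export
convert_units <- function(s, target_unit, solution = NULL) {
  assert_spectrum(s, min_points = 1L)
  from <- spectrum_unit(s)
  target_unit <- match.arg(target_unit, spectrum_units())
  if (identical(from, target_unit)) return(s)
  if (!identical(unit_family(from), unit_family(target_unit))) {
    abort(sprintf("unsupported unit conversion: %s -> %s (different channel families)",
                  from, target_unit))
  }
  molar <- c("delta_epsilon", "molar_absorption")
  needs_cl <- from %in% molar || target_unit %in% molar
  cl <- NA_real_
  if (needs_cl) {
    if (is.null(solution)) {
      abort(sprintf("conversion %s -> %s needs a `solution` (guest concentration and pathlength)",
                    from, target_unit))
    }
    cc <- solution$guest_M[1]
    ll <- solution$pathlength_cm[1]
    if (!is.finite(ll) || ll <= 0) ll <- spectrum_pathlength(s)
    if (!is.finite(cc) || cc <= 0) abort("guest concentration must be positive for molar conversions")
    if (!is.finite(ll) || ll <= 0) abort("pathlength must be positive for molar conversions")
    cl <- cc * ll
  }
  base <- s$value * to_base_factor(from, cl)
  out_val <- base / to_base_factor(target_unit, cl)
  with_spectrum_values(s, out_val, unit = target_unit)
}

## ---- smoothing --------------------------------------------------------------

grid_is_uniform <- function(wl, rel_tol = 1e-8) {
  d <- diff(wl)
  h <- stats::median(d)
  all(abs(d - h) <= rel_tol * abs(h))
}

resample_uniform <- function(s) {
  h <- stats::median(diff(s$wavelength))
  grid <- seq(min(s$wavelength), max(s$wavelength), by = h)
  v <- stats::approx(s$wavelength, s$value, xout = grid)$y
  new_spectrum(grid, v, unit = spectrum_unit(s),
               pathlength_cm = spectrum_pathlength(s), meta = attr(s, "meta"))
}

#' FFT low-pass smoothing of a spectrum
#'
#' Zeroes all Fourier components above `cutoff_fraction` of the Nyquist
#' frequency of the (uniform) wavelength grid and inverts the transform.
#' The DC component is always kept, so the signal mean is preserved, and
#' the filter is idempotent at a fixed cutoff.
#'
#' @param s an `icd_spectrum` on a uniform grid.
#' @param cutoff_fraction retained bandwidth as a fraction of Nyquist,
#'   in (0, 1]. Default 0.15.
#' @param resample if `TRUE`, a non-uniform grid is first linearly resampled
#'   to its median step; default is to error on non-uniform grids.
#' @return the smoothed `icd_spectrum` (on the resampled grid if resampling
#'   was requested).
#' @export
fft_lowpass <- function(s, cutoff_fraction = 0.15, resample = FALSE) {
  assert_spectrum(s)
  if (!is.numeric(cutoff_fraction) || cutoff_fraction <= 0 || cutoff_fraction > 1) {
    abort("`cutoff_fraction` must be in (0, 1]")
  }
  if (!grid_is_uniform(s$wavelength)) {
    if (!resample) {
      abort("non-uniform wavelength grid; pass `resample = TRUE` to interpolate to the median step")
    }
    s <- resample_uniform(s)
  }
  n <- nrow(s)
  ft <- stats::fft(s$value)
  k <- 0:(n - 1)
  frac <- pmin(k, n - k) / (n / 2)
  ft[frac > cutoff_fraction] <- 0
  smoothed <- Re(stats::fft(ft, inverse = TRUE)) / n
  with_spectrum_values(s, smoothed)
}

## ---- band maximum -----------------------------------------------------------

#' Locate a band maximum with sub-grid precision
#'
#' Finds the grid maximum inside `window` and refines it by the vertex of the
#' parabola through that point and its two neighbours. Ties go to the lower
#' wavelength. A maximum sitting on the window edge cannot be refined; it is
#' returned as-is with attribute `edge = TRUE` and a warning.
#'
#' @param s an `icd_spectrum`.
#' @param window length-2 numeric wavelength interval (nm); defaults to the
#'   full grid.
#' @return the band-maximum wavelength (nm) with logical attribute `edge`.
#' @export
find_lambda_max <- function(s, window = NULL) {
  assert_spectrum(s)
  window <- window %||% range(s$wavelength)
  keep <- which(s$wavelength >= min(window) & s$wavelength <= max(window))
  if (length(keep) == 0) abort("window does not overlap the wavelength grid")
  wl <- s$wavelength[keep]; v <- s$value[keep]
  i <- which.max(v)  # first maximum = lower-wavelength tie rule
  if (i == 1 || i == length(v)) {
    warn(sprintf("edge maximum at %g nm: band maximum lies on the window boundary", wl[i]))
    return(structure(wl[i], edge = TRUE))
  }
  x <- wl[(i - 1):(i + 1)] - wl[i]
  y <- v[(i - 1):(i + 1)]
  # quadratic through three points; vertex of a*x^2 + b*x + c
  co <- solve(cbind(x^2, x, 1), y)
  vertex <- if (co[1] < 0) -co[2] / (2 * co[1]) else 0
  # clamp to the bracketing interval in degenerate (flat) cases
  vertex <- min(max(vertex, x[1]), x[3])
  structure(wl[i] + vertex, edge = FALSE)
}
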