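## Synthetic data: titration series from a known 1:1 equilibrium with
## Gaussian CD/UV bands, and toy cyclodextrin geometries for the sign rules.
## These generators define the simulated study conditions; every downstream
## stage (smoothing, fitting, decomposition, sign prediction) is exercised
## against them without any instrument or quantum-chemistry output.

#' Gaussian band specification
#'
#' @param center band centre (nm).
#' @param width Gaussian sigma (nm), positive.
#' @param amplitude peak amplitude in the channel's molar units
#'   (Delta-epsilon for CD -- may be negative -- or epsilon for UV).
#' @return a tibble with one row per band.
#' @export
band <- function(center, width, amplitude) {
  if (any(width <= 0)) rlang::abort("band width must be positive")
  if (any(!is.finite(amplitude))) rlang::abort("band amplitude must be finite")
  tibble::tibble(center = as.numeric(center), width = as.numeric(width),
                 amplitude = as.numeric(amplitude))
}

# sum-of-Gaussians profile on a wavelength grid
band_profile <- function(wavelength, bands) {
  v <- numeric(length(wavelength))
  for (i in seq_len(nrow(bands))) {
    v <- v + bands$amplitude[i] *
      exp(-0.5 * ((wavelength - bands$center[i]) / bands$width[i])^2)
  }
  v
}

#' Titration scenario specification
#'
#' Bundles everything needed to simulate a constant-guest titration: the true
#' association constant, the solution design (guest concentration, host:guest
#' ratios, pathlength), the free and complexed UV bands (the complex band
#' carries the bathochromic shift), the complex-only CD bands, the wavelength
#' grid, and the noise level. Noise is additive Gaussian, independent per
#' wavelength, with standard deviation `noise_frac` times the peak absolute
#' clean signal of the channel across the whole series; any non-zero noise
#' requires a seed.
#'
#' Defaults are fenoprofen-like: guest 4e-4 M, free UV band at 270.6 nm with
#' a ~3 nm red-shifted, hyperchromic complex band, a structured complex-only
#' CD band peaking at 280.6 nm, and true log10 K = 3.06.
#'
#' @param true_logK generating log10 association constant.
#' @param guest_M total guest concentration (M).
#' @param host_ratios host:guest ratios of the titration points.
#' @param pathlength_cm cell pathlength (cm).
#' @param uv_free_bands,uv_complex_bands [band()] tables (epsilon, 1/M/cm).
#' @param cd_complex_bands [band()] table (Delta-epsilon, 1/M/cm).
#' @param grid wavelength grid (nm).
#' @param noise_frac Gaussian noise sd as a fraction of the peak clean signal.
#' @param seed RNG seed; mandatory when `noise_frac > 0`.
#' @return a list of class `icd_scenario`.
#' @export
scenario <- function(true_logK = 3.06,
                     guest_M = 4e-4,
                     host_ratios = c(0, 1, 2, 5, 10, 20),
                     pathlength_cm = 1,
                     uv_free_bands = band(270.6, 9, 1400),
                     uv_complex_bands = band(273.6, 9, 1750),
                     cd_complex_bands = band(c(274.6, 280.6), c(3, 4), c(1.0, 1.5)),
                     grid = seq(240, 320, by = 0.5),
                     noise_frac = 0,
                     seed = NULL) {
  if (any(host_ratios < 0)) rlang::abort("host ratios must be non-negative")
  if (guest_M <= 0) rlang::abort("guest_M must be positive")
  if (noise_frac < 0) rlang::abort("noise_frac must be non-negative")
  if (noise_frac > 0 && is.null(seed)) {
    rlang::abort("a seed is mandatory for noisy scenarios (reproducibility)")
  }
  structure(list(true_logK = true_logK, guest_M = guest_M,
                 host_ratios = sort(host_ratios), pathlength_cm = pathlength_cm,
                 uv_free_bands = uv_free_bands, uv_complex_bands = uv_complex_bands,
                 cd_complex_bands = cd_complex_bands, grid = grid,
                 noise_frac = noise_frac, seed = seed),
            class = "icd_scenario")
}

#' Fenoprofen-like scenario at the published solution design
#'
#' The three-point design actually measured for fenoprofen: guest 0.4 mM,
#' host:guest ratios 1:0, 1:5, 1:20, 1 cm cell, ~3 nm bathochromic UV shift.
#' @param ... overrides passed to [scenario()].
#' @export
fenoprofen_scenario <- function(...) {
  scenario(host_ratios = c(0, 5, 20), ...)
}

#' Nimesulide-like scenario
#'
#' Long-wavelength nitrophenyl band at 391.4 nm with a ~10 nm bathochromic,
#' hyperchromic shift on complexation; ratios 1:0, 1:5, 1:25, 1:30.
#' @param ... overrides passed to [scenario()].
#' @export
nimesulide_scenario <- function(...) {
  scenario(host_ratios = c(0, 5, 25, 30),
           uv_free_bands = band(391.4, 14, 1600),
           uv_complex_bands = band(401.4, 14, 2100),
           cd_complex_bands = band(400, 8, -1.2),
           grid = seq(340, 460, by = 0.5),
           ...)
}

#' Simulate a constant-guest titration series
#'
#' For each host:guest ratio the 1:1 speciation is computed with the true K;
#' the CD point is the complex-only ICD response and the UV point the
#' mole-fraction-weighted mixture of free and complexed guest. Seeded
#' Gaussian noise is added last. Solution metadata is embedded in every
#' spectrum so the fitters can run blind.
#'
#' @param sc an [scenario()].
#' @return a list with `cd` and `uv` [titration_series()] objects and the
#'   scenario attached as attribute `scenario`.
#' @export
generate_titration <- function(sc) {
  if (!inherits(sc, "icd_scenario")) rlang::abort("expected an `icd_scenario`")
  K <- 10^sc$true_logK
  hosts <- sc$host_ratios * sc$guest_M
  eps_free <- new_spectrum(sc$grid, band_profile(sc$grid, sc$uv_free_bands),
                           unit = "molar_absorption")
  eps_cx <- new_spectrum(sc$grid, band_profile(sc$grid, sc$uv_complex_bands),
                         unit = "molar_absorption")
  deps_cx <- new_spectrum(sc$grid, band_profile(sc$grid, sc$cd_complex_bands),
                          unit = "delta_epsilon")
  mk_point <- function(H) {
    sp <- speciate(sc$guest_M, H, K)
    list(cd = icd_response(deps_cx, sp, sc$pathlength_cm),
         uv = uv_mixture(eps_free, eps_cx, sp, sc$pathlength_cm))
  }
  pts <- purrr::map(hosts, mk_point)
  cd_vals <- purrr::map(pts, ~ .x$cd$value)
  uv_vals <- purrr::map(pts, ~ .x$uv$value)
  if (sc$noise_frac > 0) {
    sd_cd <- sc$noise_frac * max(abs(unlist(cd_vals)))
    sd_uv <- sc$noise_frac * max(abs(unlist(uv_vals)))
    set.seed(sc$seed)
    cd_vals <- purrr::map(cd_vals, ~ .x + stats::rnorm(length(.x), 0, sd_cd))
    uv_vals <- purrr::map(uv_vals, ~ .x + stats::rnorm(length(.x), 0, sd_uv))
  }
  mk_series <- function(vals, unit) {
    spectra <- purrr::map2(vals, hosts, function(v, H) {
      new_spectrum(sc$grid, v, unit = unit, pathlength_cm = sc$pathlength_cm,
                   meta = list(guest_M = sc$guest_M, host_M = H))
    })
    titration_series(spectra, guest_M = sc$guest_M, host_M = hosts,
                     pathlength_cm = sc$pathlength_cm)
  }
  out <- list(cd = mk_series(cd_vals, "delta_absorbance"),
              uv = mk_series(uv_vals, "absorbance"))
  attr(out, "scenario") <- sc
  out
}

## ---- toy geometries ---------------------------------------------------------

#' Generate a toy cyclodextrin oxygen scaffold
#'
#' An idealised macrocycle reduced to its oxygen scaffolding: `n_units`
#' glycosidic O4 atoms equally spaced on a circle in the z = 0 plane, a
#' primary-rim O6 ring below it (narrow side, smaller radius) and a
#' secondary-rim O2/O3 double ring above it (wide side, larger radius).
#' Optional seeded Gaussian jitter perturbs all coordinates.
#'
#' @param n_units number of glucose units (7 for beta-cyclodextrin), >= 3.
#' @param ring_radius O4 ring radius (A).
#' @param rim_offset axial distance of the rims from the O4 plane (A).
#' @param rim_dr radial contraction/expansion of the narrow/wide rims (A).
#' @param jitter Gaussian sd (A) applied to every coordinate.
#' @param seed RNG seed, mandatory when `jitter > 0`.
#' @return a [host_geometry()].
#' @export
generate_toy_cyclodextrin <- function(n_units = 7, ring_radius = 5.0,
                                      rim_offset = 2.0, rim_dr = 0.8,
                                      jitter = 0, seed = NULL) {
  if (n_units < 3) rlang::abort("n_units must be >= 3")
  if (jitter > 0 && is.null(seed)) rlang::abort("a seed is mandatory for jittered geometries")
  ang <- 2 * pi * (seq_len(n_units) - 1) / n_units
  ring <- function(r, z, nm, dphi = 0) {
    tibble::tibble(name = nm, resid = "GLC", resno = seq_len(n_units),
                   x = r * cos(ang + dphi), y = r * sin(ang + dphi), z = z)
  }
  atoms <- dplyr::bind_rows(
    ring(ring_radius, 0, "O4"),
    ring(ring_radius - rim_dr, -rim_offset, "O6"),
    ring(ring_radius + rim_dr, +rim_offset, "O2", dphi = -0.15),
    ring(ring_radius + rim_dr, +rim_offset, "O3", dphi = +0.15))
  if (jitter > 0) {
    set.seed(seed)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, jitter)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, jitter)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, jitter)
  }
  host_geometry(atoms)
}

#' Generate a placeholder guest chromophore with a transition dipole
#'
#' A small rigid three-atom marker whose centroid sits exactly at `position`
#' (relative to the toy cavity origin), carrying a transition dipole of the
#' requested magnitude at angle `dipole_theta` to the +z cavity axis (tilted
#' in the xz-plane).
#'
#' @param position xyz offset of the chromophore centroid (A).
#' @param dipole_theta angle between dipole and +z axis (degrees).
#' @param magnitude dipole magnitude (Debye), positive.
#' @param resid residue name for the guest atoms.
#' @return list with `atoms` (tibble) and `dipole` (xyz, Debye).
#' @export
generate_guest <- function(position = c(0, 0, 0), dipole_theta = 0,
                           magnitude = 1, resid = "LIG") {
  if (magnitude <= 0) rlang::abort("dipole magnitude must be positive")
  position <- as.numeric(position)
  # equilateral triangle of side ~1 A centred exactly on `position`
  tri <- rbind(c(0.5, 0, 0), c(-0.25, 0.433, 0), c(-0.25, -0.433, 0))
  atoms <- tibble::tibble(name = c("GC1", "GC2", "GC3"), resid = resid, resno = 1L,
                          x = position[1] + tri[, 1],
                          y = position[2] + tri[, 2],
                          z = position[3] + tri[, 3])
  th <- dipole_theta * pi / 180
  list(atoms = atoms,
       dipole = magnitude * c(sin(th), 0, cos(th)))
}

#' Write a host (+ optional guest) as a PDB file
#'
#' @param host a [host_geometry()].
#' @param file output path.
#' @param guest optional guest atom tibble (e.g. from [generate_guest()]).
#' @return the path, invisibly.
#' @export
write_complex_pdb <- function(host, file, guest = NULL) {
  atoms <- host$atoms
  if (!is.null(guest)) atoms <- dplyr::bind_rows(atoms, guest)
  xyz <- as.vector(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(file = file, xyz = xyz, type = "HETATM",
                   resno = atoms$resno, resid = atoms$resid,
                   elety = atoms$name, chain = "A")
  invisible(file)
}
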