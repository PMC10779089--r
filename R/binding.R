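#' 1:1 host-guest speciation by mass action
#'
#' Solves the 1:1 equilibrium `host + guest <-> complex` with association
#' constant `K = [complex] / ([guest][host])` under mass conservation. The
#' complex concentration is the physical root of `K (G - c)(H - c) = c`,
#' evaluated in the cancellation-safe form `c = 2 G H / (S + sqrt(S^2 - 4 G H))`
#' with `S = G + H + 1/K`, so it stays accurate at both weak- and
#' strong-binding extremes.
#'
#' @param guest_total,host_total total concentrations (mol/L); vectors recycle.
#' @param K association constant (1/M); `K = 0` gives no complex.
#' @return a tibble with columns `free_guest`, `free_host`, `complex` (mol/L).
#' @export
speciate <- function(guest_total, host_total, K) {
  n <- max(length(guest_total), length(host_total), length(K))
  G <- rep_len(as.numeric(guest_total), n)
  H <- rep_len(as.numeric(host_total), n)
  K <- rep_len(as.numeric(K), n)
  if (any(G < 0) || any(H < 0) || any(K < 0)) {
    rlang::abort("guest_total, host_total and K must be non-negative")
  }
  cx <- numeric(n)
  pos <- K > 0 & G > 0 & H > 0
  if (any(pos)) {
    S <- G[pos] + H[pos] + 1 / K[pos]
    disc <- sqrt(pmax(S^2 - 4 * G[pos] * H[pos], 0))
    cx[pos] <- 2 * G[pos] * H[pos] / (S + disc)
  }
  cx <- pmin(cx, G, H)
  tibble::tibble(free_guest = G - cx, free_host = H - cx, complex = cx)
}

#' ICD spectrum of the complex at a given speciation
#'
#' The measured ICD signal is proportional only to the complex concentration:
#' `dA(lambda) = Delta-epsilon_complex(lambda) * [complex] * l`.
#'
#' @param delta_eps_complex an `icd_spectrum` in `delta_epsilon` units: the
#'   per-molar CD band(s) of the complexed guest.
#' @param species one row of [speciate()] output (or anything with a
#'   `complex` column).
#' @param pathlength_cm cell pathlength (cm), positive.
#' @return an `icd_spectrum` in `delta_absorbance` units.
#' @export
icd_response <- function(delta_eps_complex, species, pathlength_cm = 1) {
  assert_spectrum(delta_eps_complex, min_points = 1L)
  if (pathlength_cm <= 0) rlang::abort("pathlength must be positive")
  cx <- species$complex[1]
  new_spectrum(delta_eps_complex$wavelength,
               delta_eps_complex$value * cx * pathlength_cm,
               unit = "delta_absorbance", pathlength_cm = pathlength_cm)
}

#' Two-state UV mixture spectrum
#'
#' The UV absorbance of a partially complexed solution is the
#' mole-fraction-weighted combination of the free and complexed guest:
#' `A(lambda) = (eps_free * [free guest] + eps_complex * [complex]) * l`.
#'
#' @param eps_free,eps_complex `icd_spectrum` objects in `molar_absorption`
#'   units on a common wavelength grid.
#' @param species one row of [speciate()] output.
#' @param pathlength_cm cell pathlength (cm).
#' @return an `icd_spectrum` in `absorbance` units.
#' @export
uv_mixture <- function(eps_free, eps_complex, species, pathlength_cm = 1) {
  assert_spectrum(eps_free, min_points = 1L)
  assert_spectrum(eps_complex, min_points = 1L)
  if (nrow(eps_free) != nrow(eps_complex) ||
      any(abs(eps_free$wavelength - eps_complex$wavelength) > 1e-9)) {
    rlang::abort("eps_free and eps_complex must share a wavelength grid")
  }
  if (pathlength_cm <= 0) rlang::abort("pathlength must be positive")
  A <- (eps_free$value * species$free_guest[1] +
          eps_complex$value * species$complex[1]) * pathlength_cm
  new_spectrum(eps_free$wavelength, A, unit = "absorbance",
               pathlength_cm = pathlength_cm)
}

#' Apparent band-maximum shift along a titration
#'
#' Evaluates the UV mixture model over a ladder of host concentrations and
#' reads off the apparent absorption maximum at each. With a red-shifted
#' complex band the apparent maximum drifts monotonically from the free-guest
#' maximum towards the complex maximum as the host concentration grows.
#'
#' @param eps_free,eps_complex component molar-absorption spectra.
#' @param guest_total total guest concentration (M).
#' @param host_totals vector of host concentrations (M).
#' @param K association constant (1/M).
#' @param pathlength_cm cell pathlength (cm).
#' @return a tibble with `host_M` and `lambda_max` (nm).
#' @export
shift_curve <- function(eps_free, eps_complex, guest_total, host_totals, K,
                        pathlength_cm = 1) {
  purrr::map_dfr(host_totals, function(H) {
    sp <- speciate(guest_total, H, K)
    A <- uv_mixture(eps_free, eps_complex, sp, pathlength_cm)
    tibble::tibble(host_M = H,
                   lambda_max = as.numeric(suppressWarnings(find_lambda_max(A))))
  })
}

## ---- fitting ----------------------------------------------------------------

new_binding_fit <- function(K, logK, K_stderr, logK_stderr, fitted_response,
                            residual_rms, n_points, converged, ill_conditioned,
                            method, saturation, data) {
  structure(list(K = K, logK = logK, K_stderr = K_stderr,
                 logK_stderr = logK_stderr, fitted_response = fitted_response,
                 residual_rms = residual_rms, n_points = n_points,
                 converged = converged, ill_conditioned = ill_conditioned,
                 method = method, saturation = saturation, data = data),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("1:1 binding fit (%s)\n", x$method))
  cat(sprintf("  K     = %.4g 1/M  (stderr %.3g)\n", x$K, x$K_stderr))
  cat(sprintf("  logK  = %.4f  (stderr %.3g)\n", x$logK, x$logK_stderr))
  cat(sprintf("  residual rms = %.4g over %d points; converged: %s\n",
              x$residual_rms, x$n_points, x$converged))
  if (isTRUE(x$ill_conditioned)) {
    cat("  warning: saturation-fraction range < 0.2; K is poorly determined\n")
  }
  invisible(x)
}

check_series_for_fit <- function(series) {
  if (!inherits(series, "icd_titration")) rlang::abort("expected an `icd_titration`")
  if (nrow(series) < 3) {
    rlang::abort(sprintf("at least 3 titration points are needed to fit K, got %d",
                         nrow(series)))
  }
  if (length(unique(series$host_M)) < 2) {
    rlang::abort("at least 2 distinct host concentrations are needed to fit K")
  }
  invisible(series)
}

saturation_range <- function(G, H, K) {
  f <- speciate(G, H, K)$complex / G
  diff(range(f))
}

#' Fit the association constant from a single-wavelength saturation curve
#'
#' Depicts the ICD intensity at one wavelength against the host concentration
#' (at constant guest concentration) and fits the 1:1 binding isotherm
#' `y_i = Delta-eps_c * c(G, H_i, K) * l_i` by nonlinear least squares over
#' `(log10 K, Delta-eps_c)`. The optimiser is multi-started from
#' `log10 K in {1, ..., 5}` and the best Levenberg-Marquardt solution is kept.
#'
#' A flat saturation curve carries no information on K; when the saturation
#' fraction spans less than 0.2 across the series the fit is flagged
#' `ill_conditioned` (reported, not fatal).
#'
#' @param series an `icd_titration` (CD channel).
#' @param wavelength readout wavelength (nm); the nearest grid point is used.
#' @param start_logK initial values for the multi-start.
#' @return a `binding_fit` with K, log10 K, standard errors (from the
#'   Jacobian), the fitted per-molar response at the readout wavelength,
#'   residual rms and diagnostics.
#' @export
fit_k_single_wavelength <- function(series, wavelength,
                                    start_logK = c(1, 2, 3, 4, 5)) {
  check_series_for_fit(series)
  pts <- titration_at(series, wavelength)
  y <- pts$value
  if (all(abs(y) < .Machine$double.eps * 10)) {
    rlang::abort("no binding signal: all observations are zero at this wavelength")
  }
  G <- pts$guest_M; H <- pts$host_M; l <- pts$pathlength_cm

  resid_fun <- function(par) {
    cx <- speciate(G, H, 10^par[1])$complex
    y - par[2] * cx * l
  }
  best <- NULL
  for (lk in start_logK) {
    cx0 <- speciate(G, H, 10^lk)$complex * l
    d0 <- sum(y * cx0) / max(sum(cx0^2), .Machine$double.xmin)
    fit <- try(minpack.lm::nls.lm(par = c(logK = lk, deps = d0), fn = resid_fun,
                                  control = minpack.lm::nls.lm.control(maxiter = 200)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) rlang::abort("saturation-curve fit failed from every start")
  par <- best$par
  K <- 10^par[["logK"]]
  n <- length(y)
  dof <- max(n - 2, 1)
  sigma2 <- best$deviance / dof
  cov <- try(sigma2 * solve(best$hessian), silent = TRUE)
  logK_se <- K_se <- NA_real_
  if (!inherits(cov, "try-error") && all(is.finite(diag(cov))) && all(diag(cov) >= 0)) {
    logK_se <- sqrt(cov[1, 1])
    K_se <- K * log(10) * logK_se  # delta method
  }
  cx <- speciate(G, H, K)$complex
  fitted_band <- tibble::tibble(wavelength = pts$wavelength[1],
                                delta_eps = par[["deps"]])
  new_binding_fit(
    K = K, logK = log10(K), K_stderr = K_se, logK_stderr = logK_se,
    fitted_response = fitted_band,
    residual_rms = sqrt(best$deviance / n),
    n_points = n,
    converged = !(best$info %in% c(0, 5)),  # 5 = iteration limit, 0 = bad input
    ill_conditioned = saturation_range(G, H, K) < 0.2,
    method = sprintf("single wavelength @ %.6g nm", pts$wavelength[1]),
    saturation = dplyr::mutate(pts, fitted = par[["deps"]] * cx * l),
    data = series)
}

#' Fit the association constant globally across all wavelengths
#'
#' Variable-projection fit of the full titration: for a trial K the
#' per-wavelength complex response `Delta-eps_c(lambda)` is the closed-form
#' linear least-squares solution, and the total residual is minimised over
#' `log10 K` on `[0, 6]` (coarse grid scan followed by golden-section
#' refinement). Because the CD signal is proportional to the complex alone,
#' this simultaneously recovers K and the complex-only CD band.
#'
#' @param series an `icd_titration` on a common wavelength grid.
#' @param logK_bounds search interval for log10 K.
#' @return a `binding_fit`; `fitted_response` holds the full fitted
#'   `Delta-eps_c(lambda)` band.
#' @export
fit_k_global <- function(series, logK_bounds = c(0, 6)) {
  check_series_for_fit(series)
  if (!isTRUE(attr(series, "common_grid"))) {
    rlang::abort("global fit needs all spectra on a common wavelength grid")
  }
  wl <- series$spectrum[[1]]$wavelength
  Y <- do.call(rbind, purrr::map(series$spectrum, "value"))  # points x wavelengths
  if (all(abs(Y) < .Machine$double.eps * 10)) {
    rlang::abort("no binding signal: all observations are zero")
  }
  G <- series$guest_M; H <- series$host_M; l <- series$pathlength_cm

  project <- function(logK) {
    x <- speciate(G, H, 10^logK)$complex * l
    xx <- sum(x^2)
    if (xx <= 0) return(list(rss = sum(Y^2), deps = rep(0, length(wl)), x = x))
    deps <- as.numeric(crossprod(x, Y)) / xx
    R <- Y - outer(x, deps)
    list(rss = sum(R^2), deps = deps, x = x)
  }
  grid <- seq(logK_bounds[1], logK_bounds[2], by = 0.25)
  rss <- vapply(grid, function(g) project(g)$rss, numeric(1))
  i <- which.min(rss)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(function(g) project(g)$rss, interval = c(lo, hi),
                         tol = 1e-10)
  # parabolic polish: optimize() bottoms out near sqrt(eps); two vertex steps
  # on the smooth profiled RSS push logK to ~1e-10
  logK <- opt$minimum
  for (h in c(1e-5, 1e-7)) {
    r <- vapply(logK + c(-h, 0, h), function(g) project(g)$rss, numeric(1))
    curv <- r[1] - 2 * r[2] + r[3]
    if (is.finite(curv) && curv > 0) {
      step <- -h / 2 * (r[3] - r[1]) / curv
      if (abs(step) < h * 10) logK <- logK + step
    }
  }
  sol <- project(logK)
  K <- 10^logK
  n_obs <- length(Y)
  dof <- max(n_obs - length(wl) - 1, 1)
  sigma2 <- sol$rss / dof
  # curvature of the profiled RSS in logK -> stderr of logK
  h <- 1e-4
  d2 <- (project(logK + h)$rss - 2 * sol$rss + project(logK - h)$rss) / h^2
  logK_se <- if (is.finite(d2) && d2 > 0) sqrt(2 * sigma2 / d2) else NA_real_
  K_se <- if (is.finite(logK_se)) K * log(10) * logK_se else NA_real_

  i_max <- which.max(abs(sol$deps))
  sat <- tibble::tibble(guest_M = G, host_M = H, pathlength_cm = l,
                        wavelength = wl[i_max], value = Y[, i_max],
                        fitted = sol$x * sol$deps[i_max])
  new_binding_fit(
    K = K, logK = logK, K_stderr = K_se, logK_stderr = logK_se,
    fitted_response = tibble::tibble(wavelength = wl, delta_eps = sol$deps),
    residual_rms = sqrt(sol$rss / n_obs),
    n_points = nrow(series),
    converged = TRUE,
    ill_conditioned = saturation_range(G, H, K) < 0.2,
    method = "global variable projection",
    saturation = sat,
    data = series)
}
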