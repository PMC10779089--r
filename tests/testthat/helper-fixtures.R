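# Shared fixtures and independent oracles.

# Bisection/uniroot oracle for the 1:1 mass-action equilibrium:
# the physical root of K (G - c)(H - c) = c on [0, min(G, H)].
oracle_complex <- function(G, H, K) {
  if (K == 0 || G == 0 || H == 0) return(0)
  f <- function(cc) K * (G - cc) * (H - cc) - cc
  stats::uniroot(f, c(0, min(G, H)), tol = .Machine$double.eps * min(G, H))$root
}

# Direct O(n^2) DFT low-pass oracle, independent of stats::fft.
oracle_dft_lowpass <- function(x, cutoff_fraction) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  X <- as.vector(W %*% x)
  X[pmin(k, n - k) / (n / 2) > cutoff_fraction] <- 0
  Re(as.vector(Conj(W) %*% X) / n)
}

# Uniformly random proper rotation matrix (QR of a Gaussian matrix).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  R %*% diag(c(1, 1, det(R)))
}

rigid_transform_host <- function(host, R, t) {
  xyz <- as.matrix(host$atoms[, c("x", "y", "z")]) %*% t(R)
  atoms <- host$atoms
  atoms$x <- xyz[, 1] + t[1]; atoms$y <- xyz[, 2] + t[2]; atoms$z <- xyz[, 3] + t[3]
  host_geometry(atoms)
}

# Gaussian test band on a uniform grid.
gaussian_spectrum <- function(center = 284.5, sigma = 6, amp = 1,
                              grid = seq(250, 320, by = 0.5),
                              unit = "delta_epsilon") {
  new_spectrum(grid, amp * exp(-0.5 * ((grid - center) / sigma)^2), unit = unit)
}

write_temp_spectrum_file <- function(lines) {
  tf <- tempfile(fileext = ".csv")
  writeLines(lines, tf)
  tf
}
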