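test_that("generated toy PDB round-trips with all three oxygen selections", {
  host <- generate_toy_cyclodextrin()
  guest <- generate_guest(c(0, 0, 0), dipole_theta = 0)
  tf <- tempfile(fileext = ".pdb")
  write_complex_pdb(host, tf, guest = guest$atoms)
  parsed <- parse_structure(tf, guest_resid = "LIG")
  expect_length(parsed$host$o4, 7)
  expect_length(parsed$host$o6, 7)
  expect_length(parsed$host$o23, 14)
  expect_identical(nrow(parsed$guest), 3L)

  tf2 <- tempfile(fileext = ".pdb")
  write_complex_pdb(host, tf2)
  expect_warning(p2 <- parse_structure(tf2), "no guest atoms")
  expect_identical(nrow(p2$guest), 0L)
})

test_that("oxygen name dialects are normalised and thin rings are rejected", {
  ty <- icdbind:::oxygen_type(c("O4", "o4", "O4'", "O44", "O6", "O62", "O2", "O3*", "C1", "OXT"))
  expect_identical(ty, c("4", "4", "4", "4", "6", "6", "2", "3", NA, NA))

  two <- host_geometry(tibble::tibble(name = c("O4", "O4", "O6"),
                                      resid = "GLC", resno = 1:3,
                                      x = c(0, 1, 0), y = c(0, 0, 1), z = 0))
  expect_error(fit_cavity_axis(two), "at least 3 glycosidic")
})

test_that("cavity frame of an ideal ring is exact", {
  host <- generate_toy_cyclodextrin(n_units = 7, ring_radius = 5.0)
  fr <- fit_cavity_axis(host)
  expect_equal(abs(fr$axis[3]), 1, tolerance = 1e-12)
  expect_equal(fr$axis[3], 1)  # wide rim (O2/O3) is at +z: narrow -> wide = +z
  expect_equal(fr$origin, c(0, 0, 0), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fr$ring_radius, 5.0, tolerance = 1e-9)
  expect_equal(fr$planarity_rms, 0, tolerance = 1e-12)
  expect_true(fr$oriented)
})

test_that("cavity frame is equivariant under rigid motions", {
  host <- generate_toy_cyclodextrin()
  fr0 <- fit_cavity_axis(host)
  set.seed(99)
  for (i in 1:5) {
    R <- random_rotation(); t <- rnorm(3, 0, 10)
    fr <- fit_cavity_axis(rigid_transform_host(host, R, t))
    expect_equal(fr$origin, as.numeric(R %*% fr0$origin + t), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(fr$axis, as.numeric(R %*% fr0$axis), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(fr$ring_radius, fr0$ring_radius, tolerance = 1e-9)
  }
})

test_that("planarity rms tracks seeded out-of-plane jitter and collinear rings error", {
  host <- generate_toy_cyclodextrin(jitter = 0.2, seed = 4)
  fr <- fit_cavity_axis(host)
  expect_gt(fr$planarity_rms, 0)
  expect_lt(fr$planarity_rms, 0.2 * 2)  # same order as the jitter sd

  line <- host_geometry(tibble::tibble(name = "O4", resid = "GLC", resno = 1:5,
                                       x = 1:5, y = 2 * (1:5), z = 3 * (1:5)))
  expect_error(fit_cavity_axis(line), "collinear")
})

test_that("inside/outside classification applies closed cavity bounds", {
  fr <- fit_cavity_axis(generate_toy_cyclodextrin())
  expect_identical(classify_position(c(0, 0, 0), fr), "inside")
  expect_identical(classify_position(c(0, 0, 10), fr), "outside")
  expect_identical(classify_position(c(8, 0, 0), fr), "outside")
  # boundary is closed: exactly on the ring radius, axial 0 -> inside
  expect_identical(classify_position(c(fr$ring_radius, 0, 0), fr, radial_margin = 1.0),
                   "inside")
  expect_identical(classify_position(c(0, 0, 4.0), fr, half_height = 4.0), "inside")
})

test_that("dipole angle is folded to [0, 90] about the cavity axis", {
  fr <- fit_cavity_axis(generate_toy_cyclodextrin())
  expect_equal(dipole_angle(c(0, 0, 2.3), fr), 0, tolerance = 1e-9)
  expect_equal(dipole_angle(c(0, 0, -2.3), fr), 0, tolerance = 1e-9)  # axis-sign-free
  expect_equal(dipole_angle(c(1.2, 0, 0), fr), 90, tolerance = 1e-9)
  expect_equal(dipole_angle(c(1, 0, 1), fr), 45, tolerance = 1e-9)
  expect_error(dipole_angle(c(0, 0, 0), fr), "zero")
})

test_that("dipole magnitudes reproduce every tabulated TDDFT total", {
  tab <- transition_dipole_table()
  expect_identical(nrow(tab), 9L)
  mags <- dipole_magnitude(tab[, c("X", "Y", "Z")])
  expect_true(all(abs(mags - tab$Total) <= 5e-4))
  # spot-check the two frozen rows
  expect_equal(dipole_magnitude(c(0.0917, -0.5624, -0.4419)), 0.7211, tolerance = 5e-4)
  expect_equal(dipole_magnitude(c(-0.5166, -0.3848, -1.3888)), 1.5309, tolerance = 5e-4)
  expect_equal(dipole_magnitude(c(0, 0, 0)), 0)
})

test_that("the sign rule follows the inside/outside x parallel/perpendicular table", {
  expect_identical(kodaka_harata_sign("inside", 0)$predicted_sign, "positive")
  expect_identical(kodaka_harata_sign("inside", 90)$predicted_sign, "negative")
  expect_identical(kodaka_harata_sign("outside", 0)$predicted_sign, "negative")
  expect_identical(kodaka_harata_sign("outside", 90)$predicted_sign, "positive")
  expect_identical(kodaka_harata_sign("inside", 54.7)$predicted_sign, "indeterminate")
  expect_error(kodaka_harata_sign("inside", 120), "\\[0, 90\\]")
})

test_that("flipping location is an involution on non-indeterminate signs", {
  flip <- c(positive = "negative", negative = "positive")
  for (th in c(0, 10, 20, 30, 40, 48, 62, 70, 80, 90)) {
    a <- kodaka_harata_sign("inside", th)$predicted_sign
    b <- kodaka_harata_sign("outside", th)$predicted_sign
    if (a != "indeterminate") expect_identical(b, unname(flip[a]))
  }
})

test_that("orientation factor hits its closed-form limits", {
  expect_equal(kodaka_harata_sign("inside", 0)$orientation_factor, 1)
  expect_equal(kodaka_harata_sign("inside", 90)$orientation_factor, -0.5)
  expect_equal(kodaka_harata_sign("inside", MAGIC_ANGLE_DEG)$orientation_factor, 0,
               tolerance = 1e-12)
})

test_that("end-to-end sign prediction composes the geometric stages", {
  host <- generate_toy_cyclodextrin()
  run <- function(pos, theta) {
    g <- generate_guest(pos, dipole_theta = theta)
    tf <- tempfile(fileext = ".pdb")
    write_complex_pdb(host, tf, guest = g$atoms)
    predict_complex_sign(tf, g$dipole)
  }
  expect_identical(run(c(0, 0, 0), 0)$predicted_sign, "positive")
  expect_identical(run(c(0, 0, 10), 0)$predicted_sign, "negative")
  p20 <- run(c(0, 0, 0), 20)  # dipole locked to the axis well inside 54.7 deg
  expect_identical(p20$predicted_sign, "positive")
  expect_gt(p20$orientation_factor, 0)
  expect_equal(p20$theta, 20, tolerance = 1e-6)
})

test_that("sign predictions are invariant under rigid motions of the whole complex", {
  host <- generate_toy_cyclodextrin()
  g <- generate_guest(c(1, 0, 1), dipole_theta = 25)
  set.seed(5)
  base <- NULL
  for (i in 1:5) {
    R <- random_rotation(); t <- rnorm(3, 0, 20)
    h2 <- rigid_transform_host(host, R, t)
    atoms <- g$atoms
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
    atoms$x <- xyz[, 1] + t[1]; atoms$y <- xyz[, 2] + t[2]; atoms$z <- xyz[, 3] + t[3]
    pred <- predict_complex_sign(list(host = h2, guest = atoms),
                                 as.numeric(R %*% g$dipole))
    if (is.null(base)) base <- pred
    expect_identical(pred$predicted_sign, base$predicted_sign)
    expect_equal(pred$theta, base$theta, tolerance = 1e-9)
  }
  expect_equal(base$theta, 25, tolerance = 1e-9)
})
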