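## Cavity geometry and ICD sign prediction.
##
## The cyclodextrin cavity frame is anchored on the ring of glycosidic (O4)
## oxygens -- the most rigid, conformation-insensitive feature of the
## macrocycle. The cavity axis is the normal of their least-squares plane,
## oriented from the narrow (primary, O6) towards the wide (secondary, O2/O3)
## rim. The Kodaka-Harata rules then map the angle between a guest transition
## dipole and this axis, together with the inside/outside location of the
## chromophore, to the predicted ICD band sign.

# classify an atom name as a cyclodextrin oxygen type; tolerates dialects
# like O4', O44, o4* (type digit first, any unit suffix after)
oxygen_type <- function(name) {
  n <- toupper(gsub("[\"'*]", "", trimws(name)))
  m <- regmatches(n, regexec("^O([2346])[0-9]*$", n))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
}

#' Host geometry: atoms plus cyclodextrin oxygen selections
#'
#' @param atoms tibble with columns `name`, `resid`, `resno`, `x`, `y`, `z`
#'   (coordinates in Angstrom).
#' @return a list of class `host_geometry` with the atom table and index
#'   vectors `o4` (glycosidic), `o6` (primary rim), `o23` (secondary rim).
#' @export
host_geometry <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    rlang::abort("atoms need columns name, x, y, z")
  }
  if (!all(is.finite(unlist(atoms[c("x", "y", "z")])))) {
    rlang::abort("non-finite coordinates in host atoms")
  }
  ty <- oxygen_type(atoms$name)
  structure(list(atoms = atoms,
                 o4 = which(ty == "4"),
                 o6 = which(ty == "6"),
                 o23 = which(ty %in% c("2", "3"))),
            class = "host_geometry")
}

#' @export
print.host_geometry <- function(x, ...) {
  cat(sprintf("<host_geometry: %d atoms; O4: %d, O6: %d, O2/O3: %d>\n",
              nrow(x$atoms), length(x$o4), length(x$o6), length(x$o23)))
  invisible(x)
}

## ---- structure file parsing -------------------------------------------------

read_xyz_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) rlang::abort(sprintf("malformed XYZ file %s: fewer than 3 lines", path))
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) rlang::abort(sprintf("malformed XYZ file %s at line 1: atom count expected", path))
  body <- lines[seq(3, length.out = n)]
  parts <- strsplit(trimws(body), "[\t ]+")
  bad <- which(vapply(parts, length, integer(1)) < 4)
  if (length(bad)) {
    rlang::abort(sprintf("malformed XYZ record in %s at line %d", path, bad[1] + 2))
  }
  xyz <- t(vapply(parts, function(p) suppressWarnings(as.numeric(p[2:4])), numeric(3)))
  if (any(!is.finite(xyz))) {
    rlang::abort(sprintf("non-numeric coordinates in %s", path))
  }
  tibble::tibble(name = vapply(parts, `[`, character(1), 1),
                 resid = "MOL", resno = 1L,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

read_pdb_atoms <- function(path) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  tibble::tibble(name = a$elety, resid = a$resid, resno = a$resno,
                 x = a$x, y = a$y, z = a$z)
}

#' Parse a complex structure into host geometry and guest atoms
#'
#' Reads a PDB (via bio3d) or XYZ coordinate file and partitions the atoms
#' into cyclodextrin host and guest chromophore. For PDB input the guest is
#' selected by residue name (`guest_resid`, e.g. `"LIG"`); for XYZ input,
#' which carries no residue structure, guest atoms are selected by an atom
#' label prefix (`guest_prefix`). All remaining atoms form the host, whose
#' O4/O6/O2-O3 oxygen selections are matched case-insensitively across
#' common naming dialects.
#'
#' @param path PDB or XYZ file.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @param guest_resid residue name(s) identifying the guest (PDB).
#' @param guest_prefix atom-label prefix identifying the guest (XYZ).
#' @return list with `host` (a [host_geometry()]) and `guest` (atom tibble,
#'   possibly empty with a warning).
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "xyz"),
                            guest_resid = "LIG", guest_prefix = "G") {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(sprintf("structure file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  atoms <- if (format == "xyz") read_xyz_atoms(path) else read_pdb_atoms(path)
  is_guest <- if (format == "pdb") {
    toupper(atoms$resid) %in% toupper(guest_resid)
  } else {
    startsWith(toupper(atoms$name), toupper(guest_prefix))
  }
  guest <- atoms[is_guest, ]
  host <- host_geometry(atoms[!is_guest, ])
  if (length(host$o4) < 3) {
    rlang::abort(sprintf(
      "fewer than 3 glycosidic (O4) oxygens matched in host; available atom names: %s",
      paste(unique(host$atoms$name), collapse = ", ")))
  }
  if (nrow(guest) == 0) {
    rlang::warn("no guest atoms matched the selector; guest set is empty")
  }
  list(host = host, guest = guest)
}

## ---- cavity frame -----------------------------------------------------------

#' Fit the cavity frame from the glycosidic-oxygen ring
#'
#' The frame origin is the centroid of the glycosidic (O4) oxygens; the axis
#' is the unit normal of their least-squares plane (smallest principal
#' direction of the centred coordinate scatter). The axis sign is fixed by
#' the rim convention narrow -> wide: the centroid of the secondary-rim
#' (O2/O3) oxygens gets a positive axial coordinate. Without rim selections
#' the sign is arbitrary and the frame is flagged unoriented.
#'
#' @param host a [host_geometry()] with >= 3 non-collinear O4 oxygens.
#' @return a list of class `cavity_frame`: `origin` (A), unit `axis`,
#'   `ring_radius` (mean radial O4 distance, A), `planarity_rms` (rms O4
#'   out-of-plane deviation, A), `oriented` (logical).
#' @export
fit_cavity_axis <- function(host) {
  if (!inherits(host, "host_geometry")) rlang::abort("expected a `host_geometry`")
  if (length(host$o4) < 3) rlang::abort("axis fitting needs at least 3 glycosidic (O4) oxygens")
  P <- as.matrix(host$atoms[host$o4, c("x", "y", "z")])
  origin <- colMeans(P)
  C <- sweep(P, 2, origin)
  sv <- svd(C)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    rlang::abort("glycosidic oxygens are collinear; cavity plane is undefined")
  }
  axis <- sv$v[, 3]
  axis <- axis / sqrt(sum(axis^2))
  oriented <- length(host$o23) > 0
  if (oriented) {
    wide <- colMeans(as.matrix(host$atoms[host$o23, c("x", "y", "z")]))
    if (sum((wide - origin) * axis) < 0) axis <- -axis
  } else {
    rlang::warn("no secondary-rim (O2/O3) oxygens: axis sign is arbitrary")
  }
  axial <- C %*% axis
  radial <- sqrt(rowSums((C - axial %*% t(axis))^2))
  structure(list(origin = origin, axis = as.numeric(axis),
                 ring_radius = mean(radial),
                 planarity_rms = sqrt(mean(axial^2)),
                 oriented = oriented, n_ring = nrow(P)),
            class = "cavity_frame")
}

#' @export
print.cavity_frame <- function(x, ...) {
  cat(sprintf("<cavity_frame: origin (%.3f, %.3f, %.3f) A, axis (%.4f, %.4f, %.4f), ring radius %.3f A, planarity rms %.3f A%s>\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$axis[1], x$axis[2], x$axis[3],
              x$ring_radius, x$planarity_rms,
              if (x$oriented) "" else ", unoriented"))
  invisible(x)
}

#' Classify a point as inside or outside the cavity
#'
#' Inside means the point lies within `half_height` of the O4 plane along the
#' axis AND within `radial_margin * ring_radius` of the axis; both boundaries
#' are closed. Defaults reflect canonical beta-cyclodextrin dimensions
#' (cavity height ~ 8 A).
#'
#' @param point numeric xyz (A), e.g. a chromophore centroid.
#' @param frame a [fit_cavity_axis()] result.
#' @param half_height axial half-height of the cavity (A).
#' @param radial_margin radial bound as a multiple of the ring radius.
#' @return `"inside"` or `"outside"`.
#' @export
classify_position <- function(point, frame, half_height = 4.0, radial_margin = 1.0) {
  if (!inherits(frame, "cavity_frame")) rlang::abort("expected a `cavity_frame`")
  d <- as.numeric(point) - frame$origin
  ax <- sum(d * frame$axis)
  rad <- sqrt(max(sum(d^2) - ax^2, 0))
  if (abs(ax) <= half_height && rad <= radial_margin * frame$ring_radius) "inside" else "outside"
}

## ---- transition dipoles -----------------------------------------------------

#' Magnitude of a transition dipole moment
#'
#' Euclidean norm of the Cartesian components, in Debye.
#'
#' @param components numeric xyz vector, or a matrix/data frame with three
#'   columns (one dipole per row).
#' @return numeric magnitude(s) in Debye.
#' @export
dipole_magnitude <- function(components) {
  if (is.data.frame(components)) components <- as.matrix(components)
  if (is.matrix(components)) {
    if (ncol(components) != 3) rlang::abort("dipole matrix needs 3 columns")
    return(sqrt(rowSums(components^2)))
  }
  if (length(components) != 3 || !all(is.finite(components))) {
    rlang::abort("dipole components must be a finite xyz triple")
  }
  sqrt(sum(components^2))
}

#' Angle between a transition dipole and the cavity axis
#'
#' A dipole has no intrinsic sign, so the angle is folded to `[0, 90]`
#' degrees: `theta = acos(|d-hat . axis|)`.
#'
#' @param dipole numeric xyz components (Debye).
#' @param frame a [fit_cavity_axis()] result.
#' @return angle in degrees.
#' @export
dipole_angle <- function(dipole, frame) {
  if (!inherits(frame, "cavity_frame")) rlang::abort("expected a `cavity_frame`")
  d <- as.numeric(dipole)
  m <- dipole_magnitude(d)
  if (m <= 0) rlang::abort("zero transition dipole: angle undefined")
  cosang <- abs(sum(d * frame$axis)) / m
  acos(min(max(cosang, 0), 1)) * 180 / pi
}

## ---- sign rules -------------------------------------------------------------

#' The magic angle (degrees) where 3 cos^2(theta) - 1 = 0
#' @export
MAGIC_ANGLE_DEG <- acos(1 / sqrt(3)) * 180 / pi

#' Kodaka-Harata sign rule for an induced CD band
#'
#' For a chromophore inside the cavity, a transition dipole parallel to the
#' cavity axis gives a positive ICD band and a perpendicular dipole a
#' negative one; outside the cavity both signs reverse. The parallel /
#' perpendicular dichotomy is operationalised by the orientation factor
#' `(3 cos^2 theta - 1) / 2`, which changes sign at the magic angle
#' (54.7356 deg); angles within `magic_tol` of it are called indeterminate.
#'
#' @param location `"inside"` or `"outside"`.
#' @param theta dipole-axis angle in degrees, in `[0, 90]`.
#' @param magic_tol half-width (deg) of the indeterminate band around the
#'   magic angle.
#' @return a one-row tibble of class `sign_prediction`: `location`, `theta`,
#'   `orientation_factor`, `predicted_sign`.
#' @export
kodaka_harata_sign <- function(location, theta, magic_tol = 5) {
  location <- match.arg(location, c("inside", "outside"))
  if (!is.finite(theta) || theta < 0 || theta > 90) {
    rlang::abort("`theta` must be in [0, 90] degrees")
  }
  ofac <- (3 * cos(theta * pi / 180)^2 - 1) / 2
  sign <- if (abs(theta - MAGIC_ANGLE_DEG) <= magic_tol) {
    "indeterminate"
  } else if (theta < MAGIC_ANGLE_DEG) "positive" else "negative"
  if (location == "outside" && sign != "indeterminate") {
    sign <- if (sign == "positive") "negative" else "positive"
  }
  out <- tibble::tibble(location = location, theta = theta,
                        orientation_factor = ofac, predicted_sign = sign)
  class(out) <- c("sign_prediction", class(out))
  out
}

#' Predict the ICD band sign of a complex from structure and dipole
#'
#' End-to-end composition: parse the structure, fit the cavity frame from the
#' glycosidic-oxygen ring, classify the guest-chromophore centroid as inside
#' or outside, measure the dipole-axis angle, and apply the Kodaka-Harata
#' rule. The dipole components must be expressed in the same Cartesian frame
#' as the structure coordinates; no frame is guessed.
#'
#' @param structure path to a PDB/XYZ file, or a `parse_structure()` result.
#' @param dipole transition-dipole xyz components (Debye) in the structure
#'   frame.
#' @param guest_resid,guest_prefix guest selectors, see [parse_structure()].
#' @param half_height,radial_margin cavity bounds, see [classify_position()].
#' @param magic_tol see [kodaka_harata_sign()].
#' @return a `sign_prediction` tibble (one row) with the dipole magnitude and
#'   guest centroid added; the fitted `cavity_frame` is attached as attribute
#'   `frame`.
#' @export
predict_complex_sign <- function(structure, dipole, guest_resid = "LIG",
                                 guest_prefix = "G", half_height = 4.0,
                                 radial_margin = 1.0, magic_tol = 5) {
  parsed <- if (is.character(structure)) {
    parse_structure(structure, guest_resid = guest_resid, guest_prefix = guest_prefix)
  } else structure
  if (nrow(parsed$guest) == 0) rlang::abort("no guest atoms: cannot locate the chromophore")
  frame <- fit_cavity_axis(parsed$host)
  centroid <- colMeans(as.matrix(parsed$guest[, c("x", "y", "z")]))
  loc <- classify_position(centroid, frame, half_height, radial_margin)
  theta <- dipole_angle(dipole, frame)
  pred <- kodaka_harata_sign(loc, theta, magic_tol)
  pred$dipole_D <- dipole_magnitude(as.numeric(dipole))
  pred$centroid_x <- centroid[1]; pred$centroid_y <- centroid[2]; pred$centroid_z <- centroid[3]
  attr(pred, "frame") <- frame
  pred
}

#' Printed transition-dipole components for the four model drugs
#'
#' The nine tabulated transition dipole moments (Debye, Cartesian components
#' and total magnitude) for fenoprofen, fenbufen, nimesulide and bifonazole,
#' free in water and in their beta-cyclodextrin complexes, as obtained from
#' TDDFT calculations. Shipped as a plain-text table in `extdata`.
#'
#' @return a tibble with columns `system`, `X`, `Y`, `Z`, `Total` (Debye).
#' @export
transition_dipole_table <- function() {
  path <- system.file("extdata", "transition_dipoles.csv", package = "icdbind",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, check.names = TRUE))
}
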