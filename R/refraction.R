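#' Sphero-cylindrical refraction algebra
#'
#' Vectorized operations on sphero-cylindrical refractions written as
#' sphere / cylinder / axis (degrees) / vertex distance (mm). Refractions may
#' be in negative- or positive-cylinder notation; the sign of `cylinder`
#' carries the notation. Axes follow the clinical `(0, 180]` convention and an
#' entered axis of 0 is normalized to 180.
#'
#' `transpose_cylinder()` rewrites the same optical correction in the opposite
#' cylinder sign: the sphere absorbs the cylinder, the cylinder flips sign and
#' the axis rotates 90 degrees. Applying it twice returns the input.
#'
#' @param sphere,cylinder Numeric vectors, diopters (signed).
#' @param axis Numeric vector, degrees; normalized to `(0, 180]`.
#' @return A tibble with columns `sphere`, `cylinder`, `axis`.
#' @examples
#' transpose_cylinder(-1.00, -0.50, 90) # -1.50 +0.50 x 180
#' @export
transpose_cylinder <- function(sphere, cylinder, axis) {
  check_refraction(sphere, cylinder, axis)
  tibble::tibble(
    sphere   = sphere + cylinder,
    cylinder = -cylinder,
    axis     = normalize_axis(normalize_axis(axis) + 90)
  )
}

#' Propagate a refraction to another vertex plane
#'
#' Converts each principal meridian power independently to a new reference
#' plane: for a meridian power `F` measured at vertex `v` (mm), the power at
#' `target_vertex` is `F / (1 - d * F)` with `d = (v - target_vertex) / 1000`
#' meters. The cylinder at the new plane is the difference of the propagated
#' meridians; the axis does not change. Spectacle-plane refractions
#' (typically 12 mm) are brought to the corneal plane with
#' `target_vertex = 0`.
#'
#' @inheritParams transpose_cylinder
#' @param vertex Numeric vector, vertex distance of the input refraction, mm.
#' @param target_vertex Single number, destination plane in mm (default 0,
#'   the corneal plane).
#' @return A tibble with columns `sphere`, `cylinder`, `axis`, `vertex`.
#' @examples
#' propagate_vertex(-10, 0, 180, 12)  # sphere -8.93 at the cornea
#' @export
propagate_vertex <- function(sphere, cylinder, axis, vertex, target_vertex = 0) {
  check_refraction(sphere, cylinder, axis)
  stopifnot_scalar_number(target_vertex, "target_vertex")
  if (any(vertex < 0, na.rm = TRUE) || target_vertex < 0) {
    abort("Vertex distances must be >= 0 mm.")
  }
  d <- (vertex - target_vertex) / 1000
  f1 <- sphere
  f2 <- sphere + cylinder
  den1 <- 1 - d * f1
  den2 <- 1 - d * f2
  bad <- which(abs(den1) < 1e-9 | abs(den2) < 1e-9)
  if (length(bad)) {
    mer <- ifelse(abs(den1[bad[1]]) < 1e-9, "first (sphere)", "second (sphere + cylinder)")
    abort(paste0(
      "Vertex propagation is degenerate for the ", mer,
      " meridian at row ", bad[1], ": 1 - d*F is ~0."
    ))
  }
  f1p <- f1 / den1
  f2p <- f2 / den2
  tibble::tibble(
    sphere   = f1p,
    cylinder = f2p - f1p,
    axis     = normalize_axis(axis),
    vertex   = target_vertex
  )
}

#' Spherical equivalent (SEQ)
#'
#' The scalar defocus summary of a sphero-cylinder: sphere plus half the
#' cylinder. Invariant under cylinder transposition.
#'
#' @inheritParams transpose_cylinder
#' @return Numeric vector, diopters (signed).
#' @examples
#' spherical_equivalent(-2.00, -1.00) # -2.50
#' @export
spherical_equivalent <- function(sphere, cylinder) {
  sphere + cylinder / 2
}

#' Defocus equivalent (DEQ)
#'
#' An always-positive blur-burden summary: `|SEQ| + |cylinder| / 2`. Always at
#' least `|SEQ|`, with equality exactly when the cylinder is zero.
#'
#' @inheritParams transpose_cylinder
#' @return Numeric vector, diopters (>= 0).
#' @examples
#' defocus_equivalent(-1.00, -1.00) # 2.00
#' @export
defocus_equivalent <- function(sphere, cylinder) {
  abs(spherical_equivalent(sphere, cylinder)) + abs(cylinder) / 2
}

#' SEQ accuracy to intended target
#'
#' Signed difference between the achieved and intended spherical equivalent:
#' positive means overcorrected toward hyperopia relative to target.
#'
#' @param postop_sphere,postop_cylinder Achieved postoperative refraction.
#' @param target_sphere,target_cylinder Intended target refraction.
#' @return Numeric vector, diopters (signed).
#' @export
seq_error <- function(postop_sphere, postop_cylinder, target_sphere, target_cylinder) {
  spherical_equivalent(postop_sphere, postop_cylinder) -
    spherical_equivalent(target_sphere, target_cylinder)
}

check_refraction <- function(sphere, cylinder, axis) {
  n <- length(sphere)
  if (length(cylinder) != n || length(axis) != n) {
    abort("`sphere`, `cylinder` and `axis` must have equal length.")
  }
  invisible(NULL)
}
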