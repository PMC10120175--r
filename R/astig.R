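#' Doubled-angle astigmatism vectors
#'
#' Astigmatism is analyzed in doubled-angle space (the Alpins convention):
#' a magnitude/axis pair becomes the Cartesian vector
#' `(C cos 2a, C sin 2a)`. Addition and subtraction of astigmatic effects are
#' ordinary vector operations in this space, and the single-angle axis is
#' recovered as `atan2(y, x) / 2` mapped to `(0, 180]`.
#'
#' `double_angle()` expects the positive-cylinder magnitude and its axis;
#' convert negative-cylinder refractions with [transpose_cylinder()] first.
#'
#' @param magnitude Cylinder magnitude, diopters (>= 0, positive-cylinder
#'   convention).
#' @param axis Cylinder axis in degrees.
#' @return `double_angle()`: a tibble with components `x`, `y`.
#'   `vector_magnitude()` / `vector_axis()`: numeric vectors.
#' @examples
#' double_angle(1, 90)   # (-1, 0)
#' vector_axis(0, 1)     # 45
#' @export
double_angle <- function(magnitude, axis) {
  if (any(magnitude < 0, na.rm = TRUE)) {
    abort("Astigmatism magnitudes must be >= 0; transpose to positive cylinder first.")
  }
  theta <- 2 * axis * pi / 180
  tibble::tibble(x = magnitude * cos(theta), y = magnitude * sin(theta))
}

#' @rdname double_angle
#' @param x,y Doubled-angle vector components.
#' @export
vector_magnitude <- function(x, y) sqrt(x^2 + y^2)

#' @rdname double_angle
#' @export
vector_axis <- function(x, y) {
  normalize_axis((atan2(y, x) * 180 / pi / 2) %% 180)
}

#' Target- and surgically-induced astigmatism vectors
#'
#' The TIA is the intended astigmatic change, `vector(target) -
#' vector(preop)`; the SIA is the achieved change, `vector(postop) -
#' vector(preop)`; both in doubled-angle space. All refractions must be at
#' the corneal plane (vertex 0) in positive-cylinder form — propagate and
#' transpose first.
#'
#' @param preop,to Tibbles or data frames with columns `cylinder` (>= 0,
#'   positive-cylinder magnitude), `axis` (degrees) and `vertex` (must be 0).
#' @return A tibble with columns `x`, `y`, `magnitude`, `axis`.
#' @export
astig_change <- function(preop, to) {
  for (r in list(preop, to)) {
    if (!all(c("cylinder", "axis", "vertex") %in% names(r))) {
      abort("Refraction tables need `cylinder`, `axis` and `vertex` columns.")
    }
    if (any(abs(r$vertex) > 1e-9, na.rm = TRUE)) {
      abort("Astigmatism vectors are defined at the corneal plane; run propagate_vertex(..., target_vertex = 0) first.")
    }
  }
  from_v <- double_angle(preop$cylinder, preop$axis)
  to_v <- double_angle(to$cylinder, to$axis)
  x <- to_v$x - from_v$x
  y <- to_v$y - from_v$y
  tibble::tibble(
    x = x, y = y,
    magnitude = vector_magnitude(x, y),
    axis = vector_axis(x, y)
  )
}

#' Correction index and angle of error
#'
#' The correction index (CI) is `|SIA| / |TIA|`: 1 is a perfect magnitude
#' correction, above 1 an overcorrection. It is undefined (NA) when no
#' astigmatic change was intended (`|TIA| == 0`); such eyes are excluded from
#' the CI and angle-of-error panels and counted separately.
#'
#' The angle of error (AoE) is half the signed doubled-angle between the SIA
#' and TIA, in `(-90, 90]`: positive when the achieved correction axis lies
#' counterclockwise to the intended one. Undefined when either vector has
#' zero magnitude.
#'
#' @param tia,sia Tibbles with doubled-angle components `x`, `y` (as returned
#'   by [astig_change()]).
#' @return Numeric vector (NA where undefined).
#' @export
correction_index <- function(tia, sia) {
  tia_mag <- vector_magnitude(tia$x, tia$y)
  sia_mag <- vector_magnitude(sia$x, sia$y)
  ifelse(tia_mag > 1e-12, sia_mag / tia_mag, NA_real_)
}

#' @rdname correction_index
#' @export
angle_of_error <- function(tia, sia) {
  tia_mag <- vector_magnitude(tia$x, tia$y)
  sia_mag <- vector_magnitude(sia$x, sia$y)
  cross <- tia$x * sia$y - tia$y * sia$x
  dot <- tia$x * sia$x + tia$y * sia$y
  aoe <- atan2(cross, dot) * 180 / pi / 2
  aoe <- ifelse(aoe <= -90, aoe + 180, aoe)
  ifelse(tia_mag > 1e-12 & sia_mag > 1e-12, aoe, NA_real_)
}

# Corneal-plane, positive-cylinder astigmatism state for a block of
# refraction columns; prefix selects preop/target/postop columns.
corneal_astig <- function(data, prefix) {
  sph <- data[[paste0(prefix, "_sphere")]]
  cyl <- data[[paste0(prefix, "_cylinder")]]
  ax <- data[[paste0(prefix, "_axis")]]
  vx <- data[[paste0(prefix, "_vertex")]]
  at_cornea <- propagate_vertex(sph, cyl, ax, vx, target_vertex = 0)
  neg <- at_cornea$cylinder < 0
  pos <- at_cornea
  if (any(neg)) {
    t <- transpose_cylinder(at_cornea$sphere[neg], at_cornea$cylinder[neg], at_cornea$axis[neg])
    pos$sphere[neg] <- t$sphere
    pos$cylinder[neg] <- t$cylinder
    pos$axis[neg] <- t$axis
  }
  pos
}

#' Per-eye Alpins vector outcomes for a cohort
#'
#' Computes, for every eye, the TIA and SIA vectors, the postoperative
#' corneal-plane astigmatism magnitude, the correction index and the angle
#' of error, from the standard 20-column record layout. All refractions are
#' propagated to the corneal plane and transposed to positive cylinder
#' before any vector is formed.
#'
#' @param data A cohort tibble in the standard column layout (see
#'   [read_cohort()]).
#' @return The input with columns `tia_magnitude`, `tia_axis`,
#'   `sia_magnitude`, `sia_axis`, `postop_astig`, `correction_index`,
#'   `angle_of_error` appended.
#' @export
add_vector_outcomes <- function(data) {
  preop <- corneal_astig(data, "preop")
  target <- corneal_astig(data, "target")
  postop <- corneal_astig(data, "postop")
  tia <- astig_change(preop, target)
  sia <- astig_change(preop, postop)
  dplyr::mutate(
    data,
    tia_magnitude = tia$magnitude,
    tia_axis = tia$axis,
    sia_magnitude = sia$magnitude,
    sia_axis = sia$axis,
    postop_astig = postop$cylinder,
    correction_index = correction_index(tia, sia),
    angle_of_error = angle_of_error(tia, sia)
  )
}
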