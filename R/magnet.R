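#' Cylindrical stimulation magnet
#'
#' Geometry and remanence of an axially magnetised NdFeB cylinder. The
#' defaults describe a 45 mm diameter x 30 mm thick magnet of N45 grade
#' (nominal remanence 1.35 T), the class of device used for transcranial
#' static magnetic field stimulation.
#'
#' @param radius_mm Cylinder radius in mm (> 0).
#' @param length_mm Cylinder length (thickness) in mm (> 0).
#' @param br_t Remanence in tesla (> 0).
#' @return An object of class `magnet_spec`.
#' @export
magnet_spec <- function(radius_mm = 22.5, length_mm = 30, br_t = 1.35) {
  if (radius_mm <= 0 || length_mm <= 0 || br_t <= 0)
    stop("radius, length and remanence must all be positive")
  structure(list(radius_mm = radius_mm, length_mm = length_mm, br_t = br_t),
            class = "magnet_spec")
}

#' Axial magnetic field of a cylindrical magnet
#'
#' Closed form for the field on the cylinder axis at distance `z_mm` from
#' the pole face:
#' \deqn{B(z) = \frac{B_r}{2}\left[\frac{z+L}{\sqrt{(z+L)^2+R^2}} -
#'   \frac{z}{\sqrt{z^2+R^2}}\right]}
#' returned in millitesla. Strictly decreasing in `z`; at the pole face of
#' the default magnet it evaluates to exactly 540 mT.
#'
#' @param z_mm Axial distance(s) from the pole face in mm (>= 0).
#' @param magnet A [magnet_spec()].
#' @return Field in mT, same length as `z_mm`.
#' @export
axial_field <- function(z_mm, magnet = magnet_spec()) {
  if (any(z_mm < 0)) stop("'z_mm' must be non-negative")
  R <- magnet$radius_mm; L <- magnet$length_mm
  1000 * (magnet$br_t / 2) *
    ((z_mm + L) / sqrt((z_mm + L)^2 + R^2) - z_mm / sqrt(z_mm^2 + R^2))
}

#' Axial field gradient
#'
#' Analytic derivative of [axial_field()] with respect to `z`, in mT per
#' metre (negative for all `z >= 0`).
#'
#' @inheritParams axial_field
#' @return Gradient dB/dz in mT/m.
#' @export
axial_gradient <- function(z_mm, magnet = magnet_spec()) {
  if (any(z_mm < 0)) stop("'z_mm' must be non-negative")
  R <- magnet$radius_mm; L <- magnet$length_mm
  d_term <- function(u) R^2 / (u^2 + R^2)^(3 / 2)   # d/du [u/sqrt(u^2+R^2)]
  # field is in mT and z in mm; mT/mm * 1000 = mT/m
  1000 * 1000 * (magnet$br_t / 2) * (d_term(z_mm + L) - d_term(z_mm))
}
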