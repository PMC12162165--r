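#' Optical geometry of a secondary-speckle imaging setup
#'
#' Bundles the geometric and optical parameters of a defocused-camera
#' speckle vibrometry setup: a coherent laser illuminates a rough surface
#' with a spot of diameter `D`; the back-reflected light forms a secondary
#' speckle pattern observed at distance `Z2` from the surface, imaged by a
#' lens at a further distance `Z3`.
#'
#' @param K Minimum number of detector pixels per resolved speckle
#'   (dimensionless count, >= 1).
#' @param delta_x Detector pixel pitch in metres.
#' @param Z2 Distance from the illuminated surface to the observed speckle
#'   plane, in metres.
#' @param Z3 Distance from the speckle plane to the camera lens, in metres.
#' @param D Diameter of the laser spot on the surface, in metres.
#' @param lambda Laser wavelength in metres.
#' @param F_len Optional focal length in metres; when `NULL` it can be
#'   derived with [required_focal_length()].
#'
#' @return An object of class `"speckle_geometry"`.
#' @seealso [far_field_threshold()], [required_focal_length()]
#' @examples
#' geom <- speckle_geometry(K = 2, delta_x = 3.45e-6, Z2 = 0.5, Z3 = 0.5,
#'                          D = 0.02, lambda = 532e-9)
#' far_field_threshold(geom)
#' required_focal_length(geom)
#' @export
speckle_geometry <- function(K = 2, delta_x = 3.45e-6, Z2 = 0.5, Z3 = 0.5,
                             D = 0.02, lambda = 532e-9, F_len = NULL) {
  vals <- c(K = K, delta_x = delta_x, Z2 = Z2, Z3 = Z3, D = D, lambda = lambda)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("invalid geometry: all of K, delta_x, Z2, Z3, D, lambda must be ",
         "finite and strictly positive", call. = FALSE)
  }
  if (K < 1) stop("invalid geometry: K must be >= 1", call. = FALSE)
  if (!is.null(F_len) && (!is.finite(F_len) || F_len <= 0)) {
    stop("invalid geometry: F_len must be positive when given", call. = FALSE)
  }
  structure(list(K = K, delta_x = delta_x, Z2 = Z2, Z3 = Z3, D = D,
                 lambda = lambda, F_len = F_len),
            class = "speckle_geometry")
}

#' @export
print.speckle_geometry <- function(x, ...) {
  cat("Speckle imaging geometry\n")
  cat(sprintf("  spot diameter D:      %.4g m\n", x$D))
  cat(sprintf("  wavelength lambda:    %.4g m\n", x$lambda))
  cat(sprintf("  surface->plane Z2:    %.4g m\n", x$Z2))
  cat(sprintf("  plane->lens Z3:       %.4g m\n", x$Z3))
  cat(sprintf("  pixel pitch delta_x:  %.4g m (K = %g px/speckle)\n",
              x$delta_x, x$K))
  thr <- far_field_threshold(x)
  cat(sprintf("  far-field threshold:  D^2/(4 lambda) = %.4g m (%s)\n",
              thr, if (is_far_field(x)) "satisfied" else "NOT satisfied"))
  if (!is.null(x$F_len)) cat(sprintf("  focal length F:       %.4g m\n", x$F_len))
  invisible(x)
}

#' Far-field distance threshold for speckle observation
#'
#' The speckle pattern behaves as a planar interference pattern that
#' translates rigidly with surface tilt only in the far field, i.e. when
#' the surface-to-speckle-plane distance satisfies `Z2 > D^2 / (4 lambda)`.
#' This function returns the threshold `D^2 / (4 lambda)`;
#' [is_far_field()] reports whether `Z2` exceeds it.
#'
#' @param geom A [speckle_geometry()] object.
#' @return Threshold distance in metres.
#' @examples
#' g <- speckle_geometry(D = 0.02, lambda = 532e-9)
#' far_field_threshold(g)  # ~188 m
#' is_far_field(g)
#' @export
far_field_threshold <- function(geom) {
  stopifnot(inherits(geom, "speckle_geometry"))
  geom$D^2 / (4 * geom$lambda)
}

#' @rdname far_field_threshold
#' @export
is_far_field <- function(geom) {
  geom$Z2 > far_field_threshold(geom)
}

#' Required camera focal length for resolved speckles
#'
#' For each speckle grain to cover at least `K` detector pixels, the
#' camera focal length must satisfy
#' `F = K * delta_x * Z3 * D / (Z2 * lambda)`:
#' the far-field speckle grain at the observed plane has transverse size
#' `lambda * Z2 / D` and is magnified by `F / Z3` onto the detector, so a
#' larger spot `D` (smaller grains) demands a longer focal length.
#'
#' @param geom A [speckle_geometry()] object.
#' @return Required focal length in metres.
#' @export
required_focal_length <- function(geom) {
  stopifnot(inherits(geom, "speckle_geometry"))
  geom$K * geom$delta_x * geom$Z3 * geom$D / (geom$Z2 * geom$lambda)
}
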