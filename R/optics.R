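# Physical constants: vacuum speed of light in cm/ps.
C_LIGHT_CM_PS <- 0.0299792458

#' Optical properties of a homogeneous turbid medium
#'
#' Bundles the absorption coefficient, reduced scattering coefficient and
#' refractive index with derived diffusion quantities: the speed of light in
#' the medium `v` (cm/ps), the diffusion coefficient `D = 1/(3 mu_s')` (cm,
#' absorption-independent convention of the moments literature), the
#' effective isotropic source depth `z0 = 1/mu_s'` and the extrapolated
#' boundary distance `zb = 2 A D`, with the internal-reflection factor `A`
#' from the Groenhuis/Egan polynomial approximation.
#'
#' @param mu_a Absorption coefficient, cm^-1 (> 0).
#' @param mu_s_prime Reduced scattering coefficient, cm^-1 (> 0).
#' @param n Refractive index (>= 1); default 1.33 for water-based phantoms.
#' @param boundary `"extrapolated"` (default) or `"zero"` for the
#'   zero-fluence boundary condition (zb = 0).
#' @return A list of class `optical_properties`.
#' @examples
#' optical_properties(0.1, 10)
#' @export
optical_properties <- function(mu_a, mu_s_prime, n = 1.33,
                               boundary = c("extrapolated", "zero")) {
  boundary <- match.arg(boundary)
  stopifnot(mu_a > 0, mu_s_prime > 0, n >= 1)
  D <- 1 / (3 * mu_s_prime)
  v <- C_LIGHT_CM_PS / n
  # Groenhuis/Egan effective reflection coefficient
  r_d <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  A <- (1 + r_d) / (1 - r_d)
  zb <- if (boundary == "extrapolated") 2 * A * D else 0
  structure(
    list(
      mu_a = mu_a, mu_s_prime = mu_s_prime, n = n, boundary = boundary,
      v = v, D = D, z0 = 1 / mu_s_prime, zb = zb, A = A
    ),
    class = "optical_properties"
  )
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "<optical_properties> mu_a = %.4g cm^-1, mu_s' = %.4g cm^-1, n = %.3f (%s boundary)\n",
    x$mu_a, x$mu_s_prime, x$n, x$boundary
  ))
  invisible(x)
}

#' Uniform time grid for time-resolved curves
#'
#' @param t_max Upper edge of the grid in ps.
#' @param n_bins Number of bins; bin centres sit at (i - 1/2) * bin_width.
#' @return A list of class `time_grid` with `time_ps` (centres), `bin_width`,
#'   `t_max` and `n_bins`. The default (10 ns in 4096 bins, ~2.44 ps/bin)
#'   mirrors TCSPC-scale resolution.
#' @export
time_grid <- function(t_max = 10000, n_bins = 4096) {
  stopifnot(t_max > 0, n_bins >= 2)
  bw <- t_max / n_bins
  structure(
    list(
      time_ps = (seq_len(n_bins) - 0.5) * bw,
      bin_width = bw, t_max = t_max, n_bins = as.integer(n_bins)
    ),
    class = "time_grid"
  )
}

#' Four-channel optode geometry for dual-subtraction measurements
#'
#' Two detectors (1, 2) sit between two sources (left, right) on the boundary
#' plane, all on one line (the X axis, Y = 0, Z = 0). The pairing yields two
#' far channels (left-2 and right-1 at `far_separation`) and two near
#' channels (left-1 and right-2 at `near_separation`), symmetric about the
#' detector midpoint.
#'
#' @param far_separation Source-detector distance of the far channels, cm.
#' @param near_separation Source-detector distance of the near channels, cm.
#' @return A list of class `optode_geometry` with source/detector
#'   coordinates (cm) and a `channels` tibble (name, source, detector,
#'   separation, role, source_x, detector_x).
#' @examples
#' optode_geometry()$channels
#' @export
optode_geometry <- function(far_separation = 3, near_separation = 2.5) {
  stopifnot(far_separation > near_separation, near_separation > 0)
  half_det <- (far_separation - near_separation) / 2
  src <- (far_separation + near_separation) / 2
  channels <- tibble::tibble(
    name = c("left_1", "left_2", "right_1", "right_2"),
    source = c("left", "left", "right", "right"),
    detector = c("1", "2", "1", "2"),
    source_x = c(-src, -src, src, src),
    detector_x = c(-half_det, half_det, -half_det, half_det)
  )
  channels$separation <- abs(channels$detector_x - channels$source_x)
  channels$role <- ifelse(
    abs(channels$separation - far_separation) < 1e-12, "far", "near"
  )
  structure(
    list(
      far_separation = far_separation,
      near_separation = near_separation,
      source_positions = list(left = c(-src, 0, 0), right = c(src, 0, 0)),
      detector_positions = list(`1` = c(-half_det, 0, 0), `2` = c(half_det, 0, 0)),
      channels = channels
    ),
    class = "optode_geometry"
  )
}

#' @export
print.optode_geometry <- function(x, ...) {
  cat(sprintf(
    "<optode_geometry> far %.2f cm (left-2, right-1), near %.2f cm (left-1, right-2)\n",
    x$far_separation, x$near_separation
  ))
  invisible(x)
}
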