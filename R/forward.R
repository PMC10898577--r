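# Diffusion-theory forward model for a homogeneous semi-infinite medium:
# time-resolved reflectance, fluence Green's functions with an image source
# over the extrapolated boundary, and Born-level absorption Jacobians.
# All lengths in cm, times in ps; curves are evaluated at bin centres.

# Flux-mode (Fick's law) time-resolved remission for an isotropic source at
# depth z_src below a boundary point, detected at lateral distance rho.
# Image source at -(z_src + 2 zb). Continuous-time function, t in ps.
reflectance_curve_fun <- function(props, rho, z_src = props$z0) {
  D <- props$D; v <- props$v; mu_a <- props$mu_a; zb <- props$zb
  z1 <- z_src
  z2 <- z_src + 2 * zb
  force(rho)
  function(t) {
    out <- numeric(length(t))
    ok <- t > 0
    tt <- t[ok]
    q <- 4 * D * v * tt
    out[ok] <- 0.5 * (4 * pi * D * v)^(-1.5) * tt^(-2.5) *
      exp(-mu_a * v * tt - rho^2 / q) *
      (z1 * exp(-z1^2 / q) + z2 * exp(-z2^2 / q))
    out
  }
}

#' Time-resolved diffuse reflectance of a semi-infinite medium
#'
#' Image-source solution of the diffusion equation with an extrapolated
#' boundary: an isotropic point source at depth `z0 = 1/mu_s'` and its
#' negative image mirrored over the plane `z = -zb`, detected as the
#' outward flux at the surface a lateral distance `rho` away. Absorption
#' enters only through the Beer-Lambert factor `exp(-mu_a v t)`.
#'
#' @param props [optical_properties()].
#' @param rho Source-detector separation in cm (> 0).
#' @param grid [time_grid()].
#' @param z_src Source depth in cm; defaults to the reduced scattering
#'   transport depth `1/mu_s'`. Setting it to a voxel depth gives the
#'   remission Green's function from an interior point, used by the
#'   absorption Jacobian.
#' @param tail_tol Maximum tolerated fraction of the curve's total
#'   time-integral lying beyond the grid; exceeding it raises an error
#'   naming the uncovered mass. Use a larger value deliberately for slowly
#'   decaying (low-absorption) curves.
#' @return Numeric vector of curve values at the grid bin centres
#'   (per-ps photon flux density, unnormalized).
#' @export
reflectance_td <- function(props, rho, grid = time_grid(), z_src = props$z0,
                           tail_tol = 1e-6) {
  stopifnot(inherits(props, "optical_properties"), rho > 0,
            inherits(grid, "time_grid"))
  f <- reflectance_curve_fun(props, rho, z_src)
  vals <- f(grid$time_ps)
  if (is.finite(tail_tol)) {
    total <- stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value
    tail <- stats::integrate(f, grid$t_max, Inf, rel.tol = 1e-7)$value
    if (tail > tail_tol * total) {
      stop(sprintf(
        "time grid too short: %.3g of the reflectance mass lies beyond t_max = %g ps",
        tail / total, grid$t_max
      ), call. = FALSE)
    }
  }
  vals
}

#' Fluence Green's function between two points in a semi-infinite medium
#'
#' Photon fluence rate at `r_b` due to an isotropic unit pulse at `r_a`
#' (or vice versa - the kernel is symmetric), built from the infinite-medium
#' Gaussian propagator and its negative image over the extrapolated
#' boundary. Vanishes identically on the extrapolated boundary plane
#' `z = -zb` and scales with absorption as `exp(-mu_a v t)`.
#'
#' @param props [optical_properties()].
#' @param r_a,r_b Numeric length-3 points `c(x, y, z)` in cm, `z >= 0`
#'   inside the medium (the boundary is `z = 0`).
#' @inheritParams reflectance_td
#' @return Numeric vector of fluence values at the grid bin centres.
#' @export
greens_fluence <- function(props, r_a, r_b, grid = time_grid()) {
  stopifnot(inherits(props, "optical_properties"),
            length(r_a) == 3, length(r_b) == 3)
  d2 <- sum((r_a - r_b)^2)
  if (d2 == 0) stop("coincident points: fluence Green's function is singular", call. = FALSE)
  r_b_img <- c(r_b[1], r_b[2], -r_b[3] - 2 * props$zb)
  d2i <- sum((r_a - r_b_img)^2)
  t <- grid$time_ps
  q <- 4 * props$D * props$v * t
  props$v * (pi * q)^(-1.5) * exp(-props$mu_a * props$v * t) *
    (exp(-d2 / q) - exp(-d2i / q))
}

# FFT-based causal linear convolution of curve columns with matching dt.
# a: n x k matrix (or vector), b: n x k matrix, vector, or n x 1; returns the
# first n samples of conv(a, b) * dt column-wise.
convolve_columns <- function(a, b, dt) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a)
  stopifnot(nrow(b) == n)
  m <- stats::nextn(2L * n, 2)
  pad <- function(x) rbind(x, matrix(0, m - n, ncol(x)))
  fa <- stats::mvfft(pad(a))
  fb <- stats::mvfft(pad(b))
  if (ncol(b) == 1L && ncol(a) > 1L) fb <- fb[, rep(1L, ncol(a)), drop = FALSE]
  if (ncol(a) == 1L && ncol(b) > 1L) fa <- fa[, rep(1L, ncol(b)), drop = FALSE]
  out <- Re(stats::mvfft(fa * fb, inverse = TRUE)) / m
  out[seq_len(n), , drop = FALSE] * dt
}

# Batch Born kernel: for one source and one detector on the boundary and a
# matrix of voxel centres (k x 3, cm), returns the n_bins x k matrix of
# time-resolved absorption sensitivities J(t) such that a small uniform
# absorption increase dmu_a in a voxel of volume Vvox changes the detected
# curve by dR(t) = -dmu_a * Vvox * J(t). Symmetrized over source <->
# detector exchange so that optical reciprocity holds exactly; each
# orientation individually satisfies the pathlength identity
# integral(J dV) = v t R(t), hence so does the average.
jacobian_batch <- function(props, source_pos, detector_pos, voxels, grid) {
  (jacobian_batch_one(props, source_pos, detector_pos, voxels, grid) +
     jacobian_batch_one(props, detector_pos, source_pos, voxels, grid)) / 2
}

jacobian_batch_one <- function(props, source_pos, detector_pos, voxels, grid) {
  voxels <- matrix(as.numeric(voxels), ncol = 3)
  # chunk over voxels to bound the size of the dense time x voxel temporaries
  chunk <- max(1L, floor(2^21 / grid$n_bins))
  if (nrow(voxels) > chunk) {
    idx <- split(seq_len(nrow(voxels)), ceiling(seq_len(nrow(voxels)) / chunk))
    out <- matrix(0, grid$n_bins, nrow(voxels))
    for (ii in idx) {
      out[, ii] <- jacobian_batch_one(props, source_pos, detector_pos,
                                      voxels[ii, , drop = FALSE], grid)
    }
    return(out)
  }
  t <- grid$time_ps
  n <- grid$n_bins
  q <- 4 * props$D * props$v * t
  # the Beer-Lambert factor exp(-mu_a v t) commutes with the time
  # convolution exactly (exp(-a s) exp(-a (t-s)) = exp(-a t)), so it is
  # factored out of both kernels and reapplied analytically: absorption
  # scaling of the Jacobian then holds to machine precision
  atten <- exp(-props$mu_a * props$v * t)
  # source -> voxel fluence (isotropic source buried at z0 with image)
  src <- c(source_pos[1], source_pos[2], props$z0)
  src_img <- c(source_pos[1], source_pos[2], -props$z0 - 2 * props$zb)
  d2s <- colSums((t(voxels) - src)^2)
  d2si <- colSums((t(voxels) - src_img)^2)
  phi <- (props$v * (pi * q)^(-1.5)) *
    (exp(-outer(1 / q, d2s)) - exp(-outer(1 / q, d2si)))
  # voxel -> detector remission (flux Green's function from interior point)
  rho2 <- (voxels[, 1] - detector_pos[1])^2 + (voxels[, 2] - detector_pos[2])^2
  z1 <- voxels[, 3]
  z2 <- voxels[, 3] + 2 * props$zb
  pre <- 0.5 * (4 * pi * props$D * props$v)^(-1.5) * t^(-2.5)
  rem <- pre * exp(-outer(1 / q, rho2)) *
    (sweep(exp(-outer(1 / q, z1^2)), 2, z1, `*`) +
       sweep(exp(-outer(1 / q, z2^2)), 2, z2, `*`))
  atten * convolve_columns(phi, rem, grid$bin_width)
}

#' Time-resolved absorption sensitivity (Born Jacobian) of a voxel
#'
#' Sensitivity of the detected time-resolved reflectance to a small
#' absorption increase in a voxel: the causal time-convolution of the
#' source-to-voxel fluence Green's function with the voxel-to-detector
#' remission Green's function. For a perturbation `dmu_a` (cm^-1) in a
#' voxel of volume `volume_cm3`, the detected curve changes by
#' `dR(t) = -dmu_a * volume_cm3 * J(t)`.
#'
#' @param props [optical_properties()].
#' @param source_pos,detector_pos Length-3 boundary positions in cm
#'   (`z = 0`); the source is buried at depth `z0` internally.
#' @param voxel Length-3 voxel centre in cm, strictly inside the medium
#'   (`z > 0`).
#' @param grid [time_grid()].
#' @return Numeric vector `J(t)` at the grid bin centres.
#' @export
absorption_jacobian_td <- function(props, source_pos, detector_pos, voxel,
                                   grid = time_grid()) {
  stopifnot(inherits(props, "optical_properties"), length(voxel) == 3)
  if (voxel[3] <= 0) stop("voxel must lie strictly inside the medium (z > 0)", call. = FALSE)
  drop(jacobian_batch(props, source_pos, detector_pos, rbind(voxel), grid))
}

#' Moments of the ideal time-resolved reflectance
#'
#' Mean time of flight and centralized variance (and higher central moments)
#' of the model reflectance curve for a homogeneous semi-infinite medium,
#' computed by adaptive quadrature of the continuous-time solution.
#'
#' @param props [optical_properties()].
#' @param rho Source-detector separation, cm.
#' @param orders Highest central moment order to return (2, 3 or 4).
#' @return One-row tibble with `m1` (ps), `V` (ps^2) and, when requested,
#'   `m3`, `m4`.
#' @export
theoretical_moments <- function(props, rho, orders = 2) {
  stopifnot(inherits(props, "optical_properties"), rho > 0, orders >= 2)
  f <- reflectance_curve_fun(props, rho)
  quad <- function(g) stats::integrate(
    g, 0, Inf, rel.tol = 1e-10, abs.tol = 0, subdivisions = 400L
  )$value
  i0 <- quad(f)
  m1 <- quad(function(t) t * f(t)) / i0
  out <- tibble::tibble(
    m1 = m1,
    V = quad(function(t) (t - m1)^2 * f(t)) / i0
  )
  if (orders >= 3) out$m3 <- quad(function(t) (t - m1)^3 * f(t)) / i0
  if (orders >= 4) out$m4 <- quad(function(t) (t - m1)^4 * f(t)) / i0
  out
}
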