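#' Absorber sweep grid
#'
#' The cuboid of positions over which the small absorbing inclusion is
#' stepped: X along the optode line (centred on the detector midpoint),
#' Y transverse, Z depth into the medium. Defaults mirror a stepper-motor
#' sweep of 75 mm x 20 mm x 35 mm with 2 mm steps along X and Z and 1 mm
#' along Y; the first depth plane is offset by half the inclusion height so
#' the inclusion body stays inside the medium.
#'
#' @param x_extent_mm,x_step_mm Extent and step along X (mm).
#' @param y_extent_mm,y_step_mm Extent and step along Y (mm).
#' @param z_extent_mm,z_step_mm Extent and step along Z (depth, mm).
#' @param z_offset_mm Depth of the shallowest position (mm); must be > 0.
#' @return A list of class `sweep_grid` with a `positions` tibble
#'   (`i`, `x_mm`, `y_mm`, `z_mm`; X fastest, then Z, then Y, emulating the
#'   stepper sweep order) and the axis definitions.
#' @export
sweep_grid <- function(x_extent_mm = 75, x_step_mm = 2,
                       y_extent_mm = 20, y_step_mm = 1,
                       z_extent_mm = 35, z_step_mm = 2,
                       z_offset_mm = 2.5) {
  stopifnot(x_step_mm > 0, y_step_mm > 0, z_step_mm > 0, z_offset_mm > 0)
  nx <- floor(x_extent_mm / x_step_mm) + 1L
  ny <- floor(y_extent_mm / y_step_mm) + 1L
  nz <- floor(z_extent_mm / z_step_mm) + 1L
  x <- (seq_len(nx) - (nx + 1) / 2) * x_step_mm
  y <- (seq_len(ny) - 1L) * y_step_mm
  z <- z_offset_mm + (seq_len(nz) - 1L) * z_step_mm
  pos <- tidyr::expand_grid(y_mm = y, z_mm = z, x_mm = x)[, c("x_mm", "z_mm", "y_mm")]
  pos <- tibble::as_tibble(pos)
  pos$i <- seq_len(nrow(pos))
  structure(
    list(
      positions = pos[, c("i", "x_mm", "y_mm", "z_mm")],
      x_mm = x, y_mm = y, z_mm = z,
      x_step_mm = x_step_mm, y_step_mm = y_step_mm, z_step_mm = z_step_mm
    ),
    class = "sweep_grid"
  )
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf(
    "<sweep_grid> %d x %d x %d positions (X x Z x Y), steps %g/%g/%g mm, depth %g-%g mm\n",
    length(x$x_mm), length(x$z_mm), length(x$y_mm),
    x$x_step_mm, x$z_step_mm, x$y_step_mm, min(x$z_mm), max(x$z_mm)
  ))
  invisible(x)
}

#' Absorbing inclusion
#'
#' A small cylindrical absorber (default 3 mm diameter x 5 mm height)
#' modelled at Born level: its effect on a detected curve is
#' `-dmu_a * volume * J(t)` with `J` the voxel absorption Jacobian. The
#' default perturbation strength is chosen so that the peak attenuation
#' change on the far channel stays near 0.1, well inside the linear-Born
#' regime; a physically "black" absorber exceeds linear perturbation theory
#' and is deliberately not reproduced.
#'
#' @param diameter_mm,height_mm Cylinder dimensions (mm).
#' @param dmu_a Effective absorption increase inside the inclusion, cm^-1.
#' @return A list of class `inclusion` with `volume_cm3` and the effective
#'   strength `dmu_a * volume_cm3` (cm^-1 cm^3).
#' @export
inclusion <- function(diameter_mm = 3, height_mm = 5, dmu_a = 0.25) {
  stopifnot(diameter_mm > 0, height_mm > 0, dmu_a >= 0)
  volume_cm3 <- pi * (diameter_mm / 20)^2 * (height_mm / 10)
  structure(
    list(
      diameter_mm = diameter_mm, height_mm = height_mm, dmu_a = dmu_a,
      volume_cm3 = volume_cm3, strength = dmu_a * volume_cm3
    ),
    class = "inclusion"
  )
}

#' Discretized Gaussian instrument response function
#'
#' @param grid [time_grid()].
#' @param fwhm_ps Full width at half maximum, ps (measured setups of this
#'   kind span roughly 595-717 ps; default 650 ps).
#' @param t0_ps Centre of the IRF peak on the grid; defaults to 4 standard
#'   deviations so the rising edge is fully contained.
#' @return Numeric curve on the grid bin centres, normalized to unit sum.
#' @export
gaussian_irf <- function(grid = time_grid(), fwhm_ps = 650, t0_ps = NULL) {
  stopifnot(inherits(grid, "time_grid"), fwhm_ps > 0)
  sigma <- fwhm_ps / (2 * sqrt(2 * log(2)))
  if (is.null(t0_ps)) t0_ps <- 4 * sigma
  k <- stats::dnorm(grid$time_ps, t0_ps, sigma)
  k / sum(k)
}

#' Convolve a time-resolved curve with an instrument response
#'
#' Discrete causal linear convolution on the shared grid, truncated at the
#' grid end. The kernel is normalized to unit sum so the curve's total
#' integral is preserved up to the truncated tail mass.
#'
#' @param curve Numeric curve (or matrix of curve columns) on the grid.
#' @param irf_curve Numeric IRF curve on the same grid.
#' @param grid [time_grid()] shared by both.
#' @return Convolved curve(s), same shape as `curve`.
#' @export
apply_irf <- function(curve, irf_curve, grid = time_grid()) {
  n <- if (is.matrix(curve)) nrow(curve) else length(curve)
  stopifnot(n == grid$n_bins, length(irf_curve) == grid$n_bins)
  out <- convolve_columns(curve, irf_curve / sum(irf_curve), 1)
  out <- pmax(out, 0) # FFT round-off can leave ~1e-18 negatives
  if (is.matrix(curve)) out else drop(out)
}

#' Poisson counting noise
#'
#' Scales a non-negative expected curve to a target total count and draws
#' independent Poisson counts per bin, emulating photon counting statistics.
#'
#' @param curve Non-negative numeric curve on the grid.
#' @param total_counts Expected total number of detected photons.
#' @param time_ps Bin centres for the returned DTOF.
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's random state is left untouched.
#' @param channel Channel label for the returned DTOF.
#' @return A [dtof()] of sampled counts.
#' @export
add_poisson_noise <- function(curve, total_counts, time_ps, seed = NULL,
                              channel = NA_character_) {
  stopifnot(all(curve >= 0), total_counts > 0, length(time_ps) == length(curve))
  lambda <- curve * (total_counts / sum(curve))
  draw <- function() stats::rpois(length(lambda), lambda)
  cts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  dtof(time_ps, cts, channel = channel)
}

#' Dead-time counting loss and its correction
#'
#' In interleaved two-source TCSPC acquisition the two DTOFs collected by
#' one detector share counting electronics, so the dead-time loss on one
#' channel is driven by the total event rate at the detector, including the
#' companion channel. The non-paralyzable model is used: the recorded rate
#' is `R_true / (1 + tau * R_true)` and every bin of both channels is
#' scaled by the same loss factor. `correct_deadtime()` inverts the factor
#' from the recorded total rate, restoring true counts up to round-off.
#'
#' @param counts Numeric vector (or matrix of curves) of true (`apply`) or
#'   recorded (`correct`) counts for one channel.
#' @param companion_counts Counts of the companion channel on the same
#'   detector, same shape, aligned bin-wise / column-wise.
#' @param tau_ps Dead time per recorded event, ps.
#' @param collection_time_s Acquisition time over which the counts were
#'   accumulated, s.
#' @return Scaled counts, same shape as `counts`.
#' @export
apply_deadtime <- function(counts, companion_counts, tau_ps,
                           collection_time_s = 0.09) {
  f <- deadtime_factor(counts, companion_counts, tau_ps, collection_time_s,
                       recorded = FALSE)
  scale_columns(counts, 1 / f)
}

#' @rdname apply_deadtime
#' @export
correct_deadtime <- function(counts, companion_counts, tau_ps,
                             collection_time_s = 0.09) {
  f <- deadtime_factor(counts, companion_counts, tau_ps, collection_time_s,
                       recorded = TRUE)
  scale_columns(counts, f)
}

# 1 + tau * R_true per column; for recorded input the true rate is first
# recovered by inverting R_rec = R_true / (1 + tau R_true).
deadtime_factor <- function(counts, companion_counts, tau_ps, collection_time_s,
                            recorded) {
  stopifnot(tau_ps >= 0, collection_time_s > 0)
  tau_s <- tau_ps * 1e-12
  tot <- col_totals(counts) + col_totals(companion_counts)
  rate <- tot / collection_time_s
  if (recorded) {
    if (any(tau_s * rate >= 1)) {
      stop("recorded rate implies a non-physical true rate (tau * rate >= 1)",
           call. = FALSE)
    }
    rate <- rate / (1 - tau_s * rate)
  }
  1 + tau_s * rate
}

col_totals <- function(x) if (is.matrix(x)) colSums(x) else sum(x)

scale_columns <- function(x, s) {
  if (is.matrix(x)) sweep(x, 2, s, `*`) else x * s
}

#' Noise and acquisition settings for the sweep simulator
#'
#' @param counts_per_dtof Expected photons per recorded DTOF. The default
#'   mirrors a total count rate of 3.5e6/s shared by the two DTOFs of each
#'   detector with a 0.09 s collection window: 3.5e6 / 2 * 0.09 = 157 500.
#' @param n_replicates DTOFs recorded per absorber position (default 20;
#'   the analysis later drops the first 10, recorded during motor motion,
#'   and averages the next 10).
#' @param irf_fwhm_ps IRF full width at half maximum, ps; `0` disables IRF
#'   broadening (ideal delta instrument).
#' @param poisson Draw Poisson counts (`TRUE`) or keep noiseless expected
#'   curves (`FALSE`).
#' @param deadtime_tau_ps Dead time per event, ps; `0` disables the
#'   counting-loss distortion.
#' @param collection_time_s Collection time per DTOF, s.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(counts_per_dtof = 157500, n_replicates = 20,
                         irf_fwhm_ps = 650, poisson = TRUE,
                         deadtime_tau_ps = 0, collection_time_s = 0.09) {
  stopifnot(counts_per_dtof > 0, n_replicates >= 1, irf_fwhm_ps >= 0,
            deadtime_tau_ps >= 0, collection_time_s > 0)
  structure(
    list(
      counts_per_dtof = counts_per_dtof,
      n_replicates = as.integer(n_replicates),
      irf_fwhm_ps = irf_fwhm_ps, poisson = isTRUE(poisson),
      deadtime_tau_ps = deadtime_tau_ps,
      collection_time_s = collection_time_s
    ),
    class = "noise_config"
  )
}

#' Simulate a full absorber-sweep experiment
#'
#' Generates the four-channel in-silico analogue of a liquid-phantom sweep:
#' for every channel the homogeneous baseline reflectance and, for every
#' inclusion position, the Born-perturbed curve
#' `R(t) - dmu_a * volume * J(t)`; curves are then IRF-broadened, scaled to
#' the expected count level, optionally distorted by detector-level
#' dead-time loss, and sampled with per-replicate Poisson noise. The result
#' is bit-reproducible for a given seed.
#'
#' @param props [optical_properties()] of the homogeneous medium.
#' @param geometry [optode_geometry()].
#' @param grid [sweep_grid()] of inclusion positions.
#' @param incl [inclusion()].
#' @param noise [noise_config()].
#' @param tgrid [time_grid()] for the DTOFs.
#' @param seed Integer seed controlling all Poisson draws.
#' @return A list of class `sweep_dataset`: `expected` (per channel, the
#'   noiseless n_bins x n_positions curve matrix after IRF/dead-time),
#'   `baseline_expected`, `dtofs` / `baseline_dtofs` (Poisson replicates,
#'   when enabled), `positions`, `channels`, `tgrid` and `meta`.
#' @export
simulate_sweep <- function(props, geometry = optode_geometry(),
                           grid = sweep_grid(), incl = inclusion(),
                           noise = noise_config(), tgrid = time_grid(),
                           seed = 1L) {
  stopifnot(inherits(props, "optical_properties"),
            inherits(geometry, "optode_geometry"),
            inherits(grid, "sweep_grid"), inherits(incl, "inclusion"),
            inherits(noise, "noise_config"), inherits(tgrid, "time_grid"))
  chans <- geometry$channels
  vox_cm <- as.matrix(grid$positions[, c("x_mm", "y_mm", "z_mm")]) / 10
  n_pos <- nrow(vox_cm)
  irf <- if (noise$irf_fwhm_ps > 0) gaussian_irf(tgrid, noise$irf_fwhm_ps) else NULL
  warn <- character()

  expected <- list(); baseline_expected <- list()
  for (k in seq_len(nrow(chans))) {
    ch <- chans[k, ]
    base <- reflectance_td(props, ch$separation, tgrid)
    J <- jacobian_batch(props, c(ch$source_x, 0, 0), c(ch$detector_x, 0, 0),
                        vox_cm, tgrid)
    pert <- base - incl$strength * J
    removed <- 1 - colSums(pmax(pert, 0)) / sum(base)
    if (any(removed > 0.5)) {
      warn <- c(warn, sprintf(
        "channel %s: perturbation removes > 50%% of curve mass at %d position(s); Born linearity is not credible there",
        ch$name, sum(removed > 0.5)
      ))
    }
    pert <- pmax(pert, 0)
    if (!is.null(irf)) {
      base <- apply_irf(base, irf, tgrid)
      pert <- apply_irf(pert, irf, tgrid)
    }
    # scale so the *baseline* carries the nominal count level; perturbed
    # curves keep their physical count deficit relative to it
    s <- noise$counts_per_dtof / sum(base)
    baseline_expected[[ch$name]] <- base * s
    expected[[ch$name]] <- pert * s
  }

  if (noise$deadtime_tau_ps > 0) {
    for (det in c("1", "2")) {
      pair <- chans$name[chans$detector == det]
      a <- expected[[pair[1]]]; b <- expected[[pair[2]]]
      expected[[pair[1]]] <- apply_deadtime(a, b, noise$deadtime_tau_ps,
                                            noise$collection_time_s)
      expected[[pair[2]]] <- apply_deadtime(b, a, noise$deadtime_tau_ps,
                                            noise$collection_time_s)
      ba <- baseline_expected[[pair[1]]]; bb <- baseline_expected[[pair[2]]]
      baseline_expected[[pair[1]]] <- apply_deadtime(ba, bb, noise$deadtime_tau_ps,
                                                     noise$collection_time_s)
      baseline_expected[[pair[2]]] <- apply_deadtime(bb, ba, noise$deadtime_tau_ps,
                                                     noise$collection_time_s)
    }
  }

  dtofs <- NULL; baseline_dtofs <- NULL
  if (noise$poisson) {
    nb <- tgrid$n_bins; nr <- noise$n_replicates
    dtofs <- list(); baseline_dtofs <- list()
    withr::with_seed(as.integer(seed), {
      for (nm in chans$name) {
        lam <- expected[[nm]]
        # stored as doubles so on-disk round trips are type-stable
        arr <- array(as.double(stats::rpois(nb * n_pos * nr,
                                            rep(as.vector(lam), nr))),
                     dim = c(nb, n_pos, nr))
        dtofs[[nm]] <- arr
        baseline_dtofs[[nm]] <- matrix(
          as.double(stats::rpois(nb * nr, rep(baseline_expected[[nm]], nr))),
          nb, nr
        )
      }
    })
  }

  for (w in warn) warning(w, call. = FALSE)
  structure(
    list(
      expected = expected, baseline_expected = baseline_expected,
      dtofs = dtofs, baseline_dtofs = baseline_dtofs,
      positions = grid$positions, channels = chans,
      grid = grid, tgrid = tgrid,
      meta = list(
        props = unclass(props)[c("mu_a", "mu_s_prime", "n", "boundary")],
        geometry = list(far_separation = geometry$far_separation,
                        near_separation = geometry$near_separation),
        inclusion = unclass(incl), noise = unclass(noise),
        seed = as.integer(seed), warnings = warn,
        schema_version = "dtofsens-sweep-1"
      )
    ),
    class = "sweep_dataset"
  )
}

#' @export
print.sweep_dataset <- function(x, ...) {
  cat(sprintf(
    "<sweep_dataset> %d positions x 4 channels, %d bins, %s; seed %d\n",
    nrow(x$positions), x$tgrid$n_bins,
    if (is.null(x$dtofs)) "noiseless" else
      sprintf("%d Poisson replicates", x$meta$noise$n_replicates),
    x$meta$seed
  ))
  invisible(x)
}
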