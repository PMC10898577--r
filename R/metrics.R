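map_z_step <- function(maps) {
  g <- attr(maps, "grid")
  if (!is.null(g)) return(g$z_step_mm)
  z <- sort(unique(maps$z_mm))
  if (length(z) < 2) return(NA_real_)
  min(diff(z))
}

#' Depth-related sensitivity profile
#'
#' Collapses a 3D sensitivity map into a column along depth: voxel values
#' are summed over the full X and Y extents within each Z layer, giving the
#' sensitivity to a homogeneous absorption change in that layer. Profiles
#' are normalized by the layer of maximal absolute sensitivity, preserving
#' sign.
#'
#' @param maps A `sensitivity_maps` tibble from [assemble_maps()] (any
#'   subset of methods/moments).
#' @param layer_thickness_mm Thickness of a depth layer; defaults to the
#'   map's Z grid step.
#' @return A tibble of class `depth_profile`: `method`, `moment`, `z_mm`
#'   (layer centre), `layer_sum`, `normalized`.
#' @export
depth_profile <- function(maps, layer_thickness_mm = NULL) {
  zs <- map_z_step(maps)
  if (is.null(layer_thickness_mm)) layer_thickness_mm <- zs
  z0 <- min(maps$z_mm)
  tb <- tibble::as_tibble(maps)
  tb$layer <- floor((tb$z_mm - z0) / layer_thickness_mm + 1e-9)
  prof <- dplyr::summarise(
    dplyr::group_by(tb, .data$method, .data$moment, .data$layer),
    z_mm = mean(.data$z_mm), layer_sum = sum(.data$value), .groups = "drop"
  )
  prof <- dplyr::mutate(
    dplyr::group_by(prof, .data$method, .data$moment),
    normalized = if (max(abs(.data$layer_sum)) > 0) {
      .data$layer_sum / max(abs(.data$layer_sum))
    } else {
      warning("all-zero map: normalization skipped", call. = FALSE)
      .data$layer_sum
    }
  )
  prof <- dplyr::arrange(dplyr::ungroup(prof), .data$method, .data$moment, .data$z_mm)
  prof$layer <- NULL
  class(prof) <- c("depth_profile", class(prof))
  attr(prof, "layer_thickness_mm") <- layer_thickness_mm
  prof
}

#' Depth of maximal layer sensitivity
#'
#' @param profile A [depth_profile()].
#' @return A tibble with `method`, `moment` and `z_peak_mm`, the depth of
#'   the layer with maximal absolute summed sensitivity.
#' @export
peak_sensitivity_depth <- function(profile) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(profile), .data$method, .data$moment),
    z_peak_mm = .data$z_mm[which.max(abs(.data$layer_sum))], .groups = "drop"
  )
}

#' Depth selectivity of a sensitivity map
#'
#' The ratio of summed sensitivity in a deep layer to that in an equally
#' thick superficial layer, as a function of the deep layer's start depth.
#' The perturbation strength cancels between numerator and denominator, so
#' the ratio is computed directly on the moment-change sums. A nominal
#' layer thickness of about 5 mm on a 2 mm depth grid is realized as 3 grid
#' layers (6 mm) by default.
#'
#' @param maps A `sensitivity_maps` tibble.
#' @param thickness_layers Number of consecutive Z grid layers per band.
#' @param lower_start_range Depths (mm) between which the deep band's start
#'   is slid; default 5 to 30 mm.
#' @return A tibble of class `selectivity_curve`: `method`, `moment`,
#'   `z_start_mm` (upper edge of the deep band), `S` (NA where the
#'   superficial band sum vanishes), plus band sums.
#' @export
depth_selectivity <- function(maps, thickness_layers = 3,
                              lower_start_range = c(5, 30)) {
  stopifnot(thickness_layers >= 1)
  prof <- depth_profile(maps)
  zs <- attr(prof, "layer_thickness_mm")
  out <- dplyr::group_modify(
    dplyr::group_by(tibble::as_tibble(prof), .data$method, .data$moment),
    function(d, key) {
      d <- dplyr::arrange(d, .data$z_mm)
      k <- thickness_layers
      nl <- nrow(d)
      if (nl < k + 1) stop("too few depth layers for the requested band thickness", call. = FALSE)
      upper <- sum(d$layer_sum[seq_len(k)])
      starts <- seq_len(nl - k + 1L)
      z_start <- d$z_mm[starts] - zs / 2
      lower <- vapply(starts, function(j) sum(d$layer_sum[j:(j + k - 1L)]), 0)
      keep <- z_start >= lower_start_range[1] - 1e-9 &
        z_start <= lower_start_range[2] + 1e-9
      tibble::tibble(
        z_start_mm = z_start[keep],
        lower_sum = lower[keep],
        upper_sum = upper,
        S = if (upper != 0) lower[keep] / upper else NA_real_
      )
    }
  )
  out <- dplyr::ungroup(out)
  class(out) <- c("selectivity_curve", class(out))
  attr(out, "thickness_mm") <- thickness_layers * zs
  out
}

#' Photon-noise standard deviations of the moment measurands
#'
#' Theoretical counting-noise model for the statistical moments of a DTOF
#' with total count N, variance V and fourth central moment m4:
#' `sigma^2(N) = N`, `sigma^2(m1) = V/N`, `sigma^2(V) = (m4 - V^2)/N`; the
#' attenuation measurand `dA = -log(N_i/N_0)` carries `sigma(A) = 1/sqrt(N)`
#' by the delta method. Error propagation gives the subtraction geometries:
#' `sigma^2_SS = sigma^2_far + sigma^2_near` and, because the dual
#' subtraction averages two single subtractions,
#' `sigma^2_DS = sigma^2_SS / 2`.
#'
#' @param baseline_moments Tibble with one row per channel: columns `name`,
#'   `role` (`"far"`/`"near"`), `N`, `m1`, `V`, `m4` - the shape stored by
#'   [assemble_maps()] as the `baseline_moments` attribute.
#' @return A tibble of class `noise_model` with `method`
#'   (`sd_far`, `sd_near`, `ss`, `ds`), `moment` (`N`, `A`, `m1`, `V`) and
#'   `sigma`.
#' @export
photon_noise_sd <- function(baseline_moments) {
  bm <- tibble::as_tibble(baseline_moments)
  stopifnot(all(c("role", "N", "V", "m4") %in% names(bm)))
  if (any(bm$N <= 0)) stop("photon noise undefined for zero total counts", call. = FALSE)
  per_channel <- tidyr::pivot_longer(
    tibble::tibble(
      role = bm$role,
      N = sqrt(bm$N),
      A = 1 / sqrt(bm$N),
      m1 = sqrt(bm$V / bm$N),
      V = sqrt(pmax(bm$m4 - bm$V^2, 0) / bm$N)
    ),
    cols = c("N", "A", "m1", "V"), names_to = "moment", values_to = "sigma"
  )
  sd_rows <- dplyr::summarise(
    dplyr::group_by(per_channel, .data$role, .data$moment),
    sigma = sqrt(mean(.data$sigma^2)), .groups = "drop"
  )
  sd_rows$method <- paste0("sd_", sd_rows$role)
  var_far <- sd_rows$sigma[sd_rows$role == "far"]^2
  var_near <- sd_rows$sigma[sd_rows$role == "near"]^2
  mom <- sd_rows$moment[sd_rows$role == "far"]
  ss <- tibble::tibble(method = "ss", moment = mom,
                       sigma = sqrt(var_far + var_near))
  ds <- tibble::tibble(method = "ds", moment = mom, sigma = ss$sigma / sqrt(2))
  out <- dplyr::bind_rows(sd_rows[, c("method", "moment", "sigma")], ss, ds)
  class(out) <- c("noise_model", class(out))
  out
}

#' Empirical photon-noise standard deviations by Poisson replication
#'
#' Monte-Carlo cross-check of [photon_noise_sd()]: repeatedly samples
#' Poisson counts from an expected curve and reports the standard deviation
#' of each moment across replications.
#'
#' @param curve Non-negative expected curve.
#' @param time_ps Bin centres, ps.
#' @param total_counts Expected total counts per replication.
#' @param n_rep Number of replications.
#' @param seed Integer seed.
#' @return A tibble with `moment` (`N`, `m1`, `V`) and empirical `sigma`.
#' @export
empirical_noise_sd <- function(curve, time_ps, total_counts = 1e6,
                               n_rep = 1e4, seed = 1L) {
  reps <- poisson_moment_replicates(curve, time_ps, total_counts, n_rep, seed)
  tibble::tibble(
    moment = c("N", "m1", "V"),
    sigma = c(stats::sd(reps$N), stats::sd(reps$m1), stats::sd(reps$V))
  )
}

# Vectorized per-replicate moments of Poisson draws from one expected curve.
poisson_moment_replicates <- function(curve, time_ps, total_counts, n_rep,
                                      seed = 1L) {
  stopifnot(all(curve >= 0), length(time_ps) == length(curve))
  lam <- curve * (total_counts / sum(curve))
  nb <- length(lam)
  cts <- withr::with_seed(as.integer(seed), {
    matrix(stats::rpois(nb * n_rep, rep(lam, n_rep)), nb, n_rep)
  })
  N <- colSums(cts)
  m1 <- colSums(cts * time_ps) / N
  # centralized second moment per replicate without forming nb x n_rep deviates
  t2 <- colSums(cts * time_ps^2) / N
  V <- t2 - m1^2
  tibble::tibble(rep = seq_len(n_rep), N = N, m1 = m1, V = V)
}

#' Overall performance: depth selectivity times contrast-to-noise ratio
#'
#' Splits the medium at a top-layer thickness (default 15 mm, the upper end
#' of typical adult scalp-plus-skull thickness), computes for each method
#' and moment the depth selectivity `S = sum_lower / sum_upper`, the
#' contrast-to-noise ratio `CNR = sum_lower / sigma(M)` with the
#' photon-noise sigma of the matching geometry, and their product
#' `S x CNR = (sum_lower)^2 / (sigma * sum_upper)`. Sums are signed; the
#' product's magnitude and sign are reported separately.
#'
#' @param maps A `sensitivity_maps` tibble.
#' @param noise A `noise_model` from [photon_noise_sd()]; by default built
#'   from the baseline moments stored on `maps`.
#' @param top_thickness_mm Thickness of the superficial compartment, mm.
#' @return A tibble of class `performance_score` with `method`, `moment`,
#'   `upper_sum`, `lower_sum`, `sigma`, `S`, `CNR`, `performance`
#'   (signed product) and `magnitude`.
#' @export
overall_performance <- function(maps, noise = NULL, top_thickness_mm = 15) {
  if (is.null(noise)) {
    bm <- attr(maps, "baseline_moments")
    if (is.null(bm)) stop("`maps` carries no baseline moments; supply `noise`", call. = FALSE)
    noise <- photon_noise_sd(bm)
  }
  tb <- tibble::as_tibble(maps)
  sums <- dplyr::summarise(
    dplyr::group_by(tb, .data$method, .data$moment),
    upper_sum = sum(.data$value[.data$z_mm < top_thickness_mm]),
    lower_sum = sum(.data$value[.data$z_mm >= top_thickness_mm]),
    .groups = "drop"
  )
  sigma_for <- function(method) {
    key <- dplyr::case_when(
      grepl("^sd", method) ~ "sd_far",
      grepl("^ss", method) ~ "ss",
      TRUE ~ "ds"
    )
    key
  }
  sums$noise_geometry <- sigma_for(sums$method)
  sums <- dplyr::left_join(
    sums, dplyr::rename(noise, noise_geometry = "method"),
    by = c("noise_geometry", "moment")
  )
  out <- dplyr::mutate(
    sums,
    S = ifelse(.data$upper_sum != 0, .data$lower_sum / .data$upper_sum, NA_real_),
    CNR = .data$lower_sum / .data$sigma,
    performance = .data$S * .data$CNR,
    magnitude = abs(.data$performance)
  )
  out$top_thickness_mm <- top_thickness_mm
  class(out) <- c("performance_score", class(out))
  out
}
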