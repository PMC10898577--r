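#' Changes in statistical moments caused by an absorption perturbation
#'
#' Given moments of the homogeneous (baseline) medium and of the perturbed
#' medium on one channel, computes the attenuation change
#' `dA = -log(N_i / N_0)`, the mean-time change `d_m1 = m1_0 - m1_i` and the
#' variance change `dV = V_0 - V_i`. With these sign conventions a purely
#' absorbing perturbation yields non-negative `dA` on a single channel.
#'
#' @param baseline,perturbed One-row moment tibbles from [moments()].
#' @param log_base `"natural"` (default, the moments-literature convention)
#'   or `"log10"` for the attenuation logarithm.
#' @return A one-row tibble with `dA`, `d_m1` (ps) and `dV` (ps^2).
#' @export
delta_moments <- function(baseline, perturbed, log_base = c("natural", "log10")) {
  log_base <- match.arg(log_base)
  stopifnot(all(c("N", "m1", "V") %in% names(baseline)),
            all(c("N", "m1", "V") %in% names(perturbed)))
  if (perturbed$N[1] <= 0) stop("perturbed total count must be positive", call. = FALSE)
  ratio <- perturbed$N[1] / baseline$N[1]
  tibble::tibble(
    dA = if (log_base == "natural") -log(ratio) else -log10(ratio),
    d_m1 = baseline$m1[1] - perturbed$m1[1],
    dV = baseline$V[1] - perturbed$V[1]
  )
}

#' Single and dual subtraction of moment changes
#'
#' `single_subtraction()` subtracts a near-channel moment change from the
#' far-channel change of the same source (component-wise), suppressing
#' absorption changes common to the superficial layer.
#' `dual_subtraction()` averages the two single subtractions of the two
#' sources flanking the detector pair, symmetrizing the sensitivity volume.
#'
#' @param delta_far,delta_near One-row delta tibbles (from [delta_moments()])
#'   for the far and near channel of one source. If both carry a `role`
#'   column, far/near bookkeeping is verified.
#' @return A one-row tibble with `dA`, `d_m1`, `dV`.
#' @export
single_subtraction <- function(delta_far, delta_near) {
  if ("role" %in% names(delta_far) && "role" %in% names(delta_near) &&
      identical(delta_far$role[1], delta_near$role[1])) {
    stop("single subtraction needs one far and one near channel, got two '",
         delta_far$role[1], "' channels", call. = FALSE)
  }
  tibble::tibble(
    dA = delta_far$dA[1] - delta_near$dA[1],
    d_m1 = delta_far$d_m1[1] - delta_near$d_m1[1],
    dV = delta_far$dV[1] - delta_near$dV[1]
  )
}

#' @rdname single_subtraction
#' @param ss_left,ss_right One-row single-subtraction deltas for the left
#'   and right source.
#' @export
dual_subtraction <- function(ss_left, ss_right) {
  tibble::tibble(
    dA = (ss_left$dA[1] + ss_right$dA[1]) / 2,
    d_m1 = (ss_left$d_m1[1] + ss_right$d_m1[1]) / 2,
    dV = (ss_left$dV[1] + ss_right$dV[1]) / 2
  )
}

# Moments of every column of a curve matrix. window = NULL truncates each
# column on its own 1%-of-max rule; an integer range applies a fixed bin
# window (the baseline channel's) to every column.
column_moments <- function(mat, time_ps, threshold_fraction = 0.01,
                           window = NULL) {
  res <- matrix(NA_real_, ncol(mat), 5,
                dimnames = list(NULL, c("N", "m1", "V", "m3", "m4")))
  for (j in seq_len(ncol(mat))) {
    d <- if (is.null(window)) {
      truncate_dtof(dtof(time_ps, mat[, j]), threshold_fraction)
    } else {
      dtof(time_ps[window], mat[window, j])
    }
    res[j, ] <- as.numeric(moments(d)[1, ])
  }
  tibble::as_tibble(res)
}

# Bin window retained by truncate_dtof, as an index range on the full grid.
truncation_window <- function(counts, threshold_fraction) {
  thr <- threshold_fraction * max(counts)
  imax <- which.max(counts)
  lo <- imax
  while (lo > 1L && counts[lo - 1L] >= thr) lo <- lo - 1L
  hi <- imax
  while (hi < length(counts) && counts[hi + 1L] >= thr) hi <- hi + 1L
  lo:hi
}

#' Assemble 3D sensitivity maps from a sweep dataset
#'
#' Runs the full moment pipeline on every absorber position of a
#' [simulate_sweep()] dataset (or one read back from disk): replicate
#' handling (drop the motion-period DTOFs, average the rest), optional
#' dead-time correction, tail truncation, moment computation, and baseline
#' subtraction, then forms the five method maps: the two far single-distance
#' channels (`sd_far_left` = left source to detector 2, `sd_far_right` =
#' right source to detector 1), the two single subtractions and the dual
#' subtraction.
#'
#' @param dataset A `sweep_dataset`.
#' @param drop_first Replicates discarded at each position (motor motion).
#' @param n_average Replicates averaged after the drop.
#' @param threshold_fraction Truncation threshold for [truncate_dtof()].
#' @param truncation_mode `"baseline"` (default) freezes the truncation bin
#'   window on each channel's unperturbed DTOF and applies it to every
#'   absorber position, so moment changes are not confounded by
#'   perturbation-driven shifts of the analysis window; `"per_dtof"`
#'   recomputes the 1%-of-max window for every position.
#' @param log_base Attenuation logarithm, see [delta_moments()].
#' @param deadtime_correct Apply [correct_deadtime()] before analysis when
#'   the dataset was simulated with dead-time loss.
#' @param baseline `"absent"` (default) uses the absorber-absent curves as
#'   the homogeneous reference; `"outermost"` emulates the experimental
#'   practice of averaging the acquisitions with the absorber parked at the
#'   outermost X positions of the sweep, where its influence on the
#'   channels is negligible.
#' @param use_expected Analyse the noiseless expected curves even if Poisson
#'   replicates are present.
#' @return A tibble of class `sensitivity_maps` in long form: `i`, `x_mm`,
#'   `y_mm`, `z_mm`, `method`, `moment` (`"A"`, `"m1"`, `"V"`), `value`.
#'   Attributes carry the grid, the per-channel baseline moments (for the
#'   photon-noise model) and the simulation metadata.
#' @export
assemble_maps <- function(dataset, drop_first = 10, n_average = 10,
                          threshold_fraction = 0.01,
                          truncation_mode = c("baseline", "per_dtof"),
                          log_base = c("natural", "log10"),
                          deadtime_correct = TRUE,
                          baseline = c("absent", "outermost"),
                          use_expected = is.null(dataset$dtofs)) {
  stopifnot(inherits(dataset, "sweep_dataset"))
  log_base <- match.arg(log_base)
  truncation_mode <- match.arg(truncation_mode)
  baseline <- match.arg(baseline)
  time_ps <- dataset$tgrid$time_ps
  chans <- dataset$channels
  tau <- dataset$meta$noise$deadtime_tau_ps
  tcoll <- dataset$meta$noise$collection_time_s

  # collapse replicates -> one curve matrix (n_bins x n_pos) per channel
  curves <- list(); base_curve <- list()
  for (nm in chans$name) {
    if (use_expected) {
      curves[[nm]] <- dataset$expected[[nm]]
      base_curve[[nm]] <- dataset$baseline_expected[[nm]]
    } else {
      keep <- drop_first + seq_len(n_average)
      arr <- dataset$dtofs[[nm]]
      if (max(keep) > dim(arr)[3]) {
        stop("dataset holds fewer replicates than drop_first + n_average", call. = FALSE)
      }
      curves[[nm]] <- rowMeans(arr[, , keep, drop = FALSE], dims = 2)
      base_curve[[nm]] <- rowMeans(dataset$baseline_dtofs[[nm]][, keep, drop = FALSE])
    }
  }
  if (!is.null(tau) && tau > 0 && deadtime_correct) {
    for (det in c("1", "2")) {
      pair <- chans$name[chans$detector == det]
      a <- curves[[pair[1]]]; b <- curves[[pair[2]]]
      curves[[pair[1]]] <- correct_deadtime(a, b, tau, tcoll)
      curves[[pair[2]]] <- correct_deadtime(b, a, tau, tcoll)
      ba <- base_curve[[pair[1]]]; bb <- base_curve[[pair[2]]]
      base_curve[[pair[1]]] <- correct_deadtime(ba, bb, tau, tcoll)
      base_curve[[pair[2]]] <- correct_deadtime(bb, ba, tau, tcoll)
    }
  }

  if (baseline == "outermost") {
    outer_idx <- which(abs(dataset$positions$x_mm) ==
                         max(abs(dataset$positions$x_mm)))
    for (nm in chans$name) {
      base_curve[[nm]] <- rowMeans(curves[[nm]][, outer_idx, drop = FALSE])
    }
  }

  base_moments <- list(); deltas <- list()
  for (nm in chans$name) {
    win <- truncation_window(base_curve[[nm]], threshold_fraction)
    bm <- moments(dtof(time_ps[win], base_curve[[nm]][win]))
    base_moments[[nm]] <- bm
    pm <- column_moments(
      curves[[nm]], time_ps, threshold_fraction,
      window = if (truncation_mode == "baseline") win else NULL
    )
    ratio <- pm$N / bm$N[1]
    deltas[[nm]] <- tibble::tibble(
      dA = if (log_base == "natural") -log(ratio) else -log10(ratio),
      d_m1 = bm$m1[1] - pm$m1,
      dV = bm$V[1] - pm$V
    )
  }

  ss_left <- deltas$left_2 - deltas$left_1
  ss_right <- deltas$right_1 - deltas$right_2
  ds <- (ss_left + ss_right) / 2
  methods <- list(
    sd_far_left = deltas$left_2, sd_far_right = deltas$right_1,
    ss_left = ss_left, ss_right = ss_right, ds = ds
  )

  pos <- dataset$positions
  out <- purrr::map_dfr(names(methods), function(m) {
    d <- methods[[m]]
    tibble::tibble(
      i = rep(pos$i, 3L),
      x_mm = rep(pos$x_mm, 3L), y_mm = rep(pos$y_mm, 3L), z_mm = rep(pos$z_mm, 3L),
      method = m,
      moment = rep(c("A", "m1", "V"), each = nrow(pos)),
      value = c(d$dA, d$d_m1, d$dV)
    )
  })
  baseline_tbl <- dplyr::bind_cols(
    chans[, c("name", "role")],
    dplyr::bind_rows(base_moments[chans$name])
  )
  structure(
    out,
    class = c("sensitivity_maps", class(out)),
    grid = dataset$grid,
    baseline_moments = baseline_tbl,
    dmu_a_ball = dataset$meta$inclusion$dmu_a,
    log_base = log_base,
    meta = dataset$meta
  )
}

#' Planar projection of a sensitivity map
#'
#' Sums map values over one axis, yielding the 2D images conventionally
#' shown for the XZ (sum over Y), YZ (sum over X) or XY (sum over Z) planes.
#'
#' @param maps A `sensitivity_maps` tibble.
#' @param plane `"xz"`, `"yz"` or `"xy"`.
#' @return A tibble with the two retained coordinates, `method`, `moment`
#'   and the summed `value`.
#' @export
project_maps <- function(maps, plane = c("xz", "yz", "xy")) {
  plane <- match.arg(plane)
  keep <- switch(plane,
    xz = c("x_mm", "z_mm"), yz = c("y_mm", "z_mm"), xy = c("x_mm", "y_mm")
  )
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(maps),
                    dplyr::across(dplyr::all_of(c(keep, "method", "moment")))),
    value = sum(.data$value), .groups = "drop"
  )
}
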