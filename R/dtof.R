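#' Construct a DTOF histogram
#'
#' A distribution of times of flight of photons (DTOF) is the histogram of
#' photon arrival delays recorded by a time-correlated single-photon-counting
#' channel: uniformly spaced time bins (picoseconds) and a non-negative count
#' per bin. Counts are real-valued so that averaged DTOFs are representable;
#' the Poisson interpretation enters only at the noise-model stage.
#'
#' @param time_ps Numeric vector of bin centres in picoseconds, strictly
#'   increasing with uniform spacing.
#' @param counts Numeric vector of non-negative photon counts, same length.
#' @param channel Optional channel label, e.g. `"left_2"` (source x detector).
#' @return A tibble of class `dtof` with columns `time_ps` and `counts` and
#'   attributes `bin_width` (ps) and `channel`.
#' @examples
#' d <- dtof(seq(5, 4000, by = 10), dnorm(seq(5, 4000, by = 10), 1500, 300))
#' moments(d)
#' @export
dtof <- function(time_ps, counts, channel = NA_character_) {
  stopifnot(is.numeric(time_ps), is.numeric(counts))
  if (length(time_ps) != length(counts)) {
    stop("`time_ps` and `counts` must have the same length", call. = FALSE)
  }
  if (length(time_ps) < 1L) stop("a DTOF needs at least one bin", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(!is.finite(counts))) stop("counts must be finite", call. = FALSE)
  bw <- if (length(time_ps) > 1L) diff(time_ps) else 1
  if (length(time_ps) > 1L) {
    if (any(bw <= 0)) stop("`time_ps` must be strictly increasing", call. = FALSE)
    if (max(abs(bw - bw[1])) > 1e-6 * bw[1]) {
      stop("`time_ps` must be uniformly spaced", call. = FALSE)
    }
  }
  out <- tibble::tibble(time_ps = as.numeric(time_ps), counts = as.numeric(counts))
  attr(out, "bin_width") <- bw[1]
  attr(out, "channel") <- channel
  class(out) <- c("dtof", class(out))
  out
}

#' @export
print.dtof <- function(x, ...) {
  cat(sprintf(
    "<dtof> %d bins, %.1f ps/bin, channel %s, N = %.4g\n",
    nrow(x), attr(x, "bin_width"), attr(x, "channel"), sum(x$counts)
  ))
  NextMethod()
}

restore_dtof <- function(template, time_ps, counts) {
  dtof(time_ps, counts, channel = attr(template, "channel"))
}

#' Truncate a DTOF at a fraction of its maximum
#'
#' Mirrors the standard moment-analysis preprocessing: both tails of the
#' histogram are cut where the count falls below a fraction (default 1%) of
#' the global maximum. The scan moves outward from the maximum bin and cuts
#' at the first crossing on each side, so later noise-driven re-crossings in
#' the tails do not re-extend the window. Bins exactly at the threshold are
#' retained.
#'
#' @param x A [dtof()].
#' @param threshold_fraction Fraction of the maximum count below which bins
#'   are discarded; strictly between 0 and 1. Default 0.01.
#' @return The truncated `dtof` (a contiguous bin range containing the peak).
#' @export
truncate_dtof <- function(x, threshold_fraction = 0.01) {
  stopifnot(inherits(x, "dtof"))
  if (!(threshold_fraction > 0 && threshold_fraction < 1)) {
    stop("`threshold_fraction` must be in (0, 1)", call. = FALSE)
  }
  cts <- x$counts
  peak <- max(cts)
  if (peak <= 0) stop("cannot truncate an empty DTOF (all counts zero)", call. = FALSE)
  thr <- threshold_fraction * peak
  imax <- which.max(cts)
  lo <- imax
  while (lo > 1L && cts[lo - 1L] >= thr) lo <- lo - 1L
  hi <- imax
  n <- length(cts)
  while (hi < n && cts[hi + 1L] >= thr) hi <- hi + 1L
  restore_dtof(x, x$time_ps[lo:hi], cts[lo:hi])
}

#' Statistical moments of a DTOF
#'
#' Computes the total photon count N, the mean time of flight m1 (ps), the
#' centralized variance V (ps^2) and the centralized third and fourth
#' moments m3 (ps^3) and m4 (ps^4) of a (typically truncated) DTOF. m4 is
#' required by the photon-noise model for the variance measurand.
#'
#' @param x A [dtof()]; truncation, where wanted, is applied by the caller.
#' @return A one-row tibble with columns `N`, `m1`, `V`, `m3`, `m4`.
#' @export
moments <- function(x) {
  stopifnot(inherits(x, "dtof"))
  N <- sum(x$counts)
  if (N <= 0) stop("moments undefined: DTOF has zero total counts", call. = FALSE)
  w <- x$counts / N
  m1 <- sum(w * x$time_ps)
  d <- x$time_ps - m1
  tibble::tibble(
    N = N,
    m1 = m1,
    V = sum(w * d^2),
    m3 = sum(w * d^3),
    m4 = sum(w * d^4)
  )
}

#' @rdname moments
#' @export
compute_moments <- moments

#' Bin-wise average of DTOFs
#'
#' Arithmetic mean of the counts of several DTOFs sharing one time grid and
#' channel, as used when collapsing repeated acquisitions at one absorber
#' position into a single histogram.
#'
#' @param dtofs A list of [dtof()] objects on identical bin grids.
#' @return A single `dtof` with the averaged (real-valued) counts.
#' @export
average_dtofs <- function(dtofs) {
  stopifnot(is.list(dtofs), length(dtofs) >= 1L)
  ref <- dtofs[[1L]]
  stopifnot(inherits(ref, "dtof"))
  for (d in dtofs[-1L]) {
    if (!inherits(d, "dtof") || nrow(d) != nrow(ref) ||
        max(abs(d$time_ps - ref$time_ps)) > 1e-9 * attr(ref, "bin_width")) {
      stop("all DTOFs must share the same bin grid", call. = FALSE)
    }
    ch <- c(attr(d, "channel"), attr(ref, "channel"))
    if (!anyNA(ch) && ch[1] != ch[2]) {
      stop("all DTOFs must come from the same channel", call. = FALSE)
    }
  }
  cts <- rowMeans(vapply(dtofs, function(d) d$counts, numeric(nrow(ref))))
  restore_dtof(ref, ref$time_ps, cts)
}
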