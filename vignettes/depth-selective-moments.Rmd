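---
title: "Depth-selective analysis of DTOF moments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-selective analysis of DTOF moments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtofsens)
```

## The measurement problem

Time-domain near-infrared spectroscopy (td-NIRS) injects picosecond laser
pulses into a scattering medium (tissue, or a liquid phantom standing in for
it) and histograms the arrival delays of detected photons into a
distribution of times of flight (DTOF). Its first statistical moments — the
total count $N_{tot}$, the mean time of flight $\langle t\rangle$ and the
variance $V$ — respond differently to absorption changes at different
depths: late photons are more likely to have visited deep tissue, so the
higher moments weight deep absorption changes more strongly. The practical
obstacle is that signals are contaminated by absorption changes in the
superficial layer (scalp and skull, in brain applications).

`dtofsens` implements the measurement-geometry remedy: two detectors a few
millimetres apart sandwiched between two sources, giving two *far* channels
(3 cm separation by default) and two *near* channels (2.5 cm). For each
moment $M$ and each channel, a perturbation changes the moment by

$$\Delta A = -\ln\frac{N_{tot,i}}{N_{tot,0}},\qquad
  \Delta\langle t\rangle = \langle t\rangle_0 - \langle t\rangle_i,\qquad
  \Delta V = V_0 - V_i,$$

where subscript 0 denotes the homogeneous reference. The *single
subtraction* (SS) for one source subtracts the near-channel change from the
far-channel change, cancelling contributions common to the superficial
layer; the *dual subtraction* (DS) averages the two single subtractions:

$$\Delta M_{SS,left} = \Delta M_{left,2} - \Delta M_{left,1},\quad
  \Delta M_{SS,right} = \Delta M_{right,1} - \Delta M_{right,2},\quad
  \Delta M_{DS} = \tfrac12(\Delta M_{SS,left} + \Delta M_{SS,right}).$$

Mapping these changes while a small absorber is stepped through the medium
yields 3D sensitivity maps per method and moment; collapsing them along
depth gives depth-related sensitivity profiles; and ratios of deep to
superficial layer sums give the depth selectivity $S_M$. Because photon
noise ultimately limits what a more selective measurand is worth, the
package scores each method/moment by the product of depth selectivity and
contrast-to-noise ratio,

$$S_M \times CNR_M
  = \frac{\left(\sum_{lower} \Delta M_i\right)^2}
         {\sigma(M)\,\sum_{upper} \Delta M_i},$$

with the superficial compartment 0–15 mm by default (the upper end of
typical adult scalp-plus-skull thickness) and the deep compartment from
15 mm to the bottom of the mapped volume.

## Forward model

The physics engine is the diffusion approximation for a homogeneous
semi-infinite medium, with the conventions of the moments literature:

* diffusion coefficient $D = 1/(3\mu_s')$ (absorption-independent),
* isotropic source buried at $z_0 = 1/\mu_s'$,
* extrapolated boundary at $z = -z_b$ with $z_b = 2AD$ and the
  internal-reflection factor $A$ from the Groenhuis/Egan polynomial at
  $n = 1.33$ (water-based phantoms); a zero-fluence boundary is available
  as an option,
* detected reflectance modelled as the outward flux of the image-source
  solution (`reflectance_td()`), in which absorption enters only through
  the Beer–Lambert factor $e^{-\mu_a v t}$.

Sensitivity to a small absorption change in a voxel is the Born kernel: the
causal time-convolution of the source-to-voxel fluence Green's function
with the voxel-to-detector remission Green's function
(`absorption_jacobian_td()`). Two numerical choices matter here:

* The Beer–Lambert factor commutes exactly with the time convolution, so
  it is factored out of both kernels and reapplied analytically. Absorption
  scaling of the Jacobian therefore holds to machine precision rather than
  to convolution-discretization accuracy.
* A fluence-in / flux-out kernel is not exactly symmetric under
  source–detector exchange (the two Green's functions have different
  functional forms). The Jacobian is symmetrized over the exchange; each
  orientation satisfies the total-pathlength identity
  $\int J\,dV = v\,t\,R(t)$ exactly in the continuum, hence so does the
  average, and optical reciprocity holds exactly by construction. The
  tests verify the pathlength identity to within 5% on a dense voxel grid
  (the residual is spatial-discretization error).

Discrete convolutions are computed by FFT on the shared time grid (default
0–10 ns in 4096 bins, about 2.4 ps/bin, mirroring TCSPC resolution). A
known property of the discrete causal convolution on bin centres is a
half-bin offset in the mean time (variances add exactly); it cancels in
all moment *differences* and is checked explicitly in the tests.

`estimate_optical_properties()` inverts the model: instrument-response
moments are subtracted (convolution adds $m_1$ and $V$ exactly), then
$(\mu_a, \mu_s')$ is found so the model's quadrature moments match the
IRF-free measured $(m_1, V)$ at the given separation. The solver is BFGS on
$(\log\mu_a, \log\mu_s')$ followed by a damped-Newton polish; convergence
is declared only below $10^{-6}$ relative residual on both moments, and the
achieved residuals are reported in the fit object.

## The synthetic phantom

`simulate_sweep()` generates the full in-silico experiment that the
analysis functions consume: a liquid-phantom tank with optical properties
$\mu_a \approx 0.1\ \mathrm{cm^{-1}}$, $\mu_s' \in \{5, 10, 20\}\
\mathrm{cm^{-1}}$, the four-channel optode line (sources at $\pm 2.75$ cm,
detectors at $\mp 0.25$ cm), and a small cylindrical absorber (3 mm
diameter, 5 mm height) stepped over a 75 mm × 20 mm × 35 mm cuboid in
2 mm steps along X and depth Z and 1 mm along Y. Per position and channel
the simulator produces 20 Poisson replicates at an expected
157 500 counts per DTOF (a 3.5 MHz total rate shared by the two DTOFs of a
detector over a 0.09 s collection window); the analysis drops the first 10
(recorded while the stepper motor moves) and averages the next 10.
Instrument response is a Gaussian of 650 ps FWHM by default (measured
systems of this class span roughly 595–717 ps). An optional
non-paralyzable dead-time distortion couples the two channels of a
detector through their summed count rate, emulating the cross-talk of
interleaved two-source acquisition; `correct_deadtime()` inverts it
algebraically from the recorded rates.

What the generator deliberately does **not** emulate:

* The physical absorber is effectively *black*; its contrast exceeds
  linear perturbation theory. The simulator works at Born level with a
  configurable effective strength, default $\Delta\mu_{a}$ = 0.25 cm⁻¹
  over the cylinder volume, calibrated once so the peak far-channel
  $\Delta A$ is ≈ 0.1 — comfortably inside the linear regime. Absolute
  experimental map magnitudes are therefore out of scope by design; all
  cross-method comparisons (which is what the metrics are for) are
  unaffected.
* Measured IRFs have asymmetric tails and afterpulsing; the Gaussian IRF
  reproduces only their width. Moment differences are IRF-invariant, so
  this mainly affects truncation-window placement.
* Physiological noise, motion artefacts, and layered media are absent.
  Passing tests demonstrate internal consistency of the method chain and
  its directional claims under photon noise, not in-vivo performance.

## Photon-noise model

For a DTOF with $N$ counts the theoretical standard deviations are
$\sigma^2(N) = N$, $\sigma^2(m_1) = V/N$ and
$\sigma^2(V) = (m_4 - V^2)/N$ with $m_4$ the fourth central moment. The
attenuation measurand is a log-ratio, so the delta method gives
$\sigma(\Delta A) = 1/\sqrt N$; this is the sigma used in the CNR of the
attenuation row (the printed formula for $\sigma(N)$ alone is not
dimensionally commensurate with a log-ratio contrast). Error propagation
across geometries gives
$\sigma^2_{SS} = \sigma^2_{SD,far} + \sigma^2_{SD,near}$ and, because DS
averages two single subtractions,
$\sigma^2_{DS} = \tfrac12\sigma^2_{SS}$, i.e.
$\sigma_{DS}/\sigma_{SS} = 1/\sqrt2$. `photon_noise_sd()` implements the
model; `empirical_noise_sd()` cross-validates it by Poisson replication
(the acceptance tests use $10^4$ replications at $N = 10^6$ and require
agreement within 5%, and 3% on the DS/SS ratio).

In the performance product, sums are signed: DS depth selectivity for
$\Delta\langle t\rangle$ and $\Delta V$ is genuinely negative (the
superficial layers carry small negative sensitivity), so the product's
magnitude and sign are reported separately.

## Analysis-window design choice

Moments are computed after cutting both DTOF tails where counts fall below
1% of the maximum, scanning outward from the peak and cutting at the first
crossing (robust to noisy re-crossings; bins exactly at the threshold are
kept). One genuinely open choice is whether that window is recomputed for
every absorber position or frozen on each channel's unperturbed DTOF.
`assemble_maps()` freezes it at baseline by default
(`truncation_mode = "baseline"`). The reason is quantitative: the
perturbation moves the curve maximum and hence the window edges, and the
resulting window-shift bias on $\Delta V$ is larger than the small
negative superficial DS sensitivity itself, flipping its sign. With the
frozen window the noiseless Born chain reproduces every directional
finding the metrics are designed around; the per-position mode remains
available (`truncation_mode = "per_dtof"`) for data whose baseline drifts.

The homogeneous reference is the absorber-absent simulation by default;
`baseline = "outermost"` instead averages the acquisitions with the
absorber parked at the outermost X positions, the practical choice for
real sweeps, and agrees with the absorber-absent reference to better than
1% when those positions are a few separations away from the optodes.

## Problem sizes and tolerances

The package's own test and acceptance runs use reduced sweep grids chosen
as the smallest configurations that exhibit the full qualitative structure:
15 × 16 × 3 positions (X × Z × Y, 5/2/5 mm steps) for the directional
findings, 10 × 8 × 5 for the voxel-wise Born-consistency check (within 1%
of the direct Jacobian prediction), 2048-bin time grids, and
$10^4$-replication noise Monte-Carlo. Depth bands of "about 5 mm" on the
2 mm depth grid are realized as 3 layers (6 mm) by default, with the band
start swept from 5 to 30 mm. Quadrature tolerances are $10^{-10}$
relative; moment-inversion convergence is $10^{-6}$ relative on both
moments. All randomness flows from a single integer seed, and a sweep
dataset is bit-reproducible given its configuration and seed.

## Known limitations

* Born-level perturbation: strong absorbers saturate ($\Delta A$ is
  logarithmic) and the simulator warns when a perturbation removes more
  than half of a curve's mass.
* Homogeneous semi-infinite medium only; no layered media, no
  heterogeneous backgrounds, no Monte-Carlo transport.
* The diffusion approximation is least reliable within roughly one
  transport length of sources, detectors and boundaries — exactly where
  superficial sensitivity lives — so near-surface map values are
  model-limited.
* Depth-selectivity ratios become unstable wherever the superficial band
  sum approaches zero (a real feature of DS attenuation maps); such points
  are reported as undefined rather than clipped.
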