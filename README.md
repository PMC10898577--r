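# dtofsens

Depth-selective sensitivity analysis for time-domain diffuse reflectance
(td-NIRS), built around the statistical moments of photon time-of-flight
distributions (DTOFs).

## What problem this solves

Near-infrared monitoring of deep tissue (most prominently the brain cortex)
is contaminated by absorption changes in the superficial layer. In
time-domain NIRS the DTOF moments — total counts *N*, mean time of flight
⟨t⟩ and variance *V* — carry depth information, and a measurement geometry
with two detectors sandwiched between two sources lets one subtract
near-channel from far-channel moment changes (*single subtraction*, SS) and
average the two subtractions (*dual subtraction*, DS), pushing the
sensitivity volume deeper and suppressing superficial signals.

For a moment *M* the per-channel changes against the homogeneous reference
are

    ΔA = −ln(N_i / N_0),    Δ⟨t⟩ = ⟨t⟩_0 − ⟨t⟩_i,    ΔV = V_0 − V_i,

and the subtraction geometries are

    ΔM_SS,left  = ΔM_left,2  − ΔM_left,1
    ΔM_SS,right = ΔM_right,1 − ΔM_right,2
    ΔM_DS       = (ΔM_SS,left + ΔM_SS,right) / 2.

The package scores each method and moment by depth selectivity
`S = Σ_lower ΔM / Σ_upper ΔM`, the photon-noise contrast-to-noise ratio
`CNR = Σ_lower ΔM / σ(M)` with `σ²(N) = N`, `σ²(m1) = V/N`,
`σ²(V) = (m4 − V²)/N` and `σ²_DS = σ²_SS/2`, and their product `S × CNR`.

Everything is exercisable with no external data: a diffusion-theory forward
model (semi-infinite medium, extrapolated boundary, Born absorption
Jacobians) drives an in-silico liquid-phantom experiment in which a small
absorbing cylinder is swept through the medium, with IRF broadening,
Poisson counting noise and optional TCSPC dead-time cross-talk.

Intended users: biomedical-optics researchers designing or evaluating
multi-distance td-NIRS probes and analysis chains.

## Worked example

Simulate a reduced noiseless sweep on the default phantom
(µa = 0.1 cm⁻¹, µs′ = 10 cm⁻¹, 3 / 2.5 cm separations), build the
sensitivity maps, and compare methods:

```r
library(dtofsens)
library(dplyr)

props <- optical_properties(0.1, 10)
geo   <- optode_geometry(3, 2.5)
grid  <- sweep_grid(x_extent_mm = 70, x_step_mm = 5, y_extent_mm = 10,
                    y_step_mm = 5, z_extent_mm = 30, z_step_mm = 2)
sweep <- simulate_sweep(props, geo, grid, inclusion(),
                        noise_config(poisson = FALSE, irf_fwhm_ps = 650),
                        time_grid(10000, 2048), seed = 1)
maps  <- assemble_maps(sweep)

overall_performance(maps) |>
  filter(method %in% c("sd_far_left", "ds")) |>
  select(method, moment, S, CNR, performance)
#> # A tibble: 6 × 5
#>   method      moment      S   CNR performance
#>   <chr>       <chr>   <dbl> <dbl>       <dbl>
#> 1 ds          A      0.123   19.1        2.35
#> 2 ds          V      1.60    22.3       35.6
#> 3 ds          m1     0.667   24.0       16.0
#> 4 sd_far_left A      0.0431  40.8        1.76
#> 5 sd_far_left V      0.431   48.4       20.8
#> 6 sd_far_left m1     0.209   52.4       11.0
```

Reading this: the single-distance far channel (`sd_far_left`) has the
larger raw CNR, but the dual subtraction's much higher depth selectivity
wins the product for every moment, and within each method the product
ranks attenuation < mean time < variance. The peak of the depth-related
sensitivity also sits deeper for DS:

```r
peak_sensitivity_depth(depth_profile(maps)) |>
  filter(method %in% c("sd_far_left", "ds"))
#> # A tibble: 6 × 3
#>   method      moment z_peak_mm
#>   <chr>       <chr>      <dbl>
#> 1 ds          A            8.5
#> 2 ds          V           14.5
#> 3 ds          m1          12.5
#> 4 sd_far_left A            4.5
#> 5 sd_far_left V           10.5
#> 6 sd_far_left m1           8.5
```

`autoplot(maps)`, `autoplot(depth_profile(maps))`,
`autoplot(depth_selectivity(maps))` and
`autoplot(overall_performance(maps))` render the standard figures.
`run_simulate()` / `run_analyze()` (and the `inst/cli/dtofsens` script)
drive the same pipeline from YAML configurations and write CSV/JSON
artifacts. `estimate_optical_properties()` recovers (µa, µs′) from
measured DTOF moments after IRF subtraction.

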