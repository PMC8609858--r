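# fluosignal

Photon-budget modelling of chlorophyll fluorescence as a cell-density-
dependent light signal in marine diatom populations, with the surrounding
photophysiology and station-survey statistics.

During blooms, diatoms such as *Phaeodactylum tricornutum* reach 10⁶–3×10⁸
cells/L, and the red (~685 nm) chlorophyll fluorescence re-emitted by each
cell becomes a candidate *biotic* signal: red light upregulates the
iron-uptake genes *ISIP1* and *ISIP2a*, so a cell that can sense its
neighbours' fluorescence could tune iron acquisition to population density.
This package implements the quantitative side of that hypothesis for
modellers and experimentalists working on phytoplankton optics:

* **Calibration** — from a measured bulk chlorophyll fluorescence photon
  flux density (CFPFD, µmol photons m⁻² s⁻¹) to the flux emitted by one
  cell: `u = 6·CFPFD·V^(2/3)/(N·V)`, giving `u = 9.07×10⁻¹²` µmol photons/s
  for the reference culture measurement.
* **Pairwise model** — flux density received from a neighbour at centre
  distance R: `CFPFD = u·(πr²/4πR²)/(2πr²) = u/(8πR²)`, an inverse-square
  law (r = plastid radius, 3 µm).
* **Population model** — the attenuated mean-field integral over an evenly
  distributed population of density N with diffuse attenuation Kd:
  `CFPF = ∫₀^∞ 4πR²·N·u·(πr²/4πR²)·e^(−Kd·R) dR = Nuπr²/Kd`,
  equivalently `CFPFD = Nu/(2Kd)`; plus the contribution radius
  `−log(1−f)/Kd` and adaptive quadrature for finite truncations.
* **Monte Carlo oracle** — discrete cells as a seeded Poisson point
  process, stratified radially so oceanic densities are tractable; an
  independent, unbiased check on the integral.
* **Photophysiology** — Fv/Fm, Y(II), NPQ, rETR(II), DEPS from PAM light
  curves and pigment tables; spectral peak detection and band-integrated
  CFPFD from emission spectra.
* **Station statistics** — ISIP expression shares (percentage of the
  four-gene ISIP sum, normalized by total diatom unigene expression) and
  iron-bin-stratified Pearson correlation against chlorophyll content.
* **Synthetic data** — seeded generators for spectra, PAM traces and
  station tables with exactly controlled per-bin correlations, so every
  analysis runs without external downloads.

## Worked example

```r
library(fluosignal)

# per-cell flux from the bulk measurement (1 mL at 1.6e6 cells/mL)
meas <- calibration_measurement(2.418e-2, cells_per_ml(1.6e6))
u <- calibrate_per_cell_flux(meas)
u
#> [1] 9.0675e-12

# two touching cells (R = 2r = 6 um) and two cells 100 um apart
pairwise_cfpfd(micrometres(c(6, 100)))
#> [1] 1.002455e-02 3.608838e-05

# bloom-scale population: flux density at a focal cell, and the radius
# enclosing 99.9% of it
population_cfpfd(cells_per_ml(1.6e6))
#> [1] 12.72982
contribution_radius(0.999)
#> [1] 12.11887
```

A cell touching one neighbour receives ~0.01 µmol photons m⁻² s⁻¹ — weak —
but embedded in a dense population the same cell receives ~12.7, comparable
to the red-light intensities that induce *ISIP* expression; 99.9% of that
flux originates within 12.1 m regardless of density. The Monte Carlo check:

```r
cfg <- point_process_config(1e8, outer_radius = 20, replicates = 200,
                            seed = 2024)
simulate_received_flux(cfg, tail_radius = contribution_radius(0.999))
#> Discrete-cell fluorescence simulation
#>   replicates : 200 (seed 2024)
#>   mean flux  : 4.49916e-14 +/- 2.7e-17 umol photons/s
#>   integral   : 4.49903e-14  (z = 0.05)
#>   share beyond 12.12 m: 0.0989%
```

And the station-survey statistics on a synthetic table whose per-bin
correlations mirror the qualitative ocean pattern:

```r
tab <- make_station_table(seed = 7, rho = c(0.44, 0.84, 0.66, 0))
stratified_pearson(tab)
#>        bin iron_lower iron_upper  n       r            p computable
#>  1.24-1.39       1.24       1.39 15  0.4400 0.1007419875       TRUE
#>  0.98-1.13       0.98       1.13 15  0.8400 0.0000889233       TRUE
#>   0.13-0.3       0.13       0.30 15  0.6600 0.0074169021       TRUE
#>     0-0.05       0.00       0.05 15 -0.0000 1.0000000000       TRUE
#>     pooled         NA         NA 60  0.3775 0.0029483030       TRUE
```

## Analysis workflow

The `analysis/` directory holds the numbered drivers that walk through the
full study on synthetic inputs, writing tables under `results/`:

| script | what it does |
| --- | --- |
| `01_calibrate_flux.R` | spectrum → 685 nm peak → band CFPFD → per-cell flux u |
| `02_pairwise_geometry.R` | received CFPFD versus centre distance, 6–100 µm |
| `03_population_model.R` | quadrature vs closed form, bloom density scan, contribution radii |
| `04_monte_carlo_check.R` | discrete-cell simulation vs the truncated integral |
| `05_photophysiology.R` | PAM light-curve parameters and DEPS |
| `06_station_correlation.R` | stratified Pearson analysis and rank-recovery experiment |

Run any of them from the repository root, e.g.
`Rscript analysis/03_population_model.R`.

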