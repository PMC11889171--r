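# fibdamage

Quantitative profiling of focused-ion-beam (FIB) milling damage in cryo-ET
lamellae.

Milling a lamella with a (plasma) focused ion beam damages a near-surface
layer of the sample through the ion collision cascade. `fibdamage`
implements the subtomogram-averaging analysis used to measure how deep that
damage reaches: per-particle distances to the two milling surfaces,
depth-binned particle cohorts with tomogram-matched random controls,
Rosenthal–Henderson B-factor estimation with full standard-error
propagation, and weighted exponential-decay fits of the resulting damage
curves. It also covers the companion analysis of the amorphous layer on the
lamella *backside* (1-µm distance groups, Spearman trend, amorphous-length
comparison between milling currents) and a self-contained Fourier shell
correlation module for half-map resolution estimation.

The package is aimed at cryo-ET practitioners who have per-particle
metadata (STAR files from Warp/RELION/M), sparse manual annotations of the
milling surfaces, and per-subset resolutions from refinement software — and
at method developers, who can exercise every stage on the bundled synthetic
generator without any experimental data.

## The model

Resolution and particle number are linked by the Rosenthal–Henderson
relation. With `y = 1/resolution²` (Å⁻²) and `N` the number of particles,

```
y = m · ln(N) + c,        B = 2/m   (Å²)
```

fitted by OLS over all points of three independent subset-series repeats;
`σ_B = 2σ_m/m²`. Damage at depth `d` from the milling surface is summarised
by the ratio of a depth group's B-factor to its tomogram-matched control
(same per-tomogram particle counts, drawn farther than 60 nm from the
surfaces), and by the difference in resolution extrapolated to 5000
particles, with

```
σ_y = sqrt((σ_m·x)² + σ_c²),   x = ln(5000),   σ_res = σ_y / (2 y^{3/2})
```

Both curves are fitted with a weighted (1/SE²) three-parameter exponential
decay `y = A·e^(−k·x) + c`, whose rate `k` (nm⁻¹) characterises the depth
of damage penetration.

## Worked example

The package ships reference B-factor measurements from a xenon PFIB
milling-damage experiment (5-nm surface distance groups with matched
controls, and 1-µm backside groups). Reconstructing the damage curves from
them:

```r
library(fibdamage)

surf <- surface_worked_example()
surf$points[1:3, c("bin", "x_mid_nm", "ratio", "dres_A")]
#>   bin         x_mid_nm ratio dres_A
#> 1 depth_05_10      7.5  3.33   5.30
#> 2 depth_10_15     12.5  1.58   2.05
#> 3 depth_15_20     17.5  1.40   1.08
surf$dres_fit
#> <decay_fit: y = 17.66 exp(-0.1653 x) +0.0177, R^2 = 0.983>
surf$ratio_fit
#> <decay_fit: y = 7.48 exp(-0.1831 x) +1.003, R^2 = 0.948>
```

The shallowest usable bin (5–10 nm) shows a 3.3× inflated B-factor and a
5.3 Å resolution penalty at 5000 particles relative to its matched control;
the penalty decays with rate ≈ 0.17–0.18 nm⁻¹ (decay length ≈ 5.5–6 nm), so
damage effects become negligible a few tens of nm into the lamella.

```r
back <- backside_worked_example()
c(back$min_B, back$max_B, back$spearman_r, back$spearman_p)
#> [1] 284.0000000 321.0000000  -0.3077935   0.6000000
```

Backside B-factors stay in a narrow 284–321 Å² band with no significant
distance trend — no detectable damage beyond the visible amorphous layer.

A fully synthetic run (no experimental inputs):

```r
cfg <- synthetic_config(seed = 42)          # ~80,000 particles, 20 tomograms
geo <- simulate_geometry(cfg)
parts <- simulate_particles(cfg, geo)
prof <- run_depth_profile(parts, geo$annotations,
                          synthetic_resolution_provider(cfg),
                          config = list(seed = 42))
prof$ratio_fit$k        # ~0.18 nm^-1, truth 1/5.4 = 0.185
```

A thin command-line wrapper for shell use is in
`inst/scripts/fibdamage-profile.R` (`depth`, `backside`, `simulate`,
`worked-examples` subcommands).

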