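# synaptometry

Quantitative analysis of synaptic connectivity in volume electron
microscopy (FIB-SEM) stacks of brain neuropil, built on *skeletonized*
fiber tracing rather than dense reconstruction.

Most cortical synapses lie in the neuropil — the feltwork of axons,
dendrites and spines between cell bodies. At FIB-SEM resolution
(≈ 5 × 5 × 20 nm voxels), synaptic junctions appear as dark,
electron-dense pre- and postsynaptic thickenings, and each nerve fiber
can be reduced to a 3D skeleton linked to its synapses. From a stack plus
skeletons, `synaptometry` computes the standard connectivity panel for a
tissue region, for anyone comparing the synaptic organization of brain
regions or conditions:

- **Segmentation** — Gaussian pre-filter, global gray-level threshold
  (dark = electron-dense), 3D connected components (6/18/26) with a
  minimum object size.
- **Stereology** — unbiased 3D counting frame (three acceptance planes,
  three *extended* exclusion planes: count `N` objects that intersect the
  brick and touch no exclusion plane), shrinkage-corrected volumetric
  density `N / (V / 0.87)` in synapses/µm³.
- **Skeleton metrics** — 3D lengths; linear densities `n / L_shaft` in
  synapses per µm of shaft (≥ 3 µm fibers; spine branches excluded from
  the denominator; lengths corrected by `1/0.96`); fiber classification
  (spiny/smooth dendrites, excitatory/inhibitory/myelinated axons,
  non-synaptic fibers); AS/SS × spine/shaft target distributions with the
  head/neck split; multi-contact and en-passant/terminal bouton
  statistics; per-class length densities in m/mm³ with percentage
  accounting; the spine-vs-shaft density correlation R².
- **Statistics** — chi-square for contingency tables, Mann-Whitney U for
  two groups (exact at small n), Kruskal-Wallis (exact permutation null
  at small n) with Bonferroni-corrected pairwise tests.
- **Synthetic data** — seeded phantom stacks with ground-truth voxel sets
  and fiber networks with known classes, rates and wiring, at the
  magnitudes of mouse hippocampal stratum radiatum; every stage is
  testable offline.

Everything tabular flows as tibbles, so results pipe straight into
dplyr/ggplot2; report objects have `tidy()`, `glance()` and `autoplot()`
methods.

## Worked example

```r
library(synaptometry)

nw <- generate_fiber_network(network_spec(volume_um3 = 500), seed = 1)
stopifnot(nrow(validate_fibers(nw$network, nw$synapses)) == 0)
report <- build_region_report("SR-like", nw$network, nw$synapses,
                              volume_um3 = 500)
report
#> <region_report> SR-like, 500.00 um^3 (corrected)
#>   synapses: 1297 (2.59 /um^3); AS 97.22%, SS 2.78%
#>   fibers: 1127; total length 8175.79 m/mm^3
```

2.59 synapses/µm³ with 2.78% symmetric (inhibitory) junctions is the
generator recovering its stratum-radiatum-like study conditions (≈ 2.7/µm³,
≈ 3% SS). The length accounting:

```r
tidy(report, "lengths")
#> # A tibble: 6 × 3
#>   fiber_class     length_m_per_mm3    pct
#> 1 spiny_dendrite             732.   8.95
#> 2 smooth_dendrite             79.2  0.969
#> 3 excitatory_axon           5378.  65.8
#> 4 inhibitory_axon            176.   2.16
#> 5 myelinated_axon             17.7  0.217
#> 6 non_synaptic              1793.  21.9
```

Excitatory axons dominate the fiber length, and the non-synaptic share
exceeds its nominal target because fibers that establish no synapse inside
the volume cannot be classified — the same selection a human tracer
faces (see the methods vignette). Per-fiber linear densities:

```r
library(dplyr)
linear_synapse_density(nw$network, nw$synapses) |>
  filter(included) |>
  group_by(fiber_class) |>
  summarise(n = n(), mean_density = round(mean(density_total), 2))
#>   fiber_class         n mean_density
#> 1 excitatory_axon   410         0.44
#> 2 inhibitory_axon    16         0.41
#> ...
#> 6 spiny_dendrite     58         3.35
```

Spiny dendrites carry ≈ 3.4 synapses per µm of shaft, an order of
magnitude above excitatory axons (≈ 0.4/µm) — the asymmetry that makes
linear densities informative. `glance(report)$spine_shaft_r_squared`
(≈ 0.003 here) shows spine and shaft synapse numbers varying
independently across dendrites.

A thin CLI wraps the same functions
(`inst/cli/synaptometry.R`: `simulate-stack`, `simulate-network`,
`segment`, `count`, `quantify`, `report`, `compare`), driven by a YAML
config with an embedded provenance block in every report.

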