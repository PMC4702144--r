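# pygoforage

Do sympatric Adélie (*Pygoscelis adeliae*) and gentoo (*P. papua*)
penguins compete for krill, or do they partition their foraging habitat?
`pygoforage` is an R package for biologging and movement-ecology analysts
that implements the complete analysis chain behind that question:

* **Dive analysis** — drift correction of time-depth-recorder traces,
  dive detection, and classification into *transit*, *search* and
  *forage* dives via the three krill-feeding signatures: **bottom time**
  (≥ 5 s within 80% of maximum depth), **wiggles** (vertical oscillations
  ≥ 2 m inside the bottom phase) and **plateaus** (slow flat shelves
  during ascent), plus per-individual → per-species behaviour summaries
  and the kernel-density foraging-depth mode.
* **Foraging ranges** — speed-filtered tracks, bivariate Gaussian kernel
  utilization distributions *f(x, y)* with normal-reference bandwidths,
  highest-density regions at 50% (core) and 95% (overall range) mass,
  species × tidal-regime overlap areas in km², and region labels
  (`adelie` / `gentoo` / `overlap` / `outside`) for every dive.
* **Prey field** — segmentation of AUV see-saw missions into vertical
  profiles; water-column features (chlorophyll maximum, 0–50 m integrated
  chlorophyll, mixed layer depth as max |∂σ<sub>t</sub>/∂z|, 1 W/m²
  isolume from log-linear PAR, thermocline, temperatures above/below);
  echogram segmentation of volume backscattering S<sub>v</sub> (dB) into
  **dense** vs **diffuse** krill aggregations with height / length /
  area / L:H / mean-S<sub>v</sub> morphometrics and per-profile
  presence flags.
* **Statistics** — two-sample Kolmogorov–Smirnov (two- and one-sided,
  D = sup|F₁ − F₂|), Mann–Whitney U (exact permutation p at small n),
  intraclass-correlation gating (ICC < 0.30 ⇒ K-S, else mixed model),
  random-intercept LMM/GLMMs, VIF screening, ΔAIC model sets
  (support at ΔAIC < 2), and repeated stratified 10-fold
  cross-validation (kappa, AUC, PCC, sensitivity, specificity).
* **Synthetic observing system** — generators for tracks, TDR traces and
  AUV missions with complete ground truth (planted dive signatures,
  planted elliptical aggregations, known water-column structure, and a
  planted "gentoo dive deeper in the overlap region" effect), so the
  whole pipeline is testable end to end without field data.

## Worked example

```r
library(pygoforage)

cfg <- sim_config(seed = 11, n_individuals_per_species = 6, days = 4)
bundle <- run_pipeline(cfg, cv_repeats = 3)
bundle
#> <pipeline_bundle>
#>   10782 dives (3545 forage), 1755 track fixes
#>   144 aggregations (56 dense), 80 profiles
#>   overlap area: diurnal 12.86 km2, semidiurnal 9.40 km2

bundle$summary$overlap_contrast
#> $estimate
#> [1] 26.31436
#> $t
#> [1] 18.55913
#> $p
#> [1] 1.350992e-63
```

The bundle print shows the pipeline scale: detected dives by class,
aggregations by type, and the area (km²) where the two species' 95%
foraging ranges intersect, per tidal regime. `overlap_contrast` is the
package's headline inference — a linear mixed model of gentoo forage-dive
depth with a random intercept per individual: here gentoo dives in the
overlap region are estimated 26.3 m deeper (planted truth: 30 m, slightly
attenuated by region-labelling error), t = 18.6 — the vertical
partitioning signal.

```r
report_tables(bundle)$aggregation_table[, c(1:4, 6, 8:9)]
#>     metric n_dense n_diffuse dense_mean diffuse_mean   mw_z    mw_p
#> 1    depth      56        88      28.69        33.46 -2.180 2.9e-02
#> 2   height      56        88       5.89         3.88  2.475 1.3e-02
#> 3   length      56        88      44.00        43.43  0.582 5.6e-01
#> 4     area      56        88     288.75       179.98  1.533 1.3e-01
#> 5 lh_ratio      56        88       9.33        11.73 -1.472 1.4e-01
#> 6       sv      56        88     -61.40       -65.99 10.095 5.8e-24
```

Dense aggregations are taller and return far stronger acoustic
scattering, while length and length:height ratio do not differ — the
qualitative dense/diffuse contrast. At this reduced 4-day scale the depth
and area comparisons sit near the significance boundary; at the full
11-day acoustic design (the default used by `scripts/acceptance.R`) area
also separates cleanly (heights 5.60 vs 4.15 m, Mann–Whitney Z = 3.3 for
height and 16.2 for S<sub>v</sub>, depth p = 0.92).

A thin command-line front end with `simulate`, `run` and `report` verbs
is installed at `inst/scripts/pygoforage`.

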