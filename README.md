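# openfieldr

Analysis of open field exploration tracking data for behavioural
neuroscience: from raw time-stamped coordinates of a single animal in a
circular arena to interpretable habituation parameters and group
statistics.

In a novel open field test, exploration declines as the animal
habituates to the arena.  Beyond minute-binned activity, `openfieldr`
computes measures that separate *how much* an animal moves from *how
much it has learned*:

* **Activity** — Euclidean step length
  ΔD<sub>i</sub> = √((x<sub>i+1</sub>−x<sub>i</sub>)² + (y<sub>i+1</sub>−y<sub>i</sub>)²),
  with a configurable inactivity threshold below which a step counts as
  zero.
* **Coverage** — the boundary is split into *M* sectors; visits to
  sectors inside an edge band are learning trials, and

  C(t) = v<sub>min</sub>(t) + (1/M) · #{sectors with v(i,t) > v<sub>min</sub>(t)}

  counts the visits every sector has received plus the fraction of
  sectors ahead of that minimum.  Rescalings (percent coverage, PICA,
  PGCA) express it as a fraction of full habituation.
* **Motion probabilities** — each interior sample is a decision:
  continue (P<sub>++</sub>, turning angle ≤ 90° by the law of cosines),
  reverse (P<sub>+−</sub>), stop (P<sub>+0</sub>), start
  (P<sub>0+</sub>) or stay (P<sub>00</sub>), aggregated over a group in
  given-previous, given-any and raw variants.

Each individual's relationships (e.g. activity over time, P<sub>++</sub>
over percent coverage) are fitted with small parametric forms — for the
exponential decay y = a·e<sup>bx</sup> + c, *a* is initial drive, *b*
the habituation rate, *c* the steady state — using an outlier-robust
two-pass scheme (naive fit, group mean ± 2 SD bounds, constrained
refit).  Groups are compared on the fitted parameters through a
MANOVA → MANOVA sub-test → ANOVA → pairwise t-test ladder with a
significance chain that keeps the false-positive rate near the nominal
α.  A synthetic-track simulator with known ground truth makes every
stage testable without any data download.

## Worked example

```r
library(openfieldr)

# Coverage of a 24-sector boundary where every sector has >= 4 visits
# and 21 sectors have more:
coverage(c(rep(5, 21), rep(4, 3)))
#> [1] 4.875        # prints as 4.88 at two decimals

# Two simulated cohorts, full pipeline in memory:
cfg <- of_config(
  groups_and_types = c(CS1 = "generic", CS2 = "generic"),
  arena_radius_cm = 4.2, sample_freq = 1, edge_dist_cm = 1,
  time_bin_size = 1, inactivity_threshold = 0.05,
  group_colors = c(CS1 = "#1b9e77", CS2 = "#d95f02"))
defaults <- of_defaults(node_size = 15)

c1 <- make_cohort(8, explorer_params(), 0.1, seed = 1, group = "CS1")
c2 <- make_cohort(8, explorer_params(), 0.1, seed = 2, group = "CS2")
ms <- tracks_to_measures(c(c1$tracks, c2$tracks), cfg, defaults)

ms$individuals[[1]]$track
#> Standardized track: group 'CS1', 601 samples, 600.0 s at 1 s spacing, arena radius 4.20 cm
round(ms$groups$CS1$A_grp, 3)   # visits per sector for full habituation
#> [1] 7.547

specs <- set_up_fits(cfg, defaults)
fits <- fit_relationships(ms, specs, cfg)
fit_equation(attr(fits$group, "fits")[["CS1|time~activity"]])
#> [1] "y = 1.49 e^(-0.00914 x) + 0.255"

run_tests(fits, alpha = 0.05)
#> Statistical report (alpha = 0.05 )
#> Full MANOVA Wilks p = NA
#> 0 of 32 parameters significant in both sub-test and ANOVA
```

The group fit says CS1 activity starts near 1.49 + 0.26 ≈ 1.75 cm per
second, decays with rate 0.0091 s⁻¹ (half-life ≈ 76 s), and settles at
0.26 cm/s; with 8 individuals per group the full 32-parameter MANOVA has
too few complete cases (reported NA), which is exactly what the
per-relationship sub-tests are for — and, both cohorts being draws from
the same population, no parameter passes the significance chain.

From the shell, the same pipeline runs end to end:

```sh
Rscript inst/cli/openfield.R simulate --out tracks/ --n 12 --group CS1 --seed 1
Rscript inst/cli/openfield.R all --config run.toml --inputs 'tracks/*.csv' --out results/
```

writing per-individual measure CSVs, group summaries, parameter tables,
the statistical report and all five plot categories.

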