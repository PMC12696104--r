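---
title: "Quantifying open field exploration: coverage, directional persistence, and habituation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying open field exploration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(openfieldr)
```

## The problem

In a novel open field test a single animal — a fly, a mouse — is placed in
an empty circular arena and its position recorded while it explores.
As the arena's novelty is learned, specific exploration wanes: activity
declines, the animal pauses more, and it changes direction more readily.
Most analyses stop at minute-binned activity. `openfieldr` computes
denser, more interpretable measures from the full track, fits small
parametric models to each individual, and compares experimental groups
on the fitted parameters rather than on raw curves.

Three families of measures are computed per individual:

* **Activity**: the Euclidean step length
  $\Delta D_i = \sqrt{(x_{i+1}-x_i)^2 + (y_{i+1}-y_i)^2}$, the step that
  *begins* at sample $i$.  Steps below a user-set inactivity threshold
  are treated as exactly zero, absorbing tracker jitter and body wobble.
* **Coverage**: the arena boundary is divided into $M$ sectors of equal
  central angle.  Edge-dwelling species (flies strongly thigmotax)
  accumulate *visits* to sectors while inside an edge band next to the
  wall.  Coverage at time $t$ is
  $C(t) = v_{\min}(t) + \tfrac{1}{M}\sum_i \chi[v(i,t) - v_{\min}(t)]$:
  the number of visits every sector has received, plus the fraction of
  sectors that have received more.  Each visit is a learning trial, so
  coverage counts habituation opportunities independently of arena size.
  Three rescalings express coverage as a fraction of full habituation:
  percent coverage (divide by the maximum achieved), PICA (divide by the
  individual's fitted coverage asymptote), and PGCA (divide by the group
  mean of those asymptotes).
* **Motion probabilities**: each interior sample is a decision between
  the step that ended there and the step that begins there.  With
  thresholded step lengths and the turning angle $\theta$ from the law
  of cosines ($\theta \le 90^\circ$ counts as continuing), the five
  outcomes are continue ($P_{++}$), reverse ($P_{+-}$), stop ($P_{+0}$),
  start ($P_{0+}$) and stay ($P_{00}$).  Group probabilities come in
  three variants: *given-previous* (conditioned on the previous step
  moving or resting, so $P_{++}+P_{+-}+P_{+0}=1$ and $P_{0+}+P_{00}=1$),
  *given-any* (conditioned on any classified in-edge decision, all five
  summing to 1), and *raw* (divided by group size).

## Visit counting rules

A visit is an *entry* event.  Lingering in a sector counts once.  When
consecutive edge samples land in non-adjacent sectors, every sector on
the shorter angular arc is credited a visit — at realistic frame rates
the animal necessarily passed through them.  Two conventions needed
fixing where no rule was forced:

* an exact half-circle jump has no shorter arc; it is imputed
  counterclockwise (and the rotation-invariance test exempts that tie);
* an animal that slips radially out of the edge band and back into the
  *same* sector has not made a new visit; the previous edge sector is
  remembered across interior excursions, so only entering a different
  sector starts a new visit.

The sector size default is 0.1° (3600 sectors) with coverage evaluated
every second; users should check the sector arc length against the
subject's body length.  The worked examples and tests use 15° (24
sectors) where hand counting is feasible.

## Habituation models and the two-pass fit

Six registered forms cover the observed shapes (all fit by bounded
Levenberg–Marquardt least squares via `minpack.lm`, with sign
constraints as wide naive bounds): exponential decay
$y = a e^{bx} + c$ ($a>0, b<0, c>0$), asymptotic increase
$y = a(e^{bx}-1)$ ($a<0, b<0$), linear decrease/increase $y = ax+b$, and
sigmoidal decay/increase $y = a/(1+e^{-b(x+c)})$.  For the decay model
the parameters read directly as biology: $a+c$ is initial activity
(neophilia), $b$ the habituation rate, $c$ the steady-state level.  For
the asymptotic increase fitted to coverage-versus-time, $-a$ is the
number of visits per sector needed for full habituation.

Outliers are handled without exclusion: after a naive fit per
individual, each parameter's bounds are set to the group mean ± 2 SD
(configurable via `bound_level`) of the converged naive estimates, and
every individual is refit inside those bounds.  Insiders are unchanged;
extreme individuals land on the bound rather than dragging the group.
Group-level fits apply the same bounds to the binned group means.
Degenerate cases: a single converged individual collapses the bounds to
its own value (widened by 1e-12 so the solver has an interior);
relationships with no converged individuals are dropped with a warning.
Solver settings: data-driven starting values per form, `ftol = ptol =
1e-10`, at most 5000 function evaluations.

Motion probabilities are group-level series, but the statistics need
per-individual parameters; each individual's model is therefore fit to
its own 0/1 conditional indicator series (1 where the outcome occurred,
0 where it could have occurred but did not, missing elsewhere), whose
conditional expectation is exactly the probability being modelled.

### Default model grid

The default grid pairs x ∈ {time, percent coverage} with y ∈ {activity
and the five given-previous motion probabilities}, plus
coverage-versus-time: 13 relationships, 32 parameters.  Defaults assign
exponential decay to activity, $P_{++}$ and $P_{+0}$, and asymptotic
increase to coverage, $P_{+-}$, $P_{0+}$ and $P_{00}$.  The assignment
for $P_{+0}$ is genuinely ambiguous — pausing can be read as a decaying
complement of persistence or as an increasing habit — so the default
(decay) is just a default, overridable per relationship through
`set_up_fits(overrides=)`.  $P_{0+}$ takes asymptotic increase as the
complement of $P_{00}$.

## Group comparison ladder

Refit parameters feed a one-way MANOVA (each parameter a dependent
variable, group the factor; Wilks' lambda with Rao's F approximation
reported, Pillai computed alongside).  Because the full model demands
many complete cases, per-relationship MANOVA *sub-tests* run the same
test on each relationship's 2–3 parameters.  Per-parameter one-way
ANOVAs and pairwise pooled-variance t-tests (Welch by flag) follow, the
latter adjusted across pairs by Holm–Šidák step-down
($p_{(i)}^{adj} = 1-(1-p_{(i)})^{m-i+1}$, made monotone).  The
interpretation rule is a significance chain: a parameter counts as
significant only when its relationship's sub-test *and* its own ANOVA
fall below α (default 0.05).  The chain gates interpretation, not
computation — all tables are always produced.

On a single population split at random into two groups, the chain's
false-positive fraction should sit near α; the test suite reproduces
this with 110 simulated explorers, 100 random re-splits and the default
32-parameter grid, requiring the mean fraction in [0.02, 0.09].

## The synthetic explorer

The simulator generates the one thing real data cannot give the tests:
known ground truth.  It emulates an edge-dwelling walker whose expected
step length decays exponentially, $E[\Delta D](t) = a_0 e^{b_0 t} + c_0$
(checked by Monte Carlo against the generating mean), whose directional
persistence decays toward chance with a configurable half-life, and
whose pause probability rises toward an asymptote, with pauses as exact
zero steps so inactivity-threshold semantics are testable.  The arena
wall reflects; excursions out of the edge band are turned back with
probability `edge_affinity`, making band occupancy at least that
fraction in expectation.  Defaults describe a fly-sized subject in an
8.4 cm diameter arena, 10 minutes, analysed at 1 Hz, approaching ~4
visits per sector — the scale at which a 10-minute recording shows
most of the habituation curve.  Between-individual variation multiplies
$a_0, b_0, c_0$ by independent log-normal factors (CV 0.1–0.15 in the
tests).

What the simulator does *not* emulate: real locomotor microstructure
(bout structure, wall-following curvature, grooming), tracker-specific
noise spectra, or any coupling between activity level and edge
preference.  Passing tests therefore demonstrate that the *pipeline*
computes its measures correctly and that the statistical machinery has
its nominal operating characteristics — not that any particular
biological effect exists.

Deterministic scripted tracks complement the stochastic walker: they
walk the boundary through an exact sector sequence (first detection,
whole laps, an extra path), so visit counting has a hand-countable
oracle.  A lap is defined as the $M-1$ sectors after the start, with
the start sector re-entered only between laps; this makes a single lap
visit every sector exactly once while repeated laps re-enter the start.

## Numerical and design choices

* **Standardization order**: unit conversion → zero-centering →
  smoothing → subsampling → interpolation.  Smoothing is a centered
  moving average (window `round(sample_freq/6)`, odd, minimum 3,
  configurable); sources that arrive pre-smoothed (the
  Ethovision-style dialect) skip it.  Subsampling takes the *nearest
  frame* to each target time rather than averaging, preserving the
  step-length distribution that the inactivity threshold acts on.
  Interpolation is linear and interior-only; leading/trailing missing
  samples are trimmed.  Tracks with under 3 usable samples or over 50%
  missing are rejected.
* **Arena center**: explicit metadata when present, otherwise the
  center of the minimal enclosing circle of the observed points
  (support-set iteration; collinear input falls back to the bounding
  box with a warning).
* **Angles**: degrees counterclockwise from +x in [0, 360); a turning
  angle of exactly 90° counts as continuing.
* **Summaries**: temporal relationships average across individuals at
  each time point.  Coverage-domain relationships pool (x, y) tuples
  across individuals, sort (ties broken by individual then time, for
  determinism), and bin by equal count (`n_points`, default 50; bin
  center = mean x) for coverage/PICA/PGCA or by equal width (`n_bins`,
  default 50; bin center = midpoint) for percent coverage.  Both
  methods are available for every axis.  Bins with one tuple keep their
  mean and report a missing SEM.
* **Problem sizes in the test suite**: 24 sectors, 1 Hz, 10-minute
  tracks, cohorts of 3–110; chosen so every oracle is hand- or
  brute-force-checkable and the full suite (including the 100-replicate
  split experiment) completes in minutes on one CPU.

## Known limitations

* Circular arenas only; rectangular fields would need a boundary
  mapping.
* One-way designs only; two-factor experiments should export
  `format_params()` CSVs to external tools.
* The asymptote rescalings (PICA/PGCA) inherit the asymptotic-increase
  model's bias under model mismatch: on stepwise or non-concave
  coverage series the fitted asymptote can undershoot the observed
  maximum by a few percent, so PICA can exceed 1.
* The Ethovision/AnyMaze/BuriTrack dialects cover one generic delimited
  layout per tracker family, not the proprietary binary or spreadsheet
  exports.
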