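---
title: "Measuring molecular tunnel dimensions and their thermal variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring molecular tunnel dimensions and their thermal variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tunneldim)
```

## The measurement model

A molecular tunnel is represented as an ordered chain of centerline spheres:
each node is a 3D center (Å) with the local channel radius (Å). This is the
representation that tunnel-detection tools (MOLE, CAVER and relatives)
export, so profiles can come either from such a tool (via the CSV/JSON
readers) or from the package's own tracer.

Every pair of consecutive nodes bounds one *section*, modelled as a cylinder
or truncated cone (frustum): the section height $h$ is the straight-line
distance between the two centers, and the node radii $r_1, r_2$ are its end
radii. Section volume and lateral surface are

$$V = \tfrac{1}{3}\pi h\,(r_1^2 + r_1 r_2 + r_2^2), \qquad
  S = \pi (r_1 + r_2)\sqrt{(r_1 - r_2)^2 + h^2},$$

which reduce to the cylinder formulas $\pi r^2 h$ and $2\pi r h$ when
$r_1 = r_2$. Channel totals (length, lateral surface, volume) are sums over
sections, and per-protein totals sum over all channels in the structure
(`measure_protein(longest_only = TRUE)` restricts to the single longest
channel for sensitivity analyses).

Two deliberate choices in this model:

* **The surface formula carries a radical.** Without it,
  $\pi(r_1+r_2)[(r_1-r_2)^2+h^2]$ has units of length³, not area, and fails
  every closed-form special case (cylinder, cone). The package implements
  the dimensionally correct frustum lateral area throughout; surfaces are
  labelled Å² and volumes Å³.
* **End caps are never counted** — the quantity of interest is the lateral
  (side) surface of the tunnel wall.

Degenerate inputs are pinned down explicitly: radii must be strictly
positive; consecutive nodes must be distinct points (a zero-height section
is rejected at profile construction); and at $h = 0$ the surface formula
itself degenerates smoothly to the annulus between the two radii, which is
what keeps the totals exactly invariant when a section is subdivided at an
interior point with linearly interpolated radius. That subdivision
invariance, and agreement of $S$ and $V$ with numeric
surface-/solid-of-revolution integration along the piecewise-linear radius
profile, are enforced in the test suite (100 seeded random profiles at
relative tolerance $10^{-6}$; subdivision at $10^{-9}$).

## The clearance-field tracer

To run the pipeline end to end without external tunnel software, the
package includes a toy-scale tracer. The *clearance* at a point is the
distance to the nearest atom surface,
$c(p) = \min_i \lVert p - a_i\rVert - \mathrm{vdw}_i$. `build_clearance_grid()`
evaluates it exactly (brute force over atoms) on a regular grid covering the
atom bounding box plus a padding margin; `trace_channel()` then finds the
**widest-bottleneck path** from a start voxel to any voxel of the padded-box
boundary: over 26-connected voxels whose clearance is at least `min_radius`,
it maximizes the minimum clearance along the path (a maximin Dijkstra in
C++), breaking ties by fewer steps and then by voxel order, so results are
deterministic. The node radii of the returned profile are the local
clearances.

Parameters, all in Å: `spacing` (default 0.5; allowed 0.25–2) sets the
resolution — the recovered bottleneck is accurate to roughly the spacing,
and halving the spacing moves it by at most the coarser spacing;
`pad` (default 5, minimum 3) defines where "outside" begins; `min_radius`
(default 0.9) is the narrowest passage the search may use, roughly a small
probe radius. Van der Waals radii come from a fixed element table (C 1.70,
N 1.55, O 1.52, S 1.80, H 1.20; unknown elements 1.70 with a warning).

The widest-bottleneck objective (rather than shortest path) was chosen
because the limiting radius is the downstream quantity of interest. One
consequence worth understanding: in a tube open at both ends, the maximin
path *correctly avoids* the narrow end — it escapes through the wide mouth.
A tracer run therefore reports the bottleneck of the *best* escape route
from the start, not the global minimum radius of the structure. The
recovery benchmarks in the test suite use tubes capped at the wide end with
the trace started mid-axis, which forces the path through the tube's global
minimum and makes the design radius the ground truth. On grids up to
$20^3$ the search is verified voxel-exact against an exhaustive
binary-search-over-threshold flood fill.

The tracer is plumbing, not science: it makes no claim of matching
Voronoi-based tunnel finders on real proteins, and it enumerates a single
channel per start point.

## The statistical analysis

Species are binned by optimum growth temperature into `<50`, `50-80` and
`>80` °C classes. The boundary temperatures 50 and 80 fall in the middle
class — the outer class labels are strict inequalities, so the middle class
absorbs the endpoints and the three classes partition the axis.

Per (enzyme, subunit, dimension) panel, `analyze()` reports:

* **Class summaries** — n, arithmetic mean, sample sd (n − 1 denominator,
  `NA` when n < 2), and the **amplitude** max − min, the variability
  statistic. Amplitude is translation-invariant and scale-equivariant.
* **Variance-ratio tests** of the `50-80` and `>80` classes against the
  `<50` reference. The variability claim is tested on *variances* (the
  standard F test: larger variance in the numerator, df $n-1$ each,
  two-sided p capped at 1), while the amplitude itself is summarized
  descriptively; a range-based test is not attempted because the range has
  no comparably standard reference distribution at unequal n. Comparisons
  involving a class with n < 2 (or two zero-variance samples) are flagged
  not testable and the run continues.
* **Bonferroni correction** with family size m = 2 per panel — the two
  against-reference comparisons form the natural family; m is a parameter
  for users who prefer a global family.
* **Amplitude fold ratio** amplitude(<50)/amplitude(>80), the headline
  effect size; undefined (never infinite) when the hot-class amplitude is 0.
* **Trend lines** — unweighted OLS of the dimension on T_opt with slope,
  intercept and $R^2$ (a constant response returns slope 0, $R^2$ 0 rather
  than an undefined fit).

The F test's calibration is checked empirically: under an equal-variance
normal null (n = 10 per group, 10 000 replicates) the raw two-sided
rejection rate at $\alpha = 0.05$ must land in $0.05 \pm 0.01$ and the
p-values must pass a Kolmogorov–Smirnov uniformity check at the 1% level.

## What the synthetic generator emulates — and what it does not

`generate_dimension_dataset()` draws, per class, T_opt uniformly within the
class band of an 18–110 °C range, and each dimension from a normal with
temperature-independent mean by default ($\mu$ = 100 Å length, 2000 Å²
surface, 3000 Å³ volume — plausible totals for multi-tunnel enzyme
structures) and an sd that contracts **log-linearly in T_opt** from
$\sigma_0 = \mu/8$ at the cool end to $\kappa\sigma_0$ at the hot end
($\kappa = 0.25$ by default). Draws at or below zero are rejected and
redrawn; the spec-level guard $\mu > 6\sigma_0$ keeps that truncation
negligible. Defaults of 30 species per class per panel give the
against-reference variance test high power at $\kappa = 0.25$, mirroring a
study design where hot-class contraction is detectable per panel. Under
these defaults the median <50/>80 amplitude fold ratio across seeded
replicates falls in the severalfold (2–7×) band while class-mean
comparisons reject only at the nominal error rate — the pattern of strongly
contracted variability with indistinguishable averages.

The generator emulates the *pattern*, not the biology: real dimension
tables are not normal within class, species are phylogenetically correlated
rather than independent, T_opt values cluster at culture-collection
favourites rather than spreading uniformly, structure-prediction noise is
heteroskedastic in ways unrelated to temperature, and the three dimensions
of one protein are strongly mutually correlated (the generator draws them
independently; the companion `generate_profile_sets()` even derives volume
deterministically from length and surface). Passing tests therefore show
the pipeline recovers a known variance-contraction signal at realistic
sizes — they do not validate distributional assumptions on real data.

`generate_tube_structure()` builds the tracer's benchmark: carbon-atom
rings (spacing ≤ 2 Å, so the wall is tight at the default `min_radius`)
around a piecewise-linear radius profile $R(z)$, optionally capped, with
the axis samples as ground-truth profile. Generator and geometry are kept
mutually consistent: the measured ground-truth profile equals the frustum
closed forms of $R(z)$ to $10^{-9}$ relative.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 100 random profiles for
the integration oracle (tolerance $10^{-6}$ relative — the integrator's
accuracy, not the formulas'), 50 for subdivision ($10^{-9}$), 20 seeded
tubes (length 20 Å, radii 1.5–3 Å, spacing 0.5 Å, ±0.6 Å recovery band ≈
spacing plus off-axis voxel offset), 10 000 null replicates for F-test
calibration, and 200 replicates of a single panel for the
amplitude-contraction check. These sizes make the full suite run in well
under a minute of geometry/statistics work plus a few seconds of tracing.

Ties and determinism: the tracer breaks path ties by step count then voxel
index; `analyze()` sorts panels lexicographically and its results are
invariant to dataset row order; all generators are pure functions of their
spec including the seed.

## Known limitations

* The tracer is toy-scale: exact brute-force clearance is $O(\text{cells}
  \times \text{atoms})$ and the grid is capped at 2×10⁷ cells by default.
* Centerline length is polyline length between sphere centers; no
  arc-length smoothing or curvature correction.
* No phylogenetic correction, mixed models or robust variability tests
  (Levene/Brown–Forsythe) — the analysis mirrors the classical F-on-variance
  design it implements.
* mmCIF structures and chain/model selection are out of scope; all atoms of
  a PDB file are used.
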