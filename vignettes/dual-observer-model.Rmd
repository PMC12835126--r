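---
title: "The dual observer model: geometry, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dual observer model: geometry, fitting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualobserver)
```

## The model

Extracellular spike sorting recovers well-isolated single units from
multi-channel recordings, and how many it recovers depends strongly on the
spacing of the recording electrodes. The dual observer model describes
that dependence with three interpretable parameters:

* **R** (observation radius, µm): each microelectrode observes a sphere of
  tissue of radius R within which a neuron's spikes are large enough,
  relative to noise, to be sorted from that channel.
* **p_single** (units per mm³): the density of sortable units in tissue
  observed by exactly one electrode.
* **G** (gain factor, dimensionless): cooperation between electrodes.
  Tissue observed by two or more electrodes yields units at density
  `p_double = 2 G p_single`. `G = 0.5` means a second observer adds
  nothing (independence), `G < 0.5` means overlapping observers interfere,
  and `G > 1` means two observers together sort neurons that neither could
  alone (synergy) — the empirically typical regime in neocortex.

The expected unit yield of a configuration splits the observed tissue into
the volume seen by exactly one sphere and the volume seen by at least two:

$$N = p_{single}\,(V_{single} + 2G\,V_{double}).$$

Efficiency normalises this by M independent electrodes,
$E = N / (p_{single} M V_1)$ with $V_1 = \tfrac{4\pi}{3}R^3$, so `E = 1`
when no spheres intersect, regardless of G.

## Exact geometry for linear arrays

For a collinear equidistant array the volumes are closed-form. The
intersection of two equal spheres a distance D apart is the lens
$V_2(R,D) = \tfrac{\pi}{3}(4R^3 - 3R^2D + D^3/4)$, identically zero for
$D \ge 2R$. For a chain of equal spheres, inclusion–exclusion telescopes:
third- and higher-order intersection terms cancel exactly against the
second-order intersections they create, leaving

$$V_{double} = (M-1)V_2(R,D) - (M-2)V_2(R,2D), \qquad
  V_{total} = M V_1 - (M-1)V_2(R,D),$$

and $V_{single} = V_{total} - V_{double}$ ("exactly one observer").
`v_single` is defined as *exactly-one* coverage throughout the package;
with that convention the three regimes (no intersections, first-neighbour
only, second-neighbour) are all produced by the same two formulas, the
efficiency

$$E = 1 + 2(G-1)\tfrac{M-1}{M}\tfrac{V_2(R,D)}{V_1}
        - (2G-1)\tfrac{M-2}{M}\tfrac{V_2(R,2D)}{V_1}$$

is continuous in D, and its stationary point matches the closed-form
optimum below exactly. The cancellation claim is not taken on trust: the
test suite checks `linear_array_volumes()` against two independent
oracles — a deterministic axial quadrature (the union of collinear equal
spheres is rotationally symmetric, so cross-section areas integrate to
volumes) and the seeded Monte-Carlo estimator — across electrode counts
2–64 and radius-to-pitch ratios 0.1–25.

## The optimal inter-electrode distance

For `G > 1` the efficiency has a unique interior maximum at

$$D_{opt} = R\sqrt{\frac{4MG - 12G + 4}{7MG - 3M - 15G + 7}},$$

valid for `M > 3` (for smaller arrays `optimal_distance(..., method =
"search")` maximises the curve numerically). At `G = 1` this collapses to
`D_opt = R`; for large G and M it approaches $R\sqrt{4/7} \approx 0.76R$.
The peak efficiency is well approximated by `E_opt ≈ 0.76 G + 0.16`, and
the package reports both that approximation (the convention used in
published summary tables, including for "optimal units per channel"
`p_single · V_1(R) · E_opt`) and the exact curve value at `D_opt`, which
is slightly higher (e.g. 1.43 vs 1.41 at `R = 42, G = 1.64, M = 32`).

For `G ≤ 1` there is no interior optimum: every spacing `D ≥ R` performs
alike, and within that plateau denser packing records more tissue per
shank length. Reports therefore print `"≥ R µm"` with a
`boundary_g_le_1` flag and use `d_opt = r_obs` numerically. Some summary
conventions quote a slightly larger plateau threshold (where the curve is
within a tolerance of its asymptote); we deliberately use R itself, the
exact boundary of the first-neighbour regime.

## Monte-Carlo volumes for non-linear layouts

Real high-density probes are not strictly linear: two-column zig-zag
layouts appear both in the full-resolution rodent probe and in odd
decimations of the human column pair. For those, `mc_volumes()` samples
points uniformly in the electrode bounding box expanded by
`max(margin, r)` with `margin = 200` µm by default, so every observation
sphere lies inside the box for any radius in the default fitting grid;
volumes follow from the fraction of points whose nearest (≥1) and second
nearest (≥2) electrode lies within r. Choices that matter:

* **"Double" means two or more.** Coverage is counted globally per point,
  not per adjacent pair; for chain-like layouts the two coincide.
* **One point cloud per layout.** The compiled kernel returns each
  point's two smallest electrode distances, so a single seeded cloud
  answers *every* radius by counting order statistics. The 200 × 400
  fitting grid therefore costs one sampling pass per layout, cached by
  `(layout, n_points, seed, margin)`; `mc_cache_clear()` empties the
  cache. Cached and uncached paths are bit-identical.
* **Seeded and restored RNG.** Results are deterministic given
  `mc_settings(n_points, seed, margin)`, and the caller's RNG state is
  untouched. Binomial standard errors accompany every estimate.
* **Hybrid dispatch.** `hybrid_volumes()` returns the exact
  no-intersection result without sampling whenever `r ≤ pitch/2`, the
  closed-form decomposition for layouts recognised as linear-equidistant
  (collinearity and spacing checked to 1e-8 relative), and Monte-Carlo
  otherwise; the branch taken is recorded in the result.

At the default 10⁷ points, mean relative deviations from the analytic
linear-array volumes on the test grid are a few parts per thousand.

## Fitting: grid search with cosine similarity

`fit_dual_observer()` fits the model to per-configuration medians of
units-per-channel measurements. The default grid is R = 1–200 µm in 1 µm
steps and G = 0.01–4 in 0.01 steps. For each cell the predicted pattern
across configurations is `(V_single,i + 2G V_double,i) / M_i`, compared
to the observed medians by cosine similarity — an amplitude-independent
match, since `p_single` only scales the pattern. The winning cell gives
`(R̂, Ĝ)`; `p̂_single` is then the least-squares projection
`(y·m̂)/(m̂·m̂)` of the medians onto the winning pattern, the scalar that
minimises squared error and recovers noise-free truth exactly.

Implementation notes:

* The pattern is affine in G (`A(r) + G·B(r)`), so the similarity over
  the whole grid reduces to closed-form vector algebra per radius; the
  search is exhaustive, not iterative, and costs well under a second once
  volume profiles exist.
* Ties on similarity resolve to the smallest R̂, then the smallest Ĝ, for
  determinism; the tie count is reported in `diagnostics`.
* Zig-zag configurations use one fixed Monte-Carlo seed across the whole
  grid, so sampling jitter cannot distort the similarity surface, and the
  same cached volumes serve simulation and fitting.
* Medians use the standard midpoint convention for even recording counts.
* Degenerate inputs fail loudly: fewer than 3 configurations (3 free
  parameters), all-zero medians (similarity undefined), or non-finite
  values at ingest.

On noise-free data generated at an on-grid truth the fit returns the
truth exactly; from off-grid truth it lands within one grid step.

## The synthetic-data generator

`simulate_yields()` stands in for spike-sorted recordings: it computes
each configuration's expected yield from true parameters and draws
per-recording units-per-channel values under

* `"lognormal"` (default, σ = 0.2): multiplicative recording-to-recording
  variability, the level chosen once to match the visual spread of
  published per-recording yields; medians are unbiased for the model
  prediction because the log-noise is symmetric.
* `"poisson"`: integer unit counts, appropriate for sparse configurations
  where yields are small counts.
* `"none"`: the expectation itself.

Defaults of 6 recordings per configuration and the rodent configuration
series (pitches 8.5/12/24/48/96 µm from a 256-channel zig-zag probe and
its decimations) mirror the scale of the study conditions the package is
tested under. What the generator does **not** emulate: waveform
non-stationarity, correlated noise across recordings, sorter-specific
failure modes, defective channels, or spatial inhomogeneity of neuron
density. Passing recovery tests therefore demonstrate that the *fitting
machinery* is correct and well-conditioned at realistic noise — not that
the model is true of any particular tissue.

Under those conditions (σ = 0.2, 6 recordings, 100 replicates, rodent
set), median absolute recovery errors are within 5 µm in R and 0.3 in G.

## Layouts and downsampling

Coordinates are µm, `y` along the shank (origin at the topmost
electrode), `x` across, `z` out of plane. The presets are
`rodent_probe()` (256 electrodes, 6 µm row advance, 6 µm column offset →
8.49 µm pitch; equivalently two columns at 12 µm per-column pitch) and
`human_probe()` (192 electrodes, 20 µm row advance, 16 µm column offset →
25.6 µm pitch), reverse-engineered from the published pitch tables and
probe descriptions and overridable via layout JSON. The effective pitch
of any layout is its nearest-neighbour distance.

`downsample(layout, k, offset)` keeps electrodes at sequence indices
≡ offset (mod k) along the shank. The default `offset = k − 1` keeps
literally every k-th electrode, composes under nesting
(`downsample(downsample(L, a), b)` ≡ `downsample(L, ab)`), and reproduces
the published channel-count series exactly (192 → 96/64/48/38/19);
`enumerate_shifted_configs()` yields all k shifted variants, which share
a pitch but differ in membership. Which offsets produced the published
odd decimations is not documented anywhere we know of; pitches are
offset-invariant, so nothing downstream depends on the choice.

## Problem sizes and numerical tolerances

The test suite uses 2×10⁵-point Monte-Carlo clouds for routine checks,
10⁷ for the oracle-equivalence grid (matching the estimator's default),
and 10⁶ for the 100-replicate recovery study; these sizes put MC standard
errors well below the assertion tolerances while keeping the suite fast.
Analytic identities are asserted to 1e-12 relative, quadrature oracles to
1e-4, Monte-Carlo comparisons to 3 binomial standard errors. Lens and
efficiency formulas switch branches exactly at tangency (`d = 2r`), where
both sides agree; volumes are clamped at zero only to absorb floating
cancellation below 1e-9 relative.

## Known limitations

* Observation volumes are isotropic spheres; anisotropic or non-spherical
  fields are out of scope.
* The closed-form optimum covers linear equidistant arrays with `M > 3`;
  2-D grid optima and multi-shank interactions are not modelled (shanks
  further apart than 2R are independent).
* No uncertainty quantification on fitted parameters (no bootstrap CIs);
  the grid resolution bounds the reporting precision.
* The fit targets medians; heavy-tailed recording-level outliers are
  deliberately down-weighted but not modelled.
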