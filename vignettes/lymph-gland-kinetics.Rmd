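---
title: "Methods: quantifying lymph-gland progenitor kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying lymph-gland progenitor kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgkinetics)
```

This vignette records the models, parameter choices and numerical
decisions behind each pipeline stage, and what the synthetic generators
do and do not capture.

## Imaging frame and units

Recordings are 15 s per frame (`frame_interval_s = 15`); times are
reported in minutes, positions in µm, intensities in arbitrary units
(a.u.). The organ frame is cylindrical: `tube_dir` is the heart-tube
axis, `z_dir` the dorsal–ventral axis, and the ρ–φ plane is perpendicular
to z. `default_geometry()` places the tube along x through the origin
with the posterior (PSC) end at (150, 0, 0) and an elliptical lobe
boundary of semi-axes 150 × 75 µm centred at (0, 75) — a 300 × 150 µm
primary lobe, 50 µm deep in the 3-D generator (semi-axes 150 × 75 × 25).

## Normalization and the dsRed:GFP ratio

Both channels of a track are scaled by one affine map,

$$\mathrm{Norm.X}_t = \frac{X_t - \min(G, R)}{\max(G, R) - \min(G, R)},$$

with the extrema taken jointly over the two markers. Joint (rather than
per-channel) scaling preserves the ordering *between* channels, which is
what the ratio depends on. The per-frame ratio is
`norm_red / max(norm_green, ratio_floor)` with `ratio_floor = 0.01`: once
the GFP reporter decays to the joint minimum the raw ratio is unbounded,
and the floor caps it at 100× the red signal instead of letting single
frames dominate every downstream fit. The floor only matters in the
saturated tail, after the biology of interest has happened.

## Trajectory classification

The ratio–time curve is fitted with ordinary least squares to a line and
to a 4-parameter logistic $b + A/(1 + e^{-(t - t_0)/\tau})$
(Levenberg–Marquardt via `minpack.lm`, amplitude bounded at 0,
$\tau \ge 10^{-9}$). Model selection uses small-sample corrected AIC with
an ambiguity margin of 2: among valid candidates,
$|\mathrm{AICc}_{lin} - \mathrm{AICc}_{log}| < 2$ is reported as
`ambiguous` rather than forced into a class. The RSS entering AICc is
floored at $n \cdot 10^{-24}$ so exact (noiseless) fits remain comparable
instead of sending $\log \mathrm{RSS}$ to $-\infty$.

A logistic is only a *valid sigmoid candidate* when (a) its midpoint
$t_0$ lies inside the observed window, (b) its full 10–90% fast phase
lies inside the window, and (c) $A$ exceeds twice the logistic residual
SD. Without (b), line-like logistics with very large $\tau$ sit within
the AICc margin of the straight line and flood the ambiguous class; a
rising ratio whose switch and saturation are not both observed is
constant-rate differentiation as far as the recording can tell, and is
called linear. With this rule the classifier agrees with generator labels
on ≥ 99% of noisy tracks (noise CV 0.1, 1320 frames) in all four classes.
A non-convergent logistic falls back to linear with a warning.

The fast phase is the 10–90% amplitude window: crossings at
$t_0 + \tau \log(q/(1-q))$, so its duration is exactly
$\ln(81)\,\tau \approx 4.39\,\tau$. The differentiation rate is the OLS
slope of the ratio over that window (sigmoid) or the whole track
(linear). Note the OLS slope over the fast phase is ≈ 12% above the
secant $0.8A/(\ln(81)\tau)$, because the logistic is steeper in the
middle of the window; tests pin both quantities separately.

## Division kinetics and orientation

Mitosis onset is defined 40 frames (10 min) before nuclear-envelope
breakdown (`onset_offset_frames = 40`), so
`duration = (t_complete - t_breakdown) + 10 min`. An axis is a
*z*-mitosis when $\alpha = \arccos(|\hat a \cdot \hat z|) \le 45°$
(`rho_z_angle_threshold_deg`, boundary inclusive to z) and a *ρ*-mitosis
otherwise; the absolute value makes the axis undirected. In-plane
orientation to the heart tube is the angle of the projection onto the
ρ–φ plane, on [0°, 180°) with 180° folded to 0°; relabeling the
daughters maps θ to 180° − θ, so summaries should be fold-invariant.

Orientation normality is summarized by a Q-Q report against a normal
with the sample moments, with the reference line through the quartile
pairs and $r^2 = 1 - SS_{res}/SS_{tot}$ clamped to [0, 1]. The linearity
cutoff used in examples is **0.90**, calibrated once by simulation as the
5th percentile of the null $r^2$ distribution at n = 50 (≈ 0.9035) and
pinned; a naive 0.95 cutoff rejects ~30% of genuinely normal samples at
this n. A strongly edge-biased (bimodal) alternative scores
$r^2 \approx 0.35$, far below the cutoff.

## Spatial heat maps

`align_lobe()` applies the smallest-magnitude rotation taking the tube's
in-plane direction onto the y-axis, then mirrors about the tube line if
needed so the lobe centroid faces +x. Alignment is rigid (distances are
preserved) and invertible via the recorded transform. The aligned lobe
boundary's bounding box is split into `grid_n = 5` equal segments per
side; bins are half-open with the last bin closed, so every in-boundary
point lands in exactly one bin (counts are conserved). Points outside
the boundary polygon (`pracma::inpolygon`, boundary inclusive) are
excluded but counted. Per-video maps are combined by raw count summation
— no per-video normalization — and compared by Pearson correlation of
the flattened grids, categorized as none [0, 0.25), weak [0.25, 0.5),
moderate [0.5, 0.75), strong [0.75, 1]; negative r is "none".

## Histo-cytometry

Slices at 25/50/75% of stack thickness are chosen as
`round(q (n-1))` (half-up, 0-based); the three indices collide below
n = 5, which is an error rather than a silent duplicate. Nucleus
detection runs a scale-normalized Laplacian-of-Gaussian at
$\sigma = d/(2\sqrt 2)$ (d = 13 px blob diameter) on the channel sum, so
dim-green/bright-red cells are not missed. The kernel is zero-meaned
(flat background → zero response) and scaled so a matched unit-peak
Gaussian blob scores quality 1; the default `quality_threshold = 0.2` is
on that unit scale and is **not** comparable to other software's quality
numbers. Strict 8-neighbour maxima (with a deterministic tie-break) are
pruned by greedy non-maximum suppression at radius d/2, and channel
means are measured in a disc of radius d/2.

Quadrant gates default to Otsu thresholds on log10 intensities pooled
over whatever records are passed, so conditions compared together share
gates. The Otsu implementation returns the *centre* of the maximizing
plateau of the between-class variance: with well-separated modes the
criterion is flat across the empty gap, and taking the first bin (as a
naive argmax does) would park the gate against the low mode.

## FUCCI phase calling

A channel is present when ≥ 20% of its per-trace maximum
(`presence_fraction = 0.2`) — relative, because absolute FUCCI intensity
scales vary per cell; calls are therefore invariant to per-channel
rescaling. Green-only → G1, red-only → S, both → G2. Runs shorter than
`min_run_frames = 4` (1 min) are merged into the longer neighbour before
state assignment, enforcing temporal coherence. A neither-present run is
M only when flanked by G2 before and G1 after (the G2→M→G1 sequence of
nuclear-envelope breakdown); otherwise it is `unknown`. Population
proportions at a time point are taken over called (non-unknown) cells
and sum to 1. Single-phase traces are degenerate for relative
thresholds (a constant low channel is "present" relative to its own
maximum) — population fixtures should carry ground-truth phases.

## Synthetic generators: design and limits

All generators are pure functions of (parameters, seed) and restore the
caller's RNG state (`with_seed()`).

**Differentiation tracks.** Sigmoid kinds use logistic green decay
(G 100 → 10, midpoint 150 min, τ = 15 min) and a delayed logistic red
rise (delay 25 min; `sigmoid_infected` adds a 60-min low/low intermediary
plateau). Linear kinds start from co-expressing cells (R0 ≥ 0.5 G0). A
*constant*-red track cannot produce a constant-rate normalized ratio
(the ratio is then either identically 0 or hyperbolic in t, depending on
which channel sets the joint extrema), so the red channel is constructed
as $R(t) = R_0 + r_{end}\, u\,(G(t) - R_0)$ with $u$ the normalized time
— this makes the normalized ratio *exactly* linear, rising to
$r_{end} = (R_1 - R_0)/(G_1 - R_0)$. `linear_infected` ends 1.5× higher
than `linear_wt` (the ~50% dsRed:GFP increase after infection) and
front-loads the red rise (two-thirds of it in the first half). Noise is
multiplicative Gaussian (`noise_cv = 0.1`), clipped at zero.

**Division cohorts.** Durations and mother areas are *moment-matched*
truncated normals: the parent μ, σ are solved numerically so that the
truncated distribution's mean/SD equal the targets (57.74 ± 27.58 min,
truncated above the 10-min onset offset; 71.96 ± 10 µm²). Sampling a
normal truncated at a fixed bound without re-solving would shift the
mean by over a minute and break calibration-recovery tests. Positions
are rejection-sampled inside the ellipsoidal lobe; ρ-axes are in-plane
directions with ±40° tilt and truncated-normal orientation (90° ± 30°),
z-axes lie near ±z. The generator does not model spatial gradients of
division density, daughter adhesion, or duration–position correlation.

**Images.** Isotropic Gaussian spots plus additive Gaussian noise — no
PSF anisotropy, no uneven illumination, no touching-nuclei merging
beyond what overlapping spots produce.

**FUCCI traces.** Piecewise-constant phase levels with multiplicative
noise; no gradual degron decay at phase boundaries.

## Problem sizes and runtime

A 5.5-h track is 1320 frames; classification of 2000 noisy tracks takes
≈ 20 s. A 10 000-event cohort simulates and summarizes in ≈ 10 s.
Detection on a 256 × 256 two-channel slice with 64 nuclei is well under
a second. The full test suite runs in ≈ 1 min;
`scripts/acceptance.R` in ≈ 20 s.

## Open choices

- The classifier margin (AICc 2), presence fraction (0.2), ratio floor
  (0.01) and Q-Q cutoff (0.90) are pinned conventions, not estimated
  quantities; changing them changes borderline calls only.
- Heat maps sum raw per-video counts; per-video normalization before
  combination is a defensible alternative and would change the combined
  map where video lengths differ.
- The ρ/z threshold of 45° is geometric convention; sensitivity to it
  can be probed through `lg_config(rho_z_angle_threshold_deg = ...)`.
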