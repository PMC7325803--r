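---
title: "Quantifying retinotopically organized V1-V2 U-fiber connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinotopically organized V1-V2 U-fiber connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinoconn)
```

## The scientific problem

Short association fibers (U-fibers) run just below the gray-white boundary
and connect adjacent cortical areas. Between the primary and secondary visual
cortex (V1, V2) their organization is strongly constrained by retinotopy:
neurons representing the same part of the visual field should be
preferentially connected. `retinoconn` implements a quantification pipeline
built on that prediction. Each hemisphere's V1 and V2 are divided into six
retinotopic segments (two polar-angle by three eccentricity bins of the
represented hemifield); streamlines from diffusion tractography are filtered
by their terminations into a 6x6 segment-pair matrix; and connectivity
between *corresponding* segments (the diagonal) is compared against
connectivity between non-corresponding segments (the off-diagonal) with a
restricted permutation test, reliability statistics and a repeated-measures
ANOVA. A synthetic-data generator supplies every input with known ground
truth, so the full chain is testable without scanner data.

## Phase-encoded retinotopy

### Signal model

The generator simulates the classic phase-encoded paradigm: an expanding ring
(eccentricity, cycle period 36 s) or rotating ray (polar angle, 60 s)
traverses the visual field periodically, 8.25 cycles per run at TR 3 s. A
vertex preferring visual-field position coded by phase $\varphi$ responds as

$$ s(t) = b + A\,\cos(2\pi f t - d\,\varphi - \delta) + \text{drift} + \varepsilon, $$

with stimulus frequency $f$ the inverse cycle period, run direction
$d \in \{+1,-1\}$, a common hemodynamic phase delay
$\delta = 2\pi f\,\tau_h$ (default $\tau_h$ = 5 s) and white noise
$\varepsilon$. The forward run therefore carries raw phase
$\varphi + \delta$ and the reversed run $-\varphi + \delta$.

### Recovery chain

1. **Quarter-cycle discard.** The first quarter cycle of each run is dropped
   (`discard_initial_quarter_cycle()`), leaving an integer number of cycles
   (8.25 becomes 8). The run records its absolute time origin, and
   `fourier_phase()` rotates the Fourier coefficient back to stimulus onset;
   without that correction the discard would masquerade as an extra quarter-
   cycle delay.
2. **High-pass filtering.** Drift is removed by discrete-cosine basis
   regression (`highpass_filter()`; defaults 1/120 Hz for polar-angle and
   1/72 Hz for eccentricity runs). The stimulus-frequency sine and cosine are
   included as protected regressors, so the component of interest is
   untouched by construction rather than merely approximately; the DCT basis
   avoids the boundary artifacts of periodic (FFT) filtering on a finite run.
3. **Fourier phase.** The single DFT coefficient at the stimulus frequency,
   with the convention that $\cos(2\pi f t - \varphi)$ has phase $+\varphi$
   and modulus $A$.
4. **Opposite-direction combination.** `combine_opposite_runs()` conjugates
   the reversed-run coefficient and averages complex values:
   $(e^{i(\varphi+\delta)} + e^{i(\varphi-\delta)})/2 = e^{i\varphi}\cos\delta$.
   The delay cancels for any $\delta$, and each run is weighted by its
   amplitude (robust when response amplitudes differ; averaging phases alone
   would not be). The combined amplitude scales with $\cos\delta$, so the
   method requires the hemodynamic delay to stay below a quarter cycle
   period - amply satisfied for delays of a few seconds at 36-60 s periods,
   and a documented hard limit of the approach.

### Field sign and segmentation

The visual field sign is the sign of the oriented area of the (eccentricity,
polar-angle) mapping: per triangle, phase gradients are obtained by linear
interpolation in the local tangent plane and their cross product's normal
component is area-averaged onto vertices. Only triangles entirely inside one
area contribute, so the V1/V2 border does not dilute the sign. On the
synthetic patch V1 is a mirror representation (+1) and V2 non-mirror (-1) by
construction, which the pipeline must recover.

Segmentation (`segment_v1_v2()`) min-max scales each area's eccentricity and
polar-angle phases to (0,1), splits polar angle at 1/2 and eccentricity at
1/3 and 2/3, and assigns segment id $1 + 3\,p + e$ (plus 6 in V2). Bins are
half-open $[a, b)$ - a deterministic tie-break standing in for manual border
refinement. Two numerical safeguards matter in practice:

* **Guard bands.** The generator codes values into
  $[g,\ 2\pi - g]$ (eccentricity: $g$ = 0.9 rad; polar rows are spaced
  $(2\pi - 1.2)/m$ apart and centered on the circle). Without a guard, a
  vertex with true phase at 0 wraps to $\approx 2\pi$ under noise and
  destroys min-max scaling.
* **Gap rotation.** Before scaling, the largest empty arc of the circle is
  rotated to the origin. For data that never straddle the origin this is a
  no-op (a rigid shift cancels in min-max scaling); when noise pushes values
  across, it unwraps them. The guard-band widths are chosen so the empty arc
  remains the widest gap even under ~4 SD phase outliers; with narrower
  guards we observed rare catastrophic bin rotations (an in-data gap
  overtaking the wrap gap) in long simulation sweeps.

With the default noise level (amplitude SNR ~10 over an 8-cycle run) the
segmentation recovers ground truth for 97-100% of vertices; noiselessly it
is exact and delay-invariant.

## Connectivity mapping

A streamline contributes to cell $(i, j)$ iff one endpoint lies in a voxel of
V1 segment $i$ and the other in V2 segment $j$ (order ignored), and no
sampled point touches the CSF mask. Everything else - both ends in one area,
ends in background, CSF crossings - is discarded, and tallies of each
discard reason are kept. Conventions, stated once and used everywhere:
world coordinates are mm; the NIfTI affine maps 0-based voxel indices to
voxel-center mm; a point belongs to voxel $i$ when its continuous voxel
coordinate lies in $[i - 0.5, i + 0.5)$; endpoint assignment uses the
containing voxel only (no dilation or nearest-label search), which external
tractograms must satisfy. Percent connectivity normalizes counts to the
hemisphere's retained total, so each matrix sums to 100.

The proximity matrix is the per-cell arithmetic mean of reciprocal streamline
length (mm^-1), undefined where a cell is empty; it is the first-order probe
for the short-streamline bias of tractography. Group averages are
element-wise, with undefined proximity cells excluded pairwise and the
defined count reported.

`filter_u_shaped()` retains streamlines with length at most 25 mm whose total
turning angle (sum of successive inter-segment angles) reaches 90 degrees.
Cumulative turning operationalizes "curvature threshold" for U-shape
selection; both thresholds are explicit parameters since conventions for the
length cut differ between sources at the U-fiber scale.

## Inference

### Restricted sign-flip permutation test

Per hemisphere, retinotopic and non-retinotopic strength are summarized as
the *mean per-cell* percent strength over the 6 diagonal and the 30
off-diagonal cells. Means (not sums) matter: under a uniform cell
distribution the two means are equal, whereas the raw sums would differ by
the 6:30 cell count and the swap null below would be wrong. The test
statistic is the one-tailed paired t on the within-hemisphere differences,
$t = \bar d / (s_d/\sqrt{H})$. The null is built by exhaustively enumerating
all $2^H$ within-hemisphere swaps of the pair (64 for six hemispheres,
identity included) - exactly the sign-flip group of the paired t, and the
restriction that preserves each hemisphere's total connectivity. The p-value
is the proportion of permutation t values $\ge$ the observed one, so
$p \ge 2^{-H}$ and ties count toward p. Zero-variance differences yield a
documented signed-infinity sentinel rather than an error, so enumeration can
compare degenerate assignments by value. Calibration and power are verified
by simulation: under the chance generator the rejection rate at
$\alpha = 0.05$ stays at its exact level (achievable levels at $H = 6$ are
multiples of 1/64), and at a diagonal mass of 0.7 with 1000 streamlines per
hemisphere the test rejects in essentially every run.

### Reliability and ANOVA

The ICC variant is fixed to two-way random effects, single measure, absolute
agreement - ICC(2,1) - computed per matrix cell across hemispheres with the
two acquisitions as raters; cells without between-hemisphere variance are
undefined and flagged. CoV defaults to the within-pair form (sample SD of
the two measurements over their mean, averaged across hemispheres); the
across-hemisphere form is implemented as an option since either aggregation
is defensible. The 2x2 repeated-measures ANOVA (connection type x coil) uses
the classical within-subject decomposition, each effect tested against its
own effect-by-hemisphere interaction with df (1, H-1), and takes *absolute*
streamline counts: percent shares of the two types are complementary by
construction and would make the factors dependent. All three statistics are
cross-checked in the test suite against independent `aov()`-based oracles.

## The synthetic-data generator

What it emulates: stimulus-locked sinusoidal responses with unknown common
delay, low-frequency drift and Gaussian noise; a triangulated cortical patch
with opposite field signs in V1 and V2; label volumes with a CSF
compartment; U-shaped streamline bundles whose endpoints follow a
parameterized retinotopic preference; b = 0 series with coil-dependent tSNR
profiles. Key defaults, with units and rationale:

| parameter | default | why |
|---|---|---|
| diagonal mass `retino_bias` | 0.727 | the retinotopic share of total V1-V2 connectivity observed in vivo |
| diagonal lengths | 16 +/- 4 mm | in-vivo retinotopic fiber length distribution |
| off-diagonal lengths | 32 +/- 13 mm | in-vivo non-retinotopic length distribution |
| tracking range / step | 3-100 mm / 0.2 mm | tractography settings the tractograms emulate |
| streamlines per hemisphere | 1000 | free choice (absolute in-vivo counts unreported); large enough for stable percentages |
| BOLD noise | amplitude SNR ~10 | typical phase-encoded mapping quality |
| hemodynamic delay | 5 s | typical BOLD latency |
| b=0 tSNR / near-deep ratio | 20 / 1.7 | head-coil-like baseline; surface-coil superficial gain |
| hemisphere bias spread (pipeline) | SD 0.05 | gives hemispheres trait variance so ICC has something to detect |

The cell distribution places probability `retino_bias` uniformly on the six
diagonal cells and the remainder uniformly on the thirty off-diagonal cells;
`retino_bias = 1/6` is therefore exactly the uniform (chance) matrix, and the
expected retinotopic percentage is `100 * retino_bias`. Lengths are drawn
from truncated normals by inverse-CDF (moments stay interpretable, unlike
clipping), with the lower truncation raised to the endpoint chord when
needed; endpoints are sampled uniformly over the target segment's voxels and
jittered strictly inside the voxel, making endpoint assignment round-trip
exact. Polylines are circular arcs bulging out of the patch plane, resampled
at 0.2 mm; CSF contaminants instead arc downward through the CSF slab.
Every generator call derives one RNG stream from `seed` (sub-generators use
fixed offsets) and restores the session RNG, so identical configurations are
bit-reproducible.

What it does **not** emulate - and hence what green tests do not show about
real data: cortical folding (the patch is a flat ribbon; all downstream
formulas are exercised, but gyral-bias effects cannot arise), actual fODF
estimation or tractography (streamlines are constructed, not tracked),
scanner artifacts (fat displacement, motion, distortion), and registration
error between functional and diffusion spaces (label volumes are exact
rasterizations).

## Statistical study sizes

Distribution-level properties (test calibration, power, bias recovery) are
simulated through `simulate_cell_counts()` - the exact multinomial step
`simulate_streamlines()` itself draws before building geometry - with 500
replicates of six hemispheres x 1000 streamlines; the geometric path is
separately verified against a naive brute-force reference on fifty
1000-streamline tractograms. Retinotopy recovery uses a 12x12-vertex patch;
tSNR convergence uses 300-500 volumes. These sizes were chosen so every
Monte-Carlo tolerance (3 SEM / 3 binomial SD) is met with margin.

## Known limitations

* The conjugate-average run combination degenerates as the hemodynamic delay
  approaches a quarter stimulus cycle (combined amplitude $\propto \cos\delta$).
* ICC magnitude depends on the hemisphere trait-to-noise ratio; with the
  default bias spread the synthetic per-cell ICC is modest (~0.2-0.4) and
  seed-dependent, and should not be read as a prediction for real data.
* With six hemispheres the ANOVA's coil F has heavy null variability;
  single-seed excursions of the null effects are expected.
* The permutation test is exhaustive by design and limited to H <= 20
  (2^20 assignments); sampling-based permutation is out of scope.
* TCK reading supports Float32LE/BE, the format's standard encodings;
  TRK import is not implemented.
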