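---
title: "Methods: eggshell EBSD microstructure and its phylogenetic comparative analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eggshell EBSD microstructure and its phylogenetic comparative analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
numerical choices were made the way they were. It is organised bottom-up:
orientation algebra, grain statistics, misorientation distributions, the
synthetic generator, and the phylogenetic comparative layer.

## Orientation algebra

Orientations are unit quaternions `(w, x, y, z)`, sign-canonicalised to
`w >= 0` so that averaging and hashing are stable (`q` and `-q` are the
same rotation). Euler angles follow the Bunge ZXZ convention of CTF/ANG
text formats, in degrees; the rotation matrix `R(q)` carries the sample
frame onto the crystal frame, so the crystal c-axis expressed in sample
coordinates is `R(q) %*% c(0, 0, 1)`. At the gimbal degeneracy
(`Phi ~ 0` or `180`) the split between `phi1` and `phi2` is not unique
and the back-conversion pins `phi2 = 0`; round-trip tests therefore
compare rotations, not raw angle triplets.

Misorientation uses the **proper rotational subgroup of calcite** (point
group 32, order 6: identity, +/-120 degrees about c, three 2-fold axes
along the a-axes). Proper rotations are the standard choice for
misorientation angles; whether an instrument vendor folds in the full Laue
class only matters within a fraction of a degree of the upper bound. The
disorientation angle is the minimum rotation angle over single-sided
symmetry composition — sufficient for the *angle* because rotation angle
is conjugation-invariant; the test suite verifies equality with the full
both-sided minimisation. Arguments are swapped into a canonical order per
pair before evaluation so that `theta(a, b)` and `theta(b, a)` are equal
to the last bit, not merely to rounding.

`maxDisorientation()` computes the histogram axis bound by scanning 2e5
uniform random rotations and refining the best candidate with Nelder-Mead
on the rotation-vector chart; the value is cached per group. For the
trivial group the bound is 180 degrees; for calcite-32 the computed value
is the familiar ~104.5 degrees. Raw random sampling alone systematically
undershoots the bound (the maximisers are isolated points), which is why
the refinement step exists both in the implementation and in the
independent oracle used by the tests.

IPF colours fold the crystal direction parallel to a chosen sample
direction into the fundamental sector of calcite's direction symmetry
(proper group plus the antipodal identification). With the 2-fold axes
along x, that sector is polar angle 0–90 degrees, azimuth 30–90 degrees —
not the 0–60 sector one might guess; the 30-degree offset comes from the
mirror lines induced by combining the 2-folds with the antipodal map. The
colour key is barycentric (red at the c-axis vertex, green/blue at the two
basal vertices, brightest channel saturated); the exact RGB values are a
documented convention of this package, not a claim about any instrument's
palette.

## Grain segmentation and geometry

A grain is an 8-connected (configurable to 4) flood-fill component of
indexed pixels in which adjacent pixels differ by less than the
segmentation **threshold, default 10 degrees** — the conventional grain
definition, and the low/mid class edge of the boundary colour scheme.
Components are found as connected components of the pixel similarity
graph. Grains under **minPixels = 5** are merged into their most similar
neighbouring grain (sub-resolution specks are indexing noise); with
`mergeSmall = FALSE` they are dropped instead. The partition property
(grain areas sum exactly to the indexed area) and monotonicity of grain
count in the threshold are enforced by tests.

Grain mean orientations project every pixel onto the symmetry variant and
quaternion sign nearest a reference pixel, then take the renormalised
arithmetic mean — adequate for the few-degree intra-grain spreads these
maps have.

The ellipse fit uses second central moments of the pixel coordinates with
a `step^2/12` per-pixel term for the pixel's own extent; for a uniform
ellipse the variance along a semi-axis `a` is `a^2/4`, so `a =
2*sqrt(lambda1)` and `AR = sqrt(lambda1/lambda2)`. The pixel-extent term
makes the moment AR of a filled `n x m` rectangle equal exactly `n/m`, and
gives a one-pixel-wide line of length `L` the honest AR `L` rather than a
division by zero; fits are capped at AR 100 and flagged there. The fit is
equivariant under mask rotation.

Boundary segments connect adjacent grain pairs with the misorientation of
their **mean** orientations; pairs under the **2-degree detection floor**
(the usual EBSD angular-resolution convention) are treated as intra-grain.
Classes are low [2, 10), mid [10, 20), high >= 20 degrees. The depth
profile bins boundary pixels (rook adjacency, so "length" is in pixel
edges) into horizontal bands and reports the low-angle fraction per band,
`NA` where a band has no boundary at all.

AR summaries retain grains with **area at or above the median** (ties
retained): small grains are rounder and numerically dominant, and the
median-area filter is the interpretation of "outside the 50th percentile
in area" that drops exactly them. The full per-grain table is always
reported alongside.

## Misorientation distributions and Type classes

Distributions are computed **between grains**, not pixels: one angle per
unordered adjacent pair (neighbour method), or `nPairs` random unordered
pairs of distinct grains (random method; adjacent pairs are *not*
excluded — nothing in the method requires it, and excluding them would
bias small maps). The random draw is seed-mandatory and reproducible; its
default size equals the adjacency count so the two methods have comparable
sample sizes. Means and the below-20-degree fraction are computed on the
raw sample; the histogram bin width (default 5 degrees) is display-only.

The Type classes operationalise "low-angle dominant" versus "high-angle
dominant" neighbour-pair distributions via the fraction of angles below 20
degrees: **Type1 at >= 0.50, weak-Type1 at [0.35, 0.50), Type2 below**.
The thresholds are configurable and always reported next to the raw score;
0.50 is the literal reading of "dominant", and 0.35 separates a weakened
low-angle mode from distributions indistinguishable from the uncorrelated
background (whose below-20 mass for calcite is about a third).

## The synthetic generator

`generateMap()` grows a 2-D radial section: layers stacked inner to outer,
each with nucleation sites along its base whose columns compete for pixels
under a weighted lateral distance. Habits parameterise the competition —
*prismatic* (straight, even columns), *wedge* (width-spread plus widening,
so some columns squeeze others out), *splaying* (progressive tilt with
height), *needle* (dense nucleation, short strata that re-nucleate). A
column's territory under weighted competition can disconnect; ground-truth
labels are therefore split into 8-connected components so that "grain"
always means a connected region. Grain orientations compose a c-axis drawn
from a von Mises–Fisher distribution about the growth direction
(concentration `kappa`) with an in-plane spin about c — **correlated**
spins (Gaussian scatter about a common reference) produce low-angle
neighbour pairs, **uniform** spins produce the high-angle background; this
is the lever that separates Type 1 from Type 2 while keeping the strong
vertical c-axis alignment both morphotypes share.

Intra-grain misorientation has two parts, both scaled by the gradient
parameter (degrees per 100 um): a smooth drift with height about a random
per-grain axis, and subgrain walls every 40 um whose jump magnitudes are
`N(0, gradient * 0.4)` degrees. The walls are the physically standard way
intragranular misorientation localises in columnar calcite, and they are
what makes the low-angle boundary share grow with the gradient — a purely
smooth drift never splits a flood fill and mostly perturbs grain means
upwards. The test for that property segments at a 3-degree threshold
(below the low/mid edge) and averages over a fixed four-seed set.

Presets are **caricatures for testing, not reconstructions**: layer
fractions and densities are round numbers chosen once so that the presets
express their defining behaviour — `ostrich_like` (thin wedge mammillary
layer under tall prismatic columns, kappa 150, 5-degree correlated spins)
and `rhea_like` (wedge + splaying + prismatic, kappa 100, 6-degree spins)
classify Type 1 with high and moderate aspect ratios; `tinamou_like`
(needle mammillary layer, re-nucleating upper zone, uniform spins, kappa
30) classifies Type 2 with low aspect ratio. The default map is 600 x 400
px at 2 um/px (a 1.2 x 0.8 mm section), a size at which the full pipeline
runs in a few seconds. What the generator does **not** emulate: real
indexing noise structure (dropout is uniform), pore networks and
ornamentation, 3-D grain shape (all statistics here are 2-D sectional, as
are the ones it feeds), and any species' true layer-thickness fractions.
Passing tests on synthetic maps therefore demonstrate algorithmic
correctness and sensitivity, not instrument-grade realism.

## Phylogenetic comparative layer

Trait means are analysed on the **natural-log scale** (the values are
positive, and proportional variation is the natural null); reconstructed
node states are reported both on the log scale (with symmetric 95%
intervals) and back-transformed by `exp` for reading in original units.

All six models are Gaussian, fitted by profiling the single structural
parameter on a grid of 21 (31 for OU) followed by golden-section
refinement, with the rate `sigma^2` and root state solved analytically by
GLS at every evaluation (via Cholesky; non-positive-definite proposals are
rejected). Parameter counts: BM 2, OU 3, EB 3, Trend 3, Lambda 3, White
Noise 2.

- **Lambda** scales off-diagonal covariances, preserving tip depths; the
  upper bound is the largest value keeping the matrix positive definite
  (`max(diag C)/max(offdiag C)`). The profile can be multimodal with a
  spike at the PD boundary, so the search multistarts from the interior
  optimum, `lambda = 0`, `lambda = 1`, and a second bracket above 1 —
  guaranteeing in particular that the free fit never undercuts the nested
  BM fit.
- **OU** is single-optimum with the root at the optimum, covariance
  `exp(-alpha d_ij) (1 - exp(-2 alpha t_ij)) / (2 alpha)`; `expm1` keeps
  the small-`alpha` limit numerically equal to BM.
- **EB** uses `(exp(r t_ij) - 1)/r` with `r` in `[-log(1e5)/T, 0]`.
- **Trend** adds a linear drift in the mean with tip depth; on an
  ultrametric tree the depth column is constant, the slope is
  unidentifiable, and the fit collapses to BM with `mu = 0` and a note
  (the parameter count stays 3).
- **White Noise** is an i.i.d. normal fit ignoring the tree; on an
  ultrametric tree it coincides with Lambda at 0, which the tests use as
  a nesting identity along with Lambda(1) = BM and EB(0) = BM.

AICc follows the small-sample form and refuses `n - k - 1 <= 0`. Model
selection takes the AICc minimum, reports every model within delta = 2 as
"as good as" the best, and breaks exact ties by the fixed order BM, OU,
EB, Trend, Lambda, WhiteNoise. The comparative driver performs the BM
ancestral reconstruction **only** when BM is best or as-good; otherwise it
emits an explanatory verdict and no reconstruction.

Ancestral states are joint-ML under the fitted BM model, computed by a
linear-time two-pass message-passing scheme (upward pruning, downward
redistribution) rather than dense matrix algebra; the tests verify
equality (1e-8) with the explicit GLS conditional expectation, including
the variance inflation from estimating the root state, and agreement with
an established independent implementation. Polytomies are resolved with
zero-length branches (the likelihood and node states are invariant to the
resolution order) and results are mapped back to the original nodes by
descendant sets. Zero-length cherries with distinct values are reported as
singular rather than silently pseudo-inverted. Confidence intervals use
the plug-in ML rate, which makes them slightly anticonservative at n = 12;
the calibration test accepts pooled coverage between 90% and 98%.

`graftSubstituteTips()` relabels tips (for substituting a sampled species
onto its calibrated sister's branch) without touching topology or branch
lengths — the device needed when a dated tree samples sister taxa of the
species actually measured.

## Problem sizes, determinism, degenerate inputs

Test and acceptance-script sizes were chosen so the whole suite exercises
every claim in well under a minute of computation per file: maps of
150 x 100 to 600 x 400 px, 1e5–1e6 rotation pairs for distribution
checks, 100 replicate fits at 12 tips, 60–100 lambda recoveries at 100
tips. Every stochastic step takes an explicit integer seed (`withr` scopes
them, so library calls never disturb the caller's RNG), and the pipeline
writes byte-identical outputs for identical configurations; the run log
echoes every materialised parameter and the MD5 of every artefact.
Degenerate inputs fail loudly and specifically: empty indexed sets,
constant traits, irregular grids, unknown phases, label mismatches (the
offending species are listed), and AICc with too-rich models are all
distinct errors.

## Known limitations

- The generator's growth model is 2-D and phenomenological; it makes no
  biomineralisation claims.
- Segmentation parameters (threshold, connectivity, minimum grain size)
  are conventions; absolute grain counts are convention-dependent even on
  synthetic data, which is why recovery is asserted via pairwise label
  agreement rather than raw counts.
- Only single-optimum OU is offered; multi-regime models are deliberately
  out of scope at these sample sizes.
- IPF colours are a package convention and will not match a specific
  vendor's key pixel-for-pixel.
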