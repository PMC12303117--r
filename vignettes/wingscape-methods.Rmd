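---
title: "Methods: theoretical morphospace and flight-performance landscapes"
author: "wingscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: theoretical morphospace and flight-performance landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, numerical choices
and limitations. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## Outline representation and orientation convention

An outline is an ordered, implicitly closed vertex list. Coordinates are
continuous; image digitisation happens upstream of this package. Because no
universal convention exists for how a traced wing is oriented, `wingscape`
imposes one and applies it everywhere: counter-clockwise traversal, centroid
at the origin, wing base (the proximal, humeral end) at minimum x, span
along +x, traversal starting at the base. `orient_standard()` enforces
translation, direction and start; it deliberately does not rotate, since
elliptical Fourier normalisation removes rotation anyway, and a rotation
step would need its own (arbitrary) axis convention. The two metrics that
*do* depend on the span direction — aspect ratio and the chord
distribution — internally align the major principal axis of the vertex
scatter with x, taking the rotation angle in (−90°, 90°] so that
conventionally oriented wings keep their base/tip assignment. Isotropic
shapes (equal principal moments, e.g. a square) are left unrotated.

Equal-arc-length resampling to *P* points underlies everything downstream;
*P* = 150 is the package default. Resampling is only *near*-idempotent
(~1e−7 at *P* = 150 on a smooth outline): a second pass re-measures arc
length along the resampled polygon's own chords, which are marginally
shorter than the original's. Self-intersection testing uses exact
sign-of-cross-product orientation predicates, with collinear overlap and
single-point touching counted as intersections — lattice shapes near the
viability boundary are often near-tangent, and an inclusive test keeps the
viable set conservative.

## Elliptical Fourier analysis

`efa_forward()` implements the classical closed-curve decomposition under
the cumulative chord-length parameterisation; coefficients are exact for
the piecewise-linear curve through the input vertices, and the offset terms
are the arc-length centroid. Normalisation divides by the first-harmonic
semi-major axis, rotates that axis onto +x and shifts the starting phase to
its end, pinning a₁ = 1, b₁ = 0, c₁ = 0 exactly: with H = 9 harmonics, 33
free coefficients describe each shape. H = 9 at P = 150 is validated by the
harmonic-power criterion: across sets of generated wings, the first nine
harmonics carry ≥ 99.5 % of the power of a reference decomposition at
H = 74 (`harmonic_sufficiency()`; the acceptance script recomputes this).

Two numerical facts about this parameterisation are worth recording. First,
an ellipse traversed at constant speed is *not* a single harmonic — only the
elliptic-angle parameterisation has that property — so the first-harmonic
ellipse of a 2:1 ellipse has axes ≈ (1.83, 1.07), while the full
reconstruction recovers (2, 1) to well under 1 %. Second, the
forward–inverse round trip re-parameterises the truncated series by chord
length each time, so coefficients drift by ~2×10⁻³ per trip (contracting on
further trips) even though the reconstructed *shape* is accurate to well
under 0.5 % of span. Tests assert the shape bound and the contraction, not
a fictitious exactness.

The 180° ambiguity of first-harmonic normalisation (the two ends of the
major axis) is resolved by keeping the phase-shift branch that leaves the
input's starting vertex — the base, under the orientation convention —
nearest parameter 0. The rejected branch flips the sign of every even
harmonic. This makes coefficients consistent across a data set prepared by
`resample_equal_arclength()`; outlines supplied in violation of the
orientation convention (e.g. rotated by more than ±90°) may select the
opposite branch, which is the documented residual ambiguity. Whether to
retain the sign of d₁ (reflection information) was an open choice; the
package keeps it, since inputs are consistently counter-clockwise and
discarding it would fold genuinely chiral variation.

## Morphospace and the theoretical grid

PCA is covariance-based (centred, unscaled), the standard choice in outline
morphometrics: coefficients share units, and per-column rescaling would
inflate noise harmonics. The pinned columns are constant and carry zero
variance. The theoretical lattice defaults to 26 × 19 = 494 cells spanning
the empirical (PC1, PC2) range extended by 20 % of each axis's range on
*each* side — a border surrounding the empirical box on all four sides —
with lattice values at the inclusive endpoints of the extended range
("equidistant" with the stated counts). Back-projection sets all trailing
component scores to zero and re-imposes the pinned coefficients; each cell
is reconstructed by inverse EFA at P points and screened for
self-intersection. Non-viable cells keep their reconstruction for plotting
but are excluded from every performance and optimality computation.
Whether a synthetic study produces non-viable cells depends on the latent
spread of the generated sample; the screen itself is exercised directly in
the tests either way.

## Performance metrics

* **AR = R²/S** exactly as written, for a single planform (no wing-pair
  factor).
* **Chord distribution**: vertical-slice y-extents at the midpoints of
  `n_stations` (default 200) equal spanwise intervals, summed over pieces
  when a slice is multiply connected; normalised as ĉ = cR/S so ∫ĉ dr̂ = 1.
* **r̂₂ = √(∫₀¹ ĉ r̂² dr̂)** by the midpoint rule. The square-root
  convention is used because it is the standard non-dimensional radius of
  the second moment of area and keeps the value in (0, 1) for any simple
  planform (rectangle √⅓ ≈ 0.577; base-tapered triangle √⅙ ≈ 0.408;
  tip-tapered triangle √½ ≈ 0.707 — closed forms the tests verify at 1 %).
  Midpoint integration converges at second order, which the tests check by
  station doubling.

## Finite-element stress model

The structural proxy treats the wing as a uniform flat membrane: linear
Kirchhoff plate bending with 9-DOF discrete Kirchhoff triangles (DKT), not
3-D solids — the standard idealisation for a thin membrane under a
transverse tip load, and the element's explicit formulation makes the
solver fully deterministic. Venation, composite stiffness maps, geometric
nonlinearity and fluid–structure interaction are out of scope.

Meshing triangulates the polygon exactly by ear clipping (so summed element
area equals polygon area to machine precision), converts to a constrained
Delaunay triangulation by Lawson edge flips, then inserts interior points at
the centroids of the largest elements — with local flips after each
insertion and periodic Laplacian smoothing — until the element count reaches
the target (2500 by default; each insertion adds exactly two elements, so
the achieved count is within one of the target). An in-package mesher keeps
the pipeline dependency-free and reproducible; mesh quality after flips and
smoothing is sufficient that the tip deflection of a 20:1 plate matches the
Euler–Bernoulli cantilever closed form within 15 %, and the median stress
of a wing changes by under 5 % between 2500 and 5000 elements.

Boundary conditions follow the wing idealisation: the four boundary nodes
nearest the minimum-x extreme are fully clamped (the proximal base), and a
transverse point load (default 0.003, with E = 1 GPa, ν = 0.49) acts at the
maximum-x boundary node (the apical tip). Every shape is rescaled to unit
area before meshing and given thickness 0.01, so stresses are *relative*
scores comparable across shapes, not absolute material predictions; only
their ordering feeds the optimality ranking. The element count, load,
thickness and material constants are all configurable. The summary
statistic is the median element von Mises stress (top-surface bending
stresses at element centroids); the mean is exposed as an option, as the
two summaries can reasonably be preferred for robustness or smoothness
respectively.

## Pareto optimality

Dominance uses the usual definition (at least as good everywhere, strictly
better somewhere) with per-metric directions; the default trade-off
maximises AR and r̂₂ and minimises median stress, with all metrics equally
weighted — weighting is meaningless under pure dominance, which is the
point of using it for theoretical shapes whose performance preferences are
unknown. Forward ranks come from iterative front peeling; reverse ranks
from the same procedure with every direction inverted. The rank ratio is
1 for forward rank 1, 0 for reverse rank 1 (when not on the front), and
(b − 1)/(f + b − 2) otherwise; a single solution scores 1. This is the
minimal formula satisfying both endpoint semantics (front ⇒ 1, dominated by
all ⇒ 0); identical metric vectors share ranks and therefore ratios, which
keeps the landscape deterministic without arbitrary tie-breaking. Ratios
are invariant to strictly monotone transforms of any single metric, and the
implementation is tested for exact agreement with a brute-force peeling
oracle on hundreds of random instances.

## Phylogenetic comparative methods

Trees are `ape` objects; the Brownian covariance C comes from shared
root-to-ancestor path lengths. Ancestral states are generalised
least-squares estimates via explicit C-matrix algebra (the root is the
phylogenetic mean; other nodes condition on the tips through their shared
path lengths). The O(n³) cost is irrelevant at the tree sizes involved, and
the explicit form is transparent; agreement with an independent re-rooting
implementation is asserted to 1e−6 in the tests. The phylomorphospace
projects reconstructed ancestors through the same linear shape-space map as
the tips; taxa absent from the tree are retained as unconnected points.

The multivariate signal statistic follows the standard multivariate
generalisation of Blomberg's K: the ratio of observed to Brownian-expected
signal, with traits centred on the phylogenetic mean, equal to 1 in
expectation under Brownian motion and exactly 1 on an equal-depth star
tree (an algebraic identity the tests verify numerically). Significance
uses row permutation of the trait matrix with the add-one correction, so
the smallest attainable p at the default 9999 iterations is 1e−4. K_mult
defaults to the full normalised coefficient matrix rather than retained PC
scores — the statistic is invariant to orthogonal rotation of the trait
columns, so using all coefficients avoids an arbitrary truncation choice;
a score matrix can be passed instead.

PGLS whitens the model by the Cholesky factor of C and reports R², F and p
from the whitened regression against its whitened intercept-only null; on
an equal-depth star tree it reproduces OLS to 1e−10 (asserted). The
regression battery runs five pairings — log centroid size → shape PC1,
temperature → size, temperature → shape PC1, rainfall → shape PC1,
rainfall → PC2 — with per-test complete-case n reported. Centroid size is
log-transformed in the allometric test (a flag disables this), size being
the one predictor spanning multiplicative ranges. No multiple-testing
correction is applied by default, keeping each row a self-contained test; a
Holm option exists.

## Synthetic data generator

`gen_wing_outline()` builds leading and trailing edges as smooth
single-valued curves over the span: a smoothstep blend between the base and
tip width fractions, shaped by a lens envelope (4u(1−u))^r with
r = 1/(2·tip_roundness), plus optional seeded low-order sinusoidal
roughening tapered by the same envelope. Closure and simplicity are
guaranteed by construction within the documented parameter bounds. The two
latent axes of `gen_wing_set()` map to overall breadth and to apical-tip
size relative to the humeral base, so the leading PCs of the generated
coefficient matrix recover them (|r| > 0.9 at zero noise, asserted); axes
are standard-normal per taxon, spans log-normal (σ = 0.25), and covariates
are linear in a chosen latent axis plus Gaussian noise with configurable
slope — the ground-truth table makes slope recovery a direct test.
Covariate defaults (slope 0.5 of a temperature-like covariate on the
breadth axis, zero for the rainfall-like covariate, noise 0.1) give one
clearly detectable and one null effect at moderate sample sizes. A single
integer seed drives every draw; per-taxon outline seeds derive from it by
offset.

What the generator does *not* emulate: venation, real taxonomic structure,
measurement/digitisation error correlated along the outline, and — in
`gen_wing_set()` — phylogenetic structure in the latent axes (taxa are
independent draws; Brownian trait evolution is provided separately by
`simulate_bm()` on `gen_tree()` trees). Passing tests on synthetic data
therefore demonstrates correctness of the machinery, not biological claims
about real wings.

## Problem sizes and determinism

Default analyses run comfortably on one core: the full synthetic pipeline
at 60 taxa with a 494-cell grid and 2500-element plate solves per viable
cell completes in minutes, and the test suite uses reduced sizes (hundreds
of elements, tens of taxa, tens to hundreds of permutation/simulation
replicates) chosen so each check still exercises the asymptotic behaviour
it targets. Every stochastic step takes an explicit integer seed and
restores the caller's RNG state; identical configuration and seed reproduce
byte-identical artifact tables.

## Known limitations

* EFA coefficient drift under repeated forward–inverse round trips is
  inherent to chord-length parameterisation (shapes, not coefficients, are
  the stable objects).
* The FEA stress scale is internal (unit-area, fixed-thickness
  normalisation); comparisons are ordinal across shapes.
* Clamping exactly four boundary nodes approximates a clamped root edge;
  very coarse meshes localise stress at those nodes.
* The principal-axis alignment inside AR and the chord distribution is
  undefined for isotropic shapes and flips for inputs rotated beyond ±90°
  from the convention.
* PGLS assumes strict Brownian residuals (no Pagel's λ or OU estimation).
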