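---
title: "Reverse-engineering limb bud tissue movement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse-engineering limb bud tissue movement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphomovie)
```

## The problem

A sequence of outlines of a growing organ — here the embryonic limb bud,
photographed hourly over three days — constrains but does not determine the
tissue movements inside it. The same boundary history is compatible with
uniform expansion, distally concentrated growth, posteriorly twisted growth,
and much else: a boundary point can slide along the outline without changing
the shape, and interior tissue is invisible to the outline entirely.
`morphomovie` makes this degeneracy explicit and then resolves it with
clonal data. It (i) constructs families of candidate *tissue movement maps*,
each an hour-by-hour velocity field consistent with the outline sequence,
(ii) simulates virtual clonal fate maps on every candidate, (iii) scores the
virtual clones against experimental clone images to select the best map,
and (iv) derives growth tensors, progenitor maps and growth-only
gene-expression predictions from the winner.

## From outlines to boundary velocities

Each consecutive outline pair needs a correspondence: which point on the
young outline becomes which point on the older one. The user supplies
*boundary control splines* — smooth curves, oriented roughly along the
proximo-distal (PD, +x) axis, crossing the entire outline stack. The k-th
intersection of a spline with outline *t* is paired with its k-th
intersection with outline *t+1* (rank pairing along the spline; ties broken
by arc-length order), giving a sparse set of *control vectors*. Two Gaussian
radial basis function interpolants (one per displacement component)

$$ s(\mathbf{x}) = \sum_i \lambda_i \, e^{-\|\mathbf{x}-\mathbf{c}_i\|^2 / 2\sigma^2} $$

are fitted to the control vectors by (ridge-regularized) linear least
squares and evaluated at every boundary mesh node. The width $\sigma$
defaults to the mean spacing between control-vector origins — wide enough
for smooth interpolation, narrow enough to keep the control vectors local;
the ridge $\lambda = 10^{-10}$ only guards conditioning. Displaced boundary
nodes are finally *snapped* (projected) onto the next outline, so the
deformed boundary lies on it exactly; the residual moved by snapping is the
local RBF misfit, not an extra model term. Boundary nodes of the artificial
body (see below) are held fixed: the body is identical in every frame, and
letting the wide Gaussian tails drag body nodes tangentially serves no
purpose and can crush the pinned flank corner at fine mesh resolution.

## Spring-analogy propagation into the tissue

Interior node displacements come from a lineal edge-spring analogy: every
mesh edge is a spring of stiffness

$$ k_e = f(x_e) / l_e, $$

with $l_e$ the edge length (short edges stiffer — the standard lineal
spring-analogy scaling, which protects small elements) and $f$ a profile
over the PD coordinate of the edge midpoint. Jacobi relaxation moves each
free node to the stiffness-weighted average of its neighbors until the
largest update falls below `1e-8` times the mean edge length (cap 10,000
iterations, relaxation factor 1). The fixed point is a weighted-harmonic
extension of the boundary values, so each interior displacement component is
a convex combination of boundary values — the discrete maximum principle
that the tests exercise. Flank ("deep body") nodes are pinned at zero.
After the update the solver checks for inverted elements; if any appear the
step is retried as two half-steps (at most four subdivisions). The spring
system is a *device for generating hypotheses*, not a mechanical model of
mesenchyme; its one scientific knob is $f$:

* `constant` — no PD bias;
* `sigmoid` — stiffer distally (midpoint at 2/3 of the PD extent,
  dimensionless steepness 10, range $[1, 5]$), *restricting* distal growth;
* `inverted_sigmoid` — softer distally, *allowing* distal expansion.

Three spline families (straight, fanning-out, posteriorly drifting) crossed
with the three profiles give the familiar nine-map exploration of plausible
growth asymmetries.

## Meshing and the conservative interpolation map

Shapes are meshed by a distmesh-style generator written for this package
(boundary vertices at the target spacing, hexagonal interior seeds cleared
0.55 spacings from the boundary, Bowyer–Watson Delaunay triangulation,
centroid filtering, two Laplacian smoothing passes). The generator is
deliberately pluggable: its contract is only the mesh invariant set
(positive CCW areas, edge/Euler consistency, area partition of its boundary
polygon to 1e-6 relative, minimum angle above 15 degrees on the shipped
shapes). At the documented coarse reference resolution (edge length 0.042
model units) the first-stage bud carries about 3,156 triangles; the default
working resolution (0.15) gives roughly 250 growing to 900 triangles per
frame, which keeps a full 72-frame build near ten seconds.

Advancing one hour deforms mesh *t* onto outline *t+1*; the fresh mesh at
*t+1* then reuses the snapped deformed boundary of mesh *t* verbatim as its
boundary polygon, re-meshing only the interior. Deformed-*t* and fresh-*t+1*
therefore tile the *identical* polygon, which is what lets the
triangle-interpolation map satisfy both of its conservation identities to
1e-6 and in practice to machine precision: with overlap weights $w_{ij}$
(exact Sutherland–Hodgman clipping areas; candidate pairs from a
bounding-box grid; slivers below $10^{-12}$ of the mean triangle area are
dropped and re-assigned proportionally within their row),

* partition: $\sum_j w_{ij}$ equals the deformed source-triangle area, and
* coverage: $\sum_i w_{ij}$ equals the target-triangle area.

Field transfer $v_j = \sum_i v_i w_{ij} / A_j$ is then linear, positivity-
and constant-preserving, obeys the maximum principle, and conserves the
area integral. Values are *labeled-cell densities* (1 = every cell
labeled), so these properties are exactly the physically required ones.
Reverse maps are the transposed weights — the exact adjoint of forward
transfer under the area-weighted inner product — rather than a re-run of
the deformation backwards, which would only hold approximately.

## Virtual clones, mixing, and the hourly operator order

A virtual clone seeds density 1 in one triangle and follows the
distribution through the movie. Hourly re-meshing itself smears the
distribution (the familiar numerical diffusion of conservative remapping),
and this smearing *models* part of the real mesenchymal cell mixing; the
remainder is an explicit isotropic diffusion term, solved by an explicit
Euler / finite-volume two-point flux scheme on the triangle adjacency with
zero-flux boundaries (10 substeps per hour, automatically increased to half
the stability bound). Each hour applies diffusion first and the
interpolation transfer second; the opposite order differs only at O(dt)
and a test keeps that difference small.

The mixing constant is expressed in model-area units per hour. The
calibration levels 0.03 and 0.08 quoted for the overlap analysis are
re-expressed through `scaled_diffusion()` (factor 0.05), chosen once so
that the low level spreads a clone by about half the initial bud radius
over the full 72 h window ($\sigma = \sqrt{2Dt}$) — the dispersal scale
real clones display — instead of homogenizing the bud.

## Scoring clones and selecting maps

An experimental clone is a set $E$ of $n_c$ labeled triangles on the final
mesh (rasterized from a binary mask at 50% pixel coverage). A virtual clone
$v$ is scored against it by two factors:

$$ s \;=\; \underbrace{\frac{\sum_{i \in E \cap \mathrm{supp}(v)} v_i}
  {\|v\|_2 \sqrt{n_c}}}_{\text{probability affinity}} \times
  \underbrace{\frac{|E \cap \mathrm{supp}(v)|}{n_c}}_{\text{containment}} $$

with support defined as $v_i > 10^{-6}$. The first factor is the normalized
affinity between the virtual labeled-cell distribution and the uniform
distribution on the observed clone (1 exactly when $v$ is the indicator of
$E$); the second penalizes labeled cells found outside the virtual clone.
The product is bounded in $[0,1]$, zero exactly on disjoint supports, and
can only decrease when a clone triangle moves outside the virtual support.
This normalized form was chosen over the plain mean of $v$ over $E$ after a
simulation study: the mean rewards virtual clones with large total mass
(seed triangles are not equal-area), mis-ranking the generating seed for a
third or more of simulated clones, while the normalized affinity recovers
it for 92–99 of 100. A geometric-mean (likelihood) variant recovers
similarly but can *increase* when a low-probability clone triangle is
dropped, violating the monotonicity we require of a penalized score.

`best_match()` scans every seed triangle of the first frame — transport is
linear, so all seeds are propagated at once by composing the hourly sparse
operators — and returns the argmax (ties to the lowest index). A map's
total score is the product of its clones' best scores, so one unmatched
clone vetoes a map. With the reference first-stage mesh (3,156 triangles)
and 13 clones, one map evaluation performs 41,028 clonal comparisons.

Identifiability sets the mixing level used by the recovery tests: with
binarized clones, exact-seed recovery survives D = 1e-4 (99/100) but
degrades through 5e-4 (86/100) and collapses by 5e-3 — binarizing a
strongly blurred field genuinely destroys the seed information, so the
recovery fixtures use D = 1e-4 ("small" relative to the calibration
levels).

## Growth tensors, progenitor maps, expression transport

Within each triangle the velocity field is affine, so the velocity gradient
L solves the 2x2 system mapping edge vectors to velocity differences
exactly. Its symmetric part gives the expansion rate (trace, per hour) —
reported as cell-cycle time $T = \ln 2 / \mathrm{tr}$, the area doubling
time — and the anisotropy $(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$
with principal direction (flagged `NA` when the trace vanishes, e.g. pure
shear or rigid rotation); the antisymmetric part gives the rotation rate.
Report ellipses use axes $\exp(\lambda_i \Delta t)$ with $\Delta t$ = 1 h;
heat maps clamp the display to 10–42 h, and regional summaries split the
bud at one third of the PD extent from the tip (distal) versus the rest
(proximal).

Progenitor maps pull final-frame region indicators backwards through the
transposed maps, diffusing on each earlier mesh: mixing widens membership
distributions in both time directions. Because reverse transfer preserves
constants, a partition of the final frame keeps per-triangle membership
probabilities summing to one at every hour — and with mixing on, every
region's progenitor support strictly contains its mixing-free counterpart,
which is the quantitative form of the argument against early segment
specification. Expression domains are transported with D = 0 by default
(they are tissue marks, not dispersing cell populations); differencing a
growth-only prediction against the observed domain at threshold 0.5 labels
triangles up-regulated (observed on, predicted off), down-regulated
(observed off, predicted on) or consistent.

## The synthetic trajectory

The published hourly morphometric limb trajectory is not redistributable,
so the package generates a parametric stand-in: a semicircular bud (radius
1, dimensionless model units) on a fixed rectangular "artificial body"
(depth 0.5), elongating at 0.05 per hour along +x for 72 frames and, from
hour 36, widening distally into a paddle (relative widening 0.5 at the end)
— the nascent autopod. The generator guarantees what the analyses assume:
simple outlines, monotone area growth, a frame-invariant flank. It does
*not* emulate curvature details of real buds, AP asymmetry of the real
organ, or biological variability (a smooth seeded perturbation is available
but off by default). Passing tests therefore demonstrate the correctness
and conservation of the machinery and the recoverability of known ground
truth under these idealized conditions — not that any particular growth
pattern holds in real limbs.

Stage labels follow the morphometric convention `mEdd:hh`; the 72 hourly
frames are labeled mE9:00 through mE11:23, with "E12" understood as an
alias for the final frame (a 72-frame hourly window cannot contain both
mE9:00 and mE12:00 inclusively).

## Numerical choices and problem sizes

* Clipping tolerance $10^{-12}$ of the mean triangle area; partition repair
  by proportional row rescaling; map rejection above a relative defect of
  $10^{-4}$.
* Spring tolerance `1e-8` x mean edge length; inversion retry by two
  half-steps, depth 4.
* Diffusion stability safety factor 0.5; substep count max(10, bound).
* Test and acceptance runs use the 0.15 resolution (about 250 to 900
  triangles per frame over 72 frames), 20 simulated clones for seed
  recovery, 10 repetitions for map selection, and a disc mesh of ~60
  triangles for the analytic oracles; these sizes were chosen as the
  smallest at which the studied effects are comfortably resolved.

## Known limitations

* Clone extents are axis-aligned rectangles; strongly rotated clones are
  summarized conservatively.
* The mesh generator assumes outlines without deep concavities (boundary
  Delaunay edges must survive filtering; the build fails loudly otherwise).
* Exact-seed recovery is only meaningful at small mixing; at realistic
  mixing the method identifies a neighborhood of equivalent seeds, as the
  blurred inverse problem dictates.
* The reverse map is the adjoint, not the inverse, of forward transport:
  progenitor distributions widen, they do not sharpen.
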