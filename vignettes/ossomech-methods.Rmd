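---
title: "Muscle moment arms and phylogenetic morphospaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle moment arms and phylogenetic morphospaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ossomech)
```

ossomech implements a quantitative workflow for comparing forelimb muscle
mechanics across taxa — originally motivated by quadrupedal archosaurs —
from articulated 3D musculoskeletal models through size-normalized muscle
moment arms to phylogenetically informed morphospaces. This vignette
documents the models, the numerical choices, and what the synthetic-data
validation does and does not establish.

## The articulated model

A `limb_model` is a tree of rigid segments (scapulocoracoid, humerus,
antebrachium, optionally a torso root) connected by three-axis joints.
Every joint follows a joint coordinate system in the Grood–Suntay
tradition: one rotational axis is fixed to the proximal segment, one to
the distal segment, and a floating axis is kept mutually perpendicular to
both; all three pass through a single fixed centre. For the shoulder
(glenohumeral) joint the proximal axis is abduction–adduction (along the
glenoid), the distal axis is mediolateral long-axis rotation (along the
humeral shaft), and the floating axis is protraction–retraction. For the
elbow the proximal axis is extension–flexion (through the distal humeral
epicondyles), the distal axis is long-axis rotation of the antebrachium,
and the floating axis is abduction–adduction.

Rotations are applied proximal axis first, floating second, distal third.
The axis names and their parents fix the anatomy but not an order; this
order is the standard biomechanics convention and is the one under which
the floating axis is well defined (it equals the orthogonalized cross
product of its companions in every reachable pose, a property the test
suite asserts). Rotating about the body-updated axes in this order equals
the matrix product of rotations about the pre-rotation axis directions,
which is how `apply_pose()` composes them. Companion axes within 0.5
degrees of parallel raise a singular-pose error rather than returning an
ill-conditioned floating axis.

Conventions: world frame right-handed with +x anterior, +y dorsal, +z
lateral (right side); lengths in metres; every user-facing angle in
degrees (the study literature reports poses in degrees); positive rotation
about a declared axis direction follows the right-hand rule, so the sign
convention of every action is data in the model file, not code. The
reference pose (all angles zero) is the articulated neutral from which the
standardized functional poses are struck.

A least-squares circle/sphere fit (`fit_joint_centre()`) is provided for
estimating joint centres from digitized articular surfaces: an algebraic
(Kasa-style) fit supplies the start for a nonlinear refinement of the
radial residuals, in a total-least-squares plane for circles. In practice
fossil joint centres also involve judgement about unpreserved cartilage,
so centres are model inputs; the fit is a helper, not a pipeline stage.

## Muscle paths and wrapping

Muscles are one or three strands (posterior/midline/anterior for broad
attachment sites) from origin to insertion, optionally through ordered via
points, deflecting around wrapping cylinders — simplified obstacle
volumes a path must not penetrate. Between consecutive anchors the path is
the shortest route: straight where the chord clears every cylinder,
otherwise tangent line → helical geodesic on the cylinder → tangent line,
with the analytic length `sqrt((t_p + r·delta + t_q)^2 + dz^2)` obtained by
unrolling the surface. Of the two tangent solutions the one whose arc
midpoint points along the cylinder's declared side hint is taken (exact
ties take the positive-handed candidate). Multiple cylinders on one leg are
resolved by fixed-point iteration, re-solving each cylinder against its
neighbouring tangent points until the relative length change is below
1e-10 (hard cap 100 iterations, then a structured convergence error).

Numerical edge cases: cylinders are infinite for the tangency math; a wrap
arc leaving the declared half-length band warns but proceeds, since end-cap
behaviour is not part of the obstacle definition. An attachment strictly
inside a cylinder raises a structured infeasible-attachment error, which
sweep code converts into flagged infeasible cells rather than aborting.
Length is continuous at wrap onset (asserted to 1e-9 at grazing tangency),
so tendon-excursion derivatives behave across transitions; cells adjacent
to a wrap on/off transition are flagged but still enter pooled statistics,
as no exclusion rule is part of the protocol.

## Moment arms by tendon excursion

The moment arm of a strand about a joint DOF is the negative derivative of
path length with respect to the joint angle (in radians) — the
muscle–tendon unit travel method. `moment_arm_at()` uses central
differences with half-step `h` = 2.5 degrees by default (half the 5-degree
protocol grid spacing); on-grid sweeps difference neighbouring grid cells
directly, falling back to one-sided differences at the two ends and at
infeasibility boundaries (with a warning). The identity
`L(end) − L(start) = −Σ r dθ` (trapezoid) then holds exactly by
telescoping, which the suite asserts; halving `h` shrinks truncation error
quadratically. Short strands passing close to the joint centre are the
ill-conditioned case: their length curvature is large, so oracle
comparisons in the validation suite use `h` = 0.02 degrees.

Standardized protocols mirror the study design: glenohumeral
protraction–retraction swept −40 to +40 degrees at 5-degree steps
(17 poses) with the humerus adducted 90 degrees and the elbow flexed 45;
elbow flexion swept 10 to 100 degrees (19 poses) with the humerus adducted
90 and protracted 20. All moment arms are normalized by the minimum
humeral shaft circumference — a robust postcranial body-size proxy —
making every downstream statistic dimensionless; raw values are retained
alongside. The circumference is usually a scalar model input; for meshes,
`min_shaft_circumference()` takes the minimum convex-hull perimeter of
cross-sections sampled at 100 stations over the middle 60% of the shaft.

Per muscle and DOF, the mean/min/max are pooled over the multiset of all
strand-by-angle samples (strands are not averaged per pose first; the
pooled-sample reading of the protocol is adopted and makes multi-strand
summaries directly comparable to single-strand ones). Summed action
columns then add the magnitude of each muscle's mean to the column of the
action its sign names: sums are of magnitudes of means, so within-sweep
sign variation of a muscle collapses before summation — a deliberate,
results-affecting choice that follows the summed-from-mean protocol.
Opposing-action ratios (e.g. protraction/retraction) are positive/negative
sums, with infinite and 0/0 ratios recorded as flagged sentinels.

## Time-scaling and phylogenetic PCA

Fossil trees are time-scaled by basic stratigraphic dating: tips sit at
their first appearance dates (FADs), each internal node at the oldest FAD
among its descendants, and a single rootward post-order pass pushes parent
nodes older until every branch is at least `min_bl` (default 1.0 Myr).
This guarantees an invertible Brownian-motion tree covariance
`C[i,j]` = shared root-to-MRCA path length (built on `ape::vcv.phylo`).

`ppca()` computes the generalized-least-squares phylogenetic mean
`a = (1'C⁻¹1)⁻¹ 1'C⁻¹X` and evolutionary covariance
`R = (X − 1a)' C⁻¹ (X − 1a)/(n − 1)` and eigen-decomposes either the
correlation-standardized `R*` (default `bm-correlation`, scores on
standardized deviations) or `R` itself (`bm-covariance`). Both are
first-class because reference implementations differ in their default;
`uniform-bl` substitutes unit branch lengths (topology-only phylogenetic
correction) and `ordinary` drops the tree entirely (`C = I`, reducing to
prcomp-style PCA). Loading columns are sign-fixed so each column's
largest-magnitude element is positive; eigen ties keep the symmetric
solver's stable order. Traits with zero evolutionary variance make
correlation-mode pPCA undefined and are rejected with an informative
error (the pipeline drops such columns and records them in its manifest).
The suite cross-checks scores, loadings and eigenvalues against
phytools::phyl.pca to 1e-10 and asserts the GLS estimating-equation
identity `1'C⁻¹(X − 1a) = 0`.

## Sensitivity variants and osteometric correlations

Three variant kinds probe robustness of the qualitative patterns:
splayed/tucked humeral adduction (75/115 degrees replacing 90 in the sweep
context), a steeper scapular slope (the scapulocoracoid's rest orientation
rotated about the mediolateral axis anchored at the glenohumeral centre, so
the glenoid — and hence glenohumeral geometry — stays fixed in space; the
pivot is not dictated by the protocol and this choice keeps variants
comparable), and mediolateral translation of the elbow abduction–adduction
centre to 1/3 or 2/3 across the epicondyle-to-epicondyle chord.
`rank_consistency()` compares taxon orderings of summed columns across
variants by Kendall's tau with explicit inversion pairs and min–max
envelope overlap flags; rankings break ties deterministically by taxon
name.

A note on the direction of the elbow-axis effect: geometry fixes each
muscle's |arm| as its path's distance from the axis, so translating the
axis toward one side of the condyle increases the summed arms of the
opposite side's rotation sense. Which *named* column (abduction vs
adduction) rises therefore depends on the declared positive direction of
the floating axis — a data convention. The synthetic elbow used in testing
declares that axis so the lateral-translation effect carries the sign
reported for the fossil models; the underlying monotonicity is
convention-free and is what the test asserts.

Osteometric correlations regress a muscle's mean moment arm on the
planar displacement of its attachment-related landmark from the joint
centre (projected into a declared segment plane and normalized by the same
humeral circumference; projection and normalization commute for a single
scalar). Plain OLS with Pearson r is the primary fit, matching trendline
practice for such plots; a reduced-major-axis slope is available behind a
flag. Exclusion of taxa is always data-driven (a flag plus reason string),
never inferred geometrically.

## The synthetic-data generators

Because fossil-derived model files are large, subjective and not
redistributable, every input class has a generator with known ground
truth; the generators are pure functions of a spec and seed, with one
global seed fanned out to per-component streams by a mixing hash so adding
a generator never perturbs existing fixtures.

`generate_limb()` builds a three-segment limb with randomly oriented
glenohumeral and elbow axis triads and, by default, 23 muscles of which
16/23 are three-strand — the architecture of the study models. Strands
are constructed so closed-form moment arms are known: straight-line
strands (lever formula `r = −u·(a × (q − c))`), coaxial-wrap strands
(planar attachments at twice the radius around a cylinder coaxial with one
DOF axis, giving `|r|` = radius, with attachment angles chosen so the wrap
cannot change state across ±45 degrees of sweep), and exact zeros (strands
that do not cross the measured joint). Oracles hold for single-DOF sweeps
with the other two DOFs of that joint at zero. Random placements whose
strands become infeasible anywhere in the standardized protocols (an
attachment swinging inside an obstacle at 90-degree adduction, say) are
rejected and regenerated, up to 100 attempts.

`simulate_bm_traits()` realizes multivariate Brownian motion by recursive
branch-wise Gaussian increments with covariance (branch length)·Σ;
`generate_action_table()` produces study-shaped 17-taxon, 12-action tables:
a baseline of 1.0 (typical normalized summed magnitudes) plus BM noise at
rate 4e-4 per Myr (tip SD ≈ 0.2 over a ~100 Myr tree) on a time-scaled
birth–death clade, with clade-level mean shifts of configurable effect
size (default 0.5) planted on designated actions, clipped at zero to
respect nonnegativity. These values are the generator's study conditions,
chosen once to give clade structure of the same order as the Brownian
spread.

One subtlety the generator exposed: with clades defined as subtrees, an
exchangeable permutation test of clade centroids is miscalibrated even at
zero planted effect, because shared ancestry alone makes relatives
resemble each other — precisely the signal phylogenetic PCA exists to
discount. The suite therefore checks that zero effect plants no shift
(bit-level) and calibrates the permutation machinery under a genuinely
exchangeable null (star tree, random grouping), rather than asserting a
p-value the model itself violates.

## What the validation does and does not show

The synthetic suite establishes that the kinematics are rigid and exactly
invertible, the wrapping solver matches tangent-arc-tangent closed forms
to 1e-9 and stays continuous at wrap onset, tendon-excursion arms match
independent analytic oracles to better than 1e-4 relative over 50 random
limbs, the excursion–integral identity holds to machine precision, and
pPCA reproduces an independent reference implementation to 1e-10 with
planted evolutionary structure recovered (median PC1 angle well under 10
degrees at 64 tips). It does not validate anatomical realism: synthetic
geometry is abstract, attachments are not anatomical, and no claim about
any real taxon follows from these tests. Reproducing the published
morphospace variance structure requires the study's deposited
summed-moment-arm tables, which the package cannot ship; the acceptance
test documents the expected file layout under `inst/extdata/esm/` and runs
the comparison when those files are supplied.

## Problem sizes

Default validation sizes were chosen as the smallest that exercise each
property convincingly: 50 limbs × ~30 oracle cells for the geometric
suite, 17 taxa × 23 muscles for the end-to-end pipeline, 64 tips × 100
replicates for axis recovery, and 2000 replicates for the Monte-Carlo
covariance law. All are re-derived from the seed at run time; nothing is
precomputed or stored.
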