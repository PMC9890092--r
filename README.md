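# ossomech

Comparative musculoskeletal biomechanics of archosaur forelimbs:
articulated 3D limb models, muscle moment arms by tendon excursion, and
phylogenetic morphospaces of muscle leverage.

Reconstructing how quadrupedality evolved in groups like ornithischian
dinosaurs requires comparing *muscle leverage* — not just bone shape —
across taxa of wildly different body size and build. ossomech implements
that workflow end to end for researchers in vertebrate palaeobiology and
comparative biomechanics:

1. **Articulated models.** Rigid segment hierarchies (scapulocoracoid,
   humerus, antebrachium) with three-axis joint coordinate systems: one
   rotation axis parented to the proximal segment, one to the distal, and
   a floating axis kept mutually perpendicular, all through a fixed joint
   centre. Models are one JSON document per taxon; a least-squares
   circle/sphere fit assists joint-centre estimation.
2. **Muscle paths.** One- or three-strand muscles routed from origin to
   insertion as shortest paths around wrapping cylinders
   (tangent–helical-arc–tangent geometry with analytic lengths).
3. **Moment arms.** The tendon-excursion method: the moment arm about a
   joint angle θ (radians) is

   r = −dL/dθ,

   estimated by central differences of path length L over standardized
   pose sweeps (glenohumeral −40°…+40° protraction at 5°, humerus adducted
   90°; elbow 10°…100° flexion at 5°), normalized by minimum humeral shaft
   circumference C so r/C is a dimensionless, size-free leverage.
4. **Action summaries.** Per-taxon summed magnitudes of mean normalized
   moment arms for the 12 joint actions (protraction, retraction,
   ab/adduction, medial/lateral rotation at shoulder; extension, flexion,
   ab/adduction, medial/lateral rotation at elbow) and opposing-action
   ratios.
5. **Phylogenetic morphospaces.** Trees time-scaled from first appearance
   dates (basic dating, 1.0 Myr minimum branch lengths), then
   phylogenetic PCA under Brownian motion: GLS phylogenetic mean
   a = (1ᵀC⁻¹1)⁻¹1ᵀC⁻¹X, evolutionary covariance
   R = (X−1a)ᵀC⁻¹(X−1a)/(n−1), eigen-decomposition of R or its
   correlation, with uniform-branch-length and ordinary-PCA variants.
6. **Sensitivity & osteometrics.** Splayed/tucked (75°/115°) adduction,
   steeper (70°) scapular slope and elbow-axis translation variants with
   Kendall-tau rank-consistency reports; OLS correlation of moment arms
   against planar osteological landmark displacements.
7. **Synthetic data.** Generators for limb models with closed-form
   moment-arm oracles, Brownian trait tables on known time-scaled trees,
   and study-shaped 17-taxon action tables — the whole pipeline is
   testable with no external downloads.

## Worked example

Generate a synthetic limb, sweep a muscle's glenohumeral
protraction–retraction moment arm over the standardized poses, and pool:

```r
library(ossomech)
g  <- generate_limb(synthetic_limb_spec(seed = 42, n_muscles = 4))
sw <- sweep_moment_arms(g$model, "SYN01", "glenohumeral", "protraction",
                        paper_glenohumeral_grid(g$model))
head(sw[, c("muscle", "strand", "angle_deg", "length_m", "r_raw_m", "r_norm")], 4)
#>   muscle    strand angle_deg   length_m     r_raw_m      r_norm
#> 1  SYN01 posterior       -40 0.09957271 -0.01565647 -0.13047062
#> 2  SYN01 posterior       -35 0.10093899 -0.01465053 -0.12208772
#> 3  SYN01 posterior       -30 0.10212971 -0.01262236 -0.10518630
#> 4  SYN01 posterior       -25 0.10314201 -0.01056420 -0.08803498
aggregate_sweep(sw)
#>   muscle        joint         dof       mean        min       max n_samples n_infeasible
#> 1  SYN01 glenohumeral protraction -0.3281083 -0.9529332 0.1890827        51            0
```

`r_norm` is the moment arm divided by the minimum humeral shaft
circumference: at −40° this muscle's posterior strand has a retraction
(negative) leverage of 0.13 circumference units; the pooled mean over all
three strands × 17 poses is −0.33, so the muscle is a net retractor and
contributes |−0.33| to the taxon's summed retraction column.

Phylogenetic PCA on a study-shaped synthetic action table with planted
clade structure on three shoulder actions:

```r
out <- generate_action_table(seed = 42)   # 17 taxa x 12 actions + time-scaled tree
X   <- as.matrix(`rownames<-`(out$table[, -1], out$table$taxon))
res <- ppca(X, out$tree, mode = "bm-correlation")
res
#> <ppca_result> mode: bm-correlation
#>  variance proportions: 26.7% 17.4% 12.1% 11.3% 9.3% 7.5% 5.6% 4.2% 2.5% 2.3% 0.9% 0.2%
round(res$loadings[out$shift_actions, 1], 3)
#>       gh_adduction gh_medial_rotation     gh_protraction
#>              0.511              0.446              0.493
```

The three planted actions dominate the PC1 loadings, i.e. the first axis
of the evolutionary correlation matrix recovers the clade-level leverage
differences the generator injected.

`run_pipeline(list(n_taxa = 17, seed = 1, out_dir = "run"))` chains all
stages — models → sweeps → summed action table → time-scaled tree →
pPCA/uniform-branch-length/ordinary morphospaces — and writes CSV outputs
plus a hash-indexed `manifest.json`.

## Package layout

- `R/` — kinematics, wrapping, moment arms, summaries, phylogenetics,
  osteometrics, sensitivity, synthetic generators, pipeline.
- `tests/testthat/` — oracle-based unit and property tests (all fixtures
  generated in code).
- `vignettes/ossomech-methods.Rmd` — models, assumptions, numerical
  choices and limitations.
- `scripts/acceptance.R` — headline-quantity reproduction script.
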