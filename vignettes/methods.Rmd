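---
title: "Methods: phylogenetic morphospace analysis and rate decoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic morphospace analysis and rate decoupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `morphorates`, the
choices that were genuinely open when the package was designed, and the
limits of what its synthetic-data tests demonstrate.

## The data model

The unit of analysis is a specimen × trait table of linear body
measurements in millimetres — by default the 20-trait chafer panel
(`chafer_traits()`): body/elytral heights, lengths and widths, pronotal
dimensions, head and eye measures, and leg segments including metacoxal
length (MCL) — together with a rooted phylogeny whose tips are the
specimens. Tables carry an explicit transform state (`raw_mm`, `log10`,
`size_corrected_bbpm`, `size_corrected_regression`) so that stages cannot
be chained out of order. Measurements are log10-transformed first: linear
distances then combine additively, and all traits acquire a comparable
scale of variance.

## Size correction

Linear morphometrics of whole organisms are dominated by size. Two
removals are implemented and always run side by side:

* **Burnaby back projection (BBPM).** On the log scale, pure isometric
  growth moves every trait by the same amount, i.e. along
  `a = (1,…,1)/√p`. Each row is projected onto the orthogonal complement,
  `x ← x(I − aaᵀ)`, staying in the original trait coordinates. Because `a`
  is unit-normalized the Burnaby operator reduces to this one-line form,
  which is idempotent and annihilates any isometric row exactly — both are
  tested identities. Rows of the output satisfy `|Σⱼ xⱼ| < 1e-10`.
* **Regression residuals.** Each log trait is replaced by the residuals of
  its OLS regression (with intercept) on the size proxy
  `log10(PL + EL)` computed on the mm scale. The proxy uses the summed
  pronotal and elytral lengths rather than total body length, which is
  unreliable in specimens with a mobile prothorax. Base 10 was chosen for
  the proxy logarithm for consistency with the trait transform; any base
  gives identical residuals up to the regression's rescaling.

Corrected columns are deliberately **not** re-centered: both corrections
stay purely linear operators, and the PCA downstream centers internally.
The *impact of size* is defined as the PC1 variance fraction of the
uncorrected log table.

## Ordination and phylomorphospace

PCA is covariance-based, not correlation-based: the log transform already
homogenizes trait variances, and rescaling to unit variance would undo the
size-dominance structure the analysis is about. (This was an open choice —
correlation PCA is one flag away in principle — and covariance is fixed as
the package default.) Components are sign-normalized so the
largest-magnitude loading of each component is positive, making score
tables reproducible. Group tests use the smallest leading set of components
reaching 95% cumulative variance, discarding measurement noise.

Ancestral positions for the phylomorphospace are Brownian-motion maximum
likelihood estimates (computed with `phytools::fastAnc`, i.e. the GLS
phylogenetic mean of the tree re-rooted at each node); the test suite
verifies them against an independent dense GLS solve. Estimates are
shift-equivariant and reduce to the precision-weighted mean on a cherry.

## Permutation group tests

PERMANOVA is the one-factor Euclidean form: with `SS_total` the sum of all
squared pairwise distances over `N`, and `SS_within` the within-group
analogue over group sizes, `pseudo-F = (SS_B/(g−1))/(SS_W/(N−g))`.
Significance comes from random relabelings with the `(hits+1)/(B+1)`
convention, so p is never 0 and never below `1/(B+1)`; an exact mode
enumerates all distinct relabelings for small samples and is checked
against brute-force enumeration. The default `B = 9999` is a package
choice (the permutation count behind the original tables is not recorded
anywhere); all counts are configurable. Pairwise tests apply Holm's
step-down to the full vector of raw p-values and report raw and corrected
significance flags separately. Per-pair permutation streams are hashed
from the master seed and the pair name, so pairwise results do not depend
on the order in which pairs are run.

Groups with fewer than two members cannot contribute a within-group sum
and are rejected by name; the pipeline driver excludes such singleton
lineages from PERMANOVA and LDA with a logged notice and keeps them in the
ordination.

LDA reassignment uses `MASS::lda` with leave-one-out cross-validation.
Priors default to training-fold group proportions (the convention of that
implementation); an equal-priors mode is available by flag. The retained
component count must stay below `N − g`; the driver truncates and logs
when necessary.

## Phylogenetic signal

**Blomberg's K** is implemented from its definition: with `V` the BM
covariance implied by the tree and `â` the GLS mean,
`K = (MSE₀/MSE) / ((tr V − n/(1ᵀV⁻¹1))/(n−1))`. `K = 1` under BM —
exactly 1 on an equal-branch star tree, which is a frozen test identity —
and `K > 1` when relatives resemble each other more than BM predicts.
The permutation p shuffles trait values across tips and counts
permutations with `MSE ≤` observed (ties count as extreme), +1 convention,
default 999 permutations. Polytomies are tolerated (the covariance stays
nonsingular); zero-length branches are nudged to `1e-8` of tree height.

The **subsampling sensitivity** analysis prunes a focal, species-rich
clade to a ladder of target sizes (all other tips kept), recomputes K for
every trait, and tracks the focal trait's rank. It answers whether a high
K merely reflects dense sampling of one lineage.

**PGLS** regresses each retained component on dummy-coded feeding types
(alphabetical reference level — the coding is a package choice) under
`V(λ)`: off-diagonal BM covariances scaled by Pagel's λ, diagonal
untouched; κ and δ are fixed at 1. λ is estimated by ML on a 101-point
grid over [0, 1] with local refinement — bounded and reproducible; values
above 1 are not extrapolated. The fit reports per-component adjusted r²
(computed in the whitened space against the GLS intercept-only null at the
same λ) and a pooled summary: the variance-fraction-weighted mean adjusted
r² across components. How to pool several component-wise regressions into
one number is genuinely underdetermined; the eigenvalue weighting is this
package's labeled choice and the per-component values are always reported
alongside.

**Mantel tests** correlate strict lower triangles (Pearson), permuting
rows and columns of the second matrix jointly; p is one-sided (greater),
matching the directional hypothesis that morphological divergence grows
with molecular divergence; 10,000 permutations by default. Within-feeding
analyses use the patristic submatrix against the Euclidean submatrix of
size-corrected traits, skipping types with fewer than 3 members (one pair
of distances is not a correlation) with a logged notice.

## Rate decoupling

Morphometric branch lengths are fitted on the fixed molecular topology by
ordinary (unweighted) least squares: `min ‖Ab − d‖²` with `A` the
path-incidence matrix and `d` the vectorized Euclidean distances, solved
with the SVD pseudo-inverse. On a rooted tree the two root-child edges are
linearly confounded — only their sum enters any tip-to-tip distance — so
the solution there is the minimum-norm split and the fit is flagged
`rank_deficient`; all other edges are identifiable, and the fit reproduces
additive inputs exactly. Negative estimates are clamped to zero once,
after the global solve; an iterative non-negative refit is deliberately
not performed (the clamping convention is the minimal reading of "negative
branches set to zero", and the unclamped solution is also returned).

Ratios are computed as morphological/molecular length per branch
(the report carries both lengths, so the inverse is recoverable); branches
with zero molecular length get an undefined ratio, are reported, and never
flagged. The "central 95%" screen is the empirical 2.5–97.5 percentile
interval of the ratios, applied separately to internal branches and tips
(their lengths differ systematically); a `mean ± 1.96·SD` alternative sits
behind a flag. How the original interval was constructed is not recorded;
the percentile reading is the minimal one and flags ≈2.5% per tail by
construction under a unimodal null, which the calibration tests confirm.
Classes with fewer than 20 defined ratios are skipped — their percentiles
would be noise.

Independent contrasts use Felsenstein's pruning recursion; multivariate
rates are the per-node Euclidean norm of the standardized contrasts across
all traits, with the ultrametric tree rescaled to root age 1 so rates are
per unit relative time. Contrasts require a binary tree; polytomies are
resolved into near-zero-length binary branches at call time (how the
original analyses handled unresolved nodes is unknown; this resolution is
the package's choice and is documented per function).

## The synthetic-data generator

`simulate_dataset()` produces the study conditions every test runs under:

* a pure-birth (Yule) tree conditioned on `n_tips` (default 182,
  the study's specimen count), rescaled to root age 1 — extinction
  structure is never used by the analyses, so birth–death generality was
  not worth the extra knobs;
* per-tip log10 traits = baseline + shared size factor + multivariate
  shape deviation. Size is a single Brownian factor loading equally on all
  traits (`size_sd = 0.35` at root age 1), making the BBPM target exactly
  removable — this isometry is the property the correction exploits. Shape
  is multivariate BM (default diagonal rate 0.011 per trait). These two
  defaults were calibrated once so that PC1 of the uncorrected data
  explains roughly 82–90% of variance at the default conditions, the
  size-dominance regime the analysis design assumes, and were then frozen;
* clade rate shifts multiply the shape rate matrix inside a crown clade
  (default: ×3 in the focal clade); the focal shift adds a one-off jump to
  one trait on the clade's stem branch (default: +0.5 log10 units on MCL).
  The offset default was calibrated to reproduce the magnitude of
  phylogenetic signal the study design targets for its focal trait
  (K ≈ 3.2 at the default conditions) and then frozen;
* measurement error: additive on the log scale, per repeat
  (`sd = 0.01` ≈ 2.3% per measurement), averaged over `n_repeats = 5`
  replicates before back-transforming to mm. The real protocol averaged
  raw mm values; at these error levels the difference between averaging on
  the raw and log scales is far below test tolerances, and no error model
  for the repeats was ever published — the log-additive form is a labeled
  stand-in;
* a "molecular" tree obtained by multiplying each branch by an independent
  log-normal factor (`sd = 0.3`), decoupling molecular rates from time
  while preserving topology;
* lineage groups = disjoint clades picked greedily (largest first, capped
  at 40% of tips), and feeding types (ANT/COP/HERB/SFU/NF/SAP) assigned
  per clade, with a `convergent_fraction` (default 0.15) of tips relabeled
  uniformly at random — at 1 the labels are independent of the clades,
  emulating full convergence;
* baseline trait values are plausible chafer dimensions in mm; they are
  synthetic stand-ins, since the original specimen means are unavailable.

What the generator does **not** emulate: real allometry (size enters
isometrically by design), trait-specific measurement protocols,
non-Brownian processes beyond the rate-shift and jump mechanisms (no OU
attraction, no early bursts), fossil or biogeographic structure, and
intraspecific sampling. Passing tests therefore show the pipeline's
statistics are correct and calibrated under their own assumptions — not
that those assumptions hold for any particular empirical data set.

## Numerical conventions and test scales

* Ultrametricity tolerance: relative tip-depth spread below `1e-6`
  (Newick round-trips at double precision stay far inside this).
* Permutation p-values: `(hits + 1)/(B + 1)`; ties count as extreme
  (`≥ observed − 1e-12`).
* Zero-length branches in contrast-based methods: `1e-8` × tree height.
* Degenerate inputs error early with the offending name: non-positive
  raw measurements, constant tables, singleton groups, single feeding
  levels, constant off-diagonal distances, unknown tip labels.
* The stochastic test suites use 100–200-tip trees with 200 replicates for
  the Brownian calibration of K and contrast variances, 600 null data sets
  for type-I error of PERMANOVA and Mantel, and 21–30 replicates for the
  λ-recovery, rate-shift and focal-trait recovery experiments; the
  determinism check runs the full 60-tip pipeline twice. These sizes give
  each check a comfortable margin relative to its tolerance while keeping
  the default suite quick.

## Known limitations

* PERMANOVA is the one-factor Euclidean form only; no dispersion
  (PERMDISP) companion test, so location and dispersion effects are
  confounded as in any plain PERMANOVA.
* PGLS pools multiple response components by weighted averaging of
  adjusted r² rather than by a genuine multivariate GLS.
* The rate screen is descriptive: percentile flags are not a model-based
  test of rate shifts, and the 5% flag rate is by construction, not an
  error rate.
* Least-squares branch fitting cannot separate the two root-child edges of
  a rooted topology (their sum is reported via the minimum-norm split).
* Blomberg's K is univariate; a multivariate K is not provided.
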