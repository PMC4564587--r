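---
title: "Methods: morphology-genetics concordance across cranial ontogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphology-genetics concordance across cranial ontogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontocrania)
```

## The question and the data model

Human populations differ subtly in the shape of the cranial base. If those
differences accumulate mainly by neutral processes, distances between
population mean shapes should mirror neutral genetic distances — and the
ontogenetic stage at which the mirroring appears says when
population-specific shape is established during growth. The package
operationalizes this as a chain of standard, individually testable steps:
landmark superimposition, shape ordination, population distance matrices,
genetic distance matrices, and matrix correlation.

A specimen is a `landmark_config`: K ordered, named 3D points (mm) with a
population label and an ontogenetic age category. The bundled 44-landmark
basicranial scheme is subdivided into overlapping occipital (13), temporal
(24) and sphenoid (12) regions; sutural points shared by adjacent bones
belong to more than one region, so the regions overlap exactly at
landmarks {1, 2, 13, 33, 36}. Subadult age categories AC1–AC3 are defined
by molar eruption and arrive as labels; regressions need numbers, so
categories are coded at their rough chronological midpoints (2.5, 8.5,
15.5 years). Adults' ages cannot be estimated from eruption; they are
coded 21 by default, and both codings are configurable (`age_years()`)
because any choice here is a convention, not a measurement.

Specimens missing any landmark of a region are excluded from that region's
analyses (`filter_complete()`), never imputed — incomplete subadult crania
are the norm in osteological collections and imputation would manufacture
shape where there is none. Removal counts per population × age category
are logged.

## Superimposition

`gpa()` implements Generalized Procrustes Analysis in the
partial-Procrustes convention: every configuration is centered, scaled to
unit centroid size, and rotated to the evolving consensus; the consensus
is the normalized mean of the aligned coordinates. Iteration stops when
the root-summed-squared change of the consensus drops below 1e-10 (far
below any digitizing noise) or at 100 iterations, with a `converged`
flag. The consensus is initialized from the first specimen — a
deterministic choice whose irrelevance is verified by an order-invariance
property test. Rotations are constrained to determinant +1: a reflection
would flip left and right anatomy, which is never legitimate for
bilateral structures, so mirror-image solutions are rejected even when
they fit better. Configurations with collinear landmarks or zero centroid
size are rejected before iteration with an error naming the degeneracy.

`procrustes_distance()` is the root-summed-squared landmark difference
after full optimal superimposition of one unit-size shape onto the other.
On this representation it is a metric (symmetry, identity and the
triangle inequality are property-tested on random shapes). Distances are
computed in the Procrustes representation itself, without a prior tangent
projection; an orthogonal tangent projection is available in the PCA step
where linearization actually matters.

Digitizing repeatability (`repeatability_test()`) superimposes repeated
digitizations of one specimen jointly, computes each trial's RMS residual
from the consensus, and compares trial sets with a paired t-test.

## Ordination and growth

`fit_pca()` performs PCA of the flattened aligned coordinates about their
mean. After a similarity superimposition at most min(n−1, 3K−7)
dimensions carry variance; components beyond that are dropped. The
default covariance is taken on the Procrustes residuals directly, which
is the common practice in morphometric software; a strict orthogonal
tangent projection (removing the component along the consensus direction)
is a switch, not the default, and the two differ negligibly at the shape
variances involved here. Score space is verified to be an isometric image
of aligned shape space.

`regress_pc()` fits ordinary least squares of one component's scores on
numeric age (ontogeny) or log centroid size (allometry), pooled or within
one population, reporting Pearson r, a two-sided p, slope and intercept.
Scopes with fewer than three specimens are flagged rather than tested.
`significant_pc_table()` assembles the per-region, per-population summary
of which components associate with age and size at alpha = 0.05, the
layout used to compare ontogenetic signal across cranial regions.
Components explaining more than 5% of variance (`major_pcs()`) are the
ones worth visualizing; `morph_along_pc()` deforms the consensus along a
component and `export_wireframe()` writes OBJ-style vertex/edge text.

## Population structure from shape

`population_distance_matrix()` computes per-population means of the
aligned coordinates, re-normalizes them to unit centroid size (so that
between-mean distances remain in shape space), and takes pairwise
Procrustes distances. Significance (`pairwise_permutation_test()`) pools
each pair of groups, shuffles labels preserving group sizes, and
recomputes the between-mean distance; p = (1 + #{permuted ≥ observed}) /
(1 + n_perm), the standard one-sided add-one convention, 1000 replicates
by default, fully reproducible given the seed.

`lda_loocv()` classifies specimens into populations from PC scores with a
pooled-covariance linear discriminant, evaluated by leave-one-out
cross-validation (the discriminant behind each held-out prediction is fit
without that specimen; the fit is delegated to MASS). By default the
scores entering the classifier cover 95% cumulative variance, capped at
n − g − 1 columns; near-constant columns are screened out. One leakage
caveat is inherent to the design and documented rather than hidden: the
PC basis itself is computed once on the full sample, as when a
discriminant analysis consumes precomputed PC scores, so LOOCV removes
the specimen from the classifier but not from the basis. Groups of one
specimen cannot be left out and refit and are excluded with a warning.

## Genetic distances

`pairwise_fst()` estimates multilocus pairwise differentiation from
diploid STR genotype tables as the ratio of summed variance components,
θ = Σa / Σ(a+b+c), with the among-population (a), among-individual (b)
and within-individual (c) components computed per locus and per allele
from the Weir–Cockerham formulas; `estimator = "rst_allele_size"` runs
the same nested analysis of variance on allele repeat sizes (the
microsatellite R_ST convention, which weights alleles by mutational
distance under stepwise mutation). The two estimators coincide on
two-allele loci recoded to equidistant sizes, which is property-tested.
Negative per-locus components are retained in the sums; only the final
multilocus ratio is floored at zero, and the raw value is kept alongside.
Missing genotypes are dropped per locus per individual (pairwise
deletion); a population pair sharing no adequately typed locus is an
error, not a silent zero. `slatkin_linearize()` applies D = F/(1−F)
entrywise, the drift-proportional linearization.

Whether the published molecular matrix contains raw θ or linearized
values is ambiguous in its source; the package therefore treats the
matrix as printed and makes the linearized variant one flag away, with
`mantel_report()` always computing both.

## Concordance

`mantel_test()` correlates the n(n−1)/2 off-diagonal pairs of two labeled
distance matrices (Pearson, on raw distances) and builds the null by
relabeling one matrix. For n ≤ 8 the null is the exact enumeration of all
n! relabelings — 5040 statistics for seven populations, 720 for six — so
printed-table checks are fully deterministic; larger problems fall back
to Monte-Carlo with the add-one correction. Matrices are reconciled by
label, never by position. The default reported tail is upper (large
positive correlation = concordance), but both tails are always computed
and stored, because published Mantel p-values do not always follow one
convention — the bundled tables include a negative correlation printed
with a very small p, which is incompatible with an upper-tail reading.
`exclusion_scan()` repeats the test dropping each population in turn, the
sensitivity analysis that reveals single-population leverage.

On the bundled published matrices, the combined-subadult basicranial
correlation reproduces the published value to rounding; the per-age-
category and Egypt-excluded published values do not follow from the
printed matrices under any convention the package computes (either tail,
raw or linearized molecular distances — `analysis/01` prints the full
grid). The package's stance is to report the recomputed values with their
exact nulls and document the disagreement, not to tune toward the printed
numbers.

## The synthetic generator

`synthetic_config()` fixes the study conditions: seven populations with
the published F_ST matrix as the genetic target; subadult cell counts
matching the published sampling design (48 AC1 + 51 AC2 + 85 AC3 = 184
subadults), plus 10 adults per population (the adult column is the
package's own choice of a realistic museum-series size; the published
table's adult counts were not available); 50 STR loci at fixture scale
(the original compendium has hundreds; 50 keeps runs fast while leaving
multilocus averaging realistic); and a mandatory seed — the generator has
no implicit entropy, and identical seeds give identical data.

**Genotypes.** Each locus draws an ancestral allele-size spectrum (4–8
alleles on stepwise repeat sizes 8–30, Dirichlet frequencies). Population
frequencies then drift jointly in the chord (square-root) geometry of the
simplex: deviations are Gaussian on the sphere representation with
between-population covariance equal to the Gram matrix obtained by double
centering twice the target matrix, so the expected pairwise θ between any
two populations equals the corresponding target entry — including
non-additive targets that no independent-drift or tree model can
represent. Squaring back to the simplex keeps frequencies valid without
truncation; the residual nonlinear shrinkage of realized divergence is
removed by an internal fixed-point calibration (three iterations on
frequency-level simulations, before any genotype is sampled). Realized
F_ST is then recomputed from the sampled genotypes with the package's own
estimator and returned as truth; across 10 seeds the per-pair median
error against the published target stays within about 0.01.

**Landmarks.** Population mean-shape offsets are built by classical
scaling of the genetic matrix into at most n_pop − 1 dimensions and
mapped into shape space along fixed directions orthogonal to the
translation/scale/rotation subspace — offsets with components along those
directions would be absorbed by superimposition, so orthogonality is what
makes the planted distances recoverable. The concordance dial c blends
the genetic embedding with random offsets, u(c) = c·u_genetic +
(1−c)·u_random; the random offsets share one common norm (the RMS of the
genetic offsets) rather than matching norms population by population,
because per-population matching would leak the genetic norm structure
into the supposedly null c = 0 case. Each specimen is the unit-size
template plus its population offset, a shared allometric deformation
linear in numeric age, and isotropic Gaussian coordinate noise; raw
digitization is mimicked by a random rotation, translation, and an
age-dependent centroid size with lognormal individual jitter. The
template itself is a deterministic, stylized 44-point configuration at
skull-base scale, derived from no specimen.

Defaults worth knowing (units in parentheses): `between_pop_scale = 1`
(dimensionless; at 1 the planted between-population shape distances are
on the scale of the genetic target entries, 0.04–0.15, which is also the
range of the published subadult morphological matrices);
`noise_sd = 0.01` (unit-shape coordinates; chosen so within-population
dispersion exceeds between-population separation, the regime in which
classification rates are informative rather than saturated — no
within-population shape variance is published, so this is an
artifact-internal calibration); `allometry_per_year = 0.004` (shape units
per year, giving an AC1-to-adult shape shift comparable to the planted
population offsets); centroid-size growth factors 0.72/0.85/0.95/1.0
across AC1/AC2/AC3/adult with 3% lognormal individual scatter.

What the generator does *not* emulate, and hence what passing tests do
not show about real data: anisotropic and landmark-specific digitizing
error, nonlinear growth trajectories and population-specific allometry,
non-random missingness of fragile landmarks, linkage and mutation-model
realism in the STRs, and any non-neutral component of shape divergence.
The generator validates the machinery, not the biology.

## The pipeline

`run_pipeline()` runs, for each cranial region and each age grouping
(combined subadults, AC1, AC2, AC3): region subsetting and completeness
filtering, GPA, PCA, the population distance matrix with permutation
p-values, LOOCV classification, and the age/size regression summary;
genotypes yield the molecular matrix, and each regional matrix is tested
against it with a Mantel test plus exclusion scan. Adults enter
superimposition and PCA but not the group comparisons. Every table is
written as plain text with a manifest and a run log of specimen
exclusions. The four numbered scripts under `analysis/` are thin
narrative drivers over these functions; there is no separate command-line
tool because the functions and scripts are the interface.

## Numerical choices and problem sizes

Convergence: GPA tolerance 1e-10, cap 100 iterations. Exact Mantel
enumeration whenever n! ≤ 50,000 (n ≤ 8). Permutation defaults: 1000
replicates for distance significance, 9999 for Monte-Carlo Mantel, both
with add-one correction; exact enumeration has no correction since the
identity permutation is in the set. LDA posterior ties are resolved by
the first label in sorted order. Distance-matrix symmetry tolerance 1e-9;
asymmetric inputs are errors, not silently symmetrized beyond that
tolerance.

The validation suite runs at deliberately moderate sizes chosen to keep
the full suite comfortably fast while leaving Monte-Carlo error well
inside the asserted bands: type-I calibrations use 400–500 null
simulations at 99–199 permutations each; F_ST recovery uses 10 generator
seeds; concordance recovery uses 5 seeds at c = 1 (low noise, 0.002) and
20 at c = 0; the full-design pipeline run uses the study-sized 184
subadults with 1000 permutation replicates.

## Known limitations

- The published per-age-category concordance values are not reproducible
  from the published matrices (see above); the package documents rather
  than resolves this.
- LOOCV classification inherits the fixed-PCA-basis leakage described
  above; rates are therefore mildly optimistic, as in any analysis that
  cross-validates on precomputed scores.
- Procrustes distances are computed without tangent projection; at the
  shape distances involved (≤ 0.19) the difference is far below the
  rounding of the published matrices.
- The R_ST estimator assumes the strict stepwise mutation model's
  size-distance proportionality; for loci with complex repeat structure
  the allele-size weighting is only an approximation.
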