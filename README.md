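# ontocrania

Does the shape of the human cranial base track neutral genetic distances
among populations, and from how early in development? `ontocrania` is an R
package and analysis workflow for answering that question with 3D landmark
data and microsatellite genotypes. It covers the full chain from raw
digitized coordinates to the concordance verdict:

- **Superimposition** — Generalized Procrustes Analysis (GPA) of K×3
  landmark configurations (partial-Procrustes convention: translation,
  unit-centroid-size scaling, rotation without reflection), centroid size,
  and Procrustes distances d(X₁, X₂) = √Σᵢ‖x₁ᵢ − x₂ᵢ‖² between optimally
  superimposed unit-size shapes.
- **Tangent-space ordination** — PCA of aligned coordinates, regressions of
  PC scores on numeric age (ontogeny) and log centroid size (allometry),
  and wireframe morphs along components.
- **Group structure** — pairwise population Procrustes distance matrices
  with label-permutation significance, and linear discriminant
  classification of specimens from PC scores under leave-one-out
  cross-validation.
- **Population genetics** — multilocus Weir–Cockerham θ (and the
  allele-size analogue R_ST) from diploid STR genotype tables,
  θ = Σa / Σ(a+b+c) over loci and alleles, with Slatkin linearization
  D = F/(1−F).
- **Concordance** — Mantel correlation between morphological and molecular
  distance matrices with an *exact* permutation null (all n! relabelings
  for n ≤ 8, e.g. 5040 permutations for seven populations), both tail
  conventions, and a population-exclusion sensitivity scan.
- **Synthetic truth** — a seeded generator that emulates the study design
  (seven populations, ontogenetic series over three subadult age
  categories plus adults, STR loci drifted to a target F_ST matrix, and
  population mean-shape offsets embedding the genetic distances with a
  tunable concordance dial), so every stage can be validated against known
  truth.

The bundled fixtures include the published seven-population molecular F_ST
matrix and the published basicranial Procrustes distance matrices
(combined subadults, AC1, AC2, AC3), so the headline concordance analysis
is reproducible without any specimen data.

## Worked example

```r
library(ontocrania)

fx <- printed_distance_fixtures()          # published distance matrices
res <- mantel_test(fx$subadults, fx$fst)   # basicranium vs molecular
res
#> <mantel_result> r = 0.4697, p(upper) = 0.0504  [exact_enumeration, 5040 permutations, n = 7]

exclusion_scan(fx$subadults, fx$fst)[1:3, c("excluded", "n", "r", "p")]
#>   excluded n         r          p
#> 1     none 7 0.4696871 0.05039683
#> 2   Alaska 6 0.4318132 0.07222222
#> 3  Austria 6 0.3498344 0.16527778
```

The combined-subadult basicranial shape distances correlate with the STR
F_ST matrix at r ≈ 0.47 (published: 0.48), with a fully deterministic
exact-enumeration p-value; the scan shows how the correlation shifts as
single populations are dropped (excluding Egypt raises it to r = 0.61).

A synthetic end-to-end run with known truth:

```r
cfg <- synthetic_config(seed = 1)          # study-design defaults
sim <- simulate_study(cfg)                 # genotypes + landmark series
fit <- gpa(Filter(function(cf) cf$age_category != "ADULT", sim$configs))
mantel_test(population_distance_matrix(fit), sim$truth$genetic)$r
#> [1] 0.9897094
```

With the concordance dial at its default of 1, the recovered
morphology–genetics correlation is near 1; at `concordance = 0` it centers
on 0. The numbered scripts under `analysis/` run the complete workflow
(published-table concordance, simulation, full regional pipeline,
generator validation) and write their tables under `results/`.

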