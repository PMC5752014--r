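---
title: "Integrative species delimitation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative species delimitation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(integrotax)
```

This vignette documents the statistical machinery of `integrotax`, the
choices made where a design was genuinely open, and what the package's
synthetic validation does and does not establish about real data.

## The problem

Species boundaries in morphologically conservative radiations resist
any single data source: morphometric clouds overlap, barcodes lack a
gap when divergence is recent, and distribution alone cannot separate
sympatric look-alikes. The workflow implemented here treats four
sources — morphometry, DNA barcodes, a phylogeny, and georeferenced
occurrences — first separately and then jointly through a multi-table
ordination, with a range-evolution model to reconstruct the
biogeographic history afterwards.

## Morphometrics and the between-group analysis

Specimens below 20 mm standard length (SL) are removed before analysis
(`filter_juveniles`, cutoff configurable in mm): very small juveniles
distort allometric relationships. Missing cells — broken fin rays and
the like — are imputed per (population, variable) by least squares on
SL (`impute_missing`); the procedure deliberately has no fallback when
a population has fewer than two observed values, because silently
borrowing strength across populations would bias the group structure
the analysis is meant to test. Imputed meristic values are snapped back
to the half-integer counting grid, consistent with counts made to the
nearest half plate.

`standardize` forms log(value/SL) for body measurements and
log(value/HL) for head measurements when an HL denominator is declared
(the two-denominator convention of standard morphometric tables),
retains log(SL) itself as a variable, leaves meristic counts raw, and
centers/reduces every column. Two conventions matter downstream and are
fixed here once:

* natural logarithms (any base only rescales columns and is undone by
  the reduction; the `log_base` argument exists for reporting);
* population (1/n) variances, so that the correlation-PCA total
  inertia equals the number of columns exactly.

The between-group analysis (`bga`) eigen-analyses the size-weighted
population-mean matrix. Its headline number is the ratio of
between-group to total inertia, in [0, 1]; significance comes from a
Monte-Carlo permutation of group labels with the add-one estimator
p = (#{permuted ≥ observed} + 1)/(n_perm + 1), so the smallest
attainable p at 9,999 permutations is 0.0001. Ties count against
rejection (the `≥` is deliberate and conservative).

## Barcoding

`k2p` implements the two-parameter distance with *pairwise deletion*:
a site is used only when both sequences carry an unambiguous A/C/G/T.
Ambiguity codes never partially match — R against A is deleted, not
half-counted. When the log argument is nonpositive (saturation) or no
sites remain, the distance is undefined and propagates as `NA`,
excluded from summaries with a warning count.

The gap analysis is per individual: the furthest conspecific distance
against the closest heterospecific one; a nonpositive difference means
that individual cannot be identified by its barcode alone. Threshold
optimization scans a grid (default 0.001–0.10 step 0.001, mirroring
common practice of reporting thresholds to three decimals) and
classifies every individual by its neighborhood at each candidate
threshold: individuals with no conspecific in the data are true
negatives when isolated and false positives otherwise; individuals with
conspecifics are false negatives when isolated, true positives when all
neighbors are conspecific, false positives otherwise. All minimizers of
the cumulative error are reported, smallest first.

## Ordinations

`pcoa` double-centers −½D² and eigen-decomposes. For non-Euclidean
dissimilarities (patristic and geographic matrices usually are not
Euclidean), the Cailliez correction computes the *smallest* constant c
— the largest eigenvalue of the standard 2n×2n companion matrix — to
add to every off-diagonal dissimilarity; after correction the row
scores reproduce D + c exactly, which the test suite verifies to 1e−6
on random instances along with the minimality of c. Residual negative
eigenvalues below tolerance are truncated, and axes are reported up to
rank n−1. Axis signs are fixed by making the first nonzero element of
each axis positive, so results are reproducible across linear-algebra
backends.

Geographic distances are haversine distances on a sphere of mean
radius 6,371,008.8 m. An ellipsoidal geodesic would differ by under
0.6%, which is immaterial for an ordination of basin-scale distances;
the sphere keeps the operation dependency-light and exactly testable
against closed forms.

## RV tests and multiple co-inertia

The RV coefficient compares two object configurations,
tr(XXᵀYYᵀ)/√(tr((XXᵀ)²)·tr((YYᵀ)²)); its permutation test permutes the
rows of one table. MCOA extracts, axis by axis, a unit-variance
compromise variable v maximizing Σₖ wₖ Cov²(Xₖuₖ, v) over unit
loadings uₖ; v is the leading eigenvector of Σₖ wₖ XₖXₖᵀ. Before each
further axis every table is deflated by regression of its columns on
its own previous scores (within-table orthogonality), and the summed
operator is additionally projected onto the complement of the previous
compromise axes so the compromise system is orthonormal. With a single
table the procedure collapses exactly to that table's PCA — a useful
end-to-end identity the tests exploit.

Two open choices were fixed as follows. Table weighting defaults to
uniform, but `run_integrative` scales every table to unit total inertia
before the MCOA, so the Inertia / Co-Inertia / Cos² / Cov² blocks of
its report read as comparable shares (this matches the convention in
which a rank-2 geographic table shows its full inertia on two axes).
And because the morphometric table enters with within-population
variability removed (population means), while the other tables are at
individual level, the mean rows are replicated back to the individuals
of each population — replication keeps the three tables row-conformable
without inventing within-population morphometric variation.

## Range evolution: DEC and DEC+j

The state space is every nonempty subset of the declared areas up to a
size cap (4 in eleven-area analyses, giving 561 states), plus an
absorbing null range kept in the CTMC but excluded from tip
observations and from the root prior. Anagenetic rates: each occupied
area contributes e to contraction, and expansion into any outside area
proceeds at |range|·d with uniform area adjacency (no basin-distance
matrix is assumed). At nodes, cladogenesis follows the
sympatry/subset/vicariance/jump scheme with per-pair weights
(3 − j)/3 for the three classical event types and j for jumps,
normalized over all allowed ordered daughter pairs; j = 0 recovers
plain DEC. The root prior is uniform over non-null states.

The likelihood is Felsenstein pruning with per-branch exp(Qt). The
matrix exponential uses one eigendecomposition of Q reused across
branch lengths, validated by a row-sum check and falling back to
scaling-and-squaring when ill-conditioned; per-node rescaling guards
against underflow. Fitting is bounded L-BFGS-B (d, e ∈ [1e−6, 5],
j ∈ [0, 2.99999]) from a seeded stratified start grid, plus — for DEC+j
— one start hugging j = 0 so the nested DEC optimum is always
reachable and the likelihood-ratio statistic cannot go negative beyond
numerical noise (clamped at 1e−3). The LRT refers D = 2ΔlnL to
chi-squared with one degree of freedom; with ĵ on the boundary this
p-value is conservative.

## The synthetic-data generator

Each generator emulates exactly the structure its consumer assumes:

* `simulate_tree`: pure-birth trees with a closing exponential stretch,
  so the expected root-to-tip depth has the closed form
  Σₖ₌₂ⁿ 1/(λk) used as the oracle in tests.
* `simulate_sequences`: the exact two-parameter substitution process
  (closed-form transition matrix, verified against the matrix
  exponential), so K2P is the correct estimator by construction.
* `simulate_morpho`: allometric scaling value = slope·SL·exp(noise)
  with population-specific slopes, Gaussian meristics rounded to the
  half-integer grid, and missing-completely-at-random cells.
* `simulate_ranges`: forward Gillespie simulation of the same DEC
  process the likelihood integrates, with cladogenetic draws from the
  same event distribution.

One global seed fans out to per-stream child seeds, so each modality
can be regenerated independently and regeneration is byte-identical.

In the three-species preset, population mean vectors diverge along the
species tree (the sister pair shares an ancestral deviation) and
species occupy adjacent basins along a west–east gradient. Both choices
mirror how riverine allopatric radiations actually generate congruent
signal across data types; without them the three tables would carry
three unrelated cluster geometries and the multi-table analysis would
have nothing real to find.

## Validation design, problem sizes, and what passing shows

The parameter-recovery study fits DEC to 20 datasets simulated at
d = 0.1, e = 0.02 on 50-tip trees over 5 areas. The tree timescale
(birth rate 0.05) is a design parameter: it puts the expected number of
extirpation events on a tree (e × total length ≈ 20) high enough that e
is estimable at all. Extirpation in DEC is weakly identified —
cladogenetic subset-sympatry and vicariance already shrink ranges
"for free", and conditioning the simulation on no lineage dying (tip
ranges must be observed) further depresses ê — so on short trees the
maximum-likelihood ê sits at the lower bound. Recovery medians within
50% relative error for both rates, and a DEC+j false-positive rate at
or below the nominal level on j = 0 data, are what the acceptance suite
checks. Fits in that study use two optimizer starts per model; the
user-facing default is five.

Passing synthetic tests shows the estimators are correct for data
generated under their own assumptions. Real tables violate those
assumptions in known ways the generator does not emulate: morphometric
noise is not log-normal and independent across variables, substitution
processes are not homogeneous two-parameter chains, collection
coordinates cluster along rivers rather than Gaussian blobs, and real
group labels can be wrong. The two acceptance tests that target
published summary statistics therefore require the study's deposited
raw data and fail (rather than skip) when those files are absent; the
remaining criteria are oracle- and simulation-based and run
self-contained.

## Known limitations

* No time-stratified dispersal matrices or area adjacency constraints
  in DEC; the per-pair dispersal multiplier is uniform.
* MCOA assumes commensurable tables after unit-inertia scaling; no
  STATIS-style weighting of table reliabilities.
* The imputation model is a straight line per (population, variable);
  populations with fewer than two observed values for a variable are a
  hard error by design.
* Undefined (saturated) K2P distances are excluded from summaries; a
  dataset dominated by saturation needs model-based distances instead.
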