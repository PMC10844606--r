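---
title: "Genomic evaluation of open-pollinated progeny tests with opbreed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic evaluation of open-pollinated progeny tests with opbreed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opbreed)
```

## The problem

Open-pollinated (OP) family testing evaluates forest trees from seed
collected on selected mothers, with fathers drawn from the surrounding
pollen cloud. It avoids the slow controlled-crossing phase, but the price is
an unreliable pedigree: recorded "half-sib" families actually mix selfs,
full-sibs and half-sibs, labels are corrupted during cone collection and
planting, and the pollen parents contribute hidden relatedness. Analysing
such data with a pedigree relationship matrix (ABLUP) inflates the additive
variance and heritability; marker-based relationships (GBLUP) recover the
realized relatedness, including Mendelian sampling within families.

`opbreed` implements the full evaluation chain for this setting:
relationship matrices, genomic pedigree verification, multi-site and
multi-trait individual-tree mixed models fitted by EM-REML, GWAS-based SNP
preselection by back-solving SNP effects from genomic breeding values, and
optimum contribution selection (OCS) for assembling a production population
under co-ancestry and correlated-trait constraints. A gene-dropping
simulator generates OP datasets with known truth so that every stage is
testable without external data.

## Relationship matrices

* **A** (pedigree numerator matrix) is built by the tabular method from the
  recorded pedigree. Founders are unrelated and non-inbred; the diagonal is
  `1 + F`. Ungenotyped mothers are carried in A, so pedigree-based and
  genomic analyses operate on different-sized matrices mapped by id.
* **G** follows the centered cross-product form
  `G = W W' / (2 * sum(p * (1 - p)))` where `W` holds genotype codes
  centered by twice the observed allele frequency. Monomorphic SNPs are
  excluded (they contribute zero to both numerator and denominator).
* **D** uses the dominance coding `(-2p^2, 2pq, -2q^2)` for codes 0/1/2 and
  the denominator `sum((2pq)^2)`. Mean-imputed fractional codes are rounded
  to the nearest genotype class for this coding only; the dominance
  covariate is defined per genotype class, not per dosage.
* The additive-by-dominance epistatic matrix is the Hadamard product of G
  and D.

G built from fewer informative SNPs than individuals is singular, and the
mixed-model equations need its inverse, so `blend_relmat()` shrinks G
towards the identity (`(1 - w) G + w I`, default `w = 0.01`, recorded in the
object). Blending slightly biases PEV upward; prediction error variances
that exceed the additive variance are clamped when converted to accuracies.

Missing genotypes are mean-imputed per SNP (the column mean of observed
codes), which leaves allele frequencies unchanged; SNPs with more than 50 %
missing entries are dropped at read time (configurable) because mean
imputation degrades beyond that.

## Genomic pedigree verification

`verify_pedigree()` audits family labels with three thresholds chosen to
recover injected errors in simulation (all configurable): individuals with a
G diagonal below 0.6 are removed; an individual whose mean relationship to
its recorded family is below 0.1 is tested against every other family and
reassigned where that mean reaches at least 0.15; leftover individuals that
are mutually related at 0.15 form new families, and the rest are reported
unassigned. On simulated data with 5 % mislabelled dams the procedure
recovers essentially all injected errors because a true half-sib shares
about 0.25 with its family while a mislabel shares about 0.

`network_edges()` renders any relationship matrix as a threshold graph
(edges above 0.05 or 0.10 are the conventional choices) with connected
components; on clean half-sib data the components at 0.05 are exactly the
families.

## The mixed models

The single-trait multi-site model treats the expression of a trait at each
site as a distinct but genetically correlated response: one fixed intercept
per site, site-specific additive effects `a ~ N(0, Sigma_a (x) K)` with an
unstructured 3 x 3 `Sigma_a` across sites and a relationship matrix `K` (A
or G) across individuals, and site-specific residual variances. The
multi-trait multi-site model extends the keys to the nine (trait, site)
combinations: `Omega_a` is unstructured 9 x 9, residuals are unstructured
across traits *within* a site and zero across sites (each tree grows at one
site, so cross-site residual covariances are not estimable). GBLUP-ADE adds
dominance and additive-by-dominance terms with their own unstructured
covariances and the D and Hadamard matrices.

Analysis is two-stage for tractability: `adjust_stage1()` first fits, per
site and trait, intercept + random block + random pedigree additive effect,
and subtracts the predicted block effect from each record. The genetic term
is included by default (`genetic_term = TRUE`) so block predictions are not
contaminated by the family structure of a blocked family trial; a plain
intercept + block variant is available, and with randomized complete blocks
the two differ little. Site means are retained and absorbed by the
second-stage intercepts.

### EM-REML with an average-information round

`fit_reml()` iterates the expectation-conditional-maximization form of REML
on Henderson's mixed-model equations: each round solves the MME at the
current covariances, then updates every term covariance from
`(u' Kinv u + tr(Kinv C^uu)) / n` and the within-site residual blocks from
the residual cross-products plus their MME trace corrections. The restricted
log-likelihood is evaluated every iteration and is non-decreasing (asserted
in the tests); iteration stops when its relative change falls below `tol`
(default 1e-8; the pipeline uses 1e-6) or at `max_iter` (default 2000), in
which case `converged = FALSE` is reported honestly alongside the estimates.
After convergence one average-information round builds the AI matrix over
all variance parameters; its inverse supplies standard errors, which
propagate to heritabilities by the delta method.

Numerical safeguards: unstructured covariance matrices are eigen-clipped at
1e-8 of their largest eigenvalue after every update (9 x 9 matrices drift
indefinite on small data), and variance floors prevent the residual from
collapsing to zero. Initialization splits each key's phenotypic variance
half genetic / half residual, with a small positive genetic covariance
(0.1 of the geometric mean) between sites for the same trait to break the
symmetry that would otherwise stall the recovery of cross-site
correlations; cross-trait starting covariances are zero.

A model with a single response key and a single genetic term (one trait,
one site) is fitted through an exact spectral shortcut: the relationship
matrix restricted to the recorded individuals is eigendecomposed once and
every EM iteration costs O(n). The fixed point is identical to the dense
solver's (asserted in the tests to 1e-6); breeding values and PEV for all
individuals, including unphenotyped parents, then come from one dense MME
solve at the estimates.

Heritability per trait averages the site-specific additive variances and the
site residuals: `h2 = mean(sigma2_a) / (mean(sigma2_a) + mean(sigma2_e))`,
with dominance and epistatic variances added to the denominator for ADE
models. Individual theoretical accuracy is `sqrt(1 - PEV_i / sigma2_a)`,
with PEV read off the inverse MME coefficient matrix.

## SNP preselection

`backsolve_snp_effects()` converts per-site genomic breeding values into
SNP effects through `u = W' G^{-1} ghat / (2 sum p(1-p))` — the SNP-BLUP
solution implied by the GBLUP fit (the two models are equivalent; the tests
verify the equivalence against a directly fitted ridge regression to 1e-8).
Because every analysed individual is genotyped after QC, no single-step
H-matrix machinery is needed; the back-solution is the single-step GWAS
special case with an empty ungenotyped set. Effects are averaged as absolute
values across sites, and `rank_snps()` orders SNPs by that mean (largest
first), by minor allele frequency (rarest first) or by a seeded random
shuffle, with ties always broken by ascending SNP id. `make_increments()`
reproduces near-equal cumulative panels (`round(j * m / steps)`), and
`combine_trait_top()` unions each trait's top-k for a combined multi-trait
G matrix.

## Optimum contribution selection

`ocs_optimize()` selects up to `n_max` individuals with equal contributions
`1/N` to maximize the summed (optionally per-trait standardized) breeding
value of the set, subject to a co-ancestry ceiling and mean-BV constraints
such as "no wood-density loss" (mean WD breeding value of the selected set
at or above the base-population mean of zero). Two co-ancestry scales are
implemented because printed limits like 0.25 and 0.125 sit naturally on the
relationship scale (0.25 = half-sibs): the default is the mean pairwise
relationship among the selected (off-diagonal mean of K), and
`group` (`c'Kc/2`) is available via `ocs_config()`. The co-ancestry matrix
should match the model's information set: G for genomic evaluations, A for
pedigree ones.

Small candidate sets (<= 25) are solved exactly by depth-first
branch-and-bound ordered by score with an optimistic completion bound;
because the mean-pairwise constraint is not monotone under insertion,
feasibility is checked at every node rather than used for pruning, so the
optimum carries a certificate. Larger sets use a deterministic greedy
construction plus first-improvement add/swap local search with seeded
randomized restarts (50 by default); the heuristic can never exceed the
exact optimum and matches it in at least 95 % of random trials in the test
harness. Infeasible constraint systems are reported explicitly
(`feasible = FALSE`), never as an empty selection.

On the bundled synthetic populations the co-ancestry ceiling of 0.25 rarely
binds: with 25 weakly related families and genomic Mendelian-sampling
variation, the top 30 candidates already spread across many families. The
constraint bites when kinship is concentrated — the test suite exercises
that regime with strongly related candidate sets.

## The simulator

`simulate_dataset()` generates the structure the framework assumes:

* founder allele frequencies uniform on (0.05, 0.5); unlinked SNPs under
  Hardy-Weinberg; offspring produced by gene dropping (each parent
  transmits its dosage-proportional allele independently per SNP, which is
  exact for unlinked loci);
* each OP family mixes selfs, full-sibs and half-sibs
  (default 0.05 / 0.25 / 0.70 — exposed placeholders, not estimates; the
  full-sib father is one shared pollen parent per family, half-sib fathers
  are fresh draws from an effectively infinite unrelated pollen pool);
* a common causal set (default 200 QTL) receives effects that are
  multivariate normal over the nine (trait, site) combinations with
  covariance (trait correlation matrix) x (compound-symmetric site
  correlation, default 0.8). Effect vectors are rotated against the realized
  genotype covariance so the *sample* covariance of breeding values matches
  the target exactly; each trait is then scaled to its additive SD (HT 1.5 m,
  DBH 2.5 cm, WD 0.04 g/cm3) and the residual SD is set from the target
  heritability (defaults HT 0.6, DBH 0.4, WD 0.5; correlations
  HT-DBH +0.5, WD-HT -0.53, WD-DBH -0.72);
* sites shift trait means (SD = 1 additive SD), randomized blocks add noise
  (SD = 0.5 additive SD), residuals are independent across traits;
* `inject_pedigree_errors()` replaces a fraction of recorded dams with a
  different family's dam, with the altered ids returned for ground truth.

What the simulator does *not* emulate: linkage and LD (SNPs are unlinked,
so marker-based relationships are less noisy than with a real map),
spatial autocorrelation within sites, selection history or population
structure among founders, and genotyping error. Passing tests therefore
demonstrate algorithmic correctness and the statistical behaviour that
follows from relatedness structure (e.g. pedigree-vs-genomic heritability
inflation under sibship contamination), not field-data performance.

## Problem sizes used in the checks

The test suite and the acceptance script size their simulations for
desk-scale runs, chosen once: parameter-recovery uses 50 half-sib families
x 30 offspring with 2000 SNPs (heritability 0.5, three seeds); the
sibship-contamination direction check uses 30 families x 25 offspring with a
deliberately strong contamination dose (self 0.10, full-sib 0.40) and
heritability 0.6, because the inflation it detects scales with both — at the
placeholder mixture the expected inflation (~0.07 in h2) sits below the
replicate noise of the two estimators and a ten-replicate direction test
would be underpowered whatever the implementation. The end-to-end acceptance
run evaluates 25 families x 5 offspring x 3 sites with 2000 SNPs, the
family and site structure of a typical OP proof-of-concept dataset at
reduced offspring counts.

## Known limitations

* EM-REML converges slowly near variance boundaries; runs that stop at
  `max_iter` report `converged = FALSE` and should be restarted with better
  initial values or a looser tolerance before interpretation.
* The dense solver inverts the full MME each iteration; it is comfortable
  up to a few thousand random-effect levels, beyond which sparse or
  factored approaches would be needed.
* PEV under a blended G is slightly conservative, and accuracies are
  clamped at zero rather than allowed to be imaginary.
* The OCS model optimizes equal contributions over a selected set (the
  seed-orchard use case); unequal contributions, mate allocation and
  multi-generation dynamics are out of scope.
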