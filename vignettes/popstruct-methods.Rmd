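---
title: "Models and methods behind popstruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popstruct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`popstruct` re-implements, as one coherent and testable toolchain, the
statistical path of a uniparental-marker population survey: frequency
tables, diversity, hierarchical AMOVA, distance/Mantel analysis, spatial
PCA, DAPC membership plots, TMRCA dating and mY admixture estimation.
This vignette explains each model, the assumptions it leans on, the
parameters that matter, and the choices made where the methodological
literature leaves the design open.

## Data model

An individual record carries a population id, a Y and/or mtDNA haplogroup
call, an integer Y-STR repeat profile, and a set of rCRS-relative
control-region variant tokens such as `16224C`.  Three marker-level rules
are enforced at parse time rather than downstream, because every analysis
depends on them:

* **DYS385a/b is never analysed.**  The duplicated locus is amplified as
  an unordered pair, so per-copy repeat counts are not identifiable; the
  raw columns are retained but excluded from every analysis profile.
* **DYS389b = DYS389II − DYS389I.**  DYS389II contains DYS389I; the
  derived difference replaces DYS389II in the analysis set so that loci
  are independent.  A zero difference is flagged as suspicious, a negative
  one is an error.
* **mtDNA coordinates are 1-based and circular** on the 16,569-bp rCRS
  circle.  The typed control-region window 15975–155 wraps through the
  origin; its inclusive clockwise length is exactly 750 bp, and
  `circular_region_length()` is the single arithmetic used everywhere a
  window size is needed.  Variant positions outside the typed window are
  rejected at parse time.

Missing values are written to files as the sentinel `.`; empty strings are
never given a meaning.  Haplogroup labels are free strings matched
case-sensitively against a user-editable tree config
(`inst/extdata/haplogroup_tree_y.tsv` is an example); the reduced
cross-study comparison level is part of that config, and
`collapse_haplogroups()` verifies that row totals are conserved.

## AMOVA

Sums of squares are computed from squared inter-individual distances: the
SS of any set of individuals is the sum of its pairwise squared distances
divided by the set size.  Three distance kinds cover the standard designs:
0/1 haplogroup mismatch (the "frequencies only" analysis), counts of HVS
variant differences (sequence AMOVA, Φ-statistics), and squared repeat
differences summed over STR loci (the R<sub>ST</sub> analogue).  Variance
components come from the usual expected-mean-square equations for the one-
and two-level hierarchical designs with unequal sample sizes.

Negative variance components, which arise legitimately when true
components are near zero, are retained in the returned object but floored
at zero when percentages are reported, with a flag — hiding them entirely
would overstate precision, clamping silently would hide misfit.

Each Φ statistic is tested under its own permutation scheme: individuals
among populations for Φ<sub>ST</sub>, whole populations among groups for
Φ<sub>CT</sub>, individuals among populations within groups for
Φ<sub>SC</sub>.  P-values are `(1 + #{perm ≥ obs})/(n_perm + 1)`, so they
have exactly `1/(n_perm+1)` granularity and never return zero.  The
default 10,000 permutations mirrors the Mantel convention below; tests in
this package use smaller counts only to keep suites fast, never because
fewer permutations are statistically preferable.  A population of size 1
makes the within-population component undefined and is refused by name.

## Distances and the Mantel test

Reynolds coancestry distance treats the haplogroup system as one
multi-allelic locus: D = −ln(1−θ).  Which small-sample correction of θ to
use is genuinely open, so both are exposed.  The *uncorrected* form is the
classic plug-in θ = Σ(p−q)²/(2(1−Σpq)); the *corrected* default subtracts
the unbiased within-population sampling variance (1−Σp²)/(n−1) of each
sample from the numerator, so that two samples drawn from the same
population score ≈ 0 rather than a positive sampling artefact.  θ is
clamped to [0, 1]; disjoint fixed populations give θ = 1 and D = +∞ with a
warning rather than a silent large number.

Geographic distances are great-circle (haversine) kilometres on a
spherical Earth of radius 6371 km.  The Mantel statistic is the Pearson
correlation over off-diagonal upper triangles, with a one-sided upper
permutation test (rows and columns of one matrix permuted together,
10,000 permutations by default).  A constant matrix has no defined
correlation and is an error, not an NA.

## Spatial PCA and its permutation tests

With the column-centred population × haplogroup frequency matrix X and
symmetrised connection weights Ω = (W + Wᵀ)/2, the axes are eigenvectors
of XᵀΩX / ΣΩ; for every axis the eigenvalue equals var(score) ×
Moran's I(score) **by construction**, and the package asserts that
identity to 1e−10 in its tests.  Positive eigenvalues are global (clinal)
structures, negative ones local (neighbour-contrast) structures.
Frequencies, not counts, enter X, and columns are centred but not
variance-scaled by default: haplogroup frequencies already share a scale,
and unit-scaling rare lineages inflates noise (scaling is a flag).  Axis
signs are fixed by making the largest-magnitude loading positive, so plots
are reproducible across platforms.

The connection network is Delaunay by default (built by an exact
empty-circumcircle construction on lon/lat, adequate at the scale of a
regional survey; populations are few, so the O(n⁴) construction is
immaterial).  kNN on great-circle distances and inverse-distance weights
are alternatives; duplicate coordinates are an error naming the
populations, and fewer than three points fall back to a complete graph
with a warning.

The global/local tests project each centred, unit-norm frequency column
onto the Moran eigenvectors of the network (eigenvectors of the doubly
centred Ω), and sum squared projections over components with positive
(global) or negative (local) Moran value, averaged over columns — i.e. the
mean share of each variable's variance in the global or local spatial
frequency band.  The null permutes population rows against coordinates.
The exact projection weighting of such tests varies between
implementations; this one is fixed as stated and validated by calibration:
on label-shuffled clinal data the global test stays non-significant in
well over 90% of runs, and on strongly clinal data it saturates at the
smallest attainable p.

## Clustering and DAPC

Cluster number is selected by BIC over Gaussian-mixture fits with three
covariance families — shared spherical, shared diagonal, shared full
(mclust models EII/EEI/EEE, deterministic agglomerative initialisation
under a fixed seed).  The full model is skipped with a warning when there
are too few points to estimate it.  For membership analysis of
distance-based data the coordinates are principal coordinates (classical
MDS) of the distance matrix, three dimensions by default, logged.

DAPC centres and unit-scales features, retains the smallest number of
principal components explaining ≥ 90% of variance (capped at n/3, always
reported) unless told otherwise, and solves the generalised eigenproblem
of between- versus within-group scatter in PC space.  Discriminant axes
are normalised to unit pooled within-group variance, which makes the
membership model a unit-variance Gaussian per group with equal priors —
equal rather than size-proportional priors because group sizes in survey
designs reflect sampling effort, not prevalence.  A singular within-group
covariance is ridge-regularised with a logged epsilon.  Held-out
populations can be assigned without refitting.  Memberships saturate when
groups are separated by many within-group standard deviations; that is a
property of the model, and the package's mixed-population tests are built
at moderate separation where intermediate memberships are informative.

## TMRCA estimation

**Y-STR variance dating.**  Under the single-step mutation model on a
star genealogy, the expected repeat variance at locus *l* after *t*
generations is μ<sub>l</sub>t.  The estimator inverts that identity per
locus, t̂<sub>l</sub> = V<sub>l</sub>/μ<sub>l</sub>, and averages over the
8 configured dating loci; the SE is the between-locus standard deviation
over √8, and years = generations × `generation_years`.  The exact
algebraic variant of this family of estimators differs between reports;
the per-locus-variance mean used here is validated by simulation (mean
recovery within a few percent of truth at n = 200 over 100 replicates)
rather than by refitting any published table, which would require the
underlying haplotypes.  The default `generation_years = 25` reproduces the
deterministic generation-to-year arithmetic of standard published dating
tables (the shipped reference table converts to within ±2 years on every
row).  Haplogroups with fewer than 10 members are refused: locus variances
on a handful of haplotypes date noise.

Outliers — single haplotypes many mutational steps from the core — inflate
the variance quadratically, so individuals are screened by mean squared
repeat distance to the modal haplotype over the dating loci, removing
scores above Q3 + 3·IQR.  The rule is explicit, logged, switchable off,
and skipped below n = 8 where quartiles are meaningless.  Modal-haplotype
ties break toward the smaller allele and are reported.

Locus rates ship as an editable config (`inst/extdata/clock_y.yaml`) with
placeholder values on the pedigree (Ballantyne-type) scale; no rate is
hard-coded as truth, and the choice of the 8 loci (a Busby-style
duration-of-linearity selection in the literature) is likewise a config
decision, because the optimal set depends on the panel.

**mtDNA ρ dating.**  ρ is the mean count of variant-token differences
between each sequence and a root haplotype, restricted to HVS-I
(16024–16365 by default); its star-genealogy SE is √(ρ/n), and years = ρ ×
`hvs_rate_years_per_mutation` (a Soares-style calibration).  The
calibration constant has **no default**: silently assuming one corrupts
dates, so the config must supply it.  The root is supplied explicitly
where known; otherwise the modal variant set (tokens carried by more than
half the sequences) stands in, with a message — founder and modal
haplotypes coincide under star-like expansion but can differ in structured
samples.

## mY admixture

For populations with frequency vectors x, y and inter-haplogroup distance
matrix D, the mean pairwise molecular diversity between them is xᵀDy.  If
the hybrid is the mixture Σ m<sub>k</sub>P<sub>k</sub>, its diversity to
every parental j satisfies d(H,P<sub>j</sub>) = Σ<sub>k</sub>
m<sub>k</sub> d(P<sub>k</sub>,P<sub>j</sub>); the coefficients solve that
linear system by least squares under Σm = 1 (KKT system).  The default D
is the identity 0/1 distance — pure haplogroup-frequency information —
with an arbitrary molecular D accepted for the full estimator.  Weights
are *not* clamped to [0,1]: out-of-range values are reported raw and
flagged, because they are the estimator's way of signalling a misspecified
parental model.  Two near-identical parentals make the system
ill-conditioned and are rejected with the condition number.  Bootstrap
dispersion resamples individuals multinomially within every population,
with parentals first subsampled to 50 per replicate by default to
equalise their sampling variance.

## The synthetic generators

Each generator encodes exactly the probabilistic model its estimator
assumes, so recovery tests are oracle tests, not curve fits:

* `simulate_star_str()` — independent lineages, Poisson(μt) mutations per
  locus, ±1 steps: E[repeat variance] = μt exactly.  A Kingman-coalescent
  option rescaled to the same TMRCA exists for robustness experiments;
  shared ancestry inflates estimator variance, which is the point of
  having it.  Single-step mutations only — the standard assumption behind
  variance dating.
* `simulate_hvs()` — K ~ Poisson(age/rate) mutations at uniform positions
  in the window; a site may be hit twice and a re-drawn token toggles off,
  mirroring real recurrent-mutation noise in ρ.
* `simulate_cline_frequencies()` — multinomial counts around
  softmax(log(baseline) + slope·longitude).  The multinomial-logit form is
  used because it returns the baseline exactly when all slopes are zero,
  which an elementwise logit transform would not.
* `simulate_admixed()` — multinomial counts at the exact mixture of
  parental profiles.

What the generators deliberately do **not** emulate: demographic history
(growth, migration matrices, drift since admixture), selection, STR allele
saturation/range constraints, mutation-rate heterogeneity beyond the
configured per-locus rates, and sequencing/genotyping error.  Passing
recovery tests therefore demonstrates estimator correctness under each
method's own model, not robustness of historical conclusions drawn from
real data — the same caveat that applies to the original estimators.

## Numerical and operational choices

* Permutation p-values always include the observed arrangement, so the
  smallest attainable p is 1/(n_perm+1).
* The sPCA eigen-identity is asserted to 1e−10; eigenvalues below
  max|λ|·1e−10 are treated as rank deficiency and dropped.
* DAPC's within-covariance is ridge-regularised (logged epsilon) only when
  its reciprocal condition number falls below 1e−12.
* Monte-Carlo exact tests (r×c Fisher) default to 10⁵ seeded table draws;
  full enumeration is used only by the test-suite oracles on toy tables.
* One pipeline seed expands deterministically into per-stage seeds; every
  stage logs its seed, permutation count, dropped records and removed
  outliers, and reruns are byte-identical.
* Test suites and the acceptance script use deliberately modest problem
  sizes — e.g. 100 star replicates of n = 200 for dating recovery, 500
  null datasets for AMOVA calibration, 999 permutations for the sPCA
  global test — chosen as the smallest sizes at which each property is
  sharply distinguishable from its failure mode.

## Known limitations

* No Bayesian coalescent dating, no whole-mitogenome clock with
  purifying-selection correction: HVS-I with a linear clock only.
* No haplogroup calling from raw SNPs and no Phylotree parsing —
  haplogroup calls are inputs.
* The Delaunay network is built in lon/lat coordinates; at continental
  scales or near the poles a projected or spherical triangulation would be
  preferable.
* ρ dates inherit the statistic's known sensitivity to past demography;
  the SE reported is the star-genealogy one.
* The mY estimator assumes the hybrid is exactly a mixture of the supplied
  parentals; unsampled sources bias the weights, which is why out-of-range
  values are surfaced rather than clamped.
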