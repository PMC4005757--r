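# popstruct

Population-structure, dating and admixture analysis for uniparental
(Y-chromosome and mtDNA) survey data.

Surveys of paternal and maternal lineages — the kind that genotype a few
hundred men for Y-SNP haplogroups plus Yfiler STR haplotypes, and sequence
the mtDNA control region (HVS-I/II) in the same samples — all walk the same
analytical path: haplogroup frequency tables, diversity indices,
hierarchical AMOVA, genetic-vs-geographic distance correlation, spatially
explicit ordination, cluster/membership ("admixture-like") plots, lineage
age (TMRCA) estimation, and admixture-proportion estimation against
candidate parental populations.  `popstruct` implements that whole path as
tested, seedable R functions, together with synthetic-data generators whose
truth is known by construction, so every estimator in the chain can be
validated end to end without access to anyone's raw samples.

## Methods at the core

* **AMOVA** — squared inter-haplotype distances (0/1 haplogroup mismatch,
  HVS sequence differences, or summed squared STR repeat differences for
  R<sub>ST</sub>) decomposed into within-population, among-population and
  among-group variance components; Φ<sub>ST</sub>, Φ<sub>SC</sub>,
  Φ<sub>CT</sub> with permutation tests, each statistic under its own
  permutation scheme.
* **Spatial PCA** — axes maximise var(Xv) · I(Xv), the product of variance
  and Moran's I over a Delaunay/kNN/inverse-distance connection network;
  positive eigenvalues flag global (clinal) structure, negative local
  structure, with global/local permutation tests.
* **DAPC** — PCA reduction followed by discriminant axes maximising the
  between/within variance ratio; posterior group memberships form the
  barplot tables used to describe admixed positions of populations.
  Cluster number is chosen by Gaussian-mixture BIC (via mclust).
* **TMRCA** — Y-STR variance (SD) dating: per locus t<sub>l</sub> =
  V<sub>l</sub>/μ<sub>l</sub> averaged over 8 configured dating loci with a
  modal-haplotype outlier screen (Q3 + 3·IQR rule); mtDNA ρ statistic (mean
  mutational distance to a root haplotype over HVS-I) with a linear
  years-per-mutation clock.
* **mY admixture** — the hybrid population's mean pairwise molecular
  diversity to each parental is expressed in terms of parental–parental
  diversities; coefficients solve that system by least squares under
  Σm = 1, with multinomial bootstrap dispersion.  With the identity (0/1)
  haplogroup distance this is the pure frequency-based estimator.
* **Frequency statistics** — direct-count tables with lineage collapsing to
  a reduced comparison level, Nei gene diversity with its standard error,
  Fisher exact enrichment tests (2×2 exact; r×c by seeded Monte-Carlo),
  Bonferroni-corrected per-lineage chi-square comparisons, Reynolds
  coancestry distances and Mantel tests against great-circle geography.

## Worked example

Dating a simulated haplogroup of known age (160 generations) with the
variance estimator, then running the spatial analysis of a synthetic
clinal survey:

```r
library(popstruct)

clock <- read_clock_config(system.file("extdata", "clock_y.yaml",
                                       package = "popstruct"))
founder <- setNames(rep(14L, 8), clock$dating_loci)
sim <- simulate_star_str(120, 160, founder, clock$locus_rates, seed = 42)
tmrca_ystr(sim, clock)
#> TMRCA (SIMHG) : 3607 +/- 284 YBP  [144.3 +/- 11.3 generations, 0 outliers removed]

b <- synthetic_bundle(seed = 1)     # clinal counts + metadata + truth
w <- build_weights(b$meta)          # Delaunay connection network
spca(b$counts, w)
#> Spatial PCA: 7 axes
#>      eigenvalue variance moran_i
#> sPC1     0.0463   0.0772  0.5999
#> sPC2     0.0000   0.0002  0.0804
#> ...
#> (eigenvalue = variance x Moran's I; positive = global, negative = local)

my_bootstrap(b$admixture$hybrid, b$admixture$parentals,
             n_boot = 1000, seed = 3)
#> mY admixture coefficients (identity distance):
#>      weight bootstrap_mean bootstrap_sd
#> NCI  0.5906         0.5672       0.1506
#> BALK 0.2358         0.2416       0.1980
#> LEV  0.1736         0.1912       0.1079
#> 1000 bootstrap replicates
```

The dated haplogroup comes back at 144 ± 11 generations against a true age
of 160 (one simulation replicate; the estimator is unbiased to within a few
percent over replicates).  The single large positive sPCA eigenvalue is the
simulated longitudinal cline; the mY weights recover the 0.60/0.25/0.15
mixture the hybrid was generated from, within bootstrap dispersion.

The full survey pipeline — frequencies → diversity → AMOVA/Fisher →
distances + Mantel → sPCA + tests → clustering/DAPC → enrichment → TMRCA →
admixture — runs from one seeded config and writes one TSV per stage plus
a run log:

```r
run_pipeline(list(seed = 11, out_dir = "out", n_perm = 999, n_boot = 1000))
```

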