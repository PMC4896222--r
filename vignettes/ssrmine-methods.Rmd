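---
title: "Methods behind ssrmine: SSR diversity, Q+K association mapping and elite allele mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind ssrmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ssrmine` implements the full desk-side analysis chain used in SSR-based
association studies of inbred crop diversity panels — the kind of panel in
which several hundred rice accessions are genotyped at a few hundred
multi-allelic microsatellite loci and phenotyped for grain-size traits over
replicated multi-year trials. This vignette explains the statistical models,
the conventions chosen where the field's practice is ambiguous, and what the
bundled synthetic-data generator does and does not emulate.

## Data model

Accessions are inbred lines, so each SSR locus yields a single scorable
fragment per accession: genotypes are haploid-coded, an accession × locus
matrix of fragment sizes in bp. A primer pair that fails to amplify produces
the *null allele*, written `NA` in files and carried internally as a missing
cell. The null allele is a genotype class of its own — it is excluded from
diversity denominators, dropped pairwise in LD, excluded from the marker
test, and serves as the *reference class* for allele-effect estimation.

Phenotypes are long-format records `(accession, trait, year, replicate,
value)`. All analyses of accession-level quantities use means over
replicates (and, where stated, over years).

## Diversity statistics

Per locus, with allele frequencies $p_i$ over amplified calls only:

* gene diversity (expected heterozygosity) $D = 1 - \sum_i p_i^2$;
* Botstein's polymorphism information content
  $\mathrm{PIC} = 1 - \sum_i p_i^2 - 2\sum_{i<j} p_i^2 p_j^2$, with
  informativeness classes high ($>0.5$), moderate ($0.25$–$0.5$] and slight
  ($\le 0.25$);
* panel summaries round the way the field prints them: allele counts to one
  decimal, diversity and PIC to four.

"Nei's distance" between single inbred individuals is ambiguous among the
1972/1978/1983 variants, but for one-individual haploid profiles they all
reduce to allele sharing; we therefore define
$d(i,j) = 1 - \text{(proportion of co-amplified loci with identical
alleles)}$, a premetric in $[0,1]$. Neighbor joining (Saitou–Nei) is
implemented in the package because we fix two contracts that generic
implementations leave open: ties in the Q criterion go to the lowest index
pair (determinism), and a negative branch length is clamped to zero with the
deficit moved to its sister edge, so leaf-to-leaf path lengths are
preserved and additive matrices are reconstructed exactly. Trees are `ape`
`phylo` objects and are written as standard newick.

## Population structure and kinship

Structure inference uses the classical admixture likelihood for haploid
multi-allelic data: accession $i$ has membership proportions $q_i$ over $K$
clusters with cluster-specific allele frequencies $f_{kl}$, and
$P(g_{il}) = \sum_k q_{ik} f_{kl}(g_{il})$. We fit it by EM — a
deterministic-given-seed surrogate for MCMC-based structure software with
the same Q-matrix contract; it does not implement correlated allele
frequency priors or linkage models. The log-likelihood is provably
non-decreasing across iterations (this is asserted in the tests), and runs
differ only by their restart seed. Model choice uses Evanno's
$\Delta K = \overline{|L(K{+}1)-2L(K)+L(K{-}1)|}/\mathrm{sd}(L(K))$ over
repeated runs at consecutive $K$ (sd floored at $10^{-6}$, ties to the
smaller $K$); mean log-likelihoods are reported alongside so the raw
$\Pr(X\mid K)$ comparison is also available — the two can disagree, and both
are emitted.

Kinship is background-corrected allele sharing: with $s_{ij}$ the
proportion of co-amplified loci sharing the allele and $\bar s$ the mean
off-diagonal sharing, $k_{ij} = (s_{ij}-\bar s)/(1-\bar s)$, so the average
pair scores 0 and identity scores 1. For use as a mixed-model covariance the
matrix is clamped to $[0,1]$ and repaired to positive semidefiniteness by
flooring eigenvalues at zero; the raw rescaled matrix is retained for
reporting. The distribution of pairwise values is histogrammed in the
conventional bins ($<0.05$, $0.05$–$0.10$, $>0.10$).

## Linkage disequilibrium

For a locus pair the haplotypes are the observed two-locus allele pairs of
the inbreds (no phasing). The multi-allelic $D'$ is the frequency-weighted
mean of classical standardized coefficients,
$D' = \sum_{ij} p_i q_j |D'_{ij}|$ with $D_{ij} = x_{ij} - p_i q_j$ and the
usual sign-dependent $D_{\max}$; on a biallelic pair this equals classical
$|D'|$ (tested to $10^{-12}$). Significance comes from permuting one locus's
calls, $p = (\#\{D'_\text{perm} \ge D'_\text{obs}\}+1)/(n_\text{perm}+1)$;
tests default to 1,000 permutations with 100,000 available by flag. No
multiple-testing correction is applied to the $p<0.05$ "pairs in LD" counts,
matching standard practice in these panels; per-subpopulation summaries use
hard assignments (argmax of the Q row), skip subpopulations under 10
accessions, and report each subpopulation's share of the total significant
pairs across subpopulations — the normalization consistent with the
published tables this layout mirrors.

LD decay is summarized by least squares of $D' = b\ln(x) + c$ over
syntenic significant pairs, and the *decay distance* is the crossing point
$x^* = \exp((D'_\text{crit}-c)/b)$. The critical $D'$ is not standardized in
the literature; we use the 95th percentile of the inter-chromosomal
(background) $D'$ of the same subpopulation, exposed as a flag.

## Quantitative genetics

Per trait and year, a one-way genotype ANOVA on replicate-level data gives
$\sigma_e^2 = \mathrm{MSE}$ and $\sigma_g^2 = (\mathrm{MSG}-\mathrm{MSE})/
\bar n$ ($\bar n$ = harmonic-mean replicates; negative estimates truncated
to zero and flagged), and broad-sense heritability of line means
$H^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2/n)$. $H^2$ is computed per
year because replicated two-year trials report it that way. Descriptives
use sample SD, CV = SD/mean·100, and SAS-convention adjusted skewness and
excess kurtosis (type 2), flagged undefined below 4 observations. Trait
correlations are Pearson on accession means per year with two-sided t-tests
starred at 0.05/0.01.

## The Q+K mixed-model scan

The scan fits, per trait-year, $y = X\beta + u + e$ with
$u \sim N(0, \sigma_g^2 K)$ on accession means, $X$ containing the
intercept and the first $K{-}1$ Q columns (the last is dropped against the
intercept). Variance components come from REML profiled over
$\lambda = \sigma_g^2/\sigma_e^2$ on the eigenbasis of $K$ (EMMA-style
1-D optimization), once per trait-year, and are reused for every marker
(P3D) — deterministic and fast. Each marker enters as an allele-class
factor: null-allele accessions are excluded, classes with fewer than 5
carriers (flag `rare_min`) are pooled into one "rare" class, and a pooled
rare class still below the threshold is excluded entirely. The model
covariance restricted to the tested accessions is Cholesky-whitened and the
marker factor is F-tested against the Q-only null; PVE is the marker's
residual-sum-of-squares reduction over the whitened total sum of squares
(about the whitened intercept), in percent. With $K=I$ and no Q the test
reduces exactly to the one-way ANOVA F-test (oracle-checked to $10^{-8}$).

The default significance filter retains a trait × locus row when the locus
is significant ($p<0.05$, strict) in *every* scanned year and the row's own
PVE exceeds 5% — the joint-year reading implied by two-year association
tables; `both_years = FALSE` filters year by year.

## Allele effects, elite alleles, crosses

The effect of allele $i$ at a retained locus is
$a_i = \sum_j x_{ij}/n_i - \sum_k N_k/n_k$: the mean phenotype of its
carriers minus the mean of the null-allele accessions at that locus,
computed on cross-year accession means (a per-year variant is available; the
cross-year default matches the use of loci retained in both years). If a
locus has no null-allele accession the population mean is used and flagged.
Alleles with positive effect are *elite* for trait-increasing goals (a
direction flag covers trait-decreasing targets); singleton carriers
(< 2, flag `min_carriers`) are reported but never elite. The *typical
carrier* is the highest-valued accession among the allele's carriers that
ranks in the phenotypic top 30 (flag), falling back, flagged, to the best
carrier overall.

Cross design assumes a derived inbred line fixes one allele per locus: for
a parent pair, the elite alleles carried by either parent are pooled per
locus, the largest-effect one is kept, and the predicted effect is the sum
over loci. All unordered pairs are enumerated exhaustively and ranked by
elite-allele count, then predicted effect, then lexicographic parent ids.

## The synthetic-data generator

`sim_config()` defaults emulate the motivating rice panel: 628 accessions,
262 loci on 12 chromosomes, 3–25 alleles per locus, 7 admixed
subpopulations, two years × two replicates, heritabilities ~0.9, and a low
(3%) null-allele rate. Genotypes follow a Balding–Nichols construction:
ancestral frequencies from a symmetric Dirichlet per locus, subpopulation
frequencies from a Dirichlet centred on them with concentration
$(1-F_{ST})/F_{ST}$, per-accession admixture from Dirichlet($\alpha$), and
one allele per cell from the accession's mixture frequencies. Null alleles
overlay independently of genotype — the simplest model consistent with
amplification failure. Allele labels are fragment sizes spaced 2 bp apart
(cosmetic). Phenotypes sum planted QTL allelic effects (`qtl_spec`, with
`"topN"` resolving to the locus's Nth most frequent allele) and optionally
a structure-driven term $Q\cdot\text{shifts}$ (`structure_shifts`), used to
build structured *null* traits with no QTL; the error variance is set from
the realized genetic variance so the accession-mean heritability hits
`target_h2` exactly in expectation.

What the generator does **not** emulate: linkage — loci are exchangeable
given structure, so LD among simulated loci arises from structure and drift
only and does not decay with map distance. Simulated decay regressions are
therefore exercised for their numerics (exact on noiseless curves), not for
the sign of the slope. It also omits stepwise mutation, selection and
pedigree structure. Passing recovery tests consequently demonstrate
correctness of the estimators under admixed drift, not realism of rice LD.

## Validation designs and problem sizes

The test suite validates parameter recovery at the panel scale the
estimators are meant for, with sizes chosen to keep a full run in minutes:

* heritability: 20 panels, n = 600, 3 QTL, target 0.9 — mean estimate
  within ±0.05;
* power: 20 panels, n = 600, focal QTL plus 8 background QTL sized so the
  focal allele effect is ≈1 phenotypic SD (the ratio is scale-invariant in
  the architecture, so this is fixed by design, not tuned) — detection at
  p < 0.05 with power ≥ 0.9;
* calibration: 4 structure-driven null panels of 600 × 260 (≥1000 marker
  tests) — Q+K type-I error within [0.03, 0.07] while naive per-marker
  ANOVA on the same data is grossly inflated. With a low-dimensional
  genetic signal (a handful of strong QTL) the Q+K scan is over-conservative
  instead — a known property of kinship correction — which is why the
  calibration experiment uses the polygenic/structural null;
* allele-effect signs: 20 panels, n = 600, planted effects ≥ 0.5 SD — sign
  recovered in ≥ 95% of cases;
* ΔK: panels with a generating K of 3 (n = 200, 60 loci — sized so the
  likelihood profile is informative; smaller panels make the second
  difference noisy), K ∈ 2..6, 5 runs each — the generating K chosen in
  ≥ 4 of 5 seeds.

Numerical conventions throughout: EM stops on an absolute log-likelihood
change below `tol` (default 1e-4) or `max_iter`; cluster-frequency updates
carry a 1e-12 pseudocount, so monotonicity is asserted to 1e-6; REML
optimizes $\log\lambda$ on [−12, 12]; permutation p-values use the +1/+1
estimator and so never return 0; all stochastic stages take explicit seeds
and the pipeline writes byte-identical artifacts for identical config and
seed.
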