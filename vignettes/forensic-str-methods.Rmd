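---
title: "Methods: forensic population genetics of a combined autosomal / Y-STR panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forensic population genetics of a combined autosomal / Y-STR panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strforensics)
```

## Scope and data model

`strforensics` implements the complete statistical workflow used to
characterise forensic STR multiplexes that co-amplify autosomal and
Y-chromosomal loci: per-locus forensic efficiency parameters, equilibrium
tests, Y-haplotype diversity, between-population differentiation, and
ordination/tree summaries of population relationships.  The package ships
the locus-level summary tables of a survey of 214 unrelated Southern
Shaanxi Han individuals (108 males, 106 females; 15 autosomal + 10 Y-STR
loci) which serve both as defaults for the synthetic generators and as a
fixed reference that the test suite reproduces.

Genotypes are held in a `genotype_table`: one row per individual, an
unordered allele pair per autosomal locus, one allele per single-copy Y
locus on males, and an unordered pair for the duplicated DYS385a,b locus.
Allele labels follow repeat-count nomenclature with microvariants
(`"9.3"` = 9 repeats + 3 bases); pairs are canonicalised ascending at
construction so genotype identity never depends on input order.  Published
frequency tables are ingested by `recover_counts()`, which inverts the
4-decimal rounding of printed frequencies back to integer counts
(`round(p * n_genes)`) and *flags* — never repairs — tables whose counts
fail to re-sum; all downstream arithmetic then runs on exact count
fractions rather than rounded decimals.

## Forensic efficiency parameters

For allele frequencies $p_i$, $n$ typed individuals, observed
heterozygosity $h$ and $H = 1 - h$:

* $He = \left(1 - \sum_i p_i^2\right)\frac{n}{n-1}$.  The bias correction
  uses the number of **individuals**, not gene copies.  This is the
  convention of the forensic "powerstat" spreadsheets: it is the only
  reading that reproduces the reference table (TPOX $He = 0.6167$,
  D3S1358 $0.7311$) from the published counts, and is therefore the
  default; the population-genetic $2n/(2n-1)$ estimator and the
  uncorrected gene diversity remain available via the `correction`
  argument.
* $PIC = 1 - \sum p_i^2 - \left(\sum p_i^2\right)^2 + \sum p_i^4$
  (Botstein).
* $MP = \sum_g \hat{f}_g^2$ over **observed** genotype frequencies, and
  $PD = 1 - MP$.  The Hardy-Weinberg-expected variant is available
  (`expected = TRUE`) but is never the reporting default, because the
  empirical convention is what published tables use.
* $PE = h^2\,(1 - 2hH^2)$ and $TPI = 1/(2H)$.  The source study never
  states its PE/TPI formulas; these forms were selected because they
  reproduce the reference table exactly from the printed $h$ — an
  inference, not a citation.  $h = 1$ raises an error for TPI rather than
  returning infinity.

Combined powers $1 - \prod_i MP_i$ and $1 - \prod_i (1 - PE_i)$ are
returned twice: as machine floats of the complementary products (the
machine-precision source of truth) and as exact decimal strings computed
by big-integer arithmetic on the 4-decimal inputs, because a 15-locus
combined PD of $1 - 1.13\times 10^{-17}$ is not representable in double
precision.  Report output rounds half-up at 4 decimals, matching
published tables (base R's round-half-even would disagree on exact ties).

```{r combined}
fp <- shaanxi_forensic_params()
combined_powers(fp$MP, fp$PE)[c("combined_pd", "combined_pe")]
```

## Equilibrium tests

The Hardy-Weinberg test is a Monte-Carlo exact test in the Guo-Thompson
spirit: the $2n$ observed allele copies are shuffled into random pairs
and each arrangement is scored by the conditional probability of its
genotype array given the allele counts (Levene's distribution); the
p-value is $(b+1)/(m+1)$ where $b$ counts arrangements no more probable
than the observed one, so it is never exactly 0.  The pairwise linkage
test permutes one locus' genotypes across individuals and scores the
two-locus contingency table by its log-likelihood ratio (the choice of
the Genepop program; Pearson's chi-squared is an option).  Seeds are
mandatory and recorded in every result together with $m$; the shuffle
pool is canonically sorted so p-values are invariant to row order and to
allele order within genotypes.  Monomorphic loci return an explicit
not-applicable result.

The original study's printed HWE/LD p-values came from closed-source
spreadsheet/legacy tooling whose algorithms are unspecified, so they are
*not* calibration targets.  Instead the suite demonstrates type-I-error
calibration on synthetic nulls of the study design (1000 replicates at
$n = 214$; rejection rates at $\alpha = 0.05$ within the 99% binomial
band).  Two numerical notes: exact conditional tests are inherently
slightly conservative (the fully enumerated test has size $\approx 0.039$
at this design), and the Monte-Carlo p exceeds the exact p by
$\approx 1/(m+1)$ on average, so the calibration experiment uses
$m = 4999$ to measure the test rather than the Monte-Carlo noise.
Family-wise decisions use Bonferroni's $\alpha/k$ with $k = 15$ loci,
the convention of the source study (even though 105 pairs are tested).

## Y-STR haplotypes and diversity

Haplotypes are built per male over the declared panel; DYS385a,b enters
identity as an unordered pair.  Nei's unbiased gene diversity
$GD = \frac{n}{n-1}(1 - \sum p_i^2)$ uses $n$ = number of sampled male
chromosomes — the only reading consistent with the reference Y table —
and the same formula applied to whole-haplotype frequencies gives the
haplotype diversity; discriminatory capacity is distinct/$n$.

Two documented quirks of the bundled reference table: (i) its DYS458
column prints the allele label "15" twice; the second row is encoded
here as the common microvariant "15.2", the only reading under which the
counts sum to 108 and the printed $GD = 0.8165$ is reproduced exactly.
(ii) Its DYS385a,b diversity entry (0.9983) equals the whole-panel
*haplotype* diversity, not the gene diversity of its own printed pair
frequencies, which is 0.9531 from the recovered pair counts; the package
computes the honest pair-based value and the suite pins both numbers.
The per-haplotype multiplicity spectrum of the reference males (94
singletons, 4 doubletons, 2 tripletons; `shaanxi_y_spectrum()`) is an
*inferred* reconstruction — the unique spectrum consistent with the
reported 100 distinct / 94 unique haplotypes and $HD = 0.998269$ — since
the per-individual listing is not redistributed.

## Population differentiation

Multi-allelic Weir-Cockerham $\theta$ is computed from per-allele
variance components, multi-locus as the ratio of summed components.
With raw genotypes the heterozygosity term is exact; published
frequency-only panels force its Hardy-Weinberg approximation
$h_i = 2p_i(1-p_i)$, and results carry a `mode` flag saying which route
was used.  Identical finite samples give a slightly *negative* estimate
(order $-1/2n$, the estimator's unbiasedness at zero differentiation),
so distance matrices clamp at zero while retaining raw estimates in an
attribute.  Significance uses permutation of individuals between
populations.  $R_{ST}$ for Y data is the AMOVA variance-component ratio
on squared repeat-count differences summed over single-copy loci;
DYS385a,b is excluded because a multi-copy locus has no single repeat
difference.  Tree-building distances (Nei standard — the default, as in
PHYLIP's GENDIST; Reynolds; Cavalli-Sforza chord) operate on the shared
locus set with absent alleles at frequency zero; fully disjoint allele
sets make Nei's distance infinite and raise an error rather than
returning a sentinel.

## Ordination and trees

PCA runs on the covariance matrix of the population-by-allele frequency
matrix (correlation optional); the original study's MVSP preprocessing is
unstated, and covariance of raw frequencies is the default here.  Signs
follow a deterministic convention (largest-magnitude loading positive).
Classical (Torgerson) MDS — double-centring plus eigendecomposition —
replaces the nonmetric SPSS procedure of the source study because it is
deterministic and testable; negative eigenvalues are truncated and
counted.  Neighbor joining delegates to `ape::nj` behind a wrapper that
sorts labels first (the documented tie-break, making output independent
of input order), flags negative branch lengths and clamps them to zero
by default.  The study's published ordination coordinates and variance
fractions (e.g. PC1/PC2 = 44.00%/12.73%) depend on 19 external reference
populations' frequency tables that live in other publications, so they
are out of desk-scale reach; geometry is validated instead by exact
recovery of additive matrices, Procrustes error below $10^{-8}$ on
forward-generated embeddings, and agreement of variance fractions with
an independent eigensolver to $10^{-10}$.

## Synthetic data: what it emulates, what it does not

`simulate_hwe_population()` draws two independent allele copies per locus
(optionally with inbreeding $f$: $P(aa) = p^2 + fp(1-p)$; $f=1$ forces
homozygosity) under the study design defaults (214 individuals, 108
male).  `simulate_panel()` draws subpopulation frequencies from the
Balding-Nichols Dirichlet around the bundled ancestral frequencies —
chosen because it gives a *known true* $F_{ST}$ for parameter-recovery
experiments (the source study has no generative model at all).
`simulate_y_haplotypes()` either draws loci independently or realises an
exact multiplicity spectrum.  An LD-positive control copies one locus'
genotypes with probability $\rho$ — crude, but a tunable alternative for
power checks.  All generators require a seed and are byte-reproducible.

The generators deliberately omit stepwise mutation dynamics, allele-size
constraints, genotyping artefacts (dropout, stutter) and family
structure.  Passing calibration on these synthetic nulls therefore shows
the *statistics* are correct and calibrated under their stated model; it
does not certify behaviour on degraded casework data.

## Validation problem sizes

The suite reproduces every frequency-derived figure of the bundled
reference tables exactly (PIC/He/PE/TPI at 4 decimals, all 15 loci;
combined powers; Y diversities at 4-6 decimals); calibration experiments
use 1000 replicates for each equilibrium test null and 200
Balding-Nichols replicates at $F_{ST} \in \{0.01, 0.05, 0.1\}$ (two
populations of 100; observed mean relative bias under 4%, asserted under
15%).  Enumeration oracles (all pairings of a biallelic locus; all $4!$
genotype assignments) pin the Monte-Carlo tests at small $n$.

## Known limitations

* Frequency-only $\theta$ inherits the HWE approximation; use genotype
  mode when raw data exist.
* The Monte-Carlo HWE test is mildly conservative, as all exact
  conditional tests are.
* No kinship/mutation modelling: TPI is the only paternity-flavoured
  statistic, with no $\theta$-corrected match probabilities.
* External-database haplotype matching (YHRD-style) is out of scope.
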