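---
title: "SNP-based germplasm characterization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP-based germplasm characterization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(germsnp)
```

This vignette documents the statistical models behind `germsnp`, the
estimator choices where several conventions exist, and what the synthetic
data generator does and does not emulate. It is the package's reference for
every decision a user of the numbers should know about.

## The data model

All analyses operate on a `genotype_matrix`: diploid genotypes of *n*
accessions at *L* SNP sites, stored as two matrices of 0-based allele
indices so multiallelic records survive import. A call is either fully
observed or missing; half-missing VCF calls (`./1`) are demoted to missing
because a single observed allele supports neither a dosage nor a
heterozygosity statement. Phasing is ignored throughout — every statistic
here is a function of unordered genotypes.

Two locus-level quantities drive filtering:

* **MAF** — frequency of the second-most-frequent allele among observed
  gene copies (equal to `min(p, 1-p)` for biallelic sites, and still
  well-defined for multiallelic ones);
* **INT (locus integrity)** — the fraction of samples with a non-missing
  call, computed over the full matrix rather than per population, because
  filtering precedes any population stratification.

`filter_sites()` keeps sites with MAF ≥ 0.05 **and** INT ≥ 0.3, both
inclusive; the thresholds are arguments, those are only the defaults. The
filter is idempotent and never touches the sample set.

## Diversity estimators

Population diversity reports in the germplasm literature rarely print
their formulas, and several of the indices exist in both uncorrected and
small-sample-corrected forms. `germsnp` fixes one convention per index and
states it:

| Index | Formula | Notes |
|---|---|---|
| He | $1 - \sum p_i^2$ | uncorrected; biallelic maximum exactly 0.500 |
| H (Nei) | $\frac{2n}{2n-1}\left(1 - \sum p_i^2\right)$ | unbiased correction; *n* = diploids typed at the locus |
| Ne | $1 / \sum p_i^2$ | effective allele number, in [1, Na] |
| I | $-\sum p_i \ln p_i$ | natural logarithm, so the biallelic maximum is ln 2 ≈ 0.693 |
| PIC | $1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$ | Botstein estimator; biallelic maximum 0.375 |
| Ho | het calls / typed calls | direct count |

The corrected-vs-uncorrected split between H and He is deliberate: only
this combination lets H exceed 0.5 at small *n* (e.g. 2/3 when two
diploids are typed, 5/9 at five) while He stays capped at 0.5 — the
behavior you see in published range maxima. Crucially, *n* in the
correction is the number of individuals **typed at that locus within
the population being summarized**, not the population's census size;
otherwise every population would share one H ceiling.

`summarize_population()` evaluates all indices per locus over the
population's members only, skips loci with no data in that population,
and reports min/max/mean per index plus `A`, the count of loci at which
the population shows at least two alleles. `diversity_table()` stacks the
population rows and appends a `Mean` row that is the **unweighted**
arithmetic mean of the per-population means (and of `A`, rounded to an
integer) — the convention that makes published mean rows reproducible
from their population rows regardless of unequal sample sizes. Rendered
cells use `min–max(mean)` with three decimals; `parse_range_mean()`
inverts the rendering exactly.

## Hardy–Weinberg exact test

Fingerprint marker selection needs a HWE test that behaves at small
counts, so the package implements the conditional exact test: given the
observed allele counts, the heterozygote count ranges over values of
matching parity with a hypergeometric-type probability; the p-value sums
the probabilities of all configurations no more probable than the
observed one (two-sided, not mid-p). Probabilities are computed by the
numerically stable recurrence from the distribution's mode. The test
suite checks exact agreement with a direct factorial enumeration for
every genotype table with up to 50 individuals. A chi-square variant
(`hwe_chisq_test()`) is available for users who want the classical
approximation; the exact test is the default everywhere.

## Distances, trees, PCA, kinship

**p-distance.** Between two accessions, each co-typed locus contributes
half the number of allele mismatches between the unordered genotype
pairs (0, 0.5 or 1); the distance is the mean contribution, with
pairwise deletion of loci missing in either sample. This is the simplest
distance consistent with "proportion of differing sites" on unphased
diploid data; it is computed on the dosage view, i.e. multiallelic sites
are collapsed to reference/non-reference. A pair sharing no typed locus
is an error, not a silent zero.

**Neighbor joining.** Tree construction is the classical Saitou–Nei
agglomeration. The package delegates the agglomeration to `ape::nj()`
(a reference implementation of exactly that algorithm) and clamps
negative branch lengths to zero afterwards; on additive inputs the tree
reproduces the input distances exactly, which the tests verify against
path-length matrices of randomly generated trees. Bootstrap support
resamples loci with replacement, rebuilds the tree per replicate, and
scores each internal edge by the fraction of replicates containing the
same leaf bipartition (`ape::prop.clades`); the resampling is
deterministic under a user seed. The default of 1000 replicates is the
field's convention; the test and example workloads use 30–100 replicates
on panels of tens to a couple hundred samples, which keeps each run in
seconds.

**PCA.** Missing dosages are mean-imputed, then each locus is centered
by $2\hat p$ and scaled by $\sqrt{2\hat p(1-\hat p)}$ — the
allele-frequency standardization of EIGENSOFT-style genotype PCA —
monomorphic loci dropped, and the coordinates taken from the singular
value decomposition. Variance fractions are eigenvalues over the trace,
so they are non-increasing and sum to at most 1.

**GRM.** The genomic relationship matrix uses the same standardized
dosage matrix X: $G = XX^\top/L$. Under Hardy–Weinberg the diagonal
averages about 1 and unrelated pairs score about 0, which the tests
assert on unstructured simulations.

**Tree cutting and concordance.** `cut_tree()` turns a tree into k leaf
groups by deleting the longest edges first — internal edges before
terminal ones, each deletion kept only if it increases the number of
leaf groups. (A pure "k−1 longest internal edges" rule cannot reach
k = n singleton groups, which we consider a legitimate request; the
greedy rule subsumes it.) Whether published clade labels come from such
a cut or from manual annotation is usually unstated; the cut rule here
is the package's explicit, documented choice. `partition_concordance()`
matches the two label sets by the maximum-agreement assignment over
label bijections — found by exact search on the contingency table, exact
for the ≤ 8-cluster cases this package targets — and reports the agreeing
fraction. Published concordance percentages rarely define their matching
rule, so the package documents its own and makes no claim of reproducing
any specific published figure.

## Core markers and fingerprint barcodes

`select_core_markers()` applies, in order: biallelic only → integrity
= 1.0 (no missing calls) → MAF ≥ 0.20 → PIC ≥ 0.35 → HWE exact p > 0.01
→ adjacency exclusion → per-window thinning. Two interpretation choices
deserve note:

* **Adjacency** is judged against the *unfiltered* variant set: a rare
  variant that failed every other filter still disqualifies a candidate
  within 100 bp, the conservative reading for assay robustness (any
  nearby polymorphism can disturb primer or probe binding).
* **"Uniform genomic distribution"** is operationalized as per-window
  thinning — default one marker per 1 Mb window, keeping the highest
  PIC — because no published procedure exists to copy; window size and
  quota are criteria fields. HWE is tested over all samples jointly,
  matching a single-panel design rather than per-population testing.

The audit trail records the first criterion that removed each rejected
site, so panel designers can see what the binding constraints are. Note
that the integrity criterion is genuinely severe: at 213 accessions even
0.5% random missingness leaves almost no complete locus, so panels with
missing data should be fingerprinted only after imputation or with a
relaxed `integrity_min` — the default reproduces the strict
complete-data convention.

Fingerprint cards map each marker to one state character — the base
letter of a homozygote, `H` for heterozygous, `N` for missing — with the
conventional colors (yellow C/C, green A/A, blue T/T, purple G/G, white
heterozygous, gray missing). The payload `sample|states` is the
contract; rendering it as a QR/barcode image is presentation-layer
plumbing left to the caller. `decode_fingerprint()` inverts the encoding
exactly for homozygous, heterozygous and missing states; the scheme is
deliberately lossy for heterozygotes (all render white), which the
decoder documents rather than hides.

## In silico double digestion

Enzymes are IUPAC recognition sequences with a cut offset (HaeIII GG^CC
offset 2, Hpy166II GTN^NAC offset 3, the REBASE blunt-cut conventions).
Matching is case-insensitive with overlaps allowed; fragments between
consecutive cuts tile the sequence exactly, each carrying its flanking
enzyme provenance and its soft-masked fraction. Tags are fragments with
*both* flanks enzymatic (sequence ends excluded) inside the length
window, 364–394 bp by default — the standard double-digest
reduced-representation tag definition. Scheme scoring reports tag yield,
a duplication rate (tags whose uppercase sequence recurs among tags, or
with more than half their bases soft-masked — the repeat proxy, since no
formula for "duplication in repetitive regions" is standard), and the
coefficient of variation of tag counts over fixed genomic bins (1 Mb
default) as the uniformity measure. Coordinates are 0-based half-open
internally and in anything BED-like; only VCF output is 1-based.

## The synthetic data generator

`simulate_population()` draws, per locus, an ancestral frequency
uniform on [`maf_floor`, 1 − `maf_floor`], then per ancestral cluster a
Balding–Nichols frequency Beta(p(1−F)/F, (1−p)(1−F)/F) — the standard
generative model for populations diverged at a given FST. Each labeled
collection population is anchored to a primary ancestral cluster
(assigned round-robin) with base ancestry 0.9 on that cluster; each
sample draws its ancestry proportions from Dirichlet(α·base) and its
genotype from Binomial(2, q) at the ancestry-mixed frequency q, followed
by independent per-call missingness. Defaults: K = 3 clusters at
FST = 0.1, eight populations of 29/29/10/9/11/29/35/61 accessions
(213 total), 5000 loci over 12 chromosomes, 5% missingness, α = 30.
The concentration α = 30 with a 0.9 base makes most accessions nearly
pure with a minority of visibly mixed ancestry — a realistic germplasm
panel in which ancestral clusters remain identifiable, so that
structure-recovery checks have a defined truth (the argmax ancestry).
Monomorphic loci are retained on output; removing them is the MAF
filter's job, and the filter deserves real work in tests.

What the generator does **not** emulate: linkage disequilibrium (loci are
independent), inbreeding and selfing (genotypes are HWE given q), allele
frequency spectra of real SNP discovery (no ascertainment bias),
genotyping error, and informative missingness (dropout is uniform). Tests
passing on this generator therefore validate the estimators and the
pipeline contracts, not robustness to those real-data features.

`simulate_genome()` produces uniform-random A/C/G/T with contiguous
soft-masked blocks (mean 500 bp) totaling a target fraction — enough
texture for digestion experiments, with no claim of modeling real repeat
families.

## Problem sizes and numerical choices

The shipped tests and examples run the full pipeline at 213 samples ×
1200–5000 loci, bootstrap at 30–100 replicates on ≤ 213 samples, and
oracle comparisons (exact HWE vs enumeration at n ≤ 50; NJ vs additive
path lengths at 4–8 taxa; IUPAC matching vs a sliding window at ≤ 10 kb)
— sizes chosen so the whole suite completes in about a minute while the
Monte-Carlo checks keep comfortable error margins. Frequency-vector
inputs are validated to sum to 1 within 1e-9; NJ Q-matrix ties resolve
to the lowest-index pair inside `ape::nj`, and bootstrap determinism
comes solely from the user-supplied seed. Degenerate inputs error
loudly: all-missing sites for MAF/Ho, pairs with no shared loci,
matrices without polymorphic loci for PCA/GRM, zero-sample datasets for
writers.
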