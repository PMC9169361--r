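---
title: "Quantifying APOBEC mutagenesis: enrichment scoring, signatures, and immune context"
author: "ApobecSig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying APOBEC mutagenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ApobecSig)
```

## The biology and the score

APOBEC cytidine deaminases attack cytosines in single-stranded DNA,
preferentially when the cytosine sits in a TCW trinucleotide (W = A or
T). The damage resolves as C>T transitions and C>G transversions, so a
tumor shaped by APOBEC activity carries an excess of C>T/C>G mutations
in TCW relative to what its local sequence composition would produce by
chance. The per-sample **APOBEC mutagenesis enrichment score (AMES)**
makes that comparison explicit:

$$
\mathrm{AMES} \;=\;
\frac{n_{\mathrm{TCW\to TTW}} + n_{\mathrm{TCW \to TGW}}}
     {n_{\mathrm{C\to T}} + n_{\mathrm{C \to G}}}
\;\times\;
\frac{n_{\mathrm{C}}^{\mathrm{bg}}}{n_{\mathrm{TCW}}^{\mathrm{bg}}}
$$

The first factor is the fraction of the sample's (pyrimidine-normalized)
C>T/C>G mutations that fall in a TCW motif; the second is the inverse of
the background motif fraction, where the background counts cytosines and
TCW motifs on both strands within ±20 bp of each counted mutation. A
score of 1 means TCW mutations occur exactly at the background rate;
values above 1 indicate enrichment. Samples are conventionally
stratified at cutoffs 1 and 2 into low / moderate / high (L/M/H)
enrichment levels.

Conventions worth stating precisely, because the published definitions
leave them open:

* **Purine-reference calls are reverse-complemented** (G>A in a WGA
  context is the same event as C>T in TCW), so both strands contribute.
* **C>A mutations are excluded from both numerator fractions** — the
  score is defined over C>T and C>G only.
* **Background windows are summed per mutation**, not unioned: the
  background is a per-mutation weighting, and a union would under-weight
  clustered mutations (exactly the kataegis-like clusters APOBEC
  produces). Overlapping windows therefore count shared bases once per
  mutation.
* **Background motifs** are counted when the motif start lies within the
  window and the motif fits on the contig.
* **Stratification intervals are left-closed**: a score of exactly 1
  is "M", exactly 2 is "H". Undefined scores (no C>T/C>G mutations, or
  no background TCW) propagate as `NA`, never as 0.
* **Reference-mismatch records are excluded, not corrected**: silently
  fixing alleles would corrupt motif counts. Exclusions are flagged and
  tallied.

## Mutational signatures

`buildContextMatrix()` stratifies each sample's SNVs over the 96
pyrimidine-normalized trinucleotide channels, ordered
substitution-major (C>A, C>G, C>T, T>A, T>C, T>G) and then by upstream
and downstream base — the de-facto catalog ordering, so user-supplied
SBS tables align row-wise.

`extractSignatures()` factorizes the channels × samples matrix with
multiplicative-update NMF under the Kullback–Leibler objective, the
natural choice for count data. Each rank k in the candidate range is
fitted from `nRestarts` random initializations; the best objective is
kept and the profiles are column-normalized with the scale absorbed
into the exposures. Rank stability is measured Brunet-style: every
restart assigns each sample to its dominant signature, the consensus
matrix averages co-assignment over restarts, and the **cophenetic
correlation** compares consensus distances with the average-linkage
dendrogram distances. At k = 1, and for a perfect consensus, the
coefficient is defined as 1.

`selectRank()` operationalizes "the rank where the cophenetic
coefficient begins to drop": it returns the largest k immediately
before the first successive drop exceeding 0.05 (configurable), falling
back to the argmax — ties toward the smaller rank — when no drop is
that large. Consensus-based rank selection needs enough restarts to
expose instability at the wrong ranks; 30 restarts per rank is the
setting we validate at, and fewer than ~10 makes the coefficient
unreliable on clean data.

A deliberate method choice: we use standard KL-NMF with restarts rather
than an automatic-relevance Bayesian NMF. Published descriptions of the
latter in this context leave its hyperparameters unstated, while the
cophenetic procedure is fully specified — so rank selection carries the
model-choice burden, and the factorization itself stays simple and
reproducible (one master seed; per-(k, restart) streams derived
deterministically).

`annotateSignatures()` labels each de novo profile with the
maximal-cosine entry of a reference catalog (96-row TSV in the fixed
channel ordering; `exampleCatalog()` ships four synthetic profiles for
tests, and real COSMIC v3.2 SBS tables in the same shape drop in via
`readSignatureCatalog()`). Matches under cosine 0.8 are "unassigned".
`fitExposuresNNLS()` fits per-sample exposures by Lawson–Hanson
non-negative least squares against fixed profiles, in mutation-count
units, reporting per-sample residual norms.

## Burden, DDR status, co-occurrence

`computeTMB()` counts non-synonymous mutations per megabase with the
conventional 38 Mb whole-exome size. The non-synonymous class list
(frameshift and in-frame indels, missense, nonsense, nonstop, splice
site, translation start site) is a policy object; unknown terms fall
through to synonymous with a warning. `ddrStatus()` flags a DNA damage
response pathway as mutated when any of its genes carries a non-silent
mutation, and a sample as DDR-Mut when any pathway is flagged. The
bundled pathway map covers ten commonly assigned genes across NER, HRR,
FA, MMR, NHEJ and TLS and is deliberately partial — production analyses
should supply their own `readPathwayMap()` TSV.
`pairwiseCooccurrence()` applies the standard somatic-interaction
convention (per-gene binary presence; genes mutated in fewer than 3
samples skipped), a two-sided Fisher exact test per gene pair, and
Benjamini–Hochberg adjustment across all tested pairs.

## Expression scores

`ssgseaScore()` implements single-sample GSEA: per sample, genes are
ordered by decreasing expression and the enrichment score is the summed
difference between the weighted in-set empirical CDF (weights
rank^α, α = 0.25 by default, raw unnormalized scores by default) and
the uniform out-of-set CDF. Ties are broken by stable input gene order
— the published description of the algorithm is silent on ties, and a
documented deterministic rule beats an undocumented one. Because the
score depends on ranks only, it is exactly invariant to per-sample
location shifts and to any strictly monotone transform; tests assert
both. `cytScore()` is the cytolytic activity score — the geometric mean
of PRF1 and GZMA on linear TPM, with an offset of 0.01 so zero
expression is handled (log2 input is back-transformed). A T
cell-inflamed GEP or any other gene set is supplied as data (GMT via
`readGMT()`); likewise a linear Cox-coefficient risk signature such as
a 21-gene APOBEC-related score is a (gene, coefficient) table applied
by `applyLinearSignature()` on the log2 scale, with a cohort-median
split by default. The package consumes such signatures; it does not fit
them.

## What the synthetic generators emulate

The generators exist so every stage is testable without cohort
downloads; their defaults are the study conditions the validation suite
runs at.

* `simReference()` draws an i.i.d. contig at a chosen GC fraction
  (default 0.5, 10 kb in the validation runs) — long enough that ±20 bp
  windows and motif counts are well populated.
* `plantMutations()` places, per mutation, a C>T-or-C>G change on a
  uniformly chosen TCW cytosine with probability w (the APOBEC weight)
  and on a uniformly chosen cytosine otherwise, both strands, positions
  without replacement per sample. At w = 0 the motif mutation fraction
  matches the background by construction, so the expected AMES is ~1 —
  the analytic null that calibration tests check (mean over 200 samples
  of 200 mutations within 1 ± 0.05) — and the mean score rises strictly
  with w across a 0–0.8 grid. The background process draws cytosines
  only: AMES concerns C>T/C>G fractions, and an all-base background
  would merely dilute counts without moving the null away from 1.
* `simSignatureCounts()` draws each sample's 96-channel counts as a
  multinomial over the planted profile mixture; `simExposures()` gives
  each sample a dominant signature (70% of its 2,000 mutations,
  round-robin assignment, remainder split evenly). The dominance
  structure mirrors real cohorts, where most tumors are driven by one
  leading process — and it is what consensus-based rank selection
  measures; symmetric mixtures have no co-clustering structure for the
  cophenetic coefficient to see.
* `simExpression()` plants a log2 shift (default +2) on chosen gene
  sets in one of two groups over Normal(5, 2) baselines with unit
  noise.

What the generators do **not** emulate — and hence what passing tests
do not demonstrate about real data: human genome composition
(replication timing, chromatin state, CpG depletion), indels and copy
number, kataegis clustering beyond window overlap, signature profiles
with overlapping support as blurred as some real SBS pairs, or
heavy-tailed expression with batch structure. Results on real cohorts
additionally depend on variant-calling quality, which the package takes
as given.

## Numerical choices and limitations

* NMF: objective tolerance 1e-6 (checked every 10 iterations), at most
  2,000 iterations, entries floored at 1e-10 to keep the KL updates
  defined; uniform random initialization in [0.1, 1].
* NNLS: active-set tolerance 1e-10, QR solves on the passive set,
  iteration cap 30·k; exact on noiseless inputs to well below 1e-6
  relative error and matching an independent solver to 1e-8.
* Cosine similarities are reported to 3 decimals in annotations.
* Validation problem sizes: 10 kb genomes, 50–200 samples, 100–200
  mutations per sample for AMES; 60 samples × 2,000 mutations, ranks
  2–5, 30 restarts, 10 replicates for signatures; 400 genes × 30
  samples, 20 replicates for ssGSEA. These sizes make the full suite
  run in minutes on one CPU while keeping Monte-Carlo error far from
  each test's margin.
* The 9,550-of-9,765 scored-sample fraction seen in large cohort
  analyses implies some samples are unscorable; here that surfaces
  as `NA` scores (zero counted mutations or zero background TCW), and
  `minCMut` optionally suppresses low-count samples — default 0, i.e.
  no filtering, since no published exclusion rule exists to encode.
* Not in scope: variant calling and annotation, driver detection,
  deconvolution (CIBERSORT/ESTIMATE), LASSO/Cox model fitting,
  per-signature boosted scoring (underspecified in the literature),
  and transcriptional strand-bias channels.

## A worked example

```{r example, eval = FALSE}
ref <- simReference(10000, gcFraction = 0.5, seed = 1)
sim <- plantMutations(ref, nSamples = 20, mutsPerSample = 200,
                      apobecWeight = 0.6, seed = 2)
muts <- attachContext(sim$muts, ref, flank = 20)

ames <- amesScore(muts, ref)
table(ames$level)

cm <- buildContextMatrix(muts)
cand <- extractSignatures(cm, kRange = 2:4, nRestarts = 30, seed = 3)
k <- selectRank(cand)
sigs <- annotateSignatures(cand[[as.character(k)]], exampleCatalog())
fit <- fitExposuresNNLS(cm, sigs)
head(exposures(fit))
```
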