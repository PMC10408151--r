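---
title: "Cross-protein transfer models for missense variant effect prediction"
author: "cptransfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-protein transfer models for missense variant effect prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cptransfer)
```

## The problem and the model

Most missense variants in the human proteome have unknown clinical
consequences. Deep mutational scanning (DMS) assays measure a fitness
score for thousands of single amino-acid substitutions in one protein,
but cannot be run for every protein. Cross-protein transfer (CPT)
models square this circle: they are trained on DMS data from a handful
of proteins and applied to proteins never seen during training, using
only features that are available proteome-wide.

For a variant $(g, i, a_{wt}, a_{mut})$ — gene, 1-based residue
position, wild-type and mutant amino acid — the model combines:

* **Protein homology scores.** Two external model scores consumed as
  log-probability columns (a deep alignment-based log-probability and a
  masked-LM log-probability ratio). These are always included.
* **Shallow alignment conservation.** From a 100-row vertebrate and a
  30-row mammal query-anchored alignment: the wild-type, mutant and gap
  frequencies at the variant's column, each transformed as
  $\log(f + 1)$ (range $[0, \log 2]$, strictly monotone).
* **Structure features.** Sidechain–sidechain contact count and
  per-residue pLDDT, plus two *structure-conditioned scores*: residue
  frequencies recomputed after restricting the deep alignment to rows
  matching the human amino acid at up to two contacting residues.
* **Descriptor deltas.** Component-wise differences
  $D(a_{mut}) - D(a_{wt})$ of amino-acid descriptor scales encoding
  charge, polarity, hydrophobicity, size and flexibility.

One linear sub-model is fitted **per training protein** — logistic
regression on percentile-binarised labels for clinical classification,
least squares on raw assay scores for regression — and the ensemble
prediction is the average of the sub-model outputs. Because the
sub-models carry their own intercepts and slopes, between-protein batch
effects (assay offsets and scalings) never leak into a single pooled
fit; averaging then cancels the idiosyncrasies of any one protein.

## Key procedural choices

**Percentile binarisation.** DMS score distributions differ markedly
between proteins, so for classification the top 40% of each protein's
variants are labelled functionally normal and the bottom 40%
functionally abnormal; the middle 20% is discarded. Counts are exactly
$\lfloor 0.4 n \rfloor$ per class; ties are broken by stable input
order so the split is deterministic even for degenerate score vectors.
The fractions are configuration values (`trainingConfig`) — results are
not very sensitive to the exact threshold.

**Protein-reweighted rescaling.** Features are scaled to unit standard
deviation, with the standard deviations computed after reweighting each
training protein's rows to total weight one, so large proteins do not
dominate the scale. Frequency-derived features (the six alignment
frequency columns and the two conditioned scores) live on the bounded
$[0, \log 2]$ scale already and are exempted — their scale is exactly
1. Features are never mean-centred; the per-protein intercepts absorb
location.

**Isoform reconciliation.** When an alignment was built for a different
isoform, a local pairwise alignment (match +5, mismatch −4, gap open
−4, gap extend −0.5, with the opening score charged on the first gapped
residue) maps its columns onto the canonical sequence. Canonical
positions outside the aligned fragment are *missing*, not zero, and
flow to imputation. A best local score of zero or less marks the whole
gene missing rather than raising an error.

**Frequency denominators.** All column frequencies count the query row
in the denominator by default (`includeQuery = TRUE`), making the
wild-type frequency strictly positive; the switch is exposed because
the alternative convention is equally defensible. Unknown residues
(`X`) count toward the denominator but never toward wild-type or mutant
counts.

**Structure conditioning.** Only residues with pLDDT > 70 may condition
and a position at or below 70 gets no conditioning; at most the two
contacts where the human amino acid is most frequent in the deep
alignment are used, ranked ties breaking to the lower residue index.
If the filter retains fewer than `minFilteredRows` (default 1) rows,
the conditioned scores are missing and are completed by cross-gene
imputation. With an empty conditioning set the conditioned scores equal
the unconditioned frequencies exactly — a property the tests assert.
Contacts come from precomputed lists when available; the built-in
fallback declares a contact when any two sidechain heavy atoms of
different residues are within 4.5 Å, which means glycine never forms
contacts.

**Long proteins.** Masked-LM scores for proteins longer than 1022
residues are computed in 1000-residue windows whose starts are 250
apart, the final window right-aligned to the protein's C-terminus so
the tail keeps full context (the tail convention is configurable). Each
variant takes the score from the covering window whose centre —
$(start + end)/2$ — is nearest, earlier windows winning ties.

**Weighted KNN imputation.** To impute a target column within a gene,
the five features most highly rank-correlated with it (absolute
Spearman $\rho$; the sign is irrelevant to Euclidean geometry, and a
signed variant is available) are standardised and multiplied by
$|\rho|$; the target is standardised with weight 1. Distances are
nan-Euclidean — computed over mutually observed dimensions and rescaled
by total/observed dimension count — and a missing cell becomes the
unweighted mean of the ten nearest observed rows, distance ties
breaking to the lower row index. Constant columns have undefined
$\rho$, treated as 0 and excluded; if *no* helper survives, the
distance space is zero-dimensional, every reference row is equidistant
and the tie-break makes the prediction the mean of the first ten
reference values. Genes with too few observed targets (fewer than
`nNeighbors + 1`) fall back to cross-gene imputation: imputers fitted
on the training genes each predict the column and their predictions are
averaged; query-row standardisation reuses the reference means and
standard deviations rather than refitting them on the new gene.

**Feature selection.** The two homology columns are always included.
Step one walks the categories in a fixed order — 100-vertebrate,
30-mammal, inverse-folding, conditioned scores — and exhaustively
scores every non-empty subset of each non-empty category by the mean
leave-one-protein-out (LOPO) validation metric (AUROC for
classification, Spearman for regression), appending the best subset.
Step two adds descriptor features by forward selection while the metric
strictly improves. Ties resolve to the earliest enumerated candidate,
so selection is fully deterministic.

**Regularisation.** Sub-models carry a tiny ridge penalty
($10^{-6}$, intercept unpenalised) purely to stabilise collinear
features; tests that compare against closed-form least squares set it
to zero. Classification ensembles average predicted probabilities; a
switch averages linear predictors instead, since either reading of
"averaging the model predictions" is defensible.

## Evaluation conventions

Higher score means more damaging throughout; adapters for predictors
with the opposite polarity must flip signs upstream. AUROC uses the
rank (Mann–Whitney) formulation with half-credit ties. Specificity at
sensitivity $s$ uses the most stringent threshold whose sensitivity is
at least $s$ (not the nearest operating point), and reports the benign
fraction strictly below it. Per-gene AUROC is restricted to genes with
at least four benign and four pathogenic variants. Spearman's $\rho$
uses average ranks for ties and is undefined (missing) for constant
vectors.

## What the synthetic generator emulates — and what it does not

`generateFamily()` produces a six-gene family (by default) with:

* random query sequences of 60–90 residues and per-position
  conservation strengths drawn from $[0.30, 0.98]$; alignment rows
  retain the query residue with that probability and otherwise
  substitute (or gap, at rate 0.08);
* a compact random backbone chain (3.8 Å steps, biased back toward the
  origin) whose 6 Å neighbours define contacts, with pLDDT highest in
  contact-dense regions;
* external predictor columns that are noisy monotone functions of a
  conservation/burial fitness axis;
* DMS scores that are an exact per-protein affine transform of the
  linear latent $w^\top x$ over the realised feature values, plus
  Gaussian noise at 20% of the latent's standard deviation by default;
* labels that threshold the noise-free latent at its per-gene 35%
  quantile.

All randomness flows from one seeded generator, so identical seeds
yield byte-identical bundles and pipeline outputs. Because the DMS
score is *constructed* to be affine in the features, the noise-free
family is a sharp parameter-recovery instrument: LOPO regression must
reach held-out $\rho \ge 0.99$ and recover every generative
coefficient sign in every sub-model, and it does so exactly.

What the generator does **not** emulate: phylogenetic correlation
between alignment rows (rows are independent given the conservation
profile), realistic protein geometry or contact order, non-linear
genotype–phenotype maps, and label noise in clinical annotations.
Passing the synthetic tests therefore demonstrates procedural
correctness — that every stage computes what it claims under known
generative structure — not clinical-grade accuracy on real data, which
depends on external alignments, structures and predictor scores.

## Problem sizes and runtime

The default study uses 6 genes × roughly 200–270 variants each
(three mutants per position), alignment depths 100/30/120 and a
120-row deep alignment for conditioning. The full pipeline —
simulate, featurize, impute, LOPO-train both tasks, evaluate — runs in
a few seconds on one CPU; the brute-force oracle comparisons in the
test suite (200 random imputation tables, window stitching at every
position of a length-3000 protein, 500 random metric vectors) complete
in about a minute.

## A worked run

```{r pipeline}
res <- runPipeline(generatorConfig(seed = 7))
res$report
```

The report pools leave-one-protein-out classification predictions over
all six genes (global and per-gene AUROC, specificity at 90/95/99%
sensitivity against the synthetic benign/pathogenic labels) and shows
the per-gene Spearman correlation of the held-out regression
predictions with the assay scores.

## Known limitations

* The descriptor table bundled by default is built from published
  aaindex amino-acid indices covering the standard property classes;
  the specific named descriptor sets used in the clinical literature
  (Z-scales, VHSE, Cruciani, ST-scales, ProtFP, Georgiev indices) can
  be supplied as 20-row CSVs via `readDescriptorTable()`.
* The contact fallback is a distance rule over sidechain heavy atoms,
  not a dot-surface method; precomputed contact lists are accepted
  verbatim where fidelity to surface-based contacts matters.
* Exhaustive subset search in step-one selection is exponential in the
  per-category feature count; it is intended for the small category
  sizes used here (three frequency features per alignment source).
* Cross-gene imputation assumes the helper columns are on comparable
  scales across genes, which holds for the bounded frequency features
  it is used for.
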