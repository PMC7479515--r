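---
title: "Cell states, metaprograms and copy-number inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell states, metaprograms and copy-number inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scstates)
```

This vignette is the package's account of its own methods: the models and
rules each stage implements, the assumptions they rest on, the parameters
a user might want to turn, and the design decisions made where more than
one reasonable choice existed. The README shows the workflow; here we
explain why it is built the way it is.

## Expression scales and preprocessing

The pipeline distinguishes four scales, tracked by an attribute on the
matrix so a function applied to the wrong scale fails loudly rather than
silently producing nonsense:

* **TPM** — within-cell normalized expression, columns sum to 10^6.
* **E** — `log2(TPM/10 + 1)`. The division by 10 compensates for the fact
  that a full-length single-cell library samples on the order of 100,000
  transcripts, so TPM overstates the real counting depth about tenfold;
  without it, low counts would receive inflated log expression.
* **Er** — relative expression: E centered per gene across the cells of a
  centering group, normally one anatomical compartment (PF, ST, SP).
  Centering within compartments keeps compartment-level differences from
  dominating every downstream correlation; for pan-compartment analyses
  the same function re-centers across all cells.
* **Ea** — `log2(mean(TPM) + 1)` per gene, the population expression level
  used to match control genes of comparable abundance.

Quality control mirrors standard practice for each platform. Smart-seq2
cells need ≥ 2000 detected genes (TPM > 0) and mean housekeeping E ≥ 2.5;
"detection" at zero is the field convention, and the housekeeping list is
a configuration input because no canonical list is universal — synthetic
runs use the generator's housekeeping module. Genes are kept when TPM > 10
in at least 10 cells; cells are filtered before genes. UMI cells are kept
when their detected-gene count lies within [mean/2, 2·mean] of the
pre-filter mean — computed once over the input cells, the simplest reading
of a cohort-level window — and their mitochondrial UMI fraction is ≤ 5%.

## Copy-number inference

Expression-based CNA inference assumes that a chromosome-arm dosage change
shifts the expression of most genes on the arm in the same direction, and
that averaging ~100 adjacent genes cancels gene-level biology while
preserving the dosage shift. Genes are ordered by chromosome and position
(numeric-aware chromosome ordering, stable sort), Er is clipped to ±3 so a
single extreme gene cannot mimic an arm event, and a dense sliding window
(step 1, default size 100) is averaged within each chromosome. Chromosomes
shorter than the window collapse to a single window so that every
chromosome stays represented.

Calls are made against spike-in reference cells: profiles of queries and
references are clustered together (1 − Pearson distance, Ward linkage) and
the tree is cut into `k` clusters (default 2 per sample). Clusters holding
at least 50% of all reference cells define the CNA-negative class; cells
elsewhere are CNA-positive. When every pairwise distance is numerically
identical (flat or identical profiles) there is no structure to cut and
all cells form a single negative cluster. The per-cell *signal* is the
mean squared window deviation from the references' mean profile. The
deviation is taken from the reference baseline, not from zero: in a
malignant-majority sample per-compartment centering places the cohort mean
near the malignant profile, so deviation from zero would score the normal
cells highest and invert the ranking. In synthetic runs the generator's
normal cells serve as references; real runs accept any user-supplied
reference matrix on the same window index.

## Malignancy classification

Cells are clustered on Er by principal components (default 20) followed by
Ward clustering — chosen over graph clustering because it is fully
deterministic, which the test suite requires, and equivalent in practice
at these sizes. Deliberate overclustering is recommended (we use k ≈ 2–3×
the expected number of populations) so each normal cell type can form its
own cluster; extra malignant subclusters are harmless because labels
attach per cluster. A cluster is labeled with a normal type when the
cluster mean of that type's control-matched marker score exceeds 1 and
beats every other type; the threshold mirrors the cycling-call scale since
no separate marker cutoff is canonical. Exact ties go to the
lexicographically first type and are logged.

Final classes integrate both sources of evidence: *normal* = marker
cluster and CNA-negative; *malignant* = CNA-positive outside marker
clusters; anything discordant is *excluded* rather than guessed — with one
escape hatch: samples listed in an override configuration have their
CNA-negative, non-marker cells rescued as malignant, the treatment needed
for tumors whose CNAs are below detection. CNA-positive cells inside a
marker cluster stay excluded (the conservative reading). Cross-sample
rescue by co-clustering is reduced to this per-sample switch.

## Metaprogram discovery

Per-sample programs come from NMF on the sample's malignant cells:
negative Er values are set to zero (relative expression above the
compartment mean is what defines a program), genes are restricted to the
most over-dispersed (binned variance z-scores: genes are ranked into 20
equal-frequency bins of mean log expression and each gene's variance is
z-scored within its bin — a transparent stand-in for tool-specific
overdispersion models, keeping the "variable relative to peers of equal
abundance" logic). The default of 10,000 genes retains everything in
desk-scale synthetic genomes; the factor count is a configuration choice
(10 is the reference default for patient samples) and deliberately
generous, since redundant factors merge downstream.

The solver uses multiplicative updates under the Frobenius objective with
a non-negative double-SVD initialization. The combination is fully
deterministic — no random restarts — which makes results reproducible
without seed bookkeeping; the objective is non-increasing per iteration
(asserted in tests to 1e-9 relative) and iteration stops at a relative
improvement below `tol` (default 1e-6) or `max_iter` (default 300). Zero
entries of the initialization are filled with a small data-scaled constant
(mean(V)/100) because multiplicative updates cannot move exact zeros.

Each factor is represented by its top-30 weight genes (ties broken by gene
id). Factors from all samples of a compartment are scored on all the
compartment's cells and clustered on the Pearson correlation of their
score vectors (1 − r, Ward). The tree is cut at every possible number of
clusters, coarsest first, and the first cut in which every multi-program
cluster has mean pairwise correlation above 0.5 is kept — the coarsest
merge consistent with the retention rule, so duplicated programs always
merge and orthogonal programs never do. Singletons are dropped unless
whitelisted (the manual-inspection escape). Retained clusters merge into
metaprograms by taking the top 30 genes of the members' average weight
vector, with absent genes counting as weight zero.

Signature genes per assigned population use a one-vs-rest Wilcoxon
rank-sum test on uncentered log expression with three filters: Bonferroni
p < 0.05 over tested genes, mean difference ≥ 1 on the log2 scale (a
2-fold change, computed as a difference of means of log values, consistent
with the log-scale input), and detection in ≥ 50% of the population's
cells. The rank-sum p value uses the normal approximation with tie and
continuity corrections, verified in tests against `stats::wilcox.test`.

## Scoring, states and cycling

The control-matched score `SC(i) = mean(Er(G, i)) − mean(Er(G_cont, i))`
corrects for the cell-complexity component of a raw signature mean. Each
signature gene contributes the 100 genes nearest in Ea (excluding itself,
ties by gene id); the controls of all signature genes are pooled with
multiplicity — a 100-fold larger control set — which is arithmetically the
same as averaging per-gene paired differences. The unbiasedness this buys
is what the null-calibration test measures: each cell's mean score across
200 random 30-gene signatures on signal-free synthetic data stays well
inside ±0.05 (the per-signature mean across cells is identically zero by
centering, and the per-cell spread of any single random signature is
irreducible sampling noise, so the per-cell expectation is the meaningful
null quantity).

Cells take the metaprogram with the maximum score (lexicographic
tie-break, logged). Cycling is called when the larger of the S-phase and
G2M scores strictly exceeds 1; the alternative reading (both below 1 for
non-cycling) differs only when one score is high and the other low, and
the max-rule is the one we implement and document. The NSC score is the
stem-like program score minus the larger of the two differentiation
program scores (glial-progenitor, ependymal); non-stem cells (NSC score
≤ 0) get a lineage score, glial minus ependymal — positive toward glial —
with the sign convention fixed here.

## Program comparison and regulon aggregation

Pan-compartment comparisons re-center expression across all cells, score
every metaprogram on the common cell set, and correlate score vectors;
zero-variance vectors yield missing correlations rather than arbitrary
values. Profile-to-reference comparisons correlate median expression
profiles restricted to pooled population-specific signature genes, the
restriction that keeps ubiquitous genes from inflating every correlation.
Cross-tumor gene classes use two thresholds on aggregated log2 expression:
common (> 3 in both tumor types — this rule takes precedence when both
apply), A-specific (> 3 in A and A − B > 2), B-specific symmetrically,
else none; precedence makes the classes a partition.

Binarized regulon activity (an upstream tool's output, consumed as data)
aggregates to the proportion of active cells per cell state. A regulon is
state-specific when its activity strictly exceeds 0.5 there and is at
least 1.5× its activity in every other state ("at least 50% greater" read
as non-strict); with any ratio above 1 the rule is exclusive, so a regulon
marks at most one state. The comparison spans the states present in the
supplied label table — within-compartment by construction when labels come
from one compartment.

## Bulk survival stratification

Bulk samples are scored exactly through the single-cell code path —
log-transform, pan-cohort centering, cohort Ea, control-matched scores —
with samples in the role of cells; a code-path equivalence test keeps the
two from drifting apart. Scores are split into high and low by 1-D Ward
clustering (median split available as a fallback; both are reported in
contexts where the choice matters), the high label going to the cluster
with the larger mean, invariant to constant shifts. Group separation is
tested by Kaplan-Meier estimation and the two-sample log-rank test from
the survival package; an independent observed-minus-expected
implementation serves as the oracle in tests. Progression-free and overall
survival are handled identically — the caller chooses the time/event
columns. Multivariable Cox modeling is out of scope; the cohort tibble is
already in the shape such tooling expects.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the
conditions under which the recovery guarantees are demonstrated.

*What it emulates.* A gene universe partitioned over chromosomes with p/q
arms and strictly increasing positions; disjoint planted modules — five
10-gene normal-type marker sets (microglia, T cell, OPC, oligodendrocyte,
endothelial analogues), five 30-gene tumor program modules, 30-gene S and
G2M modules, 50 housekeeping genes (given an 8× baseline so housekeeping
QC has signal). Baseline gene means are log-normal (meanlog 1, sdlog 1.2)
and counts are negative-binomial (dispersion 0.3, library size 2×10^5)
renormalized to TPM — the overdispersion regime the QC and variable-gene
stages assume; dispersion 0 gives Poisson counts for null configurations.
Malignant cells multiply their program module (and, for cycling cells, one
cell-cycle module) by `fold_up` (default 4); arm events multiply expected
expression of all genes on the arm *before* count sampling, reproducing
the dosage signal the window method detects; per-sample log-normal shifts
(sdlog 0.1) stand in for batch differences. Regulon activity is Bernoulli
within the target program with optional flip noise. Bulk cohorts mix
program mean profiles by a sampled composition; by default compositions
come from a two-component Dirichlet mixture (target-program fraction means
0.8 and 0.05, concentration 25, equal mixing) — modeling cohorts that
contain distinct high- and low-expressing patient groups, which is the
setting signature stratification addresses — while an explicit
`composition_prior` gives a single Dirichlet. Survival times are
exponential with hazard `h0 · exp(beta · fraction)` (default h0 = 0.02 per
month, beta = log 3) and censoring is an independent exponential whose
rate makes the expected censored fraction at beta = 0 equal `censor_rate`.

*What it does not emulate.* Read-level artifacts, doublets, ambient RNA,
gene-length effects, batch structure beyond mean shifts, subclonal CNA
heterogeneity, or correlated gene programs that are not planted modules.
Passing recovery tests therefore demonstrates that the implementation
extracts the signals it targets when those signals are present at
realistic strength — not that real tumors are this clean, nor that the
thresholds are optimal for any particular dataset.

## Problem sizes and reproducibility

The recovery analyses use sizes chosen to exercise every code path while
keeping a full run comfortable on a laptop: oracle comparisons on
200-gene × 20-cell matrices (agreement to 1e-12); CNA calling and
classification on three samples × 300 cells (20% normals, one gained and
one lost arm per sample, 3000-gene genome); metaprogram recovery on four
samples × 400 cells with three shared modules, per-sample NMF at k = 10 on
the top 1000 over-dispersed genes; survival power and calibration over 100
and 200 simulated 200-sample cohorts. All simulators take explicit seeds
and are bit-reproducible; `scripts/acceptance.R` reruns everything from a
single `--seed`.

## Known limitations

Dense matrices bound the practical size to a few tens of thousands of
cells; the CNA caller's ≥ 50%-of-references rule assumes references are a
coherent minority of each sample; the coarsest-valid-cut rule for program
clustering can merge two genuinely distinct but correlated programs that a
finer manual cut would separate; the overdispersion ranking is a
simplified model; and the per-sample override in classification is a blunt
instrument standing in for expert review of individual tumors.
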