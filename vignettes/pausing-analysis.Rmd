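---
title: "Promoter-proximal Pol II pausing: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter-proximal Pol II pausing: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polpause)
library(dplyr)
```

## The statistic

RNA polymerase II accumulates just downstream of the transcription start
site (TSS) at many genes before being released into productive elongation.
Single-nucleotide nascent-transcription assays (NET-seq, PRO-seq) turn this
accumulation into a per-base coverage signal, and the conventional summary
is the per-gene **pausing index**: the ratio of the promoter-proximal
signal density to the gene-body signal density,

$$\mathrm{PI}_g \;=\; \frac{\tfrac{1}{300}\sum_{i \in [\mathrm{TSS},\,
\mathrm{TSS}+300)} x_i}{\tfrac{1}{|B_g|}\sum_{i \in B_g} x_i},$$

with the body $B_g$ running from $\mathrm{TSS}+300$ to $\mathrm{PAS}-300$
for NET-seq-style data (the 3'-end of NET-seq genes carries a
termination-associated peak that would otherwise inflate the denominator)
and to the PAS for PRO-seq-style data. Both numerator and denominator are
implemented as *mean per-base densities*. The wording "signal in 300 bp
... divided by read density" admits a literal sum/density reading; we chose
density/density because it is the only convention under which PI is
unitless, equals exactly 1 on uniform coverage, and is invariant both to
global scaling (library depth) and to gene length — properties a fixed
threshold such as "ΔPI ≥ 0.5" implicitly assumes when applied across genes.
The literal reading remains available via `pausing_index(...,
numerator = "sum")`.

A gene with zero body density has an *undefined* PI (`NA`), never 0 or
infinity; downstream stages exclude such genes explicitly. This avoids
manufacturing extreme indices at silent genes, where the ratio is simply
not informative.

## Gene selection and eligibility

Three filters precede any pausing computation:

* **Biotype** — only coding genes are analysed (`biotype_filter =
  "protein_coding"`), but *all* annotated transcription units count as
  potential neighbours in the isolation filter.
* **Isolation** (`filter_isolated()`, flank 250 bp) — a gene is kept only
  when no other same-strand unit overlaps the 250 bp window upstream of its
  TSS or downstream of its PAS. Without this, promoter windows absorb
  read-through or divergent signal from neighbours. We test window overlap
  against any part of a neighbouring unit — a conservative reading of
  "within 250 bp" — and both windows reduce to the genomic intervals
  `[start−250, start)` and `[end, end+250)` regardless of strand.
* **Length and signal** (`filter_length()`, `eligible_genes()`) — strict
  inequalities: NET-seq keeps genes longer than 900 bp with body signal
  > 10 in *every* sample; PRO-seq keeps genes longer than 600 bp with any
  body signal in every sample. Applying the signal rule per sample (rather
  than pooled) is the strictest of the readings the wording admits; it
  guarantees every PI entering the differential stage is defined and not
  dominated by a single noisy replicate.

## Differential pausing

For conditions *ref* and *mut* with matched replicate indices,
$\Delta\mathrm{PI}_i = \mathrm{PI}_{\mathrm{mut},i} -
\mathrm{PI}_{\mathrm{ref},i}$. A gene is `increased` when all
$\Delta\mathrm{PI}_i > 0$ *and* $\overline{\Delta\mathrm{PI}} \ge 0.5$;
`decreased` symmetrically; otherwise `unchanged`; `excluded` when any PI is
undefined. Whether the 0.5 threshold was originally applied per replicate
or to an average is not determinable from the description; we default to
the mean (the weakest reading that still uses both clauses — sign
consistency and the 0.5 magnitude) and expose `per_replicate = TRUE` for
the stricter variant. The rule is exactly antisymmetric: swapping the two
conditions maps increased to decreased and fixes the other labels, which the
test suite asserts.

There is no per-gene significance test, by design: the analysis this
package operationalizes uses only the threshold-plus-consistency rule, and
the ratio form of PI is its implicit between-sample normalization.

## Quantiles, cross-link stratification, matching, breadth

* **Quantiles** — genes are ranked by the replicate-mean PI of the
  *reference* condition and cut into `k = 4` groups whose sizes differ by
  at most one; ties break lexicographically by `gene_id` so the split is
  deterministic.
* **Promoter binding** — a gene is "bound" when a same-strand cross-link
  interval overlaps `[TSS − 250, TSS + 300)`. No promoter definition is
  canonical here; this window reuses the two length scales already present
  in the analysis (the isolation flank and the pausing window) and is
  overridable (`window_up`, `window_down`). Windows are clipped at
  chromosome edges for this presence/absence call only — clipping cannot
  bias a boolean, whereas density windows are hard errors when out of
  bounds.
* **Expression matching** — controls for the bound set are drawn from the
  unbound pool by greedy nearest-neighbour matching without replacement on
  $\log_{10}(\text{expression} + 10^{-3})$, visiting bound genes in
  descending expression order (high-expression genes have the thinnest
  candidate margins, so they choose first). The pseudocount keeps planted
  zero-expression genes finite. The matching report carries the
  Kolmogorov–Smirnov distance between the group distributions before and
  after matching; matching is deterministic (ties break by gene id).
* **Pausing breadth** — "broader pausing" is operationalized as the number
  of positions within 500 bp downstream of the TSS at or above 25 % of the
  gene's own maximum in that window, compared between groups by a
  two-sided Wilcoxon rank-sum test. This statistic is this package's
  construction (no formal definition exists to reconstruct) and outputs are
  labelled accordingly. Genes with an all-zero window are excluded; two
  groups with identical constant breadths are flagged `degenerate` with
  p = 1 rather than pretending a test was informative.

## Metagene profiles

`reference_point_matrix()` bins oriented per-base windows (defaults
−250/+750 bp around the TSS, 10 bp bins) and `scale_regions_matrix()`
additionally rescales each gene body onto 100 fractional bins, weighting
partial bases by overlap so that bin value × genomic bin width sums exactly
to the raw body signal (asserted to 1e−9 in the tests). Profiles are
averaged over genes within each replicate, then across replicates,
unweighted. Genes whose windows leave the chromosome are dropped per panel
and logged, never zero-padded — padding would dilute the mean toward zero
at the flanks. The default windows echo the 250/300 bp scales used
throughout the analysis; no canonical figure parameters exist, and visual
parity with any particular published panel is not a goal.

## The synthetic world

`simulate_world()` is a stated model, not a tuning knob. Per gene the
expected coverage is piecewise constant: body rate $d_g$, promoter rate
$d_g \cdot \mathrm{PI}$ over the first 300 bp, plus a PAS-proximal peak of
$3 d_g$ over the last 150 bp; counts are independent Poisson draws per
base. The rectangular promoter elevation (rather than a Gaussian) makes
the planted PI *exact in expectation* under the density convention, and the
150 bp PAS peak deliberately stays outside the NET-seq body (which ends
300 bp before the PAS) so it cannot perturb the NET-seq denominator — under
the PRO-seq body it does, which is itself a property the tests exploit.

Defaults: 1000 genes of 1200–4000 bp alternating strands on one
chromosome; gaps 300–800 bp with a 5 % minority of same-strand close pairs
(< 250 bp) to exercise the isolation filter; reference PI 2; 10 % of genes
shifted +2 and 10 % shifted −2 in the mutant; 2 replicates per condition;
base body density 0.5 counts/base scaled by a log-normal (sdlog 0.5)
per-gene expression factor; 30 % of genes bound, each receiving 1–3
single-base promoter cross-links in `[TSS−100, TSS+200)`. These are
compact-fungal-genome scales: kilobase genes, sub-kilobase intergenic
distances, and a dynamic range of expression of roughly one order of
magnitude.

What the generator does *not* emulate — and what a green test therefore
does not establish: mappability and GC bias, read-level artefacts,
replicate-specific scale factors (available via a flag-free manual rescale,
off by default so that planted PIs stay exact), transcript isoforms, and
any correlation between binding and pausing class (binding is planted
independently, so recovering it tests interval arithmetic, not biology).

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 is read/written
  1-based inclusive, BED 0-based half-open. TSS and PAS are the annotated
  extremities (no UTR refinement is attempted).
* Density windows out of chromosome bounds are hard errors — silent
  clipping biases densities asymmetrically at contig edges.
* Genes too short for a mode raise an error distinct from an undefined PI:
  the former is a usage mistake, the latter a data property.
* All thresholds are strict (`>`), matching the "longer than" / "signal
  greater than" wording; boundary cases (900/901, 10/10.5, 600/601) are
  pinned in the tests.
* The pipeline writes plain TSV (profile matrices carry a JSON header
  comment) and its manifest omits timestamps, so identical configs and
  inputs reproduce byte-identical output trees.

## Limitations

The pipeline quantifies *where* polymerase accumulates, not kinetics: no
elongation-rate, backtracking or pause-duration model is fitted, and a
cross-link in a promoter is an association, not a mechanism. Counts of
differential genes are conservative by construction — the eligibility
filters restrict the analysed subset, and the consistency rule trades
sensitivity for replicate agreement.
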