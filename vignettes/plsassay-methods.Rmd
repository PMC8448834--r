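---
title: "Methods: signature status, reversal screening and connectivity scoring"
author: "plsassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature status, reversal screening and connectivity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsassay)
```

## The assay in one paragraph

A prognostic liver signature partitions a fixed gene panel into
poor-prognosis genes (induced in livers at high risk of progressing to
hepatocellular carcinoma) and good-prognosis genes (suppressed), plus six
housekeeping genes used only for normalization. Given expression of a
"case" condition (infected, injured, or drug-treated cells) and a reference
condition, the assay asks whether the poor half is enriched at the top of
the case-versus-reference ranking and the good half at the bottom. The
answer is summarized as a global status — poor, good, or indeterminate —
and, in screening mode, as a ranked list of compounds that *revert* an
induced poor-prognosis state. `plsassay` implements that pipeline
end-to-end, together with a connectivity-map style in-silico screen and the
single-cell variant in which genes are ranked by their Pearson correlation
with a per-cell viral load.

## The enrichment statistic

The core statistic is the weighted Kolmogorov–Smirnov running sum. For a
ranked list of $N$ genes with metric values $r_j$ and a gene set of $N_H$
members, walking down the list increments the sum by $|r_j|^p / N_R$ at set
members ($N_R = \sum_{hits} |r_j|^p$) and decrements by $1/(N-N_H)$
otherwise. The enrichment score (ES) is the signed extreme of the walk; the
leading edge is the set members at or before the positive extreme (or at or
after the negative one). `weight_p = 1` is the default, including for
preranked input; `weight_p = 0` gives the classical unweighted statistic.

Two numerical choices matter:

* **Tie-breaking.** Rankings order by metric descending, then gene id
  ascending, so repeated runs are byte-identical. When the positive and
  negative extremes of the walk tie in magnitude (common at `weight_p = 0`,
  where increments are rational numbers), the positive extreme is reported;
  the comparison uses a `1e-9` tolerance so the outcome cannot flip on
  floating-point accumulation order.
* **Fast permutation scoring.** The walk only peaks at hits and only
  bottoms out immediately before hits (returning exactly to zero at rank
  $N$), so permutation nulls are scored from hit positions in $O(N_H)$
  rather than $O(N)$. The test suite checks this formulation against a
  position-by-position brute-force oracle on 1000 random instances at
  `1e-12`.

**Significance.** Nulls default to `gene_set` permutation — random same-size
gene sets scored on the fixed ranking — because the assay's arms have ~3
replicates, for which phenotype (label-shuffle) permutation admits only 20
distinct relabelings; phenotype mode is nevertheless implemented. NES
divides the observed ES by the mean magnitude of same-sign null scores;
nominal p uses the add-one convention so 0 is never reported; the FDR q
follows the pooled-null NES procedure with all queried sets' normalized
nulls pooled, clamped to $[1/(n_{perm}+1), 1]$. A set whose same-sign null
sample is empty is flagged *degenerate* (NES `NA`, p = q = 1) rather than
given an arbitrary value; this genuinely occurs for strongly negative ES on
small, asymmetric rankings (see the single-cell section). The significance
convention throughout is q < 0.25.

## Status classification

`assess_pls()` merges the two arms on their shared gene space, jointly
normalizes counts by the housekeeping genes (a geometric mean of
housekeeping counts per sample, pseudocount 0.5 against zeros, rescaled so
the grand scale is preserved — joint rather than per-arm, so factors are
comparable), log2-transforms, ranks case versus reference, and scores both
signature halves. The induction score is $\Delta = NES_{poor} - NES_{good}$
and the label is poor/good by the sign of $\Delta$, gated on
$\min(q_{poor}, q_{good}) < \alpha$ with $\alpha = 0.25$. Defining $\Delta$
on NES (not raw mean expression) was an open design choice: it keeps the
global status on the same scale as the per-set readouts and makes the
label's significance gate coherent with them. Heatmap encodings are
$\mathrm{sign}(NES)\cdot(-\log_{10} q)$ with q clamped at the permutation
floor. A contrast in which every metric is exactly zero (case identical to
reference) short-circuits to indeterminate: an all-tied ranking would
otherwise be ordered alphabetically and lexicographically clustered
signature genes would show spurious enrichment.

**Ranking metric.** The phenotype metric defaults to log2 fold change. The
alternative signal-to-noise statistic floors each group's standard
deviation at $\max(0.2|\mu|, 0.2)$; that floor couples metric magnitude to
expression level, so in comparisons where both arms share a shifted
baseline (a treated arm versus the injured control, where poor genes sit
high and good genes low in *both* arms) the signature sets cluster
non-randomly in the null ranking and the gene-set-permutation FDR becomes
anti-conservative (~0.38 marginal false-reversal rate versus ~0.30 under
fold change in our null simulations). Fold change is level-independent and
calibrates cleanly with 3-replicate arms; signal-to-noise remains available
and fully tested.

**Known limitation: two-set families.** The pooled FDR is computed within
each NES sign. With only two queried sets, whenever their NES fall on
opposite sides each side contains a single set and the observed-tail
denominator is 1, so q reduces to the per-set nominal tail with no
multiplicity correction; the union probability that a null comparison gets
a non-indeterminate label then approaches $1-(1-\alpha)^2 \approx 0.44$.
We measure ~0.39 across null simulations — per-set calibration is as
published (~0.25 at q < 0.25), but the two-set family rate is inherently
liberal. Interpret a single marginally significant half with caution.

## Reversal screening

`assess_reversal()` runs the same pipeline with the treated arm as case and
the injured control as reference, and applies a one-sided direction rule: a
reversal is significant iff the poor half is *suppressed*
(q < α and NES < 0) or the good half is *induced* (q < α and NES > 0).
`run_screen()` ranks compounds by the smallest q among their
reversal-direction sets, breaking ties by $|\Delta|$ descending then
compound id; hits are compounds whose reversal is significant.

## Connectivity scoring

Perturbation profiles (per-probe differential z-scores) are collapsed to
genes by preferring landmark (measured) over inferred (imputed) probes and
keeping the probe with the largest $|z|$ (ties by probe id). A query
signature — the poor half as "up", the good half as "down" — is scored
against each profile with the classical connectivity-map KS statistic
$a = \max_j(j/t - V_j/n)$, $b = \max_j(V_j/n - (j-1)/t)$, $ks = a$ if
$a \ge b$ else $-b$; note the statistic is asymmetric: top-packed tags give
exactly $1 - t/n$ but bottom-packed tags give $-(1-(t-1)/n)$. The raw score
is $ks_{up} - ks_{down}$ when the two statistics have opposite signs, else
0; scores are scaled by the collection extremes into $[-1, 1]$. Permutation
p-values and tau percentiles come from random tag-position pairs of matched
sizes — equivalent to random query signatures — which is a deliberate,
seeded simplification of reference-database touchstone percentiles. The
selection filters are the published ones: cmap-style, negative score with
p < 0.05; LINCS-style, tau < −90. Because the tau background is only the
profile's own permutation null, about the top decile of *null* profiles
also passes tau < −90; the filters are selection heuristics, not calibrated
tests.

## Single-cell analysis

Quality control takes the published thresholds literally: cells need an
alignment rate of at least 50% *and* at least 100,000 aligned pairs (both
inclusive, "at least"); cells with >80% mitochondrial transcripts or
<1500 total transcripts are removed (both strict); genes correlating with
the artifact transcript KCNQ1OT1 at Pearson r > 0.4 are removed (including
the artifact itself), and genes must reach ≥2 counts in ≥5 cells.
Mitochondrial genes are recognized by a configurable prefix (default
`MT-`); the source protocol does not state its list. Per-cell
normalization scales each cell to the minimum passing total. With only 40
cells, an r > 0.4 cut admits roughly 0.5% of unrelated genes by chance —
a property of the published filter, not of this implementation — so the
simulator's truth-versus-filter test tolerates a small number of
chance-correlated removals.

`viral_load_enrichment()` ranks genes by Pearson correlation with the
per-cell viral load (counts are log2-transformed with pseudocount 1 first)
and scores both halves preranked; it also reports the correlation between
each half's mean expression and the viral load, since either aggregate may
be the published summary. With a heavy-tailed raw viral load at n = 40
cells, the correlation ranking can be asymmetric enough that the
opposite-direction set has no same-sign nulls — reported as degenerate, not
as a fabricated NES.

## The synthetic-data generators

`simulate_bulk()`, `simulate_screen()`, `simulate_cells()` and
`simulate_perturbation_reference()` are pure functions of a
`sim_config()` (including its seed) and return ground-truth records
sufficient to score every downstream caller. Defaults mirror the reference
designs: 186 signature genes split 93/93, six housekeeping genes, 800
background genes, 3 replicates per arm, injury effects of ±1.5 log2 units
with replicate noise σ = 0.5 and per-sample library offsets (sd 0.2 log2)
that housekeeping normalization removes; a 25-compound screen with 11
planted reversers at strength 1.5; 40 cells with 23 infected; a 20-profile
perturbation reference with one planted reverser. Counts default to a
rounded-lognormal model (NanoString-like); a negative-binomial option
provides single-cell-like overdispersion. The cell generator couples poor
genes to the standardized viral load at β = 0.18 log2 units per sd
(good genes at −β), calibrated analytically so the correlation between
mean poor-set expression and viral load is ≈0.5 given the noise defaults —
the magnitude reported for the real infected cultures. Planted QC failures
(a low-total cell, a high-mitochondrial cell, a low-alignment cell,
artifact-correlated and rare genes) are flagged in the truth record.

What the generators do *not* emulate: gene–gene correlation beyond the
planted signal, batch structure, probe-level NanoString artifacts,
dropout/zero inflation, or real signature gene identities. Passing recovery
tests therefore demonstrates that the pipeline detects the designed signal
classes at realistic sizes and calibrates on exchangeable nulls — not that
it reproduces any particular wet-lab dataset.

## Problem sizes and reproducibility

The simulation batteries in the test suite and `scripts/acceptance.R` use
full-size designs (186-gene signature over ~1000 genes, 25-arm screens,
40-cell experiments) with 200 permutations per enrichment — above the 100
floor we require for FDR reporting and small enough that the whole battery
runs in well under a minute; the package default remains 1000. Every
stochastic step takes an explicit seed, permutation streams are restored
after use, and repeated runs are byte-identical.
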