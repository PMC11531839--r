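---
title: "Quantifying transcriptional crosstalk between combined stresses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcriptional crosstalk between combined stresses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degcrosstalk)
library(dplyr)
```

## The problem

Plants in the field rarely face one stress at a time. A root system can be
water-logged (hypoxia) while the shoot perceives a bacterial elicitor such as
flg22, the flagellin peptide that triggers pattern-triggered immunity (PTI).
The transcriptional response to the combined stress is not simply the union
of the two single-stress programs: one stress can suppress the other's
program, and the combination can switch on genes that neither stress touches
alone.

`degcrosstalk` takes the three differential-expression (DE) tables of such a
factorial design — stress A alone, stress B alone, and A+B combined, each
versus the untreated control — and quantifies that interaction with set
algebra and three summary metrics. Nothing in the package is specific to
hypoxia or flg22; any pair of treatments with a combined arm fits.

## From DE tables to signed DEG sets

The unit of input is a per-contrast table of `gene_id`, `log2fc`, `adj_p`
(`as_de_table()` / `read_de_table()`, with a `dialect` mapping for
DESeq2-style column names). A gene is called differentially expressed when

* `adj_p < 0.05`, and
* `|log2fc| > 0.585` (about 1.5-fold),

with **strict** inequalities: a gene sitting exactly on either cutoff is not
called. The 0.585 is used as the literal conventional cutoff, not recomputed
as `log2(1.5)`. Both thresholds are arguments of `call_degs()`;
`hypoxia_style_degs()` applies the stricter `|log2fc| > 1` convention common
for published hypoxia datasets, and the resulting sets are always subsets of
the default call on the same table — raising the fold-change cutoff or
lowering the p cutoff can only remove genes.

Rows with a missing `adj_p` are retained in the table (they count toward the
gene universe) but never pass the thresholds. This is a convention, not a
law of nature: DE pipelines that filter low-count genes report `NA` adjusted
p-values, and whether such genes belong in DEG totals is a choice the
analyst should make consciously. Keeping them un-callable but in the
universe preserves background accounting for the overlap tests.

`call_degs()` returns a *signed* DEG set — disjoint `up` and `down` vectors
— because every downstream comparison comes in a direction-aware and a
direction-blind flavour.

## Set algebra

`venn_partition()` decomposes two or three DEG sets into their disjoint
membership regions, with member lists. `venn3_from_counts()` solves the
inverse problem for published numbers: given the three set totals, the three
pairwise overlaps and the triple overlap, it reconstructs the seven region
counts by inclusion–exclusion. Pairwise overlaps are interpreted as
*including* the triple overlap (the plain `|A ∩ B|`); this is the only
reading under which typical published count sets are self-consistent, and an
input that forces any region negative is rejected rather than clipped.

`directionality_concordance()` asks, for genes called in two conditions, how
many move the same way; with no common genes the fraction is reported as
`NA`, not 0 — an undefined quantity should look undefined.
`mean_amplitude()` averages log2 fold-changes of a fixed gene set across
tables (with the standard deviation), and `omic_fc_concordance()` pairs
mRNA with protein fold-changes, classifies sign quadrants and reports a
Spearman correlation. `relative_expression()` converts qPCR crossing points
to `2^deltaCp` relative expression against a reference gene, assuming a PCR
efficiency of 2.

## The three crosstalk metrics

Write A and B for the single-stress DEG sets and AB for the combined-stress
set (per direction, or direction-blind). The package's working definitions:

* **Similarity** `= |A ∩ B| / |A ∪ B|` — the Jaccard index. It is 1 exactly
  when the two programs are identical (and non-empty), 0 when disjoint.
* **Suppression** `= |B ∩ AB| / |B| − |A ∩ AB| / |A|` — the difference in
  retention: what fraction of each single-stress program survives into the
  combined program. It lives in [−1, 1] and is antisymmetric under swapping
  A and B. The argument convention is A = the dominating (here abiotic)
  stress and B = the stress suspected of being suppressed, so that a
  *negative* score reads "A suppresses B's program". The extremes behave as
  they should: if AB retains everything the score is 0; if A is fully kept
  and B fully lost it is −1.
* **Novel interaction** `= |AB \ (A ∪ B)| / |AB|` — the fraction of the
  combined program seen under neither single stress; 1 means an entirely
  new program.

These definitions were chosen because they satisfy every stated range,
extreme and sign property of the metrics as used in the combined-stress
literature, and because the novel-interaction formula exactly reconciles the
published per-direction scores with the published region counts (the
acceptance suite recomputes this). Each score function accepts a `formula`
argument, so a variant algebraic definition can be swapped in without
touching the rest of the pipeline; count-level forms
(`*_from_counts()`) serve published summary numbers directly.

`crosstalk_report()` assembles all scores for `up`, `down` and `all`
(direction-blind) sets, with the component counts attached. Per-direction
scores compare like with like; a gene that flips direction between
conditions contributes only to the direction-blind row. Because usage in the
field is ambiguous about *which* pair "similarity" compares, the report
carries all three pairings (`similarity` for A vs B, plus `similarity_a_ab`
and `similarity_b_ab`); we treat A vs B as the primary reading.

## Significance machinery

`overlap_chisq()` tests a two-set overlap against independence with a 2×2
contingency table over a gene universe and Pearson's chi-squared (1 df). No
continuity correction is applied by default — the correction is a choice,
exposed as a flag, and the default is documented rather than silent. The
default universe (`gene_universe()`) is the union of genes present in the
supplied DE tables: the most defensible reproducible background when the
true tested universe is unknown, and injectable for sensitivity analysis.

`enrich_terms()` is a deliberately generic term-enrichment stand-in: one
upper-tail hypergeometric test per term of a GMT-style map, Benjamini–
Hochberg correction across terms. There is no ontology graph, no true-path
propagation — published GO results depend on the annotation snapshot of the
tool that produced them and are not a reproduction target for this package.

## The synthetic experiment generator

`generate_experiment()` realises a `synthetic_spec()` into three DE tables
plus per-gene ground truth. The generative model mirrors the statistical
structure of a two-stress factorial transcriptome:

* `n_deg_a`, `n_deg_b` genes form the single-stress programs, with a
  `similarity_overlap` fraction of B's program shared with A;
* each A DEG survives into the combined program with probability
  `retention_a`, each B DEG with `retention_b` (a shared gene survives if
  either chance does);
* combined-only ("novel") genes are drawn from the null pool in the number
  that makes the expected novel fraction of AB equal `novelty`;
* directions are up with probability `prop_up`, attached to the gene and
  preserved across tables; effect magnitudes are normal on the log2 scale,
  truncated above the calling threshold; DEG adjusted p-values are uniform
  below the p cutoff, null ones uniform above it.

Because effects are placed strictly beyond the thresholds, calling DEGs on
the generated tables recovers the ground-truth classes *exactly*, which is
what makes the generator useful as an oracle: any discrepancy is a pipeline
bug, not noise. The `noisy_boundary` flag deliberately breaks the crispness
of fold-changes (a small fraction of null genes straddle the fold-change
cutoff while staying non-significant) for robustness checks.

The defaults (5,000 genes, 1,000 DEGs per stress, overlap 0.1, retentions
0.9/0.8, novelty 0.3, 60% up) describe a mid-sized transcriptome experiment
with a moderately suppressed second stress; they are study conditions, not
tuning knobs. What the generator does **not** emulate: count-level noise and
dispersion (it works at the DE-table level, since that is what the crosstalk
analysis consumes), correlated co-regulation between genes, p-value/effect
dependence, or borderline significance under the default settings. Passing
recovery tests therefore demonstrate correctness of the set algebra and the
estimators under the model, not robustness to everything real RNA-seq does.

`expected_scores()` gives the closed-form expectation and standard error of
the suppression and novel-fraction estimators under this model. With shared
genes present the expected suppression is *not* exactly
`retention_b − retention_a`, because a shared gene survives with probability
`1 − (1−r_a)(1−r_b)` and inflates both retention estimates (and correlates
them); the closed form accounts for this, including the induced covariance.
For that reason the parameter-recovery validation is run at
`similarity_overlap = 0` with `retention_a = 1`, where the retention
difference is the exact expectation of the estimator. `sweep_experiments()`
runs replicated grids with deterministically derived seeds and reports each
realisation's estimates and errors against these expectations.

Validation problem sizes: the recovery suite uses 200 replicates at 5,000
genes and 1,000 DEGs per stress (estimates within three standard errors of
their expectations in ≥95% of replicates; the suppression estimate monotone
in the retention gap), and the property suites fuzz 100 random set triples.

## Numerical and degenerate-input choices

* Strict inequalities at both DEG cutoffs; boundary genes excluded, tested.
* Undefined ratios (similarity of two empty sets, suppression with an empty
  single-stress set, novel fraction of an empty combined set, concordance
  with no common genes) are errors or `NA`, never silently 0.
* Venn reconstruction from counts refuses inconsistent inputs (negative
  regions) instead of truncating.
* Master seed → deterministic child seeds per generation stage, so the same
  spec yields byte-identical tables and sweeps are reproducible; the
  generator restores the caller's RNG state.
* Gene identifiers are whitespace-stripped and compared case-sensitively.

## Known limitations

* The crosstalk formulas are the package's working definitions; where a
  study defines variants, the `formula` hooks accommodate them, but the
  defaults carry the interpretation stated above.
* Genes are exchangeable in the generator; there is no module structure, so
  enrichment results on synthetic data are null by construction.
* The chi-squared overlap test is asymptotic; for tiny universes the
  hypergeometric tail (which the test suite uses as an oracle) is the better
  tool.
* No area-proportional Venn rendering; `autoplot()` on a partition shows
  region counts as bars.

## A worked session

```{r example}
spec <- synthetic_spec(n_genes = 2000, n_deg_a = 300, n_deg_b = 500,
                       similarity_overlap = 0.12, retention_a = 0.9,
                       retention_b = 0.7, novelty = 0.35, seed = 42)
exper <- generate_experiment(spec)

degs <- lapply(exper$tables, call_degs)
sapply(degs, function(d) glance(d)$n_all)

crosstalk_report(degs$A, degs$B, degs$AB)
```
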