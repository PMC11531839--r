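# degcrosstalk

Quantify the transcriptional crosstalk between two stresses applied alone
and in combination, from ordinary differential-expression tables.

When a plant experiences two stresses at once — say, low oxygen (hypoxia)
together with a bacterial immune elicitor such as the flagellin peptide
flg22 — the combined transcriptional response is rarely the union of the two
single-stress programs. One stress can suppress the other's program, and the
combination can activate genes neither stress touches alone. `degcrosstalk`
is for transcriptomics analysts who have the three DE result tables of such
a factorial design (A alone, B alone, A+B combined, each vs control) and
want the interaction quantified, tested, and plotted.

## What it computes

Starting from per-contrast tables of `gene_id`, `log2fc`, `adj_p`:

* **Signed DEG calling** at strict cutoffs `adj_p < 0.05` and
  `|log2FC| > 0.585` (both configurable; a `|log2FC| > 1` convenience for
  published hypoxia datasets).
* **Venn set algebra** for 2–3 DEG sets, from gene lists or from published
  summary counts by inclusion–exclusion, with consistency checking.
* **Crosstalk metrics** per direction (up / down / all), for single-stress
  sets A, B and combined set AB:
  - similarity `S = |A ∩ B| / |A ∪ B|` (Jaccard; 1 = identical programs),
  - suppression `D = |B ∩ AB|/|B| − |A ∩ AB|/|A|` ∈ [−1, 1]
    (negative = A suppresses B's program),
  - novel interaction `N = |AB \ (A ∪ B)| / |AB|` ∈ [0, 1]
    (1 = entirely new program).
* **Concordance**: directionality agreement between datasets, mean
  fold-change amplitude of a gene set across contrasts,
  transcriptome–proteome fold-change quadrants with Spearman correlation,
  and qPCR relative expression (`2^deltaCp`).
* **Significance**: chi-squared 2×2 overlap tests against a gene universe,
  and hypergeometric term enrichment (GMT input) with Benjamini–Hochberg
  correction.
* **A synthetic experiment generator** with known ground truth (retention
  rates, novelty, direction balance), so every stage of the pipeline has an
  exact recovery test, plus closed-form estimator expectations
  (`expected_scores()`) and replicated sweeps (`sweep_experiments()`).

Results come back as tibbles (with `tidy()` / `glance()` methods and
`autoplot()` figures), so everything chains with the pipe.

## Worked example

The published summary counts of a hypoxia (HM), flg22 (NF), combined
hypoxia/flg22 (HF) experiment — DEG totals 145, 1906, 2612; overlaps
`|HM∩NF| = 60`, `|HM∩HF| = 131`, `|NF∩HF| = 1601`; triple overlap 59 — are
enough to reconstruct the full Venn partition and the crosstalk scores:

```r
library(degcrosstalk)

vp <- venn3_from_counts(c(HM = 145, NF = 1906, HF = 2612),
                        pairwise = c(60, 131, 1601), triple = 59)
vp
#> # Venn partition of sets: HM, NF, HF (counts mode)
#> # A tibble: 7 × 2
#>   region   count
#> * <chr>    <int>
#> 1 HM          13
#> 2 NF         304
#> 3 HF         939
#> 4 HM&NF        1
#> 5 HM&HF       72
#> 6 NF&HF     1542
#> 7 HM&NF&HF    59
```

939 genes respond only to the combined stress, and 304 flg22-responsive
genes are lost when hypoxia is added. The suppression score on the same
counts is negative — the hypoxia program is retained more completely
(131/145) than the flg22 program (1601/1906), i.e. hypoxia dominates:

```r
suppression_from_counts(n_a = 145, n_b = 1906, n_a_ab = 131, n_b_ab = 1601)
#> [1] -0.06346926
```

With the combined program split 1904 up / 708 down, the novel-interaction
scores per direction are

```r
round(novel_from_counts(459, 1904), 3)  # up-regulated
#> [1] 0.241
round(novel_from_counts(480, 708), 3)   # down-regulated
#> [1] 0.678
```

— two thirds of the combined-stress repression is unique to the
combination. With full gene lists rather than counts, `call_degs()` +
`crosstalk_report()` produce the same metrics for up, down and all DEGs in
one tibble, and `overlap_chisq()` attaches significance to any pairwise
overlap.

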