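# compobench

Sequencing-based microbiome data are compositional: the instrument's read
budget fixes each sample's total, so counts carry only relative
information. When a treatment truly increases some taxa, the *observed*
relative abundance of every unchanged taxon must fall — a pure artefact
that differential-abundance tests readily mistake for biology.
`compobench` is a simulation benchmark that measures how large this
artefact is, and how much of it the four standard normalizations
(relative abundance/total-sum scaling, centered log-ratio, TMM,
DESeq2-style median-of-ratios) actually remove, for people who analyse
amplicon or metagenomic count tables and need to know how far to trust
flagged taxa.

## What it computes

Ground-truth absolute abundances are simulated for a two-arm intervention
(10 control + 10 treatment subjects, baseline and post samples, 100 taxa
with log-normal profiles `exp(N(12.5, 2.5))`, correlated subjects via
`exp(N(0, 0.5))` deviations, 25% uniform temporal noise). A scenario fixes
the effect size `e` — responders multiplied by `(1 + e)` or divided by it
— and the fraction of taxa responding. Sequencing is a multinomial draw of
`N(50000, 10000)` reads per sample. On the ground truth and on each
normalization the package then measures

* **detection errors** — per-taxon Kruskal–Wallis tests between groups
  with Benjamini–Hochberg correction (adjusted p < 0.1); false positives
  (flagged non-responders) and false negatives (missed responders) as
  fractions of all 100 taxa, scored against the known truth table; and
* **variance explained** — one-factor PERMANOVA R² of the treatment on
  post-intervention samples under log-Pearson (1 − correlation of log
  profiles), Bray–Curtis and Aitchison (Euclidean-on-CLR) distances.

An experiment crosses effect sizes {0.1, 0.5, 1, 5, 10} with response
proportions {1, 5, 10, 25, 50, 75}% — unidirectional (all responders
increase) or bidirectional (1:1 increases and decreases) — at 100
iterations per scenario, and aggregates scenario means into a summary
table of mean/max error rates with fold changes versus the
absolute-abundance ground truth.

## Worked example

```r
library(compobench)
grid <- data.frame(effect_size = c(1, 10), proportion = c(0.1, 0.5))
ex <- run_experiment("unidirectional", grid = grid, n_iterations = 5,
                     seed = 1)
summary(ex)
#> Experiment summary (unidirectional, 5 iterations/scenario)
#>    Method Max FP Mean FP FP fold Max FN Mean FN FN fold
#>  absolute  0.016   0.011       -  0.064   0.032       -
#>  relative  0.458   0.236  21.455  0.240   0.168    5.25
#>       clr  0.444   0.229  20.818  0.090   0.053   1.656
#>       tmm  0.438   0.229  20.818  0.088   0.073   2.281
#>     deseq  0.448   0.232  21.091  0.088   0.087   2.719
#>
#> Mean PERMANOVA R2 by representation and metric (grid average):
#>    method      metric r_squared
#>       clr   aitchison     0.281
#>  absolute bray_curtis     0.453
#>     deseq bray_curtis     0.326
#>  relative bray_curtis     0.357
#>       tmm bray_curtis     0.352
#>  absolute log_pearson     0.494
#>       clr log_pearson     0.430
#>     deseq log_pearson     0.430
#>  relative log_pearson     0.430
#>      tmm log_pearson      0.430
```

Reading it: on the ground truth, detection errors are small (mean FP ~1%,
bounded by the BH level). Every normalization of the sequenced counts
multiplies the false-positive rate roughly twenty-fold on this
strong-effect sub-grid — at a 50% response, nearly every unchanged taxon
is flagged — and none of CLR/TMM/median-of-ratios improves on plain
relative abundance. All normalizations also explain less treatment
variance than the ground truth, and the recommended Bray–Curtis/Aitchison
distances sit below the log-Pearson distance on the same data.

Lower-level entry points (`simulate_abundances()`,
`simulate_sequencing()`, `clr_transform()`, `tmm_factors()`,
`deseq_size_factors()`, `detect_responders()`, `permanova()`, ...) expose
each stage separately; `inst/cli/compobench.R` wraps the runner for shell
use, and matrices/configs round-trip as TSV/JSON via `write_matrix_tsv()`
and friends. See the vignette in `vignettes/` for the model, its
assumptions and its limitations.

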