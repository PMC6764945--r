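# mirarmkit

Analysis toolkit for microRNA **arm imbalance** and **target-directed
miRNA degradation (TDMD)** in cancer cohorts.

Many miRNA precursors produce two mature arms (5p and 3p). In tumors the
balance between the arms can flip — one arm up, the other down — and
highly complementary target RNAs can actively degrade a mature miRNA
(TDMD), leaving a signature of 3′ tailing and trimming among its
isoforms. `mirarmkit` implements the quantitative machinery used to study
this circuit:

- **qPCR quantification** — relative expression by
  `ratio = 2^-ΔΔCt` with `ΔCt = Ct(target) − Ct(reference)`, and absolute
  copy numbers via standard curves
  (`Ct = slope·log10(copies) + intercept`, efficiency `10^(−1/slope) − 1`)
  and the mass-to-copies formula
  `copies = 6.02×10²³ · m / (L · 308.95 · 2)`.
- **Arm-pair trend classification** — per-arm tumor/normal direction from
  paired log-ratios (Wilcoxon signed-rank gate plus an effect-size
  threshold), pairs labelled `same` / `opposite` / `single` / `none`.
- **Risk profiling and survival** — per-patient risk factors (5p up, 3p
  down; ratio 1.0 is the strict boundary), a linear risk score
  `w₅·z(log₂ 5p) − w₃·z(log₂ 3p)`, Kaplan–Meier curves and log-rank tests
  (via the `survival` package).
- **Pull-down enrichment** — the enrichment ratio
  `ER = (bait PD / ctrl PD) / (bait input / ctrl input)` per gene, the
  `FPKM > 0.1` expression filter, candidates at `ER > 1.2`, potential
  targets (enriched *and* depleted on overexpression,
  `|log2FC| > 1 & FDR < 0.001` as the strict gate), and CDF-shift testing
  by Kolmogorov–Smirnov.
- **Duplex architecture** — score-based miRNA:site alignment (WC +2,
  G:U +1, mismatch 0, bulge −2/−1), classification into `seed_only` /
  `tdmd_competent` / `extensive` sites (a TDMD-competent site pairs the
  full seed and the 3′-adjacent region around a central loop, tolerating
  up to two unpaired 3′-terminal nucleotides), transcript scanning, and
  design of 6× bulged sponge decoys with 4-nt spacers.
- **isomiR profiling** — read filtering (≥14 nt, dinucleotide-entropy
  complexity), anchored assignment to mature miRNAs (≤2 mismatches,
  ≤100 hits, equal fractional weights for multi-mappers), classification
  into canonical / trimmed / tailed (templated vs non-templated tails
  from precursor context), and normalized profiles
  (`count/total × mean(totals)`, then `log2(x+1)`).
- **Synthetic data with ground truth** — every input above can be
  simulated under one seed with planted truth (trend classes, spiked
  enriched genes, designed binding sites, isoform mixtures, risk-driven
  survival), so the whole pipeline is benchmarked by recovery.

## Worked example

```r
library(mirarmkit)

# a paired cohort of 50 patients x 100 arm pairs with planted trends
cfg    <- sim_config(seed = 7, n_arm_pairs = 100, n_patients = 50)
cohort <- gen_cohort(cfg)
arm_trend_summary(classify_cohort_trends(cohort$expression))
#>      trend count proportion
#> 1     same    36       0.36
#> 2 opposite     9       0.09
#> 3   single    10       0.10
#> 4     none    45       0.45
```

The classifier recovers the planted composition: 36% of pairs move
together, 9% move in opposite directions (the arm-switching pattern), the
rest change singly or not at all.

```r
# biotinylated pull-down: enrichment ratio + overexpression depletion
pd  <- gen_pulldown(cfg)
er  <- enrichment_ratio(filter_expressed(pd$abundance))
lfc <- log2fc_table(pd$abundance$oe, pd$abundance$oe_ctrl,
                    gene_id = pd$abundance$gene_id)
rec <- define_potential_targets(
         merge(er, lfc[, c("gene_id", "log2fc")], by = "gene_id"))
cdf_shift_test(rec$log2fc[rec$potential_target], rec$log2fc)
#> <cdf_comparison> D = 0.9263, p = 0, shift down (n = 207 vs 5000)
```

Of 5000 genes, 224 pass the `ER > 1.2` candidate cut and 207 are
potential targets (also depleted after overexpression); their fold-change
CDF is shifted far down relative to all genes, as expected for genuine
targets (200 were spiked).

```r
# relative quantification and sponge design
ct <- data.frame(sample = "patient_01",
                 gene = rep(c("miR-574-5p", "U6"), each = 2),
                 condition = rep(c("tumor", "normal"), 2),
                 ct = c(20, 22, 15, 15))
ddct_relative_expression(ct, "miR-574-5p", "U6")
#>       sample       gene delta_ct_case delta_ct_calibrator delta_delta_ct ratio call
#> 1 patient_01 miR-574-5p             5                   7             -2     4 high

design_sponge("UGAGGUAGUAGGUUGUAUAGUU", "hsa-let-7a-5p")
#> <sponge_design> hsa-let-7a-5p: 6x 26-nt bulged sites, 4-nt spacers (176 nt)
```

A ΔΔCt of −2 corresponds to 4-fold upregulation in the tumor sample. The
sponge construct carries six TDMD-competent bulged sites
(6·(22+4) + 5·4 = 176 nt), verified by the package's own scanner.

## Documentation

The methods vignette (`vignettes/mirarmkit-methods.Rmd`) describes the
models, parameter choices, numerical conventions and known limitations in
detail.
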