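---
title: "mirarmkit methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirarmkit methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirarmkit)
```

# Scope

`mirarmkit` quantifies two linked phenomena: the *arm imbalance* of a
miRNA precursor (the 5p/3p ratio flipping between tumor and normal
tissue) and *target-directed miRNA degradation* (TDMD), in which a
highly complementary target RNA destabilizes a mature miRNA, leaving a
3′ tailing-and-trimming signature among its sequence isoforms. The
package provides the statistics around both (qPCR quantification, trend
classification, risk scoring and survival stratification, pull-down
enrichment analysis, duplex architecture classification, isomiR
profiling) together with a fully seeded synthetic-data module that plants
known truth, so every claim the analysis makes can be checked by
recovery.

# qPCR quantification

Relative expression uses the comparative Ct method:
$\Delta C_T = C_T(\text{target}) - C_T(\text{reference})$ per condition,
$\Delta\Delta C_T = \Delta C_T(\text{case}) - \Delta C_T(\text{calibrator})$,
ratio $= 2^{-\Delta\Delta C_T}$. Replicate wells are summarized by the
**median** before differencing — a deliberate choice that makes single
failed wells harmless; the mean is the only other defensible option and
differs negligibly for clean triplicates. A ratio below 1.0 is called
*low*; exactly 1.0 falls on the *high* side (the boundary is
configurable through `low_threshold`).

Absolute quantification fits $C_T = a + b\,\log_{10}(\text{copies})$ by
least squares over a dilution series (at least three distinct points
spanning two decades), inverts that line for unknowns, and reports
amplification efficiency $10^{-1/b} - 1$ (1.0 at the theoretical slope
$-\log_2 10 \approx -3.32$ cycles per decade). Efficiency is reported
but *not* used to correct the $2^{-\Delta\Delta C_T}$ ratio, which is
the plain comparative form. Copy numbers from mass use
$N = 6.02\times10^{23}\,m / (L \cdot 308.95 \cdot 2)$ with the factor 2
dropped for single strands; the grouping (length × molar mass × strands
in the denominator) is the only reading under which a 1-kb microgram
gives the expected ~$10^{12}$ copies.

# Arm-pair trend classification

For one precursor the paired tumor/normal log2 ratios of each arm are
reduced to a direction call: *up*/*down* when a two-sided Wilcoxon
signed-rank test rejects at `alpha` (default 0.05) **and** the median
log2 ratio exceeds `min_abs_log2fc` (default 1, i.e. two-fold) in
magnitude; *unchanged* otherwise. Combining the per-arm test with an
effect-size gate is standard differential-expression practice and is
what keeps the false "moved" rate of truly null arms near zero rather
than near `alpha` per arm (with two arms per pair, a test-only gate
would call ~10% of null pairs non-`none` at `alpha` = 0.05). Pair labels
follow mechanically: `same` (both arms same direction), `opposite`
(different directions — the arm-switching pattern), `single`, `none`.

# Risk profile and survival

A patient's risk-factor count adds one for 5p upregulation
(ratio strictly > 1) and one for 3p downregulation (ratio strictly < 1);
a ratio of exactly 1 contributes nothing on either arm, so
`rf_count` ∈ {0, 1, 2}. The risk score is a linear combination of the
two arm levels on the cohort-standardized log2 scale,
$w_5 z_5 - w_3 z_3$ with unit weights by default: the score was only
ever specified as "a linear combination", so equal weights on z-scores
are the neutral choice, and an optional mode estimates the weights from
a proportional-hazards fit when survival data are available. The score
is strictly increasing in 5p and decreasing in 3p expression by
construction. Kaplan–Meier estimation and the log-rank test are
delegated to the `survival` package; curves are returned tidy (group,
time, survival, numbers at risk/events).

# Pull-down enrichment

The enrichment ratio per gene is
$\mathrm{ER} = \dfrac{(\text{bait PD} + \varepsilon)/(\text{ctrl PD} + \varepsilon)}
{(\text{bait input} + \varepsilon)/(\text{ctrl input} + \varepsilon)}$
with a pseudocount $\varepsilon = 0.01$ (in abundance units) guarding
zero denominators; $\varepsilon = 0$ is allowed when all denominators
are positive. Genes are pre-filtered to those with abundance > 0.1 in at
least one library (strictly above; the filter is idempotent and applied
*before* ER by default — the alternative order is available by simply
calling the functions in the other order). Candidates are `ER > 1.2`,
read as a strict inequality; the boundary gene at exactly 1.2 is not a
candidate. A *potential target* is a candidate whose expression falls
upon miRNA overexpression (log2FC < 0 with pseudocount 1); the stricter
gate additionally requires the differential-expression flag
(|log2FC| > 1 and FDR < 0.001, both strict). When no FDR column is
supplied, a two-sided conditional binomial test on rounded counts with
Benjamini–Hochberg adjustment stands in; it is a generic count test, not
a reimplementation of any particular DE tool, and externally computed
FDRs take precedence when provided. Distribution shifts of a target
set's fold changes are tested with the two-sided Kolmogorov–Smirnov test
(one-sided variants available; sidedness is a user choice, two-sided
being the conservative default).

ER is invariant when the bait pull-down/input pair, the control pair, or
all four libraries are rescaled together — the invariances that matter
for sequencing-depth normalization. Rescaling a *single* library does
change ER (it must: ER is a ratio of that library's values), which is
why the statistic is computed on depth-normalized abundances.

# Duplex architecture

Pairing is score-based complementarity, not thermodynamic folding:
Watson–Crick +2, G:U wobble +1, mismatch 0, bulge −2 to open and −1 to
extend, aligned antiparallel by an affine-gap dynamic program that
covers the miRNA end to end with free target overhangs. There is no
energy model on purpose — the site classes of interest are defined by
pairing architecture, not ΔG, and a scoring scheme keeps the planted
truth of the simulator exactly recoverable. Ties are broken
deterministically (pairing preferred over bulges, leftmost optimum).

Classes are assigned in fixed precedence:

* `tdmd_competent` — all six seed positions (2–7) Watson–Crick paired
  (wobbles do not count in the seed, as seed recognition is strict),
  a central loop opposite positions 9–12, at least 7 paired positions in
  the 3′-adjacent region 13..L−3 (capped at the region size for short
  miRNAs, i.e. full supplementary pairing is required when fewer than 7
  positions exist), and at most two unpaired nucleotides at the miRNA 3′
  extremity — the documented tolerance for degradation-competent sites.
* `extensive` — ≥90% of all positions paired with no central loop
  (e.g. a perfect complement).
* `seed_only` — full seed but fewer than 7 paired positions in 13..L.
* `none` — everything else.

G:U wobbles count as paired for 3′ coverage. T and U are equivalent on
the target side; miRNA inputs may be RNA or DNA strings. All coordinates
are 0-based half-open on the transcript's sense strand.

**Scanning and the mismatch-cost caveat.** Transcript scanning is
seed-anchored: every perfect match to the reverse complement of
positions 2–7 (2–8 optional) seeds a window which is then aligned and
classified. Because mismatches are cost-free under this scoring, an
unbounded window would let the 3′ half of the miRNA profitably "catch"
chance pairs in flanking sequence (about 3/8 of random juxtapositions
pair), inflating 3′-pairing counts and drifting the reported extent. The
scan window is therefore kept tight — the miRNA length plus
`window_slack` (default 4 nt, the default central-bulge size) — and the
scanner reports the geometric seed coordinates (always exact) alongside
the alignment extent. For sites with designed 3′ pairing
(TDMD-competent, extensive) the extent is exact; for seed-only sites it
may drift a few bases where flanks pair by chance, which is a property
of the scoring scheme, not a bug, and is reflected in how the generator
records truth.

**Sponge design.** A decoy construct repeats one binding site six times
with 4-nt spacers. The site is the reverse complement of the miRNA with
the four bases opposite positions 9–12 replaced by eight
non-complementary ones — a net 4-nt insertion forming a central internal
loop, so the miRNA binds through seed and 3′ region but the central
geometry needed for cleavage is absent. Each design is verified with the
package's own scanner (all six sites must classify `tdmd_competent` at
their planted coordinates); loop bases and spacers are regenerated on
the rare verification failure. Construct length is exactly
6(L+4) + 5·4.

# isomiR profiling

Reads shorter than 14 nt or with dinucleotide Shannon entropy below 0.5
bits are removed; the entropy cutoff was set so that well-formed
synthetic libraries lose well under 1% of reads (a homopolymer has
entropy 0 and is always removed at any positive cutoff). Assignment is
an exact anchored comparison against each mature reference with 5′
offsets in [−3, +3] and a variable 3′ end: mismatches are counted only
in the mature-overlapping portion (≤2 allowed), reads with more than 100
assignments are discarded, and multi-mapping reads keep their
fewest-mismatch assignment set with equal fractional weights — weight
conservation (each assigned read contributes total weight 1) is a tested
invariant. A read that matches some precursor region *outside* the
mature window with fewer mismatches is discarded; this precursor-based
filter plays the role of the usual genome-mismatch filter without
requiring a genome, and is a behavioral, not bit-exact, substitute for
aligner-based pipelines.

Classes: `canonical` (no offset, no trim, no tail), `trimmed` (3′ trim
only), `tailed` (3′ tail only), `trimmed_tailed`, and
`five_prime_variant` (any 5′ offset), which is reported separately and
excluded from 3′-isoform proportions by default since the
trimming/tailing signature of TDMD is a 3′ phenomenon; an accounting
mode that folds 5′ variants into their 3′ class is provided. A tail is
`templated` if every base matches the precursor immediately downstream
of the read's templated 3′ end, `non_templated` if none does, `mixed`
otherwise. Profiles report weighted class counts, within-miRNA
proportions, and normalized expression
`count / library_total × mean(library_totals)` followed by
`log2(x + 1)`; proportions are unaffected by library scaling by
construction. Two profiles are compared per class with a two-proportion
z-test.

# The synthetic-data module

The generators define the study conditions; their defaults are fixed and
are the conditions under which the recovery benchmarks are run.

* **Cohort** (`gen_cohort`): 800 arm pairs × 50 paired patients.
  Expression noise is lognormal (sd 0.3 on the natural-log scale) —
  multiplicative noise matches the fold-change semantics of qPCR/FPKM
  data. A shared per-patient factor (log-sd 0.5) models between-patient
  variability and cancels in paired ratios. Dysregulated arms are
  multiplied/divided by `fold_effect` = 4. Planted trend fractions are
  36% same-trend, 9% opposite, 10% single, 45% null — the same/opposite
  proportions mirror the published pan-cohort arm-pair survey
  (35.91%/9.07%); class *counts* follow the fractions exactly
  (largest-remainder apportionment) so recovered fractions estimate the
  configured composition without an extra layer of multinomial noise.
* **qPCR** (`gen_qpcr`): Ct = baseline − log2(abundance) + N(0, 0.2),
  triplicate wells, constant reference gene.
* **Pull-down** (`gen_pulldown`): per-gene abundances lognormal across
  genes (log-mean log 100, log-sd 1); each of the six libraries (bait/
  control pull-down and input, overexpression pair) measures the same
  pool through **Poisson sequencing counts** at 10⁷ expected reads —
  counting noise is the realistic technical noise model for libraries
  prepared from one RNA pool, and it concentrates false candidates among
  low-count genes exactly as in real data. Spiked genes (200 of 5000)
  have bait pull-down abundance × 3 (the true enrichment ratio) and are
  depleted 2-fold in the overexpression library. Expected values are not
  renormalized after spiking, so null genes sit at ER = 1 exactly.
* **References** (`gen_references`): random matures (22 nt, mutually
  distinct seeds), precursors with 25-nt flanks, and one transcript per
  site class per miRNA with planted, verified sites; backgrounds and
  flanks are scrubbed of chance seed matches so planted sites are the
  only ones a scanner can find.
* **Reads** (`gen_small_rna_reads`): mixture 0.70 canonical / 0.20
  trimmed (1–3 nt) / 0.05 non-templated tail / 0.05 templated tail,
  10,000 reads. Non-templated tail bases are drawn from the three bases
  differing from the precursor's downstream base, making
  templated/non-templated truth unambiguous by construction.
* **Survival** (`gen_survival`): exponential times with hazard
  $h_0 e^{\beta \cdot \text{score}}$, $h_0$ = 0.002/day (median ≈ one
  year at score 0), $\beta$ = 1 per score unit; censored subjects
  (20%) are drawn independently and observed at a uniform fraction of
  their latent event time.

One integer seed drives everything: each generator derives a fixed child
seed, so adding patients to one table never reshuffles another, and the
global RNG state of the session is saved and restored around every
generator call.

**What the simulations do not emulate:** realistic sequencing error
profiles, adapter contamination, UMI structure, secondary-structure
effects on expression, correlated biological replicates, batch effects.
Passing recovery benchmarks therefore demonstrates that the statistics
are implemented correctly and behave as designed under their stated
noise models — not that they are robust to every artifact of real
libraries.

# Benchmark problem sizes

The test suite and `scripts/acceptance.R` exercise: formula oracles on
100 random inputs each; duplex scores against an independent recursive
oracle on 200 random miRNA/site pairs plus 50 sponge round trips; isomiR
recovery on 10,000 reads; pull-down recovery on 5000 genes with a
100-seed null calibration at 2000 genes; trend recovery on 800 pairs ×
50 patients; and log-rank power/size over 100 simulation replicates of
200 patients. These sizes put Monte-Carlo error well inside the stated
tolerances while keeping a full run in the order of a minute.

# Known limitations

* Duplex pairing has no free-energy model; scores are not comparable to
  RNAhybrid/miRanda energies, and with cost-free mismatches the aligned
  extent of weakly pairing sites is not a reliable boundary (the seed
  anchor is).
* The DE stand-in test assumes count-like inputs and no replicates; for
  real experiments supply externally computed FDRs.
* The isomiR matcher is exact and anchored (no indels within reads) and
  uses precursor context rather than a genome; 5′ isomiR biology beyond
  bookkeeping is out of scope.
* Cox-estimated risk-score weights use the two arm levels only; clinical
  covariates are not modeled.
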