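---
title: "Selecting and validating qRT-PCR reference genes from stage-wise RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and validating qRT-PCR reference genes from stage-wise RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative quantification by qRT-PCR divides a target gene's signal by that
of one or more reference ("housekeeping") genes, so every conclusion is
conditional on the references actually being stable. During early
development — zebrafish embryogenesis is the motivating system, with nine
stages from cleavage to early larva — classic references such as the
beta-actins vary several-fold, and normalizing against them distorts
target profiles. `refstab` implements the complete computational workflow
for replacing them:

1. **screen** a genes × stages RPKM matrix for stably, adequately
   expressed candidates;
2. **rank** candidate stability from qRT-PCR CT data with four
   independent statistics (delta-CT, geNorm, BestKeeper, NormFinder) and
   a cross-method aggregate;
3. **validate** chosen references by comparative-CT normalization of
   target genes and concordance with the RNA-seq profiles;
4. **simulate** all of the above with known ground truth.

## Screening cascade

`run_screen()` applies five filters in order to the per-gene statistics
from `screen_stats()` (minimum, maximum, max/min ratio, mean $\mu$,
sample SD, CV $= \mathrm{SD}/\mu$):

| stage | predicate | default | boundary |
|---|---|---|---|
| expressed | $\min_s \mathrm{RPKM} \ge t$ | $t = 0.17$ | inclusive |
| stability | $\mathrm{RPKM}_{max/min} < 2$ and $\mathrm{CV} < 0.3$ | — | strict |
| abundance | $\min_s \mathrm{RPKM} > 40$ | — | strict |
| top-N | smallest ratios kept | $N = 5$ | ties: CV, then gene id |
| annotation | 1 transcript, or 2 overlapping | — | multi-isoform dropped |

Design notes, where the choices were genuinely open:

* *"Expressed" means expressed at every stage.* A reference gene that
  disappears at one stage is useless, and requiring a positive minimum
  also guarantees the max/min ratio is defined downstream. The boundary
  is inclusive; the stability and abundance limits are strict, matching
  the conventional way these thresholds are printed.
* A statistical test is sometimes quoted alongside the CV cut in this
  literature without naming the test; no test is implemented here — the
  CV cut is applied as a plain threshold.
* Genes with three or more isoforms are dropped by default because
  isoform-aware primer design is not automatable from a transcript count
  alone; `allow_multi_isoform = TRUE` keeps them.
* A gene whose minimum RPKM is 0 gets an undefined (NA) ratio marker,
  not an error, and is removed by the expression filter anyway.

The report records survivors at every stage; survivor sets are strictly
nested, and validation never drops rows silently.

## Stability statistics

All four methods consume a replicate-collapsed CT table (arithmetic mean
over technical replicates; the per-cell replicate SD is kept as
metadata). Collapsing first is a deliberate choice — technical replicates
measure pipetting noise, not biological stability — and `ct_summary()`
retains the replicate spread for inspection. The sample SD (denominator
$n-1$) is used throughout; stage counts are small, so the unbiased form
is the safer default.

**Delta-CT.** For genes $i, j$ and samples $s$, the statistic of gene $i$
is $\frac{1}{g-1}\sum_{j \ne i} \mathrm{SD}_s\!\left(CT_i(s) -
CT_j(s)\right)$, in cycles. A gene that keeps a constant CT offset to
every partner scores 0.

**geNorm.** CT converts to relative quantities $q_i(s) =
b^{\,\min_s CT_i - CT_i(s)}$ with base $b = 2$ by default (any per-gene
affine calibrator gives identical results). The M value is the mean over
partners of $\mathrm{SD}_s\!\left(\log_b q_i / q_j\right)$; the
highest-M gene is removed and M recomputed until the most stable pair
remains. Because $\log_b q_i/q_j$ is an affine function of $CT_j - CT_i$,
the full-set M equals the delta-CT statistic exactly — asserted in the
tests as a cross-method identity, which is why the two methods disagree
only through geNorm's stepwise exclusion. Excluded genes report M at
their exclusion step; the final pair shares the two-gene M and rank 1,
with the next gene at rank 3. A tie on the highest M during exclusion
removes the lexicographically last gene id, deterministically. The
pairwise variation $V_{n/n+1} = \mathrm{SD}_s \log_b
\mathrm{NF}_n/\mathrm{NF}_{n+1}$ compares normalization factors
(geometric means of quantities) as references are added in stability
order; it is reported, but no "$V < 0.15$ suffices" decision rule is
applied.

**BestKeeper.** Works on raw CT: per-gene arithmetic and geometric mean,
range, SD (cycles) and CV ($100 \cdot \mathrm{SD}/\overline{CT}$, %),
plus each gene's Pearson correlation to the BestKeeper index (per-sample
geometric mean CT of the panel). Ranking is by ascending SD with CV as
tie-break: published tables in this area sometimes order by "CV ± SD" in
ways inconsistent with either column alone, so the package ranks
strictly by its stated key and documents the choice. A zero-variance
gene has an undefined correlation (NA) and ranks by SD alone.

**NormFinder** (single-group form). The additive model $y_{ij} =
\alpha_i + \beta_j + \varepsilon_{ij}$ on $y = -CT$ (log2 expression up
to a constant that cancels under double centering) yields residual
variances $v_i$, and the unbiased per-gene variance estimate
$\hat\sigma^2_i = \frac{g}{g-2} v_i - \frac{\sum_k v_k}{(g-1)(g-2)}$,
which inverts the expectation system $E[v_i] = \sigma^2_i (g-2)/g +
\sum_k \sigma^2_k / g^2$. The reported stability value is
$\sqrt{\max(0, \hat\sigma^2_i)}$ — the estimator is unbiased but not
non-negative at small $n$, so negative estimates clamp to zero before
the square root. The two-group bias term of the original method is out
of scope here because priming groups are analyzed separately.

**Aggregation.** `rank_stability()` runs whichever methods the dataset
supports (a method whose preconditions fail is omitted with a warning),
separately per priming group, and summarises with the geometric mean of
the per-method ranks, re-ranked ascending with ties sharing a rank.

## Validation

`comparative_ct()` computes relative expression $2^{-(CT_t -
CT_{ref})}$ per sample, where $CT_{ref}$ is the arithmetic mean CT of
the reference set — equivalently the log of the geometric mean of their
quantities, the conventional way to combine multiple references — with
optional rescaling to a calibrator sample. Efficiency correction is
deliberately not applied (the equal-efficiency assumption, base 2);
per-gene bases are accepted through the `base` argument for users who
measured them. `concordance()` then reports Pearson's $r$ between the
normalized profile and the RPKM profile across matched stages, on the
log2 scale by default so that $r$ is invariant to multiplicative
rescaling of either axis (both profiles carry arbitrary units); at
least 3 matched stages are required, and zero variance on either side
yields NA with a message rather than a spurious value.

`fit_efficiency()` fits $CT = a + b\log_2(\text{dilution})$ by least
squares: slope $b = 1$ means perfect doubling, the amplification
efficiency is $E = 2^{1/b} - 1$, and a series passes QC when
$R^2 > 0.99$. A non-positive slope (CT failing to rise with dilution)
leaves $E$ undefined.

## The synthetic study

`simulate_rpkm()` / `simulate_ct()` / `simulate_dilution()` generate the
full study with known truth. Defaults are fixed once and describe the
emulated study design:

* 9 stages; 2,000 genes at desk scale (the full-transcriptome scale is
  one config change, but the desk scale keeps a complete screen under a
  second);
* designed-stable genes: flat profiles, log2 noise SD 0.1 (CV about
  0.07, max/min ratio well under 2), means log-uniform on 64–512 RPKM —
  above the abundance floor;
* designed-variable genes: stage trends drawn per gene from monotone
  ramps (random direction), maternal-decay shapes and transient
  zygotic pulses (random interior peak), with log2 spans of 2.6–3.1 —
  max/min ratios of roughly 6–8.5, the contrast actin-family
  comparators show against genuine candidates in early zebrafish
  development — plus extra per-stage CT instability with SD drawn from
  0.4–1 cycles;
* CT model: $CT = 30 - \log_2(\mathrm{RPKM}) + \delta_{g,\text{group}}
  + \tau_g(s) + \eta$, with per-gene priming-group offsets
  $\delta \sim N(0, 0.5)$ for the second group (they cancel in
  within-group statistics by shift invariance), technical triplicates
  with $\eta \sim N(0, 0.15)$ cycles;
* noise is Normal on the CT (log2) scale throughout, matching the
  multiplicative error structure qPCR assumes;
* identical config and seed give byte-identical output.

What the generator does *not* emulate: amplification curves and
melt-curve behaviour, sequence-level effects (primer specificity,
pseudogene cross-amplification), inter-library normalization artefacts
in RPKM, and co-regulation beyond what the shared trend archetypes
induce. Passing recovery tests therefore show that the statistics
identify designed stability under this noise model — not that any
particular wet-lab panel will behave.

## Numerical and testing choices

* Readers/writers use TSV with `.` decimals; doubles are written with 17
  significant digits so files round-trip bitwise.
* CT values outside 5–40 cycles are flagged in a validation report but
  never dropped.
* Tie-breaks are deterministic everywhere (documented per function), so
  identical inputs give identical rankings.
* Test problem sizes: oracle equivalence on instances up to 6 genes ×
  10 samples (50 random draws per run), cross-method identity on 100
  random 6 × 9 matrices, parameter recovery at 8 genes × 500 samples
  over 20 seeds, ranking recovery on 100 seeded 6-gene two-group
  studies, and a 2,000-gene screening substrate — sizes chosen to
  exercise each property at the scale the method is meant for.

## Known limitations

* **NormFinder with few, co-trending candidates.** In the single-group
  form the gene ranking reduces to the ordering of the raw residual
  variances $v_i$. With a 6-gene panel in which 4 genes carry
  developmental trends, panels whose variable genes happen to co-trend
  violate the method's mostly-stable-panel assumption: the sample
  effect absorbs the shared trend, deflating the co-trending genes'
  residuals and inflating the flat genes'. The recovery simulations
  make this visible — NormFinder misses the designed-stable top-2
  noticeably more often than geNorm (whose stepwise pair mechanism is
  immune) or BestKeeper (which never compares genes to each other).
  This mirrors the original method's own advice to screen candidate
  panels for co-regulation.
* The delta-CT statistic and the cross-method aggregate inherit a
  milder version of the same sensitivity, being pairwise averages over
  the whole panel.
* No Pfaffl-style efficiency-corrected ratios, no confidence intervals
  on fold changes, no multi-group NormFinder bias term, no plotting of
  stage curves beyond the provided `autoplot()` methods.
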