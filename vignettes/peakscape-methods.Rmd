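---
title: "peakscape methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{peakscape methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakscape)
```

This vignette documents the statistical model behind each module, every
default parameter with its rationale, what the synthetic generator does
and does not model, and the decisions taken where the underlying method
admitted more than one reasonable reading.

## Coordinates and interval semantics

All coordinates at the user and file boundary are BED-style: 0-based
starts, exclusive ends. Internally intervals are `GRanges` (1-based,
closed) and every function converts at the boundary. Two consequences
are load-bearing everywhere:

* **overlap** means at least one shared base pair — a fragment ending
  at position $x$ does not touch a peak starting at $x$;
* **merge** unions only overlapping intervals — abutting intervals
  (`end == start`) stay separate, and merging is idempotent and
  independent of input order (sequence names are kept in sorted order
  for this reason).

## Peak landscape

### Reproducible peaks

Each sample carries two peak calls: a high-confidence set (strict
caller threshold) and a low-confidence superset (relaxed threshold). A
high-confidence peak is *reproducible* when it overlaps a
low-confidence peak of at least one **other** sample of the same
genotype group (`support = "any"`; `"all"` requires every other
sample, and the two readings coincide with two replicates). Retained
peaks of a group are merged. Using the relaxed call of the partner
sample, rather than its strict call, keeps peaks that fell just below
threshold in one replicate — the standard guard against thresholding
artifacts — while still requiring independent evidence.

### Reference set and presence

The union of the three group peak sets is merged into a reference set;
each reference peak records a presence flag per group (≥ 1 bp overlap
with that group's reproducible peaks).

### Fragment counting

Fragments with length strictly below 2,000 bp are counted into every
reference peak they overlap by ≥ 1 bp (a long fragment may hit several
peaks). The per-sample library size is the number of size-passing
fragments, counted once, so the size filter and normalization use the
same universe.

### Moderated differential occupancy

Counts are transformed to
$\log_2\!\big((c + 0.5) / (L + 1) \times 10^6\big)$ (log2-CPM with a
0.5 pseudocount; the $+1$ on the library size keeps the transform
finite for empty samples). For each contrast (ATRX vs MYCN, ATRX vs
WT) a two-sample t-statistic uses the pooled within-group variance,
shrunk toward a common prior by empirical Bayes: the prior degrees of
freedom $d_0$ and prior variance $s_0^2$ are estimated from the
marginal distribution of $\log s^2$ by the method of moments
(digamma/trigamma equations, Newton inversion of the trigamma), and
the posterior variance is the $d_0$:$d$-weighted average. The
t-statistic is referred to $d + d_0$ degrees of freedom and p-values
are Benjamini–Hochberg adjusted per contrast. Rows with zero variance
everywhere and zero fold-change return $t = 0, p = 1$ rather than NaN.
A null simulation (Poisson counts, no group effect) keeps the raw
$p \le 0.05$ fraction near 0.05; the test suite pins it to
$[0.03, 0.07]$.

### C/E/D/O classification

Presence patterns map to labels: present in all three groups → **C**;
only in ATRX → **E**; absent in ATRX but present in both others →
**D**; in ATRX plus exactly one other → **O**; anything else is
unclassified. The default mode uses presence only. The
`presence+stats` mode additionally demotes E/D candidates whose
differential statistics do not support them (adjusted $p \le 0.05$ and
consistent fold-change sign in both contrasts). **Decision:** presence
mode is the default because the labels are defined by the peak-calling
geometry; the statistical gate is offered as a stricter optional
reading rather than silently changing what a label means.

## Annotation

* **G4 / R-loop**: a peak is G4-positive on ≥ 1 bp overlap with the
  G-quadruplex track; the R-loop flag is only evaluated for
  G4-positive peaks, since the reported fraction is
  "R-loop-forming among G4 peaks".
* **Dominant state**: the ChromHMM state covering the most bases of
  the peak; exact ties go to the lower state number (deterministic),
  and a peak with no segmentation cover is `NA`, not a guess.
* **Concordance** asks whether the chromatin state agrees with the
  occupancy call: samples of groups where the peak is present should
  show a different state than samples of groups where it is absent.
  **Decision:** the default rule (`"disjoint"`) requires the set of
  dominant states among present samples to be disjoint from that among
  absent samples. The alternative `"active_class"` rule instead asks
  that present samples sit in active state classes and absent samples
  outside them. Disjointness is the default because it needs no
  opinion about which states count as "active" and is symmetric in
  the two sides.
* **Location**: promoter when the peak overlaps
  $[\mathrm{TSS} - 2\,\mathrm{kb}, \mathrm{TSS} + 2\,\mathrm{kb})$ for
  any gene (strand-agnostic, half-open on both ends like every other
  window); otherwise enhancer when the dominant state among present
  samples is an enhancer-class state; otherwise other.
* **State-13 expansion**: per gene, the covered proportion of the
  strand-aware 2 kb window downstream of the TSS is computed in two
  segmentations; the state is *expanded* when
  $p_{\mathrm{plus}} > 2\, p_{\mathrm{minus}}$ **and**
  $p_{\mathrm{plus}} \ge 0.20$. Both cut-offs are inclusive/exclusive
  exactly as written; the boundary rows (0.20 vs 0 expands, 0.40 vs
  0.25 does not) are pinned in the tests.
* **DMR–promoter–DEG intersection** applies its gates exactly: DMR
  length ≥ 50 bp, ≥ 3 CpGs, $|\Delta\mathrm{meth}| \ge 0.2$,
  $p \le 0.01$; DEG $|\log_2\mathrm{FC}| \ge 1$, adjusted
  $p \le 0.1$; promoter window ±1 kb around the TSS.

## Clinical statistics

`fisher_two_tailed` is the point-probability two-sided Fisher test:
the sum of hypergeometric probabilities of all tables (fixed margins)
no more probable than the observed one. This matches values such as
0.6180 that tail-doubling does not reproduce. Degenerate tables (a
zero margin) return $p = 1$ with a flag.

`chi_square_test` is Pearson's test without continuity correction and
refuses tables with a zero expected count, directing the caller to
Fisher. `select_test` applies the classical rule: Fisher when any
expected count is below 5.

`table1_association` evaluates a classification of the packaged cohort
counts. **Decision:** each classification carries a *pinned* test
(recorded alongside the counts) rather than relying on the selection
rule, because the published analyses chose tests per row "depending on
sample size" without stating the rule, and one row (race) only
reproduces under the uncorrected chi-square even though the
expected-count rule alone would not force that choice. The pinned
assignments are the ones that reproduce each published value; `auto`,
`fisher` and `chi_square` remain available for sensitivity checks.

`cmh_test` wraps the Mantel–Haenszel chi-square (no continuity
correction); a single stratum uses the closed form with the
finite-population variance, so it equals Pearson's chi-square times
$(N-1)/N$. `clopper_pearson` is the exact beta-quantile interval.

## Screen scoring

A 96-well plate holds one compound per row across columns 1–10
(columns 11 and 12 are vehicle and positive control). Concentrations
follow a pin-tool transfer: stock divided by 890, then nine further
1:3 dilutions (10 mM stock → 11.236 µM top dose).

Normalization is anchored on the control means of the same plate:

* **cytotoxic**: affine map sending the vehicle mean to 1 and the
  positive-control mean to 0 (fraction of surviving signal);
* **protective**: $\log_2(\mathrm{RLU})$ minus the mean
  $\log_2(\mathrm{RLU})$ of vehicle wells, so a doubling of signal is
  exactly $+1$.

Replicate-pooled responses are fitted against $\log_{10}$
concentration with a cubic smoothing spline (GCV-selected smoothness;
constants and straight lines are reproduced exactly). The **protective
AUC** integrates, by a 256-point trapezoid rule,
$\max(\hat f(x) - \hat f(x_{\min}), 0)$ over the dose range.
**Decision:** the baseline is the *fitted value at the lowest dose*
rather than zero or the vehicle level. A compound that does nothing at
low dose and rescues viability in a mid-dose window scores its window
area; any flat or monotone-decreasing (purely cytotoxic) profile
scores exactly 0, which is the property the screen ranks on. Against
dense quadrature of a known generating curve the 256-point rule is
accurate to well under 1%.

## Assay metrics

`telomere_delta_ct` is the qPCR difference
$\overline{Ct}_{\mathrm{control}} - \overline{Ct}_{\mathrm{telomere}}$,
so larger values mean more telomeric signal. `relative_peak_area` is
the metabolite/internal-standard area ratio divided by the sample
amount; it is exactly homogeneous of degree $-1$ in the amount.

## Synthetic generator: scope and defaults

The generator plants a fully known truth and simulates only what the
pipeline consumes; it is a test harness, not a sequencing simulator.
It does **not** model read-level error, GC or mappability bias,
diploid genotypes, or caller behaviour — peak calls are derived
directly from planted peaks plus controllable corruption.

Defaults (all fixed a priori and overridable):

| parameter | default | rationale |
|---|---|---|
| genome | 3 sequences × 1 Mbp | smallest size that exercises multi-sequence code honestly |
| peak width / min gap | 600 bp / 1,000 bp | typical point-source peak scale; gap prevents accidental merges |
| replicates per group | 2 | the minimum the reproducibility rule is defined on |
| fragment length | normal(250, 300) clipped to [50, 4000] | spans the strict 2,000 bp counting cut-off from both sides |
| enrichment | 40 fragments/peak/sample | deep enough that presence is unambiguous at zero noise |
| background noise | 0.2 fragments/kbp | visible but not label-flipping at defaults |
| peak jitter | 25 bp | sub-peak-width call variation between replicates |
| low-confidence pad | 100 bp | low calls strictly contain high calls |
| spurious low-call rate | 2 × 10⁻⁵ per bp | rare unsupported low peaks |
| G4 fraction / R-loop given G4 | 0.35 / 0.70 | planted annotation fractions recovered by the pipeline |
| plate noise | σ = 0.15 on log2 RLU | realistic well-to-well CV ≈ 10% |

Cohort simulation reproduces stratum margins *exactly* (mutants are
assigned by sampling without replacement within each stratum), so
contingency tables built from any simulated cohort equal the packaged
counts for every seed. Plate simulation is a 4-parameter logistic
dose–response on the log2 scale plus an optional Gaussian
"protective" bump in $\log_{10}$ concentration.

All generators take explicit integer seeds and restore the caller's
random-number state, so results are reproducible and runs do not
interfere.
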