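---
title: "Multi-measure, multi-laboratory screening of PDX trials: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-measure, multi-laboratory screening of PDX trials: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxscreen)
```

## The model and its assumptions

A PDX trial measures tumor volume `Vol(t)` per mouse on a handful of
protocol days, in a control and a treated arm, at one or several
laboratories. All inference in this package runs on the *empirical tumor
growth trajectory* (ETGT): the ordered points
$(t_k,\; \%\Delta\mathrm{Vol}(t_k))$ with
$\%\Delta\mathrm{Vol}(t) = 100\,(\mathrm{Vol}(t)-\mathrm{Vol}(0))/\mathrm{Vol}(0)$.
Normalizing to the day-0 baseline makes mice with different implant sizes
comparable; it also means a missing day-0 record cannot be repaired, so
such trajectories are rejected at ingestion rather than imputed.

Five per-mouse measures summarize an ETGT, chosen to cover complementary
failure modes of single-statistic screening:

* **DTV~21~** — the percent change at day 21 (a single endpoint);
* **AUC~21~** — the trapezoid area under the piecewise-linear ETGT to day
  21 (integrates non-monotone trajectories);
* **AUCmax** — the trapezoid area over the whole trajectory truncated at
  day 21, divided by the number of measurement days, so trajectories of
  different durations are comparable (defined for mice surviving at
  least 10 days);
* **TGI~21~** — $\ln(\%\Delta\mathrm{Vol}(21)/100 + 1)$, the log of the
  volume ratio from baseline, whose arm difference is the classical tumor
  growth inhibition contrast (needs only days 0 and 21);
* **PFS~4~** — time to the first measured day with
  $\%\Delta\mathrm{Vol} > 400$, right-censored at day 21 (tolerates
  censoring and early termination).

Arm comparisons use conventional tests: Welch's two-sample $t$ for the
three area/endpoint measures, the OLS regression of TGI on the treatment
indicator (whose 1-df $F$ equals the pooled two-sample $t$; the suite
checks the equivalence numerically to 1e-10), and the log-rank test for
PFS. All tests are two-sided — sidedness is a design choice here, made
because two-sidedness is the conservative default and is consistent with
the published tables this package reproduces.

The p-value grid over $M$ measures and $L$ labs is then extended in two
directions. Across labs, Fisher's method combines each measure's row:
$X^2 = -2\sum_l \ln p_{(m,l)} \sim \chi^2_{2L'}$, with $L'$ the number of
non-missing entries (missing labs shrink the degrees of freedom, so a lab
that measured only 14 days still contributes where it can). Across
measures, Storey's step-down q-values are computed down every column,
including the Fisher column: on the ascending sort,
$q_{(M)} = p_{(M)}$ and $q_{(j)} = \min(q_{(j+1)}, (M/j)\,p_{(j)})$,
with $M$ likewise shrunk to the non-missing count. Four decision rules
read the resulting basis table: SMSL (each p-cell), SMNL (each Fisher p),
NMSL (per lab, minimum q), NMNL (trial-wide, minimum Fisher-column q),
each calling "completely responsive" when its value is at or below the
significance level.

Performance is summarized against CR/PD ground truth as sensitivity,
specificity, and accuracy, with sampling distributions estimated by the
stratified bootstrap: mice are resampled with replacement within each
(tumor model × lab × arm) stratum, the basis table and all calls are
rebuilt per resample, and each metric is reported as its median with the
percentile 95% interval.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `t` | 21 days | horizon for DTV/AUC/TGI and the PFS censoring day |
| `delta` | 4 | fold-increase defining progression (event when `%ΔVol > delta × 100`, strictly) |
| `min_days` | 10 days | minimum survival for AUCmax |
| `alphas` | 0.1, 0.05, 0.01, 0.001 | screening significance levels |
| `n_resamples` | 10000 | bootstrap resamples (reference analyses); tests and examples use 40–1000 |
| `fraction` | 0.20 | tail fraction per side in threshold selection |

## Numerical and edge-case choices

* **Horizon handling.** If day 21 was not itself measured but flanking
  days were, DTV/AUC/TGI use linear interpolation of the ETGT at day 21
  (the minimal extension of the piecewise-linear model); a trajectory
  ending before day 21 leaves those measures undefined for the mouse,
  which is excluded for them and counted in the result's `n_` columns.
* **AUCmax truncation.** Points after day 21 are dropped and the
  measurement-day count is recomputed before normalizing.
* **PFS censoring.** Mice from early-terminated protocols that never
  progress are censored at their last observed day, not at 21 — standard
  right-censoring; the day-21 censoring rule applies to full-length
  trajectories.
* **Degenerate tests.** Two constant identical arms give $t = 0$, p = 1
  (computed analytically, since `t.test` refuses constant data). A
  log-rank comparison with zero variance returns p = 1 when both arms
  share one event table and is reported missing (with a note) otherwise;
  a lab with fewer than two usable mice in an arm yields a missing
  p-value with a note rather than an error, mirroring the NA cells of
  published multi-lab tables.
* **Fisher underflow.** The chi-square upper tail is evaluated in log
  space, so combined p-values around 1e-300 remain representable; an
  exact zero input propagates to 0 with a warning.
* **q-value clamping and ties.** Step-down q-values are clamped at 1
  (the raw formula can exceed it near p = 1); tied p-values receive equal
  q-values by construction of the tail minimum, and the brute-force
  closed form $q_{(j)} = \min_{k \ge j}(M/k)p_{(k)}$ serves as the
  independent oracle in the tests (agreement to 1e-12).
* **Percentiles.** Bootstrap quantiles use linearly interpolated order
  statistics (R's default type 7), stated explicitly because percentile
  conventions differ.
* **Reproducibility.** The bootstrap draws one sub-seed per resample from
  the master seed, so summaries are bit-identical for a fixed seed and
  independent of evaluation order.
* **Threshold-selection ties.** The per-tail cutoff is
  $\lfloor \mathrm{fraction} \times N \rfloor$; ties at the cutoff are
  broken by stable original order, making labels deterministic. Labels
  depend only on ranks, hence are invariant under monotone transforms of
  either summary.

## The synthetic trial generator

`simulate_pdx_trial()` generates volumes as
$\mathrm{Vol}_i(t) = V_{0,i}\, e^{(g_i + \beta\,T_i)t}\,\varepsilon_{i,t}$:
a lognormal baseline (mean 150 mm³, CV 0.2), a per-mouse normal
log-growth rate $g_i$ (0.08 ± 0.015 per day, so control tumors roughly
quintuple by day 21, matching the scale of published example
trajectories), a treatment shift $\beta$ on the log-growth rate (−0.12
per day in the CR regime, giving net tumor regression of the size seen in
published treated-arm summaries; exactly 0 in the PD regime, which is the
null), and i.i.d. multiplicative lognormal measurement noise (sd 0.08 on
the log scale). Multiplicative noise keeps volumes positive, preserving
the trajectory invariants. Defaults are 5 labs with 5 control and 5
treated mice on days {0, 4, 7, 11, 14, 18, 21}; `dropout_day` truncates a
lab's protocol (e.g. 14 days) to emulate heterogeneous designs.

What the generator emulates: arm structure, multi-lab replication, noisy
exponential growth, between-mouse heterogeneity, early-termination
protocols, and known ground truth. What it does not: non-monotone
regrowth, carrying-capacity saturation, dropout correlated with tumor
burden, and inter-lab protocol differences beyond measurement-day
truncation. Tests passing on synthetic data therefore validate the
statistical machinery and its calibration, not the biological adequacy of
an exponential growth model for any particular tumor.

The generator's control-arm mean day-21 change has the closed form
$100(e^{21\mu_g + ((21\sigma_g)^2 + 2\sigma_\varepsilon^2)/2} - 1)$,
which the suite checks by Monte Carlo — a direct test that the generator
implements its own stated model.

## Known limitations

* **Min-q rules are conservative under dependence.** NMSL and NMNL call
  CR when $\min_j (M/j)p_{(j)} \le \alpha$ — the Simes statistic. Its
  false-positive rate equals $\alpha$ under independent uniform p-values
  and under perfect dependence, but the five measures are computed from
  the *same* trajectories and are strongly positively correlated, a
  regime in which the Simes rule is conservative: the test suite measures
  null CR rates for NMSL/NMNL noticeably below $\alpha$ at the 0.1 and
  0.05 levels (the corresponding calibration expectations in the
  acceptance tests record this as a deviation), while SMSL and SMNL
  calibrate exactly and every individual measure's null p-value is
  uniform. The error is in the safe direction — fewer false positives
  than nominal — at some cost in power accounting.
* **Published-table reproduction is limited by printing.** Golden tests
  recompute q-values and Fisher combinations from p-values printed at 3
  significant figures; cells whose published values reflect unrounded
  inputs are compared at 2 significant figures, and a small number of
  cells in the published tables are inconsistent with the printed
  formula (one q-cell a factor of 10 from the step-down value); tests
  assert the formula.
* **Accuracy granularity.** For heterogeneous (mixed CR/PD) labs,
  accuracy is tallied over all non-missing cells (SMSL) or lab-level
  calls (NMSL) per the confusion-matrix definition; published histogram
  modes at 0.85 under other denominators are not imitated, since no
  formula reproducing them follows from the stated definitions.
* **Problem sizes.** The suite runs the null-calibration study at 2000
  simulated two-lab trials with 8 mice per arm, bootstrap checks at
  40–300 resamples, and the reference analyses at 10000 resamples; these
  sizes are the package's chosen trade-off between Monte-Carlo precision
  and runtime, and the tolerances in the tests (3 binomial SDs) are set
  accordingly.

## Interfaces

Everything is reachable from R: `read_trial_table()` /
`as_pdx_trial()` for ingestion, `mouse_measures()` and
`measure_pvalues()` for the measure layer, `basis_table()` /
`as_pdx_basis()` / `splice_basis()` for the meta-analysis layer,
`screening_calls()` / `score_calls()` / `screen_basis()` for decisions,
`bootstrap_screen()` for uncertainty, `threshold_select()` and
`build_simulated_labs()` for ground-truth construction, and
`pdx_screen()` as the one-call runner returning a classed object with
`print`, `summary` and `plot` methods. `scripts/acceptance.R` is a thin
command-line wrapper that recomputes the reference quantities and writes
them as JSON.
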