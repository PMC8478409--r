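---
title: "Quantifying protein turnover from pulsed-SILAC labelling"
author: "silacTurnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein turnover from pulsed-SILAC labelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silacTurnover)
```

## The measurement and the model

In an in vivo pulsed-SILAC experiment, animals are switched to a diet in
which lysine carries six ^13^C atoms. Proteins synthesised during the pulse
incorporate heavy lysine; proteins made earlier retain light lysine. Mass
spectrometry reports, per protein group and replicate, a heavy/light ratio
H/L and per-channel iBAQ intensities. The fraction of the protein pool
synthesised during the pulse is estimated as

$$\%\,\text{incorporation} \;=\; 100 \cdot \frac{H/L}{H/L + 1},$$

a strictly increasing bijection from ratios in $[0,\infty)$ onto percentages
in $[0,100)$. All replicate aggregation in this package is the *mean of
per-replicate percentages*, not the percentage of the mean ratio: the two
differ under noise, and the former is the convention the summary statistics
and figures of this kind of study use.

The kinetic backbone is one-compartment first-order turnover. A protein pool
with turnover rate constant $k$ (per day), in a tissue whose mass grows at
rate $g$ (per day), replaces unlabelled molecules at effective rate $k+g$;
with precursor enrichment $p$ the labelled fraction after a pulse of $t$
days is

$$f(t) = p\left(1 - e^{-(k+g)t}\right),$$

and a subsequent chase of duration $t_c$ decays it to
$f_c = f \, e^{-(k+g)t_c}$. Two consequences shape everything downstream:

* **Growth dilution and turnover are confounded.** A single pulse
  identifies only $k+g$ (`recover_rate()` is explicit about this). The
  pulse-chase contrast separates stable proteins from fast ones regardless.
* **Saturation destroys rate information.** As $(k+g)t$ grows, $f \to p$
  and the inverse $\hat{k} = -\log(1-f/p)/t$ becomes ill-conditioned; at
  $(k+g)t \approx 21$ a double-precision fraction retains only about eight
  significant digits of rate. The tests assert recovery "to machine
  precision" at a tolerance of $10^{-8}$ for exactly this reason, and the
  ratio$\leftrightarrow$percent round-trip is asserted to 12 digits over
  ratios in $[10^{-3}, 10^{3}]$, the physically plausible range — beyond
  it the percentage is within double rounding of 100.

## Turnover classes

The pulse-chase design yields two percentages per protein: `percent_A`
(end of pulse) and `percent_B` (end of chase). Proteins with more than 80%
incorporation during the pulse that retain less than 20% after the chase
are called **fast**; of the rest, proteins whose retention ratio
$r = \%B/\%A$ is at least 0.8 are **stable**; everything else is
**intermediate**. The inequalities are strict exactly as stated, and the
three thresholds (80, 20, 0.8) are arguments of `classify_turnover()`
rather than constants: the fast rule is standard in the field, but the
stable rule operationalises a definition that is usually drawn graphically,
so an analyst may reasonably want to move it. Fast and stable cannot
overlap analytically ($\%A > 80 \wedge \%B < 20 \Rightarrow r < 0.25$),
and the classifier provably partitions its input — both are property-tested.

## Quantification statuses

Replicate aggregation (`summarize_group()`) assigns each protein one of
four statuses: `OK` (at least two replicates quantified — mean and SD are
reported), `NQ` (detected but fewer than two ratios), `NL` (only the light
isotope quantified: no ratio and no heavy iBAQ anywhere, light iBAQ
present), and `ND` (no signal at all). Only `OK` proteins enter the
retention profile; exclusions are returned with a reason rather than
silently dropped.

## Three imputation schemes, and why their extremes differ

Missingness in this kind of data is informative (missing not at random): a
channel intensity below the detection limit disappears, so a fully labelled
protein tends to lose its *light* channel and a fully turned-over protein
its *heavy* channel. The package implements three complementary schemes,
applied in this order in the differential pipeline: evidence-based extreme
imputation first, then the eligibility filter, then KNN completion.

1. **Censored-extreme (pulse-chase)** — `impute_censored_pulse()`. A
   pulse-group protein missing iBAQ L in at least 3 of 4 replicates is
   treated as fully labelled: its missing ratios are set to the *observed
   column maximum + 0.1*. A chase-group protein missing iBAQ H in at least
   3 of 4 replicates is treated as fully turned over: *column minimum −
   0.01*, floored at $10^{-4}$ because a ratio must remain positive for
   the percentage transform. The "more than 2 of 4" replicate threshold is
   configurable (`min_missing`); the strict reading (≥ 3) is the default.
   Only proteins with lysine-containing peptides are imputed — lysine is
   the labelled amino acid, so proteins without lysine peptides carry no
   labelling information.
2. **KNN (young vs older comparison)** — `impute_knn()`. Proteins with at
   least two valid values across the combined replicates have remaining
   cells filled with the mean of the target column over the $k = 3$
   nearest rows, by plain Euclidean distance on mutually observed columns.
   KNN runs on *percent incorporation*, not raw ratios: percentages are
   bounded and share units across columns, so no rescaling is needed (and
   none is applied). Ties in distance break by row order. The
   implementation is tested cell-for-cell against a brute-force all-pairs
   oracle.
3. **Uniform-near-extreme (one-group-absent rescue)** —
   `impute_extreme_uniform()`. A protein with ratios in one group but none
   in the other is rescued through its iBAQ evidence: heavy iBAQ in ≥ 2
   replicates ⇒ draws from Uniform(max, max + sd); light iBAQ only ⇒
   Uniform(0, min), where max/min/sd are taken over *all* observed ratios
   of the combined dataset — deliberately a different extreme than the
   per-column extremes of scheme 1, because the two schemes answer
   different questions (a replicate-level detection failure vs a
   group-level biological state). Draw intervals are open in practice (a
   continuous draw hits an endpoint with probability zero). Draws are
   seeded, reproducible, and the rescued proteins are flagged
   `recovered_by = "ibaq_extreme"` in the differential output.

Every imputed cell generates exactly one audit record (scheme, basis,
bounds, seed), and observed cells are bit-identical before and after every
scheme — both are invariants in the test suite.

## Differential incorporation and its operating characteristics

The young-versus-older comparison (`differential_table()`) runs an
unpaired two-sided *pooled-variance* Student's t-test per protein on
percent incorporation, Benjamini–Hochberg correction across the proteins
of one tissue, and calls a protein significant when $q < 0.05$ and the
signed fold change exceeds 1.5 in magnitude. Pooled variance (rather than
Welch) is the default because variance homogeneity is screened separately
— `distribution_screen()` runs Shapiro–Wilk on within-group-centred
replicates and Levene's test per protein, advisory only; Welch sits behind
`welch = TRUE`, and `on_log_ratio = TRUE` reruns the tests on log2 ratios
as a sensitivity analysis. The signed fold change is the ratio of mean
percentages, ≥ 1 in magnitude, positive when the older group incorporates
more.

Two simulation properties pin down the operating characteristics, both at
fixed documented seeds (11 and 12) with 500 proteins, 4 replicates and 20%
ratio CV:

* **Null control:** with no true effects, the fraction of proteins called
  significant is at most 5% (empirically it is essentially zero — BH plus
  the fold-change gate is conservative at this scale).
* **Power:** with 2-fold rate effects in 20% of proteins, sensitivity
  exceeds 50%. The cap is kinetic, not statistical: a 2-fold rate change
  in an already-saturated fast protein moves its labelled fraction from
  ~96% to ~85%, a fold change of ~1.1 that no test should call a 1.5-fold
  effect. Among kinetically identifiable (intermediate and slow) proteins
  sensitivity is 85–95%; averaged over the default mixture it is ~53%.
  These two simulations disable the dropout model so that they measure the
  testing machinery in isolation; the missingness direction and the rescue
  path are validated by their own tests.

## What the generator emulates — and what it does not

`generate_dataset()` draws per-protein rates from a three-component
log-normal mixture (defaults: fast $k \sim 0.2$/day, weight 0.40;
intermediate $k \sim 0.03$/day, weight 0.40; slow $k \sim 0.002$/day,
weight 0.20 — roughly the class proportions the four tissues span, where
fast fractions run from ~18% in cartilage to ~83% in plasma), applies the
pulse/chase kinetics per group with precursor enrichment 0.97, multiplies
observed ratios by log-normal noise (CV 0.2), builds iBAQ channels from a
log10-normal abundance (mean 7, sd 1 — a typical iBAQ dynamic range), and
censors each channel through a logistic dropout in log10 intensity
(midpoint 5.5, width 0.4), which reproduces the MNAR structure described
above. Growth dilution defaults to $g = 0.005$/day for the growing-animal
groups and 0 for adults; the value is illustrative — growth dilution in a
juvenile mouse is real but unquantified, and 0.005/day (about 10% mass
gain over a 3-week pulse) keeps a genuinely stable class possible, since
$r \ge 0.8$ over a 21-day chase requires $k + g \le 0.0106$/day. Ageing
effects enter as a multiplicative drop of $k$ in the older group (default
2-fold in a configurable fraction of proteins), reflecting reduced
incorporation with age.

The generator does **not** emulate: amino-acid recycling (precursor
enrichment is a constant, not a compartment model), peptide-level
variation, correlated replicate effects, shared-peptide protein-group
artefacts, or contaminant/decoy rows (the flags exist but default clean).
Passing tests on synthetic data therefore demonstrate the pipeline's
internal correctness and its behaviour under the *assumed* noise and
censoring model, not robustness to everything real data can do.

## Problem sizes and determinism

The test and acceptance simulations use 250–600 proteins and 4 replicates
per group — large enough that mixture proportions, FDR fractions and
Spearman-correlation signs are stable at the asserted tolerances, and
small enough to keep the whole suite interactive. Every stochastic step
takes an explicit integer seed (`generate_dataset()`,
`impute_extreme_uniform()`, `differential_table()`, `run_pipeline()`), and
the pipeline writes byte-identical output files when rerun with the same
configuration and seed; that determinism is itself a test.

## Known limitations

* The stable/intermediate boundary ($r \ge 0.8$) is an interpretation of a
  graphical definition; on real data moderate shifts of this threshold can
  move category counts noticeably. It is configurable for that reason.
* `recover_rate()` returns the *effective* rate $k+g$; absolute turnover
  rates (and half-lives) in growing tissue require an external estimate of
  $g$.
* The t-test path assumes imputed values can be treated as observations; a
  protein whose entire group was rescued by the uniform-extreme scheme has
  a fold change driven by the draw bounds. Such proteins are flagged
  (`recovered_by`) so downstream consumers can treat them separately.
* KNN distances use mutually observed columns without correcting for the
  number of shared columns; with at most 8 columns and at least 2 observed
  this bias is small, but it is a simplification.
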