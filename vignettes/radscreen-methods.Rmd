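---
title: "Models and methods behind radscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind radscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radscreen)
```

radscreen implements the quantitative core of a plate-based
radiosensitivity RNAi screen and its follow-up assays. This vignette
explains the models, the assumptions behind the synthetic-data generator,
and the numerical and design choices that were genuinely open, so that a
user can judge what a passing validation suite does and does not
demonstrate about real data.

## Clonogenic survival

The clonogenic assay plates single cells, irradiates, and counts colonies.
Two derived quantities carry all the information:

* plating efficiency, $PE = \bar{c}/n_{\mathrm{plated}}$, the mean colony
  count over replicate wells divided by cells plated;
* surviving fraction, $SF(D) = PE_D / PE_{0\,\mathrm{Gy}}$.

Dose response follows the linear-quadratic (LQ) model
$SF(D) = e^{-(\alpha D + \beta D^2)}$ with $\alpha$ (Gy$^{-1}$) the
single-track and $\beta$ (Gy$^{-2}$) the two-track killing coefficient.
`fit_linear_quadratic()` fits $\ln SF = -(\alpha D + \beta D^2)$, which is
linear in the parameters, by least squares under the physical constraint
$\alpha, \beta \ge 0$. The constraint is imposed by an exact active-set
search: the model has only two coefficients, so all four sign patterns are
fitted and the feasible one with the lowest residual sum of squares wins.
Ties and degeneracies resolve toward the boundary (a flat curve yields
$\alpha = \beta = 0$ exactly). Surviving fractions above 1 — possible with
counting noise — are flagged but enter the fit unclipped; clipping would
systematically bias $\alpha$ downward. Points with $SF \le 0$ are a hard
error: they cannot be log-transformed and indicate an uninterpretable well.

The fit is unweighted by default (technical-replicate curves rarely come
with trustworthy per-point weights); `weights = "inverse_se2"` enables
precision weighting when the per-point errors are reliable.

### Uncertainty of the fitted coefficients

Counting noise in clonogenic data is strongly dose-dependent: a 7 Gy well
may hold a tenth as many colonies as its 0 Gy partner. A homoscedastic
residual-based covariance therefore misstates the coefficient
uncertainty. When the input curve carries per-point standard errors (as
`survival_curve()` computes from replicate wells), the covariance of
$(\hat\alpha, \hat\beta)$ is instead obtained by propagating those errors
through the linear estimator (delta method on the log scale). Two
components enter: the independent per-dose errors, and the error of the
0 Gy reference, which is *shared* by every dose point of a condition
because all of them divide by the same $PE_{0\,\mathrm{Gy}}$ — it appears
as a fully correlated block in the error covariance (the `se0_log` column
of `survival_curve()` output). In simulation (200 Poisson experiments at
$\alpha = 0.25$, $\beta = 0.03$, doses 0–8 Gy, 500 cells/well, 3
replicates — the sizes also used by `scripts/acceptance.R`), ±2 se
intervals built this way cover the true $\alpha$ about 89–93% of the
time, against roughly 66% for the naive residual-based covariance. With no
`se` column the residual-based estimate is the fallback.

### SER10 and curve comparison

`dose_at_sf()` inverts the fitted curve at a target survival by the
quadratic formula — the unique positive root of
$\beta D^2 + \alpha D + \ln SF = 0$ (and $D = -\ln SF/\alpha$ when
$\beta = 0$); a flat curve is an error, not an infinite dose. The
sensitization enhancement ratio `ser10()` is the ratio of control to
treated $D_{10}$; values above 1 mean the treatment sensitizes.

`compare_curves_anova()` performs a fixed-effects two-way ANOVA with
survival as the dependent variable and dose and condition as the
independent variables. Three sub-choices were open and are switches:

* dose is treated as **categorical** (default), so no dose–response shape
  is imposed on the comparison;
* the dose × condition **interaction is included** (default) and reported
  alongside the condition main effect, which is "the" curve p-value;
* survival enters on the **log scale** (default), matching the scale on
  which the LQ model is linear and variances are closer to constant.

Unbalanced designs with empty cells are refused by name rather than
silently dropped.

## Screen scoring

Each irradiated well is paired with the 0 Gy well at the same (run,
plate, well) position, giving a per-well SF. Normalization divides by a
location estimate of the same run's non-targeting (NT) control SFs; the
default location is the **median**, which resists occasional failed
control wells (the mean is available as a switch, and makes the NT
population's mean R-score exactly zero). The R-score is

$$R_g = \frac{\mathrm{normalized\ } SF_g - 1}
             {\mathrm{MAD}(\mathrm{NT\ normalized\ } SF)},$$

where MAD is implemented literally as the mean absolute deviation about
the mean, $\mathrm{mean}\,|x - \bar x|$; a median-based variant is a
config switch for robustness at the cost of that literal form. Negative
scores mean the knockdown reduced survival after irradiation —
radiosensitization — so ranking is ascending with rank 1 the strongest
sensitizer. Ties get average ranks, and every downstream ordering breaks
remaining ties by gene id so results are bit-reproducible.

Replicate runs are combined by the rank product
$RP_g = (\prod_{i=1}^k r_{g,i})^{1/k}$, which rewards consistency: it is
1 only for a gene ranked first in every run. Its significance is computed
under the null that each run's rank column is independently permuted.
Under that null each gene's rank vector is uniform on $\{1..n\}^k$, so
when $n^k \le 10^6$ the p-value is computed **exactly** by enumerating
rank tuples; otherwise Monte-Carlo column permutations are used with the
+1 pseudo-count correction $p = (1 + \#\{RP^{perm} \le RP_g\})/(1 + B)$,
$B = 10{,}000$ by default, which keeps p-values valid (never zero, never
anti-conservative). On a fully null simulated screen of 1,000 genes in
three runs the p-value distribution is uniform (KS test, checked in the
acceptance suite).

Assay quality uses the screening-window coefficient
$Z = 1 - 3(\sigma_+ + \sigma_-)/|\mu_+ - \mu_-|$ between positive and NT
controls on the normalized SF scale; $Z > 0$ means the control
separation exceeds the joint 3-sigma bands. Hit selection takes the first
$n$ genes (default 240, a typical confirmation-screen size) by ascending
R-score (single-run primary screen) or ascending rank product
(confirmation screen).

## Synthetic screen generator

`simulate_screen()` exists so that every scoring stage can be tested
against known truth. It emulates:

* paired 0 Gy / screen-dose plates, with each **physical plate** (each
  dose copy, each run) receiving an independent multiplicative log-normal
  plate effect on plating efficiency (sd 0.1 on the log scale by
  default) — a known confounder that per-run NT normalization must
  remove;
* Poisson colony counts (single-cell plating with independent survival),
  with a negative-binomial switch for overdispersion and a noise-free
  mode that rounds expectations to the nearest integer;
* gene effects as a multiplier on $\alpha$ only — the simplest
  one-parameter radiosensitization consistent with negative R-scores
  denoting sensitization; hits are a configurable fraction (default 5%)
  with multipliers drawn uniformly from \[1.6, 2.5\];
* NT control wells (multiplier 1) and strong positive-control wells
  (multiplier 2.5, chosen so the assay window stays positive at default
  noise) on every plate;
* replicate runs sharing one ground-truth table.

The screening dose defaults to 7 Gy with baseline $\alpha_0 = 0.25$
Gy$^{-1}$, $\beta_0 = 0.03$ Gy$^{-2}$ — a HeLa-like survival of about
4% at the screen dose. Per-well cell numbers (2,000) and plating
efficiency (0.5) are invented defaults: no published screen design
dictates them, and they were chosen once as values a plate-based
clonogenic screen could plausibly use, giving roughly 40 expected
colonies in an irradiated NT well.

What the generator does **not** emulate: spatial within-plate effects
(edge wells), siRNA off-target structure, transfection-efficiency
gradients, or correlated failures. Passing the planted-hit recovery test
therefore shows the scoring pipeline is correct and well-calibrated under
the stated noise model — not that any real screen's off-target artifacts
are handled.

## Cytogenetics

Metaphase records carry six count columns (breaks, gaps, exchanges, each
dichotomized into chromatid- and chromosome-type). Summaries report
class-wise means with sample (n−1) standard deviations, the two dichotomy
totals, and the grand total; the dichotomy conservation (chromatid total
+ chromosome total = total) is an exact identity, tested as such.
Population rates per 100 cells multiply the per-metaphase mean by the
mitotic (p-H3-positive) fraction — a number the package takes as an
external flow-cytometry measurement, never computes from raw events — and
by 100. The synthetic generator draws per-class Poisson counts, which
matches the count nature of aberration scoring but not the slight
overdispersion real metaphase data can show. Group comparisons use a
two-sided t-test, Student's by default with a Welch switch; which of the
two a given published analysis used is usually unstated, so the default
is the simpler pooled form.

## Lineage fate classification

Lineage logs are timestamped per-cell events (`condensation_start`,
`karyokinesis_complete`, `cytokinesis_complete`, `daughter_fusion`,
`death` with an explicit phase label). The classifier applies the fate
taxonomy directly:

* **surviving** — no cell in the lineage died; polyploidization is
  flagged on daughter fusion or on a karyokinesis never followed by
  cytokinesis in the same cell;
* **death in interphase / death in mitosis** — at least one cell died;
  when deaths occur in parallel branches the earliest-*initiated* death
  decides the sub-class.

"Initiated earlier" is interpreted as the event's start time (death
events are points), with simultaneous ties broken by lower cell id; the
rule's clock is not defined more precisely anywhere, so this
interpretation is documented rather than claimed. Death phase is an
explicit input label, mirroring manual annotation, because a death
straddling the interphase/mitosis boundary cannot be reliably inferred
from surrounding events. Mitosis length is the time from chromatin
condensation to completed cytokinesis, or to karyokinesis alone for the
no-cytokinesis polyploidization route; a cell that died mid-mitosis has
no defined length.

The generator builds two-generation branching logs (roots tracked through
division, daughters through their own fate; observation window 48 h at
4-minute resolution in spirit, though times are continuous). One
deliberate simplification: daughter death times are drawn from a common
law regardless of death type, so when both daughters die the earlier one
is equally likely to be either type by exchangeability. That choice keeps
the lineage-level fate probabilities in closed form
(`lineage_fate_probabilities()`), which is what the round-trip test
compares observed frequencies against; the cost is that simulated
mitotic deaths are not constrained to late observation times the way real
ones are. Polyploidization is only generated at the root division —
a second simplification that does not affect the classifier, which
handles the events wherever they occur.

## Degenerate inputs and tie-breaking, collected

* `surviving_fraction()` with a zero 0 Gy plating efficiency, `r_score()`
  with zero NT deviation, `z_factor()` with equal control means,
  `dose_at_sf()` on a flat curve: all hard errors naming the cause — each
  corresponds to an uninterpretable experiment, not a missing value.
* Rank ties: average ranks within a run; final orderings always end with
  a lexicographic gene-id key.
* Exhaustive vs Monte-Carlo p-values switch at $n^k \le 10^6$ enumerated
  tuples; the exhaustive path needs no pseudo-count because it is exact.
* Validation of tabular inputs reports the offending row numbers;
  simultaneous lineage events tie-break by cell id.

## Problem sizes

The validation suite runs 200 simulated survival experiments for
parameter recovery, 100-point parameter grids for the closed-form
inversion check, 500 randomized tables for the R-score oracle, a
1,000-gene three-run screen for both the null calibration (10,000
permutations) and the planted-hit recovery (50 true sensitizers), and
1,000 lineages for the fate round trip. These sizes give 3-sigma
statistical headroom on every stochastic check while keeping the full
suite around a minute of CPU.

## Known limitations

* The LQ fit is the only survival model offered; single-hit multi-target
  or dose-rate-corrected models are out of scope.
* The screen model scores one pooled siRNA per gene; strand-level
  deconvolution and seed-sequence off-target analysis are not attempted.
* B-score/spatial polish of plates is not implemented; the generator's
  plate effect is plate-global, which is exactly the confounder the
  per-run normalization removes.
* Lineage depth is capped at two generations by default, matching a 48 h
  observation window of cells with day-scale cycle times.
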