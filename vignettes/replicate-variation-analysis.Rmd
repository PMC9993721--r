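---
title: "Replicate Variation Analysis: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate Variation Analysis: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rva)
```

## The statistic

Replicate variation analysis (RVA) treats the *variation among biological
replicates* as the measurement of interest, not as nuisance. For every
feature $i$ (a metabolite mass-spectral feature, NMR bin, or protein)
quantified in a group of $n \ge 3$ biological replicates, the coefficient
of variation is

$$\mathrm{CV}_i = 100 \cdot \frac{s_i}{\bar{x}_i}\ \%$$

with $\bar{x}_i$ the arithmetic mean and $s_i$ the sample standard
deviation ($n-1$ denominator) over that group's replicates. The collection
$\{\mathrm{CV}_i\}$ is the group's **CV profile**. Acute physiological
stress canalizes molecular variation: the stressed group's CV profile
shifts to lower values *and* narrows, relative to an unstressed control.

Two groups' profiles are compared on three axes at once:

* the two-sample Kolmogorov–Smirnov statistic
  $d = \sup_t |\hat F_a(t) - \hat F_b(t)|$ between the empirical CDFs of
  the two CV vectors, with its two-sided asymptotic $p$-value — $d$
  responds to any change of location or shape;
* a Wilcoxon test on the CV values — signed-rank on per-feature pairs when
  the groups share a feature set (the default), rank-sum otherwise;
* the shift of the mean and median CV.

`rva()` / `rva_compare()` return all of these in one `rva_comparison`
object. The per-feature view is `delta_cv_table()`: for each shared
feature, $\Delta \mathrm{CV} = \mathrm{CV}_b - \mathrm{CV}_a$ and a strict
lower-in-b flag (ties count as *not* lower), with per-category counts when
a feature → functional-category annotation is supplied.

Because the CV is scale-free, per-feature rescaling (unit changes,
feature-specific response factors) leaves the profile unchanged; this
invariance is property-tested.

## Recovery over time

`rva_temporal()` compares every timepoint-labelled group against one fixed
unstressed reference group — not against the previous timepoint — so each
$d(t)$ answers "how far is this population still from its unstressed
state?". Recovery appears as $d(t)$ shrinking toward 0 while the mean and
median CV climb back to the reference's values. `recovery_summary()`
tabulates the series with a per-step direction flag. No kinetic model is
fitted; the trend is reported as observed.

## Inputs and validation

Feature tables are plain CSV/TSV, features in rows, samples in columns,
feature ids in the first column and sample ids in the header. Values must
be nonnegative, finite intensities; negative cells abort the load with
their coordinates, since a negative abundance in a processed table
signals a parsing or dialect error rather than data. Missing cells (empty
or a configurable token, default `NA`) stay missing — no imputation. A
literal `0` is a real measurement, because upstream pipelines differ in
how they encode dropouts and guessing silently would change CVs.

Within a group, a feature's CV uses its non-missing replicates only, and
the feature is dropped from the profile when fewer than 3 remain; features
with mean $\le 0$ are dropped too. Both counts are kept on the profile
object. Every analysed group needs at least 3 biological replicates — the
same inclusion rule used when screening public repositories. Tables are
used as provided, with no cross-sample normalization.

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `missing_token` | `read_feature_table` | `"NA"` | cell text read as missing |
| `matched` | `wilcoxon_cv_test` | `TRUE` | signed-rank on feature pairs vs rank-sum |
| `scale` | `mean_variance_fit` | `"raw"` | fit variance on mean raw or log10–log10 |
| `autoscale` | `pca_scores` | `TRUE` | unit-variance feature scaling before PCA |
| `fold`, `fold_sd` | `simulate_true_distribution` | —, 0.1 | nominal SD-to-mean ratio and its per-feature spread |
| `features`, `replicates`, `folds` | `run_power_grid` | 50/500/5000, 3/6/10/20, 0.23/0.5 | the simulation grid |
| `n_iterations`, `n_distributions` | `run_power_grid` | 1000, 40 | draws per cell; true distributions they are spread over |
| `cv_center`, `cv_spread` | `generator_spec` | 0.67, 0.25 | control CV distribution (fraction) |
| `canalization` | `generator_spec` | 1 | factor $c \in (0,1]$ multiplying stress-group CVs |
| `bw` | `plot_cv_profiles` | `"nrd0"` | kernel bandwidth for the density figure |

## The power simulation

How well does a finite experiment recover a population's CV distribution?
The simulation has two levels.

**Level 1 — population truth.** Per-feature population means are drawn on
the natural-log scale, $\log \mu_i \sim N(\mu_{\log}, \sigma_{\log})$, and
exponentiated; drawing on the log scale is what guarantees positive means.
Each mean receives a standard deviation through a per-feature fold factor
$f_i \sim N(f, 0.1)$, clamped below at 0.001, so $\sigma_i = f_i \mu_i$
and the feature's true CV is exactly $f_i$. The parameters
($\mu_{\log}, \sigma_{\log}$, and the empirical fold summary) come from a
real reference group via `estimate_reference_params()`; a typical global
LC–MS metabolome has per-feature folds spanning roughly 0.02–1.65 with
mean near 0.23, which is why the grid tests $f \in \{0.23, 0.5\}$.

**Level 2 — finite experiments.** For each feature, $r$ replicates are
drawn $N(\mu_i, \sigma_i)$ and the sample CV computed; the Spearman rank
correlation $\rho$ between sample CVs and true CVs measures recovery.
Negative replicate draws are kept as drawn (they model a noisy instrument
value), but a feature whose *sample mean* lands $\le 0$ is redrawn so its
CV stays defined; redraws are counted and are rare outside extreme-CV
features.

`run_power_grid()` repeats this `n_iterations` times per grid cell,
spreading iterations cyclically over `n_distributions` level-1
distributions per (features, fold) pair; the same distributions are reused
across replicate counts, so cells differing only in replicates are
directly comparable. At the defaults that is 1000 iterations over 40
distributions, i.e. 25 per distribution; the two counts are otherwise
independent knobs. The reproducible result: median $\rho$ rises steeply
with replicate number and with a smaller SD-to-mean ratio, while feature
number (50 → 5000) barely moves it — `grid_spread_summary()` quantifies
this as the range of cell medians across feature counts (≈ 0.01) versus
across replicate counts (≈ 0.35).

## The synthetic-data generator

`generate_pair()` builds the test bed for the whole pipeline: feature
means are log-normal (`exp(N(14, 1.5))`, a TOF-MS-like intensity scale)
and shared by both groups; per-feature control CVs are
$N(\texttt{cv\_center}, \texttt{cv\_spread})$ clamped at 0.01; stress CVs
are $c \times$ control CVs; replicate values are
$N(\mu_i, \mu_i \mathrm{CV}_i)$ with negative draws clipped to 0, a
detection floor that also keeps the table within the nonnegativity
contract. The defaults (2000 features, 8 replicates, control CVs centered
at 67% with 25% spread) reproduce the scale of a global plant-metabolome
heat-shock experiment; `canalization = 0.42` reproduces the magnitude of
its observed median-CV drop (67% → 28%). `generate_timecourse()` extends
this with one group per timepoint under a non-decreasing recovery schedule
$c(t) \to 1$ plus a $c = 1$ reference.

What the generator deliberately does **not** emulate: right-skewed
empirical CV shapes (the truncated normal is a simplification), intensity
drift and batch effects, structured missingness, or correlated features.
Passing tests therefore show that the statistics behave correctly under a
clean canalization signal, not that every real-data artifact is handled.

Modelling canalization as one multiplicative factor on the whole CV
distribution is itself a choice: it shrinks location and spread together,
matching the empirically observed "lower and narrower" profiles; an
additive location shift would not narrow the distribution and is not
implemented.

Two quantitative caveats that the test suite accounts for. First, the
detection-floor clip biases measured CVs of high-CV features a few percent
low, so a control profile generated at center 67% measures a median near
58–60%; ratio-based quantities (the canalization estimate) are nearly
unaffected, which is why estimates of $c$ stay within 0.05 of truth.
Second, because both groups share per-feature true CVs, a $c = 1$ pair is
*paired*, making the K–S comparison conservative; the null-calibration
check instead compares two independently generated control tables, which
is the construction whose type-I rate should sit at $\alpha$.

## Numerical choices

* **K–S statistic.** Computed at the pooled sorted values via the
  cumulative $\pm 1/n$ formulation; with ties, only the last index of each
  tied run is a valid evaluation point, and a warning notes that the test
  assumes continuity. Equality with a brute-force ECDF supremum is
  asserted on 1000 random instances.
* **K–S p-value.** Always the two-sided asymptotic Kolmogorov series with
  effective size $nm/(n+m)$ — CV vectors routinely hold thousands of
  features, where exact computation is pointless. The series is summed to
  machine convergence (100 terms), so agreement with implementations that
  truncate their series at $10^{-6}$ is limited to about five decimals —
  by their truncation, not ours. $p$ is floored at the smallest positive
  double so it stays in $(0, 1]$.
* **Wilcoxon.** `stats::wilcox.test` (exact where R provides it; zero
  differences dropped, ties mid-ranked). All-zero paired differences are a
  degenerate design: $p = 1$ with a warning rather than an error, so
  profile-vs-itself comparisons stay total. An exhaustive
  sign-enumeration oracle checks the exact paired $p$ in the tests.
* **Truncations by clamping.** Both truncated normals (fold factors at
  0.001, control CVs at 0.01) clamp rather than redraw. Rejection
  sampling would shift the mean of a $N(0.23, 0.1)$ fold distribution by
  ≈ 0.003 — a real distortion of the nominal regime — while clamping
  shifts it by ≈ 0.0004.
* **Mean–variance diagnostic.** The raw-scale fit is the default and its
  *sign* is the diagnostic: a negative slope would indicate the
  intensity-dependent measurement artifact that would disqualify the CV.
  The raw-scale Pearson $r$, however, is attenuated by the $\chi^2$
  sampling noise of per-feature variances (relative SD
  $\sqrt{2/(n-1)}$ ≈ 53% at $n = 8$) and by heavy-tailed intensity
  distributions, so "how linear" is assessed on the log10 scale, where a
  constant-CV population obeys $\log_{10} s^2 = \mathrm{const} +
  2\log_{10}\mu$ and $r > 0.97$ in practice.
* **PCA.** `stats::prcomp` on samples, features centered and (by default)
  autoscaled, zero-variance features dropped. Whether the original score
  plots used autoscaled or raw intensities is not documented anywhere
  authoritative, so the flag exposes both; autoscaling is the default
  because mixed-magnitude omics features otherwise let the most intense
  features dominate.
* **Spearman with ties** uses average ranks; if the true CVs are tied
  constants (`fold_sd = 0`) the correlation is degenerate and 0 is
  returned with a warning.
* **Degenerate density plots.** A zero-variance CV profile has no
  data-driven bandwidth; `plot_cv_profiles()` falls back to a
  1-percentage-point kernel.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on generated data:
null calibration uses 200 pairs of independent 500-feature, 8-replicate
control tables; canalization recovery uses 30 seeds at 2000 features and
$c = 0.5$; the power grid runs its full 24-cell default grid at 100
iterations per cell; the temporal trend check fits 50 simulated recovery
courses. These sizes give the stochastic assertions comfortable margins
(binomial 99% band for calibration; observed inversion counts of zero for
grid monotonicity) while a full suite run stays around half a minute.
The full 1000-iteration grid is a single `run_power_grid()` or
`rva simulate` call away and scales linearly.

## Known limitations

* The per-protein CV reproduction for the methanogen pyrite-vs-sulfide
  proteome (`reproduce_mvoltae()`) needs the journal's supplementary
  per-protein CV table, which cannot be redistributed here; the function
  takes a user-supplied export.
* Published repository datasets (pig, *E. coli*, wild oat, cancer cells,
  mayfly, mouse, abalone, wheat) require manual download; see
  `inst/scripts/reproduce-public-datasets.R` for the documented workflow
  and expected directions of each comparison.
* RVA is a global statistic: targeted panels covering few pathways can
  miss canalization, and chronic stress can move CVs the other way.
  Interpretation belongs to the experimenter; the package reports the
  distribution comparisons.
* No multiple-testing correction across many pairwise comparisons is
  applied, matching the single-pair reporting the method was designed
  for.
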