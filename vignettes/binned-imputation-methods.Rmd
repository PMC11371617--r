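---
title: "Binned cross-day imputation: model, design choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binned cross-day imputation: model, design choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binimpute)
```

## The estimation problem

A regularly sampled univariate series with daily structure is rearranged
into a matrix $X \in \mathbb{R}^{D \times T}$ with one row per calendar day
and one column per within-day clock slot ($T = 1440$ at 1-minute
sampling). A *gap* is a short clock-anchored span (1, 5 or 15 minutes
here) missing from one day. The package's premise is that the columns of
$X$ are the meaningful statistical variables: the value at 3:24 a.m. today
is best predicted by 3:24 a.m. on other days and by the minutes adjacent
to the gap today.

Rather than handing an imputer all $T$ columns, a *bin window* of width
$w \ge$ the gap span is cut around the gap — the same clock columns for
every day — and the imputer sees only that sub-matrix. The window is
centred on the gap; an odd surplus slot goes before the gap; at day
boundaries the window is clipped, not shifted (a decision discussed
below). The whole-day window ($w = 24$ h) is the *no-binning baseline*.

Evaluation deletes the gap from one complete day at a time (all other days
stay fully observed), imputes from the window, and scores
$\mathrm{RMSE} = \sqrt{\tfrac1n \sum_i (x_i - \hat x_i)^2}$ over the gap
slots. The headline statistic is the *days-improved count*: on how many of
the $D$ days the binned RMSE is **strictly** below the baseline RMSE (ties
count as not improved — the conservative reading of "error reduced").

## The imputers

All five imputers treat rows (days) as samples and columns (clock slots)
as variables, never modify an observed cell, and fill every missing one.

**`si` — cross-day mean.** Each missing cell gets its column's observed
mean. Window contents beyond the gap columns are ignored, so binning
cannot change `si` except through which columns exist; it is the natural
control.

**`em` — Gaussian EM.** $X$'s columns are modelled as multivariate normal;
missing cells are latent. Starting from $\mu$ = column means and $\Sigma$
= diagonal column variances, the E-step computes per missingness pattern
the conditional mean of missing coordinates given observed ones plus the
conditional covariance correction, and the M-step re-estimates
$(\mu, \Sigma)$ from the completed sufficient statistics, then shrinks:
$\Sigma \leftarrow (1-\lambda)\Sigma + \lambda\,\mathrm{diag}(\Sigma)$.
With $\lambda = 0$ this is textbook EM and the recorded observed-data
log-likelihood is non-decreasing (a tested invariant). Shrinkage is
unavoidable in practice: for any window wider than the day count
($w > 30$ min with 30 days) the unshrunk covariance is singular, so
"EM has no hyperparameters" holds only for narrow windows; the default is
$\lambda = 0.1$. Missing cells are filled with conditional means under the
final model.

*Numerics.* After shrinkage $\Sigma = \mathrm{diag}(d) + WW^\top$ with
$\mathrm{rank}(W) \le D + (\text{gap width})$, so for wide windows the
E-step and likelihood are evaluated through the Woodbury identity at
$O(TD^2)$ instead of dense Cholesky at $O(T^3)$; `method = "auto"` selects
this path when $T > 4D$ and $\lambda > 0$. Tests pin the two paths to
agreement at $10^{-9}$.

**`ii` — chained ridge regressions.** Missing cells start at column means;
each incomplete column (ascending missing count) is repeatedly regressed
on all other columns of the current completed matrix, fitted on the rows
observed in the target column with ridge penalty (default $10^{-3}$; the
dual form is used when the design is wider than tall). `ridge = 0` on a
singular design raises an error advising a positive penalty.

**`knn` — nearest-neighbour days.** Donor rows are ranked by the
missing-aware distance
$d(a,b) = \sqrt{\frac{T_w}{|C|}\sum_{t\in C}(a_t-b_t)^2}$ over the columns
$C$ observed in both; each missing cell averages the $k$ nearest donors
observed at that column (skipping donors missing there), with uniform or
inverse-distance weights. Distance ties resolve to the lower row index;
with $k = D-1$ and uniform weights on fully observed donors, `knn` equals
`si` exactly (a tested equivalence).

**`rf` — iterative random forest.** missForest-style: mean-initialize,
then per incomplete column fit a regression forest (bootstrap rows, random
feature subsets of $\lceil (T_w-1)/3 \rceil$, variance-reduction splits,
minimum leaf 5, 100 trees) on the rows observed in that column and predict
its missing cells; stop at the first rise of the normalized squared change
between successive imputations, returning the previous round. The trees
are implemented in C++ with one `mt19937` stream per (round, column)
derived from the user seed, so results are bitwise reproducible; split
ties resolve to the lowest feature index, then the lowest threshold.

## Convergence and degenerate inputs

EM and `ii` stop when the largest relative change of any imputed value
drops below `tol` ($10^{-6}$ default) or at `max_iter` (100; forest: 10
rounds). The first EM E-step necessarily reproduces the mean fill (the
initial covariance is diagonal), so convergence is never declared before
the second iteration. A column with no observed value is an error naming
the slot; a singular observed-block covariance at $\lambda = 0$ is an
error advising more shrinkage — except in the likelihood computation,
where an exactly singular model (e.g. two perfectly collinear columns) is
scored by its pseudo-determinant so that the exact-linear test case runs
at $\lambda = 0$.

## Window placement decisions

Two choices were genuinely open:

* **Clip, don't shift.** A 1-h window around a 00:00–00:05 gap could keep
  its full width by sliding to 00:00–01:00, or keep its centring and lose
  the slots before midnight. The package clips (the example yields slots
  1–32): shifting would silently change which clock times all days
  contribute, making windows near midnight behave qualitatively
  differently from interior ones. The effective width is therefore
  $\le w$ near day edges.
* **The 24-h baseline is the whole day.** For any gap position, a bin of
  $\ge$ 24 h returns all $T$ columns, so "baseline" means the same matrix
  regardless of gap clock time. Without this special case a centred
  24-h window would be clipped asymmetrically (e.g. to 924 columns for a
  3:22 a.m. gap), which is neither the whole data set nor a fixed-width
  window.

Gaps are end-exclusive ("3:22–3:27" is five 1-minute slots), may not cross
midnight, and are evaluated one day at a time; simultaneous masking of all
days is deliberately not the default, since the benchmark's question is
how well one day's gap is recovered from otherwise complete data.

## The synthetic world

`generate_heart_like()` draws
$x_{d,t} = m_t + a_d + b_d(t) + \delta_d(t) + \varepsilon_{d,t}$ with

* $m_t = \text{baseline} + A\cos\!\big(2\pi(t-\phi)/24\,\mathrm h\big)$ —
  diurnal profile (defaults 65 bpm, $A = 10$, peak 16:00);
* $a_d \sim N(0, 3^2)$ — day-level offset;
* $b_d(t)$ — activity bursts: a Poisson process (10 events/h) confined to
  the 15:00–16:00 *active window*, each event decaying as
  $\text{amplitude} \cdot 2^{-\Delta t/\text{halflife}}$ (15 bpm, 5 min) —
  the simplest one-sided kernel giving asymmetric, activity-like
  excursions; the 03:00–04:00 *inactive window* has none by construction;
* $\delta_d(t)$ — optional slow drift, a stationary Ornstein–Uhlenbeck
  (AR(1)) process independent across days (off by default);
* $\varepsilon_{d,t} \sim N(0, 2^2)$ — white noise.

Defaults mirror the benchmark's setting: 30 days, 1-min sampling, quiet
3–4 a.m., volatile 3–4 p.m. Each day has its own RNG stream derived from
(seed, day index), so extending the horizon never perturbs earlier days.
`generate_power_like()` swaps the cosine for a two-plateau profile (0.3 kW
nights, 1.5 kW 07:00–23:00), re-scales offsets/noise/bursts to a kW scale,
and truncates at zero.

**What the drift term is for.** With drift off, a wide window costs EM
little: the extra columns are uninformative but not misleading. The
acceptance scenario must *construct* the regime where binning wins, which
requires within-day structure that narrow windows capture and wide-window
covariance estimation cannot. Two design iterations mattered:

* a random-phase cosine drift is finite-rank (six dimensions across days),
  so the full-day Gaussian model simply learns it — no advantage appears
  at any amplitude; the OU form is full-rank across days and cannot be
  estimated in 1440 dimensions from 30 days;
* the OU correlation time must be *long* relative to the window
  (default 240 min vs the 60-min window): then the drift is nearly
  constant within the window and the binned model absorbs it as a
  day-level offset, while a short correlation time makes the drift
  unpredictable for both models and the contrast collapses.

The acceptance world therefore fixes `drift_sd = 15` (1.5× the circadian
amplitude, so the inestimable component dominates) and `drift_tau = 240`.
With that world and seed 1, 1-h-binned EM beats the whole-day baseline on
26/30 days for 15-min gaps and 23/30 for 1-min gaps — reproducing the
qualitative span ordering. The span-ordering comparison is the fragile
one: when binning helps both spans on ~80% of days, a 30-day count can
invert by a day or two at unlucky seeds.

**What a green test does not establish.** The generator is additive and
Gaussian apart from bursts; real heart-rate data have autocorrelated,
heteroscedastic, occasionally non-stationary noise (sleep stages, illness,
sensor artefacts), and real power data are switching processes, not
plateaus plus bursts. Green acceptance shows the machinery and the
constructed mechanism work — not that binning helps any particular
person's data. Conversely, an analytic anchor keeps the generator honest:
with bursts off, the cross-day mean's expected squared gap error is
$(\sigma_a^2+\sigma_\varepsilon^2)(1 + \tfrac{1}{D-1})$, and the
Monte-Carlo mean over 200 replicates must sit within three standard errors
of it.

## Fluctuation diagnostic

`fluctuation()` is the sample standard deviation (denominator $n-1$) of
the target day's observed values inside the window — the no-formula
"fluctuation" of the companion box-plot diagnostic, computed on the target
day only (pooling across days would mix day-level variance into a
within-day dispersion measure); a coefficient-of-variation option exists
for cross-scale comparisons. `fluctuation_split()` partitions days by
strict improvement and returns both samples with medians; an empty group
is an empty sample, not an error.

## Known limitations

* Gaps crossing midnight and multiple simultaneous gaps per day are out of
  scope (the evaluation masks one span on one day at a time).
* Timestamps are naive local clock time; daylight-saving artefacts are
  rejected as alignment errors, not resolved.
* The 5-s-to-1-min reduction is the mean over non-missing samples
  (median available); the original pipeline's "preprocessing" is not
  specified anywhere, so recovery of its exact values is not claimed.
* `rf` on whole-day windows (1439 predictors) is computationally heavy by
  construction; the benchmark's interesting regime for forests is narrow
  windows.
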