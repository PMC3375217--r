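---
title: "Spike-latency coding and the temporal winner-take-all readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-latency coding and the temporal winner-take-all readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latwta)
```

## The problem

Sensory decisions are sometimes made within a few tens of milliseconds —
far less than the integration windows usually used to read out firing
rates.  Over such brief windows the most informative aspect of a neuron's
response is *when* it starts firing.  In primary visual cortex, both the
strength and the latency of a cell's response depend on stimulus
orientation, so the time to the first (or nth) spike carries orientation
information.

`latwta` implements the full analysis chain for quantifying that
information with a deliberately simple readout, the **temporal
winner-take-all (tWTA)**: the stimulus estimate is the preferred
orientation of the unit — or group of units ("column") — that is first to
fire *n* spikes after a reference signal.  Because no public data
accompany the recordings this analysis style was developed for, the
package ships a seeded spike-train generator that emulates their
structure, and every claim the package makes is demonstrated on that
generator against independent oracles.

## Latency tuning

Mean first-spike time is ill-defined when some trials have no spikes, so
latency is summarised distributionally.  For unit, orientation
$\theta$ and spike index $n$, the package estimates the density
$f_n(\theta, t)$ of the nth spike time on 10 ms bins from the reference
to $T_0$ = stimulus duration + 300 ms, normalised by the trial count $K$
(so $\sum_t f_n \le 1$; spikeless trials contribute no mass), and its
cumulative $F_n(\theta, t)$.  The **latency tuning curve** is the level
curve of $F_n$ at 0.5 — the earliest time with $F_n \ge 0.5$, linearly
interpolated inside the crossing bin.  Interpolation matters: a
step-function convention would quantise latencies to the 10 ms grid and
mask modulations comparable to the bin width.

Level curves are fitted with the cosine
$$L(\theta) = A - B\cos 2(\theta - \phi),$$
by linear regression on $\{1, \cos 2\theta, \sin 2\theta\}$: $A$ is the
mean latency, $B \ge 0$ the modulation depth, and $\phi$ the
latency-based preferred orientation (period 180°, undefined when $B$ is
numerically zero).  Orientations whose cumulative never reaches the
level are dropped from the fit rather than imputed, which would bias $B$
downward.  Error bars come from the Bernoulli nature of $F$:
$\mathrm{SEM}(F) = \sqrt{F(1-F)/K}$, and the level curves of
$F \pm \mathrm{SEM}$ bracket the estimate.

Rate tuning (mean rate from stimulus onset to 300 ms after offset) is
fitted with the von-Mises form
$base + amp\,e^{\kappa(\cos 2(\theta-\phi)-1)}$ by multistart
least squares.  A simple cosine is preferred for *latencies* because the
reference time is arbitrary: shifting it changes $A$ but not $B$,
whereas the strictly positive von-Mises form cannot absorb a reference
shift.

Units are classified from two statistics: the modulation $B$ of the
first-spike cosine fit and the spontaneous rate measured from
inter-stimulus epochs with the first 300 ms after stimulus offset
removed (post-response adaptation time).  $B > 15$ ms makes a unit
*tuned*; $B < 15$ ms together with spontaneous rate < 5 spikes/s makes
it an *onset detector*; everything else (including $B$ exactly at the
boundary or an unavailable fit) is *other*.

## Onset detection

A latency readout needs a reference signal that the brain could actually
possess.  The pooled spikes of the onset-detector units feed a running
coincidence detector: stimulus onset is the first time $t$ at which the
left-open window $(t-T, t]$ holds at least $m$ spikes, with onset
defined as the window end.  A crossing can only first occur at a spike
time, so evaluating candidates at spike times is exactly equivalent to
continuous sliding (verified against a dense grid-scan oracle).  The
threshold is calibrated from spontaneous firing: $m$ is the smallest
integer at least $N_v$ standard deviations above the mean pooled count
in non-overlapping $T$-windows tiling the spontaneous epochs, never
below 1.  Defaults are $T = 20$ ms and $N_v = 4$.  Because "no stimulus"
has no natural trial structure, false alarms are reported as a rate
(detections per second of spontaneous-only time, using only epochs at
least 300 ms after stimulus offset), while hits are the per-trial
probability of a detection inside the stimulus window.  A leaky
integrate-and-fire variant (`lif_onset`, unit increments, 20 ms decay)
reproduces the running-window onsets when its threshold is matched.

## The race and its analytic accuracy

`race_two_groups` implements the two-column competition: the group whose
nth post-reference spike comes first wins; if the two nth spikes fall at
exactly the same time, the group with more spikes in the 10 ms bin
containing that spike wins; remaining ties are uniform random.  The
multi-column race (`race_multi`) follows its own convention: groups
whose nth spikes share the earliest 10 ms bin are resolved uniformly at
random, with no count sub-rule.  The two rules differ deliberately —
each mirrors the procedure used for the corresponding task.  A race in
which no competitor reaches $n$ spikes is a *no-decision* and is scored
at chance, with its frequency reported.

For single cells the package computes 2AFC accuracy analytically from
the estimated distributions.  With preferred-stimulus density $f$ and
other-stimulus cumulative $F^\ast$ on a common grid,
$$P_c \;=\; \sum_t f(t)\,\bigl(1 - F^\ast(t)\bigr)
\;+\; \tfrac12 \sum_t f(t) f^\ast(t) \;+\; \text{tail},$$
where the middle term scores same-bin collisions at chance.  The tail
handles trials in which a response has not accumulated $n$ spikes by
$T_0$: firing is then spontaneous Poisson at the unit's measured rate
$\lambda$, so a truncation-state pair ($m_1$ and $m_2 < n$ spikes so
far, probabilities estimated from the data) races
$\Gamma(n-m_1,\lambda)$ against $\Gamma(n-m_2,\lambda)$.  For equal
rates that probability has the exact form
$P(\Gamma_a < \Gamma_b) = P\bigl(\mathrm{Bin}(a+b-1, \tfrac12) \ge a\bigr)$
(merge the two Poisson processes; each event is a fair coin), so
$\lambda$ cancels and a symmetric tail contributes exactly half the
product of survivor masses.  With $\lambda = 0$ the residual mass cannot
race and is resolved at chance, flagged.  These formulas make the
symmetry property exact: identical inputs give $P_c = 1/2$ to machine
precision, and the binned estimator converges to the exponential race
limit $\lambda_1/(\lambda_1+\lambda_2)$ as the bin shrinks.  The
rate-code comparator uses the standard all-pairs (area-under-ROC)
estimator with half credit for equal counts.  Mean decision times take
the expectation of the earlier nth-spike time under the same model
(left bin edges; with $\lambda = 0$ the mean is conditional on a
decision).

Neurometric curves split trials 50/50 (seeded, stratified by
orientation): the training half fixes $\phi$, the test half provides the
distributions, so estimating the preferred orientation cannot leak into
the accuracy estimate.

## The synthetic generator

Tuned units fire a homogeneous Poisson background at rate $\lambda$
throughout the trial, plus an evoked Poisson segment at rate
$R(\theta) = R_{max} e^{\kappa(\cos2(\theta-\phi)-1)}$ from
$L(\theta) = A - B\cos2(\theta-\phi) + s + \epsilon$ to stimulus offset,
where $s \sim N(0, \sigma_s^2)$ is shared by all units in a trial and
$\epsilon \sim N(0, \sigma_i^2)$ is private.  The latency model is a
hard onset shift of an otherwise stationary rate: real responses
modulate their whole temporal profile, but the shift model is the
minimal structure that makes the ground-truth cosine tuning of latency
exact and hence testable.  Onset-like units ($B = 0$, untuned rate, low
background) form a configurable fraction of the population (default
15%, within the 10–25% range of the emulated recordings).  Defaults:
120 units, 8 orientations 22.5° apart, 300 trials per orientation,
300 ms stimulus, 500 ms inter-stimulus interval, peak evoked rate
40 spikes/s, $\kappa = 1.5$, mean background 5 spikes/s, $A \approx 80$,
$B \approx 25$ ms with $A - B$ roughly constant across units (which
reproduces the positive $A$–$B$ correlation).  Drifting-grating phase
locking is available as an optional sinusoidal thinning of the evoked
segment, off by default.

Determinism: each trial has its own substream seed derived from the root
seed, and trials are enumerated repetition-major, so the same seed gives
byte-identical output and *increasing the trial count appends trials
without altering earlier ones*.

$\sigma_s = 2.7$ and $\sigma_i = 10$ ms make the structural shift
correlation $\sigma_s^2/(\sigma_s^2+\sigma_i^2) = 0.068$, matching the
weak positive pairwise latency correlations of the emulated data.  A
limitation worth stating plainly: the *measured* first-spike correlation
equals that ratio only in the background-free, high-rate limit (where
the package's tests verify it).  Under realistic rates, Poisson timing
jitter — especially at non-preferred orientations — dilutes measured
correlations toward zero except for similarly tuned pairs near their
preferred orientation.  Real recordings show a nonzero mean correlation
across *all* pairs, which a pure onset-shift model cannot reproduce;
global excitability fluctuations affecting rates as well as latencies
would be needed.  Decoding conclusions are insensitive to this because
the shuffle control measures the correlation contribution directly and
finds it small either way.

The two-column race model (`generate_two_column_race`) is a separate,
deliberately minimal construction for studying shared-noise
cancellation: each unit emits one spike exactly at its (noisy) latency,
so that with purely shared noise the race outcome is deterministic in
the latency offset.  It is a parameterised stand-in, not a transcription
of any published model.

## Population analyses and problem sizes

`population_neurometric` replays every trial of the two column
orientations, racing uniform without-replacement subsets of each column
(one permutation per realization; prefixes give nested subsets across
$N$, which reduces Monte-Carlo variance without biasing any single
$N$).  Trials without a detected onset are excluded and counted.
Averaging is over trials first, then realizations (default 1000;
the bundled analyses use 25–50, which leaves the subset-sampling error
well below the trial-sampling SEM at these problem sizes).

Two regimes deserve comment.  With strong rate contrast (defaults:
$\kappa = 1.5$, 40+ spikes/s) the preferred column out-fires the other
so thoroughly that raising the threshold $n$ never hurts — the
threshold/size tradeoff degenerates.  The tradeoff the race readout is
known for lives where single-unit evoked spike counts are comparable to
the threshold: the package's demonstration of that regime uses peak
evoked rate 18 spikes/s, $\kappa = 0.3$ and background 6 spikes/s.
There, plain first-spike accuracy saturates with population size while
the optimal threshold $n_{opt}(N)$ grows roughly linearly, and the
artificial-reference sweep shows the characteristic interior optimum: a
reference before the response admits pure background spikes, a late one
discards the informative latency head start.

The shuffle control permutes each unit's trials independently within
orientation (and the onset signal with them), destroying inter-unit
correlations while preserving marginals; the original and shuffled runs
share subset realizations (common random numbers) so their difference
isolates the correlation effect.  Multi-alternative discrimination
anchors the column partition so one column is centred on the stimulus,
reports the probability that this column wins against the $1/M$ chance
line, and the signed circular error (winner centre − stimulus, wrapped
to $(-90°, 90°]$); raising $n$ from 1 to 2 visibly tightens the error
distribution because single spontaneous spikes stop winning races.

Problem sizes throughout the tests and the acceptance script (hundreds
of trials, 6–25 units, tens of realizations) were chosen as the smallest
at which the Monte-Carlo error bars make the qualitative orderings
decisive; all comparisons carry explicit SE-based tolerances.

## Numerical choices and degenerate inputs

* Half-open trial interval $[0, \text{trial length})$; spikes exactly at
  a reference are kept ($\ge$).
* Ties between same-unit spikes at identical times keep input order
  (legal for multiunit clusters).
* $m$ (onset threshold) is ceiling-rounded — counts are integers.
* Cosine fits need $\ge 3$ defined orientations, von-Mises $\ge 4$;
  constants yield $B = 0$ with $\phi$ undefined; flat rate curves are
  flagged degenerate.
* Unit classification therefore needs $\ge 3$ orientations; analyses on
  two-orientation designs must supply unit labels directly.
* Boundary-sitting preferred orientations go to the lower-index column.
* Decision times above 200 ms are conventionally truncated in figure
  summaries but retained in all outputs.

## What passing tests do and do not show

The generator demonstrates that the estimators recover known ground
truth and that the decoding phenomenology is internally consistent.  It
does not capture: temporal response profiles beyond a shifted stationary
rate (no transients or oscillations unless phase locking is enabled),
spike-count noise correlations, adaptation across trials, or the
across-pair correlation structure noted above.  Conclusions about real
recordings require re-running the chain on real trial-aligned spike
tables, which `load_recording` accepts in plain CSV.
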