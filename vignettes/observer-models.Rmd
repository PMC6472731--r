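---
title: "Observer models for visual-search detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observer models for visual-search detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imperfectbayes)
```

## The task and its generative model

The package models a four-item visual-search detection task. On each
trial the observer sees four oriented stimuli at fixed locations and
reports whether a *target* is present. Orientations are measured in
degrees, clockwise-positive, with vertical at 0. On half of the trials
(Bernoulli 0.5) one uniformly chosen location holds a target drawn from
Normal($+\mu_\text{target}$, $\sigma_\text{external}$); every other item
is a distractor from Normal($-\mu_\text{target}$,
$\sigma_\text{external}$). $\sigma_\text{external}$ ("external
uncertainty") is stimulus-level variability, distinct from the
observer's internal noise; $\sigma_\text{external} = 0$ degenerates to
fixed tilts $\pm\mu_\text{target}$. Each item carries a reliability
label: the number of high-reliability items is uniform on $\{0,\dots,4\}$
and the labels are placed at random. The observer's measurement of item
$i$ is $x_i = s_i + \varepsilon_i$ with
$\varepsilon_i \sim \mathcal N(0, \sigma_i)$, where $\sigma_i$ is
$\sigma_\text{low}$ or $\sigma_\text{high}$ according to the item's
label. Orientation noise is Gaussian, not circular: at the noise levels
in play (well under 10°) the wrapped distribution is indistinguishable
from the Gaussian, and the Gaussian keeps every downstream computation
in closed form. Orientations are never wrapped.

Two display regimes are distinguished. In the *short* regime
$\sigma_\text{low}$ and $\sigma_\text{high}$ are free model parameters.
In the *unlimited* regime (long viewing time) the per-item noise SD is
fixed by the condition — either exactly 0, or a small measured value
such as 0.875° — and is not fitted; with the SD at 0 the likelihood has
a closed form and no Monte Carlo is needed.

## Observer models

The optimal (flawless Bayesian) observer pools per-item posterior
evidence,

$$d(\mathbf x) = \log\frac{p(T=1\mid\mathbf x)}{p(T=0\mid\mathbf x)}
 = \log\Bigl(\tfrac1N\sum_{i=1}^N d_\text{local}(x_i)\Bigr),\qquad
 d_\text{local}(x_i) = \exp\!\Bigl(\tfrac{2\,\mu_\text{target}\,x_i}
 {\sigma_i^2+\sigma_\text{external}^2}\Bigr),$$

and responds "present" when $d > 0$. The local evidence weights each
cue by its reliability through $\sigma_i$. The registry in
`observer_models()` contains:

* **Imperfect Bayesian** — adds late decision noise
  $\eta \sim \mathcal N(\mu_\text{late}, \sigma_\text{late})$ to $d$,
  a deliberately generic stand-in for many specific computational
  imperfections (see the error simulations below).
* **Ignorant Bayesian** (and its imperfect variant) — replaces the
  item-specific $\sigma_i$ inside $d_\text{local}$ by a single
  $\sigma_\text{single}$: no reliability weighting.
* **Heuristic rules** — compare a summary statistic with a fitted
  criterion $c$: the maximum observation, the minimum absolute
  deviation from $\mu_\text{target}$, the Minkowski distance
  $(\sum_i |x_i-\mu_\text{target}|^\beta)^{1/\beta}$, the mean, and the
  variance (population $1/N$ convention, as the rule is defined).
  Deviation-based rules respond "present" when the statistic is *below*
  the criterion, since small deviation from the expected target tilt is
  evidence for a target; the other rules respond above. Imperfect
  heuristic variants add zero-mean late noise only
  ($\mu_\text{late} = 0$), because a bias is already absorbed by $c$.
* **Posterior-sampling observer** — converts $d$ to
  $p_1 = e^d/(1+e^d)$, draws $n$ Bernoulli samples and answers
  "present" on a strict majority; even-$n$ ties are resolved by a fair
  coin (the majority rule does not cover them). As
  $n \to \infty$ it converges to the flawless Bayesian.

Every model is finished with a lapse mixture applied last:
$p = \lambda/2 + (1-\lambda)\,p_\text{core}$.

Two conventions that the definitions leave open are fixed for
determinism: ties at the decision threshold respond "absent"
(measure-zero under any noise), and the imperfect-heuristic noise is
added to the decision variable rather than the criterion (the two are
equivalent up to the sign handled by the rule's direction).

## Likelihood, priors, fitting

The probability of a recorded response given the presented stimuli
marginalises the observation noise by Monte Carlo:
`predict_response_prob()` averages the conditional response probability
over `n_mc` draws of $\mathbf x \mid \mathbf s$ (late noise, sampling
votes and lapses are integrated analytically inside each draw), floors
probabilities at $10^{-6}$, and sums logs. Three numerical choices
matter:

* **Common random numbers.** Each *trial* owns a noise substream keyed
  by (seed, trial id), regenerated identically on every evaluation. The
  likelihood surface is therefore deterministic in the parameters —
  which derivative-free optimisation requires — bit-identical across
  repeated calls, and exactly additive over any partition of the
  trials, so cross-validation folds reuse the same noise.
* **Overflow control.** The pooled evidence is evaluated by
  log-mean-exp; for the deterministic Bayesian rule only the sign of
  $d$ matters and it is resolved without exponentials whenever the
  largest term lies outside $[0, \log N]$.
* **Degenerate evidence.** With all $\sigma_i = \sigma_\text{external}
  = 0$ the local evidence is undefined; the implemented limit responds
  "present" exactly when some $x_i > 0$ (the largest local evidence
  dominates the pooled log-mean). A partially degenerate configuration
  is an error.

`fit_observer()` maximises log-likelihood plus log-prior with
Nelder–Mead restarts (Brent for one-parameter problems) on a
logistic-transformed scale inside plausible boxes: $\sigma \in [0.1,
30]$°, $\lambda \in [0, 0.5]$ constrained / $[0, 1]$ unconstrained,
$\mu_\text{late} \in [-5, 5]$, $\sigma_\text{late} \in [0.01, 10]$,
$\beta \in [0.25, 10]$, and a data-driven criterion box (the span of
the statistic on the presented stimuli, widened by 75% on each side to
absorb noise broadening). The sampling observer's integer $n$ is
profiled over a Fibonacci-like grid up to 501. In the *constrained*
regime, Normal priors on $\log\sigma_\text{low}$,
$\log\sigma_\text{high}$ (anchored at the subject's discrimination
estimates, SD 0.25 log-units) and a Beta(1, 24) prior on $\lambda$
(mode 0, mean 0.04) keep the Bayesian models from explaining away
decision imperfections as sensory noise or guessing; the exact
published prior forms are not available, so these defaults are labelled
assumptions and are override-able. AIC is always $2k - 2\log L$ with
the *pure* likelihood at the optimum, so constrained and unconstrained
fits live on one scale. Cross-validation uses a random equal-`k`
partition (the fold rule was not specified upstream; the seed is
recorded).

## Model comparison and recovery

`delta_aic_table()` reports per-dataset AIC differences to the best
model, flagging $\Delta\mathrm{AIC} \ge 10$ as "no support", with
per-model means ± SE across datasets. `model_recovery()` draws
generator parameters from a per-model multivariate Gaussian
(rejection-resampled into the plausible boxes), simulates datasets,
fits all candidates, and marks per-row winners (ties break toward the
lower model id). Heuristic candidates are always fitted unconstrained;
priors, when supplied, apply to the Bayesian families only — mirroring
the asymmetry of the constrained analysis. In the unlimited regime the
ignorant models are excluded from comparisons, being identical to
their reliability-weighted counterparts when no sensory noise is
assumed.

One identifiability fact, documented rather than hidden: when data are
generated by an imperfect Bayesian with late-noise SD around 1 (in
decision-variable units, against a decision-variable spread of a few
units), the flawless Bayesian can absorb most of the late noise by
inflating its sensory SDs within the prior, and the expected
log-likelihood advantage of the true model falls below the AIC penalty
for its two extra parameters at 1500 trials. The recovery analysis
therefore treats that pair as distinguishable only at the family level;
the strict — and scientifically load-bearing — property is that the
imperfect Bayesian is never *selected* when another model generated the
data.

## Sensitivity and the optimality decomposition

`dprime()` is $z(\text{HR}) - z(\text{FAR})$ with the standard
$1/(2n)$ correction for empty cells (the upstream correction is
unstated; this is the common convention). `optimal_dprime()` simulates
the flawless Bayesian — with the subject's fitted lapse — on freshly
drawn trials rather than the subject's exact list: with $n_\text{sim} =
10^5$ fresh trials the benchmark's Monte-Carlo error is far below the
empirical estimate's own sampling error. The relative optimality index
$I_\text{rel} = d'_\text{emp}/d'_\text{opt}$ keeps the subject's
sensory noise in the benchmark; the absolute index sets
$\sigma_i = 0$ (the lapse stays in both, matching the relative
recipe). The loss decomposition splits the total loss $1 - I_\text{abs}$
into a sensory share $100(I_\text{rel}-I_\text{abs})/(1-I_\text{abs})$
and a computational share $100(1-I_\text{rel})/(1-I_\text{abs})$; the
shares sum to 100 by construction.

## Calibration

`fit_psychometric()` fits lapse-free, bias-free cumulative Gaussians
$P(\text{cw}\mid s) = \Phi(s/\sigma)$ to discrimination data, pooled
(single) or per reliability (dual), by 1-D likelihood optimisation;
perfect separation caps $\hat\sigma$ at the 0.05° lower bound with a
flag. `simulate_discrimination()` reproduces the adaptive session: 20
uniform trials on $[-5^\circ, 5^\circ]$, then, refitting the running
pooled fit after every trial (the refit cadence was not specified;
every trial is the natural reading), a random-sign draw uniform over
the tilt band where the fit predicts 55–95% correct, falling back to
the uniform rule while the running fit is degenerate.

The design solvers invert the optimal observer's accuracy under common
random numbers (a fixed engine of standardised variates makes accuracy
a deterministic, root-findable function of the task parameters):
`solve_mu_target()` finds the tilt giving 85% optimal accuracy at
$\sigma_\text{external} = 0$; `solve_sigma_external()` finds the
external SD that lowers optimal accuracy by 5, 10 or 15 *percentage
points* from that baseline. The percentage-point reading (85 →
80/75/70) was adjudicated empirically: it round-trips the published
per-subject parameter table to within Monte-Carlo and rounding error,
which the relative-drop reading does not.

## Computational-imperfection simulations

`simulate_delta_d()` injects a specific imperfection into the optimal
observer and characterises the induced decision-variable error
$\Delta d$: noise on the log local evidences (multiplicative log-normal
on the evidence scale, preserving positivity), an overestimated
$\sigma_\text{external}$, overestimated sensory SDs, or item- and
trial-wise log-normal jitter on the believed SDs. Published figures do
not state the injected magnitudes, so the defaults (noise SD 0.5 on the
log-evidence scale, overestimation factors 1.5, jitter 0.3 log-units)
are explicit assumptions, and only qualitative structure is asserted:
misbelief-type imperfections bias $\Delta d$; noise-type imperfections
are *approximately* unbiased — convexity of log-mean-exp brackets the
induced bias in $[0, \text{SD}^2/2]$, and the measured value sits near
that upper bound; accuracy loss grows with magnitude; and
$\Delta d$ is reasonably Gaussian, summarised descriptively by
standardised skewness, excess kurtosis and total-variation distance
from the moment-fitted Gaussian, with no pass/fail threshold.

## Synthetic subjects and what passing tests show

`run_search_pipeline()` chains the stages on synthetic subjects:
adaptive discrimination session → dual-sigma psychometric fit →
per-subject calibration → search-trial simulation with a generating
observer (defaults: lapse 0.03, late-noise bias −0.2 and SD 1,
realistic mid-range values for a mildly suboptimal observer) → model
fits → comparison table → optimality report, writing seeded,
regenerable CSV artifacts. The generator emulates the study's *design*
faithfully; it does not emulate serial dependencies, learning,
attention fluctuations beyond the lapse mixture, or pop-out-driven
attentional weighting (the pop-out filter exists to *remove* such
trials, not to model them). Green tests therefore certify the
machinery — generative model, decision rules, likelihoods, solvers —
under the stated assumptions, not the behaviour of real observers.

## Problem sizes

The shipped test-suite sizes are chosen to keep a full run in minutes
while leaving every tolerance meaningful: law-of-large-number checks at
$10^5$ trials; calibration round-trips at $2\times10^5$ engine trials;
parameter recovery for the flawless Bayesian at 1500 trials × 5 seeds
(200 Monte-Carlo draws per trial, 2 restarts); the recovery grid at
one 1500-trial dataset per generator over four candidate models.
Scaling any of these up is a matter of arguments, not code.
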