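---
title: "Attractor dynamics, sequential designs and choice perseveration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attractor dynamics, sequential designs and choice perseveration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attractorchoice)
```

## The scientific problem

In a two-option foraging task, an agent repeatedly chooses between a
small-and-near (SN) coin and a large-and-far (LF) coin. Each option combines
two features — a reward (1–99 credits) and a distance (2–15 grid fields) —
and the interesting question is not which option is chosen on a single
trial, but how choices on *consecutive* trials hang together. Attractor
models of decision making predict **choice perseveration**: because the
decision system does not fully relax to a neutral state between trials, the
previous choice leaves a residue that biases the next one. The package
implements this account end to end: a one-dimensional attractor simulator,
the adaptive sequence design that makes perseveration measurable, synthetic
participants replacing a human sample, the perseveration analysis, and a
hierarchical parallel-constraint-satisfaction (PCS) network as an
alternative mechanism.

## The attractor model

The decision variable $x$ lives on one dimension; $x > 0$ is evidence for
the SN option and $x < 0$ for LF. Within a trial, $x$ diffuses in a
quartic double-well landscape

$$V(x, c) = \tfrac{x^4}{4} - \tfrac{x^2}{2} - c\,x,$$

so that

$$dx = \big(-x^3 + x + c\big)\,\frac{dt}{\tau_{\text{trial}}}
      + \sigma\,\sqrt{dt}\,\eta .$$

For $c = 0$ the two wells at $x = \pm 1$ are equally deep; the control
parameter $c$ tilts the landscape so that the well of the subjectively
better option is deeper. A choice is recorded when $|x|$ crosses the
decision bound $\theta$; exceeding the deadline records a timeout. This is
the minimal bistable family in which one scalar sets the relative depth of
the two attractors; any qualitatively equivalent landscape would serve.

During the inter-trial interval (ITI) the options are off, so the state
relaxes toward the *neutral* start point under a monostable linear force,

$$dx = -\frac{x}{\tau_{\text{iti}}}\,dt + \sigma\,\sqrt{dt}\,\eta,$$

whose noise-free solution is $x(T) = x(0)\,e^{-T/\tau_{\text{iti}}}$. We
deliberately do not keep the double-well force during the ITI: with the
inputs off, continuing bistable dynamics would relax toward the *previous*
attractor rather than toward neutrality. With the task's 1.3-s ITI and the
default $\tau_{\text{iti}} = 2$ s the state retains roughly half its
pre-ITI value — this residue is the entire perseveration mechanism. Its
dynamical signature is **hysteresis**: sweeping $c$ upward versus downward
flips the choice at different control-parameter values.

### Numerical choices

* Integration is Euler–Maruyama with fixed `dt` (default 1 ms), implemented
  in C++ and drawing noise from R's RNG so `set.seed()` governs every run.
  The linear ITI dynamics admit a closed form which the test suite uses as
  an integrator oracle (agreement within $10^{-4}$ at `dt = 1e-3`); the
  noise-free trial RT changes by less than 1% when `dt` is halved.
* $|x|$ is clipped at a ceiling (default 1.5) to prevent numerical escape
  during rare large noise excursions.
* Timeouts are recorded, never dropped, and excluded from choice ratios.
  The human task forces a choice, and with the default noise level timeouts
  are practically absent, so nothing hinges on this rule.
* Defaults ($\sigma = 0.35$, $\theta = 0.8$, $\tau_{\text{trial}} = 0.1$ s,
  $\tau_{\text{iti}} = 2$ s, $T_{\max} = 10$ s, gain 1) were chosen once so
  that stochastic runs produce graded psychometric curves and a clear
  positive perseveration index; they are model constants of this package,
  not fitted quantities.

## Valuation and the design's control variable

The task's empirical handle on $c$ is the **manipulation point**
$m = r - p^*(I)$: the trial's reward ratio $r = R_{SN}/R_{LF}$ minus the
participant's **indifference point** $p^*(I)$ at the trial's interval
$I = d_{LF} - d_{SN}$. Negative $m$ means LF is subjectively superior,
positive $m$ means SN; the map to the attractor's control parameter is
linear, $c = \text{gain} \cdot m$ (the correspondence is an analogy, so
only the sign and monotonicity are meaningful; the gain is configurable).

Synthetic participants value options by hyperbolic discounting over
distance, $\omega = R / (1 + k\,d)$, by analogy with the delay-discounting
form of the same trade-off; the functional form is a package choice, and
every downstream quantity depends on it only through the analytic
indifference points $p^*(I) = (1 + k\,d_{SN}) / (1 + k\,(d_{SN} + I))$,
which are strictly decreasing in the interval. Because the designs use SN
distances 2 and 3, the synthetic agent's valuation is referenced to their
midpoint ($d_{SN} = 2.5$), making $p^*$ a function of the interval alone —
the same simplification the per-interval psychometric fit makes.

## The adaptive design

The pipeline mirrors the study's two-stage procedure:

1. **Assessment block.** A full factorial crossing of 8 reward ratios
   (0.20–0.99), 2 SN distances (2, 3) and 4 intervals (1, 4, 8, 12) gives a
   64-trial set; five sets are generated with randomised order within each
   (320 trials), and the time-limited human block is emulated by truncating
   to a fixed count (default 134, the average completed by participants).
   LF rewards are drawn uniformly from 55–99 and SN rewards are the rounded
   ratio products, clipped into valid range.
2. **Indifference points.** Per interval, a logistic psychometric function
   of P(SN) against the reward ratio is fitted by maximum likelihood; its
   inflection $-a/b$ is the indifference point, clamped to (0.01, 0.99).
   Complete separation (a perfect step) falls back to a lightly
   ridge-penalised fit so the inflection stays identified; a flat or
   decreasing fitted slope yields no estimate. Profiles with fewer than two
   estimated intervals are flagged unusable — the synthetic counterpart of
   the study's exclusion of participants whose choices did not allow a
   sufficient sequential manipulation. Between fitted intervals the
   indifference curve is interpolated piecewise-linearly (the simplest
   monotone-preserving choice), with constant extrapolation outside.
3. **Experimental blocks.** Each block holds 16 twelve-trial sequences —
   8 per direction, 192 trials — in which the manipulation point traverses
   12 equally spaced steps spanning $[-0.3, +0.3]$
   (−0.3000, −0.2455, …, +0.2455, +0.3000), descending for SN→LF sequences
   and ascending for LF→SN. The **reward block** fixes the interval, SN
   distance and LF reward per sequence and moves only the SN reward; the
   **distance block** fixes the reward ratio (drawn between the
   indifference points at the medium intervals 6 and 7) and steps the
   interval through 1…12, with its manipulation points computed post hoc
   from the indifference curve; the **combined block** moves both features,
   drawing for each trial an interval at which the target ratio
   $p^*(I) + m$ is realisable. Target ratios are kept pre-rounding, so the
   scheduled manipulation points can be re-derived exactly; after integer
   rounding they are accurate to half a credit of the LF reward.

The interval grid 1…12 for the distance block is a package choice
(consecutive steps anchored at the assessment's endpoint intervals); the
realised manipulation points are computed post hoc from the fitted curve,
mirroring how the distance manipulation is translated into individual
manipulation points in the analysis.

## Synthetic participants

A cohort (default 40 participants) draws hyperbolic discount rates from a
log-normal distribution ($\mu = \log 0.15$, $\sigma = 0.4$), chosen once so
the implied indifference points at the design intervals fall inside the
assessment ratio range for most draws. Three choosers generate behaviour:

* `chooser_logistic(s, b)` — a lagged-logistic rule
  $P(SN) = \text{logit}^{-1}(s\,m + b\,h)$ with $h = \pm 1$ encoding the
  previous choice. With $b = 0$ it is the memoryless null model (the
  perseveration index should centre at zero); $b > 0$ injects lag-one
  perseveration directly.
* `chooser_attractor()` — the double-well simulator, threading the state
  through ITIs across the whole block, as in the task.
* `chooser_pcs()` — the PCS network below.

Each participant runs the full pipeline: assessment simulated, profile
fitted from those choices, blocks generated from the *fitted* profile,
block order balanced across the cohort, choices simulated. Infeasible or
flagged participants are replaced by fresh draws and counted. Everything is
reproducible from one master seed.

What the generator deliberately does **not** emulate: wall-clock time
limits (replaced by fixed trial counts, which carry the same statistical
information), response-time distributions matched to humans, fatigue or
learning, and human absolute effect sizes — the synthetic effects are
larger and cleaner than those reported for human samples, so passing tests
demonstrate that
the machinery detects and calibrates perseveration correctly, not that the
simulator is a quantitative model of this sample.

## Analysis

The **perseveration index** of a participant and block is
$PI = P(SN \mid SN{\to}LF) - P(SN \mid LF{\to}SN)$, pooled over trials
within each direction (timeouts excluded). Under perseveration choices
stick with the initially superior option, making the index positive; the
orientation is chosen so the one-sided tests (> 0) read naturally. The
direction-split **choice curves** report the mean percentage of LF choices
per schedule bin (or per interval for the distance block) with standard
errors across participants; for SN-coded curves the mean direction gap over
bins equals the pooled index exactly when every sequence contributes one
trial per bin. Per-block indices are tested with one-sample t tests and
Cohen's d, and blocks are compared descriptively (means, SEs and pairwise
differences with seeded bootstrap percentile intervals); no
multiple-testing correction is applied, and no mixed-model machinery is
included — the per-trial logs are exported so an external GLMM tool can
consume them.

## The PCS alternative

The PCS network is a two-layer interactive-activation system: a clamped
general-validity node feeds four feature nodes (distance and reward of each
option, min–max scaled to $[-1, 1]$ over the design ranges, distances coded
as proximity); feature nodes excite their own option node and inhibit the
other; the two option nodes inhibit each other. Each cycle updates
non-clamped nodes by
$a_i \leftarrow a_i(1 - \text{decay}) + n_i \cdot (\text{ceiling} - a_i)$
for positive net input $n_i = \sum_j w_{ij} a_j$ (mirrored toward the floor
for negative input), and the network responds when successive changes of
the energy $E = \sum_{i<j} w_{ij} a_i a_j$ fall below a stability
threshold. Exact option ties are broken by a seeded coin flip and logged.

Carryover multiplies the post-decision *option-layer* activations by a
retention factor $\rho = e^{-1.3/\tau_{\text{iti}}}$ (paralleling the
attractor's ITI relaxation) and injects them as the next trial's initial
conditions; the feature layer is reset by the new stimulus. The default
dynamics (decay 0.2, feature–option weight 0.15, option inhibition 0.1)
were chosen once so that strong feature evidence overrides the residue
while near-tie trials follow it — the regime in which the network is a
sensible chooser at all; outside it the residue locks the agent into choice
runs that destroy its own assessment psychometric fits.

The validity→feature weights encode feature importance. Down-weighting one
feature dimension collapses the perseveration index specifically in the
block that manipulates that feature (the manipulation loses its grip on the
network), which is the hierarchical explanation for block-wise differences
in perseveration. With *equal* importance weights the blocks are
structurally still not identical — the distance block concentrates its
trials differently over manipulation points than the reward block — so
block-wise indices need not be indistinguishable even though the mechanism
treats the features symmetrically; the acceptance checks report both the
paired test and the raw differences, and this residual asymmetry is a known
limitation of reading "equal weights" as "equal block effects".

## Problem sizes and tolerances used in the checks

The test suite and the acceptance script run at the study's scale where it
is cheap (40-participant cohorts, 320-trial assessments, 192-trial blocks)
and replicate stochastic claims over 20 seeded cohorts; hysteresis and
integrator checks are deterministic and exact to their stated tolerances
($10^{-12}$ for design round-trips, $10^{-4}$ for the ITI oracle). The
deterministic hysteresis demonstration uses control gain 2 so the sweep
exceeds the saddle-node point of the quartic landscape
($|c| = 2/(3\sqrt{3}) \approx 0.385$), outside of which a noise-free system
cannot switch wells at all. Indifference-point recovery is reported as the
mean absolute error against the analytic ground truth; at the design's 80
assessment trials per interval and generative sensitivity 8 the maximum-
likelihood inflection estimator's sampling error is itself of order
0.03–0.05, so the recovered MAE sits at that statistical floor rather than
at zero.

## Known limitations

* The attractor landscape, its parameters and the control-parameter gain
  are structural choices constrained only qualitatively; no quantitative
  fit to human data is attempted or claimed.
* The subjective-value form (hyperbolic over distance) is an analogy; any
  strictly monotone alternative would do if the analytic indifference
  points were updated consistently.
* The perseveration index pools trials within direction before
  differencing; per-sequence averaging would weight sequences equally but
  is not implemented.
* PCS parameters are illustrative, chosen for a functioning chooser; the
  model is a qualitative comparison point, not a fitted competitor.
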