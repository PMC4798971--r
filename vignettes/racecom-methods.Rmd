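---
title: "Bounded accumulation, confidence, and changes of mind: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded accumulation, confidence, and changes of mind: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`racecom` implements a bounded evidence-accumulation account of a binary
motion-direction decision that is reported together with a binary
confidence rating, and of the occasional mid-movement revisions of either
report ("changes of mind").

## The race

Momentary evidence drives two accumulators, one for each direction. Under
signed coherence $C$ (negative = leftward) the pair $(x_1, x_2)$ is a
correlated Brownian motion with drift $(\kappa C, -\kappa C)$ per second,
unit variance per second in each coordinate, and noise correlation
$\rho \in (-1, 0]$. The variance normalization is an identifiability
convention: $\kappa$ and the bound $B$ absorb the scale. The first
accumulator to reach the shared absorbing bound $B$ commits the initial
choice and sets the decision time; reaction time adds a Gaussian
non-decision time $\mathcal N(\mu_\mathrm{tnd}, \sigma_\mathrm{tnd}^2)$.

The bound is flat (stationary). This is what makes the analytic solution
below available, and it is also why error-trial mean reaction times are
excluded from the fitting cost: a flat bound does not reproduce their
shape, and including them would bias the other parameters.

## Method of images

For correlations of the form $\rho = -\cos(\pi/k)$, $k \ge 2$, the
survival density of the absorbed pair is an exact finite signed sum of
free Gaussian propagators. The image sources are the orbit of the start
point under the dihedral group generated by *oblique* reflections across
the two bounds — reflections that are isometries of the diffusion metric
$\Sigma^{-1}$:

* across $x_1 = B$: $(x_1, x_2) \mapsto (2B - x_1,\; x_2 - 2\rho(x_1 - B))$,
* across $x_2 = B$: symmetric in the two coordinates.

After whitening, the domain $\{x_1 < B,\ x_2 < B\}$ is a wedge of opening
angle $\pi/k$, so the reflection group is finite with $2k$ elements and
the expansion closes after $2k - 1$ images: 3 images for $\rho = 0$, 5 for
$\rho = -0.5$, and 7 for $\rho = -\cos(\pi/4) \approx -0.71$.
`minimal_image_count()` verifies these counts constructively, adding
sources in reflection-word order until the summed density vanishes on a
grid of boundary points.

Drift does not break the construction because the Girsanov factor
$\exp\!\big(\mu'\Sigma^{-1}(x - x_0) - \tfrac12 \mu'\Sigma^{-1}\mu\, t\big)$
depends only on the endpoint: each image simply acquires a constant weight
$\exp(\mu'\Sigma^{-1} a_j)$, which for this drift geometry reduces to
$\exp\{\kappa C (a_{j1} - a_{j2}) / (1 - \rho)\}$.

The default correlation is $-\cos(\pi/4) = -1/\sqrt 2 \approx -0.71$, the
7-image case, on the reading that roughly half of the accumulator noise is
shared through the stimulus. The 5-image value $-0.5$ is equally runnable
— `corr` is an ordinary parameter restricted to the solvable set, and an
unsupported value produces an error naming the nearest supported one.

## Flux in closed form

Writing the survival density as a sum of Gaussians $g_j$, the outward flux
across $x_1 = B$ is $-\tfrac12 (\Sigma \nabla p)_1$, and
$(\Sigma \nabla g_j)_1 = -g_j (x_1 - m_{j1})/t$ — so the joint density of
(decision time, losing-accumulator state) is itself a finite sum of
Gaussian terms, and its partial integrals over the loser state are
analytic (Gaussian CDFs). Two consequences the package exploits heavily:

* the first-passage-time density per winner is a cheap 1-D formula (the
  loser state integrates out up to the bound — integrating each term over
  the whole line instead makes the image terms cancel identically, which
  is a useful internal consistency check but not the marginal);
* the four initial category probabilities (correct/error × high/low) per
  coherence need no 2-D grid at all, which keeps the stage-1 likelihood
  at a fraction of a second per evaluation.

With one bound removed the same construction collapses to a single image
and reproduces the shifted-Wald (inverse Gaussian) density exactly; this
is one of the package's independent-oracle tests.

# Belief: the log-odds map

Because the winner sits at $B$ at the decision, the decision state is
summarized by the elapsed time $t$ and the balance of evidence
$\Delta$ = winner − loser. Oriented toward the leading direction, the
balance diffuses with drift $2\kappa C$ and variance rate $2(1 - \rho)$.
The belief map is

$$
L(t, \Delta) \;=\;
\log \frac{\sum_{C \,\text{congruent}} w_C\,
\phi\!\big(\Delta;\, 2\kappa C t,\, 2(1-\rho)t\big)}
{\sum_{C \,\text{opposing}} w_C\,
\phi\!\big(\Delta;\, 2\kappa C t,\, 2(1-\rho)t\big)},
$$

with the prior $w_C$ uniform over the 12 experimental signed coherences
and the 0% weight split equally between the two sides (the rewarded
direction on 0% trials is designated at random, and the split is exactly
what makes the map marginally calibrated over those trials too).

Two design points deserve emphasis:

* **Exact calibration at the decision.** One might worry that the free
  balance density is the wrong likelihood for states that are conditioned
  on absorption. It is not: the absorption flux factorizes into a
  drift-independent part times the same endpoint-only Girsanov factor, so
  coherence likelihood *ratios* — all that $L$ depends on — are identical
  whether computed from the flux or from the free balance density. The
  map is therefore calibrated by construction at absorption states
  ($P(\text{correct} \mid L) = 1/(1+e^{-L})$, which the test suite
  verifies by simulation), and, unlike a flux-based map, it extends
  smoothly to $\Delta \le 0$, which the post-initiation stage requires.
* **Closed-form evaluation.** The map is evaluated analytically
  (log-sum-exp over the coherence mixture) rather than by bilinear
  interpolation on a precomputed grid; the tabulated grid exists only for
  serialization and plotting. This removes interpolation error from the
  likelihood and makes the map exact at any $(t, \Delta)$. Inversion in
  $\Delta$ (needed to turn log-odds criteria into balance cutoffs) uses
  vectorized bisection on the strictly monotone map; 60 halvings of a
  bracket a few tens of evidence units wide leave no meaningful error.

A time-invariant criterion $\theta$ splits the reports: high confidence
iff $L \ge \theta$. Under the task payoffs (+2/−3 on the high-risk
target, +1/−1 on the low-risk target) the expected-points indifference
sits at belief $2/3$, i.e. $\theta^\ast = \log 2 \approx 0.69$;
`optimal_criterion()` solves this for arbitrary payoff matrices. Two
reduced read-outs — a threshold on the balance alone and a threshold on
decision time alone — are provided as `alternative_confidence_rule()`
for model comparison.

# The post-initiation stage

After commitment, evidence already in the sensory–motor pipeline keeps
arriving for a further $t_\mathrm{pip}$ seconds
($0 \le t_\mathrm{pip} \le \mu_\mathrm{tnd}$; the constraint is applied
against the mean because the per-trial non-decision time is random). The
balance continues as a *free* diffusion — there is no second bounded race
— and the final report is read out at $t_\mathrm{dec} + t_\mathrm{pip}$
on the same belief clock, by comparing $L(t_\mathrm{dec} + t_\mathrm{pip},
\Delta')$ against three ordered thresholds that partition the axis into
same-direction/high, same-direction/low, opposite/low and opposite/high
zones:

* initial high confidence: $(\theta - \delta\theta_1,\; -\delta\theta_2,\;
  -\theta - \delta\theta_3)$;
* initial low confidence: the first threshold becomes
  $\theta + \delta\theta_1$.

The $\delta\theta$ shifts implement hysteresis and motor-cost asymmetries
(positive $\delta\theta_1, \delta\theta_2$ resist change; fitted
$\delta\theta_3$ tends to be negative, narrowing the opposite/high zone
that would require crossing the workspace). Parameter points whose
thresholds are not strictly decreasing are invalid and are rejected — in
fitting they receive infinite cost. Leftward initial choices are handled
by reflecting the oriented axis. On 0% coherence trials the
post-initiation drift is zero: the stimulus is the evidence source, and
the random reward designation carries no signal.

Computationally, each absorption atom $(t, \Delta)$ contributes Gaussian
zone probabilities with mean $\Delta + 2\kappa C\, t_\mathrm{pip}$
(oriented) and variance $2(1-\rho) t_\mathrm{pip}$; the zone cutoffs in
$\Delta$ are obtained by inverting the map once per time-grid row and are
shared across coherences and winners. At $t_\mathrm{pip} = 0$ the
classification degenerates to the initial one exactly, and with all
$\delta\theta = 0$ the 4×4 initial-by-final table is exactly diagonal —
both are regression tests.

# Fitting

Stage 1 fits $(\kappa, B, \mu_\mathrm{tnd}, \theta)$ by maximum
likelihood to, per unsigned coherence, (i) the multinomial counts of the
four initial categories and (ii) a Gaussian term for the sample mean RT
of correct trials (all trials at 0%), with the observed s.e.m. as its
standard deviation. Constants are dropped; predicted probabilities are
floored at $10^{-10}$ (with a warning when the floor binds on an observed
category). $\rho$ and $\sigma_\mathrm{tnd} = 60$ ms are fixed. Stage 2
freezes all four stage-1 estimates — the carried set must include $B$ and
$\mu_\mathrm{tnd}$, not just $\kappa$ and $\theta$, since the predicted
16-category table depends on all of them — and fits $(t_\mathrm{pip},
\delta\theta_1, \delta\theta_2, \delta\theta_3)$ to the per-coherence
16-category counts.

The optimizer is bounded Nelder–Mead: parameters live in boxes
($\kappa \in (1, 50]$, $B \in (0.1, 5]$, $\mu_\mathrm{tnd} \in [0.1, 1]$,
$\theta \in (0.05, 5]$, $t_\mathrm{pip} \in [0, \mu_\mathrm{tnd}]$,
$\delta\theta \in [-3, 3]$ — wide brackets around typical fitted values)
mapped through a logistic transform, with multiple random starts
(30 by default) and convergence tolerance $10^{-6}$ on the cost. The best
run is then *re-started* from its own optimum until a restart no longer
improves the cost: a fresh simplex recovers from premature collapse,
which profiling showed was otherwise the dominant error source in the
4-parameter stage-2 fit (optimizer error, not likelihood flatness).
Because the absorption atoms do not depend on the stage-2 parameters,
they are computed once per fit and cached; a stage-2 likelihood
evaluation then costs about a second.

# The synthetic generator

`simulate_trials()` is the package's Monte-Carlo counterpart of the
analytic machinery — the two are developed against each other and the
test suite requires their agreement (Kolmogorov–Smirnov distance below
0.01 on first-passage distributions at $10^5$ paths per coherence, and
category frequencies within binomial error).

* **Integration.** Euler–Maruyama with a 0.5 ms step and correlated
  increments. A per-step Brownian-bridge crossing probability
  $\exp\{-2(B - x_\mathrm{prev})(B - x_\mathrm{new})/\Delta t\}$
  supplements the end-of-step bound check: plain discrete checking
  carries an $O(\sqrt{\Delta t})$ first-passage bias (about 13 ms of mean
  RT at this step size) that would dominate the KS budget; the bridge
  correction reduces it to $O(\Delta t)$. If both accumulators cross
  within one step (rare), the crossing with the larger bridge probability
  wins, and the loser state is capped at $B$.
* **Continuation.** The post-initiation balance is drawn from the exact
  free Gaussian transition rather than stepped — for an unbounded
  diffusion observed only at its endpoint the two are distributionally
  identical, and the one-shot draw removes a discretization knob.
* **Censoring.** Trials unabsorbed at 5 s are recorded as censored and
  excluded with a reported count (the task's own 3 s "too slow" rule is
  looser than the model's horizon; the cap is configurable).
* **Design.** The default session covers the 12 signed coherences
  (±0, ±3.2, ±6.4, ±12.8, ±25.6, ±51.2%) with equal trial counts, a
  truncated-exponential foreperiod (0.5–2 s, mean 0.82 s), ABBA target
  layouts and double-pass mirrored stimulus pairing carried as design
  metadata.

`synthesize_trajectories()` produces 1000 Hz minimum-jerk reaches to the
initial target with a re-plan toward the final target at a time drawn
uniformly from the middle 60% of the movement on change trials, plus
smoothed positional noise. This is a *fixture generator* for the area
detector, not a biomechanical model: durations, the re-plan draw and the
noise amplitude are chosen so that straight reaches stay well below the
0.1 cm² criterion and re-plans exceed it, and the closed-loop requirement
is that detection recovers the planted initial and final targets on at
least 99% of trials.

`generate_dot_movie()` follows the stimulus rules: three interleaved dot
sets, each reappearing three frames (40 ms) later, per-dot Bernoulli
(coherence) choice between a coherent 0.2° displacement (5°/s × 40 ms)
and random replacement, dot count per frame equal to density × aperture
area × frame time (12.5 dots deg⁻² s⁻¹, 5° aperture, 75 Hz), and a
horizontal-mirror partner for double-pass generation.

**What the generator does not emulate:** sequential dependencies and
learning across trials, non-stationary criteria, lapses, response
biases, kinematic variability beyond smooth noise, and photometric
detail of the display. Passing tests therefore certify the internal
consistency of the machinery and its statistical properties under the
model, not the model's adequacy for any particular empirical data set.

# Motion energy and kernels

Dot movies are projected onto the horizontal axis (the filters are
direction-selective in x and energy is summed over space afterwards, so
collapsing y sacrifices nothing the analyses use) and rendered on a
0.05°/one-frame space-time grid. Opponent energy is computed from a
spatial even/odd Gabor quadrature pair (1.1 cyc/deg carrier, 0.35°
envelope) crossed with fast/slow biphasic temporal filters
($(kt)^n e^{-kt}[1/n! - (kt)^2/(n+2)!]$, $k = 60$ s⁻¹, $n = 3, 5$); the
preferred displacement matches the coherent dot step. The exact filter
constants of the original analyses are not published, so all constants
live in `motion_filter_config()` and the validation is structural:
rightward motion yields positive net energy, mirroring negates the trace
to float precision, and the two-stroke impulse response is causal and
transient.

Psychophysical kernels are condition-mean residual energies (means of
trials sharing coherence × direction removed; only |coherence| ≤ 6.4%
enters), grouped by choice, confidence-within-choice, or change type,
aligned to stimulus onset or movement onset, in 13.3 ms bins, with a
minimum of 10 trials per plotted group. The non-decision latency is
re-estimated from the movement-aligned kernel by least-squares fitting of
$\alpha\,(1 - \Phi(t \mid \mu_\mathrm{tnd}, \sigma_\mathrm{tnd})) * IR(t)$
— a step at $-\mu_\mathrm{tnd}$ smoothed by Gaussian non-decision-time
variability and by the filter's impulse response. Recovery of
$(\mu_\mathrm{tnd}, \sigma_\mathrm{tnd})$ from synthetic kernels within
10% is part of the acceptance suite, giving a second, model-free route to
the latency that the race-model fit estimates parametrically.

# Behavioral analyses

* **Screening**: reaction times strictly below 150 ms are excluded
  (a trial at exactly 150 ms is retained).
* **Change detection**: the final target is the endpoint; the initial
  target is inferred from the area between the hand path and the
  vertical (direction) or horizontal (confidence) dividing line, with a
  0.1 cm² opposite-side criterion. The path is accumulated from the
  moment the hand is 1 cm from home — the movement-initiation definition
  — to target arrival. The phrase "over the first 1 cm of movement" is
  genuinely ambiguous (an area accumulated over a 1 cm segment could
  hardly exceed 0.1 cm²); the adopted reading treats "the first 1 cm" as
  marking where the path *begins*, and the closed-loop fixture tests pin
  the detector's behavior under it.
* **Logistic models**: `logistic_confidence()` fits
  $P(\text{high}) = [1 + e^{-b_0 - b_1 |C|}]^{-1}$ and
  `logistic_choice_with_confidence()` fits
  $P(\text{right}) = [1 + e^{-b_0 - b_1 C - b_2 I - b_3 I C}]^{-1}$ with
  a one-sided test of $b_3 > 0$, both via `glm`.
* **Odds ratios**: OR = odds(high | correct)/odds(high | error), with
  correctness always defined by the *initial* direction choice, computed
  from the initial and from the final confidence report; 1000 bootstrap
  resamples give intervals and per-point comparisons, a two-sided sign
  test summarizes the points, and points with an empty cell (no errors)
  are excluded and counted. OR(final) > OR(initial) is the model's
  signature confidence–accuracy dissociation arising purely from
  post-decision processing.
* **Points**: payoffs applied to the final choice; the change benefit is
  the mean, over change trials only, of points earned minus points the
  initial choice would have earned.

# Numerical choices and problem sizes

Default grids: decision time 1 ms to 5 s; loser state 201 points spanning
8 standard deviations below the bound; belief-map tabulation 10 ms ×
0.05 evidence units. Likelihood evaluations use a 5 ms time grid and a
121-point loser grid — at these resolutions the conservation defect stays
under $10^{-3}$ across the fitted parameter range, which is the accuracy
the multinomial cost can use. Absorption atoms below $10^{-7}$ of the
maximum cell weight are pruned.

The test suite chooses problem sizes that make its statistical assertions
sharp without waste: $10^5$ paths per coherence for distribution-level
oracle comparisons, 96,000 trials for the calibration check, 9,000 trials
(the scale of one subject's data set) for parameter recovery with 4
stage-1 and 2 stage-2 starts, and 30,000 trials for the qualitative
change-of-mind pattern suite. Stage-2 recovery is asserted two ways: the
generating point must lie inside the fit's 95% likelihood-ratio region
($2\,\Delta\mathrm{NLL} < \chi^2_{4,0.95}$), and the estimates must sit
within absolute bands (±0.1 s on $t_\mathrm{pip}$, ±0.25 on each
$\delta\theta$) that reflect the information a single session carries
about rare change events.

# Known limitations

* Correlations outside $\{-\cos(\pi/k)\}$ have no finite image expansion;
  the package refuses them rather than approximating.
* Collapsing or reflecting bounds are out of scope (they would break the
  image construction), as are more than two accumulators and
  time-dependent confidence criteria.
* The post-initiation stage classifies at a single fixed horizon; it does
  not model a second termination rule or the kinematics of the corrective
  movement.
* Standard errors of fitted parameters are not computed from a Hessian;
  refitting bootstrap resamples is the supported route.
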