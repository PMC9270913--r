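---
title: "Models and methods behind fireflynav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fireflynav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fireflynav)
```

# The task and its dynamics

The firefly task asks a subject to steer, via a two-axis joystick, to a
briefly cued target on a ground plane whose transient texture elements
provide optic flow but no landmarks. `fireflynav` simulates this task and
implements the statistics used to decide whether steering is guided by
integrating the optic flow or by an internal (efference-copy) model of the
control dynamics.

The plant is first order with no inertia. At each display frame
(`dt = 1/60` s) the true velocity is

    s_t = G * (v_max * a_lin, w_max * a_ang) + eta_t + p_t

where `a` is the joystick command in [-1, 1]^2, `G` the joystick gain,
`v_max = 2` m/s and `w_max = 90` deg/s the speed caps at gain 1, `eta` an
optional process noise and `p_t` the velocity of an ongoing perturbation
event. The observation (optic flow percept) is `o_t = s_t + eps_t` with
`eps` zero-mean Gaussian; its SD scales with ground-element density as
`sqrt(2.5 / rho)`, on the argument that flow elements contribute
approximately independent motion information, so Fisher information grows
with element count. At `rho = 0`, or once a finite flow duration has
elapsed, the observation is missing altogether.

Although the scalar state equation is written per component, position is
integrated with standard planar unicycle kinematics (forward Euler at the
recorded `dt`): position advances by `v dt` along the current heading,
then heading advances by `w dt`. Curved trajectories in the task make the
planar reading the only sensible one; the scalar notation is shorthand.
Headings are degrees in every interface (wrapped to (-180, 180]), radians
internally; angle 0 is the initial facing direction and positive is
rightward.

# The agent continuum

The two candidate navigation strategies are realized as the ends of one
mixing parameter. Each step, the agent estimates its velocity as

    s_hat = lambda * o_eff + (1 - lambda) * g_hat * (v_max a_lin, w_max a_ang)

with `lambda = lambda_sensory` and `g_hat = assumed_gain`. At
`lambda = 1` with noiseless observations the believed pose equals the true
pose whatever the true gain; at `lambda = 0` the belief evolves as if the
gain were `g_hat` and perturbations never happened — these two contracts
are tested exactly. When the observation is missing, the sensory channel
falls back to a slow-speed prior shrunk toward zero information:
`o_eff = (w_p / (1 + w_p)) * prior_mean_speed` on the linear component and
0 on the angular one, with `w_p = prior_weight`. This under-estimates
displacement and is what produces target overshoot when optic flow is
removed early. The fallback estimate can in addition vary from trial to
trial (`prior_cv`, a mean-preserving lognormal draw made once per trial):
an internal speed signal without sensory support is not only biased but
noisy, and this variability is what spreads endpoints into the fans seen
in data when flow is cut early. The default is 0 (deterministic); the
`flow_prior` preset uses 0.5.

The controller is deliberately simple and all analyses are
controller-agnostic: a proportional law on the *believed* state. The
angular command is `k_angular` times the believed bearing error (rad,
clipped to ±1); the linear command is `k_linear` times the believed
remaining distance, clipped to `max_linear_command`, and attenuated to
zero as the bearing error grows from 30 to 90 degrees — turn hard first,
then translate, which reproduces the early-turning shape of real
trajectories. `max_linear_command` (default 1) is the agent's preferred
cruise deflection; 0.5 gives the 1 m/s pace typical of subjects.
Commands drop to zero once the believed distance falls below
`stop_distance`, and re-engage only if it grows beyond 1.5 times that
value. The hysteresis exists so that observation noise while stationary
cannot restart steering every frame; a perturbation large enough to
displace the stopped agent beyond the margin does trigger a corrective
response.

A trial ends when the *true* speed stays below thresholds for
`stop_hold = 0.2` s after movement onset, or at `max_trial_duration`.
Both components are checked (linear below `stop_speed_threshold` =
0.05 `v_max`; angular below the same fraction of `w_max`): with a
linear-only criterion, an agent correcting an overshoot by turning in
place would be scored as stopped in mid-response. A trial whose agent
never moves is flagged invalid rather than silently kept.

# Perturbations and their counterfactual

Perturbation events have fixed 1-s duration, onset uniform in 0–1 s after
movement onset, and amplitudes drawn independently and uniformly from
±2 m/s (linear) and ±120 deg/s (angular). Two profiles are provided:
an isosceles triangle peaking at the window midpoint, and a Gaussian
`exp(-(t - mid)^2 / (2 * 0.2^2))` whose sigma is read as 0.2 *seconds* —
the only reading consistent with a 1-s window — truncated, not
renormalized, at the window edges. Whether the linear and angular
amplitudes were drawn jointly or independently is not specified anywhere;
we draw them independently.

The uncompensated counterfactual for a perturbed trial takes the
unperturbed trial with the most similar target (Cartesian Euclidean
distance between target positions; ties break to the lowest trial id,
within the same session and gain/density condition only), adds the
perturbation velocities to its steering velocities with their timing
preserved relative to movement onset, and re-integrates the whole trial.
If the matched trial ends before the perturbation window does, the
steering velocities are zero-padded and integration continues. For a
straight matched trial and a pure linear perturbation this reduces to
"endpoint plus profile area", which the tests exploit as an exact oracle
(the triangle's midpoint Riemann sum telescopes exactly when the onset
sits on the time grid).

# The metric battery

**Shuffle-null ROC.** Accuracy of continuous endpoint responses is the
area under the curve of true-positive proportion (trials with error
within a swept hypothetical reward boundary) against false-positive
proportion (the same after shuffling targets across trials). The boundary
grid is every distinct observed error plus zero — the curve is the exact
step function, and its trapezoidal area equals the rank statistic
`mean((P(A <= s) + P(A < s)) / 2)` over shuffled errors `s`, which the
tests recompute independently. Shuffles are fixed-point-free permutations
(derangements): re-pairing a trial with its own target would leak the
true pairing into the null and, in the perfect-accuracy limit, keep the
AUC strictly below 1. The default 100 shuffles stabilizes the estimator;
a single shuffle reproduces the field's original procedure.

**Compensation indices.** `pci(auc_p, auc_uc, auc_np)` locates perturbed
accuracy between the uncompensated counterfactual (0) and unperturbed
trials (1); it errors, rather than returning NaN, if the unperturbed AUC
does not exceed the uncompensated one. `gci(g, g0, b, b0)` measures bias
invariance under a gain change via no-intercept multiplicative-bias
slopes `b = sum(target * response) / sum(target^2)` (95% CIs by
percentile bootstrap over trials, 1000 resamples by default). Its
timecourse is recomputed on 20-trial prefix increments and correlated
with trial count; a zero-variance series reports correlation 0 with a
degeneracy flag instead of propagating NaN.

**Dynamic response.** For each perturbed trial the controlled velocity
(`G * v_max * a`, *excluding* the perturbation — including it would
mechanically imprint the profile and mask compensation; a flag selects
the alternative) is compared with its target-matched unperturbed trial at
lags 0–2 s from perturbation onset in 6-ms steps, linearly interpolated
from the 60-Hz grid and zero-held beyond the recorded series. The
deviation is divided by the trial's perturbation amplitude and
sign-flipped so that positive opposes the perturbation. Linear responses
group into forward/backward by amplitude sign; angular responses into
congruent/incongruent by whether the perturbation rotates toward the
remaining target bearing at perturbation onset. Zero-amplitude components
are excluded with a logged count.

**Travel-time regression.** `log T = w_r log r + w_v log v` without
intercept, by ordinary least squares; `v` is the time-averaged absolute
*linear* controlled speed between movement onset and stop (the regression
is motivated by `v = x / t` for travelled distance, so angular speed is
ignored). Non-positive or non-finite inputs are excluded with a message;
a rank-deficient design errors. One analytic subtlety deserves honesty:
because the regression has no intercept, any constant log-pace offset in
the data is absorbed by the weights. An agent whose planned travel time
is proportional to distance recovers `w_v ~ 0` only if its pace makes `T`
numerically track `r` (about 1 m/s); the `dead_reckoner` preset therefore
cruises at half deflection, which is both the subjects' typical speed and
the pace at which the time-integrator signature is identifiable. The
ideal-integrator signature `(1, -1)` is insensitive to pace because
`T = path / v` holds identically.

# What the generator emulates — and what it does not

The presets encode the task variants: `monkey_default` (targets 1–4 m,
±35 deg, Gaussian perturbations, density 2.5 or 0.1), `human_default`
(1–6 m, ±40 deg, triangular perturbations), and `human_flow` (targets
fixed at 3 m, ±30 deg, flow durations {0.5, 0.75, 1, 1.5} s — a
zero-width target range is legal and pins the coordinate). Sessions
interleave perturbed trials with probability 0.5, present gains in
500-trial blocks (monkey) or per trial (human), and draw density or flow
duration per trial. A single session seed derives per-trial seeds
deterministically, so any trial is reproducible in isolation.

The generator emulates closed-loop steering, strategy-dependent
compensation, reliability-dependent scatter and prior-driven overshoot.
It does *not* render optic flow (element lifetimes, stereo geometry),
model eye movements, reaction times, lapses, motor noise in the joystick,
or learning within a session (the GCI timecourse of a stationary agent is
flat by construction — its correlation anchor is exercised with synthetic
bias ramps). Passing tests therefore certify the statistical machinery
and the simulator's contracts, not that real subjects behave like the
agents.

# Numerical choices and problem sizes

* Euler integration at the recorded `dt` throughout; imported data on an
  irregular time grid is rejected, never resampled.
* A response exactly at the origin has an undefined bearing; it is
  reported as 0 with an `at_origin` flag.
* Per-trial seeds are `(session_seed + 100003 * i) mod (2^31 - 19)`,
  keeping every derived seed a valid 32-bit integer.
* Matching ties and degenerate variances are resolved explicitly (lowest
  id; flagged zero correlation), never left to floating-point accident.
* The test suite runs the recovery analyses at the sizes a desk check
  affords: 300 trials per agent for the regression signatures, 300 trials
  per sensory-weight level for the index sweep (both indices are strictly
  increasing in `lambda_sensory` with endpoints within ±0.1 of {0, 1}),
  500 trials for the density contrast, and 800 trials per duration for
  the flow-duration contrast — the 500 vs 750 ms AUC difference is a
  small mean effect (~0.01) and needs that resolution to order reliably.
  The script in `scripts/acceptance.R` re-derives the analytic anchors at
  the same sizes from a fresh seed.

# Known limitations

The controller is one convenient law, not a fitted model of primate
steering; absolute travel times and speeds therefore match the task only
in order of magnitude. The observation-noise model collapses the flow
field to a two-component velocity percept with density-scaled SD. The
belief is a point estimate — there is no posterior, so "reliability
weighting" is a fixed mixing constant rather than Bayes-optimal cue
combination. Fitting `lambda_sensory` to real datasets is out of scope,
though `import_session` accepts real data in the package's tabular schema
for the full metric battery.
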