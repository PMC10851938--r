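---
title: "Simulating predictive fluid allocation for hemorrhage casualties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating predictive fluid allocation for hemorrhage casualties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hemotriage)
```

## The problem

In a mass-casualty event, whole-blood units are scarce and the medic must
decide, casualty by casualty, who receives fluid and how much. Static
guidelines (here reduced to a two-step rule on heart rate and systolic
blood pressure) treat whoever currently looks unwell; a predictive policy
instead forecasts each casualty's response to each candidate treatment and
gives fluid only where it is both needed and sufficient. `hemotriage` is a
simulation framework for quantifying the gap between these policies, and
for a third question: whether the *errors* of such a forecaster can flag
casualties whose bleeding a tourniquet did not actually stop.

All data are synthetic. A ground-truth physiological simulator plays the
role of the patient; the forecaster and the allocation policies only ever
see what a vital-sign monitor would show.

## The ground-truth surrogate

The simulator is a deliberately small lumped model with three state
variables: blood volume $V$, heart rate $HR$, and systolic pressure $SBP$.

$$\frac{dV}{dt} = -b(t) + k_r\,(V_0 - V) + \frac{u(t)}{60},$$

where $b(t)$ is the hemorrhage rate (a constant until tourniquet time
$t_1$, then a residual fraction $f_{nc}$ of it), $k_r$ is a transcapillary
refill constant, and $u(t)$ is the infusion rate in L/h. The fractional
deficit $d = \max(0, (V_0 - V)/V_0)$ drives piecewise-linear targets

$$HR^*(d) = HR_0 + g_{hr}\,d, \qquad
SBP^*(d) = SBP_0 - a_{sbp}\min(d, d_c) - b_{sbp}\max(0, d - d_c),$$

toward which $HR$ and $SBP$ relax with first-order time constants
$\tau_{hr}$, $\tau_{sbp}$. The two-slope pressure target encodes the
compensated/decompensated transition at deficit $d_c$: pressure is
defended up to moderate blood loss, then falls steeply. Nominal values are
$V_0 = 5$ L, $HR_0 = 75$, $SBP_0 = 120$, $g_{hr} = 250$, $a_{sbp} = 40$,
$b_{sbp} = 250$, $d_c = 0.15$, $\tau_{hr} = \tau_{sbp} = 3$ min,
$k_r = 0.004$ min$^{-1}$. These reproduce the qualitative clinical picture:
healthy baselines, tachycardia climbing toward 200 beats/min and pressure
falling toward 40 mmHg under Class II–III losses, slow spontaneous
compensation after the tourniquet, and recovery under infusion.

Integration is fixed-step explicit Euler at 0.1 min, reported on the
whole-minute grid, chosen for determinism and exact cross-run
reproducibility rather than adaptive accuracy; at these time constants the
0.1-min step is far inside the stability region and the minute-grid output
is accurate to well below measurement resolution. HR and SBP are never
clamped — out-of-range excursions (outside 40–200 beats/min or 40–260 mmHg,
the span of field monitors) only set a flag, and a negative or non-finite
volume marks the run incomplete. Because the dynamics are first order they
cannot oscillate; the oscillation detector (more than two local HR extrema
of prominence above 2 beats/min after the tourniquet) exists to guard the
cohort filter against future surrogate changes, and a property test
confirms it stays silent on the current model.

The monitored vitals are the simulator's output without added noise.
Measurement noise is a realistic feature of field data that this study
deliberately omits so that the comparison isolates forecasting and
allocation error; a noise option can be layered on the trajectories
without touching any downstream code.

## Scenarios and cohort

A hemorrhage scenario is a (bleeding time $T_b$, volume loss $V_\ell$)
point drawn uniformly from the pentagon
$\{5 \le T_b \le 15 \text{ min},\ 0.75 \le V_\ell \le 2.0 \text{ L},\
V_\ell \le 0.22\,T_b\}$ — Class II–III losses capped at the highest
reported bleed rate of 0.22 L/min. The timeline is: injury at 0, tourniquet
at $t_1 = T_b$, infusion start at $t_2$ uniform in $t_1 + [10, 15]$ rounded
to the whole minute (so the 10-min observation window and the 60-min
forecast align with the minute grid), end of scenario at $t_3 = t_2 + 60$.
Treatments are the four block schedules over two 30-min windows — (0,0),
(0,1), (1,0), (1,1) units — with one 0.55-L unit infused at 1.10 L/h.
Uniform sampling distributions are an assumption; the admissible region and
window bounds are the constraints that matter.

Cohorts are produced by a three-stage funnel. Candidate subjects are drawn
by Latin hypercube within ±70% of the nominal parameters (one stratum per
draw per parameter). Stage 1 keeps subjects whose resting vitals are
strictly inside the healthy screen (60–100 beats/min, 100–140 mmHg). Stage
2 keeps those that can simulate all five vertices of the hemorrhage
pentagon — the extreme scenarios — without numeric failure, range violation,
or oscillation. Stage 3 assigns each survivor one random scenario and keeps
those still *outside* the target range (HR > 100 or SBP < 100) at $t_2$,
since casualties already in range would receive no fluid under any policy.
The retained pool is randomly thinned to exactly `n_f` (divisible by five),
folds are assigned by random permutation, and the four ground-truth
trajectories per casualty are generated. The default candidate pool of
5,000 per round reflects this surrogate's acceptance rate (roughly 4% end
to end); rounds repeat automatically if a round falls short.

## The forecaster

The forecaster is a gated recurrent unit (GRU) sandwiched between two
feedforward tanh layers, ending in a linear pair of outputs: at each
minute it consumes $(u_f(t), HR(t), SBP(t))$ and emits the next minute's
predicted vitals. Inputs and outputs share fixed normalization factors —
150 beats/min, 110 mmHg, 1.10 L/h. The sandwich order (input → feedforward
→ GRU → feedforward → linear) is a symmetric choice among the orderings
consistent with a two-feedforward-one-recurrent description.

Prediction proceeds in two phases. A *warm-up* consumes the 10 observed
minutes before $t_2$ (zero infusion) teacher-forced, building the hidden
state that encodes the casualty's individual physiology. The *rollout*
then runs closed loop for 60 minutes: each step feeds back the model's own
previous prediction together with the scheduled infusion rate. Training
minimizes the mean normalized squared error over the rollout,

$$\varepsilon = \frac{1}{60}\sum_{t=1}^{60}
\left[\Big(\frac{\widehat{HR}(t)-HR(t)}{150}\Big)^2 +
\Big(\frac{\widehat{SBP}(t)-SBP(t)}{110}\Big)^2\right],$$

by backpropagation through the entire closed-loop rollout (the gradient
flows through the feedback path), implemented analytically in the package
and verified against finite differences. The squared-error form without an
enclosing root is used; any monotone transform selects the same optimum.
The first fifth to quarter of the epoch budget runs teacher-forced as a
stabilizer before switching to free-running training. Optimization is Adam
(learning rate $10^{-3}$ full scale, $2\times10^{-3}$ fast scale), with
early stopping on free-running validation error and retention of the best
validation epoch's weights. RMSEs $\delta_h$, $\delta_s$ over the rollout
report the errors in physical units.

Model selection and assessment use a 5-fold nested cross-validation: for
each outer (test) fold the validation fold rotates over the remaining
four — 20 fits per hidden size. The hidden size with the lowest mean
validation $\varepsilon$ is selected, and each fold's test predictor is
the equal-weight forecast ensemble of its four inner fits (the inner fits
must collapse to one test model per fold; averaging forecasts is the
variance-reducing choice and keeps each member's closed loop intact). A
programmatic audit verifies no test casualty ever appears in its own
predictor's training or validation folds.

## Allocation policies

All policies face the same budget of whole-blood units and are scored on
ground truth: a casualty is *restored* if its simulated vitals at $t_3$
satisfy HR ≤ 100 and SBP ≥ 100 (inclusive).

* **Oracle** — reads the four ground-truth outcomes, takes the cheapest
  restoring option per casualty (1-unit tie broken toward the early unit),
  refuses fluid to 0-need and unrestorable casualties, and under scarcity
  serves 1-need casualties first, then 2-need casualties while two units
  remain. This is the upper bound on any policy.
* **Threshold rule** — 1 unit now to anyone outside the target range at
  $t_2$; 1 more at $t_2 + 30$ to anyone still outside, capped at two, first
  stage fully served before the second.
* **AI-predictive** — the oracle's decision procedure applied to the
  forecaster's predictions instead of the truth, in two steps: predicted
  cheapest restoring option at $t_2$ (second units of 2-need casualties are
  reserved), then a reassessment at $t_2 + 30$ that re-warms the hidden
  state on the 40 observed minutes (with the infusion actually given) and
  re-chooses the final block. Reassessment updates the hidden state, not
  the weights — per-casualty retraining has no place in triage. A reserved
  unit released at reassessment returns to the pool for later casualties.

Service order within each priority class is cohort (arrival) order — the
natural field analog and deterministic. Excess fluid is counted per
casualty against oracle need. The efficiency ratio
$R = (N_A/U_A)/(N_V/U_V)$ compares restored-per-unit between the AI and
rule policies; it is undefined when either method used no fluid, and
budget-0 cells are reported as 1.00 by table convention (at a zero budget
the two policies' realized schedules are identical, so the restored
*counts* agree exactly even though restored-per-unit is 0/0). Analysis-3
subgroup cells whose rule policy restored nobody are dropped from the mean
and counted, not imputed.

By construction the policies satisfy several exact properties, all
asserted in the test suite: oracle dominance at every budget, three-way
equivalence at budget 0, monotone oracle/rule restored counts in the
budget (the surrogate's fluid-never-harms comparison property), rule
saturation beyond two units per casualty, and exact collapse of the AI
policy onto the oracle when the forecaster is replaced by a ground-truth
stand-in.

## Residual-bleeding detection

The forecaster is trained entirely on controlled-bleeding data (tourniquet
stops everything). If bleeding persists at a fraction of the original rate
(10–50% here), the measured vitals drift away from the forecast: measured
HR above, measured SBP below. The detection features are exactly that
discrepancy at $t_3$ — (measured − predicted) HR and SBP under the realized
schedule, with the warm-up taken from the (still-bleeding) casualty's own
monitored window. A linear support vector machine with per-class weights
inversely proportional to class size (so the smaller controlled class is
not swamped) separates controlled from residual-bleeding trajectories in
this 2-D space; the regularization constant stays at the default 1. The
reported pool accuracy mirrors the study design; a seeded 5-fold
cross-validated accuracy is logged alongside as the honest generalization
figure. Both numbers, the class counts, and the boundary coefficients are
emitted by `cmd_detect()`.

## Problem sizes, seeds, and what the tests show

Two standard configurations are bundled. `full_config()` mirrors the
full-scale study: 160 casualties in five folds of 32, hidden-size grid
{128, 256, 512}, 500-epoch budget, budgets 0–42, subgroup sizes
{32, 16, 8, 4}, fractions 10–50%. `fast_config()` is the package's
CI-scale configuration used by the test suite and examples: 20 casualties,
a single 64-node grid point, 120 epochs at batch 8 (chosen once after
verifying the optimizer converges there — free-running validation RMSEs of
roughly 7 beats/min and 10 mmHg), subgroup sizes {4, 2}. Every stage
derives its randomness from the single configuration seed, and rerunning a
configuration reproduces its outputs to numerical tolerance.

Passing tests demonstrate internal correctness on the surrogate — exact
metric algebra, gradient correctness, leakage-free cross-validation,
policy properties, detector behaviour — under the stated synthetic
conditions. They do not demonstrate clinical performance: real casualties
carry measurement noise, fluid-type effects, multi-site and time-varying
bleeding, interventions beyond one tourniquet and one infusion line, and
physiology far richer than a three-state lumped model. Quantities that
depend on the richness of the ground-truth generator (absolute RMSEs,
restored-count curves, classifier accuracies) should be read as properties
of this surrogate, not of patients.

## Known limitations

* The surrogate's first-order dynamics cannot express baroreflex
  oscillations, so the oscillation screen never fires on current data.
* Respiratory variables, diastolic/mean pressure, and oxygenation are out
  of scope, as are fluid-type pharmacology and tourniquet failure.
* The AI policy inherits the forecaster's errors asymmetrically: a falsely
  pessimistic forecast withholds fluid entirely (a "cannot be restored"
  call), which is visible at generous budgets where the simple rule
  catches up.
* Analysis-3 ratio cells are undefined wherever the denominator policy
  restores nobody; small subgroups at small budgets are noisy and
  frequently dropped.
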