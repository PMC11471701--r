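---
title: "Predicting individual platelet dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting individual platelet dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Thrombocytopenia — an abnormally low platelet count — is a common,
frequently dose-limiting side effect of cytotoxic chemotherapy. The
clinical question this package addresses is: given a patient's first few
therapy cycles of platelet counts and their planned dosing schedule, how
low will their counts go in the coming cycles? `thrombonarx` combines two
complementary model families to answer it on an individual level: a
semi-mechanistic compartment model of thrombopoiesis, and small per-patient
NARX neural networks that can be transfer-learned from that mechanistic
model when real data are sparse.

## The semi-mechanistic model

The mechanistic backbone is the classical transit-compartment model of
chemotherapy-induced myelosuppression: a proliferating progenitor pool
$P$, three maturation compartments $T_1,T_2,T_3$ and the circulating
platelet pool $C$,

$$
\begin{aligned}
dP/dt &= k\,P\,(1 - E(t))\,(C_0/C)^\gamma - k\,P,\\
dT_j/dt &= k\,(T_{j-1} - T_j), \qquad j = 1..3,\; T_0 = P,\\
dC/dt &= k\,T_3 - k\,C,
\end{aligned}
$$

with $k = 4/\mathrm{MTT}$. Four individual parameters carry the
physiology: the mean transit time $\mathrm{MTT}$ (days) sets the delay
between an insult to proliferation and the circulating nadir; the feedback
exponent $\gamma$ governs how strongly a low count boosts proliferation
(and hence the speed of recovery and rebound); $C_0$ is the individual
untreated steady state; and $E_{\mathrm{eff}}$ scales the toxic effect of
a unit of normalized dose. Chemotherapy enters as a step function $E(t)$:
each administration contributes $E_{\mathrm{eff}} \times$ dose for one day
and vanishes afterwards; simultaneous administrations add.

Two modelling choices deserve comment.

* **Effects above one are allowed by default.** Because the drug effect
  multiplies $P$, the state stays strictly positive for any $E$; an
  effect above 1 simply means net cell kill during the dosing day. With a
  one-day step, capping $E$ at 1 would bound the achievable nadir at
  roughly half the baseline, which cannot reproduce the grade 3–4
  toxicity that intensive regimens produce. `simulate_friberg()`
  therefore defaults to `clip_effect = FALSE` and offers the cap as an
  option.
* **Integration.** Individual fitting needs on the order of $10^4$
  trajectory evaluations per patient, so the production integrator is a
  compiled fixed-step fourth-order Runge–Kutta scheme (default step 0.02
  days, 0.05 during fitting) whose steps are aligned to the dose-step
  breakpoints, making the right-hand side smooth inside every step. The
  test suite verifies it against an independent fine-step reference
  integrator (step $10^{-3}$, relative error below $10^{-4}$) and against
  an adaptive multistep solver from `deSolve`, and checks that the
  untreated steady state is conserved to $10^{-6}$ relative.

### Individual fitting

Counts are approximately log-normal, so fitting minimizes squared
residuals on log counts plus a log-normal population prior,

$$
\sum_i \big(\log y_i - \log C(t_i;\theta)\big)^2 +
w \sum_j \Big(\frac{\log\theta_j - \mu_j}{\sigma_j}\Big)^2,
$$

optimized by bounded quasi-Newton (`L-BFGS-B`) on $\log\theta$ with eight
multi-starts drawn from the prior (box bounds at $\pm 5\sigma$). The
default prior has medians $\mathrm{MTT} = 5$ d, $\gamma = 0.2$,
$C_0 = 300$, $E_{\mathrm{eff}} = 1.2$, log-SD 0.3 each, and unit penalty
weight. The $E_{\mathrm{eff}}$ location was chosen from the grade
distribution it implies: a median patient on a full-dose 21-day schedule
reaches a nadir around $140\times10^9$/l (grade 1), the upper tail and
intensified 14-day regimens reach grades 2–4, and the zero-toxicity limit
is untouched baseline — a spread matching what CHOP/CHOEP-like cohorts
show. Values much below 1 make clinically relevant thrombocytopenia
essentially unreachable in this model and were rejected for that reason.

## NARX networks

The data-driven alternative is a nonlinear autoregressive model with
exogenous input: predict tomorrow's (scaled) count from recent counts and
today's therapy. Two cores are provided:

* **ARX-FNN** — one hidden tanh layer (default 8 units) fed by a tapped
  delay line of the last 7 predicted (or observed) counts plus the dose.
* **ARX-GRU** — a single gated-recurrent-unit layer (default 8 units)
  with one count lag; its hidden state carries the longer memory that the
  FNN keeps in its delay line, and can retain or discard it adaptively.

Both end in a linear output map followed by trainable exponential
smoothing $\hat y'_0=\hat y_0$, $\hat y'_i=\alpha\hat y_i +
(1-\alpha)\hat y'_{i-1}$: the smoothed value is the reported prediction,
while the raw output feeds the autoregressive loop. The smoothing factor
is stored as a logit so gradient updates can never push it outside
$[0,1]$; a penalty $\alpha^2$ in the objective favours heavy smoothing,
which counteracts the tendency of closed-loop models to invent noisy
dynamics between distant measurements.

Counts enter the network log-transformed and affinely scaled so that
$25\times10^9$/l (the grade-4 threshold) and $300\times10^9$/l (a typical
baseline) map to $[-0.5, 0.5]$ for the GRU and $[-1, 1.5]$ for the FNN.
Doses are divided by the cohort maximum dose. The dose consumed by the
step that predicts day $t$ is the dose administered on day $t-1$, i.e.
during the interval being crossed.

Prediction starts from the assumption that an untreated patient sits at
their baseline steady state: the delay line is filled with the scaled
baseline and, for the GRU, a 7-day steady-state warm-up lets the hidden
state settle before day 0. Day 0 of every prediction track is pinned to
the baseline, so a track over `0:horizon` has `horizon + 1` entries and
the smoothing identity `smoothed[1] == raw[1]` holds by construction.

## Training

The training objective is the modified mean-squared error (below) on log
counts plus weight decay on the weight matrices and the smoothness
penalty. Optimization is Adam with global gradient-norm clipping at 5;
gradients flow through the entire closed-loop rollout, the feedback
connections and the smoothing recursion (backpropagation through time,
verified against finite differences to $10^{-5}$ relative). After every
epoch the closed-loop loss is evaluated without augmentation noise and
the best parameters seen are kept — with a handful of observations per
patient this checkpoint-on-best rule is what makes small-budget training
stable, and it guarantees a stage can never end worse than it began.

Two learning modes mirror the two ways a patient model can be built:

* **With transfer learning** (`mode = "tl"`): the mechanistic model is
  fitted to the calibration cycles, then simulated under the actual
  schedule plus systematic variants (dose scalings 0/0.5/0.75/1.25/1.5,
  ±3-day shifts of later cycle starts, single-cycle omissions). The
  network is pre-trained on these dense trajectories — first half of the
  epochs teacher-forced to learn the local dynamics, second half
  closed-loop to anchor long rollouts; no noise augmentation, since no
  real data are involved. Next, only the linear output weights are
  recalibrated on the real counts (everything else is frozen
  bit-identically), and finally the whole network is fine-tuned at a
  tenfold lower learning rate. Default epoch budgets are 500/200/200.
* **Without transfer learning** (`mode = "no_tl"`): a single stage on the
  real counts with hidden-unit dropout (rate 0.2, applied to the hidden
  vector as seen by the output layer; dropout is used only in this mode).

Stages that see real patient data add Gaussian noise (SD 0.05 in scaled
units) to the network inputs each epoch, and teacher-force the feedback at
measured days. After the final stage of either mode, the 10% (default)
smallest-magnitude weights are pruned. Training runs record per-epoch
loss and $\alpha$ in the model's `history` attribute.

## Evaluation

Because exact measurement times are unreliable, the error measure
compares each observation with the prediction at its rounded day *and*
with both neighbouring days at weight 0.3, on log counts, unscaled:

$$
\mathrm{SMSE} = \frac{1}{N}\Big[\sum_i (y_i-\hat y_i)^2 +
0.3\,s\sum_i\big((y_i-\hat y_{i-1})^2 + (y_i-\hat y_{i+1})^2\big)\Big].
$$

The constant $s$ is fixed at 1 (its only plausible alternative reading is
a per-observation indicator of timing uncertainty; with daily-resolution
data that indicator is identically 1). Adjacent terms falling outside the
horizon are dropped without reweighting.

Clinically, what matters is the toxicity grade at the nadir. Counts map
to NCI grades 0–4 with breakpoints 150/75/50/25 ($C \le$ threshold
belongs to the higher grade). For a model calibrated on $c$ cycles and a
target cycle $t$, `dd()` averages $|d_{p,t} - \hat d_{p,c,t}|$ over the
patients with observations in cycle $t$, grading the observed nadir count
and the *prediction at the observed nadir day* — not the predicted
minimum, so that observation and prediction refer to the same time point.
Cycle windows run from each cycle start to the next (the last window
extends one cycle length); within-window nadir ties break to the earliest
day.

Cohort handling follows the structure of CHOP-like lymphoma studies:
patients are eligible if at least four cycles contain counts, the first
cycle contains more than one, and they received no platelet transfusion;
eligible patients split into dense (De: every covered cycle has ≥ 5
counts) versus sparse (Sp) coverage, crossed with 14- versus 21-day
cycles.

## The synthetic cohort generator

No real study data ship with the package, so `sample_cohort()` emulates
the relevant structure: individual parameters drawn from the population
prior (so baselines concentrate near $300\times10^9$/l), 6 cycles of 14-
or 21-day regimens with full-dose day-0 administrations (intensified
variants add half doses on days 1–2, emulating etoposide), ground-truth
trajectories from the mechanistic model, and log-normal measurement noise
(default SD 0.15, a realistic analytical-plus-biological variability for
platelet counts). The dense design guarantees ≥ 5 counts per cycle
including decline, nadir and recovery days; the sparse design samples
cycle start plus 1–3 random days and deliberately does *not* chase the
nadir — under-sampling of nadirs in sparsely monitored patients is a
feature of real cohorts that evaluation must confront. An optional
per-cycle growth factor on the toxicity scale emulates cumulative
toxicity.

What the generator does not emulate: pharmacokinetics (doses are abstract
normalized units), transfusion events, informative measurement timing
(real physicians measure sicker patients more often, which biases the
De/Sp comparison), model misspecification (synthetic truth comes from the
same model family the fits use), and covariate structure (age, sex).
Passing tests on synthetic cohorts therefore demonstrate that the
machinery works and that transfer learning helps when the mechanistic
prior is informative — not that the specific accuracy numbers transfer to
real patients.

## Verification scales and numerical defaults

The test suite runs every component at sizes chosen to make the
statistical checks meaningful while staying desk-scale: parameter
recovery uses 20 dense noise-free patients (median relative error per
parameter below 5%); the transfer-learning comparison uses sparse cohorts
of 20 patients with 3 measurements per cycle, two calibration cycles,
ARX-GRU, repeated at three seeds with epoch budgets 300/100/100 (300
without TL), requiring the TL median test error to win at a majority of
seeds and the three-cycle median not to exceed the one-cycle median.
Numerical defaults collected in one place: RK4 step 0.02 d (0.05 during
fitting), optimizer bounds $\pm5\sigma$, 8 multi-starts, Adam learning
rates $10^{-2}$/$10^{-2}$/$10^{-3}$ (pretrain/recalibrate/fine-tune),
gradient clip 5, weight decay $10^{-4}$, smoothness penalty weight 0.05,
input noise SD 0.05, dropout 0.2, pruning fraction 0.1.

## Known limitations

Per-patient networks never share information across patients; a
population-level network or mixed-effects mechanistic estimation is out
of scope. The GRU's memory makes it sensitive to therapy history beyond
any fixed window, which is desirable, but also means closed-loop errors
can compound over 100+ day rollouts — the strong regularization (small
nets, smoothing, pruning, noise) trades spike accuracy for nadir
robustness, and genuinely unusual late-onset toxicity patterns cannot be
predicted from early cycles. Only platelets are modelled; other lineages
and growth-factor support would require additional exogenous channels.
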