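---
title: "Modeling nocturnal glucose-heart-rate coupling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nocturnal glucose-heart-rate coupling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucohr)
```

## The model

`glucohr` implements a minimal two-state dynamical model of nocturnal
physiology. Plasma glucose $G$ (mg/dl) and heart rate $H$ (BPM) evolve as

$$
\frac{dG}{dt} = R_g
  + \alpha_G G\,\frac{H - H_{sleep}}{H_{sleep}}
  - k_g \frac{G}{G + K_g}
  - E_g G
  + G_A \exp\!\left(-\frac{(t - t_c)^2}{2 G_w^2}\right)\chi_{t \ge t_c},
$$

$$
\frac{dH}{dt} = -\beta_H (H - H_{sleep})
  + H_v \frac{G - G_{sleep}}{G_{sleep}}.
$$

The glucose equation combines basal hepatic production ($R_g$), an
amplification of production when heart rate runs above its resting value
($\alpha_G$, a proxy for sympathetic drive on hepatic output), saturable
Michaelis-Menten tissue uptake ($k_g$, $K_g$), linear clearance ($E_g$),
and a Gaussian input switched on at $t_c$ that models the dawn-phenomenon
glucose rise. The heart-rate equation relaxes toward the resting rate
$H_{sleep}$ at rate $\beta_H$ (parasympathetic tone) and is driven upward
when glucose exceeds its nocturnal baseline $G_{sleep}$, with coupling
strength $H_v$. Units: rates in 1/min, $R_g$ and $G_A$ in mg/dl/min, $H_v$
in BPM/min, times in minutes.

There is no insulin compartment, no meal or activity input, and no
stochastic term; the model targets the quiet nocturnal window where those
influences are minimal.

### Parameters, defaults, and what is estimated

Nine parameters are estimated within fixed physiological boxes
(`parameter_bounds()`): $R_g \in [0.001, 10]$, $\alpha_G \in [0.001, 0.1]$,
$k_g \in [0.001, 10]$, $K_g \in [1, 10]$, $E_g \in [0.001, 5]$,
$\beta_H \in [0.001, 1]$, $H_v \in [0.001, 30]$, $G_A \in [0.01, 20]$,
$G_w \in [10, 300]$. Three quantities are inputs, not estimates:

* $t_c$, the spike center. The bounded set does not include it; the
  default of 480 min places the dawn rise late in a 600-min window.
* $G_{sleep}$ and $H_{sleep}$. For synthetic experiments they are known;
  for wearable data `fit_parameters()` defaults them to the 5th percentile
  of each observed signal, a robust nocturnal floor, and both are
  configurable.
* $E_g$ is held at 0.001/min by default (`fix_Eg = TRUE`): its estimate
  pins to that value even when the bounds are widened, so freeing it only
  adds a flat direction to the search. Pass `fix_Eg = FALSE` to estimate
  all nine.

## Numerical integration

Trajectories are solved with the adaptive Dormand-Prince 4/5 pair
(deSolve's `ode45`, compiled right-hand side) at relative tolerance
$10^{-6}$, absolute tolerance $10^{-8}$, and a 1-minute cap on the step
size; the cap guarantees the Gaussian transient is resolved for every
feasible width ($G_w \ge 10$ min). The indicator $\chi_{t \ge t_c}$ makes
the right-hand side discontinuous at $t_c$, so integration is split into
the pre- and post-spike segments and concatenated; the discontinuity then
always falls on a segment boundary and never degrades the error control.

The true solution is provably non-negative, so undershoots within the
absolute tolerance are clipped to zero, while larger negativity — or any
non-finite state — raises a classed `glucohr_solver_failure` condition.
The fitting layer converts that condition into a large penalty
($10^{10}$) rather than an error.

One caveat the test suite makes explicit: the boundedness guarantee does
not extend to the whole feasible box. In the strong-coupling corner
(large $\alpha_G H_v$ with tiny $\beta_H$) the quadratic cross-term
dominates and trajectories blow up in finite time; roughly a tenth of
uniform draws from the box do so within a 600-min window (more when $E_g$
is pinned at its floor). This is a property of the model, not the solver;
such draws fail cleanly and are penalized during optimization.

## Equilibria and stability

With the spike off ($G_A = 0$) the steady states satisfy a cubic
$A G^3 + B G^2 + C G + D = 0$ with

$$
A = \gamma = \frac{\alpha_G H_v}{\beta_H H_{sleep} G_{sleep}}, \quad
B = A K_g - A G_{sleep} - E_g,
$$
$$
C = R_g - A K_g G_{sleep} - E_g K_g - k_g, \quad
D = R_g K_g,
$$

obtained by substituting the heart-rate nullcline into the glucose
equation and clearing $(G + K_g)$. (Deriving the coefficients this way is
worth the two lines: the sign of the $A K_g G_{sleep}$ term in $C$ is easy
to get wrong, and the implementation is verified by requiring every root
to zero the raw right-hand side to $10^{-8}$.) Roots come from the
numeric polynomial solver (companion matrix via `polyroot`), not the
closed-form radicals, which are numerically fragile when $A$ is tiny — as
it typically is, $\gamma \sim 10^{-6}$ at realistic parameters. A Newton
polish on the uncleaned residual tightens each root afterward. Degenerate
cases ($\alpha_G = 0$ or $H_v = 0$ give $A = 0$) fall through to the
quadratic/linear solution. Roots are declared real when
$|\mathrm{Im}| < 10^{-8}\max(1, |\mathrm{Re}|)$, and only $G^* > 0$ is
reported as physiological.

Stability is classified from the eigenvalues of the Jacobian

$$
J = \begin{pmatrix}
\alpha_G \frac{H^* - H_{sleep}}{H_{sleep}} - \frac{k_g K_g}{(G^* + K_g)^2} - E_g &
\frac{\alpha_G G^*}{H_{sleep}} \\
\frac{H_v}{G_{sleep}} & -\beta_H
\end{pmatrix},
$$

equivalently (2-by-2 Routh-Hurwitz) trace $< 0$ and determinant $> 0$.
The sufficient-condition threshold
$G^* < \min\{G_{sleep} + (E_g + \beta_H)/\gamma,\;
G_{sleep}/2 + E_g/(2\gamma)\}$ is reported as a diagnostic only — it is
conservative, and when $\gamma = 0$ it is `Inf` with a degeneracy flag.
Because a stable equilibrium attracts the post-spike flow, the dawn input
produces a transient excursion that decays back to baseline; a property
test verifies this relaxation explicitly.

## Synthetic data generation

`generate_synthetic_patient()` integrates the model on the 121-point grid
$\{0, 5, \dots, 600\}$ min and adds independent Poisson($\lambda = 1$)
draws to each glucose sample. Two deliberate choices:

* **Noise goes on glucose only by default.** CGM readings carry
  quantization-like sensor noise; the heart-rate channel, averaged to the
  same grid, is much smoother. The numbers force this reading: sd-1 noise
  on a ~90 BPM signal over 121 points imposes a relative-$l_2$ floor of
  about 1.1%, while well-identified heart-rate fits reach ~0.6% — which is
  only possible if the heart-rate data are noiseless.
  `noise_targets = c("glucose", "heart_rate")` perturbs both.
* **Raw (uncentered) draws by default.** Poisson(1) noise shifts the mean
  by +1; `centered = TRUE` subtracts the mean instead. The uncentered
  variant is the literal protocol; the +1 offset on a ~120 mg/dl signal is
  below 1% and absorbed by the fit.

The generator reproduces the sampling cadence, window length and noise
marginal of real nocturnal wearable data, but not dropout, sensor drift,
irregular timestamps (the preprocessing fixtures cover those), nor any
physiology outside the model class — so passing recovery tests show
self-consistency of the pipeline, not correctness of the model on real
patients.

`generate_cohort()` rejection-samples parameter vectors uniformly in the
feasible box until each risk category is populated, for end-to-end tests
that span the stratification.

## Preprocessing raw wearable exports

`preprocess_subject()` reproduces the study pipeline for timestamped CSV
exports (`timestamp,value`): clean and sort; keep records between 21:00
and 09:00 (both boundaries inclusive — the text does not specify and
inclusivity loses no data); interpolate each night linearly onto a fixed
5-min grid anchored at 23:30; average pointwise across nights; and smooth
with a Savitzky-Golay filter (window 31 points, cubic). Notes:

* The grid runs 23:30-08:36 with the end exclusive: 08:36 is not a
  multiple of 5 min from 23:30, so the last grid point is 08:35 and the
  grid has exactly 110 offsets $\{0, 5, \dots, 545\}$.
* The 21:00-23:30 records are retained as interpolation support to the
  left of the grid; grid points outside a night's observed span get
  nearest-edge fill and a per-point flag.
* Nights are keyed by the calendar date of the 21:00 anchor; timestamps
  are treated as naive local clock times, which sidesteps daylight-saving
  ambiguity.
* Savitzky-Golay edges use polynomial fits within truncated windows
  (trimming would change the length); the filter is exact on cubics,
  which the tests assert to $10^{-8}$.
* Smoothing is applied after averaging and reparameterization, following
  the order of the protocol; numerically the order is immaterial.

## Parameter estimation

The loss is the unweighted sum of the two per-signal mean squared errors
over the observation grid, with initial conditions taken from the first
observed values. An optional weight pair is available, but the default is
the literal unweighted form (glucose, with its larger scale, then
dominates — which matches how the reported fits behave). Minimization
uses particle swarm optimization with the classical global-best updates

$$
v_i \leftarrow w v_i + c_1 r_1 (p_i^{best} - x_i) + c_2 r_2 (g^{best} - x_i),
\qquad x_i \leftarrow x_i + v_i,
$$

60 particles and 300 iterations. Free choices fixed as follows:

* $w = 0.729$, $c_1 = c_2 = 1.49445$ (standard constriction values).
* Positions initialize uniformly in the box; velocities at zero.
* Velocities are clamped to 20% of each bound range per iteration;
  positions leaving the box are clamped with the offending velocity
  component zeroed.
* If every particle of the initial swarm lands in the penalized
  (non-integrable) region, the swarm is redrawn — with zero initial
  velocities an all-penalty swarm would otherwise contract onto a
  penalized point and never recover. This matters in practice because the
  explosive corner of the box is large when $E_g$ is pinned.
* Execution is serial; a fixed seed makes the entire fit reproducible.
* An optional derivative-free Nelder-Mead polish of the swarm optimum is
  deliberately **not** run by default; on these landscapes the swarm
  optimum is already at the data's noise floor.

Parameter recovery is *not* the goal and is not asserted anywhere: the
model is strongly non-identifiable from a single night (very different
parameter vectors produce near-identical trajectories). What the tests
assert is trajectory recovery — on noiseless synthetic data with bounds
shrunk to ±10% of the truth the fitted trajectories match within 1%
relative $l_2$, and on noisy data at full bounds the fit errors sit at the
few-percent level.

## Sensitivity analysis and the risk score

`sensitivity_analysis()` draws a Latin hypercube (exactly one sample per
equal-probability stratum per dimension) over ±20% of a center vector,
truncated to the feasible box, simulates each sample noiselessly, and
computes partial rank correlation coefficients of each parameter against
two outputs: the maximum nocturnal glucose and the final-time glucose.
The ±20% spread is a configurable default; zero spread is rejected
because it would create constant columns. PRCC is computed by the
residual method on ranks and verified in the tests against explicit
normal-equations partial correlations to $10^{-10}$; p-values use
$t = r\sqrt{(n - 2 - p)/(1 - r^2)}$ with $n - 2 - p$ degrees of freedom.

Because the model is deterministic, a parameter's PRCC reflects its
monotone influence relative to the "noise" contributed by the other
varying parameters. A consequence worth stating: which parameters test
significant depends on the center. Around a center with near-zero
coupling ($\alpha_G$ at its lower bound), $\alpha_G$ and $\beta_H$ cannot
move the glucose outputs against $R_g$ and $k_g$ variation and test
insensitive; around the wearable-derived fits, the union over the four
reference centers flags exactly $\{R_g, \alpha_G, k_g, \beta_H\}$ at
$p < 0.05$, and the acceptance checks encode that four-center protocol.

Those four parameters combine into the risk score

$$
S = 10 R_g + 100 k_g + 10000 \alpha_g + 100 (1 - \beta_H),
$$

with weights compensating the parameters' range scales and PRCC
magnitudes, stratified as low ($S \le 500$), moderate
($500 < S \le 1000$), high ($S > 1000$). The boundaries are half-open
exactly as stated; `categorize_risk(500)` is low and
`categorize_risk(1000)` is moderate. The score ignores $E_g$ and all
fixed quantities.

```{r}
sc <- study_cases()
vapply(sc, function(cs) risk_score(cs$fitted)$score, numeric(1))
```

## Problem sizes used by the checks

The bundled checks run at the protocol's native sizes: 121-point series,
60-particle/300-iteration swarms (three replicate seeds per synthetic
case), LHS-PRCC at $n = 500$ per center, and property suites over a few
dozen randomized draws. The RK4 cross-check oracle uses a fixed 0.01-min
step over the full 600-min window.

## Known limitations

* Two states only: no insulin, meals, activity, or circadian modulation
  beyond the single Gaussian input; stochastic (Fokker-Planck/Liouville)
  extensions are out of scope.
* The boundedness lemma fails in the strong-coupling corner of the
  feasible box (see above); the fitting penalty handles it, but cohort
  sampling at extreme bounds will reject some draws.
* Identifiability: fitted parameter values should be interpreted through
  the risk score and trajectories, not individually.
* The preprocessing pipeline assumes generic `timestamp,value` CSVs;
  vendor-specific export dialects must be converted upstream.
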