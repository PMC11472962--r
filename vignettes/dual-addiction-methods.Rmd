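---
title: "Methods: dual-addiction dynamics, optimal control and cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-addiction dynamics, optimal control and cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coaddiction)
```

## The model and its assumptions

`coaddiction` models the joint spread of smoking and alcohol addiction as a
deterministic compartmental system with eleven classes: at-risk $S$,
education-protected $P$, a smoking chain $E_S \to I_S \to P_S$, an alcohol
chain $E_A \to I_A \to P_A$, dual addiction $C_{SA} \to P_{SA}$, and
rehabilitated $T$. Uptake is socially transmitted with standard incidence:

$$\lambda_A = \frac{\beta_1}{N}\bigl(I_A + P_A + \theta_1(C_{SA}+P_{SA})\bigr),
\qquad
\lambda_S = \frac{\beta_2}{N}\bigl(I_S + P_S + \theta_2(C_{SA}+P_{SA})\bigr),$$

with $\theta_1,\theta_2 \ge 1$ weighting the dual-addicted classes. The
structural assumptions: homogeneous mixing; recruitment $K$ split
$(1-\pi)/\pi$ between $S$ and $P$; a uniform natural death rate $\mu$ plus
class-specific addiction mortality; permanently addicted classes that no
treatment reaches; dual addiction entered only from single addiction (an
addicted person acquires the other addiction at a modified rate); and
rehabilitated individuals who do not relapse. Summing the system gives the
demographic identity
$dN/dt = K - \mu N - d_S I_S - d_{PS} P_S - d_A I_A - d_{PA} P_A - d_C C_{SA} - d_{SA} P_{SA}$,
which the test suite checks along every simulated trajectory; positivity and
$N \le \max(N(0), K/\mu)$ are the well-posedness invariants.

Single-addiction sub-models (six compartments each) are obtained by zeroing
the other chain; the full-model right-hand side restricted that way
reproduces them exactly, which is tested.

### Parameters

All rates are per year; `addiction_params()` carries the baseline
calibration (e.g. $\beta_1 = 0.75$, $\beta_2 = 0.38$, $\mu = 0.0135$,
$K = 20$, $\pi = 0.5$, $\delta = 0.21$). Two wrinkles in that calibration are
handled explicitly:

* the progression rate $\alpha_1$ is listed twice in the source material
  (0.0002 and 0.0003); the constructor defaults to the first value and the
  alternative is an ordinary override;
* the protected-class modifiers are *described* as reductions
  ($\delta_1, \rho_1 < 1$) but *assigned* 1.1 and 1.2. Validation therefore
  treats $\delta_1,\rho_1 \ge 1$ as a soft warning, not an error, and only
  nonnegativity is enforced for $\delta_2,\delta_3,\rho_2,\rho_3$, whose
  published constraint strings are not self-consistent inequalities.

### The default scenario

The published analyses never state their initial data or horizon, so the
package fixes its own defaults and treats them as part of the study
conditions: initial state
$(S,P,E_S,I_S,P_S,E_A,I_A,P_A,C_{SA},P_{SA},T)(0) = (800,300,60,40,20,60,40,20,20,10,30)$
(a community of 1400 with modest addicted prevalence) and a five-year
horizon. Consequently the simulation-derived control and cost-effectiveness
numbers are internally consistent but are **not** expected to reproduce any
externally tabulated averted/cost totals; those totals are instead bundled
as reference inputs (`reference_outcomes()`) for the ICER worked examples.

## Reproduction numbers

The next-generation construction at the addiction-free equilibrium
$S_0 = (1-\pi)K/(\delta+\mu)$, $P_0 = K(\delta+\pi\mu)/(\mu(\delta+\mu))$
gives

$$R_{0A} = \frac{\beta_1\alpha_1(\alpha_2+\mu+d_{PA})
  \left[\mu(1-\pi)+\rho_1(\delta+\pi\mu)\right]}
  {(\mu+\alpha_1)(\alpha_2+\varepsilon_1+\mu+d_A)(\mu+d_{PA})(\delta+\mu)}$$

and the symmetric $R_{0S}$; the dual model's threshold is
$\max(R_{0A}, R_{0S})$. The published account of this model prints two
mutually inconsistent closed forms for $R_{0A}$, and neither follows from its
own $F$ and $V$ matrices; the form above is re-derived directly from the
next-generation matrices and is certified in the test suite against an
independent numeric oracle (`ngm_r0()`, which builds $F$ and $V$ by
linearizing the implemented right-hand side and returns the spectral radius
of $FV^{-1}$) to $10^{-8}$ relative accuracy over a hundred random parameter
sets. On the baseline calibration $R_{0A} \approx 0.095$ and
$R_{0S} \approx 0.637$; the headline values $1.74$ and $1.53$ quoted
alongside the source calibration are not recoverable from it under any of
the printed closed forms, and the package makes no attempt to match them.

## Equilibria, stability, bifurcation

Endemic equilibria of a sub-model are zeros of the scalar fixed-point map
$g(\lambda) = \lambda - \beta\,(\text{weighted addicted})(\lambda)/N^*(\lambda)$,
where every equilibrium compartment is a closed-form cascade in the
equilibrium force $\lambda$. Rather than trusting the published (typo-laden)
quadratic coefficients, roots are located by a dense sign scan on
$(0, \beta]$ — the force can never exceed $\beta$ because the weighted
prevalence fraction is below one — refined by bisection to $10^{-13}$;
the quadratic coefficients of the cleared-denominator polynomial are then
recovered numerically (three-point interpolation) for the sign-based case
classification: $c_2 > 0$ always, $\operatorname{sign}(c_0) =
\operatorname{sign}(1 - R_0)$, at most two positive roots.

Local stability is assessed from central-difference Jacobians (relative step
$10^{-6}$) and, for the cubic factors arising at the addiction-free
equilibrium, by the Routh–Hurwitz criterion ($a>0$, $c>0$, $ab>c$), which is
itself tested against explicit root computation.

### Backward bifurcation

Two independent detectors are implemented and cross-validated:

1. **Root count**: two positive endemic roots with $R_0 < 1$.
2. **Centre-manifold coefficients**: at the critical dissemination rate
   $\beta^*$ (obtained exactly, since $R_0$ is linear in $\beta$), the
   Jacobian at the addiction-free state has a simple zero eigenvalue; with
   right/left null vectors $u, v$ normalized to $v \cdot u = 1$,
   $$a = \sum_{k,i,j} v_k u_i u_j
     \frac{\partial^2 h_k}{\partial z_i \partial z_j}, \qquad
     b = \sum_{k,i} v_k u_i
     \frac{\partial^2 h_k}{\partial z_i \partial \beta},$$
   evaluated by second-order central differences of the right-hand side
   (relative step $10^{-4}$ for the $u$-direction, $10^{-6}$ for $\beta$).
   Backward bifurcation iff $a > 0$ and $b > 0$.

Because $a$ is quadratic in $u$ and linear in $v$, its sign depends on the
orientation convention: under $v\cdot u = 1$, flipping $u$ flips $a$. The
package fixes the *exposed* component of the critical pathway positive — the
convention under which the bifurcating branch points into the positive cone
and the standard sign test applies. (Fixing the susceptible component
positive instead would reverse the orientation, since the susceptible
component of $u$ is negative at a transcritical epidemic threshold.)

Where does backward bifurcation live in this model? A short calculation on
the null vector shows the condition is a competition between the decline of
the effective susceptible pool and the decline of the total population along
the bifurcating direction. If $\rho_1 \ge 1$ (protection does not reduce
susceptibility) a Cauchy–Schwarz bound forces $a < 0$: the bifurcation is
always forward — notably, on the baseline calibration itself
($\rho_1 = 1.2$). Backward bifurcation requires genuinely protective
education ($\rho_1 < 1$) combined with strong addiction mortality
($d_A \gg \mu$), fast progression ($\alpha_1 \gg \mu$), high protection
uptake ($\delta \gg \mu$) and a small protected recruitment fraction. The
fixture generator's `backward-candidate` regime samples exactly that region
and rescales $\beta_1$ to put $R_{0A}$ just below one; on its fixtures the
two detectors agree (two roots, $a>0$, $b>0$, lower branch unstable, upper
branch stable, addiction-free state stable), and on `forward`-regime
fixtures ($\rho_1 \ge 1$) the coefficient comes out negative with no
sub-threshold roots.

## Sensitivity indices

`sensitivity_index()` returns elasticities
$(\partial R_0/\partial p)(p/R_0)$ of the *implemented* closed form —
analytic where the form factorizes (dissemination rates, progression,
improvement and death rates, $\pi$, $\rho_1$, $\delta$), finite-difference
for $\mu$ — and the suite requires analytic and central-difference routes to
agree to $10^{-6}$. The index of $\beta_1$ is exactly $+1$ (linearity), the
recruitment $K$ cancels entirely (index 0), and parameters outside the
chosen pathway report 0.

The externally tabulated index values for this model could not be adopted:
several contradict the very formulas printed beside them (e.g. for $d_{PA}$
the printed formula gives $-0.87$, the printed table $-0.38$, and the
NGM-certified closed form $-0.73$), and none are reproducible from the
published calibration under either $\alpha_1$ candidate. Internal
consistency (analytic $=$ finite difference on the certified form) is the
testable property, so that is what the package asserts. One consequence of
the calibration's $\rho_1 = 1.2 > 1$ is worth flagging: the elasticities of
$\pi$ and $\delta$ come out *positive* (protecting more people raises
$R_{0A}$, because protected individuals are modelled as more susceptible);
with any protective $\rho_1 < 1$ they revert to the conventional negative
signs.

## The optimal-control problem

Six controls $w_1..w_6 \in [0,1]$ (education against smoking, alcohol and
dual addiction; treatment of the three addicted classes) enter the
controlled system exactly as printed in its source, including two
idiosyncrasies that are implemented literally and flagged rather than
repaired:

* the protection flow is $w_3 \delta S$, so the no-control limit switches
  protection **off** (it does not recover the uncontrolled model); likewise
  $w_4, w_5, w_6$ multiply the improvement rates $\varepsilon_2,
  \varepsilon_1, \varepsilon_3$, so $w = 0$ also switches rehabilitation
  off. The tested reduction is therefore: $w=0$ equals the uncontrolled
  model with $\delta$ and all $\varepsilon_i$ zeroed.
* the inflow to $C_{SA}$ carries $(1-w_2)$ where the matching outflows from
  $I_S, P_S$ carry $(1-w_4)$, so mass balance between those flows breaks
  when $w_2 \neq w_4$.

The objective is
$J = \int_0^{T_F} \bigl(\sum_i D_i\,(\text{addicted class})_i +
\tfrac12\sum_i \psi_i w_i^2\bigr)\,dt$ with defaults $\psi_i = 10$,
$D_i = 7$. The **Hamiltonian is the single source of truth** for the
optimality system: the adjoint equations are computed analytically as
$-\nabla_x L - J(x,w)^\top f$ from the implemented right-hand-side Jacobian,
and each control update extracts the linear coefficient of $H$ in $w_i$ from
two Hamiltonian evaluations (the Hamiltonian has no cross-control terms), so
transcription typos cannot leak into the characterization. A direct
transcription of the published costate equations is kept internally for
reconciliation: its susceptible/protected/exposed/rehabilitated components
agree with $-\partial H/\partial x$ wherever the forces of addiction vanish,
but the published equations systematically treat the forces as exogenous —
omitting the standard-incidence feedback through $N$ (visible even in
$df_{11}/dt = \mu f_{11}$, which ignores that the rehabilitated class
dilutes both forces) — and several addicted-class components additionally
swap treatment rates between pathways or substitute $N^*$ for $S^*$. The
package follows the Hamiltonian; the finite-difference identity
$f' = -\partial H/\partial x$, $x' = \partial H/\partial f$ is enforced at
$10^{-6}$ relative over a hundred random points.

### Sweep numerics

Forward–backward sweep with classical RK4 on one fixed uniform grid
(default 1001 nodes over five years): forward state integration, backward
adjoint integration from the zero terminal condition with states and
controls linearly interpolated at half-steps, pointwise control update, and
convex relaxation $w \leftarrow \tfrac12(w_{\text{old}} + w_{\text{new}})$
(factor configurable). Convergence is declared when the maximum control
change, relative to the control scale with an absolute floor of one, drops
below $10^{-3}$; non-convergence within `max_iter` (default 100) is flagged
in the result, not raised. On the baseline scenario all nine strategies
converge in 10–13 iterations, the objective history is monotone, adding
instruments never worsens the optimum ($J_I \le J_A \le J_{w=0}$), and
prohibitive effort weights ($\psi = 10^9$) drive all controls numerically to
zero — these are the sweep's acceptance checks. The acceptance and test runs
use 401 grid nodes; results at 401 and 1001 nodes agree to well within the
convergence tolerance, and the smaller grid keeps the nine-strategy suite
comfortably fast.

## Cost-effectiveness

The outcome measures are the only quantities the optimality system prices:
*addictions averted* $= \int_0^{T_F} (A_{\text{base}} - A_{\text{ctrl}})\,dt$
with $A$ the unweighted sum of the six addicted classes against the
uncontrolled baseline on the same grid, and *cost*
$= \int_0^{T_F} \tfrac12 \sum_i \psi_i w_i^2\,dt$ (trapezoid rule). The ICER
table ranks strategies ascending by averted; the first row's ratio is
cost/averted (zero sentinel) and each later row is
$\Delta\text{cost}/\Delta\text{averted}$ against the previous surviving row.
Elimination removes the single largest-ICER strategy per round — negative
ICERs (cheaper *and* more effective) never get removed — and ties, which the
reference material never encounters, raise an error rather than being
silently broken.

Replaying the bundled reference cells reproduces every
arithmetic-consistent published ratio to four significant figures and all
three documented elimination narratives (four-control case → D, five-control
case → F, overall → A). Known inconsistencies in the reference material,
resolved as follows:

* the three-control case's two published ratios are inconsistent with their
  own averted/cost cells by roughly a factor of ten; recomputed from the
  cells, the ordering *reverses* the narrated elimination (the recomputed
  procedure removes A, not B), so that case is excluded from the reproduced
  narratives and reported as recomputed arithmetic only;
* strategy I's cost appears in two variants ($1.9857\times 10^7$ and
  $1.9857\times 10^6$); only the latter is consistent with the overall
  table's own ratios and is the bundled value;
* two further single cells (the five-control G ratio and the four-control C
  ratio at first ranking) disagree with their own cells' arithmetic; the
  recomputed values are asserted.

## What the synthetic fixtures do and do not show

`fixture_params()` draws parameter sets, not data: `generic` samples broad
log-uniform ranges of plausible annual rates (used for oracle-equivalence,
threshold-stability and positivity properties), `forward` restricts to
provably forward-bifurcating configurations, and `backward-candidate`
searches the backward-capable region described above. Passing the property
suite on these draws demonstrates internal mathematical correctness —
closed forms against matrix oracles, stability against eigenvalues,
Pontryagin consistency against finite differences — on the stated model. It
does not validate the model against observed smoking/drinking prevalence:
no demographic fitting is attempted, mixing is homogeneous, rates are
time-invariant, and the behavioural interpretation of parameters like
$\rho_1$ is taken as given.

## Numerical choices, in one place

* RK4 fixed step, 1001-node default grid; no clipping of small negative
  overshoot (invariants are tested with tolerance $10^{-8} N(0)$ instead, so
  integrator artefacts cannot mask sign errors in the right-hand side).
* Jacobians: central differences, relative step $10^{-6}$; centre-manifold
  second derivatives: relative step $10^{-4}$; zero-eigenvalue acceptance
  $10^{-6}$, simplicity required.
* Endemic root scan: $10^4$ nodes on $(0,\beta]$, bisection to $10^{-13}$;
  more than two roots raises an internal-consistency error.
* Sweep: relaxation $0.5$, tolerance $10^{-3}$, `max_iter` 100.
* Elasticities: analytic where available, central difference (relative step
  $10^{-6}$) otherwise; agreement enforced at $10^{-6}$.
* Test problem sizes: positivity 8 parameter draws × 6 initial states at 200
  steps (plus 10 draws at 400 steps in the acceptance block), threshold
  suite 200 draws, oracle equivalence 100 draws, Pontryagin consistency 100
  points, nine-strategy sweep at 401 nodes.

## Limitations

Deterministic, homogeneous, constant-rate model; no age structure,
stochasticity, relapse, or media/seasonal forcing. The centre-manifold
coefficients are numeric (finite differences), so extremely small $|a|$ near
degenerate configurations inherits finite-difference noise — the fixture
search deliberately certifies its candidates with the independent two-root
criterion. Simulation-derived cost-effectiveness depends on the package's
default initial state and horizon, which are package choices; the ICER
worked examples rest on the bundled reference totals.
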