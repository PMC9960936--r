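---
title: "Designing switching-observer soft sensors for the Monod chemostat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing switching-observer soft sensors for the Monod chemostat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchsense)
```

## The estimation problem

A chemostat holds a microbial culture at steady state by continuously
feeding fresh medium and withdrawing culture at the dilution rate $u(t)$
(1/day). Its two states are the substrate concentration $x_1$ (kg COD/m³),
which a probe measures online, and the biomass concentration $x_2$
(kg/m³), which in practice is known only from delayed laboratory assays.
With Monod uptake kinetics,

$$\dot x_1 = u\,(s_{in} - x_1) - \frac{\mu_m x_1 x_2}{\delta (x_1 + K)},
\qquad
\dot x_2 = \frac{\mu_m x_1 x_2}{x_1 + K} - u\, x_2 , \qquad y = x_1 .$$

The goal is a *soft sensor* for $x_2$ that uses only $u$, $y$, the yield
constant $\delta$ (a stoichiometric quantity, typically known), and the
operating trajectory $Y(U) = K U/(\mu_m - U)$ — the curve of equilibria,
which plants map out experimentally — while $\mu_m$, $K$ and $s_{in}$
remain unknown to the designer. All defaults use the benchmark constants
$\delta = 1/6.6$, $\mu_m = 1.2$/day, $K = 4.95$ kg/m³, $s_{in} = 9$ kg/m³,
for which the admissible input range is $(0, 0.7742)$/day; above the upper
bound the culture washes out.

## From input/output data to a state-space model

Around an admissible operating point the linearized dynamics have system
matrices

$$A = \begin{pmatrix} -h_D - U & -U/\delta \\ h_D \delta & 0 \end{pmatrix},
\quad b = \begin{pmatrix} h_N \\ -\delta h_N \end{pmatrix},
\quad c = (1 \;\; 0),$$

with poles $\{-U, -h_D\}$, both negative, and the input/output behavior
collapses (after cancelling the uncontrollable pole at $-U$) to the
first-order model $\dot{\Delta y} + h_D \Delta y = h_N \Delta u$. The
structural fact the whole design rests on is *reconstructability*: on the
admissible set $\mathbb H = \{h_D > 0,\ h_N > 0,\ h_N U - h_D Y > 0\}$ the
map from $(h_D, h_N, U, Y, \delta)$ to $(A, b, c, \tilde X)$ is invertible
in closed form,

$$\mu_m = \frac{h_N U^2}{h_N U - h_D Y}, \qquad s_{in} = h_N + Y, \qquad
K = \frac{h_D Y^2}{h_N U - h_D Y},$$

so an identified $(\hat h_D, \hat h_N)$ plus the known operating point
determines the observer's model with no physical parameter knowledge. At
the boundary $h_N U - h_D Y \to 0$ the inversion degenerates
($\mu_m, K \to \infty$); the package raises there rather than
regularizing, and identification results are projected onto $\mathbb H$
(nearest point, with a $10^{-8}$ margin) before use.

## How far the linear approximant can be trusted

Three discrepancy metrics compare the nonlinear response with the linear
approximant's, as percentages of the approximant deviation itself: a
sup-norm ratio $J_\infty$, a steady-state ratio $J_1$, and an $L_2$ ratio
$J_2$ truncated at each component's 2% settling time. Two readings in the
formulas are ambiguous as printed and are fixed here as follows: the
per-component normalization of $J_\infty$ is taken as a ratio of sup-norms
over both components and time, and improper integrals are truncated at the
settling times with limits estimated from the trailing 5% of samples. For
a step input $u = U(1 + p_u)$ the steady-state metric has the closed form
$J_1 = 100\,|p_u U / ((1+p_u)U - \mu_m)|$, independent of initial
conditions — `accuracy_experiment()` reproduces it by simulation to well
under half a percentage point, which doubles as a regression test on the
transcription. `accuracy_region()` maps the set of input and
initial-condition perturbations where all three metrics stay below their
thresholds (5% each by default); regions extend around the operating
trajectory and overlap between neighboring operating points. The default
scan grid is 21×21×21 over the admissible ranges; tests and examples use
coarser grids, which changes resolution, not the pass/fail structure.

## The observer and its two metrics

The full-order observer $\dot{\Delta z} = F \Delta z + g \Delta y +
m \Delta u$, $F = A - gc$, $m = b$, estimates $\hat x = \Delta z + \tilde
X$. Placing distinct real poles $\{-\rho_1, -\rho_2\}$ with margin
$a < \rho_1 < \rho_2$ gives $g_1 = \rho_1 + \rho_2 - h_D - U$ and
$g_2 = \delta (U h_D - \rho_1 \rho_2)/U$; the approximant is observable
iff $U \neq 0$, independently of the coefficients. Two scalar metrics
steer the pole choice:

* **Convergence**: $J_{e,A} = e^{-a}(\lVert\Phi_1\rVert_2 +
  \lVert\Phi_2\rVert_2)$, with $\Phi_k$ the rank-one spectral projectors
  of $F$ — an envelope on the free error response at $t = 1$ day. The two
  projector norms coincide, giving a closed form that diverges as the
  poles coalesce and is independent of $(h_D, h_N)$.
* **Steady-state accuracy**: for a step to $U + u_w$ the model error of
  the approximant settles at $\varepsilon_{x,SS} = -A(\tilde X_D - \tilde
  X) - b u_w$ and the observer error at $e_{O,SS} = -F^{-1}
  \varepsilon_{x,SS}$; the ratio $J_{e,O} = \lVert e_{O,SS}\rVert^2 /
  \lVert \tilde X_D - \tilde X \rVert^2$ factors exactly as $u_w^2\,
  \tilde J_{e,O}(h_D, h_N, U, \rho_1, \rho_2)$ along the operating
  trajectory.

Several of the printed closed forms for these quantities circulate with
typographic corruption; the package treats the matrix path
($\varepsilon_{x,SS}$, $F^{-1}$, norms) as authoritative, derives the
closed forms from it, and cross-checks the two routes to $10^{-8}$
relative in the test suite. Two sign slips were found and corrected this
way: the steady-state error is $-F^{-1}\varepsilon_{x,SS}$ (co-simulation
of plant and observer confirms the sign and the worked values
$(+4.38\times 10^{-4}, +3.48\times 10^{-3})$ at $U = 0.6$,
$u_w = 0.05$), and the fixed ratio between its components is
$e_1/e_2 = -U/(\delta(U + g_1) + g_2)$.

`optimize_poles()` minimizes $\tilde J_{e,O}$ subject to $J_{e,A} \le
\zeta_{O,A}$ and the ordering constraint, with the slow pole allowed down
to $a(1 + 10^{-6})$. The geometry makes the outcome predictable: the
steady-state metric rewards slow, close pole pairs while the convergence
bound caps their closeness, so the optimum pins $\rho_1$ at the margin
with the $J_{e,A}$ constraint active — the search (deterministic
multi-start Nelder–Mead plus a boundary line search; no randomness) simply
confirms it and reports constraint activity in its diagnostics rather
than asserting it. Defaults $a = 3.5$/day, $\zeta_{O,A} = 0.5$, $\alpha =
2$ norm.

## Identification

Each operating point is probed with $u(t) = U + \lambda f_w(t)$, where
$f_w$ is a seeded uniform random series band-limited to 1 rad/day
(frequency-domain truncation, then unit-peak normalization — this makes
the smoothness and spectral-confinement properties exact) and $\lambda$
is 0.5% of the largest input deviation that keeps the linear approximant
accurate at the 5% thresholds, obtained by inverting the $J_1$ closed
form. The probe is therefore deliberately tiny: the plant stays within a
fraction of a percent of its operating point throughout identification.

The records are prefiltered with an analog Butterworth low-pass designed
to the tight specification passband 1 rad/day (≤ 1 dB), stopband 1.1
rad/day (≥ 40 dB), which realizes order 56. The filter is implemented as
cascaded second-order sections discretized exactly under first-order
hold; a monolithic polynomial realization is numerically unusable at this
order. The regression $\dot y_f = -\hat h_D y_f + \hat h_N u_f$ takes its
derivative channel from the final section's state equation, so the
measured output is never differenced. The edge frequencies are
interpreted in the simulation's time unit (rad/day); interpreting them in
rad/s would place the filter far beyond the sampling Nyquist rate and
reduce it to the identity.

The recursion is standard RLS with inverse-correlation initialization
$10^4 I$, zero initial estimates and no forgetting, with one addition:
the three channels are normalized to unit RMS first and the estimates
rescaled afterwards. This matters because the slow, narrow-band probe
makes the two regressors nearly collinear, and with raw $10^{-4}$-scale
signals the initialization acts as a prior whose precision exceeds the
data information along the weak (pole) direction — the estimates would be
biased toward zero by tens of percent however long the record. On
normalized channels the initialization is vacuous, and noise-free
identification recovers the coefficients to about $10^{-5}$ relative.
Final estimates are the time averages of the estimate traces over days
200–400 of a 400-day record at 0.01-day sampling, with the per-coefficient
fluctuation (100·(max − min)/|mean| over the window) reported.

Measurement noise is band-limited (10 rad/day) Gaussian, exactly
demeaned and RMS-scaled. Its default amplitude is set relative to the
probe, not the measurement: RMS equal to 3% of the output-deviation scale
$\lambda h_N / h_D$ (a deviation-channel SNR near 30). An amplitude tied
to the absolute output level would be enormous compared with the
deliberately small probe and would swamp the regression; scaling the two
together keeps the identification problem meaningful at any probe size.
Under these defaults the noisy estimates stay within a few percent with
roughly 1% fluctuation. The shipped transition-experiment configs use
noise-free records: the per-mille estimation-error budgets those
experiments demonstrate require coefficient errors well below the
percent-level floor that noisy identification leaves, and noise
robustness is exercised separately.

## Target areas, the dense web, and switching

An observer's *target operating area* is the interval of destination
inputs around its nominal $U_i$ where $J_{e,A} \le \chi_{O,A}$ and
$J_{e,O} \le \chi_{O,B}$ (defaults 0.5 and 0.001), destinations taken on
the nonlinear operating trajectory of the reconstructed model. Areas are
scanned on 400 grid points per side with bisection refinement to
$10^{-4}$/day, symmetric by default and saturated at the admissible
bounds — which is why high-dilution areas come out asymmetric and can
cover the entire range, while low-dilution areas are narrow (the
steady-state metric scales like $(h_N U - h_D Y)^2/(U^4 Y^2)$, which
blows up as $U \to 0$). The asymmetric mode grows each side
independently to failure or saturation.

A bank of observers supports stepwise transitions when consecutive areas
overlap — the *dense web* principle; `dense_web_check()` reports any
uncovered gaps, and the design pipeline halts there with the instruction
to densify the point set. `auto_bank_points()` builds a covering chain
automatically, using the closed-form half-width estimate
$\sqrt{\chi_{O,B}/\tilde J_{e,O}}$ and keeping half of each half-width as
overlap; the scan-based areas remain the authority on the produced set.

Transitions are planned by greedy farthest reach: from the current area,
hop to the highest-indexed overlapping area, placing the intermediate
destination at the overlap midpoint; hand-picked intermediates are
accepted and assigned the covering area with the nearest nominal. Reverse
transitions run the same recursion downward, so plans are direction
dependent. Each stage lasts 1.1 times the 2% settling time of the entered
observer's linear approximant for that step (within the one-to-two
settling-times convention; the settling time of the stage being entered
is used). At a switch the supervisor keeps the physical estimate
continuous: the incoming observer starts from $\Delta z_{new} =
\hat x_{old} - \tilde X_{new}$. Copying the raw deviation state between
observers indexed to different nominals — available as
`literal_handoff = TRUE` — jumps the physical estimate by the nominal
difference, which is measurable in the tests; continuity is the default
because the estimate, not the deviation coordinate, is the sensor's
output. The first observer starts with its measured component on the
measurement ($c\,\Delta z = \Delta y$, so the measured error component
starts at zero) and the unmeasured component at the nominal.

## What the generator does and does not emulate

The synthetic data source is the nonlinear Monod model itself, integrated
with `deSolve::lsoda` at rtol $10^{-8}$/atol $10^{-10}$, sampled at 0.01
day, with band-limited sensor noise. It does not emulate model-structure
mismatch (real uptake kinetics deviating from Monod), slow parameter
drift, input actuator dynamics, or sampled/delayed laboratory assays.
Passing tests therefore demonstrate the internal consistency and
data-driven character of the design chain — identification error enters
the observers exactly as it would from a real plant — but not robustness
to structural mismatch, which the admissibility projection and the
accuracy regions only partially address.

## Numerical choices and problem sizes

States are never clipped in the integrator (a negative state raises);
admissibility intervals are open with a $10^{-6}$ relative margin;
observer and filter propagation uses exact first-order-hold
discretization via augmented matrix exponentials, so linear subsystems
are integrated without truncation error on piecewise-linear inputs;
settling times use the trailing-5% mean as the steady value and fall back
to the steady-state value as band reference for excursion-free
transients. Worked examples and the shipped experiments use the defaults
above; the test suite runs the same code on shorter records (for
pipeline determinism checks) and coarser area scans (120–150 points per
side), sizes chosen so the full suite completes in about two minutes of
simulation-dominated work without changing any scientific conclusion.

## Known limitations

Only the first-order ($n_c = 1$) input/output structure of the chemostat
is implemented; the general higher-order interface is declared but not
built. Monod kinetics only — no Haldane or Contois uptake, no stochastic
dynamics. The observers are open-loop soft sensors: no control loop is
closed on the estimates, and the error series are exposed but no fault
detection logic is built on them. The asymmetric-area growth rule (both
sides independently to failure) is one of several defensible conventions;
where a unique nonsymmetric determination matters, a side-priority
algorithm would need to be specified.
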