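---
title: "Methods: fractal-fractional tumor-normal competition under radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractal-fractional tumor-normal competition under radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fftumor)
```

## The model

Two cell populations, healthy ($x_1$) and malignant ($x_2$), measured as
proportions, grow logistically, compete, and are hit by a continuous
radiation dose rate $\gamma$ (Gray/hour):

$$
\begin{aligned}
D^{\mu,\nu} x_1 &= \alpha_1 x_1\Big(1-\frac{x_1}{K_1}\Big)
  - \beta_1 x_1 x_2 - \varepsilon\gamma x_1,\\
D^{\mu,\nu} x_2 &= \alpha_2 x_2\Big(1-\frac{x_2}{K_2}\Big)
  - \beta_2 x_1 x_2 - \gamma x_2,
\end{aligned}
$$

where $D^{\mu,\nu}$ is the fractal-fractional derivative with
Mittag-Leffler (Atangana-Baleanu) kernel, fractional order $\mu \in (0,1]$
and fractal dimension $\nu \in (0,1]$. $\mu$ tunes how strongly the history
of the populations weighs on their present rate of change (memory);
$\nu$ replaces ordinary time by $t^\nu$, a crude model of the irregular,
self-similar structure of tissue response. $\mu = \nu = 1$ recovers the
classical ODE system. Radiation kills malignant cells at rate $\gamma$ and
collaterally damages healthy cells at rate $\varepsilon\gamma$ (collateral
fraction $\varepsilon$, here $8\times 10^{-4}$). $\gamma = 0$ is the
untreated system, in which the malignant population grows to its carrying
capacity and suppresses the healthy one.

Key analytics implemented in the `model` layer:

* Boundary equilibria: cancer-free
  $E_0 = (K_1(\alpha_1-\gamma\varepsilon)/\alpha_1,\, 0)$ and healthy-free
  $E_* = (0,\, K_2(\alpha_2-\gamma)/\alpha_2)$. A negative coordinate is
  reported but flagged infeasible. One printed form of $E_*$ in the source
  analysis carries $K_1$ where the model structure implies $K_2$; the two
  agree for the presets ($K_1 = K_2 = 1$), and `equilibria()` exposes the
  $K_1$ variant as `E_star_printed`.
* Thresholds: $R_0 = \alpha_2/(\gamma+\beta_2 K_1)$ (malignant reproduction
  ratio; $R_0 < 1$ predicts eradication) and
  $R_h = (\alpha_1-\varepsilon\gamma)/(\beta_1 K_2)$ (healthy net growth
  ratio).
* Local stability: eigenvalues of the analytic Jacobian at each equilibrium,
  combined with the Matignon condition $|\arg\lambda| > \mu\pi/2$. The
  published $J(E_0)$ differs from the analytic Jacobian in its (2,2) entry;
  the analytic form is authoritative here and the printed variant is kept
  available via `jacobian_E0_printed()` for comparison. For the presets both
  give negative $\lambda_2$, so no verdict changes.

### A note on $R_h$

The sufficient condition for the second-derivative global-stability argument
requires $R_h > 1$, yet the preset parameters give $R_h \approx 0.0086$
while every treated simulation still converges to $E_0$. The condition is
sufficient, not necessary: healthy-cell recovery is slow
($\alpha_1 \sim 10^{-3}\,\mathrm{h}^{-1}$) but un-opposed once the malignant
population is gone. The package therefore *reports* the condition's truth
value (`global_stability_check()$sufficient_condition`) alongside the
numerical evidence and never lets it short-circuit the numeric check.

## The calculus layer

Two integral operators are provided on sampled functions. Printed
definitions of the fractal factor vary between $\xi^{\nu-1}$,
$\xi^{1-\nu}$ and the scheme's $\nu\sigma^{\nu-1}$; the package fixes the
convention the numerical scheme (and hence every quantitative result) is
built on:

$$
I^{FFM}(t) = \frac{\nu t^{\nu-1}(1-\mu)}{AB(\mu)}\,z(t)
 + \frac{\mu\nu}{AB(\mu)\Gamma(\mu)} \int_0^t
   \sigma^{\nu-1}(t-\sigma)^{\mu-1} z(\sigma)\,d\sigma,
$$

with $AB(\mu) = 1-\mu+\mu/\Gamma(\mu)$, and the power-law variant
$I^{FFP}(t) = \Gamma(\mu)^{-1}\int_0^t (t-\xi)^{\mu-1}\xi^{\nu-1} z(\xi)
\,d\xi$. The alternative fractal-derivative normalization factor
$(2-\nu)$ that appears in one printed definition of the underlying
derivative is documented here for completeness but enters no computation:
the solver consumes only the integral operators. An exponential-kernel
(Caputo-Fabrizio-type) variant exists in the literature with its own
normalization $M(\mu)$; no results flow from it and it is deliberately not
implemented.

**Quadrature.** The kernel $\sigma^{\nu-1}(t-\sigma)^{\mu-1}$ is weakly
singular at both ends. The operators integrate it *exactly* against a
piecewise-linear interpolant of $z$: on each cell the two moment integrals
$\int \sigma^{c-1}(t-\sigma)^{\mu-1} d\sigma$ ($c = \nu, \nu+1$) are
incomplete Beta functions, evaluated through `pbeta`. No midpoint rule, no
regularization constant; for constants and monomials the result matches the
Beta-function closed forms to quadrature-interpolation error only (tested at
relative $10^{-5}$ on 4000-point grids, and to $10^{-10}$ in the classical
limit where the linear interpolant is integrated exactly).

**Mittag-Leffler function.** $E_\alpha(z) = \sum_k z^k/\Gamma(\alpha k+1)$
is evaluated by its truncated power series (stop when a term falls below
$10^{-16}$ of the running sum; 10,000-term cap; arguments that overflow the
series raise rather than silently switching algorithms). The series for
negative arguments is violently alternating — at $\alpha = 1$, $z = -20$
the largest term is $\sim 4\times 10^7$ while the sum is
$\sim 2\times 10^{-9}$, so plain double-precision summation loses seven
digits. Terms and partial sums are therefore carried in compensated
double-double arithmetic, with the exact recurrence $t_k = t_{k-1}z/k$ at
$\alpha = 1$; the measured error against $e^z$ is then at rounding level
across $|z| \le 20$. For fractional $\alpha$ the Gamma ratio between
consecutive terms is computed via `lgamma`, which is amply accurate at the
small-argument range the identities exercise (e.g.
$E_{1/2}(-x) = e^{x^2}\mathrm{erfc}(x)$).

## The two-step solver

The integral form of the system at $t_{r+1}$ is discretized with piecewise
Lagrange (linear) interpolation of the integrand on each history cell,
giving the explicit scheme

$$
x^{r+1} = x^0 + \frac{\nu t_r^{\nu-1}(1-\mu)}{AB(\mu)} A(t_r,x^r)
 + \frac{\mu\nu(\Delta t)^\mu}{AB(\mu)\Gamma(\mu+2)}
 \sum_{v=0}^{r}\Big[t_v^{\nu-1}A(t_v,x^v)\,w_1(q)
   - t_{v-1}^{\nu-1}A(t_{v-1},x^{v-1})\,w_2(q)\Big],
$$

with lags $q = r+1-v$, $p = r-v$ and weights
$w_1 = q^\mu(q+1+\mu)-p^\mu(1+2\mu+q)$,
$w_2 = q^{\mu+1}-p^\mu(q+\mu)$. Conventions the printed scheme leaves open:

* **$v = 0$ history.** The sum references $t_{-1}$ and $x^{-1}$; the package
  sets $x^{-1} := x^0$, $t_{-1} := t_0$, so the first step degenerates to
  Euler and the convention is irrelevant once $r$ grows.
* **Fractal weight at the origin.** $t_0^{\nu-1}$ is singular for
  $\nu < 1$ at $t_0 = 0$; the origin node uses $t := \Delta t$ (one-cell
  regularization, exact at $\nu = 1$, flagged in a log message whenever
  $\nu < 1$).
* **$\mu = 1$ fast path.** The weights collapse to $(3,1)$ for every lag
  (algebraically: $(p+1)(p+3)-p(p+4) = 3$, $(p+1)^2-p(p+2) = 1$), the
  history sum telescopes, and the scheme *is* the cumulative two-step
  Adams-Bashforth rule; the implementation then uses the algebraically
  identical $O(N)$ recurrence instead of the $O(N^2)$ sum.

The classical-limit oracle `integrate_classical()` (adaptive lsoda at
rel/abs $10^{-10}$) is kept strictly separate from the scheme; at
$\mu = \nu = 1$, $\Delta t = 0.01$, the two agree to better than $10^{-4}$
max-norm over $[0,200]$ h on all six presets (measured $\sim 5\times
10^{-6}$ for patient 1), and `convergence_study()` recovers the expected
empirical order $\approx 2$.

**Step size.** The published tables state no $\Delta t$. The default is
$\Delta t = 0.05$ h with an explicit convergence rule: table output is
labelled converged only if halving $\Delta t$ changes no reported 4-decimal
value. Negative excursions near extinction are reported raw, with a warning
below $-10^{-9}$; no clipping.

## Lyapunov diagnostics

The Volterra function
$L = \sum_i (x_i - x_i^* - x_i^*\ln(x_i/x_i^*))$ is evaluated with the
boundary convention $x^*\ln(x/x^*) \to 0$ as $x^* \to 0$, so $L$ stays
finite against both boundary equilibria.

The published global-stability argument splits the derivative into
competing non-negative groups $\Upsilon_1$ (destabilizing) and $\Upsilon_2$
(stabilizing) and concludes stability from $\Upsilon_1 < \Upsilon_2$. The
algebra behind that split substitutes the deviation $x - x^*$ into the
right-hand sides, so the printed all-squared groups satisfy (exactly, and
verified in the tests)

$$
\Upsilon_1-\Upsilon_2 = \sum_i \frac{(x_i-x_i^*)^2}{x_i}
 \Big[\alpha_i\Big(1-\tfrac1{K_i}\Big) - (\text{cross})_i -
 (\text{dose})_i\Big],
$$

which is *not* the along-trajectory derivative
$\dot L = \sum_i (1-x_i^*/x_i) F_i(x)$. The package keeps both honestly
separate: `lyapunov_decomposition()` returns the printed groups (both
non-negative by construction, used for the $\Upsilon_1 < \Upsilon_2$
dominance diagnostic), while `lyapunov_derivative()` returns the true chain
rule $\dot L$ — the quantity finite differences of $L$ along an orbit
reproduce, and the one `lyapunov_second_derivative()` differentiates
(tested against centered differences at relative $10^{-3}$). Conflating the
two would make either the non-negativity of the groups or the
finite-difference identity false; this separation is the package's own
design resolution of the tension.

Near extinction the decomposition divides by $x_2 \to 0$;
`global_stability_check()` excludes points with a component below $10^{-9}$
from the division-based columns and counts them, rather than returning
infinities. On every treated preset the dominance diagnostic holds at 100%
of evaluable points and $L$ decreases monotonically once $x_2 < 10^{-4}$.

## Existence constants

The linear-growth and Lipschitz constants
$k_i$, $\bar k_i$ follow the printed derivation exactly, with the ten sup
slots $M_1..M_{10}$ collapsed onto two user-suppliable scalars (one per
component, defaults $K_1^2$, $K_2^2$ from the invariant region); the
ten-slot expansion is retained in the report for traceability. One printed
line of the $k_2$ derivation carries $\alpha_1^2$ where the preceding lines
consistently use $\alpha_2^2$; the consistent $\alpha_2^2$ is implemented.
`verify_conditions()` stress-tests both inequalities by seeded uniform
sampling; the six uniforms per sample are drawn sample-by-sample so that
runs at the same seed nest and the worst observed ratio is provably
non-decreasing in the sample count. The Lipschitz check pins the non-varied
component at its sup, matching the derivation's treatment of cross terms.

## Presets, tables, synthetic data, fitting

The six presets (three patients, high/low dose arm) freeze the published
parameter set; `patient_table()` round-trips them bit-exactly. The
regenerated approximation tables agree with the published grids in the
$\mu = 1$ extinction cells — at $\mu = \nu = 1$ the model is the
unambiguous classical system whose malignant decay rate
($\approx 0.35$–$0.58\ \mathrm{h}^{-1}$) drives $x_2$ below $10^{-20}$ well
before the reported times, so those cells are robust to any reasonable step
size. The remaining cells (normal-cell columns, fractional-order
cancer-cell columns) are *not* asserted: the published values are
inconsistent with direct integration of the stated system (e.g. the printed
classical normal-cell growth to $0.3019$ by $t = 400$ h would require
roughly five times the maximum net rate $\alpha_1 - \varepsilon\gamma$
allows, and the printed $\mu = 0.75$ cancer-cell decay is far slower than
the model's), and the generating step size is unstated.
`reproduce_tables()` therefore emits the regenerated grid next to the
published one with absolute differences — a quantified discrepancy report —
and the qualitative structure (monotone extinction in time, memory ordering
in $\mu$, dip-then-recover normal cells) is what the tests assert.

`synthesize_observations()` is the study's data stand-in: it integrates a
preset and adds iid Gaussian noise (default exercised at SD 0.005, 200
points) to both series, seed recorded. It emulates dense, homoscedastic,
independently observed proportions; real radiotherapy observations are
sparse, irregular, and correlated, so passing recovery tests demonstrate
identifiability under the model's own assumptions, not clinical validity.
`least_squares_fit()` minimizes the residual sum of squares over any free
parameter subset with bounded Levenberg-Marquardt and seeded multi-start;
zero-noise fits recover $\gamma$ to $10^{-4}$ and noisy fits to within 5%.

## Problem sizes and numerical choices

Defaults used throughout the tests and examples: $\Delta t = 0.05$ h for
table regeneration (with the halving rule above), $\Delta t = 0.01$ h for
classical-limit comparisons over $[0,200]$ h, 10,000 samples for the
existence stress test, 200 observation points over $[0,50]$ h for fitting.
The history sum costs $O(N^2)$; at these sizes a fractional run to
$t = 400$ h takes a couple of seconds, so no fast-history approximation is
used. Ties, floors and tolerances: 4-decimal table rounding is
half-away-from-zero (matching printed tables rather than banker's
rounding); the positivity floor in Lyapunov traces is $10^{-9}$; weights
and fractal factors use $0^\mu = 0$ ($\mu > 0$) and $0^0 = 1$.

## Known limitations

* The fractional-order ($\mu < 1$) trajectories carry the scheme's own
  first-kind discretization error near $t = 0$ where the kernel is
  singular; only self-convergence is verified there, not an external
  oracle.
* No implicit or predictor-corrector variant: the explicit scheme can
  overshoot for step sizes far beyond the defaults.
* The exponential-kernel operator and the two-parameter Mittag-Leffler
  function are out of scope.
* Stability regions in $(\mu,\nu)$ are not mapped; `local_stability()`
  answers per-$(\mu)$ queries only.
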