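---
title: "Methods: a stochastic delayed SVIR model and its positivity-preserving schemes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a stochastic delayed SVIR model and its positivity-preserving schemes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvir)
```

## The model

`ssvir` simulates a compartmental epidemic model with three active
classes: susceptibles $S$, individuals in the vaccination process $V$,
and infected $I$ (the recovered class decouples from these three
equations and is not simulated).  Two features distinguish it from a
plain stochastic SVIR system:

* **Temporary immunity.** Recovered infected individuals lose their
  infection-induced immunity after a period $\tau_1$ and, having
  survived natural death with probability $e^{-\mu\tau_1}$, return to
  $S$; recovered vaccinees analogously re-enter $V$ after $\tau_2$.
  These delayed return flows, $\gamma_1 e^{-\mu\tau_1} I(t-\tau_1)$ and
  $\gamma_2 e^{-\mu\tau_2} V(t-\tau_2)$, make the system a set of
  stochastic *delay* differential equations.
* **General saturated incidence.** New infections arise at the
  Hattaf-type rate
  $F_1(S,I) = \beta_1 S I / (1 + \lambda_1 S + \lambda_2 I + \lambda_3 S I)$,
  and analogously $F_2(V,I)$ with $\beta_2,\eta_{1..3}$ for contacts of
  not-yet-immune vaccinees.  Setting the saturation factors to zero
  gives bilinear incidence; $\lambda_3 = 0$ the Beddington–DeAngelis
  form; $\lambda_3 = \lambda_1\lambda_2$ the Crowley–Martin form.

Each equation carries multiplicative Brownian noise
$\sigma_i X_i \, dW_i$.  The drift is exposed directly as
`svir_drift()`; it vanishes at the disease-free equilibrium
$E_0 = (\mu/(\alpha+\mu),\, \alpha\mu/c_2,\, 0)$, where
$c_2 = (\gamma_2(1-e^{-\mu\tau_2})+\mu)(\alpha+\mu)$.

## Threshold theory

The central dimensionless quantity is the stochastic reproduction number

$$
R_0^s \;=\;
\frac{\beta_1\mu}{(\alpha+(1+\lambda_1)\mu)\,(\gamma_1+\mu+\sigma_3^2/2)}
+ \frac{\beta_2\alpha\mu}{(\eta_1\alpha\mu + c_2)\,(\gamma_1+\mu+\sigma_3^2/2)},
$$

with the deterministic counterpart $R_0^d$ obtained at $\sigma_3 = 0$,
so $R_0^s \le R_0^d$ always.  When $R_0^s < 1$ the infection dies out
almost surely with
$\limsup_t \ln I(t)/t \le (\gamma_1+\mu+\sigma_3^2/2)(R_0^s-1) < 0$;
`extinction_report()` compares the realized finite-horizon rate with
this bound.  When $R_0^s > 1$ and the side condition
$c_1/(\alpha+\mu) - \beta_2\alpha\mu/(\eta_1\alpha\mu+c_2) > 0$ holds
(with $c_1$ the $\gamma_1,\tau_1$ analogue of $c_2$), the infection is
persistent in mean: the long-run time average of $I$ stays above

$$
I^* = \frac{(\gamma_1+\mu+\sigma_3^2/2)(R_0^s-1)}{L_1+L_2},
$$

with companion bounds $S^*$, $V^*$ on the averages of $S$ and $V$.

**The second denominator uses $c_2$.** The V-contact term of $R_0^s$
descends from the per-capita bound
$\bar F_2 \le \beta_2\alpha\mu/(\eta_1\alpha\mu + c_2)$, which involves
$c_2$ — the composite rate of the V compartment.  Every reported
threshold value under the shipped study conditions (0.9561, 1.0177,
1.0994, 1.2396, 0.8553, 1.2402) is reproduced only by this reading, so
the package uses $c_2$ throughout.

**Two variants of $L_2$.** The persistence derivation admits two
readings of the denominator constant $L_2$.  The closed form stated
with the theorem,
$L_2 = \beta_2\alpha(\beta_2\alpha\mu(\alpha+\mu)+c_1(\eta_1\alpha\mu+c_2)) / ((\eta_1\alpha\mu+c_2)^2(\alpha+\mu))$,
gives $I^* \approx 0.0761$ under the high-transmission preset.  The
coefficient that actually multiplies $\langle I\rangle$ in the
expansion step of the same derivation is
$\beta_2 c_1/(\eta_1\alpha\mu+c_2)$, and it yields
$I^* \approx 0.1246$, consistent with the reported trio
$(I^*, S^*, V^*) = (0.125, 0.0898, 0.2168)$ and with what the
simulations show.  `persistence_thresholds()` exposes both as
`mode = "expansion"` (default, matching the reported values) and
`mode = "theorem"`; the discrepancy is surfaced rather than resolved.
Both variants vanish at $\beta_2 = 0$, where the modes coincide.

`threshold_report()` additionally rounds to the conventional reporting
precision ($I^*$ to 3 decimals, $S^*, V^*$ to 4) with $V^*$ recomputed
from the already-rounded $I^*, S^*$, so the three reported numbers are
mutually consistent at that precision.  Internal computation is always
full precision.

## The two integrators

Both schemes live on a uniform grid with step $h$ that must divide the
horizon and both delays ($m_1 = \tau_1/h$, $m_2 = \tau_2/h$ integer);
non-commensurate grids are an error, never silently rounded, because
the delayed indices would otherwise refer to times the scheme never
visits.  A delayed state at lag $m h$ is approximated by the split-step
convex combination $\theta x_{n-m+1} + (1-\theta) x_{n-m}$, with
indices at or before time zero resolved through the history function.
Only point initial values are prescribed under the shipped study
conditions, so the default history is the constant extension of the
initial triple — the minimal consistent choice; arbitrary positive
history functions are supported.

**Split-step θ-Milstein (`sstm_simulate`).** The explicit
Milstein-type update with diagonal noise: each equation gets drift
times $h$, the noise term $\sigma X_n \Delta W_n$, and its own Milstein
correction $(\sigma^2/2) X_n (\Delta W_n^2 - h)$.  The sweep is
sequential (Gauss–Seidel-like): $S_{n+1}$ feeds the $\alpha S_{n+1}$
inflow of the $V$ update, and both feed the incidence fractions of the
$I$ update, paired with $I_n$.

**Split-step θ-NSFD (`ssstnsfd_simulate`).** A nonstandard finite
difference scheme in the Mickens sense: the step $h$ is replaced by the
denominator function $v(h) = 1-e^{-h}$ (satisfying $v(h)=h+O(h^2)$ and
$0 < v(h) < 1$), and every loss term is treated implicitly, which after
rearrangement puts it in the *denominator* of an explicit update.  With
zero noise all numerators and denominators are positive, so positivity
from positive history holds for **any** step size — the property the
Milstein scheme loses at coarse steps.  With noise, a sufficiently
negative increment ($\sigma_3\Delta W_3 < -1$) can still push the $I$
numerator negative; the implementation records every such step in
`positivity_violations` rather than assuming positivity, because
unbounded Gaussian increments make the claim of unconditional
positivity untenable.

**Brownian increments.** A step of length $h$ carries an increment of
variance $h$, so increments are drawn as $\Delta W = \sqrt{h}\,\xi$,
$\xi \sim N(0,1)$.  The per-step draw order is fixed
($\Delta W_1, \Delta W_2, \Delta W_3$) so both schemes can be driven by
an identical noise table (`svir_noise`) for coupled comparisons, and a
seed fully determines a trajectory.  Ensemble path $k$ uses seed
`base_seed + k - 1`.

**Degenerate and pathological inputs.** Negative states produced by
the Milstein scheme are recorded, never clipped — clipping would hide
exactly the pathology the scheme comparison is about.  If a state
becomes non-finite (the explicit scheme is explosive for
$|1-(\mu+\alpha)h| > 1$ under stiff rates), the run is truncated at
that step: the remaining values are `NA`, `diverged_at` records the
step, and a warning is raised.  Truncation rather than a hard error
was chosen so that violation counts accumulated *before* the blow-up
remain observable in multi-seed scans.  Incidence denominators are
$\ge 1$ for nonnegative arguments and need no epsilon guard.

## Diagnostics

* `time_average()` — trapezoidal $(1/T)\int_0^T g$; exact on constant
  and linear paths, linear and monotone as an operator.
* `extinction_report()` — realized $\ln I(T)/T$ against the
  closed-form bound; all verdicts are finite-horizon observations with
  the horizon recorded, never limit claims.
* `persistence_report()` — time averages against $(I^*, S^*, V^*)$,
  path-wise or ensemble-averaged.
* `boundedness_certificate()` — the discrete envelope
  $M_n = \mu v(h) + (1+\sigma\Delta W_n) M_{n-1}$, $M_{-1} = T^*$, with
  $\sigma = \max_i \sigma_i$ and $\Delta W_n$ the per-step maximum
  increment, which bounds the total density $S_n+V_n+I_n$ for the NSFD
  scheme.  The ceiling is read as the sum of two fractions,
  $T^* = \mu/(\gamma_2(1-e^{-\mu\tau_2})+\mu) + \alpha\mu/c_2
  \approx 0.6208$ under the baseline conditions, by analogy with the
  DFE coordinate $\alpha\mu/c_2$; `T_star_override` lets users supply
  any alternative reading.  Two honesty mechanisms: steps with
  $1+\sigma\Delta W_n \le 0$ (possible, since the increments are
  signed) void the certificate and are flagged; and because the
  default initial total $0.8$ exceeds $T^* \approx 0.62$, the default
  envelope starts from $\max(T^*, S_0+V_0+I_0)$ so the monitor is
  usable on the shipped presets, while `strict = TRUE` enforces the
  hypothesis as stated.  With $\sigma = 0$ the recursion collapses to
  the arithmetic progression $M_n = T^* + \mu v(h)(n+1)$, which the
  tests check against the product-form expansion to $10^{-12}$.

## Study-condition presets

All presets share the baseline set $\mu=1$, $\alpha=10$,
$\gamma_1=1.5$, $\gamma_2=2.4$, $\theta=0.5$, $\tau_1=1$, $\tau_2=2$,
$\sigma=(0.1, 0.02, 0.05)$, $\lambda=(0.2,0.3,0.4)$,
$\eta=(0.4,0.2,0.1)$, horizon $T=100$, initial values $(0.3,0.3,0.2)$:

| preset | change | consequence |
|---|---|---|
| `extinction` | $\beta_1=10.5$, $\beta_2=5.5$, $h=0.1$ | $R_0^s = 0.9561$: die-out |
| `short_immunity` | $\tau_1=0.8$, $\tau_2=1.3$ | $R_0^s = 1.0177$: persistence |
| `weak_saturation` | plus $\lambda=(0.02,0.03,0.04)$, $\eta=(0.04,0.02,0.01)$ | $R_0^s = 1.0994$ |
| `persistence` | $\beta_1=14$, $\beta_2=7$ | $R_0^s = 1.2396$, $I^*=0.125$ |
| `large_noise` | plus $\sigma_3=1.5$ | $R_0^s=0.8553 < 1 < R_0^d=1.2402$ |
| `coarse_step` | $h=0.5$ | Milstein loses positivity; NSFD does not |

Two preset readings were genuinely open and are fixed as follows.
`weak_saturation` *retains* the shortened immunity periods of the
preceding experiment — the experiments are cumulative; this is the only
reading consistent with its threshold value 1.0994 (the baseline-delay
reading gives $\approx 1.023$).  And each figure-style experiment uses
a single noise realization per method with the seed recorded, since no
ensemble size is prescribed; `ensemble_run()` covers multi-path use.

```{r thresholds}
p <- load_preset("persistence")$params
derived_constants(p)
threshold_report(p)
```

## What the tests do and do not show

The test suite checks the closed-form thresholds to the printed
precision, single-step hand oracles for both schemes, structural
invariants (incidence domination, monotonicity of $R_0^s$, invariance
of the disease-free axis, equilibrium holding, noise-free NSFD
positivity for $h \in \{0.01, 0.1, 0.5, 1, 5\}$ — the $h=5$ case on a
delay-commensurate parameter variant, since $\tau_1 = 1$ does not admit
a 5-unit step), self-convergence of the two schemes under refinement,
and Monte-Carlo renditions of the extinction and persistence behaviour
(30 paths, $T=100$, $h=0.1$; sizes chosen so the whole suite runs in
well under a minute).  These simulations emulate the model's own
dynamics under the shipped conditions; they do not validate the model
against surveillance data, fit parameters, or certify a strong
convergence order for either scheme — all outside the package's scope.
The coarse-step Milstein blow-up is treated as an empirical, seed-wise
report, not an assertion about all seeds.

## Known limitations

* Only the constant-$\theta$, diagonal-noise schemes of the model are
  provided; they are not general SDE integrators.
* The certificate and persistence verdicts are finite-horizon
  observations; no almost-sure statement is verified numerically.
* The $L_2$ ambiguity above is documented, not adjudicated.
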