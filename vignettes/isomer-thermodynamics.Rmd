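---
title: "Isomer-group thermodynamics and the dissolution of alpha-lactose monohydrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isomer-group thermodynamics and the dissolution of alpha-lactose monohydrate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isolact)
```

## The problem

Aqueous sugar solutions that look binary are usually not: lactose in water is
a ternary mixture in which the two anomers, alpha- and beta-lactose,
interconvert by mutarotation until their ratio reaches a
composition-dependent equilibrium value $K_x = x_\beta/x_\alpha$. Phase
equilibria that must distinguish the isomers — the solubility of
alpha-lactose monohydrate most prominently — therefore need activity
coefficients *per isomer*, but only the solvent activity and the isomer
ratio are measurable. `isolact` implements a thermodynamically consistent
route from those two measurables to per-isomer activity coefficients,
solid–liquid equilibrium, and a full dissolution simulator.

## The model

**Water activity.** The solvent activity coefficient follows the two-suffix
Margules model, $\ln \gamma_w = A(1-x_w)^2$, a one-parameter parabolic
excess-Gibbs-energy model that describes concentrated sugar solutions well.
For lactose at 25&nbsp;°C the calibrated constant is $A = -5.8$ (strongly
negative deviations: water–sugar attraction beats the homotypic
interactions). `A` is temperature-specific but composition-independent.

**Isomer group.** Because the isomers are in chemical equilibrium, their
chemical potentials are equal and the Gibbs phase rule leaves a single
composition degree of freedom, $x_w$. Treating the interconverting pair as a
pseudospecies ("isomer group", $x_{iso} = x_\alpha + x_\beta$), the
Gibbs–Duhem relation integrates the Margules form in closed form to
$\ln\gamma^*_{iso} = A(x_w^2 - 1)$ on the solute standard state
($\gamma^* \to 1$ at infinite dilution).

**Per-isomer coefficients.** Carrying the isomer-ratio term through the same
integration from infinite dilution (where the measured ratio equals the
thermodynamic constant $K^*$) gives

$$\ln \gamma^*_\alpha = A(x_w^2-1) + \ln\frac{1+K_x(x_w)}{1+K^*}, \qquad
  \ln \gamma^*_\beta  = A(x_w^2-1) + \ln\frac{1+1/K_x(x_w)}{1+1/K^*}.$$

Three independent facts pin these forms down, and all three are enforced as
tests: (i) their difference is exactly $\ln(K_x/K^*)$, the consistency
identity tying the drift of the measured ratio to the coefficient ratio;
(ii) a purely numerical Gibbs–Duhem quadrature
(`gamma_star_isomers_numeric()`), assembled only from the Margules water
activity and the $K_x(x_w)$ line, reproduces them to $10^{-6}$; and (iii)
they reproduce the published solubility product of the monohydrate (below).
The group coefficient is recovered as a corrected geometric average of the
two (`gamma_average_residual()` checks the exact mixing correction).

**Ratio model.** $K_x(x_w) = K^* - s\,(1-x_w)$, matching the linear
extrapolation by which $K^*$ is estimated from data. The default slope is
$s = 0$ because no calibrated value is printed for lactose; a positive $s$
(order 1–3) reproduces the observed slight decrease of $K_x$ with
concentration and is exposed in the configuration. Results that matter are
insensitive to it: the saturation point and $K_{sp}$ are *algebraically*
independent of $s$ (the $1+K_x$ factors cancel), which the tests verify for
$s \in \{0, 1, 3\}$.

**Solid–liquid equilibrium.** With unit solid activity, saturation with
respect to the monohydrate requires
$K_{sp} = a_w\,\gamma^*_\alpha\,x_\alpha$. At the equilibrium saturation
composition $x_w = 0.9886$ this evaluates to $K_{sp} = 0.00494$:

```{r}
ksp_from_equilibrium_point(0.9886, margules_model(-5.8), mutarotation_model(1.60))
equilibrium_solubility(solubility_model())
```

$K^* = 1.60$ is itself not printed for lactose; it is the unique value that
makes $K_{sp} = 0.00494$, $x_{w,eq} = 0.9886$ and $A = -5.8$ mutually
consistent (and it matches the well-known ~61:39 beta:alpha equilibrium).
It is documented as inferred, and `fit_mutarotation()` estimates it from
data when data exist.

**The F parameter.** Linearizing $x_{\alpha,sat}(x_w)$ around the
equilibrium saturation point and eliminating $x_w$ with the mole balance
gives the classic empirical depression ratio
$F = -\Delta x_{\alpha,sat}/\Delta x_\beta = S/(1+S)$ with
$S = x_{\alpha,sat,eq}\,[-\mathrm{d}\ln a_w/\mathrm{d}x_w - 2Ax_w]$.
The default freezes $K_x$ at its saturation value; whether the historical
expression includes the $K_x$ slope term cannot be settled from the
available sources, so `include_slope = TRUE` provides the variant for
sensitivity analysis. The constant-$K_x$ default gives

```{r}
f_parameter(solubility_model())
```

against the literature estimate 0.0434 from sucrose-addition experiments.

**Foreign sugars.** The central physical hypothesis is that $a_w$ and
$\gamma^*_\alpha$ depend on the *total* dissolved sugar content (through
$x_w$) rather than on which sugar it is. A foreign, non-interconverting
sugar then enters the saturation condition only through the mole balance,
and the depression of lactose solubility is predicted with pure
lactose–water parameters:

```{r}
solubility_depression(solubility_model(), c(0, 0.05, 0.10, 0.15), "sucrose")
```

Only the *mole* loading of the foreign sugar matters, so disaccharides
(same molar mass as lactose) mimic beta-lactose exactly, while
monosaccharide predictions are qualitative — consistent with the reported
sugar-specific Margules constants (sucrose $-6.01$ vs glucose $-1.77$),
which this package deliberately does not use in the prediction.

## The dissolution simulator

Dissolving monohydrate powder releases $\chi = M_\alpha/M_{\alpha\cdot H_2O}
= 0.95$ g alpha-lactose and 0.05 g water per gram of crystal. The model
couples (i) mass balances for dissolved alpha, beta and water; (ii)
first-order reversible mutarotation
$r = k_\alpha c_\alpha - (k_\alpha/K_x)c_\beta$ referenced to the solution
mass ($k_\alpha = 0.64\ \mathrm{h^{-1}}$ at 25&nbsp;°C); (iii) a
size-independent linear-driving-force dissolution rate
$D = k_D(x_{\alpha,sat} - x_\alpha)$ with $x_{\alpha,sat}$ from the
solubility product at the current $x_w$; and (iv) a population balance for
the crystal-size distribution, solved by the method of characteristics.

Because $D$ is size-independent, every characteristic translates in
lockstep; the solver therefore integrates a single cumulative shrinkage
coordinate $s(t)$ with $L_i(t) = \max(L_{0,i} - s,\,0)$, which is the exact
method-of-characteristics solution for this rate law. The seed distribution
(Gaussian, mean 10&nbsp;µm, sd 1&nbsp;µm) is discretized into 200
equal-probability quantile characteristics — deterministic by construction,
with a third-moment error of order $10^{-4}$. Complete dissolution is an
integration event: a root on $s - \max L_0$ terminates the solids phase
exactly, after which the smooth solids-free kinetics are integrated
separately (the two-species linear system with relaxation rate
$k_\alpha(1+1/K_x)$, for which `mutarotation_relaxation()` is the closed
form). Dissolution is one-way: the model contains no growth, so the rate is
clamped at zero when the liquid transiently sits at saturation.

Loadings map onto three regimes relative to the saturation concentrations
at mutarotation equilibrium ($c_{\alpha,sat,eq} = 0.0843$ and
$c_{tot,sat,eq} = 0.2191$ g/g water for the defaults): Type I (everything
dissolves in seconds), Type II (saturation first, then mutarotation
undersaturates the liquid and the solid disappears, here after ~1.5 h for
a 0.16 g/g loading), Type III (a saturated suspension persists).
`classify_regime()` computes the boundaries from the *attainable* dissolved
concentration $\chi L/(1+(1-\chi)L)$, which accounts for the water the
hydrate releases and is exactly consistent with the simulator's long-time
behaviour; the Type II/III boundary then sits at a loading of 0.2333 g/g
water. Note that a loading of 0.23 — often quoted as a saturated-suspension
experiment — lies marginally *below* this boundary under the default
parameter set: it is a boundary-band case, and the package classifies it
Type II. Demonstration runs for the persistent-suspension regime therefore
use 0.30 g/g.

```{r}
res <- simulate_dissolution(sim_params(loading = 0.30, horizon = 20))
glance(res)
```

### Time scales, horizons and numerical choices

Dissolution equilibrates the alpha concentration within seconds to minutes,
mutarotation needs hours: in the run above the liquid is within 1% of
saturation about four orders of magnitude sooner than beta reaches 1% of
its equilibrium value. One subtlety the tests respect: while solids are
present, the isomer ratio relaxes at roughly $k_\alpha/K_x = 0.40\ h^{-1}$
— continued dissolution of alpha partially offsets its consumption — which
is slower than the solids-free rate $k_\alpha(1+1/K_x) = 1.04\ h^{-1}$. A
saturated-suspension run therefore needs ~20 h to bring
$|c_\beta/c_\alpha - K_x|/K_x$ below $10^{-3}$, whereas a solids-free
system does so well within 12 h. Demonstration and test horizons are chosen
accordingly (20 h for Type III, 12 h for Type II).

Other numerical commitments, all fixed a priori:

* integrator `deSolve::lsoda`/`lsodar`, `rtol = atol = 1e-12`; at these
  tolerances all three conservation laws (lactose
  $m_\alpha + m_\beta + \chi m_{cry}$, water
  $m_w + (1-\chi) m_{cry}$, total suspension mass) hold to better than
  $10^{-9}$ relative in every regime, comfortably inside the $10^{-8}$
  contract;
* the saturation root is bracketed on $x_w \in (0.9, 1-10^{-9})$ and solved
  to a residual of $10^{-12}$; the thermodynamic functions refuse to
  extrapolate below $x_w = 0.9$ (the calibration range) and raise a
  validity error instead;
* the Gibbs–Duhem quadrature uses the composite trapezoid on $10^4$
  intervals with a step-halving convergence check; the removable singularity
  of the integrand at $x_w = 1$ is evaluated by its limit $2A$;
* time is in hours and sizes in metres internally; `k_D` is accepted in SI
  (m/s) and converted once.

## What the synthetic fixtures emulate — and what they do not

`synth_water_activity()` and `synth_kx_ratio()` generate measurement tables
with the structure the calibration assumes: a Margules-shaped $a_w(x_w)$
curve and a linear $K_x(x_w)$, both with additive homoscedastic Gaussian
noise (symmetric error bars), on a 20-point grid over
$x_w \in [0.96, 0.999]$ spanning dilute to supersaturated solutions. The
defaults ($A = -5.8$, $K^* = 1.60$, slope 1.5, noise sd $5\times10^{-4}$ on
$a_w$ and $0.01$ on $K_x$) are the calibrated lactose values with noise at
the resolution of a dew-point water-activity meter and an HPLC ratio
measurement. What they do *not* emulate: instrument drift, heteroscedastic
replicate variance, correlated errors between the two tables, or any
systematic bias of the metastable-zone protocol by which supersaturated
points are measured. Parameter-recovery tests passing on these fixtures
show the estimators are correctly implemented and correctly calibrated
*under the assumed noise model* — not that real measurements are that
well-behaved.

On interval calibration: `fit_margules()` reports the regression standard
error; with the default 20-point design a $\pm2\,\mathrm{se}$ interval is a
94.0% interval (it is a $t_{19}$, not a normal, pivot), so Monte-Carlo
coverage estimates over a few hundred replicates are expected to land near
0.94, below the nominal 0.954 of the asymptotic $\pm2\sigma$ rule. Users
wanting exact 95% coverage should use `qt(0.975, df)` times the standard
error.

## Known limitations

* Two isomers only; three-isomer systems (e.g. fructose) have no closed
  form here and would need the numerical route.
* All defaults are 25&nbsp;°C values; other temperatures enter only through
  user-supplied parameter sets, never through a built-in temperature model.
* No nucleation, growth, agglomeration or breakage: the population balance
  is dissolution-only.
* The foreign-sugar prediction is quantitative for disaccharides and
  qualitative for monosaccharides, by design (lactose–water parameters
  only).
* The $K_x$ composition slope is exposed but defaults to zero; only
  slope-invariant outputs ($x_{w,eq}$, $K_{sp}$) are unaffected by that
  choice, and per-isomer coefficients with a nonzero slope should be
  treated as sensitivity scenarios until a calibrated slope is supplied.
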