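---
title: "Promoter logic and feedback prediction: models, parameters and numerical choices"
author: "promoterlogic"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(promoterlogic)
```

# The scientific setting

In the LuxI/LuxR quorum-sensing paradigm, the enzyme LuxI synthesizes the
diffusible signal AHL, whose concentration reads out cell density; AHL-bound
LuxR activates the pR promoter. Wiring either LuxI or LuxR back under pR
turns the promoter into a density sensor whose behaviour — smooth induction,
abrupt switching, or hysteresis — depends on the interplay of promoter
biochemistry and feedback topology. This package implements the central
claim of that framework: the two-input *promoter logic function* (PLF) of
pR, measured feedforwardly, contains everything needed to predict the
steady-state responses of feedback circuits built on the same promoter.

# The model

## Promoter logic function

With cell density $\rho$ clamped, the AHL concentration settles to
$A = c\,\rho\,I$, where $I$ is the LuxI level (fluorescence units) and $c$
an AHL-to-density proportionality constant that depends on the growth
protocol. The transcription rate of pR, as a fraction of its maximum
(normalized to 1), is modelled as two nested Hill functions realizing the
two documented cooperativities — AHL-LuxR binding (coefficient $m$) and
LuxR-DNA binding (coefficient $n$):

$$
R^{*} = R\,\frac{A^{m}}{K_A^{m}+A^{m}}, \qquad
f(I, R) = \frac{\varepsilon K_R^{n} + {R^{*}}^{n}}{K_R^{n} + {R^{*}}^{n}}.
$$

The basal activity $\varepsilon$ enters as an additive, LuxR-independent
numerator term: $f = \varepsilon$ when either input vanishes (the AND
property) and $f \to 1$ at saturation. Because $A$ appears only through
$c\rho I$, moving between densities squeezes the surface along the LuxI
axis (`density_rescale()`), and $K_A$ and $c$ are not separately
identifiable from a single-density experiment: fitting estimates the scaled
constant $\tilde c = c\rho/K_A$.

## Circuits

All circuits share $f$; the topology fixes the differential equations
(`ode_rhs()`). In scaled units where $\lambda$ is protein produced per unit
transcription rate (per unit decay):

* feedforward: $\dot Z = \gamma_Z(\lambda_Z f(\bar I,\bar R) - Z)$,
* LuxR feedback: $\dot R = \gamma_R(\lambda_R f(\bar I, R) - R)$,
* LuxI feedback: $\dot I = \gamma_I(\lambda_I f(I,\bar R) - I)$,

with barred symbols clamped by the external regulator. Steady states of a
loop are the fixed points $x = \lambda f(x)$; over a density sweep they
trace the *density-dependent response* (DDR), classified against the
terminal density $\rho_T$ as M (monostable), B+ (threshold crossed before
$\rho_T$), B± (hysteretic at $\rho_T$) or B− (bistable region never
reached).

## Model-independent prediction

Without any fitted model, a feedback steady state must lie where the
measured *input-output characteristic* (a slice of the PLF at fixed
regulator) crosses the *line of equivalence* $y = s\,x$, whose slope is the
ratio of translation rates of the output and input channels, estimated by
an affine calibration fit. The package interpolates IOCs as power laws
(linear in log-log), extrapolates flat beyond the measured range (the
conservative choice: it can only remove, never invent, crossings), and
solves each log-log-linear segment against the line analytically — no
iterative root-finding on this path. Stability follows the 1-D alternation
rule: crossings from above are stable. Measurement uncertainty is
propagated by perturbing log-outputs with Gaussian noise scaled by
replicate standard errors and re-running the procedure (1000 trials by
default), reporting the fraction of trials predicting multistability.

# Default parameters and what they emulate

The study's fitted parameter table is not available in machine-readable
form, so the package ships one documented canonical set
(`default_plf_params()`, `inst/extdata/default_plf_params.tsv`) chosen once
to reproduce the qualitative regime the experiments establish, in arbitrary
fluorescence units:

| parameter | default | meaning / rationale |
|---|---|---|
| $\varepsilon$ | 0.008 | basal fraction; puts the AND surface span just over two decades |
| $K_A$ | 1 | AHL half-saturation (absorbed into $\tilde c$; unit by convention) |
| $K_R$ | 300 | LuxR-DNA half-saturation (fluorescence) |
| $m$ | 2 | AHL-LuxR cooperativity; held fixed during fitting |
| $n$ | 1.45 | LuxR-DNA cooperativity |
| $c$ | 0.04 | AHL per (OD600 × LuxI fluorescence); protocol-specific |
| $\rho$ | 0.1 | nominal grid measurement density (OD600) |

Inducer ranges follow the experimental design: aTc at
$\{0,1,5,10,20,50\}$ ng/ml and IPTG at $\{0,5,10,50,100,500,1000\}$ µM — 42
combinations, three replicates by default (two suffice for the design;
three make replicate SDs estimable). Induction curves are Hill-shaped with
half-saturations inside those ranges.

The default loop strengths (`default_topologies()`) encode the paper's
central contrast deliberately. A 1-D Hill loop with exponent 1.45 and
$\varepsilon = 0.008$ is bistable only for $\lambda/K_{\mathrm{eff}}$ in a
narrow window (≈1.9–2.4); the LuxR loop ($\lambda_R/K_R \approx 1.7$) sits
just below it, so it is monostable at *every* density and regulator level —
the "hardwired" topology. The LuxI loop sees the much steeper effective
exponent $mn = 2.9$ (AHL feedback passes through both Hill layers), whose
window is an order of magnitude wide; with $\lambda_I/K_R = 10$ it runs
through B−, B± and B+ as the regulator rises. This is a structural
asymmetry of the model, not a fine-tuned coincidence.

## Noise model

Measurement noise is multiplicative log-normal with unit mean,
applied independently to both input channels and the output (single-cell
fluorescence is approximately log-normal and replicate averaging is
geometric). The default cv = 0.15 makes Monte-Carlo ensembles visibly
broadened yet unimodal away from bifurcations. cv = 0 reproduces model
output exactly, which the tests exploit for round-trip identities. The
generator emulates replicate-to-replicate scatter only: it does not model
cell-to-cell population structure, background autofluorescence drift, or
instrument nonlinearity, so passing tests certify the analysis chain, not
robustness to those real-data pathologies.

# Estimation choices

* **Log-space residuals.** Noise is multiplicative, so least squares runs
  on log outputs; replicate aggregation is by geometric mean.
* **Moderated weights.** Per-combination SEMs of log output estimated from
  three replicates have two degrees of freedom and are extremely noisy;
  weights use variances shrunk half-way toward the pooled median variance.
  Fully per-point weights let lucky zero-scatter triplets dominate and
  inflate the spread of recovered Hill coefficients several-fold.
* **Fixed $m$.** Freeing $m$ lets it grow without bound (the data only
  bound $m$ from below once AHL binding saturates); `sweep_m()` documents
  the monotone chi-square decrease and the weak dependence of $n$ on $m$.
  $m = 2$ is the working default.
* **Multi-start.** Five log-spaced initializations of the scale-like
  parameters; lowest chi-square wins, ties to the first index.
* **Goodness of fit.** `goodness_of_fit_mc()` refits synthetic datasets
  drawn from the fitted model with the estimated output noise; Q is the
  fraction of synthetic chi-squares above the observed one. Q is
  calibrated against output-channel noise; input-channel noise (which the
  fit treats as exact regressors) biases Q low, so small Q on full-noise
  grids indicates errors-in-variables as much as model misfit.
* **Calibration fits.** Lines of equivalence use ordinary least squares
  (errors-in-variables alternatives were considered out of scope); with
  cv = 0.1 noise on both channels OLS pays a small attenuation price, so
  slope-recovery accuracy sits near, not above, the 95% mark at 10%
  tolerance. The background split between channels is convention-dependent
  and configurable: $b_x$ comes from the zero-inducer reading, $b_y$ from
  the fitted intercept at $b_x$.

# Numerical choices

* **Root finding (1-D loops).** Bracket scan of 512 log-spaced points over
  $[\lambda\varepsilon/10,\,10\lambda]$ (all fixed points lie in
  $[\lambda\varepsilon, \lambda]$), bisection refinement to $10^{-8}$
  relative; stability from the derivative sign, alternation cross-checked.
  Dense-scan oracles (10^4–10^5 points) verify this on randomized instances
  in the test suite.
* **Folds.** Bisection on the root-count change to $10^{-3}$ relative
  density; DDR grids default to 400 log-spaced densities over
  $[10^{-4}, 1]$ OD600 (carrying capacity ≈ 1). The generic 1-or-3-root
  assumption is asserted, never silently patched: other counts flag the
  parameter set.
* **Intersections.** Solved per segment in log-log coordinates; crossings
  closer than $10^{-9}$ log units merge as tangencies with unknown
  stability. Values at or below background are clamped to a positive floor
  ($10^{-6}$ of the channel maximum) before the log transform.
* **Terminal densities.** $\rho_T = 0.05$ OD600 for autonomous loops and
  0.1 for sender-receiver protocols, matching the growth targets of the
  corresponding experiments. The grid is measured at 0.1; LuxI-axis IOCs
  are carried to other densities by the exact input-axis stretch
  (`input_scale` in `ioc_from_grid()`).
* **Oscillator reduction.** LacI is taken at quasi-steady state
  proportional to pR activity, giving the 2-D phase plane
  $\dot R = \gamma_R(\lambda_R f - R)$,
  $\dot I = \gamma_I(\beta_I/(1+(L/K_L)^{h_L}) - I)$ with
  $L = \lambda_L f$; an explicit-LacI 3-D variant is provided because the
  exact reduction used originally is not recoverable. $h_L = 2$ is a
  LacI-cooperativity convention, a package choice. Density is clamped at
  0.185 OD600 (chemostat operating point) and enters only through
  $A = c\rho I$. The default oscillator places the fixed point on the steep
  flank of the LuxR Hill (local logistic slope ≈ 1.2 > 1), so the fixed
  point loses stability when the LuxI response rate $\gamma_I$ drops below
  the Hopf boundary (≈ 0.113 in units of $\gamma_R$); periods are reported
  only when at least three consecutive inter-peak intervals agree within
  5%, on the second half of the run.
* **Problem sizes.** The shipped analyses use 150–400-density DDR sweeps,
  25×25 bifurcation maps over 120 densities, 100-seed fit recovery, 400
  goodness-of-fit trials and 1000-trial Monte-Carlo predictions; these
  sizes give boundary locations stable to about a grid cell and Monte-Carlo
  fractions stable to a few percent, and are the package's reference
  configuration.

# Known limitations

* Quantitative correspondence with the original study's fluorescence
  magnitudes is not attempted: the raw measurements and fitted constants
  were never deposited, so all fluorescence units here are arbitrary and
  self-consistent only within the synthetic study design.
* The model-independent route predicts from a 6- or 7-node characteristic;
  near folds, interpolation error and measurement noise blur bistability
  (the shipped analysis shows a hysteretic slice recovered with a 27%
  multistable trial fraction rather than deterministically).
* Stability labeling of intersections relies on the 1-D monotone-response
  argument; it is validated against ODE basins in the tests but carries no
  formal monotone-systems proof, and tangencies are deliberately labeled
  `unknown`.
* The oscillator analysis is a proof of principle in arbitrary time units;
  no attempt is made to match experimental periods or amplitudes, and
  density-clamp transients (the AHL priming protocol) are out of scope.
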