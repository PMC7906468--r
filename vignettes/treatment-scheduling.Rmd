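---
title: "Growth-rate heterogeneity, treatment scheduling and relapse: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-rate heterogeneity, treatment scheduling and relapse: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoswitch)
```

## The model

`phenoswitch` treats a tumour as an ecological community of $\Omega$
subpopulations that differ in a single phenotypic trait, their intrinsic
growth rate. Growth rates increase linearly from $r_{\min}$ (slowest class)
to $r_{\max}$ (fastest class) along a trait axis $v_i \in [0,1]$. Every
subpopulation grows exponentially; heterogeneity is maintained by
phenotypic switching between adjacent classes, and switching is tied to
division: a dividing cell's daughter lands in the next-slower class with
probability $p_S$ and in the next-faster class with probability $p_F$, so
switching fluxes are proportional to growth rates.

Two treatment types act on this community:

* **trait-dependent treatment** (cell-cycle-specific chemotherapy): per-cell
  mortality $\delta\, r_i$, proportional to how fast the cell divides;
* **trait-independent treatment** (e.g. antibody-mediated immunotherapy):
  per-cell mortality $m$, identical for all classes.

For interior classes,
$$
\frac{dx_i}{dt} = (1 - p_S - p_F)\, r_i x_i
  + p_S\, r_{i+1} x_{i+1} + p_F\, r_{i-1} x_{i-1}
  - (\delta r_i + m)\, x_i .
$$
At the two ends of the trait axis the disallowed switching direction is a
null event, so the slowest class keeps $(1-p_F) r_1 x_1$ of its own
divisions and the fastest keeps $(1-p_S) r_\Omega x_\Omega$. The system is
linear, $\dot{x} = A x$ with tridiagonal $A$ (`system_matrix()`), which has
three consequences the package leans on:

1. **Scale invariance.** Multiplying the initial state by $c$ multiplies
   every trajectory by $c$; frequencies, relapse times relative to a
   relative reference, and the calibrated $m$ do not depend on the absolute
   population size. The detection load (default $10^{10}$ cells) is
   therefore cosmetic.
2. **Uniform-mortality factorization.** A trait-independent mortality
   contributes $-mI$ to $A$, so
   $x(t) = e^{-mt}\, x_{\text{untreated}}(t)$ exactly. Frequencies, and
   hence trait diversity, are untouched by trait-independent treatment.
3. **Stable trait distribution.** The frequencies converge to the
   (Perron) eigenvector of the untreated $A$, with asymptotic growth at the
   dominant eigenvalue $\lambda^*$; since the fastest class loses a fraction
   $p_S$ of its divisions, $(1-p_S) r_{\max} < \lambda^* < r_{\max}$.

### Reference parameters

| parameter | meaning | default |
|---|---|---|
| $\Omega$ | number of subpopulations | 25 |
| $r_{\min}$ | slowest growth rate | 0.25 / time unit |
| $r_{\max}$ | fastest growth rate | 0.5 / time unit |
| $p_S$, $p_F$ | switching fractions per division | 0.2, 0.2 |
| $\delta$ | trait-dependent mortality factor | 2 |
| $m$ | trait-independent mortality rate | calibrated, 0.86 / time unit |
| $T$ | treatment duration | 150 time units |
| monitoring | post-treatment window | 150 time units |

Time units are treated as days when labelling outputs; all computations are
unit-agnostic.

### Equilibration

Scenarios start from the stable trait distribution: the untreated system is
integrated for 200 time units from the exponential seed
$x_i = 10^{-60} e^{80 v_i}$, which loads almost all mass near, but not on,
the fastest class. Because abundances grow without bound, `equilibrate()`
integrates in chunks and renormalizes the total whenever it leaves a wide
window — the system is linear, so only the frequencies matter and they are
unaffected. After 200 units the frequencies agree with the dominant
eigenvector to about $10^{-5}$ (sup-norm); the eigen-oracle tests use a
600-unit burn-in, where agreement is below $10^{-8}$.

## Calibration of the matched mortality

To compare treatment types at equal effect, $m$ is chosen so that the total
load at the end of treatment equals that of the trait-dependent treatment.
The factorization above makes this a closed form,
$$
m^* = \frac{1}{T}\,
  \log\!\frac{X_{\text{untreated}}(T)}{X_{\text{dep}}(T)},
$$
with both loads started from the equilibrated distribution. A bracketed
root-finder on $m \mapsto \log X_{\text{indep}}(T;m) - \log X_{\text{dep}}(T)$
(strictly decreasing, slope $-T$) is implemented as an independent route and
agrees with the closed form to the requested tolerance ($10^{-8}$ relative
on the matched loads). At the defaults, $m^* \approx 0.86$ per time unit.

## Treatment schemes

* **Predefined sequences** split $[0, T]$ into $n$ equal intervals (8 by
  default, giving $2^8 = 256$ sequences, at most 7 alterations) and assign
  one treatment type per interval. Equal intervals are the symmetric
  reading of an $n$-interval sequential design; no other split is offered.
* **Realistic adaptive schemes** re-decide every $\Delta t$: at
  $t = 0, \Delta t, 2\Delta t, \dots$ the type with the larger current
  population mortality is applied, comparing
  $\sum_i \delta r_i x_i$ against $m \sum_i x_i$ — equivalently, applying
  the trait-dependent type iff the mean trait
  $\bar{r} = \sum r_i x_i / \sum x_i$ exceeds $m/\delta$. The first
  decision is taken at treatment start, so $\Delta t \ge T$ degenerates to
  the single-type scheme favoured by the initial distribution (the
  trait-dependent one, since the pre-treatment distribution is fast-heavy).
  Exact ties keep the current type, preventing chatter at the
  equal-mortality manifold.
* **The optimal adaptive scheme** is the $\Delta t \to 0$ limit.

### The continuous-reevaluation limit is a sliding mode

Starting from the stable distribution the rule picks the trait-dependent
type, which drives $\bar{r}$ down until the mortality terms are equal
($\bar{r} = m/\delta$; about $t \approx 51$ at the defaults). On that
manifold each pure type pushes the balance back across it —
trait-dependent treatment lowers $\bar{r}$, while under trait-independent
treatment the frequencies evolve as if untreated and $\bar{r}$ rises — so
continuous reevaluation alternates infinitely fast and the limit dynamics
slide *along* the manifold (a Filippov sliding mode). The package
integrates the sliding motion as the convex combination of the two vector
fields, an effective setting $(\alpha\delta,\ (1-\alpha) m)$ with
$$
\alpha(x) =
 \frac{c^\top A_0 x - m\, c^\top x}{\sum_i c_i^2 x_i},
 \qquad c_i = \delta r_i - m,
$$
the unique fraction that keeps $g(x) = c^\top x$ (the mortality imbalance)
constant. The sliding state converges to a quasi-stationary shape: the
dominant eigenvector of $A_0 - \alpha^*\delta R - (1-\alpha^*) m I$ whose
mean trait is exactly $m/\delta$, with per-capita net growth
$\bar r - \max(\delta\bar r, m) = -m/\delta$. If $\alpha$ ever leaves
$[0,1]$ the scheme exits to the pure type favoured on the side it leaves
towards; at the reference parameters it never does
($\alpha^* \approx 0.486$).

Two numerical safeguards matter here:

* Solving for $\alpha$ enforces $dg/dt = 0$ at whatever value $g$ has, so
  integration error in $g$ is never corrected and off-manifold
  perturbations grow. The implementation targets $dg/dt = -\kappa g$
  instead ($\kappa = 10$ per time unit), which coincides with the exact
  fraction on the manifold and restores it exponentially off it. Without
  this, the computed fraction drifts off $[0,1]$ after roughly 50 time
  units of sliding.
* The sliding state decays by tens of orders of magnitude over the
  treatment window. The sliding field is 1-homogeneous, so the state is
  renormalized every 5 time units and the absolute scale carried in log
  space, exactly as in the equilibration.

With both in place the sliding solution reproduces a brute-force
realization of the limit (re-deciding every 0.1 time units) to four
significant digits in the end-of-treatment load, and the mean trait stays
within $10^{-6}$ of $m/\delta$ after the transient.

One subtlety is worth recording: the instantaneous per-capita kill rate of
the adaptive rule is $\max(\delta\bar r, m)$, a convex function of
$\bar r$. A scheme chattering with finite $\Delta t$ oscillates around the
manifold and therefore averages a kill rate slightly *above* the sliding
value, so realistic adaptive schemes with small $\Delta t$ can end a
fraction of a percent below the sliding limit's load. The optimality
statement checked by the tests — no predefined sequence beats the
continuous scheme's end-of-treatment load — is unaffected.

## Outcome metrics

* **Minimum tumour load** is taken over the treatment window on the dense
  output grid (10 points per time unit by default). At the reference
  parameters the per-capita net growth rate is negative under both
  treatment types ($\delta > 1$ makes it $-\bar{r}$; the calibrated $m$
  exceeds $r_{\max}$'s net rate), so the load declines monotonically during
  treatment and the minimum equals the end-of-interval value; the grid
  introduces no error there.
* **Relapse time** is the first time after treatment initiation at which
  the total load *strictly* exceeds a reference: the pre-treatment maximum
  (default), the load at treatment initiation, or an absolute cell count
  (the stochastic analysis uses 1000 cells). The crossing is located by
  root-finding on the log-linear interpolant between the bracketing output
  points; since regrowth is locally exponential this is accurate to well
  below $10^{-6}$ time units at the default grid. Runs that never cross are
  reported censored.
* **Trait diversity** is Pielou's Shannon evenness
  $-\sum f_i \ln f_i / \ln \Omega \in [0, 1]$. The normalization by
  $\ln \Omega$ is chosen so that the measure is 1 for a uniform
  distribution and comparable across $\Omega$; a single-class population
  returns 0 by convention.
* **Step-size statistics** pool per-interval increments of diffusion-only
  paths across replicates and report
  $\Delta\sigma/\bar\sigma = (\sigma_{\text{fast}} - \sigma_{\text{slow}})
  / \text{mean}(\sigma_{\text{slow}}, \sigma_{\text{fast}})$.

## The two-class stochastic model

Near the end of treatment the population is small and extinction and
relapse become stochastic. The stochastic counterpart keeps the two extreme
classes ($r_{\min}$, $r_{\max}$), whose dynamics differ the most, and is
built from the same microscopic processes as the deterministic model, so
the mean field of the reaction set equals the two-class system exactly
(this is an oracle test).

Two microscopic switching schemes share that mean field but differ in
noise. The default ties switching to division — a dividing mother stays,
the daughter is born into the adjacent class — because switching rates are
proportional to growth rates and own-class births carry no loss term. The
alternative (plain births plus independent cell moves between classes) is
exposed behind `switching = "moves"` for sensitivity analysis.

* `gillespie_simulate()` draws statistically exact jump paths (direct
  method, compiled; propensities are linear in the counts), absorbing at 0
  total cells, and records first-passage times over a relapse threshold.
* `sde_simulate()` integrates the Langevin approximation
  $dx = a(x)\,dt + V^{-1/2} B(x)\,dW$ by Euler–Maruyama, with
  $B B^\top = \sum_j a_j(x)\, s_j s_j^\top$ assembled from the reaction set
  (propensities $a_j$, stoichiometries $s_j$); the system-size parameter
  $V$ defaults to 25 and the step to $dt = 0.01$. The matrix square root
  uses the closed form for symmetric 2×2 matrices. Paths are reflected at
  zero by clipping; extinction *probabilities* are computed with the jump
  engine, where absorption is exact, not with the SDE.
* `diffusion_only_simulate()` integrates the noise term alone
  ($a \equiv 0$) and feeds the step-size analysis: under trait-dependent
  treatment the diffusion diagonal grows proportionally to $r_i$, widening
  the gap between the classes' step sizes, whereas a trait-independent
  mortality adds equally to both diagonal entries and narrows it. The slow
  class's smaller steps make it a refuge against extinction.

The stochastic reference scenario is chosen so that the deterministic
two-class solution ends the treatment near one cell, the regime where
stochastic fates split: 1000 initial cells on the stable two-class
distribution (about 310 slow, 690 fast), treatment for 25 time units,
monitoring for 50, relapse at 1000 cells. These values are this package's
choice of a realistic minimal-residual-disease scenario; the matched
trait-independent mortality for a 25-unit two-class treatment calibrates to
about 0.73 per time unit (the package also accepts the constant 0.722 used
as the default treatment-phase mortality). Replicate ensembles draw one
sub-seed per replicate from the master seed, so individual replicates can
be reproduced in isolation.

## Numerical choices

* Integration uses `deSolve::lsoda` (stiff-capable, adaptive) with
  `rtol = 1e-10` and `atol = 1e-60`; the absolute tolerance sits far below
  the $10^{-60}$ equilibration seed so that accuracy is carried by the
  relative tolerance across the ~60 orders of magnitude the states span.
* Treatment switching events (the mortality-balance root in the optimal
  scheme) are located by `deSolve::lsodar`'s root-finder, not by grid
  scanning.
* Output density defaults to 10 points per time unit; metrics that depend
  on event timing refine on the interpolant as described above.
* Abundances are clipped at zero only at solver output (they are
  non-negative analytically; clipping removes $-10^{-40}$-scale wobble).

### Problem sizes used by the tests

The test suite runs the full 256-sequence sweep plus a 13-value
reevaluation-period family and the optimal scheme (about 300 stiff solves
of the 25-class system, ~15 s), stochastic ensembles of 400–1000
replicates, diffusion-only ensembles of 20 replicates × 2000 steps, and
small (2–5 class) models for closed-form oracles. These sizes were
chosen to keep Monte-Carlo standard errors well inside the tested margins.

## What the simulator does and does not capture

The model is deliberately minimal: exponential (density-independent)
growth, a single heritable-or-plastic trait, memoryless switching tied to
division, instantaneous treatment effect with no pharmacokinetics, no
spatial structure, no acquired resistance mechanism other than the trait
itself, and mutually exclusive treatment types. Passing tests demonstrate
the internal consistency of this idealization — calibration, scheme
orderings, sliding-mode optimality, stochastic refuge effects — not that a
clinical population obeys it. Absolute population sizes are arbitrary in
the deterministic model; only the stochastic model attaches meaning to
"one cell". The relapse-time definition matters near censoring boundaries,
which is why both relative references and the absolute threshold are
exposed as options.
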