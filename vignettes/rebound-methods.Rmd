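---
title: "Receptor rebound in TMDD models with feedback: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor rebound in TMDD models with feedback: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmddrebound)
```

## The model and its assumptions

The core model is the one-compartment target-mediated drug disposition
(TMDD) system for ligand $L$, receptor $R$ and complex $P$, extended
with homeostatic negative feedback on the receptor synthesis rate via a
moderator $F$:

$$
\begin{aligned}
\dot L &= -k_{e(L)} L - k_{on} L R + k_{off} P,\\
\dot P &= k_{on} L R - k_{off} P - k_{e(P)} P,\\
\dot R &= k_{in} F - k_{out} R - k_{on} L R + k_{off} P,\\
\dot F &= \alpha\,(H(R) - F),
\end{aligned}
$$

started at the drug-free baseline $R_0 = k_{in}/k_{out}$ with a bolus
$L(0) = L_0$, $F(0) = 1$.  The feedback function $H$ is positive,
fixes the baseline ($H(R_0) = 1$), increases synthesis below baseline
and decreases it above, and is $C^2$.  $\alpha \ge 0$ is the feedback
response speed: $\alpha = 0$ recovers the classical TMDD model, and
$\alpha \to \infty$ the quasi-equilibrium "direct feedback" model with
$F = H(R)$.

Everything is analysed in dimensionless form ($x = L/L_0$, $y = R/R_0$,
$z = P/R_0$, $w = F$, $\tau = k_{on} R_0\, t$), with rates
$\mu, k_1, k_2, k_3, k_4$, feedback speed
$\epsilon = \alpha/(k_{on} R_0)$, and the feedback slope at baseline
$h_0 = -h'(1)$ where $h(y) = H(R_0 y)$.  Dimensional simulation is
performed by converting to this form, integrating, and mapping time
back via $t = \tau/(k_{on}R_0)$; this conditions the system well and
keeps the baseline Jacobian in the literal block form used by the
theory.  The state ordering is fixed as $(x, z, y, w)$ throughout, so
the Jacobian is block lower-triangular in the $(x,z)/(y,w)$ split.

*Rebound* means: after the post-dose dip, the receptor exceeds its
baseline during the return to steady state.  The key theoretical fact
is that the baseline is globally asymptotically stable, and generic
trajectories approach it tangent to the eigenvector of the eigenvalue
(real part) closest to zero — so the sign structure of that eigenvector,
together with invariant-region arguments, decides rebound.

## Why the classifiers look the way they do

The classification logic is organised by model variant:

* **No feedback.** Rebound iff $k_4 < k_1$ and $k_4 < k_3$ (complex
  eliminated more slowly than both ligand and receptor).  This is an
  iff with strict inequalities; the classifier never returns
  "indeterminate" here.
* **Direct feedback.** The receptor eigenvalue becomes
  $-k_3(1 + h_0)$, and two secant bounds of the feedback function,
  $m = \inf_{[0,1)} \frac{h(y)-1}{1-y}$ and
  $M = \sup_{[0,1)} \frac{h(y)-1}{1-y}$ (with the $y \to 1$ limit
  $h_0$ injected), bracket $h$ between two lines through $(1,1)$.
  They give a no-rebound region ($k_1 \le k_4$, or
  $k_3 \le k_4/(1+M)$) and a rebound region
  ($k_1 > k_4$ and $k_3 > \min(k_4/(1+m), -\lambda_1/(1+h_0))$),
  separated by a band where the outcome genuinely depends on the
  particular $h$; for mainly linear feedback $m = M = h_0$ and the
  band is empty.
* **Moderator feedback.** The receptor–moderator block has eigenvalues
  $\lambda_{3,4}(\epsilon)$ that start at $-k_3$ and $0$, collide at
  $\epsilon_1^-$, are complex until $\epsilon_1^+$, and tend to
  $-\infty$ and $\lambda_\infty = -k_3(1+h_0)$.  The classifier
  determines which row of the final rebound summary applies (position
  of $\lambda_1$ relative to $\lambda_*^\pm$ and $\lambda_\infty$) and
  whether $\epsilon$ lies in the proven rebound interval.  A deliberate
  design decision: **this classifier never returns "no rebound"**.
  The theory proves only rebound results for finite positive feedback
  speed; cells outside the proven intervals are reported indeterminate
  and can be resolved by simulation.  We preferred not to overclaim
  beyond what is proven.
* **Generalised models** (multi-compartment PK, nonlinear moderator
  dynamics $\dot w = \epsilon g(y, w)$): rebound is guaranteed for
  $0 < \epsilon < \min(\epsilon_1^-, \tilde\epsilon_2)$, where
  $\tilde\epsilon_2$ is where the moderator-block eigenvalue nearest
  zero crosses the leading PK-block eigenvalue.  We compute
  $\tilde\epsilon_2$ in closed form from the block's characteristic
  polynomial; when the crossing does not occur on the real branch the
  threshold is effectively $\epsilon_1^-$.

Boundary cases (eigenvalue collisions $\epsilon = \epsilon_1^\pm$,
crossings $\epsilon = \epsilon_2, \epsilon_3$, the line
$\lambda_1 = \lambda_\infty$) are detected with relative tolerance
$10^{-12}$ and classified as rebound only where the theory proves the
boundary itself rebounds (e.g. the $\epsilon = \epsilon_2$ collision
with an eigenvector/generalised-eigenvector pair); otherwise they fall
into the indeterminate outcome.  At the pole
$\lambda_1 = \lambda_\infty$ the crossing speed $\epsilon_2$ diverges;
it is reported as undefined and treated as $+\infty$ for
classification.

## The mainly linear tail: a constructive choice

The "mainly linear" family is exactly $1 + h_0 (1 - y)$ up to
$y_\beta = 1 + \beta/h_0$ and must continue with a $C^2$ tail with
value $1-\beta$, slope $-h_0$, zero second derivative at the junction,
staying strictly inside $(0,1)$.  The theory constrains only these
junction conditions, not the tail's shape.  We use

$$h_1(y_\beta + s) = (1-\beta) - h_0\,\sigma \tanh(s/\sigma),
\qquad \sigma = \frac{1-\beta}{2h_0},$$

the simplest smooth ($C^\infty$) closed form matching all three
conditions, with range $((1-\beta)/2,\, 1-\beta]$.  Since the rebound
theory for this family only ever evaluates $h$ on $[0, y_\beta]$, the
tail choice cannot affect any verdict; it only matters for simulating
large receptor excursions, which do not occur from the standard
initial condition.

For custom feedback functions the secant bounds are computed on a
2048-point grid over $[0,1)$ with the endpoint limit $h_0$ injected
explicitly (the inf/sup runs over a half-open interval, so the limit
contributes but is never sampled) and a bounded local refinement
around the grid extrema via `optimize`.  Packaged families use closed
forms.

## Numerical choices

* **Integrator.** `deSolve::lsoda` with `rtol = 1e-10`,
  `atol = 1e-12` by default and unrestricted steps; when lsoda's
  dense-output interpolation fails near numerical equilibrium (a rare
  solver quirk at very fast parameter draws) the same problem is
  re-run with the BDF method.  The output grid is dense over the dip
  and log-spaced to the horizon.
* **Horizon.** `"auto"` sets the horizon to $60/r$ where $r$ is the
  slowest spectral decay rate at baseline (at least 200, capped at
  $10^7$); `"to_steady_state"` doubles the horizon until the state is
  within $10^{-10}$ of baseline in sup norm.  Slow eigenvalues near
  degeneracies have long tails, hence the spectral link.
* **Rebound detection.** A trajectory rebounds when, after first
  falling below $1 - \delta$, the receptor exceeds $1 + \delta$; the
  relative threshold $\delta = 10^{-6}$ by default.  $\delta$ is an
  explicit artifact parameter, not a theoretical constant: the
  rebound magnitude tends to zero as $\epsilon \to 0$ and at region
  boundaries, so any detector has a floor, and the threshold is
  surfaced in every result.  Near-boundary verification (in the test
  suite's concordance sweeps) refines marginal cells at
  `rtol = 1e-12`, `atol = 1e-15`, $\delta = 10^{-12}$ before calling
  a disagreement; overshoots of order $10^{-12}$ are resolved
  reliably at those tolerances.
* **Feedback-speed scans.** The largest rebounding $\alpha$ is located
  by bisection (absolute tolerance $10^{-3}$) after bracketing on a
  16-point log-spaced pre-scan of $(10^{-3}, 1.2]$.
* **Oscillatory approaches.** When the moderator-block pair is complex
  and dominant, rebound recurs infinitely often with exponentially
  decreasing amplitude; `detect_rebound` reports the global post-nadir
  maximum, which is then the first and largest local maximum.

## The psoriasis model

The five-state efalizumab model (PK depot/central/peripheral in
µg/kg, total %CD11a, and its production rate as moderator) is
implemented exactly as published, with two deliberate additions:

* The feedback Michaelis constant `Kmc03` is absent from the published
  parameter list.  We derive it by asserting a baseline total %CD11a
  of $Y_0 = 100$ — the natural normalisation for a percentage
  variable — which forces $F_0 = k_{30} Y_0 / k_{03max} = 0.1329$ and
  $K_{mc03} = k_{03max} F_0^2 / (k_{30}(1 - F_0)) = 15.33$.  This is
  also the unique choice consistent with the published
  moderator-block eigenvalue $-1.37\times 10^{-2}$.  $Y_0$ remains an
  explicit, overridable parameter.
* The default moderator rate is `koff = 0.0154`/day (the modified
  value needed to reproduce the published rebound magnitude); the
  originally reported `0.00154`/day ships as a named alternative
  fixture and yields a smaller rebound, about 110% of baseline.  The
  published binding-affinity inconsistency (0.033 µg/mL reported,
  versus ~2 pM implied by `koff`/`kon`) has no computational
  resolution; we inherit the parameter set as printed.

The reduction to the generalised framework uses
$k_3 = k_{30}/V_{m2}$, $\epsilon = k_{off}/V_{m2}$, and the hyperbolic
feedback $h(y) = 1/(F_0 + (1-F_0)y)$ with $h_0 = 1-F_0$.  Dose studies
default to a 150-day horizon: the dominant slow rate is about
$0.0138 \cdot V_{m2} \approx 0.03$/day, so the rebound peak (observed
at day ~52 for a 3 mg/kg IV dose) sits well inside the window; the
low-`koff` variant uses 400 days for the same reason.

## What the tests do and do not show

The test suite verifies the implementation against independent
numerical oracles: dense eigendecompositions of the printed Jacobians
(300–500 random draws), characteristic-polynomial roots for the PK
block, finite-difference Jacobians for the reduction consistency, and
— most importantly — classifier-versus-simulator concordance on
$12 \times 12$ log-spaced grids over $(k_1, k_3)$ under four
model/feedback settings, with indeterminate cells exempt.  Property
sweeps check positivity and global attraction (60 random draws at
`rtol = 1e-8`), the total-receptor plane bounds in both regimes, the
moderator-sign property and its rebound shortcut, and the
$\epsilon \to 0$ and $\epsilon \to \infty$ spectral limits.  Problem
sizes (grid resolutions, draw counts, solver tolerances per sweep)
were chosen so the full suite represents each property densely while
staying desk-scale; they are stated in the test files.

Two caveats on interpretation.  First, all simulated verification uses
the standard bolus initial condition; "generic" rebound excludes a
measure-zero set of initial conditions, so concordance on these runs
is evidence for the generic statement, not a proof.  Second, the
synthetic parameter draws (log-uniform rates over $[10^{-2}, 10^2]$)
probe the mathematical structure, not the distribution of real drug
parameters; real antibody programmes live in a small corner of this
space, and features such as multiple dosing, absorption compartments
for the core model, and inter-individual variability are out of scope.

## Known limitations

* The full-model classifier cannot certify absence of rebound for
  finite $\epsilon > 0$; "indeterminate" there means "not provable
  with these methods", and simulation at a detection threshold is the
  only recourse.
* Rebound magnitude is not predicted by the theory — only its
  occurrence.  The scan utilities measure magnitude numerically.
* Detection cannot distinguish rebound below the threshold $\delta$
  from no rebound; near region boundaries the magnitude vanishes, so
  boundary cells are intrinsically threshold-dependent.
* The $C^2$ validator checks smoothness by a mean-value-theorem
  surrogate on a grid; a function with a removable corner in its
  derivative between grid points can evade it.
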