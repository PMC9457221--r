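---
title: "Quantifying feedback control by mathematically controlled comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying feedback control by mathematically controlled comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cora)
```

## The metric

Consider a biochemical network written as ODEs with parameters $\Theta$, a
controlled species $Y$, and a designated feedback signal $f_\Theta(Y)$ — the
one term through which $Y$ influences the rest of the network. The package
quantifies the loop's contribution to adaptation by comparing the intact
system against its *locally analogous system without feedback*: the same
equations with $f_\Theta(Y)$ replaced by a constant input equal to its value
at the intact system's steady state. By construction both systems rest at the
identical steady state (all species, not just $Y$) and share every local
nonlinearity and saturation. After the same small multiplicative perturbation
$\rho \to \rho\,\lambda$ of a parameter $\rho \in \Theta$, the control ratio
is

$$\mathrm{CoRa}_\Theta(Y,\rho) \;=\;
\frac{\Delta\log Y}{\Delta\log Y_{NF}} \;=\;
\frac{\log(Y'/Y^*)}{\log(Y_{NF}'/Y^*)},$$

with $Y'$ and $Y_{NF}'$ the perturbed steady states with and without
feedback. A ratio of 0 is perfect adaptation, 1 is an ineffective loop,
values in $(0,1)$ grade attenuation, and values outside $[0,1]$ (amplifying
or overshooting loops) are reported as-is, without clipping. The ratio does
not depend on the logarithm base.

### Constructing the analogue

The feedback is routed through the single reserved symbol `F` in the rate
expressions; model authors route *all* of $Y$'s influence through it.
Freezing (`freeze_feedback()`) pins the **species** dependence of the
feedback expression at the reference steady state while leaving parameter
symbols live. At the freezing parameter set the input equals the constant
$f_\Theta(Y^*)$ exactly; under a subsequent perturbation of a parameter that
appears inside $f$ (say the feedback gain itself), the analogue's input
scales with that parameter, as a constitutive replacement of the feedback
link would. Freezing the whole expression to one number would instead make
such perturbations — and the open-loop fixture's only parameter —
unreachable in the comparison system, producing 0/0 ratios for cases whose
answer is plainly defined. Species values are never re-frozen after the
perturbation: the comparison is anchored at the pre-perturbation state.

`verify_locally_analogous()` checks the construction by re-solving the
analogue from a neutral initial condition and comparing against the
reference state. Two situations legitimately fail this check and are
reported loudly rather than patched: an analogue with a conserved linear
combination (see below) settles on a different leaf of its foliation when
started elsewhere, and an analogue whose frozen input removed the only
stabilising influence has no attracting state at all.

## Steady-state solver

`solve_steady_state()` uses integrate-then-refine:

1. **Stiff integration** (`deSolve::lsoda`) from a cold start of $10^{-6}$
   for every species, over geometrically growing windows up to a horizon of
   $10^7$ minutes — comfortably beyond the slowest shipped timescale
   (dilution at $10^{-4}\,\mathrm{min}^{-1}$ relaxes in $\sim 10^4$ min).
   Integration selects the dynamically reached attractor and is the reason a
   limit cycle is reported as *no steady state* rather than as a spurious
   root.
2. **Damped Newton refinement** of the rate function with a central
   finite-difference Jacobian, triggered once the trajectory is roughly
   settled. The linear solve uses an SVD pseudo-inverse, so rank-deficient
   Jacobians (conservation laws) take the minimum-norm step, which preserves
   conserved quantities to first order. Refinement is accepted only if the
   residual falls below $10^{-10}$ with the state in the nonnegative
   orthant, and iterates on toward machine residual because ill-conditioned
   fixed points (a near-zero slow eigenvalue) amplify residual into state
   error by the condition number.

The residual is componentwise: each $|\dot x_i|$ is scaled by
$\max(|x_i|,\,10^{-6}\max_j |x_j|,\,10^{-6})$. A max-norm residual would let
a pseudo-root hide an $O(0.1)$ drift on a trace species behind a large one —
a real failure mode here, since the saturated antithetic regime pairs
concentrations of order $10^7$ with partners of order $10^{-7}$.

### Stability and conservation laws

Validity of the metric requires both perturbed systems to reach *stable*
steady states. The strict primitive `is_stable()` demands all Jacobian
eigenvalue real parts below $-10^{-9}$; a marginal zero mode fails it.
`solve_steady_state()` refines this judgement: an eigenvalue within
tolerance of zero whose left eigenvector $v$ satisfies $v^\top f(x) \equiv 0$
(checked numerically at several probe states) spans an exactly conserved
linear combination. Motion along such a direction is fixed by the initial
condition, so it is excluded from the stability verdict. The canonical case
is the frozen analogue of the *ideal* antithetic motif ($\gamma = 0$): with
the feedback signal constant and equal to $\mu_W$, $W - U$ is conserved, the
Jacobian has an exact zero eigenvalue, and yet the state reached from the
shared pre-perturbation steady state is perfectly well defined. Without this
refinement the framework's own flagship case — perfect adaptation of the
ideal antithetic controller — would be rejected as unstable.

### Initial conditions

The base (unperturbed) feedback solve is a cold start. The two perturbed
solves start from the shared pre-perturbation steady state — the physically
meaningful initial condition, since both systems rest there when the
perturbation lands; for an analogue with a conserved direction it is also
the only start that stays on the correct leaf. During sweeps the base solve
can warm-start from the previous grid point; it is then cross-checked
against a cold start, and disagreement beyond $10^{-6}$ relative marks the
point `ambiguous_multistable` rather than silently choosing a branch.

## Perturbation size

The default fold is 1.05 (a 5% increase). The metric approximates a ratio of
logarithmic gains; 5% balances finite-difference noise (too-small folds
divide two tiny log-changes) against nonlinearity bias (large folds leave
the linear regime). The suite checks that folds 1.01 and 1.001 agree within
$5 \times 10^{-3}$ and that up- and down-perturbations agree to
$O(\lambda - 1)$, so conclusions do not hinge on the choice. Ratios with
$|\Delta\log Y_{NF}| < 10^{-12}$ are reported `undefined_denominator`: the
perturbation does not reach the output even without feedback, and the ratio
is genuinely 0/0. One instructive instance: jointly perturbing `mu_Y` and
`gamma_Y` by the *same* fold cancels exactly in the no-feedback output.

## The motif library

All rates are per minute; concentrations are arbitrary units. Defaults are
this package's reference parameterization, chosen so that each motif sits in
its scientifically interesting regime; the qualitative claims the tests
assert (bounds, limits, transitions) are robust across parameter ranges, and
the property suites draw parameters log-uniformly around the defaults.

* **`atf_v1()`** — antithetic feedback with an explicit annihilation complex:
  $W$ and $U$ bind at rate $\eta_+$ into a complex $C$ degraded at $\eta_-$;
  $W$ drives synthesis of $Y$ at $\mu_Y$; $Y$ induces $U$ at $\mu_U$
  (the feedback signal); $W, U, C$ are individually diluted at $\gamma$
  ($10^{-4}\,\mathrm{min}^{-1}$ by default, the slow dilution due to growth),
  and $Y$ has its own removal $\gamma_Y$. Defaults: $\mu_W = 0.1$,
  $\mu_U = \mu_Y = 0.125$, $\eta_+ = 0.05$, $\eta_- = 0.5$,
  $\gamma_Y = 0.1$. With $\gamma = 0$ the motif is the ideal antithetic
  integral controller: $\mathrm{d}(W-U)/\mathrm{d}t = \mu_W - \mu_U Y$
  integrates the setpoint error, pinning $Y^* = \mu_W/\mu_U$ and giving
  $\mathrm{CoRa} = 0$ for perturbations of $\mu_Y$. With $\gamma > 0$ the
  integral action leaks and adaptation degrades at low and high $\mu_Y$,
  while remaining near-perfect around the nominal regime.
* **`atf_v2()`** — identical except $C$ retains activity,
  $\mathrm{d}Y/\mathrm{d}t = \mu_Y (W + C) - \gamma_Y Y$ (both with the same
  rate constant $\mu_Y$; a distinct constant for $C$ would be a one-line
  model-document edit). Because the annihilation flux bounds $C$ at
  $\mu_W/(\eta_- + \gamma)$, the complex saturates past a threshold
  $\mu_Y$ and control collapses abruptly from near 0 to 1 — the sweep
  summary's transition detector (adjacent-point jump > 0.5) flags it.
* **`fb_hill(n)`** — two-species repression loop,
  $\mathrm{d}W/\mathrm{d}t = \mu_W/(1 + (Y/K)^n) - \gamma W$,
  $\mathrm{d}Y/\mathrm{d}t = \mu_Y W - \gamma Y$ (defaults
  $\mu_W = \mu_Y = K = 1$, $\gamma = 0.1$). Implicit differentiation of the
  steady-state balance gives the closed-form gain
  $1/(1 + n\sigma/(1+\sigma))$ with $\sigma = (Y^*/K)^n$, an independent
  oracle for the numeric pipeline (`closed_form_cora_hill()`). Its infimum
  is $1/(1+n)$: Michaelian repression ($n = 1$) can never beat 1/2, and
  ultrasensitivity lowers the floor. The Hill coefficient is an ordinary
  model parameter so it can itself be swept.
* **`open_loop()`** — $\mathrm{d}Y/\mathrm{d}t = F - \gamma Y$ with $F$ a
  constant; freezing is the identity and the ratio is 1 for any
  perturbation, anchoring the "ineffective feedback" end of the scale.

## Problem sizes and determinism

The canonical sweeps used in the tests and the acceptance script are
41-point logarithmic grids of $\mu_Y$ over $[10^{-2}, 10^4]$; property
suites use 100+ random parameter draws (log-uniform, $\pm 1$ decade around
defaults for the antithetic motifs, $\pm 2$ for the Hill family), skipping
draws whose base state is not converged-and-stable with a cap on the skip
fraction. The entire pipeline is deterministic — randomness appears only in
test-driven parameter draws, always under fixed seeds — so identical run
configurations produce byte-identical TSV output.

## Limitations

* The metric is a steady-state comparison. Oscillatory or non-convergent
  regimes are flagged (`no_convergence_*`, `unstable`) and omitted from
  summaries, not averaged; dynamic and stochastic extensions of the ratio
  are out of scope.
* The analogue construction requires the model author to route all of the
  controlled species' influence through the single `F` channel; the package
  does not discover feedback links in unannotated networks.
* At extreme parameter values (e.g. the far saturated tail of `atf_v2()`
  sweeps) the combination of $10^7$-fold concentration separation and
  near-zero eigenvalues defeats the solver for a few grid points; these are
  reported honestly by status rather than interpolated.
* Conservation-law detection is numerical (left eigenvectors tested at probe
  states); exact symbolic moiety analysis is not attempted.
* Random-draw properties demonstrate robustness around the shipped
  parameterizations, not global behaviour of all conceivable models.
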