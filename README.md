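# cora

Quantifying what a biological feedback loop actually contributes to
adaptation, by mathematically controlled comparison.

## The problem

Negative feedback underlies homeostasis at every scale of biology, but there
is no off-the-shelf way to ask *how much* a given loop contributes to the
adaptation of a molecular species after a sustained perturbation. Classical
control-engineering quantities (setpoint, regulation error) are often
ill-defined for biochemical networks, where saturation and ultrasensitivity
can mimic "zero error" without any feedback at all.

`cora` implements the control-ratio approach for any feedback system written
as a solvable set of ODEs. Given a model with a designated feedback signal
f(Y) and a controlled species Y, it:

1. solves the feedback system's steady state Y\*;
2. builds the *locally analogous system without feedback* — the identical
   network with the species dependence of f(Y) frozen at the steady state, so
   both systems rest at exactly the same state;
3. applies the same small perturbation ρ → ρ·λ to both systems; and
4. reports the control ratio

   CoRa<sub>Θ</sub>(Y, ρ) = Δlog(Y) / Δlog(Y<sub>NF</sub>),

   the steady-state log-response with feedback over the log-response
   without. 0 means perfect adaptation, 1 means the feedback contributes
   nothing, values in between grade attenuation.

Because the comparison system shares every nonlinearity and saturation of
the original at the operating point, differences in response isolate the
feedback itself.

The package ships motif constructors used throughout the tests and
documentation: antithetic integral feedback with an explicitly modelled
annihilation complex (`atf_v1()`), a variant whose complex retains activity
(`atf_v2()`), Hill-repression loops (`fb_hill()`), and an open-loop fixture
(`open_loop()`). Arbitrary models load from declarative JSON documents via
`parse_model()`.

## Worked example

```r
library(cora)

m <- atf_v1()        # antithetic feedback, default parameterization
m
#> <feedback model> atf_v1
#>   species:    W, U, C, Y
#>   output:     Y
#>   dW/dt = mu_W - eta_p*U*W - gamma*W
#>   dU/dt = F - eta_p*U*W - gamma*U
#>   dC/dt = eta_p*U*W - (eta_m + gamma)*C
#>   dY/dt = mu_Y*W - gamma_Y*Y
#>   F = mu_U*Y
#>   parameters: mu_W=0.1, mu_U=0.125, mu_Y=0.125, eta_p=0.05, eta_m=0.5, gamma=0.0001, gamma_Y=0.1

cora_point(m, perturb = "mu_Y", fold = 1.05)
#> # A tibble: 1 × 8
#>   theta_value    cora   dlog_y dlog_y_nf  y_ss y_fb_pert y_nf_pert status
#>         <dbl>   <dbl>    <dbl>     <dbl> <dbl>     <dbl>     <dbl> <chr>
#> 1          NA 0.00380 0.000185    0.0488 0.802     0.802     0.842 ok
```

A 5% increase in the synthesis rate `mu_Y` moves the uncontrolled output by
Δlog(Y_NF) = 0.0488 (that is, the full 5%), but the feedback system by only
0.000185 — a control ratio of 0.0038, i.e. the loop absorbs 99.6% of the
perturbation. With the antithetic dilution `gamma` set to 0 the same call
returns 0 to solver precision: perfect adaptation.

Sweeps map a loop's operating range. For Michaelis–Menten repression the
ratio can never drop below 1/2:

```r
sw <- cora_sweep(fb_hill(n = 1), sweep = "mu_Y", from = 1e-2, to = 1e4,
                 n = 41, perturb = "mu_Y")
glance(sw)
#> # A tibble: 1 × 7
#>   n_points  n_ok frac_ok min_cora max_cora max_jump transition
#>      <int> <int>   <dbl>    <dbl>    <dbl>    <dbl> <lgl>
#> 1       41    41       1    0.500    0.721   0.0295 FALSE

autoplot(sw)   # CoRa against mu_Y, log axis
```

`tidy()` returns the per-point tibble, `summarize_sweep()`/`glance()` the
aggregate (including detection of abrupt control collapse, as in the
`atf_v2()` complex-saturation failure), `cora_grid()` repeats a sweep over a
second parameter, and `cora_multi()` perturbs several parameters jointly.

A command-line front end wraps the same verbs:

```sh
Rscript inst/cli/cora.R sweep --model fb_hill --hill 1 \
  --perturb mu_Y --fold 1.05 --sweep mu_Y --range 1e-2:1e4 --points 41 --out s.tsv
```

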