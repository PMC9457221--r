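## Built-in feedback motifs. Each constructor returns a validated cora_model;
## the same models ship as JSON documents under inst/extdata/models, which the
## constructors are tested against (parse round-trip).

#' Built-in feedback motifs
#'
#' @description
#' The package ships a small library of negative-feedback motifs used as
#' fixtures, demos, and carriers of closed-form oracles:
#'
#' * `atf_v1()` — antithetic feedback with an explicit annihilation complex.
#'   Two antithetic molecules W and U bind irreversibly into a transitory
#'   complex C (degraded at rate `eta_m`); W drives synthesis of the
#'   controlled species Y (rate `mu_Y`), and Y feeds back by inducing U
#'   synthesis (`F = mu_U * Y`). All three antithetic species are diluted at a
#'   small individual rate `gamma`; Y has its own removal rate `gamma_Y`.
#'   With `gamma = 0` the motif is the ideal antithetic integral controller:
#'   the steady state of Y is pinned at the setpoint `mu_W / mu_U` and adapts
#'   perfectly to perturbations elsewhere; `gamma > 0` degrades the integral
#'   action.
#'
#' * `atf_v2()` — identical except the complex C retains biological activity,
#'   contributing to Y synthesis until it is degraded
#'   (`dY/dt = mu_Y * (W + C) - gamma_Y * Y`). This variant loses control
#'   abruptly past a threshold of `mu_Y` (complex saturation).
#'
#' * `fb_hill()` — two-species synthesis-repression loop. W is produced under
#'   Hill repression by Y (`F = mu_W / (1 + (Y/K)^n)`) and drives Y synthesis.
#'   With `n = 1` (Michaelis–Menten repression) the control ratio for
#'   perturbations of `mu_Y` is bounded below by 1/2; larger Hill
#'   coefficients (ultrasensitivity) lower the bound to `1/(1+n)`.
#'
#' * `open_loop()` — single-species fixture whose "feedback" expression is a
#'   constant, so the frozen analogue is the system itself and the control
#'   ratio is identically 1.
#'
#' Rates are per minute; concentrations are in arbitrary units. Defaults are
#' the package's reference parameterization (see the methods vignette).
#'
#' @param overrides named numeric vector of parameter overrides (nonnegative;
#'   `gamma = 0` selects the ideal antithetic limit).
#' @param n Hill coefficient (>= 1); stored as an ordinary model parameter so
#'   it can be swept or perturbed.
#' @return a `cora_model`.
#' @examples
#' atf_v1()
#' solve_steady_state(atf_v1(c(gamma = 0)))$state[["Y"]]  # mu_W/mu_U = 0.8
#' @name motifs
NULL

apply_overrides <- function(defaults, overrides) {
  if (is.null(overrides) || length(overrides) == 0L) return(defaults)
  overrides <- unlist(overrides)
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    stop("overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(overrides)) || any(overrides < 0)) {
    stop("parameter overrides must be finite and nonnegative", call. = FALSE)
  }
  defaults[names(overrides)] <- overrides
  defaults
}

#' @rdname motifs
#' @export
atf_v1 <- function(overrides = NULL) {
  params <- apply_overrides(
    c(mu_W = 0.1, mu_U = 0.125, mu_Y = 0.125, eta_p = 0.05, eta_m = 0.5,
      gamma = 1e-4, gamma_Y = 0.1),
    overrides
  )
  model_spec(
    name = "atf_v1",
    species = c("W", "U", "C", "Y"),
    parameters = params,
    rates = list(
      W = "mu_W - eta_p*U*W - gamma*W",
      U = "F - eta_p*U*W - gamma*U",
      C = "eta_p*U*W - (eta_m + gamma)*C",
      Y = "mu_Y*W - gamma_Y*Y"
    ),
    feedback = "mu_U*Y",
    output = "Y"
  )
}

#' @rdname motifs
#' @export
atf_v2 <- function(overrides = NULL) {
  m <- atf_v1(overrides)
  m$name <- "atf_v2"
  m$rate_strings[["Y"]] <- "mu_Y*(W + C) - gamma_Y*Y"
  m$rate_exprs[["Y"]] <- parse_expr(m$rate_strings[["Y"]], "rate of Y")
  m
}

#' @rdname motifs
#' @export
fb_hill <- function(n = 1, overrides = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("Hill coefficient n must be a single number >= 1", call. = FALSE)
  }
  params <- apply_overrides(
    c(mu_W = 1, mu_Y = 1, K = 1, gamma = 0.1, n = n),
    overrides
  )
  model_spec(
    name = "fb_hill",
    species = c("W", "Y"),
    parameters = params,
    rates = list(
      W = "F - gamma*W",
      Y = "mu_Y*W - gamma*Y"
    ),
    feedback = "mu_W/(1 + (Y/K)^n)",
    output = "Y"
  )
}

#' @rdname motifs
#' @export
open_loop <- function(overrides = NULL) {
  params <- apply_overrides(c(mu = 1, gamma = 0.1), overrides)
  model_spec(
    name = "open_loop",
    species = "Y",
    parameters = params,
    rates = list(Y = "F - gamma*Y"),
    feedback = "mu",
    output = "Y",
    quiet = TRUE
  )
}

#' Motif registry
#'
#' Names of the built-in motifs and a uniform constructor interface, as used
#' by the command-line front end.
#'
#' @param name motif name (see [list_motifs()]).
#' @param overrides named parameter overrides.
#' @param n Hill coefficient, used by the `fb_hill` motif only.
#' @return `list_motifs()`: character vector; `motif()`: a `cora_model`.
#' @export
list_motifs <- function() c("atf_v1", "atf_v2", "fb_hill", "open_loop")

#' @rdname list_motifs
#' @export
motif <- function(name, overrides = NULL, n = 1) {
  switch(name,
    atf_v1 = atf_v1(overrides),
    atf_v2 = atf_v2(overrides),
    fb_hill = fb_hill(n = n, overrides = overrides),
    open_loop = open_loop(overrides),
    stop(sprintf("unknown motif \"%s\"; available: %s",
                 name, paste(list_motifs(), collapse = ", ")), call. = FALSE)
  )
}

#' Closed-form control ratio for the Hill-repression motif
#'
#' For the two-species repression loop of [fb_hill()], implicit
#' differentiation of the steady-state balance
#' `Y* = mu_Y * mu_W * g(Y*) / gamma^2` with `g(Y) = 1/(1 + (Y/K)^n)` gives
#' the logarithmic gain `dlog(Y)/dlog(mu_Y) = 1 / (1 + n*sigma/(1+sigma))`
#' where `sigma = (Y*/K)^n` is the repression saturation. The frozen
#' no-feedback analogue has gain exactly 1, so this expression equals the
#' control ratio in the small-perturbation limit. Its infimum over
#' `sigma -> Inf` is `1/(1+n)`: 1/2 for Michaelian repression, lower with
#' ultrasensitivity.
#'
#' @param y_star steady-state value of the controlled species.
#' @param K repression threshold.
#' @param n Hill coefficient.
#' @return the predicted control ratio.
#' @examples
#' closed_form_cora_hill(1, K = 1, n = 1)  # sigma = 1 -> 2/3
#' @export
closed_form_cora_hill <- function(y_star, K = 1, n = 1) {
  stopifnot(y_star >= 0, K > 0, n >= 1)
  sigma <- (y_star / K)^n
  1 / (1 + n * sigma / (1 + sigma))
}
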