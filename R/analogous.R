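## Construction of the locally analogous no-feedback system: the feedback
## signal F is replaced by a constant equal to its value at the feedback
## system's steady state, so both systems share the same pre-perturbation
## steady state while only the intact one can react through the loop.

#' Freeze the feedback signal into a constant input
#'
#' Builds the locally analogous system without feedback: a copy of `model` in
#' which the reserved symbol `F` is bound to the constant value of the feedback
#' expression evaluated at the feedback system's steady state. Structure and
#' parameters are otherwise identical, so the analogue rests at the same steady
#' state as the intact system before any perturbation.
#'
#' @param model a `cora_model` with dynamic feedback.
#' @param theta parameter overrides at which `ss` was computed.
#' @param ss a converged, stable [solve_steady_state()] result for
#'   `(model, theta)`; if omitted it is solved here.
#' @return a `cora_analog` model (fields `f_const`, plus attributes
#'   `theta_ref` and `ss_ref`).
#' @examples
#' m <- atf_v1()
#' a <- freeze_feedback(m)
#' a$f_const
#' @export
freeze_feedback <- function(model, theta = NULL, ss = NULL) {
  if (inherits(model, "cora_analog")) {
    stop("model is already a frozen analogue", call. = FALSE)
  }
  theta <- resolve_theta(model, theta)
  if (is.null(ss)) ss <- solve_steady_state(model, theta)
  if (!isTRUE(ss$converged)) {
    stop("cannot freeze feedback: the feedback system's steady state did not converge",
         call. = FALSE)
  }
  f_const <- eval_feedback(model, ss$state, theta)
  if (!is.finite(f_const)) {
    stop("feedback expression is non-finite at the steady state", call. = FALSE)
  }
  analog <- model
  analog$f_const <- as.numeric(f_const)
  analog$frozen_state <- ss$state
  class(analog) <- c("cora_analog", "cora_model")
  attr(analog, "theta_ref") <- theta
  attr(analog, "ss_ref") <- ss$state
  analog
}

#' Verify that a frozen analogue is locally analogous
#'
#' Solves the no-feedback system's steady state from a neutral cold start and
#' reports the maximum relative deviation from the reference steady state at
#' which the feedback was frozen. Passing confirms both systems rest at the
#' same state before perturbation.
#'
#' @param model the original feedback `cora_model`.
#' @param analog the frozen `cora_analog` built from it.
#' @param theta parameter overrides; must equal the analogue's `theta_ref`.
#' @param tol relative tolerance for the pass flag.
#' @param control a [solver_control()] list.
#' @return list with `pass`, `max_rel_dev`, per-species `deviation`, and the
#'   no-feedback `ss`.
#' @export
verify_locally_analogous <- function(model, analog, theta = NULL, tol = 1e-6,
                                     control = solver_control()) {
  if (!inherits(analog, "cora_analog")) stop("analog must be a frozen analogue", call. = FALSE)
  theta <- resolve_theta(model, theta)
  theta_ref <- attr(analog, "theta_ref")
  if (!isTRUE(all.equal(theta, theta_ref, tolerance = 1e-12))) {
    stop("theta differs from the parameter set at which the analogue was frozen",
         call. = FALSE)
  }
  ss_ref <- attr(analog, "ss_ref")
  ss_nf <- solve_steady_state(analog, theta, control = control)
  if (!isTRUE(ss_nf$converged)) {
    return(list(pass = FALSE, max_rel_dev = NA_real_,
                deviation = setNames(rep(NA_real_, length(model$species)), model$species),
                ss = ss_nf,
                reason = "no-feedback system failed to converge from a neutral start"))
  }
  denom <- pmax(abs(ss_ref), 1e-12)
  dev <- abs(ss_nf$state - ss_ref) / denom
  list(pass = max(dev) <= tol, max_rel_dev = max(dev), deviation = dev, ss = ss_nf)
}
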