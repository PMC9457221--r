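## The control-ratio metric: after the same small parameter perturbation
## rho -> rho*fold applied to the feedback system and its frozen no-feedback
## analogue, CoRa = dlog(Y) / dlog(Y_NF). Zero means perfect adaptation; one
## means the feedback contributes nothing; values in between grade attenuation.

CORA_STATUS <- c("ok", "undefined_denominator", "no_convergence_fb",
                 "no_convergence_nf", "no_convergence_base", "unstable",
                 "ambiguous_multistable")

point_cols <- function() {
  tibble::tibble(
    theta_value = numeric(), cora = numeric(), dlog_y = numeric(),
    dlog_y_nf = numeric(), y_ss = numeric(), y_fb_pert = numeric(),
    y_nf_pert = numeric(), status = character()
  )
}

empty_point <- function(status, theta_value = NA_real_, y_ss = NA_real_) {
  tibble::tibble(
    theta_value = theta_value, cora = NA_real_, dlog_y = NA_real_,
    dlog_y_nf = NA_real_, y_ss = y_ss, y_fb_pert = NA_real_,
    y_nf_pert = NA_real_, status = status
  )
}

# Shared core: given the base FB steady state, freeze, perturb both systems
# and form the log-ratio. `folds` is a named vector of fold changes (one or
# several parameters perturbed jointly).
cora_from_base <- function(model, theta, folds, ss_base, theta_value = NA_real_,
                           control = solver_control(), denom_floor = 1e-12) {
  y <- model$output
  if (!isTRUE(ss_base$converged)) {
    return(empty_point("no_convergence_base", theta_value))
  }
  if (!isTRUE(ss_base$stable)) {
    return(empty_point("unstable", theta_value, y_ss = ss_base$state[[y]]))
  }
  y_ss <- ss_base$state[[y]]
  if (!is.finite(y_ss) || y_ss <= 0) {
    return(empty_point("no_convergence_base", theta_value))
  }

  analog <- freeze_feedback(model, theta, ss_base)

  theta_p <- theta
  theta_p[names(folds)] <- theta_p[names(folds)] * folds

  # Both systems are at ss_base when the perturbation lands; solve onward
  # from that shared state.
  ss_fb <- solve_steady_state(model, theta_p, x0 = ss_base$state, control = control)
  if (!isTRUE(ss_fb$converged) || ss_fb$state[[y]] <= 0) {
    return(empty_point("no_convergence_fb", theta_value, y_ss = y_ss))
  }
  if (!isTRUE(ss_fb$stable)) {
    return(empty_point("unstable", theta_value, y_ss = y_ss))
  }
  ss_nf <- solve_steady_state(analog, theta_p, x0 = ss_base$state, control = control)
  if (!isTRUE(ss_nf$converged) || ss_nf$state[[y]] <= 0) {
    return(empty_point("no_convergence_nf", theta_value, y_ss = y_ss))
  }
  if (!isTRUE(ss_nf$stable)) {
    return(empty_point("unstable", theta_value, y_ss = y_ss))
  }

  y_fb <- ss_fb$state[[y]]
  y_nf <- ss_nf$state[[y]]
  dlog_y <- log(y_fb / y_ss)
  dlog_y_nf <- log(y_nf / y_ss)
  if (abs(dlog_y_nf) < denom_floor) {
    return(tibble::tibble(
      theta_value = theta_value, cora = NA_real_, dlog_y = dlog_y,
      dlog_y_nf = dlog_y_nf, y_ss = y_ss, y_fb_pert = y_fb, y_nf_pert = y_nf,
      status = "undefined_denominator"
    ))
  }
  tibble::tibble(
    theta_value = theta_value, cora = dlog_y / dlog_y_nf, dlog_y = dlog_y,
    dlog_y_nf = dlog_y_nf, y_ss = y_ss, y_fb_pert = y_fb, y_nf_pert = y_nf,
    status = "ok"
  )
}

#' Control ratio for a single parameter perturbation
#'
#' Runs the full controlled-comparison pipeline at one parameter set: solve the
#' feedback system's steady state, freeze the feedback signal into its locally
#' analogous no-feedback system, apply the perturbation `rho -> rho * fold` to
#' both systems (keeping the frozen input at its pre-perturbation value), solve
#' both perturbed steady states, and report
#' `log(Y'/Y*) / log(Y_NF'/Y*)`. The ratio is independent of the logarithm
#' base; natural log is used.
#'
#' @param model a `cora_model` with dynamic feedback (or an open-loop fixture).
#' @param perturb identifier of the perturbed parameter rho.
#' @param fold multiplicative perturbation size (> 0, != 1); default 1.05, a
#'   5% increase.
#' @param theta parameter overrides (see [resolve_theta()]).
#' @param control a [solver_control()] list.
#' @param denom_floor |dlog(Y_NF)| below this is reported as
#'   `undefined_denominator` (the perturbation does not reach the output even
#'   without feedback).
#' @return a one-row tibble with columns `theta_value` (NA for a single
#'   point), `cora`, `dlog_y`, `dlog_y_nf`, `y_ss`, `y_fb_pert`, `y_nf_pert`,
#'   `status`. Any solver failure is reported in `status`, never thrown.
#' @examples
#' cora_point(open_loop(), perturb = "mu")         # exactly 1: no feedback
#' cora_point(atf_v1(overrides = c(gamma = 1e-9)), perturb = "mu_Y")
#' @export
cora_point <- function(model, perturb, fold = 1.05, theta = NULL,
                       control = solver_control(), denom_floor = 1e-12) {
  theta <- resolve_theta(model, theta)
  check_perturbation(theta, perturb, fold)
  ss_base <- solve_steady_state(model, theta, control = control)
  cora_from_base(model, theta, setNames(fold, perturb), ss_base,
                 control = control, denom_floor = denom_floor)
}

#' Control ratio for simultaneous perturbations
#'
#' Multidimensional variant: several parameters are perturbed jointly (each
#' `rho_i -> rho_i * fold_i`) in both the feedback system and its frozen
#' analogue; the ratio definition is unchanged.
#'
#' @param model a `cora_model`.
#' @param folds named numeric vector of fold changes, one per perturbed
#'   parameter (distinct names).
#' @inheritParams cora_point
#' @return a one-row tibble as in [cora_point()].
#' @export
cora_multi <- function(model, folds, theta = NULL,
                       control = solver_control(), denom_floor = 1e-12) {
  theta <- resolve_theta(model, theta)
  if (is.null(names(folds)) || any(names(folds) == "") || anyDuplicated(names(folds))) {
    stop("folds must be a named vector with distinct parameter names", call. = FALSE)
  }
  for (p in names(folds)) check_perturbation(theta, p, folds[[p]])
  ss_base <- solve_steady_state(model, theta, control = control)
  cora_from_base(model, theta, folds, ss_base,
                 control = control, denom_floor = denom_floor)
}

check_perturbation <- function(theta, perturb, fold) {
  if (!perturb %in% names(theta)) {
    stop(sprintf("perturbed parameter \"%s\" is not a model parameter", perturb),
         call. = FALSE)
  }
  if (!is.finite(fold) || fold <= 0 || fold == 1) {
    stop("fold must be a positive number different from 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Control ratio across a parameter sweep
#'
#' Computes [cora_point()] on a logarithmic grid of a chosen parameter theta,
#' re-freezing the no-feedback constant input at every grid point so the
#' controlled comparison holds pointwise. The swept and perturbed parameters
#' may coincide.
#'
#' With `warm_start = TRUE` (default) the base steady-state solve at each grid
#' point starts from the previous point's solution and is cross-checked
#' against the default cold start; disagreement beyond 1e-6 relative marks the
#' point `ambiguous_multistable` rather than silently picking a branch.
#'
#' @param model a `cora_model`.
#' @param sweep identifier of the swept parameter.
#' @param from,to sweep range (strictly positive; log-spaced).
#' @param n number of grid points.
#' @param perturb perturbed parameter; defaults to the swept one.
#' @param fold perturbation fold change.
#' @param theta parameter overrides applied before sweeping.
#' @param warm_start warm-start base solves from the previous grid point (with
#'   cold-start cross-check).
#' @param control a [solver_control()] list.
#' @param denom_floor see [cora_point()].
#' @return a tibble of class `cora_sweep`, one row per grid point, columns as
#'   in [cora_point()] with `theta_value` the swept value; attribute `spec`
#'   records the sweep configuration.
#' @examples
#' \donttest{
#' sw <- cora_sweep(fb_hill(n = 1), sweep = "mu_Y", from = 1e-2, to = 1e4,
#'                  n = 11, perturb = "mu_Y")
#' glance(sw)
#' }
#' @export
cora_sweep <- function(model, sweep, from, to, n = 41, perturb = sweep,
                       fold = 1.05, theta = NULL, warm_start = TRUE,
                       control = solver_control(), denom_floor = 1e-12) {
  theta <- resolve_theta(model, theta)
  check_perturbation(theta, perturb, fold)
  if (!sweep %in% names(theta)) {
    stop(sprintf("swept parameter \"%s\" is not a model parameter", sweep), call. = FALSE)
  }
  if (!(from > 0 && to > from && n >= 2)) {
    stop("sweep grid must be strictly positive and increasing with n >= 2", call. = FALSE)
  }
  grid <- 10^seq(log10(from), log10(to), length.out = n)

  prev_state <- NULL
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    th <- theta
    th[[sweep]] <- grid[[i]]
    ss_cold <- solve_steady_state(model, th, control = control)
    ss_base <- ss_cold
    ambiguous <- FALSE
    if (warm_start && !is.null(prev_state)) {
      ss_warm <- solve_steady_state(model, th, x0 = prev_state, control = control)
      if (isTRUE(ss_warm$converged) && isTRUE(ss_cold$converged)) {
        # per-species deviation relative to the species' own scale, floored at
        # a fraction of the overall state scale so that trace species do not
        # trigger spurious multistability flags
        denom <- pmax(abs(ss_cold$state), 1e-6 * max(abs(ss_cold$state)), 1e-9)
        if (max(abs(ss_warm$state - ss_cold$state) / denom) > 1e-6) {
          ambiguous <- TRUE
        }
      } else if (isTRUE(ss_warm$converged) && !isTRUE(ss_cold$converged)) {
        ss_base <- ss_warm
      }
    }
    if (ambiguous) {
      rows[[i]] <- empty_point("ambiguous_multistable", theta_value = grid[[i]])
    } else {
      rows[[i]] <- cora_from_base(model, th, setNames(fold, perturb), ss_base,
                                  theta_value = grid[[i]], control = control,
                                  denom_floor = denom_floor)
    }
    if (isTRUE(ss_base$converged)) prev_state <- ss_base$state
  }

  out <- dplyr::bind_rows(rows)
  attr(out, "spec") <- list(model = model$name, sweep = sweep, from = from,
                            to = to, n = n, perturb = perturb, fold = fold,
                            warm_start = warm_start)
  class(out) <- c("cora_sweep", class(out))
  out
}

#' Control-ratio sweeps across a second parameter
#'
#' Repeats [cora_sweep()] at each value of a second parameter, yielding one
#' labelled curve per value (e.g. the family of curves obtained when the
#' complex degradation rate is varied alongside the synthesis-rate sweep).
#'
#' @inheritParams cora_sweep
#' @param second identifier of the second varied parameter.
#' @param second_values numeric vector of its values (strictly positive).
#' @return a tibble of class `cora_grid`: the row-bound sweeps with an extra
#'   leading column `second_value` (and attribute `second_param`).
#' @export
cora_grid <- function(model, sweep, from, to, n = 41, perturb = sweep,
                      fold = 1.05, second, second_values, theta = NULL,
                      warm_start = TRUE, control = solver_control(),
                      denom_floor = 1e-12) {
  theta <- resolve_theta(model, theta)
  if (!second %in% names(theta)) {
    stop(sprintf("second parameter \"%s\" is not a model parameter", second), call. = FALSE)
  }
  if (any(second_values <= 0)) stop("second_values must be strictly positive", call. = FALSE)
  curves <- lapply(second_values, function(v) {
    th <- theta
    th[[second]] <- v
    sw <- cora_sweep(model, sweep = sweep, from = from, to = to, n = n,
                     perturb = perturb, fold = fold, theta = th,
                     warm_start = warm_start, control = control,
                     denom_floor = denom_floor)
    dplyr::mutate(tibble::as_tibble(sw), second_value = v, .before = 1L)
  })
  out <- dplyr::bind_rows(curves)
  attr(out, "spec") <- list(model = model$name, sweep = sweep, from = from,
                            to = to, n = n, perturb = perturb, fold = fold,
                            second = second, second_values = second_values)
  attr(out, "second_param") <- second
  class(out) <- c("cora_grid", class(out))
  out
}

#' Summarize a control-ratio sweep
#'
#' Deterministic aggregation over a sweep: extremes of the control ratio among
#' `ok` points, the fraction of points that are `ok`, the largest jump between
#' consecutive `ok` points, and a transition flag (jump > 0.5) that detects
#' abrupt feedback failure such as the switch from near-perfect adaptation to
#' no control.
#'
#' @param sweep a `cora_sweep` (or any tibble with `cora` and `status`).
#' @param jump_threshold adjacent-point |delta CoRa| above which the
#'   transition flag is set.
#' @return a one-row tibble: `n_points`, `n_ok`, `frac_ok`, `min_cora`,
#'   `max_cora`, `max_jump`, `transition`.
#' @export
summarize_sweep <- function(sweep, jump_threshold = 0.5) {
  ok <- sweep$status == "ok"
  vals <- sweep$cora[ok]
  jump <- if (sum(ok) >= 2L) max(abs(diff(vals))) else NA_real_
  tibble::tibble(
    n_points = nrow(sweep),
    n_ok = sum(ok),
    frac_ok = if (nrow(sweep)) sum(ok) / nrow(sweep) else 0,
    min_cora = if (length(vals)) min(vals) else NA_real_,
    max_cora = if (length(vals)) max(vals) else NA_real_,
    max_jump = jump,
    transition = isTRUE(jump > jump_threshold)
  )
}
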