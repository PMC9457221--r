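## Steady-state location: stiff integration to the attractor, then damped
## Newton refinement on the rate function. Integration selects the dynamically
## reached stable fixed point; Newton polishes it to tight residuals so that
## log-ratio sensitivities are computed from accurate states.

#' Solver tolerances and limits
#'
#' Defaults used by [solve_steady_state()]. The integration horizon (1e7 min)
#' sits comfortably beyond the slowest shipped timescale (dilution at
#' 1e-4 / min relaxes in ~1e4 min).
#'
#' @param resid_tol relative derivative norm below which the state counts as
#'   converged (phase 1 stop and final convergence flag).
#' @param newton_tol relative residual required to accept a Newton-refined
#'   state.
#' @param horizon maximum integrated time, in minutes.
#' @param eig_tol eigenvalue tolerance: stable means max real part < -eig_tol.
#' @param x0_default cold-start value used for every species.
#' @param rtol,atol relative/absolute tolerances passed to the stiff integrator.
#' @return a list of solver settings.
#' @export
solver_control <- function(resid_tol = 1e-9, newton_tol = 1e-10, horizon = 1e7,
                           eig_tol = 1e-9, x0_default = 1e-6,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(resid_tol > 0, newton_tol > 0, horizon > 0, eig_tol > 0, x0_default > 0)
  list(resid_tol = resid_tol, newton_tol = newton_tol, horizon = horizon,
       eig_tol = eig_tol, x0_default = x0_default, rtol = rtol, atol = atol)
}

# Componentwise relative residual: each |dx_i| is scaled by its own species'
# magnitude, floored at a fraction of the overall state scale (and at an
# absolute floor for all-but-zero states). A single max-norm scale would let a
# pseudo-root hide an O(1) drift on a trace species behind a huge one — states
# with widely separated concentrations are routine here (e.g. an antithetic
# molecule accumulating to 1e7 while its partner sits at 1e-7).
rel_residual <- function(dx, x, floor = 1e-6) {
  scale <- pmax(abs(x), 1e-6 * max(abs(x)), floor)
  max(abs(dx) / scale)
}

#' Find a stable steady state of a model
#'
#' Two-phase solve: (1) stiff integration (`deSolve::lsoda`) from `x0` over
#' geometrically growing windows until the relative derivative norm drops below
#' `control$resid_tol` or the horizon is exhausted; (2) damped Newton
#' refinement with a finite-difference Jacobian, using a minimum-norm
#' (pseudo-inverse) step so that conserved linear combinations of species are
#' preserved, accepted only if the residual falls below `control$newton_tol`
#' with the state in the nonnegative orthant. Non-convergence (including
#' sustained oscillations, which never satisfy the derivative criterion) is
#' reported via the `converged` flag, never as an error.
#'
#' Stability is assessed from the Jacobian eigenvalues at the returned state.
#' Eigenvalues within `eig_tol` of zero whose left eigenvector corresponds to
#' an exactly conserved linear combination of species (checked numerically at
#' several states) are excluded: motion along a conserved direction is fixed by
#' the initial condition, so such directions do not threaten stability of the
#' reached state. This situation arises, e.g., when the feedback of an ideal
#' antithetic controller is frozen, leaving W - U invariant.
#'
#' @param model a `cora_model` (feedback model or frozen analogue).
#' @param theta parameter overrides (see [resolve_theta()]).
#' @param x0 optional initial state (species order); default is a cold start at
#'   `control$x0_default` for every species.
#' @param f_value `"dynamic"`, a constant, or `NULL` for the model's default
#'   feedback binding (see [evaluate_rates()]).
#' @param control a [solver_control()] list.
#' @return an object of class `cora_ss`: list with `state` (named), `residual`,
#'   `converged`, `stable`, `max_eig_real`, `n_conserved`, and `method_trace`.
#' @examples
#' m <- open_loop()
#' solve_steady_state(m)$state  # mu/gamma = 10
#' @export
solve_steady_state <- function(model, theta = NULL, x0 = NULL, f_value = NULL,
                               control = solver_control()) {
  theta <- resolve_theta(model, theta)
  if (is.null(f_value)) f_value <- default_f_value(model, theta)
  ns <- length(model$species)
  if (is.null(x0)) x0 <- rep(control$x0_default, ns)
  if (length(x0) != ns) stop("x0 length does not match species count", call. = FALSE)
  x0 <- pmax(as.numeric(x0), 0)

  env <- rate_env(model, theta)
  rhs <- function(x) eval_rates_env(model, x, env, f_value)
  ode_fun <- function(t, y, parms) {
    list(eval_rates_env(model, pmax(y, 0), env, f_value))
  }

  trace <- list(integrated_time = 0, windows = 0L, newton_iters = 0L,
                newton_accepted = FALSE, overflow = FALSE)

  ## Newton sub-step used between integration windows once the trajectory is
  ## near the attractor; returns NULL if refinement does not reach newton_tol.
  newton_refine <- function(x) {
    xr <- x
    fr <- tryCatch(rhs(xr), error = function(e) NULL)
    if (is.null(fr)) return(NULL)
    res <- rel_residual(fr, xr)
    iters <- 0L
    # Iterate well past newton_tol (down to ~machine residual): ill-conditioned
    # fixed points (a near-zero slow eigenvalue) amplify residual into state
    # error by the condition number, and the systems are small enough that the
    # extra iterations are free.
    for (it in seq_len(100L)) {
      if (res < 1e-14) break
      J <- fd_jacobian(rhs, xr)
      if (any(!is.finite(J))) break
      step <- tryCatch(-pinv_solve(J, fr), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      lambda <- 1
      improved <- FALSE
      for (k in seq_len(25L)) {
        cand <- xr + lambda * step
        if (min(cand) >= -1e-12) {
          cand <- pmax(cand, 0)
          fc <- tryCatch(rhs(cand), error = function(e) NULL)
          if (!is.null(fc)) {
            rc <- rel_residual(fc, cand)
            if (rc < res) {
              xr <- cand; fr <- fc; res <- rc; improved <- TRUE
              break
            }
          }
        }
        lambda <- lambda / 2
      }
      iters <- iters + 1L
      if (!improved) break
    }
    if (res < control$newton_tol && min(xr) >= -1e-12) {
      list(x = pmax(xr, 0), iters = iters)
    } else {
      NULL
    }
  }

  ## phase 1: integrate over growing windows; once the trajectory is roughly
  ## settled (relative residual < 1e-4) hand over to Newton, which either
  ## polishes to newton_tol or sends us back to integrating.
  x <- x0
  span <- 10
  refined <- NULL
  repeat {
    dx <- tryCatch(rhs(x), error = function(e) NULL)
    if (is.null(dx)) { trace$overflow <- TRUE; break }
    res_now <- rel_residual(dx, x)
    if (res_now < control$resid_tol) break
    coarse <- max(abs(dx)) / max(max(abs(x)), 1e-6)
    if (res_now < 1e-2 || coarse < 1e-4) {
      # near-settled: let Newton try to finish; acceptance is gated on the
      # strict componentwise residual, and the stability check plus the
      # warm/cold cross-check downstream guard against spurious roots
      refined <- newton_refine(x)
      if (!is.null(refined)) break
    }
    if (trace$integrated_time >= control$horizon) break
    span <- min(span, control$horizon - trace$integrated_time)
    sol <- tryCatch(
      suppressWarnings(
        deSolve::lsoda(y = x, times = span * (0:4) / 4, func = ode_fun,
                       parms = NULL, rtol = control$rtol, atol = control$atol,
                       maxsteps = 20000)
      ),
      error = function(e) NULL
    )
    # keep whatever part of the window completed (stiff problems can exhaust
    # the step budget mid-window without having diverged)
    last_ok <- 0L
    if (!is.null(sol) && nrow(sol) >= 1L) {
      finite_rows <- which(apply(is.finite(sol[, -1L, drop = FALSE]), 1L, all))
      if (length(finite_rows)) last_ok <- max(finite_rows)
    }
    if (last_ok <= 1L) {
      # no progress: states with widely separated scales (slow dilution under
      # fast oscillation) may still be refinable; give Newton a chance
      refined <- newton_refine(x)
      if (!is.null(refined)) break
      trace$overflow <- TRUE
      break
    }
    x <- pmax(as.numeric(sol[last_ok, -1L]), 0)
    trace$integrated_time <- trace$integrated_time + sol[last_ok, 1L]
    trace$windows <- trace$windows + 1L
    if (last_ok == 5L) span <- span * 10
  }

  ## phase 2: final refinement from the integration endpoint if not already done
  if (!trace$overflow && is.null(refined)) refined <- newton_refine(x)
  if (!is.null(refined)) {
    x <- refined$x
    trace$newton_iters <- refined$iters
    trace$newton_accepted <- TRUE
  }

  dx <- tryCatch(rhs(x), error = function(e) rep(NA_real_, ns))
  residual <- if (any(!is.finite(dx))) Inf else rel_residual(dx, x)
  converged <- is.finite(residual) && residual <= control$resid_tol && min(x) >= -1e-12
  x <- pmax(x, 0)

  stable <- FALSE
  max_eig_real <- NA_real_
  n_conserved <- 0L
  if (converged) {
    J <- tryCatch(fd_jacobian(rhs, x), error = function(e) NULL)
    if (!is.null(J) && all(is.finite(J))) {
      st <- stability_with_conservation(J, rhs, x, eig_tol = control$eig_tol)
      stable <- st$stable
      max_eig_real <- st$max_eig_real
      n_conserved <- st$n_conserved
    }
  }

  structure(
    list(state = setNames(x, model$species), residual = residual,
         converged = converged, stable = stable, max_eig_real = max_eig_real,
         n_conserved = n_conserved, method_trace = trace),
    class = "cora_ss"
  )
}

#' @export
print.cora_ss <- function(x, ...) {
  cat("<steady state>",
      if (x$converged) "converged" else "NOT converged",
      if (x$stable) "stable" else "not stable", "\n")
  print(signif(x$state, 6))
  cat(sprintf("  residual %.3g, max Re(eig) %.3g, conserved directions %d\n",
              x$residual, x$max_eig_real, x$n_conserved))
  invisible(x)
}

## ---- Jacobians & stability --------------------------------------------------

# Central finite-difference Jacobian of fun at x; step per coordinate
# max(1e-7*|x_i|, 1e-9). States are clamped to stay numerically evaluable.
fd_jacobian <- function(fun, x) {
  n <- length(x)
  J <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    h <- max(1e-7 * abs(x[[i]]), 1e-9)
    xp <- x; xp[[i]] <- x[[i]] + h
    xm <- x; xm[[i]] <- x[[i]] - h
    J[, i] <- (fun(xp) - fun(xm)) / (2 * h)
  }
  J
}

#' Finite-difference Jacobian of a model's rate function
#'
#' @param model a `cora_model`.
#' @param theta parameter overrides.
#' @param state state vector (species order), finite and nonnegative.
#' @param f_value feedback binding, as in [evaluate_rates()].
#' @return square numeric matrix, rows = equations, columns = species.
#' @export
model_jacobian <- function(model, theta = NULL, state, f_value = NULL) {
  theta <- resolve_theta(model, theta)
  if (is.null(f_value)) f_value <- default_f_value(model, theta)
  env <- rate_env(model, theta)
  x <- as.numeric(state)
  if (any(!is.finite(x))) stop("state must be finite", call. = FALSE)
  J <- fd_jacobian(function(z) eval_rates_env(model, z, env, f_value), x)
  if (any(!is.finite(J))) {
    bad <- which(!is.finite(J), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite Jacobian entry for equation %s, species %s",
                 model$species[bad[[1L]]], model$species[bad[[2L]]]), call. = FALSE)
  }
  dimnames(J) <- list(model$species, model$species)
  J
}

#' Strict linear stability from a Jacobian
#'
#' Stable iff the largest real part of the eigenvalues is below `-eig_tol`.
#' A zero eigenvalue (marginal case) is reported as not stable; use
#' [solve_steady_state()] for the conservation-aware judgement.
#'
#' @param jac square numeric matrix.
#' @param eig_tol strictness margin on the real part.
#' @return list with `stable` (flag) and `max_eig_real`.
#' @export
is_stable <- function(jac, eig_tol = 1e-9) {
  ev <- tryCatch(eigen(jac, only.values = TRUE)$values,
                 error = function(e) NULL)
  if (is.null(ev)) {
    return(list(stable = FALSE, max_eig_real = NA_real_))
  }
  mre <- max(Re(ev))
  list(stable = mre < -eig_tol, max_eig_real = mre)
}

# Stability with exactly conserved directions excluded. A left eigenvector v
# with eigenvalue ~0 spans a conserved linear combination iff v . f(x) == 0
# identically; we test this at a fixed set of probe states derived from the
# solution point. Conserved directions carry no dynamics, so the fixed point
# reached by integration is stable iff all remaining eigenvalues have negative
# real part.
stability_with_conservation <- function(J, rhs, x, eig_tol = 1e-9) {
  es <- tryCatch(eigen(t(J)), error = function(e) NULL)
  if (is.null(es)) return(list(stable = FALSE, max_eig_real = NA_real_, n_conserved = 0L))
  re <- Re(es$values)
  im <- Im(es$values)
  mre <- max(re)
  if (mre < -eig_tol) {
    return(list(stable = TRUE, max_eig_real = mre, n_conserved = 0L))
  }
  scale <- max(abs(x), 1)
  near_zero <- abs(re) <= eig_tol & abs(im) <= eig_tol
  suspect <- which(re >= -eig_tol)
  conserved <- logical(length(suspect))
  for (k in seq_along(suspect)) {
    i <- suspect[[k]]
    if (!near_zero[[i]]) next
    v <- Re(es$vectors[, i])
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) next
    v <- v / nv
    probes <- probe_states(x)
    ok <- vapply(probes, function(p) {
      f <- tryCatch(rhs(p), error = function(e) NULL)
      !is.null(f) && abs(sum(v * f)) <= 1e-8 * max(max(abs(f)), 1)
    }, logical(1))
    conserved[[k]] <- all(ok)
  }
  if (!all(conserved)) {
    return(list(stable = FALSE, max_eig_real = mre, n_conserved = sum(conserved)))
  }
  rest <- re[-suspect]
  stable <- length(rest) == 0L || max(rest) < -eig_tol
  list(stable = stable, max_eig_real = mre, n_conserved = sum(conserved))
}

# Deterministic probe states around x used to test conservation of a direction.
probe_states <- function(x) {
  s <- max(abs(x), 1)
  base <- pmax(x, 0)
  list(
    base * 0.37 + 0.11 * s,
    base * 1.71 + 0.03 * s,
    base * 0.93 + 0.57 * s,
    rev(base) * 0.5 + 0.29 * s,
    base + seq_along(x) * 0.13 * s
  )
}

# Minimum-norm solve via SVD pseudo-inverse; tolerance relative to the largest
# singular value so rank-deficient Jacobians (conservation laws) are handled.
pinv_solve <- function(A, b) {
  sv <- svd(A)
  tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps * 100
  d_inv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  sv$v %*% (d_inv * (t(sv$u) %*% b))
}
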