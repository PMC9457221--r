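# Shared fixtures for the suite. All randomness is seeded at the call site.

# Single-species open-loop fixture with adjustable rates, built from source
# text so model parsing is exercised alongside the motif constructors.
decay_model <- function(mu = 1, gamma = 0.1) {
  model_spec("decay", species = "Y",
             parameters = c(mu = mu, gamma = gamma),
             rates = list(Y = "F - gamma*Y"),
             feedback = "mu", output = "Y", quiet = TRUE)
}

# Log-uniform parameter draw around a model's defaults. `fixed` names
# parameters kept at their defaults (e.g. the Hill coefficient).
draw_theta <- function(model, decades = 1, fixed = character(0)) {
  th <- model$parameters
  idx <- !(names(th) %in% fixed) & th > 0
  th[idx] <- th[idx] * 10^stats::runif(sum(idx), -decades, decades)
  th
}

# Run fn over random draws, skipping draws whose base steady state is not
# converged and stable; fails if more than max_skip_frac of draws skip.
for_converged_draws <- function(model_fn, n_draws, fn, decades = 1,
                                fixed = character(0), max_skip_frac = 0.5) {
  skips <- 0L
  done <- 0L
  for (i in seq_len(n_draws)) {
    m <- model_fn()
    th <- draw_theta(m, decades = decades, fixed = fixed)
    ss <- solve_steady_state(m, th)
    if (!isTRUE(ss$converged) || !isTRUE(ss$stable)) {
      skips <- skips + 1L
      next
    }
    fn(m, th, ss)
    done <- done + 1L
  }
  expect_lte(skips / n_draws, max_skip_frac)
  done
}
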