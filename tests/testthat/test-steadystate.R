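test_that("linear decay reaches its closed-form steady state", {
  ss <- solve_steady_state(decay_model(mu = 1, gamma = 0.1))
  expect_true(ss$converged)
  expect_true(ss$stable)
  expect_equal(ss$state[["Y"]], 10, tolerance = 1e-9)
})

test_that("the ideal antithetic setpoint is mu_W/mu_U, independent of mu_Y", {
  m <- atf_v1(c(gamma = 0))
  for (mu_y in c(0.05, 0.125, 2)) {
    ss <- solve_steady_state(m, c(mu_Y = mu_y))
    expect_true(ss$converged)
    expect_true(ss$stable)
    expect_equal(ss$state[["Y"]], 0.8, tolerance = 1e-8)
  }
})

test_that("a system without a positive fixed point reports non-convergence", {
  m <- model_spec("runaway", species = "Y", parameters = c(mu = 1),
                  rates = list(Y = "F + Y"), feedback = "mu", output = "Y",
                  quiet = TRUE)
  ss <- solve_steady_state(m, control = solver_control(horizon = 1e4))
  expect_false(ss$converged)
  expect_false(ss$stable)
})

test_that("the finite-difference Jacobian matches linear closed forms", {
  m <- decay_model(gamma = 0.1)
  J <- model_jacobian(m, state = c(Y = 3))
  expect_equal(dim(J), c(1L, 1L))
  expect_equal(J[1, 1], -0.1, tolerance = 1e-6)

  # ideal antithetic motif is locally stable at its steady state
  m <- atf_v1(c(gamma = 0))
  ss <- solve_steady_state(m)
  J <- model_jacobian(m, state = ss$state)
  expect_lt(max(Re(eigen(J, only.values = TRUE)$values)), 0)
})

test_that("the frozen analogue's Jacobian differs only where F propagates", {
  m <- atf_v1()
  ss <- solve_steady_state(m)
  a <- freeze_feedback(m, ss = ss)
  J_fb <- model_jacobian(m, state = ss$state)
  J_nf <- model_jacobian(a, state = ss$state)
  d <- abs(J_fb - J_nf)
  # the only feedback-carrying entry is dU/dY = mu_U
  expect_equal(d["U", "Y"], 0.125, tolerance = 1e-6)
  d["U", "Y"] <- 0
  expect_lt(max(d), 1e-6)
})

test_that("strict stability classification handles marginal and oscillatory cases", {
  s <- is_stable(matrix(-1))
  expect_true(s$stable)
  expect_equal(s$max_eig_real, -1)
  expect_false(is_stable(matrix(0))$stable)                       # marginal
  expect_false(is_stable(matrix(c(0, -1, 1, 0), 2))$stable)       # +/- i pair
})

test_that("refined steady states agree with brute-force long integration", {
  set.seed(101)
  brute <- function(model, theta) {
    # oracle: pure stiff integration, x10 horizon, x0.1 tolerance, no Newton
    env <- cora:::rate_env(model, resolve_theta(model, theta))
    f <- function(t, y, p) list(cora:::eval_rates_env(model, pmax(y, 0), env, "dynamic"))
    x <- rep(1e-6, length(model$species))
    t_left <- 1e8
    span <- 10
    repeat {
      dx <- f(0, x, NULL)[[1]]
      if (max(abs(dx)) / max(max(abs(x)), 1e-6) < 1e-10 || t_left <= 0) break
      s <- suppressWarnings(deSolve::lsoda(x, c(0, span), f, NULL,
                                           rtol = 1e-10, atol = 1e-12,
                                           maxsteps = 200000))
      x <- pmax(s[nrow(s), -1], 0)
      t_left <- t_left - span
      span <- span * 10
    }
    x
  }
  n_checked <- 0L
  for (mk in list(function() fb_hill(n = 2), function() atf_v1())) {
    for (i in 1:3) {
      m <- mk()
      th <- draw_theta(m, decades = 1, fixed = "n")
      ss <- solve_steady_state(m, th)
      if (!ss$converged || !ss$stable) next
      xb <- brute(m, th)
      denom <- pmax(abs(xb), 1e-6 * max(abs(xb)), 1e-9)
      expect_lt(max(abs(ss$state - xb) / denom), 1e-6)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 3L)
})

test_that("warm and cold starts land on the same state", {
  set.seed(202)
  m <- fb_hill(n = 1)
  th1 <- resolve_theta(m, c(mu_Y = 0.5))
  th2 <- resolve_theta(m, c(mu_Y = 0.9))
  cold <- solve_steady_state(m, th2)
  warm <- solve_steady_state(m, th2, x0 = solve_steady_state(m, th1)$state)
  denom <- pmax(abs(cold$state), 1e-6 * max(abs(cold$state)), 1e-9)
  expect_lt(max(abs(warm$state - cold$state) / denom), 1e-6)
})

test_that("conserved directions are recognised, bare zero modes are not", {
  # frozen ideal antithetic analogue: W - U is exactly conserved, yet the
  # reached state is reported stable with one conserved direction
  m <- atf_v1(c(gamma = 0))
  ss <- solve_steady_state(m)
  a <- freeze_feedback(m, ss = ss)
  ss_nf <- solve_steady_state(a, x0 = ss$state)
  expect_true(ss_nf$stable)
  expect_identical(ss_nf$n_conserved, 1L)
  # the strict primitive still reports the zero mode as not stable
  J <- model_jacobian(a, state = ss_nf$state)
  expect_false(is_stable(J)$stable)
})
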