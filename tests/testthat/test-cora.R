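test_that("an open loop yields a control ratio of exactly one", {
  pt <- cora_point(open_loop(), perturb = "mu", fold = 1.05)
  expect_identical(pt$status, "ok")
  expect_equal(pt$cora, 1, tolerance = 1e-9)
  # any other parameter and direction too
  pt2 <- cora_point(open_loop(), perturb = "gamma", fold = 0.8)
  expect_equal(pt2$cora, 1, tolerance = 1e-9)
})

test_that("the ideal antithetic motif adapts perfectly to mu_Y perturbations", {
  pt <- cora_point(atf_v1(c(gamma = 0)), perturb = "mu_Y", fold = 1.05)
  expect_identical(pt$status, "ok")
  expect_lt(abs(pt$cora), 1e-6)
})

test_that("the Hill-repression ratio matches its closed-form logarithmic gain", {
  # mu_Y = 2, gamma = 1, K = 1 puts Y* exactly at K, so sigma = 1 and the
  # predicted ratio is 1/(1 + n/2) = 2/3 for n = 1
  m <- fb_hill(n = 1, overrides = c(K = 1, gamma = 1, mu_Y = 2))
  ss <- solve_steady_state(m)
  expect_equal(ss$state[["Y"]], 1, tolerance = 1e-8)
  pt <- cora_point(m, perturb = "mu_Y", fold = 1.001)
  expect_equal(pt$cora, 2 / 3, tolerance = 1e-3)
  expect_equal(closed_form_cora_hill(1, K = 1, n = 1), 2 / 3, tolerance = 1e-12)
})

test_that("the ratio is invariant to the logarithm base", {
  pt <- cora_point(fb_hill(n = 2), perturb = "mu_Y")
  with_log10 <- log10(pt$y_fb_pert / pt$y_ss) / log10(pt$y_nf_pert / pt$y_ss)
  expect_equal(pt$cora, with_log10, tolerance = 1e-12)
})

test_that("the metric is consistent across small perturbation sizes", {
  set.seed(404)
  for_converged_draws(function() fb_hill(n = 2), 6, function(m, th, ss) {
    a <- cora_point(m, perturb = "mu_Y", fold = 1.01, theta = th)
    b <- cora_point(m, perturb = "mu_Y", fold = 1.001, theta = th)
    if (a$status == "ok" && b$status == "ok") {
      expect_lt(abs(a$cora - b$cora), 5e-3)
    }
  }, decades = 1, fixed = "n")
  # two-sided consistency: up- and down-perturbations agree to O(fold - 1)
  pt_up <- cora_point(atf_v1(), perturb = "mu_Y", fold = 1.05)
  pt_dn <- cora_point(atf_v1(), perturb = "mu_Y", fold = 1 / 1.05)
  expect_lt(abs(pt_up$cora - pt_dn$cora), 0.05)
})

test_that("attenuating feedback shrinks the output response by construction", {
  set.seed(505)
  pts <- dplyr::bind_rows(
    cora_point(fb_hill(n = 1), perturb = "mu_Y"),
    cora_point(fb_hill(n = 4), perturb = "mu_Y"),
    cora_point(atf_v1(), perturb = "mu_Y"),
    cora_point(atf_v2(), perturb = "mu_Y")
  )
  ok <- pts[pts$status == "ok" & pts$cora >= 0 & pts$cora < 1, ]
  expect_gt(nrow(ok), 0)
  expect_true(all(abs(ok$dlog_y) < abs(ok$dlog_y_nf)))
})

test_that("a perturbation that cannot reach the output is flagged undefined", {
  # in ATF v1 the complex C is a dead end: with the feedback frozen, eta_m
  # touches nothing upstream of Y
  pt <- cora_point(atf_v1(), perturb = "eta_m", fold = 1.05)
  expect_identical(pt$status, "undefined_denominator")
  expect_true(is.na(pt$cora))
})

test_that("joint perturbations reduce to the single-parameter case and to zero for the ideal motif", {
  single <- cora_multi(fb_hill(n = 1), folds = c(mu_Y = 1.05))
  point <- cora_point(fb_hill(n = 1), perturb = "mu_Y", fold = 1.05)
  expect_equal(single$cora, point$cora, tolerance = 1e-12)

  # equal folds on mu_Y and gamma_Y cancel in the no-feedback output too
  # (Y_NF' = Y*), so the ratio is an honest 0/0
  degen <- cora_multi(atf_v1(c(gamma = 0)), folds = c(mu_Y = 1.05, gamma_Y = 1.05))
  expect_identical(degen$status, "undefined_denominator")
  # opposite folds move Y_NF while the ideal controller still adapts fully
  both <- cora_multi(atf_v1(c(gamma = 0)), folds = c(mu_Y = 1.05, gamma_Y = 0.9))
  expect_identical(both$status, "ok")
  expect_lt(abs(both$cora), 1e-6)

  ol <- cora_multi(open_loop(), folds = c(mu = 1.1, gamma = 0.9))
  expect_equal(ol$cora, 1, tolerance = 1e-9)
})

test_that("perturbation arguments are validated", {
  expect_error(cora_point(open_loop(), perturb = "nope"), "nope")
  expect_error(cora_point(open_loop(), perturb = "mu", fold = 1), "fold")
  expect_error(cora_multi(open_loop(), folds = c(1.05)), "named")
})

test_that("sweeps carry one point per grid value with recomputable summaries", {
  sw <- cora_sweep(fb_hill(n = 1), sweep = "mu_Y", from = 0.1, to = 10, n = 7,
                   perturb = "mu_Y")
  expect_s3_class(sw, "cora_sweep")
  expect_identical(nrow(sw), 7L)
  expect_equal(sw$theta_value, 10^seq(-1, 1, length.out = 7))
  s <- summarize_sweep(sw)
  expect_identical(s$n_ok, sum(sw$status == "ok"))
  expect_equal(s$min_cora, min(sw$cora[sw$status == "ok"]))
  # glance() is the same aggregation
  expect_equal(glance(sw), s)
})

test_that("a degenerate grid equals the plain sweep, and equal values give equal rows", {
  sw <- cora_sweep(fb_hill(n = 1), sweep = "mu_Y", from = 0.1, to = 10, n = 5,
                   perturb = "mu_Y")
  gr <- cora_grid(fb_hill(n = 1), sweep = "mu_Y", from = 0.1, to = 10, n = 5,
                  perturb = "mu_Y", second = "K", second_values = 1)
  expect_equal(tibble::as_tibble(gr)[names(sw)], tibble::as_tibble(sw),
               ignore_attr = TRUE)
  gr2 <- cora_grid(fb_hill(n = 1), sweep = "mu_Y", from = 0.1, to = 10, n = 5,
                   perturb = "mu_Y", second = "K", second_values = c(2, 2))
  half <- nrow(gr2) / 2
  expect_equal(gr2$cora[seq_len(half)], gr2$cora[half + seq_len(half)])
})

test_that("tidy and autoplot accessors work on sweeps and grids", {
  sw <- cora_sweep(fb_hill(n = 1), sweep = "mu_Y", from = 0.5, to = 2, n = 4,
                   perturb = "mu_Y")
  td <- tidy(sw)
  expect_false(inherits(td, "cora_sweep"))
  expect_identical(nrow(td), 4L)
  p <- autoplot(sw)
  expect_s3_class(p, "ggplot")
  gr <- cora_grid(fb_hill(n = 1), sweep = "mu_Y", from = 0.5, to = 2, n = 3,
                  perturb = "mu_Y", second = "K", second_values = c(0.5, 2))
  expect_identical(nrow(glance(gr)), 2L)
  expect_s3_class(autoplot(gr), "ggplot")
})
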