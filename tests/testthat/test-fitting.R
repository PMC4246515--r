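test_that("starting-value heuristic follows its stated rules", {
  p <- ctrl_params()
  d <- simulate_leaf_series(p, t = daily_schedule())
  g <- initial_guess(d)
  expect_true(g$Lm >= 535 && g$Lm <= 1.05 * 535 + 1e-9)
  expect_true(g$te >= 217 && g$te <= 231 + 14)
  expect_true(g$t0 == 0 && g$tm > g$t0 && g$tm < g$te)
  expect_error(initial_guess(data.frame(t = 1:8, length = rep(5, 8))),
               "degenerate")
  expect_error(initial_guess(data.frame(t = 1:2, length = 1:2)),
               "at least 5")
})

test_that("noiseless growth fits recover the generating parameters", {
  for (p in random_growth_params(12, seed = 31)) {
    d <- simulate_leaf_series(p, t = seq(0, p$te * 1.05, length.out = 15))
    f <- fit_growth(d)
    expect_true(f$converged)
    expect_equal(f$params$Lm, p$Lm, tolerance = 1e-3)
    expect_equal(f$params$tm, p$tm, tolerance = 1e-3)
    expect_equal(f$params$te, p$te, tolerance = 1e-3)
    expect_equal(f$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("noisy growth fits reach the R-squared regime of real series", {
  d <- simulate_leaf_series(ctrl_params(), t = seq(0, 238, length.out = 15),
                            sd = 5, seed = 42)
  f <- fit_growth(d)
  expect_true(f$converged)
  expect_gt(f$r_squared, 0.99)
})

test_that("fit SSE never exceeds the SSE at the starting values", {
  for (s in 1:8) {
    d <- simulate_leaf_series(ctrl_params(), t = daily_schedule(),
                              sd = 12, seed = s)
    f <- fit_growth(d)
    g0 <- initial_guess(d)
    sse0 <- sum((d$length - beta_length(g0, d$t))^2)
    expect_lte(f$sse, sse0 + 1e-8)
  }
})

test_that("constant series fail loudly, not silently", {
  d <- data.frame(t = seq(0, 100, by = 10), length = rep(50, 11))
  expect_error(fit_growth(d), "degenerate")
})

test_that("fits are invariant to uniform length rescaling", {
  d <- simulate_leaf_series(ctrl_params(), t = daily_schedule(),
                            sd = 5, seed = 9)
  f_mm <- fit_growth(d)
  d_cm <- dplyr::mutate(d, length = length / 10)
  f_cm <- fit_growth(d_cm)
  expect_equal(f_cm$params$Lm * 10, f_mm$params$Lm, tolerance = 1e-4)
  expect_equal(f_cm$params$tm, f_mm$params$tm, tolerance = 1e-4)
  expect_equal(f_cm$sse * 100, f_mm$sse, tolerance = 1e-4)
  expect_equal(f_cm$r_squared, f_mm$r_squared, tolerance = 1e-8)
})

test_that("free-t0 fitting works and defaults keep t0 at sowing", {
  p <- growth_params(400, 30, 150, 220)
  d <- simulate_leaf_series(p, t = seq(30, 230, length.out = 15))
  f_free <- fit_growth(d, fix_t0 = FALSE)
  expect_equal(f_free$params$t0, 30, tolerance = 0.05)
  expect_equal(f_free$params$Lm, 400, tolerance = 1e-2)
  f_fix <- fit_growth(simulate_leaf_series(ctrl_params(),
                                           t = daily_schedule()))
  expect_equal(f_fix$params$t0, 0)
})

test_that("noiseless cell profiles recover the generating parameters", {
  cp <- ctrl_cells()
  d <- simulate_cell_profile(cp, p = seq(0.5, 60, by = 0.5))
  f <- fit_cell_profile(d)
  expect_true(f$converged)
  expect_equal(f$params$Lb, cp$Lb, tolerance = 1e-3)
  expect_equal(f$params$Lm, cp$Lm, tolerance = 1e-3)
  expect_equal(f$params$Pm, cp$Pm, tolerance = 1e-3)
  expect_equal(f$params$Pe, cp$Pe, tolerance = 1e-3)
  expect_error(fit_cell_profile(d[1:5, ]), "at least 8")
})

test_that("noisy cell profiles land in the published R-squared band", {
  d <- simulate_cell_profile(ctrl_cells(), p = seq(0.5, 60, by = 0.5),
                             cv = 0.25, seed = 7)
  f <- fit_cell_profile(d)
  expect_true(f$converged)
  expect_gt(f$r_squared, 0.75)
  expect_lt(f$r_squared, 0.95)
})

test_that("alternative families fit beta-generated data almost as well", {
  d <- simulate_cell_profile(ctrl_cells(), p = seq(0.5, 60, by = 0.5))
  for (fam in c("weibull", "gompertz", "logistic")) {
    f <- fit_cell_profile(d, family = fam)
    expect_true(f$converged)
    expect_gt(f$r_squared, 0.99)
    expect_lt(f$r_squared, 1)
  }
})

test_that("goodness of fit uses the centred R-squared definition", {
  g <- goodness_of_fit(c(1, 2, 3), c(1, 2, 4))
  expect_equal(g$sse, 1)
  expect_equal(g$r_squared, 0.5)
  perfect <- goodness_of_fit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r_squared, 1)
  expect_equal(goodness_of_fit(c(1, 2, 3), rep(2, 3))$r_squared, 0)
  expect_error(goodness_of_fit(rep(2, 3), rep(2, 3)), "zero variance")
})

test_that("pooled predicted-vs-observed regression behaves", {
  po <- predicted_vs_observed(
    data.frame(observed = c(1, 2, 3), fitted = c(2, 3, 4)))
  expect_equal(po$slope, 1)
  expect_equal(po$intercept, 1)
  expect_equal(po$r_squared, 1)
  fits <- lapply(1:4, function(s) {
    fit_growth(simulate_leaf_series(ctrl_params(), t = daily_schedule(),
                                    sd = 2, seed = s))
  })
  po2 <- predicted_vs_observed(fits)
  expect_gt(po2$r_squared, 0.99)
  expect_equal(po2$slope, 1, tolerance = 0.05)
  expect_error(predicted_vs_observed(
    data.frame(observed = 1, fitted = 1)), "at least 2")
})

test_that("empirical LER approximates the analytic rate curve", {
  e <- empirical_ler(data.frame(t = c(0, 10, 20), length = c(0, 50, 150)))
  expect_equal(e$t_mid, c(5, 15))
  expect_equal(e$ler, c(5, 10))
  expect_equal(empirical_ler(data.frame(t = c(0, 5, 9),
                                        length = rep(3, 3)))$ler,
               c(0, 0))
  expect_error(empirical_ler(data.frame(t = c(0, 0, 5), length = 1:3)),
               "increasing")
  d <- simulate_leaf_series(ctrl_params(), t = daily_schedule())
  calc_max <- max(empirical_ler(d)$ler)
  analytic <- beta_max_rate(ctrl_params())$lermax
  expect_equal(calc_max, analytic, tolerance = 0.02)
})

test_that("glance/tidy/augment expose the fit in broom shape", {
  d <- simulate_leaf_series(ctrl_params(), t = daily_schedule(),
                            sd = 3, seed = 2)
  f <- fit_growth(d)
  td <- tidy(f)
  expect_setequal(td$term, c("Lm", "t0", "tm", "te"))
  gl <- glance(f)
  expect_equal(gl$nobs, nrow(d))
  expect_true(gl$converged)
  au <- augment(f)
  expect_equal(au$.resid, au$length - au$.fitted)
  expect_equal(sum(au$.resid^2), gl$sse)
})
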