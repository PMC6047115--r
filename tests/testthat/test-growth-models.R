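test_that("curve evaluators satisfy their closed-form identities", {
  # logistic midpoint, zero-rate limit, arithmetic spot check
  expect_equal(eval_logistic(100, 0.2, 120, 120), 50)
  expect_equal(eval_logistic(80, 0, 120, c(1, 500)), c(40, 40))
  expect_equal(eval_logistic(100, 0.2, 120, 150), 100 / (1 + exp(-6)))
  # 4PL halfway point at t = C, exponent-zero limit, arithmetic spot check
  expect_equal(eval_4pl(3, 7, 130, 90, 130), (3 + 90) / 2)
  expect_equal(eval_4pl(3, 0, 130, 90, c(10, 400)), rep((3 + 90) / 2, 2))
  expect_equal(eval_4pl(0, 11, 130, 100, 260), 100 + (0 - 100) / (1 + 2^11))
  # Gompertz asymptote, t = 0 value, arithmetic spot check
  expect_equal(eval_gompertz(100, 5, 0.05, 1e6), 100)
  expect_equal(eval_gompertz(100, 5, 0.05, 0), 100 * exp(-5))
  expect_equal(eval_gompertz(100, 5, 0.05, 40), 100 * exp(-5 * exp(-2)))
})

test_that("evaluators are overflow-guarded and finite for extreme inputs", {
  expect_true(all(is.finite(eval_logistic(100, 50, 120, c(1, 1e4)))))
  expect_true(all(is.finite(eval_4pl(0, 500, 130, 100, c(1e-6, 1e6)))))
  expect_true(all(is.finite(eval_gompertz(100, 1e8, 10, c(0, 1e5)))))
  expect_error(eval_4pl(0, 11, 130, 100, -1), "t must be > 0")
})

test_that("r_squared follows the coefficient-of-determination formula", {
  y <- c(3, 1, 4, 1, 5)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 5)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "zero total sum of squares")
  expect_error(r_squared(1:3, 1:4), "equal-length")
})

test_that("noiseless series are recovered exactly by each model fit", {
  t <- seq(90, 200, by = 5)
  cases <- list(
    list(model = "fourpl",   truth = c(A = 0, B = 11, C = 130, D = 100),
         y = eval_4pl(0, 11, 130, 100, t)),
    list(model = "fourpl",   truth = c(A = 500, B = -6, C = 140, D = 9000),
         y = eval_4pl(500, -6, 140, 9000, t)),
    list(model = "logistic", truth = c(L = 85000, k = 0.12, t0 = 135),
         y = eval_logistic(85000, 0.12, 135, t)),
    list(model = "gompertz", truth = c(a = 700, b = 40, c = 0.035),
         y = eval_gompertz(700, 40, 0.035, t))
  )
  for (cs in cases) {
    f <- fit_growth_model(t, cs$y, cs$model)
    expect_true(f$converged)
    rel <- abs(f$params[names(cs$truth)] - cs$truth) / abs(cs$truth)
    rel[cs$truth == 0] <- abs(f$params[names(cs$truth)][cs$truth == 0])
    expect_lt(max(rel), 1e-4)
    expect_gte(f$r_squared, 1 - 1e-10)
  }
})

test_that("degenerate inputs are flagged, not fatal", {
  t <- seq(90, 160, by = 5)
  f <- fit_growth_model(t, rep(50, length(t)), "fourpl")
  expect_false(f$converged)
  expect_error(fit_growth_model(t[1:3], c(1, 2, 3), "fourpl"), "at least")
})

test_that("model selection maximises R2 and breaks ties by parsimony", {
  mk <- function(model, r2, conv = TRUE)
    growthqtl:::new_fit_result(model, c(x = 1), r2, 0.1, conv, 20)
  expect_equal(select_model(list(mk("fourpl", 0.99), mk("logistic", 0.95))), "fourpl")
  expect_equal(select_model(list(mk("fourpl", 0.99), mk("logistic", 0.99))), "logistic")
  expect_equal(select_model(list(mk("fourpl", 0.5), mk("logistic", 0.99, FALSE))), "fourpl")
  expect_error(select_model(list(mk("fourpl", 0.9, FALSE))), "no converged")
})

test_that("4PL matches or beats the 3-parameter logistic on 4PL data with A > 0", {
  t <- seq(90, 200, by = 4)
  set.seed(7)
  for (i in 1:5) {
    y <- eval_4pl(1500, 9 + i, 125 + 2 * i, 80000, t) + rnorm(length(t), sd = 500)
    f4 <- fit_growth_model(t, y, "fourpl")
    fl <- fit_growth_model(t, y, "logistic")
    expect_true(f4$converged)
    if (fl$converged) expect_gte(f4$r_squared, fl$r_squared - 1e-8)
  }
})

test_that("polynomial baselines obey OLS theory", {
  t <- seq(90, 160, by = 5)
  y_par <- 3 + 0.5 * t - 0.01 * t^2
  f2 <- fit_polynomial(t, y_par, 2)
  expect_equal(f2$r_squared, 1)
  set.seed(11)
  y <- y_par + rnorm(length(t), sd = 2)
  r2s <- vapply(2:4, function(d) fit_polynomial(t, y, d)$r_squared, 1)
  expect_true(all(diff(r2s) >= -1e-12))  # nested OLS: R2 non-decreasing in degree
  f3 <- fit_polynomial(t[1:10], y[1:10], 3)
  expect_equal(unname(f3$params), polyfit_oracle(t[1:10], y[1:10], 3), tolerance = 1e-8)
  expect_error(fit_polynomial(t, y, 5), "degree")
  expect_error(fit_polynomial(c(1, 1, 1, 1, 1, 2), rnorm(6), 4), "rank-deficient")
})

test_that("fit_trait_curves returns one converged row per line and replicate", {
  t <- seq(90, 200, by = 8)
  series <- toy_series(c("L1", "L2"), 1:2, t, function(l, r, d)
    eval_4pl(0, 10 + 2 * (l == "L2"), 130, 5e4, d))
  tab <- fit_trait_curves(series, "Area")
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$converged))
  expect_equal(tab$B[tab$line == "L2"], rep(12, 2), tolerance = 1e-5)
})
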