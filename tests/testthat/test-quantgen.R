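test_that("variance components honour their exact limits", {
  # replicates identical within lines: all variance is genetic
  vals <- matrix(rep(c(10, 14, 20, 26), 2), 4, 2)
  vc <- variance_components(vals)
  expect_equal(vc$s2_e, 0)
  expect_equal(vc$s2_g, var(c(10, 14, 20, 26)))
  expect_equal(heritability(vc), 1)
  # all values identical: both components zero, H2 undefined
  vc0 <- variance_components(matrix(5, 6, 2))
  expect_equal(vc0$s2_g, 0)
  expect_equal(vc0$s2_e, 0)
  expect_error(heritability(vc0), "undefined")
  expect_error(variance_components(matrix(rnorm(4), 4, 1)), "single replicate")
  expect_equal(heritability(list(s2_g = 3, s2_e = 1)), 0.75)
  expect_equal(heritability(list(s2_g = 0, s2_e = 2)), 0)
})

test_that("method-of-moments estimates recover planted components", {
  set.seed(21)
  n <- 500; r <- 2
  g <- rnorm(n, sd = sqrt(3))
  vals <- matrix(rep(g, r), n, r) + matrix(rnorm(n * r), n, r)
  vc <- variance_components(vals)
  # sampling s.e. of the MoM estimators from expected mean squares
  msb_e <- r * 3 + 1; msw_e <- 1
  se_g <- sqrt(2 * msb_e^2 / (n - 1) + 2 * msw_e^2 / (n * (r - 1))) / r
  se_e <- sqrt(2 * msw_e^2 / (n * (r - 1)))
  expect_lt(abs(vc$s2_g - 3), 3 * se_g)
  expect_lt(abs(vc$s2_e - 1), 3 * se_e)
})

test_that("negative genetic variance estimates are truncated and flagged", {
  set.seed(33)
  vals <- matrix(rnorm(40), 20, 2)  # pure noise, small n: s2_g often negative
  found <- FALSE
  for (i in 1:20) {
    vc <- variance_components(matrix(rnorm(40), 20, 2))
    if (vc$truncated) { found <- TRUE; expect_equal(vc$s2_g, 0) }
  }
  expect_true(found)
})

test_that("covariances obey the sum-trait identities", {
  set.seed(8)
  x <- matrix(rep(rnorm(50, sd = 2), 2), 50, 2) + matrix(rnorm(100), 50, 2)
  rownames(x) <- sprintf("L%02d", 1:50)
  cc <- covariance_components(x, x)
  vx <- variance_components(x)
  expect_equal(cc$S_g, vx$s2_g, tolerance = 1e-12)
  expect_equal(cc$S_e, vx$s2_e, tolerance = 1e-12)
  ccn <- covariance_components(x, -x)
  expect_equal(ccn$S_g, -vx$s2_g, tolerance = 1e-12)
  expect_equal(ccn$S_e, -vx$s2_e, tolerance = 1e-12)
})

test_that("independent traits with no genetic effects have near-zero genetic covariance", {
  set.seed(13)
  reps <- vapply(1:20, function(i) {
    x <- matrix(rnorm(400), 200, 2, dimnames = list(sprintf("L%03d", 1:200), NULL))
    y <- matrix(rnorm(400), 200, 2, dimnames = list(sprintf("L%03d", 1:200), NULL))
    covariance_components(x, y)$S_g
  }, 1)
  expect_lt(abs(mean(reps)), 3 * sd(reps) / sqrt(20))
})

test_that("correlations hit their exact limits and recover planted values", {
  set.seed(44)
  g <- rnorm(100, sd = 2)
  x <- matrix(rep(g, 2), 100, 2) + matrix(rnorm(200), 100, 2)
  rownames(x) <- sprintf("L%03d", 1:100)
  r_self <- genetic_correlation(x, x)
  expect_equal(r_self$r_g, 1, tolerance = 1e-12)
  expect_equal(r_self$r_e, 1, tolerance = 1e-12)
  # y = -x is a perfect negative environmental (and genetic) copy
  r_neg <- genetic_correlation(x, -x)
  expect_equal(r_neg$r_e, -1, tolerance = 1e-12)
  # planted genetic correlation 0.9 between two parameters
  n <- 500
  gz <- matrix(rnorm(2 * n), n, 2) %*% chol(matrix(c(1, 0.9, 0.9, 1), 2))
  mk <- function(col) matrix(rep(gz[, col], 2), n, 2,
                             dimnames = list(sprintf("L%03d", 1:n), NULL)) +
    matrix(rnorm(2 * n, sd = 0.4), n, 2)
  r <- genetic_correlation(mk(1), mk(2))
  expect_equal(r$r_g, 0.9, tolerance = 0.1)
})

test_that("the printed arithmetic-mean denominator variant is available", {
  set.seed(55)
  g <- rnorm(80, sd = 2)
  x <- matrix(rep(g, 2), 80, 2) + matrix(rnorm(160), 80, 2)
  rownames(x) <- sprintf("L%02d", 1:80)
  y <- 3 * x  # scale change separates the two denominators
  r_geo <- genetic_correlation(x, y)
  r_ari <- genetic_correlation(x, y, denominator = "arithmetic")
  expect_equal(r_geo$r_g, 1, tolerance = 1e-10)
  expect_lt(r_ari$r_g, 1)  # arithmetic mean >= geometric mean
})

test_that("components are scale-equivariant and symmetric", {
  set.seed(66)
  g1 <- rnorm(60, sd = 1.5); g2 <- 0.5 * g1 + rnorm(60)
  x <- matrix(rep(g1, 2), 60, 2) + matrix(rnorm(120), 60, 2)
  y <- matrix(rep(g2, 2), 60, 2) + matrix(rnorm(120), 60, 2)
  rownames(x) <- rownames(y) <- sprintf("L%02d", 1:60)
  c_scaled <- 7
  vx <- variance_components(x)
  vxs <- variance_components(c_scaled * x)
  expect_equal(vxs$s2_g, c_scaled^2 * vx$s2_g, tolerance = 1e-12)
  expect_equal(heritability(vxs), heritability(vx), tolerance = 1e-12)
  cc_xy <- covariance_components(x, y)
  cc_yx <- covariance_components(y, x)
  expect_equal(cc_xy$S_g, cc_yx$S_g, tolerance = 1e-12)
  cc_s <- covariance_components(c_scaled * x, y)
  expect_equal(cc_s$S_g, c_scaled * cc_xy$S_g, tolerance = 1e-10)
  r_xy <- genetic_correlation(x, y); r_yx <- genetic_correlation(y, x)
  expect_equal(r_xy$r_g, r_yx$r_g, tolerance = 1e-12)
  expect_equal(genetic_correlation(c_scaled * x, y)$r_g, r_xy$r_g, tolerance = 1e-10)
})

test_that("heritability and correlation tables cover all parameters", {
  set.seed(77)
  n <- 80
  tab <- data.frame(line = rep(sprintf("L%02d", 1:n), each = 2),
                    rep = rep(1:2, n))
  g <- rnorm(n, sd = 2)
  tab$A <- rep(g, each = 2) + rnorm(2 * n)
  tab$B <- rnorm(2 * n)
  tab$converged <- TRUE
  h <- heritability_table(tab, params = c("A", "B"))
  expect_equal(h$parameter, c("A", "B"))
  expect_gt(h$H2[1], h$H2[2])
  cm <- correlation_matrices(tab, params = c("A", "B"))
  expect_equal(diag(cm$r_g), c(A = 1, B = 1))
  expect_equal(cm$r_e["A", "B"], cm$r_e["B", "A"])
})
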