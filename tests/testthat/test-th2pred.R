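test_that("noiseless linear responses give Q2 near 1, null responses do not", {
  set.seed(41)
  X <- matrix(rnorm(60 * 4), 60)
  y <- drop(X %*% c(1, -2, 0.5, 0)) + 3
  fit <- crossval_q2_regression(X, y)
  expect_gte(fit$q2_y, 0.99)
  expect_gte(fit$r2_y, 0.99)
  expect_lt(fit$model_p, 1e-10)

  y0 <- rnorm(60)
  set.seed(42)
  fit0 <- crossval_q2_regression(X, y0, n_perm = 99)
  expect_lt(fit0$q2_y, 0.2)
  expect_gt(fit0$q2_p, 0.05)
})

test_that("Q2 is invariant to affine rescaling of predictors", {
  set.seed(43)
  X <- matrix(rnorm(40 * 3), 40)
  y <- drop(X %*% c(1, 1, -1)) + rnorm(40)
  f1 <- crossval_q2_regression(X, y)
  X2 <- sweep(sweep(X, 2L, c(10, 0.1, 5), "*"), 2L, c(-3, 2, 100), "+")
  f2 <- crossval_q2_regression(X2, y)
  expect_equal(f1$q2_y, f2$q2_y, tolerance = 1e-10)
})

test_that("in-sample R2 matches the least-squares oracle", {
  set.seed(44)
  X <- matrix(rnorm(50 * 3), 50)
  y <- drop(X %*% c(0.5, 0, 1)) + rnorm(50)
  fit <- crossval_q2_regression(X, y)
  ref <- summary(stats::lm(y ~ X))
  expect_equal(fit$r2_y, ref$r.squared, tolerance = 1e-10)
  expect_equal(fit$model_p,
               stats::pf(ref$fstatistic[1], ref$fstatistic[2],
                         ref$fstatistic[3], lower.tail = FALSE),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("ridge fallback engages when predictors outnumber samples", {
  set.seed(45)
  X <- matrix(rnorm(10 * 12), 10)
  y <- rnorm(10)
  expect_message(fit <- crossval_q2_regression(X, y, k_folds = 2), "ridge")
  expect_true(is.finite(fit$q2_y))
})

test_that("Wilks lambda hits its perfect-fit and null limits", {
  set.seed(46)
  X <- matrix(rnorm(40 * 3), 40)
  Y1 <- X %*% matrix(rnorm(9), 3)  # exact linear transform
  f1 <- multivariate_wilks(X, Y1)
  expect_gte(f1$r2_y, 0.99)
  Y0 <- matrix(rnorm(40 * 3), 40)
  f0 <- multivariate_wilks(X, Y0)
  expect_lt(f0$r2_y, 0.4)
  expect_gt(f0$model_p, 0.01)
})

test_that("Wilks lambda and Rao F match the manova oracle", {
  set.seed(47)
  X <- matrix(rnorm(40 * 4), 40)
  Y <- matrix(rnorm(40 * 3), 40) + X[, 1:3] * 0.5
  fit <- multivariate_wilks(X, Y)
  # lambda is invariant to the per-variable standardisation used inside
  mv <- summary(stats::manova(Y ~ X), test = "Wilks")$stats
  expect_equal(fit$lambda, mv[1, "Wilks"], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$model_p, mv[1, "Pr(>F)"], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("out-of-sample 1 - lambda stays below the in-sample value", {
  set.seed(48)
  X <- matrix(rnorm(56 * 4), 56)
  Y <- X %*% matrix(rnorm(12), 4) + matrix(rnorm(56 * 3), 56)
  fit <- multivariate_wilks(X, Y)
  expect_lte(fit$q2_y, fit$r2_y + 0.05)
})

test_that("coefficient clustering flags duplicates and anti-patterns", {
  set.seed(49)
  X <- matrix(rnorm(50 * 5), 50, dimnames = list(NULL, paste0("x", 1:5)))
  B <- matrix(rnorm(5 * 2), 5)
  base <- X %*% B
  Y <- cbind(r1 = base[, 1], r2 = base[, 1], r3 = -3 * base[, 1],
             r4 = base[, 2]) + matrix(rnorm(50 * 4), 50) * 0.05
  cl <- coefficient_clustering(X, Y, n_boot = 60)
  co <- cl$coefficients
  # duplicated responses: correlation distance ~0; negated: ~2
  expect_lt(1 - stats::cor(co["r1", ], co["r2", ]), 0.01)
  expect_gt(1 - stats::cor(co["r1", ], co["r3", ]), 1.9)
  sup <- cl$response_support
  pair <- sup[sup$members == "r1,r2", ]
  expect_equal(nrow(pair), 1L)
  expect_gte(pair$support, 0.95)
  expect_true(pair$significant)
})

test_that("independent noise coefficients do not form supported clusters", {
  set.seed(50)
  X <- matrix(rnorm(40 * 4), 40)
  Y <- matrix(rnorm(40 * 4), 40, dimnames = list(NULL, paste0("y", 1:4)))
  cl <- coefficient_clustering(X, Y, n_boot = 80)
  expect_false(any(cl$response_support$significant))
})

test_that("too few rows or columns skip clustering gracefully", {
  set.seed(51)
  X <- matrix(rnorm(30 * 2), 30)
  Y <- matrix(rnorm(30 * 2), 30)
  expect_message(cl <- coefficient_clustering(X, Y, n_boot = 10),
                 "skipped")
  expect_null(cl$response_support)
})

test_that("the synthetic protein response is predicted out of sample", {
  pipe_cfg <- tiny_config(seed = 52)
  sim <- simulate_expression(pipe_cfg)
  members <- unique(unlist(sim$truth$crossing_edges))
  X <- t(sim$study$exprs[members, ])
  set.seed(6)
  fit <- crossval_q2_regression(X, sim$protein, n_perm = 99)
  expect_gt(fit$q2_y, 0)
  expect_lte(fit$q2_p, 0.05)
  expect_lte(fit$q2_y, fit$r2_y + 0.05)
  # the multivariate response panel is predicted as well
  set.seed(7)
  mv <- multivariate_wilks(X, sim$panel, n_perm = 99)
  expect_gt(mv$q2_y, 0)
  expect_lte(mv$q2_p, 0.05)
  expect_lte(mv$q2_y, mv$r2_y + 0.05)
})
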