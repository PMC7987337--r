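test_that("class weights follow the balanced convention", {
  expect_equal(unname(class_weights(rep(c(0, 1), each = 78))), c(1, 1))
  expect_equal(unname(class_weights(c(rep(0, 9), 1))), c(10 / 18, 5))
  w <- class_weights(c(rep(1, 79), rep(0, 77)))
  expect_equal(unname(w), c(156 / 154, 156 / 158), tolerance = 1e-12)
  expect_error(class_weights(rep(1, 5)), "both classes")
})

test_that("the null penalty kills every coefficient and leaves the weighted log-odds", {
  set.seed(41)
  X <- matrix(rbinom(40 * 6, 1, 0.3), 40, 6)
  y <- rbinom(40, 1, 0.4)
  if (sum(y) %in% c(0, 40)) y[1] <- 1 - y[1]
  lmax <- lambda_max(X, y)
  fit <- fit_weighted_lasso(X, y, lmax)
  expect_true(all(fit$beta == 0))
  w <- expand_weights <- xburden:::expand_weights(NULL, y)
  expect_equal(fit$intercept, qlogis(sum(w * y) / sum(w)), tolerance = 1e-6)
  fit2 <- fit_weighted_lasso(X, y, lmax * 1.5)
  expect_true(all(fit2$beta == 0))
})

test_that("a single informative column gets a positive, monotonically shrinking coefficient", {
  y <- rep(c(1, 0), each = 15)
  x <- c(rep(1, 10), rep(0, 5), rep(0, 13), rep(1, 2))
  X <- matrix(x, ncol = 1)
  lams <- c(0.002, 0.01, 0.05, 0.1)
  fit <- fit_weighted_lasso(X, y, lams, tol = 1e-12)
  b <- fit$beta[1, ]
  expect_true(all(b >= 0))
  expect_true(all(diff(b) <= 1e-10))  # lambda increasing -> coef shrinks
  expect_gt(b[1], 0)
  # brute-force 2-parameter grid minimization of the stated objective
  w <- xburden:::expand_weights(NULL, y)
  for (k in c(1, 3)) {
    best <- grid_min_2param(X, y, w, lams[k])
    expect_equal(fit$beta[1, k], best$b1, tolerance = 0.01)
    expect_equal(fit$intercept[k], best$b0, tolerance = 0.01)
  }
})

test_that("unpenalized weighted fit matches glm", {
  set.seed(43)
  n <- 50
  X <- matrix(rbinom(n * 3, 1, 0.4), n, 3)
  y <- rbinom(n, 1, plogis(-0.3 + X %*% c(1, -0.8, 0.2)))
  w <- xburden:::expand_weights(NULL, y)
  fit <- fit_weighted_lasso(X, y, 0, tol = 1e-13)
  oracle <- suppressWarnings(glm(y ~ X, family = binomial, weights = w))
  expect_equal(c(fit$intercept, fit$beta[, 1]), unname(coef(oracle)),
               tolerance = 1e-5)
})

test_that("the weighted fit agrees with an independent penalized solver", {
  set.seed(44)
  n <- 60
  X <- matrix(rbinom(n * 5, 1, 0.35), n, 5)
  y <- rbinom(n, 1, plogis(X %*% c(1.2, -1, 0, 0.4, 0)))
  w <- xburden:::expand_weights(NULL, y)  # sums to n, glmnet's scale
  for (lam in c(0.01, 0.04)) {
    fit <- fit_weighted_lasso(X, y, lam, tol = 1e-13)
    ref <- glmnet::glmnet(X, y, family = "binomial", weights = w,
                          lambda = lam, standardize = FALSE, thresh = 1e-14)
    expect_equal(c(fit$intercept, fit$beta[, 1]),
                 as.numeric(c(ref$a0, as.matrix(ref$beta))),
                 tolerance = 1e-4)
  }
})

test_that("objective decreases monotonically across solver sweeps", {
  set.seed(45)
  X <- matrix(rbinom(80 * 10, 1, 0.3), 80, 10)
  y <- rbinom(80, 1, 0.5)
  fit <- fit_weighted_lasso(X, y, 0.01)
  tr <- fit$trace[[1]]
  expect_true(all(diff(tr) <= 1e-12))
  # and the solution is no worse than the all-zero coefficient vector
  w <- xburden:::expand_weights(NULL, y)
  b0_null <- qlogis(sum(w * y) / sum(w))
  expect_lte(fit$objective[1], obj_wlasso(X, y, w, b0_null, rep(0, 10), 0.01))
})

test_that("equal class sizes give weights of one and the unweighted objective", {
  set.seed(46)
  X <- matrix(rbinom(30 * 4, 1, 0.4), 30, 4)
  y <- rep(c(0, 1), 15)
  expect_equal(unname(class_weights(y)), c(1, 1))
  fit_w <- fit_weighted_lasso(X, y, 0.02)
  fit_u <- fit_weighted_lasso(X, y, 0.02, weights = rep(1, 30))
  expect_equal(fit_w$beta, fit_u$beta)
  expect_equal(fit_w$objective, fit_u$objective)
})

test_that("sparsity is monotone in cardinality along the penalty path", {
  for (seed in c(51, 52, 53)) {
    inst <- random_lasso_instance(seed)
    lmax <- lambda_max(inst$X, inst$y)
    lams <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 25))
    fit <- fit_weighted_lasso(inst$X, inst$y, lams, tol = 1e-10)
    card <- colSums(fit$beta != 0)
    expect_true(all(diff(card) >= 0))  # lambda decreasing -> cardinality grows
  }
})

test_that("feature ranking orders by absolute weight with sign annotation", {
  model <- structure(list(beta = matrix(c(0.8, -0.3, 0, 0.3),
                                        dimnames = list(c("A", "B", "C", "AB"),
                                                        NULL)),
                          intercept = 0, lambda = 0.1),
                     class = "xburden_lasso")
  rf <- rank_features(model)
  expect_equal(rf$gene, c("A", "AB", "B"))  # tie 0.3 breaks lexicographically
  expect_equal(rf$direction, c("susceptible", "susceptible", "protective"))
  zero <- structure(list(beta = matrix(0, 2, 1,
                                       dimnames = list(c("A", "B"), NULL)),
                         intercept = 0, lambda = 0.1),
                    class = "xburden_lasso")
  expect_equal(nrow(rank_features(zero)), 0)
})

test_that("invalid inputs are rejected", {
  X <- matrix(rbinom(20, 1, 0.5), 10, 2)
  expect_error(fit_weighted_lasso(X, c(rep(0, 5), rep(2, 5)), 0.1), "binary")
  expect_error(fit_weighted_lasso(X, rep(c(0, 1), 5), -0.1), "lambda")
  expect_error(fit_weighted_lasso(X, rep(c(0, 1), 3), 0.1), "align")
})
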