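# Planted-signal designs with known support exercise the penalized fits.

make_planted <- function(n = 500, q = 10, k_active = 3, sd = 0.3, seed = 31) {
  set.seed(seed)
  X <- matrix(rnorm(n * q), n, q)
  beta <- numeric(q)
  beta[seq_len(k_active)] <- c(2, -1.5, 1)[seq_len(k_active)]
  y <- drop(X %*% beta) + rnorm(n, 0, sd)
  list(X = X, y = y, beta = beta)
}

test_that("LASSO null and OLS limits", {
  d <- make_planted()
  # large lambda: all coefficients exactly zero
  Xs <- scale(d$X)
  lmax <- 2 * max(abs(crossprod(Xs, d$y - mean(d$y))))
  res0 <- effect_lasso(d$y, d$X, lambda = lmax * 1.01)
  expect_true(all(res0$beta == 0))
  expect_equal(nrow(res0$selected), 0)
  # lambda = 0: least-squares solution
  res1 <- effect_lasso(d$y, d$X, lambda = 0)
  ols <- coef(lm(d$y ~ d$X))[-1]
  expect_equal(drop(res1$beta), unname(ols), tolerance = 1e-6)
  expect_error(effect_lasso(d$y, d$X, lambda = -1), ">= 0")
})

test_that("KKT conditions hold at the reported solution", {
  d <- make_planted()
  lam <- 20
  res <- effect_lasso(d$y, d$X, lambda = lam)
  g <- -2 * drop(crossprod(res$Xs, res$Yc - res$Xs %*% res$beta_std))
  act <- abs(res$beta_std) > 0
  expect_true(all(abs(g[!act]) <= lam + 1e-4))
  expect_equal(g[act], -lam * sign(res$beta_std[act]), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("planted support is recovered before any null feature", {
  d <- make_planted()
  # moderate lambda keeps the active set, drops the nulls
  res <- effect_lasso(d$y, d$X, lambda = 50)
  expect_setequal(res$selected$feature, 1:3)
  # cross-validated lambda also finds the true support first
  rescv <- effect_lasso(d$y, d$X)
  top3 <- rescv$selected$feature[1:3]
  expect_setequal(top3, 1:3)
})

test_that("coordinate descent agrees with glmnet", {
  skip_if_not_installed("glmnet")
  d <- make_planted(n = 300, q = 8)
  lam <- 30
  res <- effect_lasso(d$y, d$X, lambda = lam)
  # glmnet objective: 1/(2n)||y - Xg c||^2 + lambda_g ||c||_1.  With
  # Xg = Xs * s (s converting sample-sd to population-sd standardization),
  # b = s*c minimizes ||y - Xs b||^2 + (2n lambda_g / s) |b|.
  n <- 300
  s <- sqrt(n / (n - 1))
  fit <- glmnet::glmnet(scale(d$X) * s, d$y, lambda = lam * s / (2 * n),
                        standardize = FALSE, thresh = 1e-14)
  bg <- as.numeric(coef(fit))[-1]
  expect_equal(drop(res$beta_std), bg * s, tolerance = 1e-4)
})

test_that("dose-adjusted fit reduces exactly to the plain fit at T = 0", {
  d <- make_planted(n = 200, q = 6)
  T0 <- matrix(0, 200, 2)
  plain <- effect_lasso(d$y, d$X, lambda = 25)
  dosed <- effect_lasso_continuous(d$y, T0, d$X, lambda1 = 7, lambda2 = 25)
  expect_identical(dosed$gamma, matrix(0, 2, 1))
  expect_equal(dosed$beta, plain$beta, tolerance = 1e-10)
})

test_that("dose-adjusted fit recovers planted dose and covariate supports", {
  set.seed(41)
  n <- 1000
  X <- matrix(rnorm(n * 6), n, 6)
  Tm <- cbind(rexp(n), 0)
  y <- 0.8 * Tm[, 1] + 1.5 * X[, 2] + rnorm(n, 0, 0.2)
  res <- effect_lasso_continuous(y, Tm, X, lambda1 = 10, lambda2 = 50)
  expect_true(abs(res$gamma[1, 1]) > 0.5)
  expect_equal(res$selected$feature[1], 2)
  # huge lambda1 with lambda2 = 0: gamma = 0, beta = OLS
  res2 <- effect_lasso_continuous(y, Tm, X, lambda1 = 1e6, lambda2 = 0)
  expect_true(all(res2$gamma == 0))
  ols <- coef(lm(y ~ scale(X)))[-1]
  expect_equal(drop(res2$beta_std), unname(ols), tolerance = 1e-6)
})

test_that("optimal_treatment_lasso selects best-arm response with tie rule", {
  set.seed(51)
  n <- 300
  X <- matrix(rnorm(n * 5), n, 5)
  # column 1 uniformly larger: response is column 1
  Y <- cbind(2 + 0.5 * X[, 1], -1 + 0 * X[, 1])
  res <- optimal_treatment_lasso(Y, X, lambda = 1)
  expect_true(all(res$z == 1))
  direct <- effect_lasso(Y[, 1], X, lambda = 1)
  expect_equal(res$alpha, drop(direct$beta))
  # all-equal columns: ties resolve to arm 1
  Yeq <- cbind(X[, 2], X[, 2])
  expect_true(all(optimal_treatment_lasso(Yeq, X, lambda = 1)$z == 1))
  # planted best-arm signal driven by one covariate has the largest |alpha|
  # (offset keeps the best-arm response correlated with its driver)
  Yp <- cbind(1 + X[, 3], -1 - X[, 3])
  resp <- optimal_treatment_lasso(Yp, X, lambda = 5)
  expect_equal(which.max(abs(resp$alpha)), 3L)
})

test_that("r2_decomposition matches refits and is monotone", {
  set.seed(61)
  n <- 300
  X <- matrix(rnorm(n * 5), n, 5)
  eff <- X[, 1]
  r2 <- r2_decomposition(eff, X, order = 1:3)
  expect_equal(r2$r2_single[1], 1)
  # refit oracle at every prefix (perfect-fit warnings are the point here)
  for (m in 1:3) {
    fit <- lm(eff ~ X[, 1:m, drop = FALSE])
    expect_equal(r2$r2_accumulated[m],
                 suppressWarnings(summary(fit)$r.squared),
                 tolerance = 1e-8)
  }
  # noisy effect: accumulated R2 non-decreasing, matches refits
  eff2 <- 0.5 * X[, 2] - X[, 4] + rnorm(n)
  r22 <- r2_decomposition(eff2, X)
  expect_true(all(diff(r22$r2_accumulated) >= -1e-12))
  for (m in seq_len(5)) {
    fit <- lm(eff2 ~ X[, r22$feature[1:m], drop = FALSE])
    expect_equal(r22$r2_accumulated[m], summary(fit)$r.squared,
                 tolerance = 1e-8)
  }
  # constant feature gives 0, not NaN
  Xc <- cbind(X[, 1:2], 1)
  r2c <- r2_decomposition(eff, Xc, order = 3)
  expect_equal(r2c$r2_single, 0)
})

test_that("orthonormal design: accumulated R2 is the sum of single R2s", {
  set.seed(71)
  n <- 256
  # centred columns keep the orthogonality exact in the presence of the
  # regression intercept, making the additivity identity hold for any effect
  Q <- qr.Q(qr(scale(matrix(rnorm(n * 4), n, 4), scale = FALSE)))
  eff <- Q %*% c(1, 2, 0.5, 0) + rnorm(n, 0, 0.1)
  r2 <- r2_decomposition(eff, Q, order = 1:3)
  expect_equal(r2$r2_accumulated[3], sum(r2$r2_single[1:3]), tolerance = 1e-8)
})

test_that("garson importance is a proper decomposition", {
  # single hidden layer, one nonzero input weight
  W1 <- matrix(0, 3, 4); W1[2, ] <- 1
  W2 <- matrix(1, 4, 1)
  imp <- garson_importance(list(W1, W2))
  expect_equal(unname(imp), c(0, 1, 0))
  # nonnegative, sums to 1 for arbitrary weights
  set.seed(81)
  Wa <- matrix(rnorm(12), 3, 4); Wb <- matrix(rnorm(8), 4, 2)
  imp2 <- garson_importance(list(Wa, Wb))
  expect_true(all(imp2 >= 0))
  expect_equal(sum(imp2), 1)
  # permuting two inputs and their weight rows permutes the importances
  Wp <- Wa[c(2, 1, 3), ]
  imp3 <- garson_importance(list(Wp, Wb))
  expect_equal(unname(imp3), unname(imp2[c(2, 1, 3)]))
})
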