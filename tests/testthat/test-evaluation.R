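test_that("outcome_metrics: identities and closed forms", {
  truth <- cbind(c(1, 0, 1, 0), c(0, 0, 1, 1))
  m <- outcome_metrics(truth, truth, binary = TRUE)
  expect_equal(m$mse, 0)
  expect_equal(m$accuracy, 1)
  # constant 0.5 scores against balanced binary truth: thresholded entries
  # are all 1, so half are wrong
  m2 <- outcome_metrics(matrix(0.5, 4, 2), truth, binary = TRUE)
  expect_equal(m2$mse, 0.5)
  # continuous branch: mse over raw errors
  m3 <- outcome_metrics(truth + 0.5, truth, binary = FALSE)
  expect_equal(m3$mse, 0.25)
  expect_true(is.na(m3$accuracy))
  expect_error(outcome_metrics(truth, truth[, 1, drop = FALSE]), "shape")
})

test_that("outcome_metrics agrees with a brute-force loop", {
  set.seed(15)
  est <- matrix(runif(60), 20, 3)
  truth <- matrix(rbinom(60, 1, 0.5), 20, 3)
  m <- outcome_metrics(est, truth, binary = TRUE)
  errs <- c()
  for (i in 1:20) for (k in 1:3)
    errs <- c(errs, as.numeric((est[i, k] >= 0.5) != truth[i, k]))
  expect_equal(m$mse, mean(errs), tolerance = 1e-12)
  expect_equal(m$std, sd(errs), tolerance = 1e-12)
})

test_that("replication error and separation distance closed forms", {
  expect_equal(replication_error(1, 1), 0)
  expect_equal(replication_error(1, exp(-1)), 1)
  expect_error(replication_error(1, -0.5), "negative")
  set.seed(16)
  yf <- rbinom(30, 1, 0.5)
  yh <- runif(30)
  expect_equal(replication_error(yf, yh),
               mean(sapply(1:30, function(i) -yf[i] * log(yh[i]))),
               tolerance = 1e-12)

  M <- cbind(rep(1, 2), rep(0, 2))
  # counterfactual slots exactly opposite the factuals: maximal distance
  expect_equal(separation_distance(c(1, 0), cbind(c(9, 9), c(0, 1)), M), 1)
  # counterfactual slots equal to the factuals: zero distance
  expect_equal(separation_distance(c(1, 1), cbind(0, c(1, 1)), M), 0)
})

test_that("rank-based AUC equals the O(n^2) pair-counting oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  set.seed(17)
  n <- 1000
  scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
  labels <- rbinom(n, 1, 0.5)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(roc_auc(scores, labels), mean(cmp), tolerance = 1e-12)
  expect_warning(a <- roc_auc(scores, rep(1, n)), "one class")
  expect_true(is.na(a))
  # random scores hover around 1/2
  aucs <- replicate(20, roc_auc(runif(200), rbinom(200, 1, 0.5)))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("KL divergence: zero iff equal (after smoothing), nonnegative", {
  expect_equal(kl_ite_divergence(c(-1, 0, 1, 1), c(-1, 0, 1, 1)), 0)
  # hand-computed: p = (.5, .5, 0), q = (.25, .25, .5) with eps smoothing
  a <- c(rep(-1, 2), rep(0, 2))
  b <- c(-1, 0, 1, 1)
  eps <- 1e-6
  p <- (c(2, 2, 0) + eps) / (4 + 3 * eps)
  q <- (c(1, 1, 2) + eps) / (4 + 3 * eps)
  expect_equal(kl_ite_divergence(a, b), sum(p * log(p / q)), tolerance = 1e-10)
  set.seed(18)
  for (i in 1:20) {
    x <- sample(c(-1, 0, 1), 50, replace = TRUE)
    y <- sample(c(-1, 0, 1), 50, replace = TRUE)
    expect_gte(kl_ite_divergence(x, y), 0)
  }
  # continuous ITEs get a shared histogram
  expect_gte(kl_ite_divergence(rnorm(100), rnorm(100, 1)), 0)
})

test_that("FPR complements the true-negative proportion", {
  set.seed(19)
  est <- sample(c(-1, 0, 1), 200, replace = TRUE)
  tru <- sample(c(-1, 0, 1), 200, replace = TRUE)
  fpr <- false_positive_rate(est, tru)
  tnr <- mean(est[tru != 1] != 1)
  expect_equal(fpr + tnr, 1)
})

test_that("baseline harness is invariant to subject ordering", {
  sim <- small_binary_sim(n = 300)
  res <- run_baseline_harness(sim$frame, sim$truth, methods = c("LR", "LogR"),
                              eval_subset = 1:300)
  perm <- sample(300)
  fr2 <- treatment_frame(sim$frame$X[perm, ], sim$frame$eta[perm],
                         sim$frame$Y_f[perm], K = 2,
                         outcome_type = "binary")
  tr2 <- list(Y0 = sim$truth$Y0[perm], Y1 = sim$truth$Y1[perm],
              ITE = sim$truth$ITE[perm])
  res2 <- run_baseline_harness(fr2, tr2, methods = c("LR", "LogR"),
                               eval_subset = 1:300)
  expect_equal(res$mse_cf, res2$mse_cf, tolerance = 1e-10)
  expect_equal(res$ate, res2$ate, tolerance = 1e-10)
})

test_that("a baseline given the true surfaces as features is near-perfect", {
  sim <- small_binary_sim(n = 400)
  fr <- sim$frame
  oracle_X <- cbind(sim$truth$surface1, sim$truth$surface0)
  fr2 <- treatment_frame(oracle_X, fr$eta, fr$Y_f, K = 2,
                         outcome_type = "binary")
  res <- run_baseline_harness(fr2, sim$truth, methods = "RF_C",
                              eval_subset = seq_len(400))
  expect_gt(res$accuracy, 0.95)
})

test_that("unknown method names are rejected", {
  sim <- small_binary_sim(n = 100)
  expect_error(run_baseline_harness(sim$frame, sim$truth, methods = "XGB"),
               "unknown baseline")
})
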