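# The compiled trainer's semantics are pinned down two ways: the pure-R
# network is checked against numeric gradients, and a single sequential batch
# of the compiled trainer is reproduced exactly in R.

test_that("reference network gradients match numeric differentiation", {
  set.seed(101)
  net <- cfgan:::nn_init(3, 2, 2, hidden = 8)
  X <- matrix(rnorm(12), 4, 3)
  E <- matrix(rnorm(8), 4, 2)
  Y <- matrix(rbinom(8, 1, 0.5), 4, 2)
  loss <- function(net) {
    p <- cfgan:::nn_forward(net, X, E)
    -mean(rowSums(Y * log(p) + (1 - Y) * log(1 - p)))
  }
  fw <- cfgan:::nn_forward(net, X, E, cache = TRUE)
  g <- cfgan:::nn_backward(net, fw, (fw$out - Y) / 4)
  for (l in 1:5) {
    for (i in sample(length(net$W[[l]]), 3)) {
      eps <- 1e-5
      np <- net; np$W[[l]][i] <- np$W[[l]][i] + eps
      nm <- net; nm$W[[l]][i] <- nm$W[[l]][i] - eps
      expect_equal(g$gW[[l]][i], (loss(np) - loss(nm)) / (2 * eps),
                   tolerance = 1e-6)
    }
  }
  # gradient w.r.t. the concatenated extra inputs
  i <- 3; eps <- 1e-5
  Ep <- E; Ep[i] <- Ep[i] + eps
  Em <- E; Em[i] <- Em[i] - eps
  lp <- { p <- cfgan:::nn_forward(net, X, Ep); -mean(rowSums(Y * log(p) + (1 - Y) * log(1 - p))) }
  lm_ <- { p <- cfgan:::nn_forward(net, X, Em); -mean(rowSums(Y * log(p) + (1 - Y) * log(1 - p))) }
  expect_equal(g$dE[i], (lp - lm_) / (2 * eps), tolerance = 1e-6)
})

test_that("one compiled training batch equals the R reference exactly", {
  set.seed(202)
  n <- 16; q <- 4; K <- 2
  X <- matrix(rnorm(n * q), n, q)
  eta <- rep(1:2, 8)
  M <- matrix(0, n, K); M[cbind(1:n, eta)] <- 1
  Tm <- M
  yf <- rbinom(n, 1, 0.5)
  seed <- 77
  yc <- mean(yf); ys <- sd(yf)
  yfin <- (yf - yc) / ys
  res <- cfgan:::with_seed(seed,
    cfgan:::cpp_train_imputation(X, M, Tm, yf, yfin, yc, ys, 8L, 1e-4, 1e-3,
                                 0.1, 0.7, 1L, 16L, 0, 1, TRUE, FALSE, 0L,
                                 0.9, 0.999, TRUE))
  # R replica: same RNG stream -> same init, same z; sequential batch = rows
  set.seed(seed)
  G <- cfgan:::nn_init(q, 1 + 3 * K, K, hidden = 8)
  D <- cfgan:::nn_init(q, K, K, hidden = 8)
  z <- matrix(2 * runif(n * K) - 1, n, K)
  Eg <- cbind(yfin, Tm * M, M, (1 - M) * z)
  fwG <- cfgan:::nn_forward(G, X, Eg, cache = TRUE)
  Yt <- fwG$out
  Ybar <- (Yt * (1 - M) + yf * M - yc) / ys
  lr_fac <- 0.1  # batch 1 of 1 lies past the 70% decay window: floor rate
  fwD <- cfgan:::nn_forward(D, X, Ybar, cache = TRUE)
  p <- pmin(pmax(fwD$out, 1e-7), 1 - 1e-7)
  gD <- cfgan:::nn_backward(D, fwD, (p - M) / n)
  upD <- cfgan:::adam_update(D, cfgan:::adam_new(D), gD, 1e-4 * lr_fac)
  fwD2 <- cfgan:::nn_forward(upD$net, X, Ybar, cache = TRUE)
  p2 <- pmin(pmax(fwD2$out, 1e-7), 1 - 1e-7)
  gD2 <- cfgan:::nn_backward(upD$net, fwD2, (M - p2) / n)
  dYbar <- (gD2$dE / ys) * (1 - M)
  dPre <- dYbar * Yt * (1 - Yt) + (pmin(pmax(Yt, 1e-7), 1 - 1e-7) - yf) * M / n
  gG <- cfgan:::nn_backward(G, fwG, dPre)
  upG <- cfgan:::adam_update(G, cfgan:::adam_new(G), gG, 1e-3 * lr_fac)
  for (l in 1:5) {
    expect_equal(res$generator$W[[l]], upG$net$W[[l]], tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(res$discriminator$W[[l]], upD$net$W[[l]], tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_false(isTRUE(all.equal(res$generator$W[[l]],
                                  cfgan:::with_seed(seed, cfgan:::nn_init(
                                    q, 1 + 3 * K, K, hidden = 8))$W[[l]])))
  }
})

test_that("imputation_loss closed forms, monotonicity and oracle", {
  expect_equal(imputation_loss(rbind(c(0.5, 0.5)), rbind(c(1, 0))),
               2 * log(0.5), tolerance = 1e-12)
  # increasing in the factual-slot probability
  vals <- sapply(c(0.2, 0.4, 0.6, 0.8), function(p)
    imputation_loss(rbind(c(p, 0.5)), rbind(c(1, 0))))
  expect_true(all(diff(vals) > 0))
  # brute-force double loop on a batch of 16
  set.seed(33)
  Dm <- matrix(runif(32), 16, 2)
  M <- cbind(rbinom(16, 1, 0.5), 0); M[, 2] <- 1 - M[, 1]
  acc <- 0
  for (i in 1:16) for (k in 1:2)
    acc <- acc + M[i, k] * log(Dm[i, k]) + (1 - M[i, k]) * log(1 - Dm[i, k])
  expect_equal(imputation_loss(Dm, M), acc / 16, tolerance = 1e-10)
  # invariant under simultaneous column permutation
  expect_equal(imputation_loss(Dm[, 2:1], M[, 2:1]), imputation_loss(Dm, M))
  expect_error(imputation_loss(rbind(c(1.2, 0)), rbind(c(1, 0))), "outside")
})

test_that("loss at a fitted logistic discriminator equals its log-likelihood", {
  set.seed(44)
  n <- 80
  fr <- tiny_frame(n = n, q = 2, seed = 44)
  Ybar <- matrix(runif(n * 2), n, 2)
  Ybar[cbind(1:n, fr$eta)] <- fr$Y_f
  ll <- 0
  probs <- matrix(0, n, 2)
  for (k in 1:2) {
    fit <- suppressWarnings(glm(fr$M[, k] ~ fr$X + Ybar,
                                family = binomial()))
    probs[, k] <- fitted(fit)
    ll <- ll + as.numeric(logLik(fit))
  }
  expect_equal(imputation_loss(probs, fr$M), ll / n, tolerance = 1e-10)
})

test_that("generator ignores noise at the factual slot and is deterministic", {
  fr <- tiny_frame(n = 20, q = 3, seed = 55)
  fit <- train_imputation(fr, fast_config(total = 20))
  z1 <- matrix(0.3, 20, 2)
  z2 <- z1
  z2[cbind(1:20, fr$eta)] <- -0.9  # perturb only factual-slot noise
  o1 <- generate_counterfactuals(fit$generator, fr, z = z1)
  o2 <- generate_counterfactuals(fit$generator, fr, z = z2)
  expect_identical(o1$values, o2$values)
  # identical z twice -> identical output
  o3 <- generate_counterfactuals(fit$generator, fr, z = z1)
  expect_identical(o1$values, o3$values)
  # same seed -> identical draws
  a <- generate_counterfactuals(fit$generator, fr, n_draws = 3, seed = 8)
  b <- generate_counterfactuals(fit$generator, fr, n_draws = 3, seed = 8)
  expect_identical(a$values, b$values)
  expect_error(generate_counterfactuals(fit$generator, tiny_frame(q = 5)),
               "dimension")
})

test_that("training is reproducible and a single batch updates parameters", {
  fr <- tiny_frame(n = 32, q = 3, seed = 66)
  f1 <- train_imputation(fr, fast_config(total = 50, seed = 5))
  f2 <- train_imputation(fr, fast_config(total = 50, seed = 5))
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$generator$W, f2$generator$W)
  init <- cfgan:::with_seed(5, cfgan:::nn_init(3, 7, 2))
  f3 <- train_imputation(fr, gan_config(total_batches = 1, seed = 5,
                                        trace_every = 1))
  expect_false(isTRUE(all.equal(f3$generator$W[[1]], init$W[[1]])))
  expect_error(train_imputation(fr, gan_config(batch_size = 64)),
               "batch_size")
})

test_that("discriminator probabilities are valid and trend upward in accuracy", {
  sim <- small_binary_sim(n = 400)
  fit <- train_imputation(sim$frame, fast_config(total = 1500, seed = 2))
  po <- generate_counterfactuals(fit$generator, sim$frame, n_draws = 5,
                                 seed = 3)
  yb <- make_complete(po, sim$frame)
  p <- discriminator_probs(fit$discriminator, sim$frame, yb)
  expect_true(all(p > 0 & p < 1))
  expect_equal(dim(p), c(400, 2))
  # smoothed early-vs-late discriminator accuracy does not degrade
  tr <- fit$trace
  half <- nrow(tr) %/% 2
  expect_gte(mean(tr$disc_accuracy[(half + 1):nrow(tr)]),
             mean(tr$disc_accuracy[1:half]) - 0.05)
})
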