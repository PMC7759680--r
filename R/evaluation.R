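# Evaluation metrics and the multi-method comparison harness.

#' Potential-outcome estimation metrics
#'
#' For binary outcomes, estimates are thresholded at 0.5 and the mean squared
#' error equals the misclassification proportion, so `mse = 1 - accuracy` and
#' `std = sd` of the 0/1 error indicator.  For continuous outcomes, raw
#' errors are used and `accuracy` is `NA`.
#'
#' @param est n x K estimated outcomes (probabilities or values).
#' @param truth n x K true outcomes.
#' @param binary logical.
#' @param subset optional logical/integer index selecting entries (e.g. only
#'   counterfactual slots).
#' @return list with `mse`, `std`, `accuracy`.
#' @export
outcome_metrics <- function(est, truth, binary = TRUE, subset = NULL) {
  est <- as.matrix(est)
  truth <- as.matrix(truth)
  if (!all(dim(est) == dim(truth))) stop("outcome_metrics: shape mismatch")
  if (binary) {
    err <- as.numeric(((est >= 0.5) + 0) != truth)
  } else {
    err <- as.numeric(est - truth)
  }
  if (!is.null(subset)) err <- err[subset]
  if (binary) {
    list(mse = mean(err), std = sd(err), accuracy = 1 - mean(err))
  } else {
    list(mse = mean(err^2), std = sd(err), accuracy = NA_real_)
  }
}

#' Replication error (factual-slot cross-entropy)
#'
#' Mean of `-y_f * log(yhat_f)` over subjects, where `yhat_f` is the
#' generator's reconstruction of the factual outcome at the assigned arm.
#' Probabilities are clamped below at 1e-7.
#'
#' @param y_f factual outcomes (0/1).
#' @param y_hat_f generator outputs at the factual slot.
#' @return scalar.
#' @examples
#' replication_error(1, exp(-1))  # 1
#' @export
replication_error <- function(y_f, y_hat_f) {
  if (any(y_hat_f < 0)) stop("replication_error: negative probabilities")
  mean(-y_f * log(pmax(y_hat_f, 1e-7)))
}

#' Separation distance
#'
#' Mean absolute difference between the factual outcome and the generated
#' outcomes at non-assigned arms, averaged over the non-assigned slots of
#' each subject and then over subjects.
#'
#' @param y_f factual outcomes.
#' @param Y_cf n x K generated outcome matrix.
#' @param M one-hot assignment matrix.
#' @return scalar.
#' @export
separation_distance <- function(y_f, Y_cf, M) {
  Y_cf <- as.matrix(Y_cf)
  M <- as.matrix(M)
  per <- rowSums(abs(Y_cf - y_f) * (1 - M)) / rowSums(1 - M)
  mean(per)
}

#' Rank-based AUC (Mann-Whitney form)
#'
#' Equals brute-force pair counting with ties counted one half.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical).
#' @return scalar in `[0, 1]`, or `NA` (with a warning) when only one class
#'   is present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("roc_auc: only one class present; AUC undefined")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Kullback-Leibler divergence between two ITE distributions
#'
#' Discrete KL over a shared support: the cells `{-1, 0, 1}` for binary ITEs,
#' otherwise a shared histogram over the combined range.  Every cell gets
#' `smooth` added before renormalization, so empty cells do not produce
#' infinities and identical samples give exactly 0.
#'
#' @param ite_a,ite_b numeric vectors (e.g. in-sample and out-of-sample ITE
#'   estimates).
#' @param bins number of histogram cells for continuous ITEs.
#' @param smooth additive smoothing constant.
#' @return scalar `>= 0`.
#' @export
kl_ite_divergence <- function(ite_a, ite_b, bins = 20L, smooth = 1e-6) {
  stopifnot(length(ite_a) > 0, length(ite_b) > 0)
  both <- c(ite_a, ite_b)
  if (all(both %in% c(-1, 0, 1))) {
    breaks <- c(-1.5, -0.5, 0.5, 1.5)
  } else {
    rg <- range(both)
    if (diff(rg) == 0) rg <- rg + c(-0.5, 0.5)
    breaks <- seq(rg[1], rg[2], length.out = bins + 1)
  }
  p <- graphics::hist(ite_a, breaks = breaks, plot = FALSE)$counts
  q <- graphics::hist(ite_b, breaks = breaks, plot = FALSE)$counts
  p <- (p + smooth) / sum(p + smooth)
  q <- (q + smooth) / sum(q + smooth)
  sum(p * log(p / q))
}

#' False-positive rate of positive-response prediction
#'
#' Among subjects whose true ITE is not +1, the proportion whose estimated
#' ITE is +1.  (The alternative all-subject denominator is obtained with
#' `denominator = "all"`.)
#'
#' @param ite_est estimated ITEs.
#' @param ite_true true ITEs.
#' @param denominator `"nonpositive"` (default) or `"all"`.
#' @return proportion in `[0, 1]`.
#' @export
false_positive_rate <- function(ite_est, ite_true,
                                denominator = c("nonpositive", "all")) {
  denominator <- match.arg(denominator)
  wrong <- ite_est == 1 & ite_true != 1
  if (denominator == "all") mean(wrong) else
    mean(ite_est[ite_true != 1] == 1)
}

# ---- baseline estimators (per-arm / T-learner protocol) --------------------

# Each baseline fits the outcome on covariates separately within every
# treatment arm and predicts every subject's outcome under every arm.
# Returns an n x K matrix of predictions on the outcome scale.

baseline_predict <- function(method, frame, k_neighbors = 5L, seed = 1L,
                             query_dose = NULL) {
  X <- frame$X
  n <- frame$n
  K <- frame$K
  binary <- frame$outcome_type == "binary"
  est <- matrix(NA_real_, n, K)
  # dose at which counterfactual dosed-arm outcomes are queried: the
  # subject's own dose when known (retained ground truth), else the factual
  dose_all <- if (!is.null(query_dose)) query_dose
              else frame$T[cbind(seq_len(n), frame$eta)]
  for (arm in seq_len(K)) {
    in_arm <- frame$eta == arm
    if (!any(in_arm)) stop("baseline_predict: empty arm ", arm)
    ytr <- frame$Y_f[in_arm]
    # continuous dosed arms include the dose as a predictor and predictions
    # are made at the subject's own (queried) dose
    dosed <- frame$outcome_type == "continuous" &&
      length(unique(frame$T[in_arm, arm])) > 1
    Xtr <- if (dosed) cbind(X[in_arm, , drop = FALSE], frame$T[in_arm, arm])
           else X[in_arm, , drop = FALSE]
    Xte <- if (dosed) cbind(X, dose_all) else X
    est[, arm] <- fit_predict_one(method, Xtr, ytr, Xte, binary, k_neighbors,
                                  seed)
  }
  est
}

fit_predict_one <- function(method, Xtr, ytr, Xte, binary, k_neighbors,
                            seed) {
  dtr <- as.data.frame(Xtr)
  names(dtr) <- paste0("v", seq_len(ncol(Xtr)))
  dte <- as.data.frame(Xte)
  names(dte) <- names(dtr)
  switch(method,
    LR = {
      fit <- lm(y ~ ., data = cbind(y = ytr, dtr))
      unname(predict(fit, dte))
    },
    LogR = {
      if (!binary) stop("LogR requires a binary outcome")
      fit <- suppressWarnings(glm(y ~ ., data = cbind(y = ytr, dtr),
                                  family = binomial()))
      unname(predict(fit, dte, type = "response"))
    },
    SVM = {
      fit <- e1071::svm(y ~ ., data = cbind(y = if (binary) factor(ytr)
                                            else ytr, dtr))
      pr <- predict(fit, dte)
      if (binary) as.numeric(as.character(pr)) else unname(pr)
    },
    KNN = {
      if (binary) {
        as.numeric(as.character(class::knn(Xtr, Xte, factor(ytr),
                                           k = k_neighbors)))
      } else {
        FNN::knn.reg(Xtr, Xte, ytr, k = k_neighbors)$pred
      }
    },
    BLR = bayes_ridge_predict(Xtr, ytr, Xte),
    RF_C = {
      if (!binary) stop("RF_C requires a binary outcome")
      fit <- ranger::ranger(y ~ ., data = cbind(y = factor(ytr), dtr),
                            num.trees = 200, seed = seed)
      as.numeric(as.character(predict(fit, dte)$predictions))
    },
    RF_R = {
      fit <- ranger::ranger(y ~ ., data = cbind(y = ytr, dtr),
                            num.trees = 200, seed = seed)
      predict(fit, dte)$predictions
    },
    stop("unknown baseline method: ", method)
  )
}

# Bayesian linear (ridge) regression with conjugate normal-gamma prior and
# evidence-maximization updates of the noise and weight precisions.
#' @noRd
bayes_ridge_predict <- function(Xtr, ytr, Xte, maxit = 50L, tol = 1e-6) {
  Xtr <- cbind(1, as.matrix(Xtr))
  Xte <- cbind(1, as.matrix(Xte))
  n <- nrow(Xtr)
  p <- ncol(Xtr)
  XtX <- crossprod(Xtr)
  Xty <- crossprod(Xtr, ytr)
  alpha <- 1e-6
  beta <- 1 / max(var(ytr), 1e-12)
  ev <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  for (it in seq_len(maxit)) {
    A <- alpha * diag(p) + beta * XtX
    m <- beta * solve(A, Xty)
    gamma <- sum(beta * ev / (alpha + beta * ev))
    alpha_new <- gamma / max(sum(m^2), 1e-12)
    beta_new <- (n - gamma) / max(sum((ytr - Xtr %*% m)^2), 1e-12)
    if (abs(alpha_new - alpha) < tol * alpha &&
        abs(beta_new - beta) < tol * beta) {
      alpha <- alpha_new; beta <- beta_new
      break
    }
    alpha <- alpha_new
    beta <- beta_new
  }
  A <- alpha * diag(p) + beta * XtX
  drop(Xte %*% (beta * solve(A, Xty)))
}

#' Multi-method comparison harness
#'
#' Fits each baseline per treatment arm (T-learner protocol), predicts every
#' arm for every subject and reports: counterfactual-slot estimation error
#' (`mse_cf`, `std`, `accuracy` for binary outcomes), the effect summary
#' under the complete-data convention (factual outcome kept, counterfactual
#' imputed) on the evaluation subset, and the false-positive rate of
#' positive-response prediction.  For continuous outcomes two dosed-arm
#' errors are reported: the prediction error on subjects with an observed
#' dose and the imputation error for untreated subjects queried at their
#' true dose; see the methods vignette for why the first is the headline.
#'
#' @param frame a [treatment_frame()] (arm 1 is the treated/dosed arm).
#' @param truth ground truth list from the simulators (`Y0`, `Y1`, `ITE`,
#'   optionally `dose`, `eval_idx`).
#' @param methods character vector among `LR`, `LogR`, `SVM`, `KNN`, `BLR`,
#'   `RF_C`, `RF_R` (`KNN` uses `k_neighbors`).
#' @param k_neighbors k for the KNN baseline.
#' @param eval_subset row indices for effect summaries; defaults to
#'   `truth$eval_idx` or all rows.
#' @param seed seed for stochastic baselines (random forest).
#' @return data frame with one row per method: `method`, `mse_cf`, `std`,
#'   `accuracy`, `att`, `atc`, `ate`, `n_neg`, `n_zero`, `n_pos`, `fpr`
#'   (binary outcomes) or `method`, `mse_ite` (dosed-arm prediction error on
#'   dosed subjects), `std`, `mse_ite_oos` (dosed-arm imputation error for
#'   untreated subjects at their true dose), `ate` (continuous).
#' @export
run_baseline_harness <- function(frame, truth, methods = c("LR", "RF_C"),
                                 k_neighbors = 5L, eval_subset = NULL,
                                 seed = 1L) {
  validate_frame(frame)
  binary <- frame$outcome_type == "binary"
  if (is.null(eval_subset))
    eval_subset <- if (!is.null(truth$eval_idx)) truth$eval_idx
                   else seq_len(frame$n)
  truth_mat <- cbind(truth$Y1, truth$Y0)
  rows <- lapply(methods, function(m) {
    est <- baseline_predict(m, frame, k_neighbors = k_neighbors, seed = seed,
                            query_dose = truth$dose)
    if (binary) {
      cf_mask <- frame$M == 0
      met <- outcome_metrics(est, truth_mat, binary = TRUE, subset = cf_mask)
      comp <- (est >= 0.5) + 0
      comp[cbind(seq_len(frame$n), frame$eta)] <- frame$Y_f
      rep_ <- effect_summary(comp, frame, 1, 2, subset = eval_subset)
      ite_full <- comp[, 1] - comp[, 2]
      data.frame(method = m, mse_cf = met$mse, std = met$std,
                 accuracy = met$accuracy,
                 att = rep_$att, atc = rep_$atc, ate = rep_$ate,
                 n_neg = rep_$counts[["-1"]], n_zero = rep_$counts[["0"]],
                 n_pos = rep_$counts[["1"]],
                 fpr = false_positive_rate(ite_full, truth$ITE))
    } else {
      # headline: dosed-arm prediction error on subjects with an observed
      # dose (in-sample for the per-arm fits); alongside it the
      # counterfactual variant: dosed-arm imputation for untreated subjects
      # at their true dose
      dosed <- frame$eta == 1
      err_in <- est[dosed, 1] - frame$Y_f[dosed]
      ite_oos <- est[!dosed, 1] - frame$Y_f[!dosed]
      err_oos <- ite_oos - truth$ITE[!dosed]
      data.frame(method = m, mse_ite = mean(err_in^2), std = sd(err_in),
                 mse_ite_oos = mean(err_oos^2),
                 ate = mean(est[, 1] - est[, 2]))
    }
  })
  do.call(rbind, rows)
}
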