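# Sparse biomarker selection: multi-response LASSO on estimated treatment
# effects, a dose-adjusted variant for continuous treatments, best-arm
# (optimal-treatment) selection, R-square decompositions and Garson
# importance for the trained generator networks.
#
# The penalized objectives are
#   min_B  || Y - X B ||_F^2 + lambda * sum |B_jl|                      (effects)
#   min_{G,B} || Y - T G - X B ||_F^2 + l1 sum|G| + l2 sum|B|           (dosed)
# solved by cyclic coordinate descent on standardized covariates, with
# coefficients reported on the original scale.  The objectives separate over
# response columns, so each column is solved independently.

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# Cyclic coordinate descent for ||y - Xb||^2 + sum_j penalty_j |b_j|.
# X and y are used as given (callers standardize); zero-variance columns keep
# coefficient 0.
#' @noRd
lasso_cd <- function(X, y, penalty, tol = 1e-10, maxit = 5000L) {
  p <- ncol(X)
  stopifnot(length(penalty) == p)
  cn2 <- colSums(X^2)
  b <- numeric(p)
  r <- y
  active <- which(cn2 > 1e-12)
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in active) {
      z <- sum(X[, j] * r) + cn2[j] * b[j]
      bn <- soft_threshold(z, penalty[j] / 2) / cn2[j]
      if (bn != b[j]) {
        r <- r - X[, j] * (bn - b[j])
        delta <- max(delta, abs(bn - b[j]))
        b[j] <- bn
      }
    }
    if (delta < tol) break
  }
  b
}

std_design <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv < 1e-12] <- 1
  list(Xs = sweep(sweep(X, 2, mu, "-"), 2, sdv, "/"), mu = mu, sd = sdv)
}

# Pooled (across response columns) single-feature and prefix R-squares.
pooled_r2 <- function(Y, X, features, accumulated = FALSE) {
  Y <- as.matrix(Y)
  sst <- sum(sweep(Y, 2, colMeans(Y), "-")^2)
  if (sst < 1e-12) return(rep(0, length(features)))
  vapply(seq_along(features), function(m) {
    cols <- if (accumulated) features[1:m] else features[m]
    Xm <- X[, cols, drop = FALSE]
    keep <- apply(Xm, 2, sd) > 1e-12
    if (!any(keep)) return(0)
    Xm <- cbind(1, Xm[, keep, drop = FALSE])
    sse <- sum(lm.fit(Xm, Y)$residuals^2)
    max(0, 1 - sse / sst)
  }, numeric(1))
}

biomarker_result <- function(beta, gamma = NULL, alpha = NULL, delta = NULL,
                             lambda, selected, extra = list()) {
  structure(c(list(beta = beta, gamma = gamma, alpha = alpha, delta = delta,
                   lambda = lambda, selected = selected), extra),
            class = "biomarker_result")
}

#' @export
print.biomarker_result <- function(x, ...) {
  cat("<biomarker_result>", nrow(x$selected), "features selected, lambda =",
      paste(signif(unlist(x$lambda), 4), collapse = ", "), "\n")
  if (nrow(x$selected)) print(utils::head(x$selected, 10))
  invisible(x)
}

#' LASSO selection of effect-predicting biomarkers
#'
#' Multi-response LASSO of estimated treatment effects (or potential
#' outcomes) on covariates: `argmin_B ||Y - X B||_F^2 + lambda sum |B_jl|`.
#' Covariates are standardized internally; coefficients are reported on the
#' original scale.  When `lambda` is `NULL` it is chosen by 5-fold
#' cross-validation on a log-spaced grid.
#'
#' @param Y_hat n x K matrix (or vector) of estimated effects.
#' @param X n x q covariate matrix.
#' @param lambda penalty (>= 0), or `NULL` for cross-validation.
#' @return A `biomarker_result` with `beta` (q x K, original scale),
#'   `intercept`, `lambda`, the standardized-problem fields (`beta_std`,
#'   `Xs`, `Yc`) used for optimality checks, and `selected`: the nonzero
#'   features ordered by decreasing single-feature R-square with accumulated
#'   R-square alongside.
#' @export
effect_lasso <- function(Y_hat, X, lambda = NULL) {
  Y <- as.matrix(Y_hat)
  X <- as.matrix(X)
  if (!is.null(lambda) && lambda < 0) stop("effect_lasso: lambda must be >= 0")
  sd_ <- std_design(X)
  Yc <- sweep(Y, 2, colMeans(Y), "-")
  if (is.null(lambda)) lambda <- cv_lambda(sd_$Xs, Yc)
  bstd <- vapply(seq_len(ncol(Y)),
                 function(l) lasso_cd(sd_$Xs, Yc[, l], rep(lambda, ncol(X))),
                 numeric(ncol(X)))
  bstd <- matrix(bstd, ncol = ncol(Y))
  beta <- bstd / sd_$sd
  intercept <- colMeans(Y) - drop(crossprod(beta, sd_$mu))
  sel_idx <- which(rowSums(abs(bstd)) > 0)
  selected <- selection_table(Y, X, sel_idx)
  biomarker_result(beta = beta, lambda = list(lambda = lambda),
                   selected = selected,
                   extra = list(intercept = intercept, beta_std = bstd,
                                Xs = sd_$Xs, Yc = Yc))
}

selection_table <- function(Y, X, sel_idx) {
  if (!length(sel_idx))
    return(data.frame(feature = integer(), r2_single = numeric(),
                      r2_accumulated = numeric()))
  r2s <- pooled_r2(Y, X, sel_idx)
  ord <- sel_idx[order(r2s, decreasing = TRUE)]
  data.frame(feature = ord,
             r2_single = sort(r2s, decreasing = TRUE),
             r2_accumulated = pooled_r2(Y, X, ord, accumulated = TRUE))
}

#' @noRd
cv_lambda <- function(Xs, Yc, nfolds = 5L, nlambda = 30L) {
  n <- nrow(Xs)
  lmax <- 2 * max(abs(crossprod(Xs, Yc)))
  grid <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = nlambda))
  folds <- rep_len(seq_len(nfolds), n)
  err <- matrix(0, nlambda, nfolds)
  for (f in seq_len(nfolds)) {
    tr <- folds != f
    for (i in seq_along(grid)) {
      b <- vapply(seq_len(ncol(Yc)), function(l)
        lasso_cd(Xs[tr, , drop = FALSE], Yc[tr, l], rep(grid[i], ncol(Xs))),
        numeric(ncol(Xs)))
      pred <- Xs[!tr, , drop = FALSE] %*% matrix(b, ncol = ncol(Yc))
      err[i, f] <- mean((Yc[!tr, , drop = FALSE] - pred)^2)
    }
  }
  grid[which.min(rowMeans(err))]
}

#' Dose-adjusted LASSO for continuous treatments
#'
#' Joint sparse fit of effects on doses and covariates:
#' `argmin_{G,B} ||Y - T G - X B||_F^2 + lambda1 sum|G| + lambda2 sum|B|`.
#' With an all-zero dose matrix this reduces exactly to [effect_lasso()]
#' with penalty `lambda2`.
#'
#' @param Y_hat n x K estimated effects.
#' @param T n x K dose matrix.
#' @param X n x q covariates.
#' @param lambda1 penalty on dose coefficients.
#' @param lambda2 penalty on covariate coefficients (`NULL`: cross-validated
#'   with `lambda1` fixed at its given value or 0).
#' @return A `biomarker_result` with `gamma` (K x K) and `beta` (q x K).
#' @export
effect_lasso_continuous <- function(Y_hat, T, X, lambda1 = 0, lambda2 = NULL) {
  Y <- as.matrix(Y_hat)
  T <- as.matrix(T)
  X <- as.matrix(X)
  if (lambda1 < 0 || (!is.null(lambda2) && lambda2 < 0))
    stop("effect_lasso_continuous: penalties must be >= 0")
  K <- ncol(T); q <- ncol(X)
  sd_ <- std_design(X)
  Tc <- sweep(T, 2, colMeans(T), "-")
  Yc <- sweep(Y, 2, colMeans(Y), "-")
  if (is.null(lambda2)) lambda2 <- cv_lambda(sd_$Xs, Yc)
  D <- cbind(Tc, sd_$Xs)
  pen <- c(rep(lambda1, K), rep(lambda2, q))
  coefs <- vapply(seq_len(ncol(Y)), function(l) lasso_cd(D, Yc[, l], pen),
                  numeric(K + q))
  coefs <- matrix(coefs, ncol = ncol(Y))
  gamma <- coefs[seq_len(K), , drop = FALSE]
  bstd <- coefs[K + seq_len(q), , drop = FALSE]
  beta <- bstd / sd_$sd
  sel_idx <- which(rowSums(abs(bstd)) > 0)
  biomarker_result(beta = beta, gamma = gamma,
                   lambda = list(lambda1 = lambda1, lambda2 = lambda2),
                   selected = selection_table(Y, X, sel_idx),
                   extra = list(beta_std = bstd, design = D, Yc = Yc,
                                penalty = pen))
}

#' Biomarkers for optimal treatment selection
#'
#' For each subject the best arm is `z_i = argmax_k Y_hat[i, k]` (ties broken
#' toward the lowest arm index) and the response is the best-arm outcome
#' `Y_hat[i, z_i]`; a LASSO of that response on covariates (and doses, for
#' continuous treatments) yields the optimal-treatment biomarkers as the
#' nonzero coefficients.
#'
#' @param Y_hat n x K estimated potential outcomes.
#' @param X covariates.
#' @param lambda covariate penalty (`NULL`: cross-validated).
#' @param T optional dose matrix for the continuous-treatment variant.
#' @param lambda1 dose penalty when `T` is given.
#' @return A `biomarker_result` with `alpha` (length q) and, when `T` is
#'   given, `delta` (length K); `extra$z` holds the best-arm indices.
#' @export
optimal_treatment_lasso <- function(Y_hat, X, lambda = NULL, T = NULL,
                                    lambda1 = 0) {
  Y <- as.matrix(Y_hat)
  X <- as.matrix(X)
  z <- max.col(Y, ties.method = "first")
  ybest <- Y[cbind(seq_len(nrow(Y)), z)]
  if (is.null(T)) {
    res <- effect_lasso(ybest, X, lambda)
    out <- biomarker_result(beta = res$beta, alpha = drop(res$beta),
                            lambda = res$lambda, selected = res$selected,
                            extra = list(z = z, intercept = res$intercept,
                                         beta_std = res$beta_std,
                                         Xs = res$Xs, Yc = res$Yc))
  } else {
    res <- effect_lasso_continuous(ybest, T, X, lambda1 = lambda1,
                                   lambda2 = lambda)
    out <- biomarker_result(beta = res$beta, gamma = res$gamma,
                            alpha = drop(res$beta), delta = drop(res$gamma),
                            lambda = res$lambda, selected = res$selected,
                            extra = list(z = z))
  }
  out
}

#' Single and accumulated R-square decomposition
#'
#' For an ordered feature selection, `r2_single` is the R-square of the
#' effect regressed on that feature alone, `r2_accumulated` the R-square on
#' the first m selected features jointly (non-decreasing by construction).
#' Constant features contribute 0, not `NaN`.
#'
#' @param effect numeric vector (or matrix; R-squares are pooled across
#'   columns).
#' @param X covariate matrix.
#' @param order integer feature indices in selection order; `NULL` ranks all
#'   features by decreasing `r2_single`.
#' @return data frame with `feature`, `r2_single`, `r2_accumulated`.
#' @export
r2_decomposition <- function(effect, X, order = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(effect)
  if (is.null(order)) {
    r2s <- pooled_r2(Y, X, seq_len(ncol(X)))
    order <- order(r2s, decreasing = TRUE)
  }
  data.frame(feature = order,
             r2_single = pooled_r2(Y, X, order),
             r2_accumulated = pooled_r2(Y, X, order, accumulated = TRUE))
}

#' Garson importance of covariate inputs
#'
#' Weight-magnitude decomposition of a trained feedforward network: the
#' absolute weight matrices along the covariate-to-output path are composed,
#' each covariate's contribution summed over outputs and the result
#' normalized to sum to one.  For the package's two-stage generators the path
#' runs through the covariate trunk (rows of the concatenation layer that
#' correspond to the trunk output).
#'
#' @param net a trained `cf_generator`/`ite_generator`, or a plain list of
#'   weight matrices for a generic feedforward network.
#' @return named numeric vector of importances (nonnegative, summing to 1).
#' @export
garson_importance <- function(net) {
  if (inherits(net, c("cf_generator", "ite_generator"))) {
    h <- net$hidden
    chain <- list(abs(net$W[[1]]), abs(net$W[[2]]),
                  abs(net$W[[3]][seq_len(h), , drop = FALSE]),
                  abs(net$W[[4]]), abs(net$W[[5]]))
  } else {
    chain <- lapply(net, function(w) abs(as.matrix(w)))
  }
  comp <- Reduce(`%*%`, chain)
  imp <- rowSums(comp)
  tot <- sum(imp)
  if (tot <= 0) return(rep(1 / length(imp), length(imp)))
  stats::setNames(imp / tot, paste0("x", seq_along(imp)))
}
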