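# ITE block: second conditional GAN learning the distribution of the full
# potential-outcome vector given covariates and treatment, trained on the
# completed dataset produced by the imputation block.

#' Train the ITE block
#'
#' The ITE generator `Yhat = G_I(X, T, Z)` is trained against a scalar
#' discriminator `D_I(X, T, Y*)` that scores the probability of `Y*` coming
#' from the complete dataset rather than the generator.  Each batch performs
#' one discriminator step (real up, generated down) and one generator step;
#' the generator loss adds a supervised match to the complete data (all K
#' slots) weighted by `config$supervised_weight`.  Unlike the imputation
#' generator, `G_I` is not conditioned on the factual outcome, so its
#' predictions for a new subject need only covariates and a treatment vector.
#'
#' @param Y_bar a `po_matrix` with provenance `"complete"` (from
#'   [make_complete()]), or a plain n x K matrix of complete outcomes.
#' @param frame the [treatment_frame()].
#' @param config a [gan_config()].
#' @return A list of class `ite_fit` with `generator` (class
#'   `ite_generator`), `discriminator`, `trace` (`batch`, `disc_accuracy`,
#'   `supervised_loss`, `loss_v`) and `config`.
#' @export
train_ite_block <- function(Y_bar, frame, config = gan_config()) {
  validate_frame(frame)
  vals <- if (inherits(Y_bar, "po_matrix")) {
    if (Y_bar$provenance != "complete")
      stop("train_ite_block: Y_bar must have provenance 'complete'")
    Y_bar$values
  } else as.matrix(Y_bar)
  if (frame$n < config$batch_size) stop("train_ite_block: n < batch_size")
  binary <- frame$outcome_type == "binary"
  sc <- frame_scaling(frame)
  sc$y_center <- mean(vals)
  sc$y_scale <- max(sd(vals), 1e-12)
  res <- with_seed(config$seed,
    cpp_train_ite(scale_x(frame$X, sc), scale_t(frame$T, sc), vals,
                  sc$y_center, sc$y_scale, config$hidden_width,
                  config$lr_discriminator, config$lr_generator,
                  config$decay_rate, config$decay_fraction,
                  config$total_batches, config$batch_size, config$dropout,
                  config$supervised_weight, binary, config$trace_every,
                  config$adam_beta1, config$adam_beta2, FALSE))
  gen <- structure(c(res$generator,
                     list(q = frame$q, K = frame$K, binary = binary,
                          scaling = sc)),
                   class = "ite_generator")
  disc <- structure(c(res$discriminator,
                      list(q = frame$q, K = frame$K, scaling = sc)),
                    class = "ite_discriminator")
  trace <- as.data.frame(res$trace)
  if (nrow(trace))
    names(trace) <- c("batch", "disc_accuracy", "supervised_loss", "loss_v")
  structure(list(generator = gen, discriminator = disc, trace = trace,
                 config = config),
            class = "ite_fit")
}

#' Sample potential-outcome vectors from a trained ITE generator
#'
#' Independent draws of `G_I(X, T, Z)` with `Z ~ U((-1,1)^K)`.  The first
#' array dimension indexes the draw.
#'
#' @param generator a trained `ite_generator`.
#' @param X covariate matrix (n x q).
#' @param T treatment-quantity matrix (n x K); this is a query, so doses may
#'   be placed in any arm, e.g. to read off a dose-response counterfactual.
#' @param n_draws number of draws.
#' @param seed optional seed.
#' @return numeric array `n_draws x n x K`.
#' @export
sample_potential_outcomes <- function(generator, X, T, n_draws = 100L,
                                      seed = NULL) {
  stopifnot(inherits(generator, "ite_generator"))
  if (n_draws < 1L) stop("sample_potential_outcomes: n_draws >= 1")
  X <- as.matrix(X)
  T <- as.matrix(T)
  if (ncol(X) != generator$q) stop("covariate dimension mismatch")
  K <- generator$K
  n <- nrow(X)
  sc <- generator$scaling
  Xs <- scale_x(X, sc)
  Ts <- scale_t(T, sc)
  net <- list(W = generator$W, b = generator$b,
              out_sigmoid = generator$binary, hidden = generator$hidden)
  run <- function() {
    out <- array(NA_real_, c(n_draws, n, K))
    for (s in seq_len(n_draws)) {
      z <- matrix(runif(n * K, -1, 1), n, K)
      out[s, , ] <- nn_forward(net, Xs, cbind(Ts, z))
    }
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Point estimate of the potential-outcome matrix from ITE-block draws
#'
#' Mean over draws; binary outcomes are thresholded at 0.5 afterwards when
#' `threshold = TRUE`.
#'
#' @param draws array from [sample_potential_outcomes()].
#' @param threshold threshold binarized output at 0.5 (binary outcomes).
#' @return n x K matrix.
#' @export
ite_point_estimate <- function(draws, threshold = FALSE) {
  est <- apply(draws, c(2, 3), mean)
  if (threshold) est <- (est >= 0.5) + 0
  est
}
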