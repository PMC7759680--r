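# Imputation block: counterfactual generator vs slot discriminator.

# Input standardization shared by both blocks: covariates centred and scaled,
# dose columns scale-only (structural zeros must stay zero), outcomes scaled
# for the network inputs while remaining raw as supervised targets.
#' @noRd
frame_scaling <- function(frame) {
  x_center <- colMeans(frame$X)
  x_scale <- apply(frame$X, 2, sd)
  x_scale[!is.finite(x_scale) | x_scale < 1e-12] <- 1
  t_scale <- apply(frame$T, 2, sd)
  t_scale[!is.finite(t_scale) | t_scale < 1e-12] <- 1
  y_center <- mean(frame$Y_f)
  y_scale <- sd(frame$Y_f)
  if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1
  list(x_center = x_center, x_scale = x_scale, t_scale = t_scale,
       y_center = y_center, y_scale = y_scale)
}

#' @noRd
scale_x <- function(X, sc) sweep(sweep(X, 2, sc$x_center, "-"), 2,
                                 sc$x_scale, "/")

#' @noRd
scale_t <- function(T, sc) sweep(T, 2, sc$t_scale, "/")

#' Train the counterfactual-imputation block
#'
#' Adversarial training of the counterfactual generator
#' `Ytilde = G(X, Y_f, T*M, (1-M)*z, theta)` against the discriminator that
#' scores, for each treatment slot, the probability of being the factual
#' component of the completed outcome vector.  Each batch performs one
#' discriminator ascent step and one generator descent step on the loss
#' `V = E[ M' log D + (1-M)' log(1-D) ]`; the generator additionally
#' minimizes a factual-reconstruction term weighted by
#' `config$supervised_weight`.
#'
#' @param frame a [treatment_frame()].
#' @param config a [gan_config()].
#' @return A list of class `imputation_fit` with `generator` (class
#'   `cf_generator`), `discriminator` (class `cf_discriminator`), a `trace`
#'   data frame (`batch`, `disc_accuracy`, `replication_error`,
#'   `separation_distance`, `loss_v`) and the `config`.
#' @export
train_imputation <- function(frame, config = gan_config()) {
  validate_frame(frame)
  stopifnot(inherits(config, "gan_config"))
  if (frame$n < config$batch_size)
    stop("train_imputation: n < batch_size")
  binary <- frame$outcome_type == "binary"
  sc <- frame_scaling(frame)
  res <- with_seed(config$seed,
    cpp_train_imputation(scale_x(frame$X, sc), frame$M,
                         scale_t(frame$T, sc), frame$Y_f,
                         (frame$Y_f - sc$y_center) / sc$y_scale,
                         sc$y_center, sc$y_scale,
                         config$hidden_width, config$lr_discriminator,
                         config$lr_generator, config$decay_rate,
                         config$decay_fraction, config$total_batches,
                         config$batch_size, config$dropout,
                         config$supervised_weight, binary,
                         config$disc_sees_tm, config$trace_every,
                         config$adam_beta1, config$adam_beta2, FALSE))
  gen <- structure(c(res$generator,
                     list(q = frame$q, K = frame$K, binary = binary,
                          scaling = sc)),
                   class = "cf_generator")
  disc <- structure(c(res$discriminator,
                      list(q = frame$q, K = frame$K,
                           sees_tm = config$disc_sees_tm, scaling = sc)),
                    class = "cf_discriminator")
  trace <- as.data.frame(res$trace)
  if (nrow(trace))
    names(trace) <- c("batch", "disc_accuracy", "replication_error",
                      "separation_distance", "loss_v")
  structure(list(generator = gen, discriminator = disc, trace = trace,
                 config = config),
            class = "imputation_fit")
}

#' @export
print.imputation_fit <- function(x, ...) {
  cat("<imputation_fit>\n")
  print(x$config)
  if (nrow(x$trace)) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("final: disc accuracy %.3f, replication error %.4f, separation %.4f\n",
                last$disc_accuracy, last$replication_error,
                last$separation_distance))
  }
  invisible(x)
}

#' Generate potential outcomes from a trained counterfactual generator
#'
#' Evaluates `G(X, Y_f, T*M, (1-M)*z)`.  The noise is masked to the
#' counterfactual slots, so the factual slot of the output is a deterministic
#' reconstruction of the observed outcome.  With `n_draws > 1` the outputs
#' are averaged over independent noise draws (the Monte-Carlo point
#' estimate); with an explicit `z` a single evaluation is returned.
#'
#' @param generator a trained `cf_generator`.
#' @param frame the [treatment_frame()].
#' @param z optional n x K noise matrix in (-1, 1); drawn uniformly when
#'   `NULL`.
#' @param n_draws number of noise draws to average over (ignored when `z` is
#'   given).
#' @param seed optional seed for the noise draws.
#' @return A [po_matrix()] with provenance `"generated"`.
#' @export
generate_counterfactuals <- function(generator, frame, z = NULL, n_draws = 1L,
                                     seed = NULL) {
  stopifnot(inherits(generator, "cf_generator"))
  if (ncol(frame$X) != generator$q)
    stop("generate_counterfactuals: covariate dimension mismatch")
  K <- generator$K
  run <- function() {
    if (is.null(z)) {
      out <- 0
      for (s in seq_len(n_draws)) {
        zs <- matrix(runif(frame$n * K, -1, 1), frame$n, K)
        out <- out + gen_forward(generator, frame, zs) / n_draws
      }
      out
    } else {
      gen_forward(generator, frame, as.matrix(z))
    }
  }
  vals <- if (is.null(seed)) run() else with_seed(seed, run())
  po_matrix(vals, "generated", factual_mask = frame$M)
}

#' @noRd
gen_forward <- function(generator, frame, z) {
  sc <- generator$scaling
  E <- cbind((frame$Y_f - sc$y_center) / sc$y_scale,
             scale_t(frame$T, sc) * frame$M, frame$M, (1 - frame$M) * z)
  net <- list(W = generator$W, b = generator$b,
              out_sigmoid = generator$binary, hidden = generator$hidden)
  nn_forward(net, scale_x(frame$X, sc), E)
}

#' Discriminator probabilities for a completed outcome matrix
#'
#' For each subject and arm, the modeled probability that the arm is the
#' factual one, evaluated on the complete data `Ybar`.
#'
#' @param discriminator a trained `cf_discriminator`.
#' @param frame the [treatment_frame()].
#' @param Y_bar a `po_matrix` with provenance `"complete"` (or a plain
#'   matrix).
#' @return n x K matrix with entries in (0, 1).
#' @export
discriminator_probs <- function(discriminator, frame, Y_bar) {
  stopifnot(inherits(discriminator, "cf_discriminator"))
  vals <- if (inherits(Y_bar, "po_matrix")) Y_bar$values else as.matrix(Y_bar)
  if (!all(dim(vals) == dim(frame$M)))
    stop("discriminator_probs: shape mismatch")
  sc <- discriminator$scaling
  vals_s <- (vals - sc$y_center) / sc$y_scale
  E <- if (isTRUE(discriminator$sees_tm))
    cbind(vals_s, scale_t(frame$T, sc), frame$M) else vals_s
  net <- list(W = discriminator$W, b = discriminator$b, out_sigmoid = TRUE,
              hidden = discriminator$hidden)
  p <- nn_forward(net, scale_x(frame$X, sc), E)
  if (any(!is.finite(p))) stop("discriminator_probs: non-finite output")
  p
}

#' Imputation-block adversarial loss
#'
#' Batch mean of `sum_k M_k log D_k + (1 - M_k) log(1 - D_k)`.  The
#' discriminator maximizes this quantity, the generator minimizes it.
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` inside the logarithms.
#'
#' @param D_out n x K matrix of discriminator probabilities.
#' @param M one-hot indicator matrix.
#' @return scalar loss value.
#' @examples
#' imputation_loss(rbind(c(0.5, 0.5)), rbind(c(1, 0)))  # 2*log(0.5)
#' @export
imputation_loss <- function(D_out, M) {
  D_out <- as.matrix(D_out)
  M <- as.matrix(M)
  if (!all(dim(D_out) == dim(M))) stop("imputation_loss: shape mismatch")
  if (any(D_out < 0 | D_out > 1)) stop("imputation_loss: probs outside [0,1]")
  p <- pmin(pmax(D_out, 1e-7), 1 - 1e-7)
  mean(rowSums(M * log(p) + (1 - M) * log(1 - p)))
}
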