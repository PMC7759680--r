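#' Hyperparameters for the adversarial blocks
#'
#' Architecture and training settings shared by the imputation and ITE
#' blocks: hidden width 64, batch size 16, discriminator/generator learning
#' rates 1e-4/1e-3, learning rate decayed exponentially to `decay_rate` of
#' its initial value over the first `decay_fraction` of batches and held
#' there, 20% dropout, Adam.  `total_batches` defaults to 50,000, scaled
#' down from the method's full schedule of 1,000,000 so a run trains in
#' minutes; see the methods vignette for how estimates vary with the
#' budget.
#'
#' @param hidden_width nodes per hidden layer.
#' @param batch_size minibatch size.
#' @param lr_discriminator,lr_generator Adam learning rates.
#' @param decay_rate final learning-rate multiplier after decay.
#' @param decay_fraction fraction of `total_batches` over which the
#'   exponential decay runs.
#' @param total_batches number of minibatch updates (one discriminator and
#'   one generator step each).
#' @param dropout dropout probability on hidden layers during training.
#' @param supervised_weight weight of the factual-reconstruction term added
#'   to the generator's adversarial loss (cross-entropy for binary outcomes,
#'   squared error for continuous ones).
#' @param disc_sees_tm if `TRUE` the imputation discriminator is additionally
#'   conditioned on `T` and `M` (the literal signature); the default `FALSE`
#'   conditions on `(X, Ybar)` only, since `M` (and one-hot `T`) identify the
#'   factual slot exactly and make the game degenerate.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param trace_every record training diagnostics every this many batches
#'   (0 disables the trace).
#' @param seed integer seed applied before weight initialization and
#'   training.
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(hidden_width = 64L, batch_size = 16L,
                       lr_discriminator = 1e-4, lr_generator = 1e-3,
                       decay_rate = 0.1, decay_fraction = 0.7,
                       total_batches = 50000L, dropout = 0.2,
                       supervised_weight = 1, disc_sees_tm = FALSE,
                       adam_beta1 = 0.9, adam_beta2 = 0.999,
                       trace_every = NULL, seed = 1L) {
  cfg <- list(hidden_width = as.integer(hidden_width),
              batch_size = as.integer(batch_size),
              lr_discriminator = lr_discriminator,
              lr_generator = lr_generator,
              decay_rate = decay_rate, decay_fraction = decay_fraction,
              total_batches = as.integer(total_batches), dropout = dropout,
              supervised_weight = supervised_weight,
              disc_sees_tm = isTRUE(disc_sees_tm),
              adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
              trace_every = if (is.null(trace_every))
                max(1L, as.integer(total_batches %/% 100)) else
                  as.integer(trace_every),
              seed = as.integer(seed))
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("gan_config: dropout in [0,1)")
  if (cfg$lr_discriminator <= 0 || cfg$lr_generator <= 0)
    stop("gan_config: learning rates must be positive")
  if (cfg$total_batches < 1L) stop("gan_config: total_batches >= 1")
  class(cfg) <- "gan_config"
  cfg
}

#' @export
print.gan_config <- function(x, ...) {
  cat(sprintf(paste0("<gan_config> hidden %d, batch %d, lr D/G %g/%g, ",
                     "decay %g over %g, %d batches, dropout %g, sup.w %g, seed %d\n"),
              x$hidden_width, x$batch_size, x$lr_discriminator,
              x$lr_generator, x$decay_rate, x$decay_fraction,
              x$total_batches, x$dropout, x$supervised_weight, x$seed))
  invisible(x)
}
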