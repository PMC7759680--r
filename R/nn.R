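# Reference (pure R) implementation of the two-stage feedforward network used
# by both GAN blocks.  The compiled trainer in src/gan.cpp is the fast path;
# this implementation defines the semantics: prediction from trained weights
# goes through nn_forward(), and the test-suite checks the compiled trainer's
# single-batch updates and numeric gradients against nn_backward().
#
# Layer plan: input -> 2 hidden -> [concat extra] -> 2 hidden -> output.
# All activations sigmoid; output sigmoid (binary outcomes) or identity.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @noRd
nn_init <- function(d_in, d_extra, d_out, hidden = 64, out_sigmoid = TRUE) {
  fin <- c(d_in, hidden, hidden + d_extra, hidden, hidden)
  fout <- c(hidden, hidden, hidden, hidden, d_out)
  W <- vector("list", 5)
  b <- vector("list", 5)
  for (l in 1:5) {
    lim <- sqrt(6 / (fin[l] + fout[l]))
    W[[l]] <- matrix((2 * runif(fin[l] * fout[l]) - 1) * lim, fin[l], fout[l])
    b[[l]] <- numeric(fout[l])
  }
  list(W = W, b = b, out_sigmoid = out_sigmoid, hidden = hidden)
}

# Forward pass; when `masks` (list of 4 dropout masks) is given they are
# applied after each hidden activation (inverted-dropout convention).
#' @noRd
nn_forward <- function(net, X, E, masks = NULL, cache = FALSE) {
  A <- Araw <- vector("list", 4)
  Z <- X
  for (l in 1:4) {
    if (l == 3) Z <- cbind(Z, E)
    a <- sigmoid(sweep(Z %*% net$W[[l]], 2, net$b[[l]], "+"))
    Araw[[l]] <- a
    if (!is.null(masks)) a <- a * masks[[l]]
    A[[l]] <- a
    Z <- a
  }
  out <- sweep(A[[4]] %*% net$W[[5]], 2, net$b[[5]], "+")
  if (isTRUE(net$out_sigmoid)) out <- sigmoid(out)
  if (!cache) return(out)
  list(out = out, A = A, Araw = Araw, X = X, E = E, masks = masks)
}

# Backward pass. `d_out` is the gradient w.r.t. the PRE-activation of the
# output layer.  Returns weight/bias gradients plus the gradient w.r.t. the
# extra (concatenated) inputs.
#' @noRd
nn_backward <- function(net, fw, d_out) {
  h <- net$hidden
  gW <- vector("list", 5)
  gb <- vector("list", 5)
  gW[[5]] <- crossprod(fw$A[[4]], d_out)
  gb[[5]] <- colSums(d_out)
  d <- d_out %*% t(net$W[[5]])
  dE <- NULL
  for (l in 4:1) {
    if (!is.null(fw$masks)) d <- d * fw$masks[[l]]
    d <- d * fw$Araw[[l]] * (1 - fw$Araw[[l]])
    inp <- if (l == 1) fw$X else if (l == 3) cbind(fw$A[[2]], fw$E) else fw$A[[l - 1]]
    gW[[l]] <- crossprod(inp, d)
    gb[[l]] <- colSums(d)
    d <- d %*% t(net$W[[l]])
    if (l == 3) {
      dE <- d[, (h + 1):ncol(d), drop = FALSE]
      d <- d[, 1:h, drop = FALSE]
    }
  }
  list(gW = gW, gb = gb, dE = dE)
}

#' @noRd
adam_new <- function(net) {
  list(mW = lapply(net$W, function(w) w * 0), vW = lapply(net$W, function(w) w * 0),
       mb = lapply(net$b, function(b) b * 0), vb = lapply(net$b, function(b) b * 0),
       t = 0L)
}

#' @noRd
adam_update <- function(net, st, g, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - b1^st$t
  c2 <- 1 - b2^st$t
  for (l in 1:5) {
    st$mW[[l]] <- b1 * st$mW[[l]] + (1 - b1) * g$gW[[l]]
    st$vW[[l]] <- b2 * st$vW[[l]] + (1 - b2) * g$gW[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (st$mW[[l]] / c1) / (sqrt(st$vW[[l]] / c2) + eps)
    st$mb[[l]] <- b1 * st$mb[[l]] + (1 - b1) * g$gb[[l]]
    st$vb[[l]] <- b2 * st$vb[[l]] + (1 - b2) * g$gb[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (st$mb[[l]] / c1) / (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(net = net, state = st)
}
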