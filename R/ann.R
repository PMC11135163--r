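# Internal feed-forward network machinery.
#
# A network is a list:
#   layer_sizes : integer vector, e.g. c(9, 19, 16, 1)
#   W           : list of weight matrices, W[[l]] is (m_{l-1} x m_l)
#   b           : list of bias vectors, length m_l
#   x_scale     : list(min, max) per input feature  (min-max to [-1, 1])
#   y_scale     : list(min, max) for the response
# Hidden layers use tanh; the output layer is affine. All training happens
# in the scaled space; predictions are mapped back through y_scale.

minmax_fit <- function(x) {
  x <- as.matrix(x)
  list(min = apply(x, 2L, min), max = apply(x, 2L, max))
}

minmax_scale <- function(x, sc) {
  x <- as.matrix(x)
  rng <- sc$max - sc$min
  rng[rng == 0] <- 1            # constant feature maps to -1, harmless
  sweep(sweep(x, 2L, sc$min), 2L, rng, "/") * 2 - 1
}

minmax_unscale <- function(u, sc) {
  u <- as.matrix(u)
  rng <- sc$max - sc$min
  rng[rng == 0] <- 1
  sweep(sweep((u + 1) / 2, 2L, rng, "*"), 2L, sc$min, "+")
}

# number of free parameters of an architecture
ann_n_weights <- function(layer_sizes) {
  l <- as.integer(layer_sizes)
  sum(l[-length(l)] * l[-1L]) + sum(l[-1L])
}

# seeded symmetric-uniform init scaled by fan-in
ann_init <- function(layer_sizes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(layer_sizes) - 1L
  W <- b <- vector("list", L)
  for (l in seq_len(L)) {
    m <- layer_sizes[l]; k <- layer_sizes[l + 1L]
    r <- 1 / sqrt(m)
    W[[l]] <- matrix(runif(m * k, -r, r), m, k)
    b[[l]] <- runif(k, -r, r)
  }
  list(W = W, b = b)
}

# flatten weights into one parameter vector (per layer: vec(W), then b)
ann_pack <- function(W, b) {
  unlist(c(rbind(lapply(W, as.numeric), lapply(b, as.numeric))),
         use.names = FALSE)
}

ann_unpack <- function(w, layer_sizes) {
  L <- length(layer_sizes) - 1L
  W <- b <- vector("list", L)
  pos <- 0L
  for (l in seq_len(L)) {
    m <- layer_sizes[l]; k <- layer_sizes[l + 1L]
    W[[l]] <- matrix(w[pos + seq_len(m * k)], m, k); pos <- pos + m * k
    b[[l]] <- w[pos + seq_len(k)]; pos <- pos + k
  }
  list(W = W, b = b)
}

# forward pass in scaled space; returns output and all layer activations
ann_forward_scaled <- function(W, b, U, keep = FALSE) {
  L <- length(W)
  A <- vector("list", L + 1L)
  A[[1L]] <- U
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% W[[l]], 2L, b[[l]], "+")
    A[[l + 1L]] <- if (l < L) tanh(Z) else Z
  }
  if (keep) list(yhat = A[[L + 1L]], A = A) else A[[L + 1L]]
}

# Jacobian d yhat / d w for a single-output network, plus outputs.
# Column order matches ann_pack. Backprop deltas D_l = d yhat / d z_l.
ann_jacobian <- function(W, b, U) {
  L <- length(W)
  fw <- ann_forward_scaled(W, b, U, keep = TRUE)
  A <- fw$A
  n <- nrow(U)
  D <- vector("list", L)
  D[[L]] <- matrix(1, n, 1L)                      # linear output unit
  for (l in rev(seq_len(L - 1L)))
    D[[l]] <- (D[[l + 1L]] %*% t(W[[l + 1L]])) * (1 - A[[l + 1L]]^2)
  blocks <- vector("list", 2L * L)
  for (l in seq_len(L)) {
    m <- nrow(W[[l]]); k <- ncol(W[[l]])
    blocks[[2L * l - 1L]] <-
      A[[l]][, rep(seq_len(m), times = k), drop = FALSE] *
      D[[l]][, rep(seq_len(k), each = m), drop = FALSE]
    blocks[[2L * l]] <- D[[l]]
  }
  list(J = do.call(cbind, blocks), yhat = fw$yhat)
}

# d yhat_scaled / d U (scaled inputs), n x n_inputs
ann_input_gradients_scaled <- function(W, b, U) {
  L <- length(W)
  fw <- ann_forward_scaled(W, b, U, keep = TRUE)
  A <- fw$A
  D <- matrix(1, nrow(U), 1L)
  for (l in rev(seq_len(L))) {
    D <- D %*% t(W[[l]])
    if (l > 1L) D <- D * (1 - A[[l]]^2)
  }
  D
}
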