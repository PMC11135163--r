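# shared fixtures: small random networks, toy datasets, numeric oracles

# a predict-ready network with random weights and given scalers
random_network <- function(layer_sizes, seed, x_scale = NULL, y_scale = NULL,
                           feature_names = NULL) {
  set.seed(seed)
  L <- length(layer_sizes) - 1L
  W <- lapply(seq_len(L), function(l)
    matrix(rnorm(layer_sizes[l] * layer_sizes[l + 1L], sd = 0.8),
           layer_sizes[l], layer_sizes[l + 1L]))
  b <- lapply(seq_len(L), function(l) rnorm(layer_sizes[l + 1L], sd = 0.3))
  ann_network(layer_sizes, W, b, x_scale = x_scale, y_scale = y_scale,
              feature_names = feature_names)
}

# composed-expression forward oracle: explicit per-point loop, no shared code
# with the layer-by-layer implementation
forward_oracle <- function(model, X) {
  net <- model$net
  xr <- net$x_scale$max - net$x_scale$min
  yr <- net$y_scale$max - net$y_scale$min
  vapply(seq_len(nrow(X)), function(i) {
    a <- 2 * (X[i, ] - net$x_scale$min) / xr - 1
    L <- length(net$W)
    for (l in seq_len(L)) {
      z <- drop(t(net$W[[l]]) %*% a) + net$b[[l]]
      a <- if (l < L) tanh(z) else z
    }
    (a + 1) / 2 * yr + net$y_scale$min
  }, numeric(1))
}

# central finite differences of predict() w.r.t. physical inputs, with the
# step taken as `step` in the scaled space
fd_gradients <- function(model, X, step = 1e-6) {
  xr <- model$net$x_scale$max - model$net$x_scale$min
  g <- matrix(NA_real_, nrow(X), ncol(X))
  for (j in seq_len(ncol(X))) {
    h <- step * xr[j] / 2
    Xp <- X; Xp[, j] <- Xp[, j] + h
    Xm <- X; Xm[, j] <- Xm[, j] - h
    g[, j] <- (predict(model, Xp, warn_extrapolation = FALSE) -
                 predict(model, Xm, warn_extrapolation = FALSE)) / (2 * h)
  }
  g
}

# 9-input data.frame with the model's column names, uniform features
toy_feature_frame <- function(n, seed) {
  set.seed(seed)
  d <- as.data.frame(matrix(runif(n * 8, 0, 30), n, 8))
  names(d) <- paste0("S", 1:8)
  d$T_K <- runif(n, 283.15, 363.15)
  d
}

# small viscosity-style dataset whose response is generated by a teacher
# network (exactly representable by a student of >= that capacity)
teacher_dataset <- function(n_systems = 10, per_system = 25, hidden = 4,
                            seed = 1, noise_sd = 0) {
  d <- toy_feature_frame(n_systems * per_system, seed)
  teacher <- random_network(c(9L, hidden, 1L), seed = seed + 100,
    x_scale = list(min = c(rep(0, 8), 283.15), max = c(rep(30, 8), 363.15)),
    y_scale = list(min = 0, max = 3))
  d$log_eta <- predict(teacher, as.matrix(d), warn_extrapolation = FALSE)
  if (noise_sd > 0) {
    set.seed(seed + 200)
    d$log_eta <- d$log_eta + rnorm(nrow(d), 0, noise_sd)
  }
  d$system_id <- rep(paste0("SYS", seq_len(n_systems)), each = per_system)
  list(data = d, teacher = teacher)
}
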