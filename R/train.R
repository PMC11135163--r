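# Levenberg-Marquardt training with Bayesian regularization.
#
# The regularized objective is
#     F(w) = beta * E_D + alpha * E_W,
# with E_D the sum of squared errors on the scaled targets and E_W the sum
# of squared weights. Under the evidence framework the hyperparameters are
# re-estimated each outer iteration from the effective number of parameters
#     gamma = N_w - 2 * alpha * tr(H^-1),       H = 2 beta J'J + 2 alpha I,
#     alpha = gamma / (2 E_W),   beta = (n - gamma) / (2 E_D),
# where J is the Jacobian of the network output with respect to the weights
# (Gauss-Newton approximation to the Hessian). The inner step is standard
# Levenberg-Marquardt damping on F.

ann_train <- function(X, y, hidden = c(19L, 16L),
                      method = c("br", "l2"),
                      max_iter = 150L, tol = 1e-9, seed = NULL,
                      lambda = 1e-3, mu0 = 5e-3, mu_max = 1e10,
                      x_scale = NULL, y_scale = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X); y <- as.numeric(y)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("features and targets must be finite", call. = FALSE)
  n <- nrow(X)
  layer_sizes <- c(ncol(X), as.integer(hidden), 1L)
  if (is.null(x_scale)) x_scale <- minmax_fit(X)
  if (is.null(y_scale)) y_scale <- minmax_fit(matrix(y))
  U <- minmax_scale(X, x_scale)
  t_sc <- as.numeric(minmax_scale(matrix(y), y_scale))

  init <- ann_init(layer_sizes, seed = seed)
  w <- ann_pack(init$W, init$b)
  Nw <- length(w)
  Id <- diag(Nw)

  alpha <- if (method == "br") 0.01 else lambda
  beta <- 1
  mu <- mu0
  singular <- FALSE

  eval_F <- function(w) {
    nb <- ann_unpack(w, layer_sizes)
    e <- as.numeric(ann_forward_scaled(nb$W, nb$b, U)) - t_sc
    list(ed = sum(e^2), ew = sum(w^2), e = e)
  }

  cur <- eval_F(w)
  Fcur <- beta * cur$ed + alpha * cur$ew
  rmse0 <- sqrt(cur$ed / n)
  hist <- vector("list", max_iter)
  converged <- FALSE
  gamma <- NA_real_
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    nb <- ann_unpack(w, layer_sizes)
    jac <- ann_jacobian(nb$W, nb$b, U)
    e <- as.numeric(jac$yhat) - t_sc
    ed <- sum(e^2); ew <- sum(w^2)
    JtJ <- crossprod(jac$J)

    if (method == "br") {
      H <- 2 * (beta * JtJ + alpha * Id)
      Hinv <- tryCatch(chol2inv(chol(H)), error = function(err) NULL)
      if (is.null(Hinv)) {        # ridge-stabilized fallback
        singular <- TRUE
        Hinv <- chol2inv(chol(H + 1e-8 * max(diag(H)) * Id))
      }
      gamma <- Nw - 2 * alpha * sum(diag(Hinv))
      gamma <- min(max(gamma, 1e-6), Nw)
      alpha <- gamma / max(2 * ew, 1e-12)
      beta <- max(n - gamma, 1e-3) / max(2 * ed, 1e-12)
    }

    Fcur <- beta * ed + alpha * ew
    g <- 2 * (beta * drop(crossprod(jac$J, e)) + alpha * w)
    A0 <- 2 * (beta * JtJ + alpha * Id)

    accepted <- FALSE
    while (mu <= mu_max) {
      step <- tryCatch(
        solve(A0 + mu * Id, -g),
        error = function(err) NULL)
      if (!is.null(step)) {
        w_try <- w + step
        trial <- eval_F(w_try)
        Ftry <- beta * trial$ed + alpha * trial$ew
        if (is.finite(Ftry) && Ftry < Fcur) {
          w <- w_try; cur <- trial
          mu <- max(mu / 10, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * 10
    }

    hist[[iter]] <- c(iter = iter, objective = Fcur, ed = ed, ew = ew,
                      alpha = alpha, beta = beta, gamma = gamma, mu = mu)
    if (!accepted) { converged <- TRUE; break }   # mu exhausted: local optimum
    rel <- abs(Fcur - (beta * cur$ed + alpha * cur$ew)) / max(Fcur, 1e-12)
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("training stopped at the iteration budget without convergence",
            call. = FALSE)
  if (singular)
    warning("near-singular Hessian approximation; ridge-stabilized inverse used",
            call. = FALSE)

  nb <- ann_unpack(w, layer_sizes)
  final <- eval_F(w)
  structure(
    list(layer_sizes = layer_sizes, W = nb$W, b = nb$b,
         x_scale = x_scale, y_scale = y_scale,
         method = method, seed = seed,
         alpha = alpha, beta = beta, gamma = gamma,
         n_weights = Nw, n_train = n,
         rmse_scaled = sqrt(final$ed / n), rmse_scaled_init = rmse0,
         iterations = iter, converged = converged,
         history = as.data.frame(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))),
    class = "des_ann_net")
}

# predictions (physical scale) from a raw net on a feature matrix
ann_predict <- function(net, X, warn_extrapolation = TRUE) {
  X <- as.matrix(X)
  if (warn_extrapolation) {
    lo <- sweep(X, 2L, net$x_scale$min, "<")
    hi <- sweep(X, 2L, net$x_scale$max, ">")
    n_out <- sum(rowSums(lo | hi) > 0)
    if (n_out > 0)
      warning(sprintf(
        "%d input point(s) outside the training feature ranges (extrapolation)",
        n_out), call. = FALSE)
  }
  U <- minmax_scale(X, net$x_scale)
  yhat <- ann_forward_scaled(net$W, net$b, U)
  as.numeric(minmax_unscale(yhat, net$y_scale))
}

#' Architecture grid search
#'
#' Trains one network per candidate architecture (same seed and training
#' configuration for all) and ranks them by RMSE of log10 viscosity on the
#' pooled train + test records. The selected architecture is the one with
#' the fewest weights among all candidates whose RMSE is within
#' `tolerance` (relative) of the best -- the simplest model that achieves
#' one of the lowest errors.
#'
#' @param data viscosity data.frame with descriptor columns and a `split`
#'   column (see [split_dataset()], [add_descriptors()]).
#' @param hidden_grid list of hidden-layer size vectors, e.g.
#'   `architecture_grid(1:25, 1:25)` for the full 25 single-layer + 625
#'   two-layer search.
#' @param tolerance relative RMSE tolerance for the simplicity tie-break
#'   (default 0.01).
#' @param ... passed to the trainer via [des_ann()] (`method`, `max_iter`,
#'   `seed`, ...).
#' @return An object of class `"des_ann_search"`: a data.frame with columns
#'   `architecture`, `n_weights`, `rmse` (sorted by RMSE), and attributes
#'   `selected` (the chosen hidden-layer vector) and `tolerance`.
#' @export
architecture_search <- function(data, hidden_grid, tolerance = 0.01, ...) {
  if (length(hidden_grid) == 0L)
    stop("`hidden_grid` is empty", call. = FALSE)
  pool <- if (!is.null(data$split)) data$split %in% c("train", "test") else
    rep(TRUE, nrow(data))
  rows <- lapply(hidden_grid, function(h) {
    fit <- des_ann(data = data, hidden = h, ...)
    pred <- predict(fit, data[pool, , drop = FALSE],
                    warn_extrapolation = FALSE)
    res <- pred - data$log_eta[pool]
    data.frame(architecture = paste(c(fit$net$layer_sizes), collapse = "-"),
               n_weights = fit$net$n_weights,
               rmse = sqrt(mean(res^2)))
  })
  tab <- do.call(rbind, rows)
  tab$hidden <- hidden_grid
  tab <- tab[order(tab$rmse), ]
  rownames(tab) <- NULL
  best <- tab$rmse[1L]
  ok <- tab$rmse <= best * (1 + tolerance)
  sel <- tab[ok, ][which.min(tab$n_weights[ok]), ]
  structure(tab, class = c("des_ann_search", "data.frame"),
            selected = sel$hidden[[1L]], tolerance = tolerance)
}

#' Candidate hidden-layer grid
#'
#' @param single neuron counts for single-hidden-layer candidates.
#' @param double neuron counts for each layer of two-hidden-layer
#'   candidates (full cross product, `length(double)^2` configurations);
#'   `NULL` for none.
#' @return List of hidden-layer size vectors.
#' @export
architecture_grid <- function(single = 1:25, double = 1:25) {
  grid <- lapply(single, function(k) k)
  if (!is.null(double))
    grid <- c(grid, unlist(lapply(double, function(k1)
      lapply(double, function(k2) c(k1, k2))), recursive = FALSE))
  grid
}

#' @export
print.des_ann_search <- function(x, n = 10L, ...) {
  cat("architecture search over", nrow(x), "candidates\n")
  sel <- attr(x, "selected")
  cat("selected (simplest within", sprintf("%.1f%%", 100 * attr(x, "tolerance")),
      "of best RMSE):", paste(sel, collapse = "-"), "\n\n")
  print.data.frame(head(x[, c("architecture", "n_weights", "rmse")], n))
  invisible(x)
}
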