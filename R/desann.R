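#' Default model formula: log10 viscosity on the nine QSPR inputs
#'
#' The network's inputs are the eight sigma-profile region areas S1..S8 and
#' the absolute temperature in kelvin; the response is log10 of viscosity
#' in mPa s.
#'
#' @return A formula.
#' @export
viscosity_formula <- function() {
  log_eta ~ S1 + S2 + S3 + S4 + S5 + S6 + S7 + S8 + T_K
}

#' Fit the sigma-profile neural-network viscosity model
#'
#' Fits a feed-forward neural network with tanh hidden layers and a linear
#' output unit that maps mixture descriptors (S1..S8, temperature) to log10
#' viscosity. Inputs and response are min-max scaled to \[-1, 1\] before
#' training. The default trainer minimizes the Bayesian-regularized
#' objective `beta * E_D + alpha * E_W` (sum of squared errors plus weight
#' decay) by Levenberg-Marquardt, with `alpha` and `beta` re-estimated each
#' iteration from the effective number of parameters
#' `gamma = N_w - 2 alpha tr(H^-1)` (evidence framework); `method = "l2"`
#' uses a fixed weight-decay penalty instead.
#'
#' If `data` carries a `split` column (see [split_dataset()]), only the
#' `"train"` rows are fitted and fit statistics are reported per split;
#' otherwise all rows are used for training.
#'
#' @param formula model formula; the default [viscosity_formula()] uses the
#'   columns produced by [add_descriptors()].
#' @param data data.frame with the model columns (and optionally `split`).
#' @param hidden integer vector of hidden-layer sizes, e.g. `c(19, 16)` for
#'   the 9-19-16-1 architecture.
#' @param method `"br"` (Bayesian regularization, default) or `"l2"`
#'   (fixed weight decay `lambda`).
#' @param max_iter outer Levenberg-Marquardt iteration budget.
#' @param tol relative objective-change convergence tolerance.
#' @param seed integer seed for the weight initialization (mandatory for
#'   reproducible fits).
#' @param lambda fixed weight-decay coefficient for `method = "l2"`.
#' @return An object of class `"des_ann"`; see Details. Methods:
#'   [print.des_ann()], [summary.des_ann()], [predict.des_ann()],
#'   [coef.des_ann()], [residuals.des_ann()], [fitted.des_ann()],
#'   [plot.des_ann()], [simulate.des_ann()].
#' @details The returned object contains `net` (layer sizes, weights,
#'   biases, input/output scalers), `training` diagnostics (final `alpha`,
#'   `beta`, effective parameters `gamma`, iteration history, convergence
#'   flag, seed), the model `terms`, per-split [fit_metrics()] and the
#'   fitted values and residuals for every row of `data`.
#' @examples
#' sim <- simulate_viscosity_dataset(n_hbd = 3, seed = 1,
#'                                   temperatures = seq(293.15, 333.15, 20))
#' d <- split_dataset(sim$data, seed = 1)
#' fit <- des_ann(data = d, hidden = c(6, 4), max_iter = 40, seed = 1)
#' fit
#' predict(fit, d[1:3, ], type = "eta")
#' @export
des_ann <- function(formula = viscosity_formula(), data,
                    hidden = c(19L, 16L),
                    method = c("br", "l2"),
                    max_iter = 150L, tol = 1e-9, seed = 1L,
                    lambda = 1e-3) {
  method <- match.arg(method)
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  tt <- attr(mf, "terms")
  X <- stats::model.matrix(tt, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  y <- unname(stats::model.response(mf))

  split_lab <- if (!is.null(data$split)) as.character(data$split) else
    rep("train", nrow(X))
  itrain <- which(split_lab == "train")
  if (length(itrain) == 0L)
    stop("no training rows (split == \"train\")", call. = FALSE)

  net <- ann_train(X[itrain, , drop = FALSE], y[itrain], hidden = hidden,
                   method = method, max_iter = max_iter, tol = tol,
                   seed = seed, lambda = lambda)

  fitted_all <- ann_predict(net, X, warn_extrapolation = FALSE)
  metrics <- lapply(base::split(seq_along(y), split_lab), function(idx)
    fit_metrics(y[idx], fitted_all[idx]))

  structure(
    list(net = net, terms = tt, formula = formula, call = cl,
         feature_names = colnames(X),
         X = X, y = y, split = split_lab,
         fitted = fitted_all, residuals = fitted_all - y,
         metrics = metrics),
    class = "des_ann")
}

# feature matrix for new data (data.frame via terms, or plain matrix)
des_ann_features <- function(object, newdata) {
  if (is.matrix(newdata)) {
    if (ncol(newdata) != length(object$feature_names))
      stop(sprintf("expected %d feature columns, got %d",
                   length(object$feature_names), ncol(newdata)),
           call. = FALSE)
    return(newdata)
  }
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, na.action = stats::na.fail)
  X <- stats::model.matrix(tt, mf)
  X[, colnames(X) != "(Intercept)", drop = FALSE]
}

#' Predict viscosity from a fitted model
#'
#' @param object a fitted [des_ann()] model.
#' @param newdata data.frame with the model's input columns (or a numeric
#'   feature matrix in the training column order). Omit for fitted values.
#' @param type `"log_eta"` (default) for log10 viscosity, `"eta"` for
#'   viscosity in mPa s.
#' @param warn_extrapolation warn when inputs fall outside the training
#'   feature ranges (the network will extrapolate there; see
#'   [williams_report()] for a quantitative reliability check).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.des_ann <- function(object, newdata, type = c("log_eta", "eta"),
                            warn_extrapolation = TRUE, ...) {
  type <- match.arg(type)
  pred <- if (missing(newdata) || is.null(newdata)) object$fitted else
    ann_predict(object$net, des_ann_features(object, newdata),
                warn_extrapolation = warn_extrapolation)
  if (type == "eta") 10^pred else pred
}

#' @export
fitted.des_ann <- function(object, ...) object$fitted

#' @rdname predict.des_ann
#' @param which split subset for residuals: `"all"`, `"train"`, `"test"` or
#'   `"external"`.
#' @export
residuals.des_ann <- function(object,
                              which = c("all", "train", "test", "external"),
                              ...) {
  which <- match.arg(which)
  if (which == "all") object$residuals else
    object$residuals[object$split == which]
}

#' Extract network weights
#'
#' @param object a fitted [des_ann()] model.
#' @param flat if `TRUE` (default) one named vector in packing order
#'   (per layer: column-major weights, then biases); otherwise the list of
#'   weight matrices and bias vectors.
#' @param ... unused.
#' @return Named numeric vector, or `list(W = , b = )`.
#' @export
coef.des_ann <- function(object, flat = TRUE, ...) {
  net <- object$net
  if (!flat) return(list(W = net$W, b = net$b))
  w <- ann_pack(net$W, net$b)
  nms <- unlist(lapply(seq_along(net$W), function(l) {
    m <- nrow(net$W[[l]]); k <- ncol(net$W[[l]])
    c(sprintf("W%d[%d,%d]", l, rep(seq_len(m), k), rep(seq_len(k), each = m)),
      sprintf("b%d[%d]", l, seq_len(k)))
  }))
  stats::setNames(w, nms)
}

#' @export
print.des_ann <- function(x, ...) {
  net <- x$net
  cat("sigma-profile neural-network viscosity model\n")
  cat("  architecture:", paste(net$layer_sizes, collapse = "-"),
      sprintf("(%d weights)\n", net$n_weights))
  cat(sprintf("  trainer: %s, %d iterations%s\n",
              if (net$method == "br") "Bayesian regularization (LM)"
              else sprintf("fixed L2 (lambda = %g)", x$call$lambda %||% 1e-3),
              net$iterations,
              if (net$converged) "" else " (budget reached)"))
  if (net$method == "br")
    cat(sprintf("  alpha = %.4g, beta = %.4g, effective parameters gamma = %.1f\n",
                net$alpha, net$beta, net$gamma))
  for (sp in intersect(c("train", "test", "external"), names(x$metrics))) {
    m <- x$metrics[[sp]]
    cat(sprintf("  %-8s n = %4d  R2 = %.5f  RMSE = %.5f  AARD = %.3f%%\n",
                sp, m$n, m$r_squared, m$rmse, m$aard_percent))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.des_ann <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$metrics, function(m)
    data.frame(n = m$n, r_squared = m$r_squared, rmse = m$rmse,
               aard_percent = m$aard_percent)))
  structure(list(model = object, metrics_table = tab),
            class = "summary.des_ann")
}

#' @export
print.summary.des_ann <- function(x, ...) {
  print(x$model)
  cat("\nfit statistics (log10 viscosity scale):\n")
  print(x$metrics_table, digits = 5)
  invisible(x)
}

#' Diagnostic plots for a fitted viscosity model
#'
#' `which = 1` draws the parity plot (calculated vs experimental log10
#' viscosity, by split); `which = 2` draws the Williams plot of
#' standardized residuals against leverage with the applicability-domain
#' boundaries (see [williams_report()]).
#'
#' @param x a fitted [des_ann()] model.
#' @param which 1 (parity) or 2 (Williams plot).
#' @param ... passed to the underlying plot call.
#' @return Invisibly, the plotted data.
#' @export
plot.des_ann <- function(x, which = 1L, ...) {
  if (which == 1L) {
    cols <- c(train = "#1f77b4", test = "#ff7f0e", external = "#2ca02c")
    col <- cols[x$split]; col[is.na(col)] <- "grey40"
    plot(x$y, x$fitted, col = col, pch = 16, cex = 0.6,
         xlab = expression(log[10] ~ eta[exp]),
         ylab = expression(log[10] ~ eta[calc]), ...)
    abline(0, 1, lty = 2)
    legend("topleft", legend = names(cols), col = cols, pch = 16, bty = "n")
    invisible(data.frame(observed = x$y, fitted = x$fitted, split = x$split))
  } else {
    rep <- williams_report(x)
    plot(rep, ...)
    invisible(rep)
  }
}

#' Simulate responses from a fitted model
#'
#' Draws log10-viscosity responses at the rows of `newdata` (default: the
#' training data) as model prediction plus Gaussian noise with the
#' training-residual standard deviation -- i.e. multiplicative lognormal
#' noise on the viscosity itself.
#'
#' @param object a fitted [des_ann()] model.
#' @param nsim number of simulated response vectors.
#' @param seed integer seed.
#' @param newdata optional data.frame of predictor rows.
#' @param ... unused.
#' @return data.frame with `nsim` columns of simulated log10 viscosities.
#' @export
simulate.des_ann <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                             ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- if (is.null(newdata)) object$fitted else
    predict(object, newdata, warn_extrapolation = FALSE)
  s <- stats::sd(residuals(object, "train"))
  out <- as.data.frame(replicate(nsim, mu + rnorm(length(mu), 0, s)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
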