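# Williams-plot applicability domain.
#
# The reliability region of a QSPR model is characterized by the leverage
# of each point in the training design and the standardized residual:
# points with leverage above the critical value h* are structurally far
# from the training chemistry; points with |SDR| > 3 are response outliers.

#' Leverage values against a training design
#'
#' Leverage of a point v (1 x d) against the training feature matrix V
#' (p x d) is `h = v (V'V)^-1 v'`, the diagonal of the hat matrix when the
#' query points are the training points themselves. The features must be on
#' the model's (scaled) input scale, with no intercept column, so the
#' design dimension d* equals the number of network inputs (9 here).
#'
#' @param V training feature matrix (p x d, full column rank expected).
#' @param query matrix of query points (defaults to `V` itself).
#' @return Numeric vector of leverages, one per query row.
#' @export
leverages <- function(V, query = V) {
  V <- as.matrix(V); query <- as.matrix(query)
  G <- crossprod(V)
  if (qr(V)$rank < ncol(V)) {
    warning("rank-deficient training design; using pseudo-inverse",
            call. = FALSE)
    Ginv <- MASS::ginv(G)
  } else {
    Ginv <- chol2inv(chol(G))
  }
  rowSums((query %*% Ginv) * query)
}

#' Critical leverage of a Williams plot
#'
#' The conventional warning leverage `h* = 3 (d* + 1) / p`, with d* the
#' number of model inputs and p the number of training points.
#'
#' @param d_star number of model inputs (9 for the S1..S8 + T model).
#' @param p number of training records; must exceed `d_star`.
#' @return Scalar h*.
#' @export
critical_leverage <- function(d_star, p) {
  if (p <= d_star)
    stop("need more training points than model inputs", call. = FALSE)
  3 * (d_star + 1) / p
}

#' Standardized residuals
#'
#' Residuals divided by the standard deviation of the reference (training)
#' residuals, so points from any split are judged against the training
#' error scale.
#'
#' @param residuals numeric residuals to standardize.
#' @param reference_residuals training residuals defining the scale.
#' @return Numeric SDR values.
#' @export
standardized_residuals <- function(residuals, reference_residuals = residuals) {
  s <- stats::sd(reference_residuals)
  if (!is.finite(s) || s == 0)
    stop("reference residuals have no spread; SDR undefined", call. = FALSE)
  residuals / s
}

#' Williams-plot applicability-domain report
#'
#' Flags every record of the model's dataset (training, internal test and
#' external test alike) by the two applicability-domain boundary tests:
#' leverage below the critical value `h* = 3 (d* + 1) / p` and standardized
#' residual within `(-sdr_limit, +sdr_limit)`. Coverage is the percentage
#' of all points inside both boundaries; predictions for points outside
#' should be taken with care.
#'
#' @param model a fitted [des_ann()] model.
#' @param newdata optional data.frame of extra query records to flag
#'   against the model's training domain (they contribute rows but the
#'   boundaries are still defined by the training set). Requires the
#'   response column for the residual test.
#' @param sdr_limit standardized-residual boundary (default 3).
#' @return An object of class `"des_ad"`: a data.frame with columns
#'   `leverage`, `sdr`, `flag` (inside / leverage_outlier /
#'   response_outlier / both) and `split`, with attributes `h_star`,
#'   `d_star`, `p` and `coverage_percent`.
#' @export
williams_report <- function(model, newdata = NULL, sdr_limit = 3) {
  stopifnot(inherits(model, "des_ann"))
  net <- model$net
  U_all <- minmax_scale(model$X, net$x_scale)
  itrain <- model$split == "train"
  V <- U_all[itrain, , drop = FALSE]
  d_star <- ncol(V)
  p <- nrow(V)
  res <- model$residuals
  split <- model$split
  U_q <- U_all
  if (!is.null(newdata)) {
    Xq <- des_ann_features(model, newdata)
    U_q <- rbind(U_q, minmax_scale(Xq, net$x_scale))
    obs <- stats::model.response(stats::model.frame(model$terms, newdata))
    res <- c(res, ann_predict(net, Xq, warn_extrapolation = FALSE) - obs)
    split <- c(split, rep("query", nrow(Xq)))
  }
  h <- leverages(V, U_q)
  h_star <- critical_leverage(d_star, p)
  ref <- res[seq_along(model$split)][itrain]
  if (stats::sd(ref) == 0) {        # degenerate perfect fit: no response outliers
    warning("training residuals have zero spread; all SDR set to 0",
            call. = FALSE)
    sdr <- rep(0, length(res))
  } else {
    sdr <- standardized_residuals(res, ref)
  }
  lev_out <- h >= h_star
  res_out <- abs(sdr) >= sdr_limit
  flag <- ifelse(lev_out & res_out, "both",
          ifelse(lev_out, "leverage_outlier",
          ifelse(res_out, "response_outlier", "inside")))
  out <- data.frame(leverage = h, sdr = sdr, flag = flag, split = split)
  structure(out, class = c("des_ad", "data.frame"),
            h_star = h_star, d_star = d_star, p = p,
            sdr_limit = sdr_limit,
            coverage_percent = 100 * mean(flag == "inside"))
}

#' @export
print.des_ad <- function(x, ...) {
  cat("Williams-plot applicability domain\n")
  cat(sprintf("  d* = %d, p = %d, h* = %.5f, |SDR| < %g\n",
              attr(x, "d_star"), attr(x, "p"), attr(x, "h_star"),
              attr(x, "sdr_limit")))
  print(table(x$flag))
  cat(sprintf("  coverage: %.3f%% of %d points inside\n",
              attr(x, "coverage_percent"), nrow(x)))
  invisible(x)
}

#' @export
plot.des_ad <- function(x, ...) {
  cols <- c(inside = "grey40", leverage_outlier = "#d62728",
            response_outlier = "#ff7f0e", both = "#9467bd")
  plot(x$leverage, x$sdr, col = cols[x$flag], pch = 16, cex = 0.6,
       xlab = "leverage h", ylab = "standardized residual", ...)
  abline(h = c(-1, 1) * attr(x, "sdr_limit"), lty = 2)
  abline(v = attr(x, "h_star"), lty = 2)
  invisible(x)
}

#' Export the Williams-plot table
#'
#' @param x a `"des_ad"` report.
#' @param path output CSV path (columns leverage, sdr, flag, split).
#' @return `path`, invisibly.
#' @export
write_ad_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
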