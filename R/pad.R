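# Partial-derivatives (PaD) sensitivity analysis.

#' Gradients of the predicted log10 viscosity with respect to the inputs
#'
#' Exact chain-rule derivatives of the network output through the affine
#' min-max scalers and the tanh hidden layers (`tanh' = 1 - tanh^2`). Both
#' the physical-scale derivatives d(log10 eta)/dx and the scaled-space
#' derivatives (network output per scaled input, the quantity used for
#' input-contribution ranking) are returned.
#'
#' @param model a fitted [des_ann()] model (or an object with the same
#'   `net` structure).
#' @param newdata data.frame or feature matrix of evaluation points
#'   (default: the model's own data).
#' @return List with matrices `physical` and `scaled` (rows = points,
#'   columns = the 9 inputs).
#' @export
pad_gradients <- function(model, newdata = NULL) {
  net <- model$net
  X <- if (is.null(newdata)) model$X else des_ann_features(model, newdata)
  U <- minmax_scale(X, net$x_scale)
  G_sc <- ann_input_gradients_scaled(net$W, net$b, U)   # d yhat_sc / d U
  x_rng <- net$x_scale$max - net$x_scale$min
  x_rng[x_rng == 0] <- 1
  y_rng <- net$y_scale$max - net$y_scale$min
  phys <- sweep(G_sc, 2L, 2 / x_rng, "*") * (y_rng / 2)
  colnames(G_sc) <- colnames(phys) <- model$feature_names
  list(physical = phys, scaled = G_sc)
}

#' Relative input contributions (PaD method)
#'
#' Ranks the model inputs by the partial derivatives of the output:
#' per-point gradients are squared, summed over the evaluation records, and
#' normalized to percentages over the reported input subset,
#' \deqn{C_j = 100 \frac{\sum_i g_{ij}^2}{\sum_{k \in subset} \sum_i g_{ik}^2}.}
#' Gradients are taken in the scaled input space, so the ranking does not
#' depend on the physical units of the inputs. By default only the eight
#' molecular descriptors are reported (temperature, a state variable rather
#' than a structural descriptor, is excluded from the normalization) and
#' gradients are aggregated over the training records.
#'
#' @param model a fitted [des_ann()] model.
#' @param newdata optional evaluation records (default: training split, or
#'   all rows if the model has no splits).
#' @param subset character vector of input names to report (default
#'   S1..S8).
#' @return An object of class `"des_pad"`: data.frame with columns `input`
#'   and `contribution_percent` (summing to 100), with the per-point
#'   scaled-gradient matrix as attribute `"gradients"`.
#' @export
relative_contributions <- function(model, newdata = NULL,
                                   subset = paste0("S", 1:8)) {
  if (is.null(newdata)) {
    idx <- if (any(model$split == "train")) model$split == "train" else
      rep(TRUE, length(model$split))
    G <- pad_gradients(model)$scaled[idx, , drop = FALSE]
  } else {
    G <- pad_gradients(model, newdata)$scaled
  }
  missing <- setdiff(subset, colnames(G))
  if (length(missing) > 0L)
    stop("unknown input(s): ", paste(missing, collapse = ", "), call. = FALSE)
  ssq <- colSums(G[, subset, drop = FALSE]^2)
  tot <- sum(ssq)
  if (tot == 0)
    stop("all gradients are zero; contributions undefined", call. = FALSE)
  out <- data.frame(input = subset,
                    contribution_percent = 100 * ssq / tot,
                    row.names = NULL)
  structure(out, class = c("des_pad", "data.frame"), gradients = G)
}

#' @export
print.des_pad <- function(x, ...) {
  cat("PaD relative input contributions (%)\n")
  ord <- order(-x$contribution_percent)
  for (i in ord)
    cat(sprintf("  %-4s %6.2f\n", x$input[i], x$contribution_percent[i]))
  invisible(x)
}

#' Export a contribution report
#'
#' @param x a `"des_pad"` report.
#' @param path output path; `.json` writes JSON, otherwise CSV. The
#'   per-point derivative table can be exported with `gradients = TRUE`
#'   (CSV only).
#' @param gradients include the per-point scaled gradients.
#' @return `path`, invisibly.
#' @export
write_pad <- function(x, path, gradients = FALSE) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(x), path, auto_unbox = TRUE,
                         digits = NA)
  } else if (gradients) {
    utils::write.csv(as.data.frame(attr(x, "gradients")), path,
                     row.names = FALSE)
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}
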