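# Model serialization: a documented JSON layout, plus a flat per-neuron
# weight-table CSV mirroring the way trained network weights are usually
# published in supplementary tables.

.model_schema_version <- "1.0"

#' Assemble a network from explicit weights
#'
#' Builds a predict-ready model object from layer sizes, weights, biases
#' and scalers, without training -- for importing published weights or
#' constructing small networks by hand.
#'
#' @param layer_sizes integer vector, inputs first, 1 output last.
#' @param W list of weight matrices, `W[[l]]` of dimension
#'   (`layer_sizes[l]` x `layer_sizes[l+1]`).
#' @param b list of bias vectors.
#' @param x_scale,y_scale min-max scaler lists (`list(min =, max =)`); the
#'   defaults are identity scalers on \[-1, 1\].
#' @param feature_names input column names (default S1..S8, T_K when 9
#'   inputs).
#' @return An object of class `"des_ann"` supporting [predict.des_ann()],
#'   [coef.des_ann()], [pad_gradients()] and serialization (no data-bound
#'   methods like [summary.des_ann()]).
#' @export
ann_network <- function(layer_sizes, W, b,
                        x_scale = NULL, y_scale = NULL,
                        feature_names = NULL) {
  layer_sizes <- as.integer(layer_sizes)
  L <- length(layer_sizes) - 1L
  stopifnot(length(W) == L, length(b) == L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(as.numeric(W[[l]]), layer_sizes[l], layer_sizes[l + 1L])
    b[[l]] <- as.numeric(b[[l]])
    if (length(b[[l]]) != layer_sizes[l + 1L])
      stop(sprintf("bias %d has wrong length", l), call. = FALSE)
  }
  n_in <- layer_sizes[1L]
  if (is.null(x_scale))
    x_scale <- list(min = rep(-1, n_in), max = rep(1, n_in))
  if (is.null(y_scale)) y_scale <- list(min = -1, max = 1)
  if (any(x_scale$max <= x_scale$min) || y_scale$max <= y_scale$min)
    stop("scalers must have max > min", call. = FALSE)
  if (is.null(feature_names))
    feature_names <- if (n_in == 9L) c(paste0("S", 1:8), "T_K") else
      paste0("x", seq_len(n_in))
  net <- list(layer_sizes = layer_sizes, W = W, b = b,
              x_scale = x_scale, y_scale = y_scale,
              method = "imported", seed = NULL,
              alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
              n_weights = ann_n_weights(layer_sizes),
              n_train = NA_integer_, iterations = 0L, converged = TRUE,
              history = NULL)
  structure(list(net = net, terms = NULL, formula = NULL,
                 call = sys.call(), feature_names = feature_names,
                 X = NULL, y = NULL, split = character(0),
                 fitted = NULL, residuals = NULL, metrics = list()),
            class = "des_ann")
}

#' Save / load a fitted model as JSON
#'
#' The JSON layout (schema version 1.0) stores layer sizes, per-layer
#' weight matrices and biases, the input/output min-max scalers, feature
#' names and training metadata -- everything needed to reproduce
#' predictions exactly.
#'
#' @param model a [des_ann()] or [ann_network()] model.
#' @param path JSON file path.
#' @return `write_des_ann`: `path`, invisibly. `read_des_ann`: the model.
#' @export
write_des_ann <- function(model, path) {
  stopifnot(inherits(model, "des_ann"))
  net <- model$net
  obj <- list(
    schema = "desvisc-ann", schema_version = .model_schema_version,
    layer_sizes = net$layer_sizes,
    weights = lapply(net$W, as.numeric),   # column-major per layer
    biases = net$b,
    x_scale = list(min = unname(net$x_scale$min),
                   max = unname(net$x_scale$max)),
    y_scale = list(min = unname(net$y_scale$min),
                   max = unname(net$y_scale$max)),
    feature_names = model$feature_names,
    metadata = list(method = net$method, seed = net$seed,
                    alpha = net$alpha, beta = net$beta, gamma = net$gamma,
                    iterations = net$iterations, converged = net$converged,
                    n_train = net$n_train))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_des_ann
#' @export
read_des_ann <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("not a readable model file: ", conditionMessage(e),
                         call. = FALSE))
  if (is.null(obj$schema) || obj$schema != "desvisc-ann")
    stop("file is not a desvisc model (missing schema marker)",
         call. = FALSE)
  if (!identical(as.character(obj$schema_version), .model_schema_version))
    stop(sprintf("unsupported model schema version '%s' (expected %s)",
                 obj$schema_version, .model_schema_version), call. = FALSE)
  ls <- as.integer(obj$layer_sizes)
  L <- length(ls) - 1L
  # jsonlite may simplify equal-length layer lists to a matrix; undo that
  as_layers <- function(x) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ])
    else if (is.list(x)) lapply(x, as.numeric)
    else list(as.numeric(x))
  }
  wflat <- as_layers(obj$weights)
  if (length(wflat) != L)
    stop("corrupt model file: weight layer count mismatch", call. = FALSE)
  W <- lapply(seq_len(L), function(l) matrix(wflat[[l]], ls[l], ls[l + 1L]))
  b <- as_layers(obj$biases)
  model <- ann_network(ls, W, b,
                       x_scale = list(min = obj$x_scale$min,
                                      max = obj$x_scale$max),
                       y_scale = list(min = obj$y_scale$min,
                                      max = obj$y_scale$max),
                       feature_names = obj$feature_names)
  md <- obj$metadata
  model$net$method <- md$method %||% "imported"
  model$net$seed <- md$seed
  model$net$alpha <- md$alpha %||% NA_real_
  model$net$beta <- md$beta %||% NA_real_
  model$net$gamma <- md$gamma %||% NA_real_
  model
}

#' Export / import the per-neuron weight table
#'
#' A flat CSV with one row per neuron: `layer`, `neuron`, `bias`, then the
#' incoming weights `w1, w2, ...` (padded with empty cells). This mirrors
#' the per-neuron tabulation used when network weights are published.
#' Scalers are not part of the table; `import_weight_table()` takes them
#' (or a template model) separately.
#'
#' @param model a [des_ann()] model.
#' @param path CSV path.
#' @return `export_weight_table`: `path`, invisibly.
#' @export
export_weight_table <- function(model, path) {
  net <- model$net
  maxin <- max(net$layer_sizes[-length(net$layer_sizes)])
  rows <- list()
  for (l in seq_along(net$W)) {
    k <- ncol(net$W[[l]])
    for (j in seq_len(k)) {
      w <- rep(NA_real_, maxin)
      w[seq_len(nrow(net$W[[l]]))] <- net$W[[l]][, j]
      rows[[length(rows) + 1L]] <-
        c(layer = l, neuron = j, bias = net$b[[l]][j], w)
    }
  }
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("layer", "neuron", "bias", paste0("w", seq_len(maxin)))
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_weight_table
#' @param x_scale,y_scale,feature_names scalers and names for the imported
#'   network (see [ann_network()]); alternatively pass `template`, a model
#'   whose scalers are reused.
#' @param template optional model providing scalers and feature names.
#' @return `import_weight_table`: an [ann_network()] model.
#' @export
import_weight_table <- function(path, x_scale = NULL, y_scale = NULL,
                                feature_names = NULL, template = NULL) {
  tab <- utils::read.csv(path)
  if (!all(c("layer", "neuron", "bias") %in% names(tab)))
    stop("not a weight-table CSV (need layer, neuron, bias columns)",
         call. = FALSE)
  if (!is.null(template)) {
    x_scale <- x_scale %||% template$net$x_scale
    y_scale <- y_scale %||% template$net$y_scale
    feature_names <- feature_names %||% template$feature_names
  }
  layers <- sort(unique(tab$layer))
  wcols <- grep("^w[0-9]+$", names(tab), value = TRUE)
  W <- b <- vector("list", length(layers))
  sizes <- integer(length(layers) + 1L)
  for (l in layers) {
    sub <- tab[tab$layer == l, ]
    sub <- sub[order(sub$neuron), ]
    wm <- as.matrix(sub[, wcols, drop = FALSE])
    n_in <- max(which(colSums(!is.na(wm)) > 0))
    W[[l]] <- t(wm[, seq_len(n_in), drop = FALSE])
    b[[l]] <- sub$bias
    sizes[l] <- n_in
    sizes[l + 1L] <- nrow(sub)
  }
  ann_network(sizes, W, b, x_scale = x_scale, y_scale = y_scale,
              feature_names = feature_names)
}
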