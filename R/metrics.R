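#' Fit statistics on the log10-viscosity scale
#'
#' Computes the three standard QSPR fit statistics between calculated and
#' experimental log10 viscosities:
#' \deqn{R^2 = 1 - \sum (y_{calc} - y_{exp})^2 / \sum (y_{exp} - \bar y_{exp})^2}
#' \deqn{RMSE = \sqrt{\sum (y_{calc} - y_{exp})^2 / n}}
#' \deqn{AARD = \frac{100}{n} \sum \left| \frac{y_{calc} - y_{exp}}{y_{exp}} \right| \%}
#' All three are computed on the logarithmic property, the scale the model
#' is trained and reported on. Points with `|y_exp| < 1e-9` are excluded
#' from the AARD (the relative deviation is undefined there, i.e. at
#' viscosities of ~1 mPa s exactly); their count is reported and a warning
#' is emitted.
#'
#' @param observed experimental log10 viscosities.
#' @param predicted calculated log10 viscosities, same length (n >= 2).
#' @return An object of class `"des_metrics"`: list with `r_squared`,
#'   `rmse`, `aard_percent`, `n`, `n_aard_excluded` and the per-record
#'   `residuals` (calculated minus experimental). `r_squared` is `NA` when
#'   the experimental values are constant (zero total sum of squares).
#' @export
fit_metrics <- function(observed, predicted) {
  observed <- as.numeric(observed); predicted <- as.numeric(predicted)
  if (length(observed) != length(predicted))
    stop("`observed` and `predicted` must have the same length", call. = FALSE)
  n <- length(observed)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  res <- predicted - observed
  ss_res <- sum(res^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  ok <- abs(observed) >= 1e-9
  if (any(!ok))
    warning(sprintf("AARD undefined for %d point(s) with |log eta| < 1e-9; excluded",
                    sum(!ok)), call. = FALSE)
  aard <- if (any(ok)) 100 * mean(abs(res[ok] / observed[ok])) else NA_real_
  structure(
    list(r_squared = r2, rmse = sqrt(ss_res / n), aard_percent = aard,
         n = n, n_aard_excluded = sum(!ok), residuals = res),
    class = "des_metrics")
}

#' @export
print.des_metrics <- function(x, ...) {
  cat(sprintf("n = %d  R2 = %s  RMSE = %.5f  AARD = %.4f%%\n", x$n,
              if (is.na(x$r_squared)) "NA" else sprintf("%.5f", x$r_squared),
              x$rmse, x$aard_percent))
  if (x$n_aard_excluded > 0)
    cat(sprintf("  (%d point(s) excluded from AARD)\n", x$n_aard_excluded))
  invisible(x)
}

#' Fraction of residuals within a band
#'
#' @param x a `"des_metrics"` object or a numeric residual vector.
#' @param band half-width of the closed band (default 0.05 log10 units:
#'   `|r| <= band` counts as inside).
#' @return Fraction in `[0, 1]`.
#' @export
residual_band_fraction <- function(x, band = 0.05) {
  r <- if (inherits(x, "des_metrics")) x$residuals else as.numeric(x)
  mean(abs(r) <= band)
}

#' Leave-one-system-out cross-validation
#'
#' For each DES system in turn, refits the model on every other system and
#' computes the coefficient of determination on the held-out system's
#' records. The cross-validation coefficient Q2 is the unweighted mean of
#' the per-system R2 values. Systems with fewer than 2 records, or with a
#' constant response, have no defined R2 and are excluded with a warning.
#'
#' @param data viscosity data.frame with `system_id` and the model columns.
#' @param formula model formula (default [viscosity_formula()]).
#' @param hidden,method,max_iter,tol,seed,lambda passed to [des_ann()];
#'   every refit uses the same configuration and seed.
#' @return An object of class `"des_loso"`: list with `systems` (data.frame
#'   of system id, n records, held-out R2), `q_squared`, and `excluded`.
#' @export
loso_cv <- function(data, formula = viscosity_formula(),
                    hidden = c(19L, 16L), method = "br",
                    max_iter = 150L, tol = 1e-9, seed = 1L, lambda = 1e-3) {
  ids <- unique(data$system_id)
  data$split <- NULL                      # refits use all remaining rows
  rows <- lapply(ids, function(id) {
    hold <- data$system_id == id
    if (sum(hold) < 2L) return(data.frame(system_id = id, n = sum(hold),
                                          r_squared = NA_real_))
    fit <- des_ann(formula, data[!hold, , drop = FALSE], hidden = hidden,
                   method = method, max_iter = max_iter, tol = tol,
                   seed = seed, lambda = lambda)
    pred <- predict(fit, data[hold, , drop = FALSE],
                    warn_extrapolation = FALSE)
    obs <- stats::model.response(
      stats::model.frame(formula, data[hold, , drop = FALSE]))
    m <- fit_metrics(obs, pred)
    data.frame(system_id = id, n = sum(hold), r_squared = m$r_squared)
  })
  tab <- do.call(rbind, rows)
  bad <- is.na(tab$r_squared)
  if (any(bad))
    warning(sprintf("%d system(s) with undefined held-out R2 excluded from Q2",
                    sum(bad)), call. = FALSE)
  structure(
    list(systems = tab, q_squared = mean(tab$r_squared[!bad]),
         excluded = tab$system_id[bad]),
    class = "des_loso")
}

#' @export
print.des_loso <- function(x, ...) {
  cat(sprintf(
    "leave-one-system-out cross-validation over %d systems\n  Q2 = %.4f\n",
    nrow(x$systems), x$q_squared))
  invisible(x)
}

#' Export a metrics or cross-validation report
#'
#' @param x a `"des_metrics"` or `"des_loso"` object.
#' @param path output path; `.json` extension writes JSON, anything else
#'   CSV (per-record residual table for metrics, per-system table for CV).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- unclass(x)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else if (inherits(x, "des_metrics")) {
    utils::write.csv(data.frame(residual = x$residuals), path,
                     row.names = FALSE)
  } else if (inherits(x, "des_loso")) {
    utils::write.csv(x$systems, path, row.names = FALSE)
  } else stop("unsupported report object", call. = FALSE)
  invisible(path)
}
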