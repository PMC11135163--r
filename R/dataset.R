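#' Columns required in a viscosity dataset
#'
#' The record schema mirrors the usual tabulation of DES viscosity data:
#' one row per measurement, identifying the system (acceptor, donor,
#' cosolvent and their molar composition), the temperature and the measured
#' viscosity.
#'
#' @format Character vector of required column names.
#' @keywords internal
viscosity_columns <- c("system_id", "hba", "hbd", "cosolvent",
                       "ratio_hba", "ratio_hbd", "x_hba", "x_hbd", "x_cosolv",
                       "T_K", "eta_mPas", "source")

# temperature window of the experimental database the model emulates
.t_domain <- c(283.15, 373.15)

#' Validate a viscosity data frame
#'
#' Checks the schema, positivity of viscosity, and that the three
#' mole-fraction columns sum to 1; sums within 1e-6 of 1 are renormalized,
#' larger discrepancies are rejected. Adds the derived `log_eta`
#' (log10 of viscosity in mPa s) column. Temperatures outside the
#' 283.15--373.15 K window are flagged with a warning (they are outside the
#' range the model family is normally trained on) but kept.
#'
#' @param data data.frame with the columns of [viscosity_columns].
#' @return The validated data.frame with `log_eta` added.
#' @export
validate_viscosity_data <- function(data) {
  missing <- setdiff(viscosity_columns, names(data))
  if (length(missing) > 0L)
    stop("viscosity data is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(data$eta_mPas) | data$eta_mPas <= 0)
  if (length(bad) > 0L)
    stop("viscosity must be positive; offending row(s): ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) ", ..." else "", call. = FALSE)
  xs <- data$x_hba + data$x_hbd + data$x_cosolv
  off <- which(abs(xs - 1) > 1e-6)
  if (length(off) > 0L)
    stop("mole fractions do not sum to 1; offending row(s): ",
         paste(head(off, 10L), collapse = ", "), call. = FALSE)
  data$x_hba <- data$x_hba / xs
  data$x_hbd <- data$x_hbd / xs
  data$x_cosolv <- data$x_cosolv / xs
  out_t <- sum(data$T_K < .t_domain[1L] | data$T_K > .t_domain[2L])
  if (out_t > 0L)
    warning(sprintf("%d record(s) outside the %.2f-%.2f K domain", out_t,
                    .t_domain[1L], .t_domain[2L]), call. = FALSE)
  data$log_eta <- log10(data$eta_mPas)
  data
}

#' Read a viscosity dataset from CSV
#'
#' @param path CSV file with header columns [viscosity_columns]; an optional
#'   `split` column (train/test/external) is preserved.
#' @return Validated data.frame with `log_eta` computed.
#' @export
read_viscosity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_viscosity_data(df)
}

#' Write a viscosity dataset to CSV
#'
#' @param data validated viscosity data.frame.
#' @param path output path. Split labels, descriptors and `log_eta`, when
#'   present, are written as extra columns.
#' @return `path`, invisibly.
#' @export
write_viscosity_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Ordered-response selection of the external test set
#'
#' Sorts all records by ascending log10 viscosity and labels every k-th
#' record (the k-th, 2k-th, ... in sorted order) as the external test set.
#' This systematic sampling gives an external set that spans the full
#' response range, from the least to the most viscous mixtures. Ties are
#' broken by original record order (stable sort).
#'
#' @param data validated viscosity data.frame with `log_eta`.
#' @param every_kth stride k >= 2; the default 9 takes roughly 11% of the
#'   data.
#' @return `data` with a `split` column: `"external"` for selected records,
#'   `NA` for the remainder (to be assigned by [random_split()]).
#' @export
ordered_response_split <- function(data, every_kth = 9L) {
  every_kth <- as.integer(every_kth)
  if (is.na(every_kth) || every_kth < 2L)
    stop("`every_kth` must be an integer >= 2", call. = FALSE)
  n <- nrow(data)
  ord <- order(data$log_eta)            # stable: ties keep original order
  pick <- ord[seq.int(every_kth, n, by = every_kth)]
  data$split <- NA_character_
  data$split[pick] <- "external"
  data
}

#' Random train/test assignment of the non-external records
#'
#' Shuffles the records not labelled external and assigns the first
#' `round(train_fraction * N)` of them to training (N is the TOTAL dataset
#' size, so `train_fraction = 0.8` gives the conventional 80% training
#' share of all data); the remaining non-external records form the internal
#' test set. Fully deterministic given the seed.
#'
#' @param data data.frame with the `split` column from
#'   [ordered_response_split()] (or all-`NA` split for no external set).
#' @param train_fraction training fraction of the total dataset, in (0, 1).
#' @param seed integer RNG seed (mandatory: splits must be reproducible).
#' @return `data` with `split` filled in as train/test/external.
#' @export
random_split <- function(data, train_fraction = 0.8, seed) {
  if (missing(seed) || is.null(seed))
    stop("`seed` is required for a reproducible split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  if (is.null(data$split)) data$split <- NA_character_
  n <- nrow(data)
  open <- which(is.na(data$split))
  n_train <- round(train_fraction * n)
  if (n_train > length(open) || n_train < 1L)
    stop(sprintf(
      "train fraction %.3f needs %d records but only %d are not external",
      train_fraction, n_train, length(open)), call. = FALSE)
  set.seed(seed)
  shuffled <- sample(open)
  data$split[shuffled[seq_len(n_train)]] <- "train"
  data$split[shuffled[-seq_len(n_train)]] <- "test"
  data
}

#' One-shot train / test / external partition
#'
#' Convenience wrapper: [ordered_response_split()] followed by
#' [random_split()].
#'
#' @inheritParams ordered_response_split
#' @inheritParams random_split
#' @return `data` with a complete `split` column.
#' @export
split_dataset <- function(data, every_kth = 9L, train_fraction = 0.8, seed) {
  random_split(ordered_response_split(data, every_kth), train_fraction, seed)
}

#' Attach mixture descriptors to a viscosity dataset
#'
#' Computes, for every record, the mole-fraction-weighted mixture
#' descriptors S1..S8 from the pure-compound descriptor table and the
#' record's composition, and adds them as columns. Records with
#' `x_cosolv = 0` ignore the cosolvent column (it may be empty).
#'
#' @param data validated viscosity data.frame.
#' @param descriptors pure-compound descriptor matrix from
#'   [descriptor_table()]; rownames must include every compound referenced.
#' @return `data` with columns S1..S8 appended.
#' @export
add_descriptors <- function(data, descriptors) {
  smat <- matrix(NA_real_, nrow(data), 8L,
                 dimnames = list(NULL, paste0("S", 1:8)))
  for (i in seq_len(nrow(data))) {
    comp <- c(data$hba[i], data$hbd[i])
    frac <- c(data$x_hba[i], data$x_hbd[i])
    if (data$x_cosolv[i] > 0) {
      comp <- c(comp, data$cosolvent[i])
      frac <- c(frac, data$x_cosolv[i])
    }
    # components may repeat across roles; aggregate before mixing
    frac <- tapply(frac, comp, sum)
    smat[i, ] <- mix_descriptors(descriptors, frac / sum(frac) * 1)
  }
  data[paste0("S", 1:8)] <- as.data.frame(smat)
  data
}
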