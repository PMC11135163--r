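# Synthetic sigma-profiles and viscosity datasets.
#
# The generator emulates the statistical structure of the experimental
# databases the viscosity model is built on: sigma-profiles as sums of
# Gaussian peaks (a dominant nonpolar band, plus donor-side and
# acceptor-side hydrogen-bonding peaks), and viscosities following a
# Vogel-Fulcher-Tammann temperature law whose coefficients are affine in
# the mixture descriptors, with multiplicative lognormal measurement noise.

#' Regular sigma grid
#'
#' @param n_points number of grid points (default 31, the conventional
#'   tabulation over \[-0.03, +0.03\]).
#' @param span half-width of the symmetric grid (e/A^2).
#' @return Numeric vector of sigma values.
#' @export
sigma_grid <- function(n_points = 31L, span = 0.03) {
  seq(-span, span, length.out = n_points)
}

#' Build a sigma-profile from Gaussian peaks
#'
#' Deterministic helper: samples a sum of Gaussian peaks on the regular
#' grid. Used by the random generator and directly in tests (e.g. a purely
#' nonpolar compound is a single narrow peak at sigma = 0).
#'
#' @param compound_id compound label.
#' @param centers,amplitudes,widths numeric vectors (one entry per peak) of
#'   peak centers (e/A^2), heights (A^2) and Gaussian standard deviations
#'   (e/A^2).
#' @param n_points,span grid specification, see [sigma_grid()].
#' @return A [sigma_profile()] object.
#' @export
gaussian_peak_profile <- function(compound_id, centers, amplitudes, widths,
                                  n_points = 31L, span = 0.03) {
  grid <- sigma_grid(n_points, span)
  dens <- rep(0, length(grid))
  for (i in seq_along(centers))
    dens <- dens + amplitudes[i] * exp(-(grid - centers[i])^2 /
                                         (2 * widths[i]^2))
  sigma_profile(compound_id, grid, dens)
}

#' Simulate a compound set of sigma-profiles
#'
#' Generates one hydrogen-bond acceptor (a chloride-salt-like profile with
#' a strong acceptor-side peak), `n_hbd` donors (nonpolar band plus
#' donor-side and acceptor-side peaks of random height) and `n_cosolvent`
#' small diluents (the same shape at a smaller total surface area).
#' All randomness is driven by `seed`.
#'
#' @param n_hbd number of hydrogen-bond donor compounds.
#' @param n_cosolvent number of cosolvent compounds.
#' @param seed integer seed (mandatory).
#' @param n_points grid points per profile (default 31).
#' @return Named list of [sigma_profile()] objects (`"ChCl"`, `"HBD1"`...,
#'   `"COS1"`...), with a named character vector of roles as attribute
#'   `"roles"`.
#' @export
simulate_sigma_profiles <- function(n_hbd = 6L, n_cosolvent = 2L, seed,
                                    n_points = 31L) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  set.seed(seed)
  rand_profile <- function(id, scale) {
    centers <- c(runif(1, -0.004, 0.004),                  # nonpolar band
                 runif(1, -0.006, 0.006),
                 runif(1, -0.022, -0.010),                 # HBD-side peak
                 runif(1, 0.010, 0.022))                   # HBA-side peak
    amps <- scale * c(runif(1, 60, 120), runif(1, 0, 60),
                      runif(1, 5, 45), runif(1, 5, 45))
    widths <- runif(4, 0.0015, 0.0035)
    gaussian_peak_profile(id, centers, amps, widths, n_points)
  }
  profiles <- list(
    ChCl = gaussian_peak_profile(
      "ChCl",
      centers = c(runif(1, -0.003, 0.003), runif(1, -0.016, -0.010),
                  runif(1, 0.013, 0.019)),
      amplitudes = c(runif(1, 50, 90), runif(1, 10, 30), runif(1, 60, 100)),
      widths = runif(3, 0.002, 0.0035), n_points = n_points))
  for (i in seq_len(n_hbd))
    profiles[[paste0("HBD", i)]] <- rand_profile(paste0("HBD", i), 1)
  for (i in seq_len(n_cosolvent))
    profiles[[paste0("COS", i)]] <-
      rand_profile(paste0("COS", i), runif(1, 0.25, 0.45))
  roles <- c("hba", rep("hbd", n_hbd), rep("cosolvent", n_cosolvent))
  names(roles) <- names(profiles)
  attr(profiles, "roles") <- roles
  profiles
}

#' Simulate a DES viscosity dataset
#'
#' Builds a full viscosity dataset over a grid of systems (acceptor:donor
#' molar ratios, optionally diluted by each cosolvent over a mole-fraction
#' grid) and temperatures. The noise-free law is Vogel-Fulcher-Tammann in
#' temperature with coefficients affine in the mixture descriptors,
#' \deqn{\log_{10} \eta = A(S) + B(S) / (T - T_0(S)),}
#' with `B > 0` (viscosity falls with temperature) and positive
#' descriptor loadings on `B` (dilution by a low-surface-area cosolvent
#' lowers the viscosity). The law is affinely calibrated so the noise-free
#' viscosities span `eta_range`; the calibrated coefficients are returned
#' as the recorded ground truth. Measurement noise is multiplicative
#' lognormal: Gaussian with standard deviation `noise_sd` on log10 eta.
#'
#' @param n_hbd,n_cosolvent,seed,n_points passed to
#'   [simulate_sigma_profiles()] (or supply `profiles` directly).
#' @param profiles optional pre-built profile list with a `"roles"`
#'   attribute.
#' @param ratios donor molar parts per part of acceptor, one pure DES
#'   system per donor and ratio.
#' @param cosolvent_fractions cosolvent mole-fraction grid for the diluted
#'   systems (zeros are dropped; dilution series use the first ratio).
#' @param temperatures temperature grid in K.
#' @param noise_sd noise standard deviation in log10 units (default 0.02).
#' @param eta_range target span of the noise-free viscosities in mPa s
#'   (default 0.39--4722, the realistic experimental span).
#' @return An object of class `"des_sim"`: list with `data` (validated
#'   viscosity data.frame including descriptor columns S1..S8), `profiles`,
#'   `descriptors` (pure-compound table), `truth` (coefficient vectors and
#'   the vectorized law `truth$law(S, T)`), and the generating `config`.
#' @export
simulate_viscosity_dataset <- function(n_hbd = 6L, n_cosolvent = 2L, seed,
                                       profiles = NULL,
                                       ratios = c(2, 3),
                                       cosolvent_fractions = c(0.2, 0.4, 0.6),
                                       temperatures = seq(283.15, 363.15, 10),
                                       noise_sd = 0.02,
                                       eta_range = c(0.39, 4722),
                                       n_points = 31L) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (is.null(profiles))
    profiles <- simulate_sigma_profiles(n_hbd, n_cosolvent, seed = seed,
                                        n_points = n_points)
  roles <- attr(profiles, "roles")
  hbds <- names(roles)[roles == "hbd"]
  cosolvents <- names(roles)[roles == "cosolvent"]
  hba <- names(roles)[roles == "hba"][1L]
  desc <- descriptor_table(profiles)

  set.seed(seed + 1L)
  coefs <- list(a0 = runif(1, -2.2, -1.6), a = runif(8, -0.005, 0.010),
                b0 = runif(1, 350, 450), b = runif(8, 1, 4),
                t0 = runif(1, 130, 150), t = runif(8, 0, 0.4))

  cosolvent_fractions <- cosolvent_fractions[cosolvent_fractions > 0]
  rows <- list()
  sysno <- 0L
  for (h in hbds) {
    for (r in ratios) {
      sysno <- sysno + 1L
      base_id <- paste0("DES", sysno)
      x <- ratio_to_fractions(1, r, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        system_id = base_id, hba = hba, hbd = h, cosolvent = "none",
        ratio_hba = 1, ratio_hbd = r,
        x_hba = x[["hba"]], x_hbd = x[["hbd"]], x_cosolv = 0,
        T_K = temperatures, eta_mPas = NA_real_, source = "synthetic")
      if (r == ratios[1L]) {
        for (ci in seq_along(cosolvents)) {
          rows[[length(rows) + 1L]] <- do.call(rbind, lapply(
            cosolvent_fractions, function(f) {
              x <- ratio_to_fractions(1, r, f)
              data.frame(
                system_id = paste0(base_id, ".", ci),
                hba = hba, hbd = h, cosolvent = cosolvents[ci],
                ratio_hba = 1, ratio_hbd = r,
                x_hba = x[["hba"]], x_hbd = x[["hbd"]],
                x_cosolv = x[["cosolvent"]],
                T_K = temperatures, eta_mPas = NA_real_,
                source = "synthetic")
            }))
        }
      }
    }
  }
  data <- do.call(rbind, rows)
  data <- add_descriptors(data, desc)
  S <- as.matrix(data[paste0("S", 1:8)])

  raw_law <- function(S, T_K) {
    A <- coefs$a0 + drop(S %*% coefs$a)
    B <- coefs$b0 + drop(S %*% coefs$b)
    T0 <- coefs$t0 + drop(S %*% coefs$t)
    if (any(T_K <= T0))
      stop("temperature at or below the divergence temperature T0",
           call. = FALSE)
    A + B / (T_K - T0)
  }
  raw <- raw_law(S, data$T_K)
  target <- log10(eta_range)
  if (diff(range(raw)) > 0) {
    slope <- diff(target) / diff(range(raw))
    inter <- target[1L] - slope * min(raw)
  } else {
    slope <- 1; inter <- 0
  }
  # calibrated law stays VFT with descriptor-affine coefficients
  coefs$a0 <- inter + slope * coefs$a0
  coefs$a <- slope * coefs$a
  coefs$b0 <- slope * coefs$b0
  coefs$b <- slope * coefs$b
  law <- function(S, T_K) {
    S <- matrix(S, ncol = 8L)
    A <- coefs$a0 + drop(S %*% coefs$a)
    B <- coefs$b0 + drop(S %*% coefs$b)
    T0 <- coefs$t0 + drop(S %*% coefs$t)
    if (any(T_K <= T0))
      stop("temperature at or below the divergence temperature T0",
           call. = FALSE)
    A + B / (T_K - T0)
  }
  log_eta_true <- law(S, data$T_K)
  set.seed(seed + 2L)
  data$eta_mPas <- 10^(log_eta_true + rnorm(nrow(data), 0, noise_sd))
  data <- validate_viscosity_data(data)
  data$log_eta_true <- log_eta_true

  structure(
    list(data = data, profiles = profiles, descriptors = desc,
         truth = c(coefs, list(law = law, noise_sd = noise_sd)),
         config = list(seed = seed, ratios = ratios,
                       cosolvent_fractions = cosolvent_fractions,
                       temperatures = temperatures, noise_sd = noise_sd,
                       eta_range = eta_range, n_points = n_points)),
    class = "des_sim")
}

#' @export
print.des_sim <- function(x, ...) {
  cat(sprintf(
    "synthetic DES viscosity dataset: %d records, %d systems, %d compounds\n",
    nrow(x$data), length(unique(x$data$system_id)), length(x$profiles)))
  cat(sprintf("  viscosity span %.4g - %.4g mPa s, noise sd %.3g (log10)\n",
              min(x$data$eta_mPas), max(x$data$eta_mPas), x$truth$noise_sd))
  invisible(x)
}

#' Write the synthetic fixtures to disk
#'
#' Writes the dataset CSV, one sigma-profile file per compound, and the
#' ground-truth law coefficients as JSON.
#'
#' @param sim a `"des_sim"` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_viscosity_csv(sim$data, file.path(dir, "viscosity.csv"))
  pdir <- file.path(dir, "profiles")
  dir.create(pdir, showWarnings = FALSE)
  for (p in sim$profiles)
    write_sigma_profile(p, file.path(pdir, paste0(p$compound_id, ".txt")))
  truth <- sim$truth[setdiff(names(sim$truth), "law")]
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
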