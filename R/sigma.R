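#' Construct a sigma-profile object
#'
#' A sigma-profile is the histogram of screening charge density over a
#' molecule's COSMO surface: for each charge density `sigma` (e/A^2) it gives
#' the surface area density `p(sigma)*A` (A^2). Profiles from COSMO-SAC-type
#' calculations are tabulated on a regular grid, conventionally 31 points over
#' \[-0.03, +0.03\]; grids with 31--61 points are accepted.
#'
#' The negative-sigma end of the grid corresponds to positively charged
#' (hydrogen-bond donating) surface patches, the positive end to negatively
#' charged (accepting) patches.
#'
#' @param compound_id character label for the compound.
#' @param sigma numeric vector of screening charge densities (e/A^2),
#'   strictly increasing.
#' @param area_density numeric vector of `p(sigma)*A` values (A^2), same
#'   length as `sigma`, all non-negative.
#' @return An object of class `"sigma_profile"`: a list with elements
#'   `compound_id`, `sigma`, `area_density` and `n_points`.
#' @seealso [read_sigma_profile()], [sigma_descriptors()]
#' @export
sigma_profile <- function(compound_id, sigma, area_density) {
  sigma <- as.numeric(sigma)
  area_density <- as.numeric(area_density)
  if (length(sigma) != length(area_density))
    stop("`sigma` and `area_density` must have the same length", call. = FALSE)
  if (length(sigma) < 2L)
    stop("a sigma-profile needs at least 2 grid points", call. = FALSE)
  if (any(!is.finite(sigma)) || any(!is.finite(area_density)))
    stop("sigma-profile values must be finite", call. = FALSE)
  if (any(diff(sigma) <= 0))
    stop("sigma grid must be strictly increasing", call. = FALSE)
  if (any(area_density < 0))
    stop("area density must be non-negative everywhere", call. = FALSE)
  structure(
    list(compound_id = as.character(compound_id)[1L],
         sigma = sigma,
         area_density = area_density,
         n_points = length(sigma)),
    class = "sigma_profile"
  )
}

#' @export
print.sigma_profile <- function(x, ...) {
  cat("sigma-profile for", x$compound_id, "\n")
  cat(sprintf("  %d grid points over [%g, %g] e/A^2\n",
              x$n_points, min(x$sigma), max(x$sigma)))
  cat(sprintf("  total surface area: %.4f A^2\n", profile_area(x)))
  invisible(x)
}

#' Read a sigma-profile file
#'
#' Reads the two-column plain-text dialect used by open sigma-profile
#' databases: optional comment lines starting with `#`, then one row per grid
#' point with the charge density and the area density, separated by
#' whitespace or commas.
#'
#' @param path path to the file (or a connection).
#' @param compound_id compound label; defaults to the file name without
#'   extension.
#' @return A [sigma_profile()] object. Rows are sorted by ascending sigma.
#' @export
read_sigma_profile <- function(path, compound_id = NULL) {
  if (is.null(compound_id)) {
    compound_id <- if (is.character(path))
      sub("\\.[^.]*$", "", basename(path)) else "profile"
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- lines[keep]
  line_no <- seq_along(lines)[keep]
  if (length(rows) == 0L)
    stop("no data rows found in sigma-profile file", call. = FALSE)
  parts <- strsplit(trimws(rows), "[,[:space:]]+")
  bad <- which(vapply(parts, length, 1L) != 2L)
  vals <- suppressWarnings(lapply(parts, as.numeric))
  bad <- sort(unique(c(bad, which(vapply(vals, anyNA, TRUE)))))
  if (length(bad) > 0L)
    stop(sprintf("malformed sigma-profile row at line %d: '%s'",
                 line_no[bad[1L]], rows[bad[1L]]), call. = FALSE)
  m <- do.call(rbind, vals)
  ord <- order(m[, 1L])
  sigma_profile(compound_id, m[ord, 1L], m[ord, 2L])
}

#' Write a sigma-profile file
#'
#' Inverse of [read_sigma_profile()]; writes a `#`-comment header and the
#' two whitespace-separated columns.
#'
#' @param profile a [sigma_profile()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sigma_profile <- function(profile, path) {
  stopifnot(inherits(profile, "sigma_profile"))
  header <- sprintf("# sigma-profile: %s", profile$compound_id)
  body <- sprintf("%.17g %.17g", profile$sigma, profile$area_density)
  writeLines(c(header, "# sigma(e/A^2)  p(sigma)*A(A^2)", body), path)
  invisible(path)
}

#' Total area under a sigma-profile
#'
#' Trapezoidal integral of the area density over the whole grid; equals the
#' molecule's total COSMO surface area.
#'
#' @param profile a [sigma_profile()] object.
#' @return scalar area (A^2).
#' @export
profile_area <- function(profile) {
  stopifnot(inherits(profile, "sigma_profile"))
  trapz(profile$sigma, profile$area_density)
}

# trapezoidal rule on tabulated points
trapz <- function(x, y) sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)

# trapezoidal integral of the piecewise-linear interpolant of (x, y) over
# [a, b]; a and b may fall between grid points (linear interpolation there)
trapz_between <- function(x, y, a, b) {
  if (b <= a) return(0)
  ya <- stats::approx(x, y, xout = a, rule = 2)$y
  yb <- stats::approx(x, y, xout = b, rule = 2)$y
  inner <- x > a & x < b
  xs <- c(a, x[inner], b)
  ys <- c(ya, y[inner], yb)
  trapz(xs, ys)
}

#' Charge-density region scheme for descriptor discretization
#'
#' Partitions the sigma-profile span into eight contiguous regions whose
#' areas form the S1..S8 molecular descriptors. The default uses eight
#' equal-width intervals over \[-0.03, +0.03\] (width 0.0075), which places
#' the conventional hydrogen-bonding threshold |sigma| ~ 0.0075 at the
#' S3/S4 and S5/S6 edges and reproduces the standard grouping:
#' S1, S2 strong hydrogen-bond donor; S3 weak donor; S4, S5 nonpolar;
#' S6 weak acceptor; S7, S8 strong acceptor.
#'
#' @param edges nine strictly increasing sigma values bounding the eight
#'   regions; first and last must span the profile grid.
#' @return An object of class `"region_scheme"`: list with `edges` and the
#'   fixed `labels` mapping S1..S8 to their chemical interpretation.
#' @export
region_scheme <- function(edges = seq(-0.03, 0.03, length.out = 9L)) {
  edges <- as.numeric(edges)
  if (length(edges) != 9L)
    stop("a region scheme needs exactly 9 edges (8 regions)", call. = FALSE)
  if (any(diff(edges) <= 0))
    stop("region edges must be strictly increasing", call. = FALSE)
  structure(
    list(edges = edges,
         labels = c(S1 = "strong HBD", S2 = "strong HBD", S3 = "weak HBD",
                    S4 = "nonpolar", S5 = "nonpolar", S6 = "weak HBA",
                    S7 = "strong HBA", S8 = "strong HBA")),
    class = "region_scheme"
  )
}

#' @export
print.region_scheme <- function(x, ...) {
  cat("sigma-profile region scheme (8 regions)\n")
  for (i in 1:8)
    cat(sprintf("  S%d [%+.4f, %+.4f]  %s\n", i, x$edges[i], x$edges[i + 1L],
                x$labels[i]))
  invisible(x)
}

#' Discretize a sigma-profile into the S1..S8 region-area descriptors
#'
#' Integrates the area density over each of the eight charge-density regions
#' by the trapezoidal rule. Region edges falling between grid points are
#' handled by linear interpolation of the area density at the edge, so the
#' eight areas always sum to the total area under the profile.
#'
#' @param profile a [sigma_profile()] object.
#' @param scheme a [region_scheme()]; its edges must cover the profile grid.
#' @return Named numeric vector `c(S1 = ..., ..., S8 = ...)` of region areas,
#'   with the total area as attribute `"total_area"`.
#' @export
sigma_descriptors <- function(profile, scheme = region_scheme()) {
  stopifnot(inherits(profile, "sigma_profile"))
  if (!inherits(scheme, "region_scheme")) scheme <- region_scheme(scheme)
  e <- scheme$edges
  rng <- range(profile$sigma)
  tol <- 1e-12
  if (e[1L] > rng[1L] + tol || e[9L] < rng[2L] - tol)
    stop(sprintf(
      "region scheme [%g, %g] does not cover the profile grid [%g, %g]",
      e[1L], e[9L], rng[1L], rng[2L]), call. = FALSE)
  s <- vapply(1:8, function(i) {
    trapz_between(profile$sigma, profile$area_density,
                  max(e[i], rng[1L]), min(e[i + 1L], rng[2L]))
  }, numeric(1))
  names(s) <- paste0("S", 1:8)
  attr(s, "total_area") <- profile_area(profile)
  s
}

#' Descriptor table for a set of compounds
#'
#' @param profiles a (named) list of [sigma_profile()] objects.
#' @param scheme a [region_scheme()].
#' @return Numeric matrix, one row per compound (rownames are compound ids),
#'   columns S1..S8.
#' @export
descriptor_table <- function(profiles, scheme = region_scheme()) {
  if (inherits(profiles, "sigma_profile")) profiles <- list(profiles)
  tab <- t(vapply(profiles, sigma_descriptors, numeric(8), scheme = scheme))
  rownames(tab) <- vapply(profiles, function(p) p$compound_id, character(1))
  colnames(tab) <- paste0("S", 1:8)
  tab
}

#' Mole-fraction mixture descriptors
#'
#' Combines pure-component S1..S8 descriptors into the descriptors of a
#' mixture by the molar-weighted average
#' \deqn{S_i^{mix} = \sum_j x_j S_i^j, \quad i = 1..8,}
#' the conventional mixing rule for sigma-profile area descriptors.
#'
#' @param descriptors matrix of pure-component descriptors (rows = compounds,
#'   rownames = compound ids, columns S1..S8), e.g. from
#'   [descriptor_table()]; or a named list of descriptor vectors.
#' @param fractions named numeric vector of mole fractions (names = compound
#'   ids present in `descriptors`); must be non-negative and sum to 1 within
#'   1e-9.
#' @return Named numeric vector of mixture descriptors S1..S8.
#' @export
mix_descriptors <- function(descriptors, fractions) {
  if (is.list(descriptors) && !is.matrix(descriptors))
    descriptors <- do.call(rbind, descriptors)
  if (is.null(names(fractions)))
    stop("`fractions` must be named by compound id", call. = FALSE)
  if (any(fractions < 0))
    stop("mole fractions must be non-negative", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop(sprintf("mole fractions must sum to 1 (got %.12f)", sum(fractions)),
         call. = FALSE)
  missing <- setdiff(names(fractions), rownames(descriptors))
  if (length(missing) > 0L)
    stop("no descriptors for compound(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  s <- drop(fractions %*% descriptors[names(fractions), , drop = FALSE])
  names(s) <- colnames(descriptors)
  s
}

#' Mole fractions from an HBA:HBD molar ratio and a cosolvent fraction
#'
#' Deep eutectic solvents are specified as molar ratios of the hydrogen-bond
#' acceptor to the donor, e.g. choline chloride : glycerol (1:2); cosolvent
#' content is given as the cosolvent mole fraction of the final mixture.
#' The HBA and HBD parts are normalized to the DES mole fractions, then
#' rescaled by `1 - cosolvent_fraction`.
#'
#' @param hba_parts,hbd_parts positive molar parts of acceptor and donor.
#' @param cosolvent_fraction cosolvent mole fraction in `[0, 1)`.
#' @return Numeric vector `c(hba = , hbd = , cosolvent = )` summing to 1.
#' @examples
#' ratio_to_fractions(1, 2)        # ChCl:glycerol (1:2) -> (1/3, 2/3, 0)
#' ratio_to_fractions(1, 2, 0.5)   # the same DES diluted 50 mol% cosolvent
#' @export
ratio_to_fractions <- function(hba_parts, hbd_parts, cosolvent_fraction = 0) {
  if (hba_parts <= 0 || hbd_parts <= 0)
    stop("molar parts must be positive", call. = FALSE)
  if (cosolvent_fraction < 0 || cosolvent_fraction >= 1)
    stop("`cosolvent_fraction` must be in [0, 1)", call. = FALSE)
  tot <- hba_parts + hbd_parts
  x <- c(hba = hba_parts / tot, hbd = hbd_parts / tot) *
    (1 - cosolvent_fraction)
  c(x, cosolvent = cosolvent_fraction)
}

#' Export a descriptor table as CSV
#'
#' @param descriptors matrix from [descriptor_table()].
#' @param path output CSV path (columns `compound_id,S1..S8`).
#' @return `path`, invisibly.
#' @export
write_descriptor_csv <- function(descriptors, path) {
  df <- data.frame(compound_id = rownames(descriptors), descriptors,
                   row.names = NULL, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
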