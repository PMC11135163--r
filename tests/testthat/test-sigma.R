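# sigma-profile parsing, region discretization and mixture descriptors

write_profile_file <- function(path, sigma, dens, comments = TRUE,
                               sep = " ") {
  lines <- character(0)
  if (comments) lines <- c("# test profile", "")
  lines <- c(lines, paste(sigma, dens, sep = sep))
  writeLines(lines, path)
  path
}

test_that("the standard 31-point file parses with comments and either separator", {
  grid <- sigma_grid(31)
  dens <- pmax(0, 1 - abs(grid) / 0.03)
  for (sep in c(" ", "\t", ",")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_profile_file(f, grid, dens, sep = sep)
    p <- read_sigma_profile(f, "tri")
    expect_s3_class(p, "sigma_profile")
    expect_identical(p$n_points, 31L)
    expect_equal(range(p$sigma), c(-0.03, 0.03))
    expect_equal(p$area_density, dens)
  }
})

test_that("malformed files are rejected with an informative error", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header", "-0.03 1.0", "-0.02 oops", "-0.01 2.0"), f)
  expect_error(read_sigma_profile(f), "line 3")
  writeLines(c("0.01 1.0", "0.01 2.0"), f)   # duplicated grid point
  expect_error(read_sigma_profile(f), "strictly increasing")
  writeLines(c("-0.01 1.0", "0.01 -2.0"), f)
  expect_error(read_sigma_profile(f), "non-negative")
})

test_that("an all-zero profile is valid and has zero area and descriptors", {
  p <- sigma_profile("zero", sigma_grid(31), rep(0, 31))
  expect_equal(profile_area(p), 0)
  s <- sigma_descriptors(p)
  expect_equal(unname(s), rep(0, 8), ignore_attr = TRUE)
})

test_that("a 51-point synthetic profile round-trips through write and parse", {
  p <- gaussian_peak_profile("rt", centers = c(-0.012, 0, 0.015),
                             amplitudes = c(30, 90, 40),
                             widths = c(0.003, 0.002, 0.0025),
                             n_points = 51)
  f <- withr::local_tempfile(fileext = ".txt")
  write_sigma_profile(p, f)
  q <- read_sigma_profile(f, "rt")
  expect_equal(q$sigma, p$sigma)
  expect_equal(q$area_density, p$area_density)
  expect_identical(q$n_points, 51L)
})

test_that("region areas of a triangular profile match a fine Riemann oracle", {
  grid <- sigma_grid(31)
  tri <- function(x) pmax(0, 1 - abs(x) / 0.03)
  p <- sigma_profile("tri", grid, tri(grid))
  s <- sigma_descriptors(p)
  edges <- region_scheme()$edges
  # midpoint Riemann sum with 1e6 points per region on the exact function;
  # the 31-point grid includes the only kink (0), so the interpolant is exact
  for (i in 1:8) {
    m <- 1e6
    x <- seq(edges[i], edges[i + 1], length.out = m + 1)
    mid <- (x[-1] + x[-(m + 1)]) / 2
    oracle <- sum(tri(mid)) * (edges[i + 1] - edges[i]) / m
    expect_equal(s[[i]], oracle, tolerance = 1e-9)
  }
})

test_that("region areas always sum to the total profile area", {
  for (seed in 1:5) {
    profs <- simulate_sigma_profiles(n_hbd = 2, n_cosolvent = 1, seed = seed)
    for (p in profs) {
      s <- sigma_descriptors(p)
      expect_equal(sum(s), profile_area(p), tolerance = 1e-9)
    }
  }
})

test_that("region edges between grid points are handled by interpolation", {
  # 5-point coarse grid: every default region edge falls inside a segment
  p <- sigma_profile("coarse", seq(-0.03, 0.03, length.out = 5),
                     c(2, 1, 4, 0.5, 3))
  s <- sigma_descriptors(p)
  expect_equal(sum(s), profile_area(p), tolerance = 1e-12)
  # per-region oracle: dense midpoint sum of the linear interpolant
  f <- approxfun(p$sigma, p$area_density)
  edges <- region_scheme()$edges
  for (i in 1:8) {
    x <- seq(edges[i], edges[i + 1], length.out = 200001)
    mid <- (x[-1] + x[-length(x)]) / 2
    oracle <- sum(f(mid)) * diff(edges[i:(i + 1)]) / 200000
    expect_equal(s[[i]], oracle, tolerance = 1e-8)
  }
})

test_that("a scheme that does not cover the grid is a domain error", {
  p <- sigma_profile("x", sigma_grid(31), rep(1, 31))
  expect_error(sigma_descriptors(p, region_scheme(seq(-0.02, 0.02, length.out = 9))),
               "does not cover")
  expect_error(region_scheme(1:5), "9 edges")
  expect_error(region_scheme(c(0, 0, 1, 2, 3, 4, 5, 6, 7)), "increasing")
})

test_that("mixture descriptors are the mole-fraction weighted average", {
  tab <- rbind(A = c(2, rep(1, 7)), B = c(4, rep(3, 7)))
  colnames(tab) <- paste0("S", 1:8)
  expect_equal(mix_descriptors(tab, c(A = 1)), tab["A", ])
  m <- mix_descriptors(tab, c(A = 0.25, B = 0.75))
  expect_equal(m[["S1"]], 3.5)
  expect_equal(m[["S2"]], 2.5)
  expect_error(mix_descriptors(tab, c(A = 0.5, C = 0.5)), "C")
  expect_error(mix_descriptors(tab, c(A = 0.5, B = 0.6)), "sum to 1")
  expect_error(mix_descriptors(tab, c(A = -0.1, B = 1.1)), "non-negative")
})

test_that("mixing is associative and permutation invariant", {
  set.seed(11)
  tab <- matrix(runif(24, 0, 10), 3, 8,
                dimnames = list(c("A", "B", "C"), paste0("S", 1:8)))
  flat <- mix_descriptors(tab, c(A = 0.2, B = 0.3, C = 0.5))
  # nested: mix A and B first (renormalized), then combine with C
  ab <- mix_descriptors(tab, c(A = 0.4, B = 0.6))
  tab2 <- rbind(tab, AB = ab)
  nested <- mix_descriptors(tab2, c(AB = 0.5, C = 0.5))
  expect_equal(nested, flat, tolerance = 1e-12)
  perm <- mix_descriptors(tab, c(C = 0.5, A = 0.2, B = 0.3))
  expect_equal(perm, flat, tolerance = 1e-15)
})

test_that("molar ratios and cosolvent dilution convert to mole fractions", {
  expect_equal(unname(ratio_to_fractions(1, 2)), c(1, 2, 0) / 3,
               tolerance = 1e-12)
  x <- ratio_to_fractions(1, 2, 0.5)
  expect_equal(unname(x), c(1 / 6, 1 / 3, 1 / 2), tolerance = 1e-12)
  expect_equal(sum(x), 1)
  # a 1:3 acceptor:donor DES has donor mole fraction 0.75
  expect_equal(ratio_to_fractions(1, 3)[["hbd"]], 0.75)
  expect_error(ratio_to_fractions(-1, 2), "positive")
  expect_error(ratio_to_fractions(1, 2, 1), "cosolvent_fraction")
})

test_that("descriptor tables export to CSV", {
  profs <- simulate_sigma_profiles(n_hbd = 2, n_cosolvent = 1, seed = 4)
  tab <- descriptor_table(profs)
  expect_identical(dim(tab), c(4L, 8L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_csv(tab, f)
  back <- read.csv(f)
  expect_identical(names(back), c("compound_id", paste0("S", 1:8)))
  expect_equal(as.matrix(back[, -1]), tab, ignore_attr = TRUE,
               tolerance = 1e-12)
})
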