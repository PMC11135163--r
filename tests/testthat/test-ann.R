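# forward math, scaling, training, architecture search, serialization

test_that("a zero network predicts the midpoint of the output scaler", {
  m <- ann_network(c(9, 3, 1),
                   W = list(matrix(0, 9, 3), matrix(0, 3, 1)),
                   b = list(rep(0, 3), 0),
                   y_scale = list(min = 1, max = 3))
  X <- matrix(runif(45, -1, 1), 5, 9)
  expect_equal(predict(m, X, warn_extrapolation = FALSE), rep(2, 5))
})

test_that("a hand-built 2-1-1 tanh unit matches the closed form", {
  m <- ann_network(c(2, 1, 1),
                   W = list(matrix(c(1, 1), 2, 1), matrix(1, 1, 1)),
                   b = list(0, 0))
  U <- matrix(runif(40, -1, 1), 20, 2)
  expect_equal(predict(m, U, warn_extrapolation = FALSE),
               tanh(U[, 1] + U[, 2]), tolerance = 1e-15)
})

test_that("hidden activations stay strictly inside (-1, 1)", {
  m <- random_network(c(9, 7, 5, 1), seed = 3)
  X <- matrix(runif(900, -1.5, 1.5), 100, 9)  # beyond the scaler range
  U <- desvisc:::minmax_scale(X, m$net$x_scale)
  fw <- desvisc:::ann_forward_scaled(m$net$W, m$net$b, U, keep = TRUE)
  for (l in 2:3) {
    expect_true(all(fw$A[[l]] > -1))
    expect_true(all(fw$A[[l]] < 1))
  }
})

test_that("layer-by-layer evaluation matches a composed per-point oracle", {
  for (seed in 1:5) {
    sizes <- list(c(3, 4, 1), c(9, 5, 3, 1), c(2, 2, 2, 1))[[seed %% 3 + 1]]
    m <- random_network(sizes, seed = seed,
                        x_scale = list(min = rep(-2, sizes[1]),
                                       max = rep(5, sizes[1])),
                        y_scale = list(min = -0.5, max = 4))
    X <- matrix(runif(20 * sizes[1], -2, 5), 20, sizes[1])
    expect_equal(predict(m, X, warn_extrapolation = FALSE),
                 forward_oracle(m, X), tolerance = 1e-12)
  }
})

test_that("min-max scaling is invertible on the feature ranges", {
  set.seed(2)
  X <- matrix(runif(200, -10, 300), 20, 10)
  sc <- desvisc:::minmax_fit(X)
  expect_equal(desvisc:::minmax_unscale(desvisc:::minmax_scale(X, sc), sc),
               X, tolerance = 1e-12, ignore_attr = TRUE)
  U <- desvisc:::minmax_scale(X, sc)
  expect_equal(max(U), 1)
  expect_equal(min(U), -1)
})

test_that("training recovers a noiseless linear target to high accuracy", {
  d <- toy_feature_frame(500, seed = 31)
  set.seed(32)
  beta <- runif(9, -0.05, 0.05)
  d$log_eta <- drop(as.matrix(d) %*% beta)
  fit <- des_ann(data = d, hidden = 5, max_iter = 120, seed = 1)
  expect_lt(fit$metrics$train$rmse, 0.01)
})

test_that("training is bit-reproducible from the seed", {
  d <- teacher_dataset(4, 20, seed = 5, noise_sd = 0.05)$data
  f1 <- des_ann(data = d, hidden = c(4), max_iter = 25, seed = 9)
  f2 <- des_ann(data = d, hidden = c(4), max_iter = 25, seed = 9)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$net$history, f2$net$history)
  f3 <- des_ann(data = d, hidden = c(4), max_iter = 25, seed = 10)
  expect_false(identical(coef(f1), coef(f3)))
})

test_that("training error never ends above its initialization", {
  d <- teacher_dataset(4, 20, seed = 6, noise_sd = 0.05)$data
  for (seed in 1:3) {
    fit <- des_ann(data = d, hidden = c(3), max_iter = 30, seed = seed)
    expect_lte(fit$net$rmse_scaled, fit$net$rmse_scaled_init)
  }
})

test_that("with a vanishing penalty the fit approaches least squares", {
  # no hidden layer: the network is affine, so unregularized LM training
  # must agree with the closed-form linear regression
  d <- toy_feature_frame(120, seed = 41)
  set.seed(42)
  d$log_eta <- drop(0.5 + as.matrix(d) %*% runif(9, -0.02, 0.02) +
                      rnorm(120, 0, 0.05))
  fit <- des_ann(data = d, hidden = integer(0), method = "l2",
                 lambda = 1e-12, max_iter = 60, seed = 2)
  ols <- lm(log_eta ~ ., data = d)
  expect_equal(unname(fitted(fit)), unname(fitted(ols)), tolerance = 1e-6)
})

test_that("a student of the teacher's architecture reaches the noise floor", {
  td <- teacher_dataset(8, 30, hidden = 3, seed = 13, noise_sd = 0.01)
  d <- split_dataset(td$data, every_kth = 5, train_fraction = 0.8, seed = 1)
  fit <- des_ann(data = d, hidden = 3, max_iter = 150, seed = 4)
  held <- d$split != "train"
  rmse <- sqrt(mean((predict(fit, d[held, ], warn_extrapolation = FALSE) -
                       d$log_eta[held])^2))
  expect_lt(rmse, 3 * 0.01)
})

test_that("Bayesian regularization reports evidence-framework diagnostics", {
  d <- teacher_dataset(4, 25, seed = 20, noise_sd = 0.02)$data
  fit <- des_ann(data = d, hidden = c(4), max_iter = 40, seed = 3)
  net <- fit$net
  expect_gt(net$alpha, 0)
  expect_gt(net$beta, 0)
  expect_gt(net$gamma, 0)
  expect_lte(net$gamma, net$n_weights)
  expect_identical(net$n_weights, 9L * 4L + 4L + 4L + 1L)
})

test_that("the architecture grid enumerates 25 + 625 candidates", {
  g <- architecture_grid(1:25, 1:25)
  expect_identical(length(g), 650L)
  expect_identical(sum(lengths(g) == 2L), 625L)
  expect_identical(length(architecture_grid(1:25, NULL)), 25L)
})

test_that("the search ranks by pooled RMSE and prefers simple architectures", {
  td <- teacher_dataset(6, 25, hidden = 3, seed = 17, noise_sd = 0.01)
  d <- split_dataset(td$data, every_kth = 5, train_fraction = 0.8, seed = 2)
  single <- architecture_search(d, list(3), max_iter = 40, seed = 1)
  expect_identical(nrow(single), 1L)
  expect_identical(attr(single, "selected"), 3)
  res <- architecture_search(d, list(1, 3, 6), max_iter = 40, seed = 1)
  expect_identical(nrow(res), 3L)
  expect_false(is.unsorted(res$rmse))
  # capacity ordering: the winner is at least as good as the 1-unit net
  rmse1 <- res$rmse[res$architecture == "9-1-1"]
  expect_lte(min(res$rmse), rmse1)
  expect_error(architecture_search(d, list()), "empty")
})

test_that("models round-trip losslessly through JSON", {
  m <- random_network(c(9, 6, 4, 1), seed = 8,
                      x_scale = list(min = c(rep(0, 8), 283.15),
                                     max = c(rep(30, 8), 363.15)),
                      y_scale = list(min = -0.4, max = 3.7))
  X <- matrix(runif(900, 0, 30), 100, 9)
  X[, 9] <- runif(100, 283.15, 363.15)
  f <- withr::local_tempfile(fileext = ".json")
  write_des_ann(m, f)
  m2 <- read_des_ann(f)
  expect_identical(m2$net$layer_sizes, m$net$layer_sizes)
  expect_identical(predict(m2, X, warn_extrapolation = FALSE),
                   predict(m, X, warn_extrapolation = FALSE))
})

test_that("corrupt or foreign model files fail loudly, not silently", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema": "desvisc-ann", "schema_version": "9.9"}', f)
  expect_error(read_des_ann(f), "schema version")
  writeLines('{"foo": 1}', f)
  expect_error(read_des_ann(f), "schema")
  full <- withr::local_tempfile(fileext = ".json")
  write_des_ann(random_network(c(3, 2, 1), seed = 1), full)
  txt <- readLines(full)
  writeLines(substr(paste(txt, collapse = ""), 1, 40), f)  # truncated
  expect_error(read_des_ann(f), "readable|schema")
})

test_that("the per-neuron weight table reimports to identical predictions", {
  m <- random_network(c(9, 5, 3, 1), seed = 14,
                      x_scale = list(min = c(rep(0, 8), 283.15),
                                     max = c(rep(30, 8), 363.15)),
                      y_scale = list(min = 0, max = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  export_weight_table(m, f)
  m2 <- import_weight_table(f, template = m)
  X <- matrix(runif(450, 0, 30), 50, 9)
  expect_equal(predict(m2, X, warn_extrapolation = FALSE),
               predict(m, X, warn_extrapolation = FALSE), tolerance = 1e-12)
  expect_identical(m2$net$layer_sizes, m$net$layer_sizes)
})

test_that("prediction outside the training ranges warns of extrapolation", {
  d <- teacher_dataset(4, 20, seed = 25, noise_sd = 0.02)$data
  fit <- des_ann(data = d, hidden = 3, max_iter = 20, seed = 1)
  far <- d[1:2, ]
  far$T_K <- 500
  expect_warning(predict(fit, far), "extrapolation")
  expect_silent(predict(fit, d[1:2, ]))
})

test_that("the fitted object supports the standard modelling methods", {
  d <- split_dataset(teacher_dataset(5, 20, seed = 61, noise_sd = 0.03)$data,
                     every_kth = 5, train_fraction = 0.8, seed = 1)
  fit <- suppressWarnings(des_ann(data = d, hidden = 3, max_iter = 25,
                                  seed = 2))
  expect_output(print(fit), "architecture: 9-3-1")
  expect_output(print(summary(fit)), "fit statistics")
  expect_identical(length(coef(fit)), fit$net$n_weights)
  expect_identical(length(residuals(fit)), nrow(d))
  expect_identical(length(residuals(fit, "train")), sum(d$split == "train"))
  expect_equal(unname(fitted(fit) - d$log_eta), residuals(fit))
  s1 <- simulate(fit, nsim = 2, seed = 5)
  s2 <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(s1, s2)
  expect_identical(dim(s1), c(nrow(d), 2L))
  pdf(NULL)
  expect_silent(plot(fit, which = 1))
  invisible(plot(fit, which = 2))
  dev.off()
})
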