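toy_features <- function(centers, n, sd, seed) {
  # 4 Gaussian clusters embedded in the 11-feature space
  withr::with_seed(seed, {
    purrr::map_dfr(seq_along(centers), function(k) {
      base <- matrix(stats::rnorm(n * 11, centers[[k]], sd), n, 11, byrow = TRUE)
      out <- tibble::as_tibble(as.data.frame(base))
      names(out) <- feature_names()
      out$class <- paste0("class", k)
      out
    })
  })
}

test_that("standardization uses training statistics only", {
  tr <- sample_feature_vectors(8, seed = 1)
  te <- sample_feature_vectors(8, seed = 2)
  z <- standardize(tr, tr)
  expect_equal(unname(vapply(z[feature_names()], mean, double(1))),
               rep(0, 11), tolerance = 1e-12)
  expect_equal(unname(vapply(z[feature_names()], stats::sd, double(1))),
               rep(1, 11), tolerance = 1e-12)

  # test-set standardization reuses training center/scale
  zte <- standardize(tr, te)
  f <- feature_names()[1]
  expect_equal(zte[[f]], (te[[f]] - mean(tr[[f]])) / stats::sd(tr[[f]]))

  # constant feature passes through centered
  tr2 <- tr; tr2$solidity <- 50
  z2 <- standardize(tr2, tr2)
  expect_equal(z2$solidity, rep(0, nrow(tr2)))
})

test_that("forward pass equals a hand-coded matrix chain on a toy net", {
  p <- list(list(W = matrix(c(0.3, -0.2, 0.5, 0.1), 2, 2), b = c(0.1, -0.1)),
            list(W = matrix(c(0.4, 0.2, -0.3, 0.6), 2, 2), b = c(0, 0.2)),
            list(W = matrix(c(1, -1, 0.5, 0.25), 2, 2), b = c(-0.2, 0.3)))
  x <- c(0.7, -1.2)
  a1 <- tanh(p[[1]]$W %*% x + p[[1]]$b)
  a2 <- tanh(p[[2]]$W %*% a1 + p[[2]]$b)
  y_ref <- 1 / (1 + exp(-(p[[3]]$W %*% a2 + p[[3]]$b)))
  ours <- asNamespace("macuseg")$forward_pass(p, matrix(x, 1, 2))
  expect_equal(as.vector(ours[[4]]), as.vector(y_ref), tolerance = 1e-12)
})

test_that("prediction at zero weights gives 0.5 outputs with lowest-class tie", {
  model <- structure(
    list(params = list(
      list(W = matrix(0, 4, 11), b = rep(0, 4)),
      list(W = matrix(0, 4, 4), b = rep(0, 4)),
      list(W = matrix(0, 4, 4), b = rep(0, 4))),
      classes = c("a", "b", "c", "d"),
      center = stats::setNames(rep(0, 11), feature_names()),
      scale = stats::setNames(rep(1, 11), feature_names())),
    class = "macule_net")
  pr <- predict(model, sample_feature_vectors(1, seed = 3))
  expect_true(all(abs(as.matrix(pr[c("a", "b", "c", "d")]) - 0.5) < 1e-12))
  expect_true(all(pr$.pred == "a"))
  expect_error(predict(model, tibble::tibble(area = 1)), "missing feature")
})

test_that("well-separated clusters are classified perfectly", {
  centers <- list(rep(0, 11), rep(6, 11), c(rep(0, 5), rep(6, 6)), rep(-6, 11))
  data <- toy_features(centers, n = 8, sd = 0.05, seed = 10)
  fit <- train_network(data, train_config(seed = 10))
  expect_equal(fit$report$accuracy, 100)
  expect_gt(fit$report$regression_r, 0.95)
})

test_that("accepted LM steps never increase the training loss", {
  data <- sample_feature_vectors(10, seed = 4)
  fit <- train_network(data, train_config(seed = 4))
  expect_true(all(diff(fit$loss_trace) <= 0))
  expect_equal(dim(fit$report$confusion), c(4L, 4L))
})

test_that("LM step direction tends to Gauss-Newton and gradient limits", {
  ns <- asNamespace("macuseg")
  p <- withr::with_seed(8, ns$init_params(3, c(2), 2))
  X <- withr::with_seed(9, matrix(stats::rnorm(12), 4, 3))
  Tm <- matrix(c(1, 0, 0, 1, 1, 0, 0, 1), 4, 2)
  J <- ns$network_jacobian(p, X)
  Y <- t(ns$forward_pass(p, X)[[3]])
  e <- as.vector(t(Tm - Y))
  g <- crossprod(J, e); A <- crossprod(J)
  gn <- solve(A + 1e-12 * diag(nrow(A)), g)
  step_small <- solve(A + 1e-9 * diag(nrow(A)), g)
  cosang <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  expect_gt(cosang(step_small, gn), 1 - 1e-6)

  step_big <- solve(A + 1e9 * diag(nrow(A)), g)
  expect_gt(cosang(step_big, g), 1 - 1e-6)      # scaled gradient direction
})

test_that("evaluation bookkeeping: confusion rows, accuracy, degenerate R", {
  data <- sample_feature_vectors(10, seed = 6)
  fit <- train_network(data, train_config(seed = 6))
  conf <- fit$report$confusion
  expect_equal(sum(conf), fit$report$n_test)
  idx <- asNamespace("macuseg")$stratified_split(factor(data$class), 0.6, 6)
  test_counts <- table(factor(data$class[idx$test], levels = fit$classes))
  expect_equal(unname(rowSums(conf)), unname(as.vector(test_counts)))
  expect_true(fit$report$accuracy >= 0 && fit$report$accuracy <= 100)
  expect_true(abs(fit$report$regression_r) <= 1)

  # constant 0.5 outputs against balanced targets: R defined as 0
  zero_model <- fit
  zero_model$params <- lapply(fit$params, function(l)
    list(W = l$W * 0, b = l$b * 0))
  ev <- evaluate_network(zero_model, data)
  expect_equal(ev$regression_r, 0)
  expect_error(evaluate_network(fit, data[0, ]), "empty")
})

test_that("petechiae and trophic macules are separated by a huge area margin", {
  # the petechiae area distribution sits >100 petechiae-SDs below the
  # trophic one, so the two classes never overlap on that single feature
  p <- macule_feature_params()
  gap <- (p$mean[p$class == "trophic" & p$feature == "area"] -
            p$mean[p$class == "petechiae" & p$feature == "area"]) /
    p$sd[p$class == "petechiae" & p$feature == "area"]
  expect_gt(gap, 100)

  # the fitted network reflects that margin on the data it was fit to
  data <- sample_feature_vectors(10, seed = 7005)
  fit <- train_network(data, train_config(seed = 7005))
  idx <- asNamespace("macuseg")$stratified_split(factor(data$class), 0.6, 7005)
  pr <- predict(fit, data[idx$train, ])
  truth <- data$class[idx$train]
  expect_equal(sum(truth == "petechiae" & pr$.pred == "trophic") +
                 sum(truth == "trophic" & pr$.pred == "petechiae"), 0)
})

test_that("tidy and glance summarize a fit", {
  fit <- train_network(sample_feature_vectors(10, seed = 12),
                       train_config(seed = 12))
  td <- tidy(fit)
  expect_equal(sum(td$term == "weight"), 11 * 4 + 4 * 4 + 4 * 4)
  expect_equal(sum(td$term == "bias"), 12)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("accuracy", "regression_r", "accuracy_all") %in% names(gl)))
})
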