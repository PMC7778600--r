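make_two_class <- function(n, p, sep, seed, noise = 1) {
  praman:::with_seed(seed, {
    labels <- rep(c("a", "b"), length.out = n)
    mu <- matrix(0, 2, p)
    mu[2, seq_len(min(5, p))] <- sep
    X <- mu[as.integer(factor(labels)), ] + matrix(rnorm(n * p, 0, noise), n, p)
    list(X = X, labels = labels)
  })
}

test_that("full-rank PLS reproduces ordinary least squares", {
  for (seed in 1:3) {
    d <- praman:::with_seed(seed, {
      X <- matrix(rnorm(20 * 5), 20, 5)
      labels <- rep(c("a", "b"), 10)
      list(X = X, Y = cbind(a = as.numeric(labels == "a"),
                            b = as.numeric(labels == "b")))
    })
    m <- fit_pls(d$X, d$Y, n_lv = 5, class_order = c("a", "b"))
    yhat <- predict_plsda(m, d$X)$yhat
    ols <- apply(d$Y, 2, function(y)
      stats::fitted(stats::lm(y ~ d$X)))
    expect_lt(max(abs(yhat - ols)), 1e-6)
  }
})

test_that("fit_pls rejects degenerate inputs and names the achievable rank", {
  X <- matrix(rnorm(20 * 5), 20, 5)
  Yc <- cbind(a = rep(1, 20), b = rep(0, 20))
  expect_error(fit_pls(X, Yc, 2), "zero-variance")
  Y <- cbind(a = rep(c(1, 0), 10), b = rep(c(0, 1), 10))
  X_low <- cbind(X[, 1], X[, 2], X[, 1] + X[, 2], X[, 1] - X[, 2],
                 2 * X[, 2])  # rank 2
  expect_error(fit_pls(X_low, Y, 4), "rank 2")
})

test_that("duplicating every sample leaves the coefficients unchanged", {
  d <- praman:::with_seed(5, {
    X <- matrix(rnorm(30 * 8), 30, 8)
    labels <- rep(c("a", "b", "c"), 10)
    list(X = X, Y = outer(labels, c("a", "b", "c"), `==`) * 1)
  })
  m1 <- fit_pls(d$X, d$Y, 3)
  m2 <- fit_pls(rbind(d$X, d$X), rbind(d$Y, d$Y), 3)
  expect_lt(max(abs(m1$B - m2$B)), 1e-8)
})

test_that("model coefficients reproduce fitted training responses", {
  d <- make_two_class(24, 10, sep = 3, seed = 2)
  Y <- outer(d$labels, c("a", "b"), `==`) * 1
  m <- fit_pls(d$X, Y, 4, c("a", "b"))
  # fitted scores path: T Q' + y_mean must equal the B path
  yhat_b <- predict_plsda(m, d$X)$yhat
  yhat_t <- m$scores %*% t(m$Q) + matrix(m$y_mean, nrow(d$X), 2, byrow = TRUE)
  expect_lt(max(abs(yhat_b - yhat_t)), 1e-8)
})

test_that("prediction identities hold", {
  d <- make_two_class(30, 12, sep = 20, seed = 3)
  Y <- outer(d$labels, c("a", "b"), `==`) * 1
  m <- fit_pls(d$X, Y, 3, c("a", "b"))

  # x = x_mean predicts the class prior vector
  at_mean <- predict_plsda(m, matrix(m$x_mean, 1))$yhat
  expect_lt(max(abs(at_mean - m$y_mean)), 1e-10)

  # labels equal argmax of independently recomputed yhat
  Xnew <- praman:::with_seed(9, matrix(rnorm(10 * 12), 10, 12))
  pr <- predict_plsda(m, Xnew)
  yhat_direct <- sweep(Xnew, 2, m$x_mean) %*% m$B +
    matrix(m$y_mean, 10, 2, byrow = TRUE)
  expect_equal(pr$labels,
               c("a", "b")[apply(yhat_direct, 1, which.max)])

  # perfectly separated training samples classify to their own class
  expect_equal(predict_plsda(m, d$X)$labels, d$labels)

  expect_error(predict_plsda(m, Xnew[, 1:5]), "channel mismatch")
})

test_that("venetian blinds folds interleave by index", {
  expect_equal(venetian_blinds_folds(20, 10), rep(1:10, 2))
  expect_equal(venetian_blinds_folds(10, 10), 1:10)
  sizes <- table(venetian_blinds_folds(23, 10))
  expect_lte(diff(range(sizes)), 1)
  expect_error(venetian_blinds_folds(5, 10), "at least as many samples")
})

test_that("cross-validation is deterministic, scale invariant and accurate when separable", {
  d <- make_two_class(60, 30, sep = 20, seed = 4)
  cfg <- plsda_config(n_lv = 4, cv_splits = 10)
  cv1 <- cross_validate(d$X, d$labels, cfg)
  expect_equal(cv1$accuracy, 1.0)
  expect_equal(sum(cv1$confusion), 60)
  expect_equal(sum(diag(cv1$confusion)) / 60, cv1$accuracy)

  cv2 <- cross_validate(d$X, d$labels, cfg)
  expect_identical(cv1$predicted, cv2$predicted)
  expect_identical(cv1$accuracy, cv2$accuracy)

  cv3 <- cross_validate(d$X * 17, d$labels, cfg)
  expect_equal(cv3$accuracy, cv1$accuracy)
})

test_that("indistinguishable inputs carry no class information", {
  # every row appears twice, once per label: X is exactly orthogonal to
  # the centred indicator, so no latent direction exists and the fit is
  # refused as degenerate rather than returning a sham classifier
  base <- praman:::with_seed(8, matrix(rnorm(20 * 10), 20, 10))
  X <- base[rep(1:20, each = 2), ]
  labels <- rep(c("a", "b"), 20)
  Y <- outer(labels, c("a", "b"), `==`) * 1
  expect_error(fit_pls(X, Y, 3, c("a", "b")), "degenerate")
})

test_that("a training fold lacking a class is refused with ordering advice", {
  d <- make_two_class(30, 10, sep = 5, seed = 6)
  labels <- rep("b", 30)
  labels[c(1, 11, 21)] <- "a"  # class a entirely inside fold 1
  expect_error(cross_validate(d$X, labels, plsda_config(n_lv = 2,
                                                        cv_splits = 10)),
               "reorder")
})

test_that("subject-blocked folds keep replicates together", {
  d <- make_two_class(40, 10, sep = 5, seed = 7)
  block <- rep(sprintf("subj%02d", 1:10), each = 4)
  cv <- cross_validate(d$X, rep(c("a", "b"), each = 20),
                       plsda_config(n_lv = 2, cv_splits = 5,
                                    block_by = block))
  for (b in unique(block))
    expect_equal(length(unique(cv$fold_of[block == b])), 1)
})
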