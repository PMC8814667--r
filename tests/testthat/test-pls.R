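make_arr <- function(X) {
  array(X, c(nrow(X), 1, ncol(X)),
        dimnames = list(sprintf("s%02d", seq_len(nrow(X))), NULL,
                        sprintf("f%d", seq_len(ncol(X)))))
}

test_that("duplicated informative features share the weight equally", {
  set.seed(11)
  n <- 40
  sig <- rnorm(n)
  y <- as.integer(sig + rnorm(n, 0, 0.5) > 0)
  X <- cbind(sig, sig, matrix(5, n, 7))   # two duplicates, rest zero-variance
  fit <- fit_vertex_pls(make_arr(X), y)
  expect_equal(abs(fit$w[1, 1:2]), rep(1 / sqrt(2), 2), tolerance = 1e-10)
  expect_equal(fit$w[1, 3:9], rep(0, 7))
})

test_that("the weight concentrates on a single informative feature at large n", {
  set.seed(12)
  n <- 400
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * 9), n, 9)
  X[, 4] <- X[, 4] + 2 * y
  fit <- fit_vertex_pls(make_arr(X), y)
  expect_gt(fit$w[1, 4]^2, 0.9)
})

test_that("the component correlates non-negatively with the label in training", {
  set.seed(13)
  for (rep_i in 1:5) {
    n <- 30
    y <- rbinom(n, 1, 0.5)
    X <- matrix(rnorm(n * 9), n, 9)
    arr <- make_arr(X)
    fit <- fit_vertex_pls(arr, y)
    sc <- predict(fit, arr)[, 1]
    expect_gte(cor(sc, y), 0)
  }
})

test_that("transform reproduces training scores and honours affine invariance", {
  set.seed(14)
  n <- 25
  y <- rep(c(0, 1), length.out = n)
  X <- matrix(rnorm(n * 9), n, 9)
  arr <- make_arr(X)
  fit <- fit_vertex_pls(arr, y)
  sc <- predict(fit, arr)[, 1]
  # positive per-feature affine rescaling of the raw inputs changes nothing
  scale_f <- runif(9, 0.5, 4)
  shift_f <- rnorm(9, 0, 10)
  X2 <- sweep(sweep(X, 2, scale_f, "*"), 2, shift_f, "+")
  fit2 <- fit_vertex_pls(make_arr(X2), y)
  sc2 <- predict(fit2, make_arr(X2))[, 1]
  expect_equal(sc2, sc, tolerance = 1e-10)
})

test_that("a subject at the training minimum scores minus the centring offset", {
  set.seed(15)
  n <- 20
  y <- rep(0:1, each = 10)
  X <- matrix(runif(n * 9), n, 9)
  arr <- make_arr(X)
  fit <- fit_vertex_pls(arr, y)
  at_min <- make_arr(matrix(fit$fmin[1, ], 1, 9))
  dimnames(at_min)[[3]] <- dimnames(arr)[[3]]
  expect_equal(unname(predict(fit, at_min)[1, 1]),
               -sum(fit$w[1, ] * fit$xbar[1, ]), tolerance = 1e-12)
})

test_that("the model refuses mismatched feature sets and degenerate training", {
  set.seed(16)
  arr <- make_arr(matrix(rnorm(90), 10, 9))
  y <- rep(0:1, each = 5)
  fit <- fit_vertex_pls(arr, y)
  expect_error(predict(fit, arr[, , 1:5, drop = FALSE]), "feature count")
  arr2 <- arr
  dimnames(arr2)[[3]] <- paste0("x", 1:9)
  expect_error(predict(fit, arr2), "feature names")
  expect_error(fit_vertex_pls(arr, rep(1, 10)), "binary|2 training")
  expect_error(fit_vertex_pls(arr[1:3, , , drop = FALSE], c(0, 1, 1)),
               ">= 2")
})

test_that("an all-zero-covariance vertex is flagged undefined", {
  X <- matrix(5, 10, 9)    # all features constant
  fit <- fit_vertex_pls(make_arr(X), rep(0:1, 5))
  expect_false(fit$defined[1])
  expect_true(all(is.na(predict(fit, make_arr(X))[, 1])))
})

test_that("the fit depends only on the training subjects (hash hygiene)", {
  set.seed(17)
  n <- 30
  y <- rep(0:1, 15)
  X <- matrix(rnorm(n * 9), n, 9)
  arr <- make_arr(X)
  tr <- 1:20
  f1 <- fit_vertex_pls(arr[tr, , , drop = FALSE], y[tr])
  arr2 <- arr
  arr2[25, , ] <- 999   # corrupt a non-training subject
  f2 <- fit_vertex_pls(arr2[tr, , , drop = FALSE], y[tr])
  expect_identical(mssm:::object_hash(f1), mssm:::object_hash(f2))
})
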