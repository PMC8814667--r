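# Synthetic feature arrays (no phantom) for fast tests of the trainable core.
fake_features <- function(n = 40, v = 25, seed = 1) {
  set.seed(seed)
  y <- rep(c("AD", "CN"), each = n / 2)
  arr <- array(rnorm(n * v * 9), c(n, v, 9),
               dimnames = list(sprintf("s%02d", 1:n), NULL,
                               c("thickness", paste0("c", 1:8))))
  # disease signal on a subset of vertices, thickness and two ratios
  sig <- 1:8
  arr[y == "AD", sig, c(1, 3, 5)] <- arr[y == "AD", sig, c(1, 3, 5)] + 1.2
  list(x = arr, labels = y,
       cohort = data.frame(subject_id = sprintf("s%02d", 1:n), label = y))
}

fast_config <- function(seed = 1L)
  mssm_config(seed = seed,
              models = c("svm_linear", "svm_rbf", "logistic_regression",
                         "knn", "random_forest"))

test_that("the trained model separates a signal-bearing synthetic cohort", {
  fx <- fake_features()
  sp <- make_splits(fx$cohort, seed = 4L)$split
  mod <- mssm_train(fx$x, fx$labels, sp, positive = "AD",
                    config = fast_config())
  expect_s3_class(mod, "mssm_model")
  expect_output(print(mod), "mssm_model")
  rep_ <- mssm_evaluate(mod, fx$x[sp == "test", , , drop = FALSE],
                        fx$labels[sp == "test"])
  expect_gt(rep_$auroc, 0.7)
  probs <- predict(mod, fx$x)
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("training is reproducible and blind to test subjects", {
  fx <- fake_features()
  sp <- make_splits(fx$cohort, seed = 4L)$split
  m1 <- mssm_train(fx$x, fx$labels, sp, positive = "AD", config = fast_config())
  m2 <- mssm_train(fx$x, fx$labels, sp, positive = "AD", config = fast_config())
  expect_identical(mssm:::object_hash(m1), mssm:::object_hash(m2))
  # permuting test-subject labels changes nothing fitted
  labs <- fx$labels
  te <- which(sp == "test")
  labs[te] <- sample(labs[te])
  m3 <- mssm_train(fx$x, labs, sp, positive = "AD", config = fast_config())
  expect_identical(mssm:::object_hash(m1), mssm:::object_hash(m3))
  # corrupting test-subject features changes nothing fitted either
  x4 <- fx$x
  x4[te, , ] <- 1e6
  m4 <- mssm_train(x4, fx$labels, sp, positive = "AD", config = fast_config())
  expect_identical(mssm:::object_hash(m1), mssm:::object_hash(m4))
})

test_that("label permutation destroys the signal (null band downstream)", {
  fx <- fake_features(n = 48)
  sp <- make_splits(fx$cohort, seed = 6L)$split
  mod <- mssm_train(fx$x, fx$labels, sp, positive = "AD",
                    config = fast_config())
  set.seed(99)
  perm <- sample(fx$labels)
  rep_perm <- transfer_predict(mod, fx$x, perm, positive = "AD")
  expect_gt(rep_perm$auroc, 0.2)
  expect_lt(rep_perm$auroc, 0.8)
})

test_that("the thickness-only model trains without PLS", {
  fx <- fake_features()
  sp <- make_splits(fx$cohort, seed = 4L)$split
  mod <- mssm_train(fx$x, fx$labels, sp, positive = "AD",
                    config = fast_config(), feature = "thickness")
  expect_null(mod$pls)
  expect_gt(mssm_evaluate(mod, fx$x[sp == "test", , , drop = FALSE],
                          fx$labels[sp == "test"])$auroc, 0.5)
})

test_that("the top-k cap restricts classifier inputs by training effect size", {
  fx <- fake_features()
  sp <- make_splits(fx$cohort, seed = 4L)$split
  mod <- mssm_train(fx$x, fx$labels, sp, positive = "AD",
                    config = fast_config(), top_k = 6)
  expect_length(mod$vertices_used, 6L)
  expect_true(mean(mod$vertices_used %in% 1:8) > 0.5)
})

test_that("transfer to a copy of the evaluated cohort reproduces its metrics", {
  fx <- fake_features()
  sp <- make_splits(fx$cohort, seed = 4L)$split
  mod <- mssm_train(fx$x, fx$labels, sp, positive = "AD", config = fast_config())
  te <- sp == "test"
  r1 <- mssm_evaluate(mod, fx$x[te, , , drop = FALSE], fx$labels[te])
  r2 <- transfer_predict(mod, fx$x[te, , , drop = FALSE], fx$labels[te],
                         positive = "AD")
  expect_equal(r1$auroc, r2$auroc)
  expect_equal(r1$accuracy, r2$accuracy)
})
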