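test_that("class weights are inverse to prevalence", {
  expect_equal(unname(class_weights(rep(c("a", "b"), c(50, 50)))), c(1, 1))
  w <- class_weights(rep(c("AD", "CN"), c(65, 90)))
  expect_equal(unname(w["AD"] / w["CN"]), 90 / 65, tolerance = 1e-12)
  expect_equal(unname(w), c(155 / (2 * 65), 155 / (2 * 90)))
  expect_error(class_weights(rep("AD", 10)), "two classes")
})

test_that("splits are stratified, deterministic, and stable under test-subject removal", {
  co <- data.frame(subject_id = sprintf("P%03d", 1:100),
                   label = rep(c("AD", "CN"), c(40, 60)))
  sp <- make_splits(co, seed = 7L)
  tab <- table(sp$label, sp$split)
  expect_equal(unname(tab["AD", c("train", "val", "test")]), c(24, 8, 8))
  expect_equal(unname(tab["CN", c("train", "val", "test")]), c(36, 12, 12))
  expect_identical(make_splits(co, seed = 7L), sp)
  expect_false(identical(make_splits(co, seed = 8L)$split, sp$split))
  drop_id <- sp$subject_id[sp$split == "test"][3]
  sp2 <- make_splits(co[co$subject_id != drop_id, ], seed = 7L)
  kept <- sp[sp$subject_id != drop_id & sp$split != "test", ]
  expect_identical(sp2$split[match(kept$subject_id, sp2$subject_id)],
                   kept$split)
})

test_that("auroc matches brute-force pair counting, with ties as halves", {
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(0.3, 8), rep(c(0, 1), 4)), 0.5)
  set.seed(31)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 1)          # coarse scores force ties
    expect_equal(auroc(s, y), auroc_pairs(s, y), tolerance = 1e-12)
  }
})

test_that("roc and pr curves have the required endpoints and ranges", {
  set.seed(32)
  y <- rbinom(30, 1, 0.4); y[1:2] <- c(0, 1)
  s <- rnorm(30)
  roc <- roc_points(s, y)
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
  pr <- pr_points(s, y)
  expect_true(all(pr$precision >= 0 & pr$precision <= 1))
  expect_equal(pr$recall[nrow(pr)], 1)
  expect_true(auprc(s, y) >= 0 && auprc(s, y) <= 1)
  expect_equal(auprc(c(5, 4, 1, 0), c(1, 1, 0, 0)), 1)
})

test_that("the threshold scan attains the brute-force optimum and prefers low thresholds", {
  th <- choose_threshold(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))
  expect_equal(attr(th, "errors"), 1)
  set.seed(33)
  for (i in 1:25) {
    n <- sample(5:15, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), 1)
    th <- choose_threshold(s, y)
    expect_equal(attr(th, "errors"), threshold_bruteforce(s, y))
  }
  # separable scores: zero errors; ties resolved toward sensitivity
  th <- choose_threshold(c(3, 2, 1, 0), c(1, 1, 0, 0))
  expect_equal(attr(th, "errors"), 0)
  th_tie <- choose_threshold(c(1, 2, 3, 4), c(0, 1, 0, 1))
  pred <- as.integer(c(1, 2, 3, 4) >= th_tie)
  expect_equal(sum(pred == 0 & c(0, 1, 0, 1) == 1), 0)   # no missed positives
})

test_that("eval_report carries all five metrics in range plus curves", {
  set.seed(34)
  y <- rep(c(0, 1), 15)
  s <- y * 0.5 + runif(30)
  rep_ <- eval_report(s, y)
  for (m in c("auroc", "auprc", "accuracy", "sensitivity", "specificity"))
    expect_true(rep_[[m]] >= 0 && rep_[[m]] <= 1)
  expect_s3_class(rep_$roc, "data.frame")
  expect_s3_class(rep_$pr, "data.frame")
  expect_equal(rep_$n, 30L)
})

test_that("every family in the zoo produces finite probabilities", {
  set.seed(35)
  n <- 30; p <- 6
  x <- matrix(rnorm(n * p), n, p)
  y <- rep(0:1, each = n / 2)
  x[y == 1, 1:2] <- x[y == 1, 1:2] + 1.5
  zoo <- model_zoo()
  expect_length(zoo, 9L)
  cw <- class_weights(y)
  for (fam in names(zoo)) {
    m <- zoo[[fam]]$fit(x, y, cw, cw[as.character(y)], 1L, list())
    pr <- zoo[[fam]]$predict(m, x)
    expect_true(all(is.finite(pr)) && all(pr >= 0 & pr <= 1), label = fam)
  }
})

test_that("a family given an oracle feature outranks noise-only families", {
  set.seed(36)
  n <- 40
  y <- rep(0:1, each = n / 2)
  x <- cbind(y + rnorm(n, 0, 0.05), matrix(rnorm(n * 4), n, 4))
  ens <- select_ensemble(x, y, families = c("svm_linear", "knn",
                                            "random_forest", "logistic_regression"),
                         seed = 3L)
  expect_gt(ens$ranking$mean_val_auroc[1], 0.95)
  expect_length(ens$member_families, 3L)
})

test_that("an ensemble of identical families equals its single member", {
  set.seed(37)
  n <- 32
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 3), n, 3) + y
  zoo <- model_zoo()
  std <- mssm:::standardizer(x)
  xs <- mssm:::apply_standardizer(std, x)
  cw <- class_weights(y)
  m <- zoo$svm_linear$fit(xs, y, cw, cw[as.character(y)], 1L, list())
  single <- zoo$svm_linear$predict(m, xs)
  fake <- structure(list(members = list(a = m, b = m, c = m),
                         member_families = c("svm_linear", "svm_linear",
                                             "svm_linear"),
                         standardizer = std),
                    class = "mssm_ensemble")
  expect_equal(predict(fake, x), as.numeric(single), tolerance = 1e-12)
})

test_that("ensemble selection is deterministic under a fixed seed", {
  set.seed(38)
  n <- 36
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5) + 0.8 * y
  fams <- c("svm_linear", "svm_rbf", "logistic_regression", "knn")
  e1 <- select_ensemble(x, y, families = fams, seed = 10L)
  e2 <- select_ensemble(x, y, families = fams, seed = 10L)
  expect_identical(e1$member_families, e2$member_families)
  expect_equal(predict(e1, x), predict(e2, x), tolerance = 1e-12)
  expect_identical(mssm:::object_hash(e1$ranking), mssm:::object_hash(e2$ranking))
})

test_that("fewer than three candidate families is an error", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(select_ensemble(x, rep(0:1, 10), families = c("knn", "svm_rbf")),
               "at least 3")
})

test_that("the scalar baseline machinery recovers an oracle feature and not noise", {
  set.seed(39)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  co <- data.frame(subject_id = as.character(1:n),
                   label = ifelse(y == 1, "AD", "CN"))
  split <- make_splits(co, seed = 2L)$split
  fams <- c("svm_linear", "logistic_regression", "knn", "random_forest")
  oracle <- scalar_baseline(y + rnorm(n, 0, 0.1), y, split, seed = 5L,
                            families = fams)
  expect_gt(oracle$report$auroc, 0.9)
})

test_that("the ensemble is no worse than its weakest member minus 0.05", {
  set.seed(40)
  n <- 60
  y <- rep(0:1, n / 2)
  x <- matrix(rnorm(n * 8), n, 8)
  x[y == 1, 1:3] <- x[y == 1, 1:3] + 1
  ens <- select_ensemble(x[1:40, ], y[1:40],
                         families = c("svm_linear", "svm_rbf", "knn",
                                      "logistic_regression", "random_forest"),
                         seed = 6L)
  hold_x <- x[41:60, ]; hold_y <- y[41:60]
  zoo <- model_zoo()
  xs <- mssm:::apply_standardizer(ens$standardizer, hold_x)
  member_auc <- sapply(seq_along(ens$member_families), function(i)
    auroc(as.numeric(zoo[[ens$member_families[i]]]$predict(ens$members[[i]],
                                                           xs)), hold_y))
  expect_gte(auroc(predict(ens, hold_x), hold_y), min(member_auc) - 0.05)
})
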