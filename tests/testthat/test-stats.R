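test_that("the vertex t-map matches the pooled-variance formula and t.test", {
  set.seed(21)
  for (i in 1:20) {
    a <- matrix(rnorm(8), 8, 1)
    b <- matrix(rnorm(10, 0.5), 10, 1)
    st <- vertex_ttest(a, b)
    expect_equal(st$t[1], t_bruteforce(a[, 1], b[, 1]), tolerance = 1e-10)
    tt <- t.test(a[, 1], b[, 1], var.equal = TRUE)
    expect_equal(st$t[1], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(st$p[1], tt$p.value, tolerance = 1e-10)
  }
})

test_that("identical groups give t = 0, p = 1, d = 0; separated means give d near 1", {
  m <- matrix(rnorm(60), 6, 10)
  st <- vertex_ttest(m, m)
  expect_equal(st$t, rep(0, 10))
  expect_equal(st$p, rep(1, 10))
  expect_equal(st$d, rep(0, 10))
  set.seed(22)
  a <- matrix(rnorm(3000, 1), 300, 10)
  b <- matrix(rnorm(3000, 0), 300, 10)
  expect_equal(vertex_ttest(a, b)$d, rep(1, 10), tolerance = 0.2)
})

test_that("zero pooled variance yields undefined vertices, not infinities", {
  a <- matrix(5, 4, 2); b <- matrix(5, 4, 2)
  a[, 2] <- rnorm(4); b[, 2] <- rnorm(4)
  st <- vertex_ttest(a, b)
  expect_true(is.na(st$t[1]) && is.na(st$d[1]))
  expect_false(is.na(st$t[2]))
  expect_equal(st$n_defined, 1L)
})

test_that("BH step-up matches hand-worked examples", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(bh_fdr(rep(1, 6), 0.05), rep(FALSE, 6))
  expect_equal(bh_fdr(0.04, 0.05), TRUE)
  expect_equal(bh_fdr(numeric(0), 0.05), logical(0))
  expect_equal(bh_fdr(c(0.01, NA, 0.5), 0.05), c(TRUE, FALSE, FALSE))
  expect_error(bh_fdr(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
})

test_that("percent_significant is a straight count ratio", {
  st <- list(p = c(0.01, 0.2, NA, 0.03), significant = c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(percent_significant(st), 100 * 2 / 3)
  st$significant <- c(TRUE, TRUE, FALSE, TRUE)
  expect_equal(percent_significant(st), 100)
  st$significant <- rep(FALSE, 4)
  expect_equal(percent_significant(st), 0)
})

test_that("effect-size comparison of identical maps is zero everywhere", {
  set.seed(23)
  a <- matrix(rnorm(50), 5, 10); b <- matrix(rnorm(50, 1), 5, 10)
  st <- vertex_ttest(a, b)
  cmp <- effect_size_comparison(st, st)
  expect_equal(cmp$d_diff, rep(0, 10))
  expect_false(any(cmp$a_stronger))
})

test_that("extra-region correlation: score equal to y gives coefficient 1", {
  set.seed(24)
  n <- 20; v <- 30
  mssm_vals <- matrix(rnorm(n * v), n, v)
  ct_vals <- matrix(rnorm(n * v, 2.5, 0.2), n, v)
  mssm_sig <- rep(c(TRUE, FALSE), c(12, v - 12))
  ct_sig <- rep(c(TRUE, FALSE, FALSE), c(4, 8, v - 12))
  res <- extra_region_correlation(mssm_vals, ct_vals, mssm_sig, ct_sig,
                                  score = rowMeans(mssm_vals[, mssm_sig & !ct_sig]))
  expect_false(res$empty)
  expect_true(all(!(res$extra_mask & ct_sig)))   # disjoint by construction
  raw <- res$correlations[res$correlations$control == "none", ]
  expect_equal(raw$pearson, 1)
  expect_equal(raw$spearman, 1)
})

test_that("an empty extra region returns an explicit empty analysis", {
  m <- matrix(rnorm(40), 4, 10)
  res <- extra_region_correlation(m, m, rep(FALSE, 10), rep(TRUE, 10),
                                  score = rnorm(4))
  expect_true(res$empty)
  expect_equal(res$n_extra, 0L)
})

test_that("partialling on an independent control barely changes the correlation", {
  set.seed(25)
  diffs <- replicate(100, {
    n <- 60
    y <- rnorm(n)
    score <- y + rnorm(n)
    control <- rnorm(n)          # independent of both
    abs(cor(y, score) - partial_cor(y, score, control))
  })
  expect_lt(mean(diffs), 0.05)
})

test_that("partial correlation removes a genuine confounder", {
  set.seed(26)
  n <- 500
  z <- rnorm(n)
  a <- z + rnorm(n, 0, 0.3)
  b <- z + rnorm(n, 0, 0.3)
  expect_gt(cor(a, b), 0.8)
  expect_lt(abs(partial_cor(a, b, z)), 0.15)
})

test_that("covariate adjustment removes a confounded group difference", {
  set.seed(27)
  n <- 30
  z_a <- rnorm(n, 2); z_b <- rnorm(n, 0)     # confounder differs by group
  a <- matrix(2 * z_a + rnorm(n * 5, 0, 0.5), n, 5)
  b <- matrix(2 * z_b + rnorm(n * 5, 0, 0.5), n, 5)
  raw <- vertex_ttest(a, b)
  adj <- vertex_ttest(a, b, covariates = data.frame(z = c(z_a, z_b)))
  expect_true(all(raw$p < 1e-4))
  expect_true(all(adj$p > 0.05))
  expect_equal(adj$df, raw$df - 1L)
  # a genuine effect survives adjustment for an unrelated covariate
  a2 <- a + 3
  adj2 <- vertex_ttest(a2, b, covariates = data.frame(z = rnorm(2 * n)))
  expect_true(all(adj2$p < 0.01))
})
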