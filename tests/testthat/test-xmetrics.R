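# Explanation assessment metrics against closed forms and brute-force
# oracles.

test_that("normalization scales the maximum to one and passes zeros through", {
  e <- matrix(c(1, 2, 4, 0), 2, 2)
  n <- normalize_explanation(e)
  expect_equal(max(n), 1)
  expect_equal(n, c(1, 2, 4, 0) / 4)
  z <- normalize_explanation(matrix(0, 3, 3))
  expect_equal(max(abs(z)), 0)
  expect_error(normalize_explanation(matrix(-1, 2, 2)), "nonnegative")
})

test_that("normalization never reorders pixels", {
  set.seed(8)
  for (i in 1:20) {
    v <- abs(rnorm(30))
    expect_identical(order(normalize_explanation(v)), order(v))
  }
})

test_that("rmse matches closed forms and its bounds", {
  expect_equal(rmse(c(1, 0, 1, 0), c(1, 0, 1, 0)), 0)
  expect_equal(rmse(c(1, 0, 1, 0), c(1, 0, 0, 0)), 0.5)
  set.seed(2)
  for (i in 1:20) {
    a <- runif(25); b <- as.numeric(runif(25) > 0.5)
    expect_lte(rmse(a, b), 1)
    expect_gte(rmse(a, b), 0)
  }
  expect_error(rmse(1:3, 1:4), "lengths differ")
})

test_that("cosine similarity matches closed forms and flags zero norms", {
  expect_equal(cosine_similarity(c(1, 1), c(1, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0, 0), c(1, 0, 0, 0)),
               1 / sqrt(2), tolerance = 1e-9)
  expect_warning(v <- cosine_similarity(c(0, 0), c(1, 0)), "zero-norm")
  expect_true(is.na(v))
})

test_that("pip handles the trivial all-ones mask and the printed toy case", {
  set.seed(3)
  a <- runif(16)
  expect_equal(suppressWarnings(pip(a, rep(1, 16), 25)), 1.0)
  # 4x4 explanation, four known top pixels, mask marks two of them
  a <- rep(0.1, 16)
  top <- c(3, 7, 11, 14)
  a[top] <- c(0.9, 0.8, 0.7, 0.6)
  b <- rep(0, 16)
  b[c(3, 11)] <- 1
  expect_equal(suppressWarnings(pip(a, b, 25)), 0.5)
})

test_that("pip matches a brute-force sort oracle on random 16-pixel instances", {
  set.seed(7)
  for (i in 1:50) {
    a <- round(runif(16), 2)        # duplicates exercise the tie rule
    b <- as.numeric(runif(16) > 0.5)
    pct <- sample(c(10, 25, 50), 1)
    k <- ceiling(16 * pct / 100)
    ord <- order(-a, seq_along(a))  # highest value, ties by lowest index
    brute <- sum(b[ord[seq_len(k)]] == 1) / k
    expect_equal(suppressWarnings(pip(a, b, pct)), brute)
  }
})

test_that("uniform explanations follow the documented tie rule", {
  a <- rep(0.5, 20)
  b <- c(rep(1, 6), rep(0, 14))
  # top ceiling(20 * 25 / 100) = 5 pixels are flat indices 1..5, all in RM
  expect_equal(suppressWarnings(pip(a, b, 25)), 1)
  b2 <- c(rep(0, 3), rep(1, 17))
  expect_equal(pip(a, b2, 25), 2 / 5)
})

test_that("pip validates percent and warns when the mask cannot contain IP", {
  a <- runif(16); b <- c(1, rep(0, 15))
  expect_error(pip(a, b, 0), "percent")
  expect_error(pip(a, b, 101), "percent")
  expect_warning(pip(a, b, 50), "cannot fit")
})

test_that("model assessment aggregates per-sample metrics exactly", {
  ds <- make_patch_dataset(n = 10, seed = 4, test_frac = 0.3)
  m <- build_network(network_spec("tiny", 2, c(32, 32, 3)), seed = 6)
  rep <- assess_model(m, ds, "test")
  expect_s3_class(rep, "assessment_report")
  expect_named(rep, c("accuracy_pct", "rmse", "cosines", "pip_1", "pip_5",
                      "pip_10", "n_samples", "n_cosine_excluded"))
  per <- attr(rep, "per_sample")
  # recompute one sample by hand through the public operations
  i <- per$sample[1]
  e <- gradcam_explain(m, ds$images[, , , i], ds$labels[i])
  a <- normalize_explanation(e)
  b <- as.vector(ds$assessments[, , i])
  expect_equal(per$rmse[1], rmse(a, b))
  expect_equal(per$pip_5[1], suppressWarnings(pip(a, b, 5)))
  # report means equal hand-computed means
  expect_equal(rep$rmse, mean(per$rmse))
  expect_equal(rep$pip_5, 100 * mean(per$pip_5, na.rm = TRUE))
  expect_equal(rep$n_samples, 3)
})

test_that("two identical models produce identical reports", {
  ds <- make_patch_dataset(n = 10, seed = 4, test_frac = 0.3)
  m1 <- build_network(network_spec("tiny", 2, c(32, 32, 3)), seed = 6)
  m2 <- build_network(network_spec("tiny", 2, c(32, 32, 3)), seed = 6)
  expect_identical(as.data.frame(assess_model(m1, ds, "test")),
                   as.data.frame(assess_model(m2, ds, "test")))
})

test_that("assessment is invariant to sample order", {
  ds <- make_patch_dataset(n = 12, seed = 9, test_frac = 0.5)
  m <- build_network(network_spec("tiny", 2, c(32, 32, 3)), seed = 2)
  r1 <- assess_model(m, ds, "test")
  perm <- rev(seq_len(dim(ds$images)[4]))
  ds2 <- ds
  ds2$images <- ds$images[, , , perm, drop = FALSE]
  ds2$labels <- ds$labels[perm]
  ds2$annotations <- ds$annotations[, , perm, drop = FALSE]
  ds2$assessments <- ds$assessments[, , perm, drop = FALSE]
  ds2$splits$test <- match(ds$splits$test, perm)
  r2 <- assess_model(m, ds2, "test")
  for (col in c("accuracy_pct", "rmse", "cosines", "pip_5")) {
    expect_equal(r1[[col]], r2[[col]])
  }
})
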