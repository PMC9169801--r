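# Network construction, forward contracts, training behaviour.

test_that("built networks have the declared output width and deterministic init", {
  spec <- network_spec("tiny", n_classes = 2, input_size = c(32, 32, 3))
  m1 <- build_network(spec, seed = 3)
  m2 <- build_network(spec, seed = 3)
  expect_identical(m1$layers, m2$layers)
  m3 <- build_network(spec, seed = 4)
  expect_false(identical(m1$layers, m3$layers))

  x0 <- array(0, c(32, 32, 3))
  p <- predict(m1, x0, type = "prob")
  expect_equal(nrow(p), 2)
  expect_true(all(is.finite(p)))
  expect_equal(colSums(p), 1, tolerance = 1e-6)
})

test_that("the alexnet-like variant builds with 5 conv and 3 dense stages", {
  spec <- network_spec("alexnet_like", n_classes = 10,
                       input_size = c(64, 64, 3))
  m <- build_network(spec, seed = 1)
  types <- vapply(m$layers, function(l) l$type, character(1))
  expect_equal(sum(types == "conv"), 5)
  expect_equal(sum(types == "dense"), 3)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  z <- predict(m, x, type = "logits")
  expect_equal(nrow(z), 10)
  expect_true(all(is.finite(z)))
})

test_that("input sizes below the variant minimum are rejected", {
  expect_error(network_spec("tiny", 2, c(16, 16, 3)), "at least 32x32")
  expect_error(network_spec("alexnet_like", 2, c(48, 48, 3)), "at least 64x64")
})

test_that("cross-entropy parameter gradients match finite differences", {
  m <- make_small_net(seed = 7)
  set.seed(3)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  y <- c(1L, 3L)
  fw <- rightreasons:::net_forward(m, x)
  ce <- rightreasons:::ce_loss(fw$logits, y)
  bp <- rightreasons:::net_backward(m, fw, ce$glogits)
  lossfun <- function(model) {
    f <- rightreasons:::net_forward(model, x, keep = FALSE)
    rightreasons:::ce_loss(f$logits, y)$loss
  }
  h <- 1e-5
  for (l in seq_along(m$layers)) {
    if (is.null(bp$gW[[l]])) next
    for (trial in 1:3) {
      i <- sample(length(m$layers[[l]]$W), 1)
      m2 <- m; m2$layers[[l]]$W[i] <- m2$layers[[l]]$W[i] + h
      m3 <- m; m3$layers[[l]]$W[i] <- m3$layers[[l]]$W[i] - h
      fd <- (lossfun(m2) - lossfun(m3)) / (2 * h)
      expect_lt(abs(fd - bp$gW[[l]][i]) / max(1e-8, abs(fd)), 1e-4)
    }
  }
})

test_that("a tiny net overfits a separable patch task to perfect accuracy", {
  ds <- make_patch_dataset(n = 20, seed = 1)
  m <- build_network(network_spec("tiny", 2, c(32, 32, 3)), seed = 3)
  m <- train_network(m, ds, loss_spec(lambda = 0),
                     train_config(epochs = 30, batch_size = 8, seed = 4))
  expect_equal(evaluate_accuracy(m, ds, "train"), 1.0)
  expect_equal(nrow(m$history), 30)
})

test_that("training is reproducible given identical seeds and configs", {
  ds <- make_patch_dataset(n = 16, seed = 2)
  tc <- train_config(epochs = 3, batch_size = 8, seed = 9)
  m1 <- train_network(build_network(network_spec("tiny", 2, c(32, 32, 3)), 5),
                      ds, loss_spec(0), tc)
  m2 <- train_network(build_network(network_spec("tiny", 2, c(32, 32, 3)), 5),
                      ds, loss_spec(0), tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$layers, m2$layers)
})

test_that("one optimizer step changes the parameters when the loss is positive", {
  ds <- make_patch_dataset(n = 8, seed = 3)
  m0 <- build_network(network_spec("tiny", 2, c(32, 32, 3)), seed = 1)
  m1 <- train_network(m0, ds, loss_spec(0),
                      train_config(epochs = 1, batch_size = 8, seed = 2))
  expect_false(identical(m0$layers, m1$layers))
})

test_that("accuracy evaluation matches a hand argmax count", {
  ds <- make_patch_dataset(n = 10, seed = 4)
  m <- build_network(network_spec("tiny", 2, c(32, 32, 3)), seed = 6)
  acc <- evaluate_accuracy(m, ds, "train")
  probs <- predict(m, ds$images, type = "prob")
  hand <- mean(apply(probs, 2, which.max) == ds$labels)
  expect_equal(acc, hand)
  expect_gte(acc, 0)
  expect_lte(acc, 1)
})

test_that("a constant-majority model scores one half on a balanced split", {
  ds <- make_patch_dataset(n = 10, seed = 4)
  m <- build_network(network_spec("tiny", 2, c(32, 32, 3)), seed = 6)
  L <- length(m$layers)
  m$layers[[L]]$W[] <- 0
  m$layers[[L]]$b <- c(1, 0)
  expect_equal(evaluate_accuracy(m, ds, "train"), 0.5)
})

test_that("empty splits are rejected", {
  ds <- make_patch_dataset(n = 8, seed = 1)
  m <- build_network(network_spec("tiny", 2, c(32, 32, 3)), seed = 1)
  expect_error(evaluate_accuracy(m, ds, "validation"), "empty")
})

test_that("checkpoints round-trip with provenance", {
  m <- make_small_net(seed = 2)
  path <- tempfile(fileext = ".rds")
  save_leafnet(m, path)
  m2 <- load_leafnet(path)
  expect_identical(m2$layers, m$layers)
  expect_true(grepl("tiny", m2$provenance))
  unlink(path)
})
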