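# Right-reason machinery: input gradients, masked penalty, Balance algebra,
# combined loss, and the double-backprop parameter gradient.

test_that("input gradients vanish for a constant model and keep the input shape", {
  m <- make_small_net(seed = 2)
  L <- length(m$layers)
  m$layers[[L]]$W[] <- 0   # logits = bias, constant in x
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  g <- input_gradient(m, x)
  expect_identical(dim(g), dim(x))
  expect_equal(max(abs(g)), 0)
})

test_that("input gradients match central finite differences", {
  m <- make_small_net(seed = 7)
  set.seed(11)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  g <- input_gradient(m, x)
  h <- 1e-5
  for (trial in 1:8) {
    i <- sample(length(x), 1)
    x2 <- x; x2[i] <- x2[i] + h
    x3 <- x; x3[i] <- x3[i] - h
    fd <- (log1p_objective(m, x2) - log1p_objective(m, x3)) / (2 * h)
    expect_lt(abs(fd - g[i]) / max(1e-7, abs(fd)), 1e-3)
  }
})

test_that("the masked penalty reproduces hand-computed values", {
  grad <- array(c(1, 0, -2, 3), c(2, 2, 1))   # [[1,-2],[0,3]] row-major
  ones <- matrix(1L, 2, 2)
  expect_equal(rrr_penalty(grad, ones, "squared"), 14)
  expect_equal(rrr_penalty(grad, ones, "literal_sum"), 2)
  zeros <- matrix(0L, 2, 2)
  expect_equal(rrr_penalty(grad, zeros, "squared"), 0)
  expect_equal(rrr_penalty(grad, zeros, "literal_sum"), 0)
  expect_error(rrr_penalty(grad, matrix(1L, 3, 3)), "does not match")
})

test_that("the squared penalty grows monotonically as mask pixels are added", {
  set.seed(4)
  grad <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  ann <- matrix(0L, 6, 6)
  prev <- 0
  for (i in sample(36)) {
    ann[i] <- 1L
    cur <- rrr_penalty(grad, ann, "squared")
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("balance reproduces the worked examples", {
  expect_equal(balance(2.0, 2.0), 2.0)
  expect_equal(balance(0.003, 2.0), 3.0)
  expect_equal(balance(5.0, 0.04), 0.05)
})

test_that("balance brackets into the reference decade and is homogeneous", {
  set.seed(1)
  l1 <- 10^runif(2000, -8, 4)
  l2 <- 10^runif(2000, -8, 4)
  r <- vapply(seq_along(l1), function(i) balance(l1[i], l2[i]), numeric(1))
  expect_true(all(r >= l2 * (1 - 1e-9)))
  expect_true(all(r < 10 * l2 * (1 + 1e-9)))
  cs <- 10^runif(200, -3, 3)
  for (i in 1:200) {
    expect_equal(balance(cs[i] * l1[i], cs[i] * l2[i]),
                 cs[i] * balance(l1[i], l2[i]), tolerance = 1e-9)
  }
})

test_that("balance guards degenerate arguments", {
  expect_error(balance(0, 1), "1e-12")
  expect_error(balance(1e-14, 1), "1e-12")
  expect_error(balance(1, 0), "positive")
  expect_error(balance(1, -2), "positive")
})

test_that("the combined loss follows the balanced form and its reductions", {
  spec0 <- loss_spec(lambda = 0)
  expect_equal(combined_loss(0.7, 0.5, spec0), 0.7)
  spec2 <- loss_spec(lambda = 2)
  expect_equal(combined_loss(0.7, 0, spec2), 0.7)
  expect_equal(combined_loss(0.7, 0.0007, spec2), 0.7 + 2 * 0.7)
  expect_error(combined_loss(-0.1, 0.5, spec2), "nonnegative")
})

test_that("the penalty parameter gradient matches finite differences (both variants)", {
  m <- make_small_net(seed = 7)
  set.seed(13)
  Nb <- 2L
  x <- array(runif(32 * 32 * 3 * Nb), c(32, 32, 3, Nb))
  ann <- array(0L, c(32, 32, Nb))
  ann[sample(length(ann), 900)] <- 1L

  penalty_value <- function(model, variant) {
    fw <- rightreasons:::net_forward(model, x)
    p <- rightreasons:::softmax_cols(fw$logits)
    gx <- rightreasons:::net_backward(
      model, fw, rightreasons:::log1p_softmax_grad(p),
      param_grads = FALSE)$g
    tot <- 0
    for (n in seq_len(Nb)) {
      tot <- tot + rrr_penalty(gx[, , , n], ann[, , n], variant)
    }
    tot / Nb
  }

  for (variant in c("squared", "literal_sum")) {
    fw <- rightreasons:::net_forward(m, x)
    p <- rightreasons:::softmax_cols(fw$logits)
    pen <- rightreasons:::rrr_batch(m, fw, p, ann, variant)
    expect_equal(pen$rloss, penalty_value(m, variant), tolerance = 1e-10)
    h <- 1e-5
    for (l in seq_along(m$layers)) {
      if (is.null(pen$gW[[l]])) next
      for (trial in 1:3) {
        i <- sample(length(m$layers[[l]]$W), 1)
        m2 <- m; m2$layers[[l]]$W[i] <- m2$layers[[l]]$W[i] + h
        m3 <- m; m3$layers[[l]]$W[i] <- m3$layers[[l]]$W[i] - h
        fd <- (penalty_value(m2, variant) - penalty_value(m3, variant)) / (2 * h)
        expect_lt(abs(fd - pen$gW[[l]][i]) / max(1e-6, abs(fd)), 1e-3)
      }
      i <- sample(length(m$layers[[l]]$b), 1)
      m2 <- m; m2$layers[[l]]$b[i] <- m2$layers[[l]]$b[i] + h
      m3 <- m; m3$layers[[l]]$b[i] <- m3$layers[[l]]$b[i] - h
      fd <- (penalty_value(m2, variant) - penalty_value(m3, variant)) / (2 * h)
      expect_lt(abs(fd - pen$gb[[l]][i]), 1e-4 * max(1, abs(fd)))
    }
  }
})

test_that("all-zero annotations make every batch loss equal cross-entropy", {
  ds <- make_patch_dataset(n = 16, seed = 5)
  m <- build_network(network_spec("tiny", 2, c(32, 32, 3)), seed = 2)
  tc <- train_config(epochs = 2, batch_size = 8, seed = 3)
  mr <- train_network(m, ds, loss_spec(lambda = 1.5), tc)
  expect_equal(mr$history$nloss, mr$history$closs)
  expect_true(all(mr$history$rloss == 0))
})
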