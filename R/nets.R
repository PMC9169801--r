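# Classifier networks: an AlexNet-like stack for paper-scale runs and a
# reduced "tiny" variant sized so a full experiment runs on one CPU core.
# The engine is plain reverse-mode backprop over a fixed layer list; the
# layer caches it keeps (im2col matrices, pooling argmax, ReLU masks) are
# exactly what the double-backprop pass of the right-reason penalty needs.

#' Describe a classifier network
#'
#' @param variant `"tiny"` (2 conv + 2 dense stages, for desk-scale runs) or
#'   `"alexnet_like"` (5 conv + 3 dense stages in the classic layout).
#' @param n_classes number of output classes, `>= 2`.
#' @param input_size integer `c(U, V, B)`: image rows, cols, channels.
#' @return an object of class `"network_spec"`.
#' @export
network_spec <- function(variant = c("tiny", "alexnet_like"), n_classes = 2L,
                         input_size = c(64L, 64L, 3L)) {
  variant <- match.arg(variant)
  n_classes <- as.integer(n_classes)
  input_size <- as.integer(input_size)
  if (length(input_size) != 3L) stop("input_size must be c(U, V, B)")
  if (n_classes < 2L) stop("n_classes must be >= 2")
  minside <- if (variant == "tiny") 32L else 64L
  if (input_size[1] < minside || input_size[2] < minside) {
    stop("variant '", variant, "' requires input at least ",
         minside, "x", minside)
  }
  structure(list(variant = variant, n_classes = n_classes,
                 input_size = input_size),
            class = "network_spec")
}

# Layer constructors ---------------------------------------------------------

.layer_conv <- function(H, W, Cin, Cout, k, stride, pad) {
  ci <- conv_index(H, W, Cin, k, stride, pad)
  list(type = "conv", ci = ci, kdim = c(k, k, Cin, Cout),
       out_shape = c(ci$P, ci$Q, Cout))
}

.he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

#' Build an untrained classifier
#'
#' Constructs the network described by `spec` with seed-deterministic
#' He-scaled Gaussian initialization (no pretrained weights).  The last
#' convolutional stage is recorded as the Grad-CAM target layer.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the parameter initialization.
#' @return an object of class `"leafnet"`.
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  U <- spec$input_size[1]; V <- spec$input_size[2]; B <- spec$input_size[3]
  plan <- if (spec$variant == "tiny") {
    list(
      list(op = "center"),
      list(op = "conv", cout = 16L, k = 3L, s = 2L, p = 1L),
      list(op = "relu"),
      list(op = "pool", k = 2L, s = 2L),
      list(op = "conv", cout = 32L, k = 3L, s = 1L, p = 1L),
      list(op = "relu", cam = TRUE),
      list(op = "pool", k = 2L, s = 2L),
      list(op = "flatten"),
      list(op = "dense", out = 64L),
      list(op = "relu"),
      list(op = "dense", out = spec$n_classes)
    )
  } else {
    list(
      list(op = "center"),
      list(op = "conv", cout = 64L,  k = 11L, s = 4L, p = 2L),
      list(op = "relu"),
      list(op = "pool", k = 3L, s = 2L),
      list(op = "conv", cout = 192L, k = 5L, s = 1L, p = 2L),
      list(op = "relu"),
      list(op = "pool", k = 3L, s = 2L),
      list(op = "conv", cout = 384L, k = 3L, s = 1L, p = 1L),
      list(op = "relu"),
      list(op = "conv", cout = 256L, k = 3L, s = 1L, p = 1L),
      list(op = "relu"),
      list(op = "conv", cout = 256L, k = 3L, s = 1L, p = 1L),
      list(op = "relu", cam = TRUE),
      list(op = "pool", k = 3L, s = 2L),
      list(op = "flatten"),
      list(op = "dense", out = 4096L),
      list(op = "relu"),
      list(op = "dense", out = 4096L),
      list(op = "relu"),
      list(op = "dense", out = spec$n_classes)
    )
  }
  set.seed(as.integer(seed))
  layers <- list()
  cam_layer <- NA_integer_
  shape <- c(U, V, B)   # spatial shape until flattened, then scalar length
  for (step in plan) {
    l <- switch(step$op,
      conv = {
        lay <- .layer_conv(shape[1], shape[2], shape[3], step$cout,
                           step$k, step$s, step$p)
        lay$W <- .he_init(lay$kdim, step$k * step$k * shape[3])
        lay$b <- numeric(step$cout)
        shape <- lay$out_shape
        lay
      },
      relu = list(type = "relu"),
      center = list(type = "center"),
      pool = {
        ci <- conv_index(shape[1], shape[2], 1L, step$k, step$s, 0L)
        shape <- c(ci$P, ci$Q, shape[3])
        list(type = "pool", k = step$k, s = step$s, out_shape = shape)
      },
      flatten = {
        nfeat <- prod(shape)
        shape <- nfeat
        list(type = "flatten", n = nfeat)
      },
      gap = {
        lay <- list(type = "gap", PQ = shape[1] * shape[2],
                    in_shape = shape)
        shape <- shape[3]
        lay
      },
      dense = {
        lay <- list(type = "dense",
                    W = matrix(stats::rnorm(step$out * shape,
                                            sd = sqrt(2 / shape)),
                               step$out, shape),
                    b = numeric(step$out))
        shape <- step$out
        lay
      })
    layers[[length(layers) + 1L]] <- l
    if (isTRUE(step$cam)) cam_layer <- length(layers)
  }
  structure(list(spec = spec, layers = layers, cam_layer = cam_layer,
                 seed = as.integer(seed), epochs_trained = 0L,
                 loss_descriptor = "untrained", history = NULL),
            class = "leafnet")
}

# Forward / backward ---------------------------------------------------------

# Forward pass.  Returns activations a[[1]] = input .. a[[L+1]] = logits and
# per-layer caches.  `x` is (H, W, C, N).
net_forward <- function(model, x, keep = TRUE) {
  L <- length(model$layers)
  acts <- vector("list", L + 1L)
  caches <- vector("list", L)
  a <- x
  acts[[1L]] <- a
  for (l in seq_len(L)) {
    lay <- model$layers[[l]]
    if (lay$type == "conv") {
      cf <- conv_forward(a, lay$W, lay$b, lay$ci, keep_col = keep)
      a <- cf$out
      caches[[l]] <- cf$col
    } else if (lay$type == "center") {
      a <- center_map(a)
    } else if (lay$type == "relu") {
      a <- a * (a > 0)
    } else if (lay$type == "pool") {
      pc <- maxpool_forward(a, lay$k, lay$s)
      a <- pc$out
      caches[[l]] <- pc[c("argidx", "argoff", "kk", "in_dim")]
    } else if (lay$type == "flatten") {
      dim(a) <- c(lay$n, dim(a)[4])
    } else if (lay$type == "gap") {
      da <- dim(a)
      dim(a) <- c(lay$PQ, da[3] * da[4])
      a <- matrix(colSums(a) / lay$PQ, da[3], da[4])
    } else { # dense
      a <- lay$W %*% a + lay$b
    }
    acts[[l + 1L]] <- if (keep) a else NULL
  }
  list(logits = a, acts = acts, caches = caches)
}

# Reverse pass from a logits-shaped gradient down to layer `to_layer`
# (0 = input).  Optionally accumulates parameter gradients and records the
# per-level gradients gs[[l]] = d(objective)/d a[[l]].
net_backward <- function(model, fw, glogits, to_layer = 0L,
                         param_grads = TRUE, record = FALSE) {
  L <- length(model$layers)
  gW <- if (param_grads) vector("list", L) else NULL
  gb <- if (param_grads) vector("list", L) else NULL
  gs <- if (record) vector("list", L + 1L) else NULL
  g <- glogits
  if (record) gs[[L + 1L]] <- g
  for (l in L:max(1L, to_layer + 1L)) {
    lay <- model$layers[[l]]
    if (lay$type == "conv") {
      if (param_grads) {
        wg <- conv_backward_weight(fw$caches[[l]], g, lay$kdim)
        gW[[l]] <- wg$gW; gb[[l]] <- wg$gb
      }
      g <- conv_backward_input(g, lay$W, lay$ci, dim(g)[4])
    } else if (lay$type == "center") {
      g <- center_map(g)
    } else if (lay$type == "relu") {
      g <- g * (fw$acts[[l + 1L]] > 0)
    } else if (lay$type == "pool") {
      g <- maxpool_backward(g, fw$caches[[l]])
    } else if (lay$type == "flatten") {
      dim(g) <- dim(fw$acts[[l]])
    } else if (lay$type == "gap") {
      d <- dim(fw$acts[[l]])
      g <- array(rep(g / lay$PQ, each = lay$PQ), d)
    } else { # dense
      if (param_grads) {
        gW[[l]] <- tcrossprod(g, fw$acts[[l]])
        gb[[l]] <- rowSums(g)
      }
      g <- crossprod(lay$W, g)
    }
    if (record) gs[[l]] <- g
    if (l == to_layer + 1L) break
  }
  list(g = g, gW = gW, gb = gb, gs = gs)
}

# Per-sample mean removal over all pixels and channels (input whitening
# against global brightness shifts).  The map x - mean(x) is a symmetric
# linear projection, so it is its own transpose in backward and
# double-backward passes.
center_map <- function(a) {
  d <- dim(a)
  m <- prod(d[1:3])
  a2 <- a
  dim(a2) <- c(m, d[4])
  a2 <- sweep(a2, 2L, colMeans(a2), "-")
  dim(a2) <- d
  a2
}

# Softmax / loss heads -------------------------------------------------------

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# Mean cross-entropy and its logits gradient for integer labels 1..n.
ce_loss <- function(logits, labels) {
  N <- ncol(logits)
  p <- softmax_cols(logits)
  picked <- p[cbind(labels, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-300)))
  g <- p
  g[cbind(labels, seq_len(N))] <- g[cbind(labels, seq_len(N))] - 1
  list(loss = loss, glogits = g / N, probs = p)
}

# Gradient of s = sum_c log(p_c + 1) wrt the logits, per column.
log1p_softmax_grad <- function(p) {
  q <- p / (1 + p)
  sweep(-p, 2L, colSums(q), "*") + q   # q_j - p_j * r
}

# Hessian-vector product of s wrt the logits (symmetric head of the
# double-backprop sweep).  p, v: (n, N) column-per-sample.
log1p_softmax_hvp <- function(p, v) {
  q <- p / (1 + p)
  w <- p / (1 + p)^2
  r <- colSums(q)
  Sw <- colSums(w)
  pv <- colSums(p * v)
  wv <- colSums(w * v)
  coef <- w - sweep(p, 2L, r, "*")   # coef_j = w_j - r * p_j
  t1 <- coef * sweep(v, 2L, pv, "-")
  t2 <- sweep(p, 2L, wv - Sw * pv, "*")
  t1 - t2
}

# Adam ----------------------------------------------------------------------

adam_init <- function(model) {
  st <- list(t = 0L, m = list(), v = list())
  for (l in seq_along(model$layers)) {
    lay <- model$layers[[l]]
    if (!is.null(lay$W)) {
      st$m[[l]] <- list(W = array(0, dim(lay$W) %||% length(lay$W)),
                        b = numeric(length(lay$b)))
      st$v[[l]] <- st$m[[l]]
    }
  }
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(model, gW, gb, st, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (l in seq_along(model$layers)) {
    if (is.null(gW[[l]])) next
    st$m[[l]]$W <- beta1 * st$m[[l]]$W + (1 - beta1) * gW[[l]]
    st$v[[l]]$W <- beta2 * st$v[[l]]$W + (1 - beta2) * gW[[l]]^2
    st$m[[l]]$b <- beta1 * st$m[[l]]$b + (1 - beta1) * gb[[l]]
    st$v[[l]]$b <- beta2 * st$v[[l]]$b + (1 - beta2) * gb[[l]]^2
    model$layers[[l]]$W <- model$layers[[l]]$W -
      lr * (st$m[[l]]$W / bc1) / (sqrt(st$v[[l]]$W / bc2) + eps)
    model$layers[[l]]$b <- model$layers[[l]]$b -
      lr * (st$m[[l]]$b / bc1) / (sqrt(st$v[[l]]$b / bc2) + eps)
  }
  list(model = model, st = st)
}

# Training -------------------------------------------------------------------

#' Training configuration
#'
#' @param epochs number of passes over the train split, `>= 1`.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size; defaults to `1e-3` for the tiny
#'   variant and `1e-4` for `alexnet_like` when left `NULL`.
#' @param optimizer_name only `"adam"` is implemented.
#' @param warmup_epochs epochs of linear learning-rate warmup; stabilizes the
#'   first optimizer steps on small batches.
#' @param beta2 Adam second-moment decay; 0.99 tracks the gradient scale
#'   faster than the textbook 0.999, which matters over short runs.
#' @param seed seed for minibatch shuffling.
#' @return an object of class `"train_config"`.
#' @export
train_config <- function(epochs = 15L, batch_size = 16L, learning_rate = NULL,
                         optimizer_name = "adam", warmup_epochs = 3L,
                         beta2 = 0.99, seed = 1L) {
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (optimizer_name != "adam") stop("only the 'adam' optimizer is implemented")
  structure(list(epochs = epochs, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer_name = optimizer_name,
                 warmup_epochs = as.integer(warmup_epochs), beta2 = beta2,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a classifier under cross-entropy or the combined right-reason loss
#'
#' Runs minibatch Adam on the train split.  With a plain cross-entropy
#' [loss_spec()] this is ordinary training.  With an RRR loss the per-batch
#' objective is `NLoss = CLoss + lambda * Balance(RLoss, CLoss)`, where
#' `RLoss` penalizes input gradients on pixels the per-sample annotation
#' matrix marks as useless, and `Balance` rescales the penalty into the decade
#' of the classification loss.  The order-of-magnitude factor is held fixed
#' within a batch when differentiating.  Batches whose raw penalty falls below
#' `1e-12` (e.g. all annotations zero) skip the penalty term entirely, so
#' training with all-zero annotation matrices reproduces the cross-entropy
#' trajectory exactly.
#'
#' @param model an untrained or previously trained `"leafnet"`.
#' @param data a `"leaf_dataset"` (see [build_dataset()]).
#' @param loss a [loss_spec()]; `lambda = 0` or `closs_name = "cross_entropy"`
#'   without annotations gives plain cross-entropy.
#' @param config a [train_config()].
#' @return the trained `"leafnet"`; `$history` holds one row per epoch with
#'   columns `epoch, closs, rloss, nloss, val_accuracy, n_rloss_skipped`.
#' @export
train_network <- function(model, data, loss = loss_spec(lambda = 0),
                          config = train_config()) {
  stopifnot(inherits(model, "leafnet"), inherits(data, "leaf_dataset"),
            inherits(loss, "loss_spec"), inherits(config, "train_config"))
  tr <- data$splits$train
  if (!length(tr)) stop("train split is empty")
  lr <- config$learning_rate %||%
    if (model$spec$variant == "tiny") 2e-3 else 1e-4
  use_rrr <- loss$lambda > 0
  st <- adam_init(model)
  nb <- config$batch_size
  hist <- data.frame()
  set.seed(config$seed)
  warm <- max(0L, config$warmup_epochs %||% 0L)
  for (ep in seq_len(config$epochs)) {
    lr_ep <- if (warm > 0L && ep <= warm) lr * ep / warm else lr
    perm <- sample(tr)
    ep_c <- ep_r <- ep_n <- 0
    nskip <- 0L
    nbatches <- 0L
    for (start in seq(1L, length(perm), by = nb)) {
      idx <- perm[start:min(start + nb - 1L, length(perm))]
      x <- data$images[, , , idx, drop = FALSE]
      y <- data$labels[idx]
      fw <- net_forward(model, x)
      ce <- ce_loss(fw$logits, y)
      if (!is.finite(ce$loss)) {
        stop("training aborted: cross-entropy loss became non-finite at epoch ",
             ep)
      }
      bp <- net_backward(model, fw, ce$glogits)
      gW <- bp$gW; gb <- bp$gb
      rloss <- 0; nloss <- ce$loss
      if (use_rrr) {
        ann <- data$annotations[, , idx, drop = FALSE]
        pen <- rrr_batch(model, fw, ce$probs, ann, loss$rloss_variant)
        rloss <- pen$rloss
        if (!is.finite(rloss)) {
          stop("training aborted: right-reason penalty became non-finite ",
               "at epoch ", ep)
        }
        if (rloss > 1e-12) {
          f <- balance_factor(rloss, ce$loss)
          scale <- loss$lambda * f
          if (is.finite(loss$grad_cap)) {
            nce2 <- sum(vapply(seq_along(gW), function(l) {
              if (is.null(gW[[l]])) 0 else sum(gW[[l]]^2) + sum(gb[[l]]^2)
            }, numeric(1)))
            npen2 <- sum(vapply(seq_along(pen$gW), function(l) {
              if (is.null(pen$gW[[l]])) 0 else
                sum(pen$gW[[l]]^2) + sum(pen$gb[[l]]^2)
            }, numeric(1)))
            lim <- loss$grad_cap * max(sqrt(nce2), 1)
            if (npen2 > 0 && scale * sqrt(npen2) > lim) {
              scale <- lim / sqrt(npen2)
            }
          }
          for (l in seq_along(gW)) {
            if (!is.null(pen$gW[[l]])) {
              gW[[l]] <- gW[[l]] + scale * pen$gW[[l]]
              gb[[l]] <- gb[[l]] + scale * pen$gb[[l]]
            }
          }
          nloss <- ce$loss + loss$lambda * f * rloss
        } else {
          nskip <- nskip + 1L
        }
      }
      up <- adam_step(model, gW, gb, st, lr_ep, beta2 = config$beta2 %||% 0.999)
      model <- up$model; st <- up$st
      ep_c <- ep_c + ce$loss; ep_r <- ep_r + rloss; ep_n <- ep_n + nloss
      nbatches <- nbatches + 1L
    }
    va <- if (length(data$splits$validation)) {
      evaluate_accuracy(model, data, "validation")
    } else NA_real_
    hist <- rbind(hist, data.frame(
      epoch = ep, closs = ep_c / nbatches, rloss = ep_r / nbatches,
      nloss = ep_n / nbatches, val_accuracy = va, n_rloss_skipped = nskip))
  }
  model$epochs_trained <- model$epochs_trained + config$epochs
  model$loss_descriptor <- if (use_rrr) {
    sprintf("rrr(lambda=%g, variant=%s)", loss$lambda, loss$rloss_variant)
  } else "cross_entropy"
  model$history <- hist
  model
}

#' Classification accuracy on a dataset split
#'
#' @param model a trained `"leafnet"`.
#' @param data a `"leaf_dataset"`.
#' @param split `"train"`, `"validation"` or `"test"`.
#' @return fraction of correctly classified samples in `[0, 1]`.
#' @export
evaluate_accuracy <- function(model, data, split = "test") {
  idx <- data$splits[[split]]
  if (is.null(idx) || !length(idx)) stop("split '", split, "' is empty")
  pred <- predict(model, data$images[, , , idx, drop = FALSE], type = "class")
  mean(pred == data$labels[idx])
}

#' @export
predict.leafnet <- function(object, newdata, type = c("prob", "class", "logits"),
                            chunk = 64L, ...) {
  type <- match.arg(type)
  if (length(dim(newdata)) == 3L) dim(newdata) <- c(dim(newdata), 1L)
  N <- dim(newdata)[4]
  out <- NULL
  for (start in seq(1L, N, by = chunk)) {
    idx <- start:min(start + chunk - 1L, N)
    z <- net_forward(object, newdata[, , , idx, drop = FALSE],
                     keep = FALSE)$logits
    out <- cbind(out, z)
  }
  switch(type,
    logits = out,
    prob = softmax_cols(out),
    class = apply(softmax_cols(out), 2L, which.max))
}

n_parameters <- function(model) {
  sum(vapply(model$layers,
             function(l) length(l$W) + length(l$b), numeric(1)))
}

#' @export
print.leafnet <- function(x, ...) {
  cat(sprintf("<leafnet> %s, %d classes, input %s\n", x$spec$variant,
              x$spec$n_classes, paste(x$spec$input_size, collapse = "x")))
  cat(sprintf("  parameters: %s  epochs trained: %d  loss: %s\n",
              format(n_parameters(x), big.mark = ","),
              x$epochs_trained, x$loss_descriptor))
  invisible(x)
}

#' @export
summary.leafnet <- function(object, ...) {
  print(object)
  shapes <- vapply(object$layers, function(l) {
    switch(l$type,
           conv = sprintf("conv %s", paste(l$kdim, collapse = "x")),
           dense = sprintf("dense %dx%d", nrow(l$W), ncol(l$W)),
           l$type)
  }, character(1))
  cat("  layers: ", paste(shapes, collapse = " -> "), "\n", sep = "")
  if (!is.null(object$history)) {
    cat("  last epochs:\n")
    print(utils::tail(object$history, 3L), row.names = FALSE)
  }
  invisible(object)
}

#' Save / load a trained model with embedded JSON provenance
#'
#' The checkpoint is an RDS file whose object carries a JSON provenance block
#' (spec, init seed, epochs trained, loss descriptor).
#'
#' @param model a `"leafnet"`.
#' @param path file path for the checkpoint.
#' @return `save_leafnet` returns `path` invisibly; `load_leafnet` returns the
#'   restored `"leafnet"`.
#' @export
save_leafnet <- function(model, path) {
  model$provenance <- jsonlite::toJSON(list(
    variant = model$spec$variant, n_classes = model$spec$n_classes,
    input_size = model$spec$input_size, seed = model$seed,
    epochs_trained = model$epochs_trained,
    loss_descriptor = model$loss_descriptor), auto_unbox = TRUE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_leafnet
#' @export
load_leafnet <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "leafnet")) stop("not a leafnet checkpoint: ", path)
  m
}
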