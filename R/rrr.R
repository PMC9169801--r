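# Modified right-for-the-right-reasons (RRR) regularizer: input gradients of
# the log-transformed class probabilities, masked by a per-sample binary
# annotation matrix (1 = useless pixel), rescaled into the decade of the
# classification loss by an order-of-magnitude Balance function, and added to
# cross-entropy.  The penalty's gradient with respect to the network weights
# is computed by an explicit double-backpropagation sweep (rrr_param_grad).

#' Loss specification for training
#'
#' @param lambda nonnegative weight of the right-reason term; `0` gives plain
#'   cross-entropy.  Defaults used in the experiments: `1.5` for the
#'   fake-vs-real task, `2` otherwise.
#' @param rloss_variant `"squared"` (default; penalty is the masked sum of
#'   squared input gradients, guaranteed nonnegative as the Balance rescaling
#'   requires) or `"literal_sum"` (the masked plain sum, signed).
#' @param closs_name the classification loss; only `"cross_entropy"`.
#' @param grad_cap trust-region cap on the penalty's parameter-gradient
#'   contribution, as a multiple of the classification-gradient norm.  The
#'   Balance factor is piecewise constant (hence non-differentiable), and
#'   multiplying the raw penalty gradient by it can scale the penalty's pull
#'   to orders of magnitude above the classification signal whenever the raw
#'   penalty is many decades below the classification loss; a handful of
#'   such steps is enough to destroy a small network.  The cap limits the
#'   balanced penalty gradient to `grad_cap` times the classification
#'   gradient norm per batch — guidance biases the descent direction but
#'   never overrides learning.  Default 1 (same order of magnitude, the
#'   principle behind Balance itself); `Inf` disables the cap.  The reported
#'   loss value is always the exact combined loss.
#' @return an object of class `"loss_spec"`.
#' @export
loss_spec <- function(lambda = 0, rloss_variant = c("squared", "literal_sum"),
                      closs_name = "cross_entropy", grad_cap = 1) {
  rloss_variant <- match.arg(rloss_variant)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("lambda must be a single nonnegative number")
  }
  if (closs_name != "cross_entropy") {
    stop("only the cross-entropy classification loss is implemented")
  }
  if (!is.numeric(grad_cap) || length(grad_cap) != 1L || grad_cap <= 0) {
    stop("grad_cap must be a single positive number (Inf disables the cap)")
  }
  structure(list(lambda = lambda, rloss_variant = rloss_variant,
                 closs_name = closs_name, grad_cap = grad_cap),
            class = "loss_spec")
}

#' Gradient of the log-transformed output with respect to the input image
#'
#' Computes `d( sum_c log(p_c + 1) ) / dx`, where `p` are the softmax class
#' probabilities of the model at input `x`.  The log argument uses the
#' probabilities rather than the raw pre-softmax scores so that `log(. + 1)`
#' is always defined; each summand then lies in `[0, log 2]`.  The same
#' quantity, computed batched, is what the right-reason penalty masks and
#' sums during training, where it stays differentiable with respect to the
#' model parameters (double backpropagation).
#'
#' @param model a `"leafnet"`.
#' @param x a single image `(U, V, B)` or a batch `(U, V, B, N)`.
#' @return an array of the same shape as `x`.
#' @export
input_gradient <- function(model, x) {
  single <- length(dim(x)) == 3L
  if (single) dim(x) <- c(dim(x), 1L)
  fw <- net_forward(model, x)
  p <- softmax_cols(fw$logits)
  gy <- log1p_softmax_grad(p)
  g <- net_backward(model, fw, gy, to_layer = 0L, param_grads = FALSE)$g
  if (!all(is.finite(g))) {
    stop("input gradient is non-finite; model parameters may have diverged")
  }
  if (single) dim(g) <- dim(g)[1:3]
  g
}

#' Right-reason penalty of one sample
#'
#' Masks the input gradient with the annotation matrix (1 = useless pixel,
#' replicated across channels) and sums.  The default `"squared"` variant
#' squares the masked gradients first, so the penalty is nonnegative;
#' `"literal_sum"` sums the signed gradients as-is.
#'
#' @param grad input gradient, `(U, V, B)` (or `(U, V)` for a single band).
#' @param annotation binary `U x V` matrix, 1 = useless pixel.
#' @param variant `"squared"` or `"literal_sum"`.
#' @return a scalar; nonnegative under `"squared"`.
#' @export
rrr_penalty <- function(grad, annotation,
                        variant = c("squared", "literal_sum")) {
  variant <- match.arg(variant)
  if (length(dim(grad)) < 2L) stop("grad must be at least 2-d")
  d <- dim(grad)
  if (!identical(dim(annotation), d[1:2])) {
    stop("annotation shape ", paste(dim(annotation), collapse = "x"),
         " does not match gradient spatial shape ",
         paste(d[1:2], collapse = "x"))
  }
  B <- if (length(d) >= 3L) d[3] else 1L
  a <- array(rep(as.vector(annotation), B), c(d[1:2], B))
  g <- array(grad, c(d[1:2], B))
  if (variant == "squared") sum(a * g^2) else sum(a * g)
}

# Order-of-magnitude rescaling factor 10^ceil(log10(l2 / l1)).  A small guard
# keeps exact powers of ten from being bumped a decade up by floating-point
# noise in log10.
balance_factor <- function(l1, l2) {
  10^ceiling(log10(l2 / l1) - 1e-9)
}

#' Order-of-magnitude loss balancing
#'
#' `balance(l1, l2) = 10^ceil(log10(l2 / l1)) * l1`: rescales `l1` by the
#' power of ten that lifts it into the decade of `l2`, so the result lies in
#' `[l2, 10 * l2)` and equals `l2` exactly when `l2 / l1` is a power of ten.
#'
#' @param l1 positive scalar (the loss being rescaled, e.g. the right-reason
#'   penalty).
#' @param l2 positive scalar (the reference loss, e.g. cross-entropy).
#' @return the rescaled value of `l1`.
#' @export
balance <- function(l1, l2) {
  if (!is.finite(l2) || l2 <= 0) stop("l2 must be a positive number")
  if (!is.finite(l1) || l1 <= 1e-12) {
    stop("l1 must exceed 1e-12; the magnitude ratio is undefined at zero ",
         "(callers skip the penalty term for such batches)")
  }
  balance_factor(l1, l2) * l1
}

#' Combined training loss
#'
#' `NLoss = CLoss + lambda * Balance(RLoss, CLoss)`.  When `lambda = 0`, or
#' when the penalty falls below the `1e-12` guard (all-zero annotation
#' matrices), the combined loss is exactly the classification loss.
#'
#' @param closs nonnegative classification loss.
#' @param rloss right-reason penalty.
#' @param spec a [loss_spec()].
#' @return the combined scalar loss.
#' @export
combined_loss <- function(closs, rloss, spec) {
  stopifnot(inherits(spec, "loss_spec"))
  if (closs < 0) stop("closs must be nonnegative")
  if (spec$lambda == 0 || rloss <= 1e-12) return(closs)
  closs + spec$lambda * balance(rloss, closs)
}

# Batched penalty + parameter gradient (double backpropagation) -------------
#
# RLoss = (1/N) sum_n sum_{u,v,b} A_n[u,v] * g_x[u,v,b,n]^2   (squared)
# where g_x = d( sum_c log(p_c + 1) ) / dx.  The parameter gradient has two
# parts: (i) adjoints picked up while sweeping the *backward* graph upward
# with ghat_0 = dRLoss/dg_x (conv/dense backward nodes contribute weight
# terms; ReLU masks and pooling argmax are piecewise constant); (ii) a
# standard backward pass of the logits adjoint yhat = H_s(y) %*% ghat_top,
# H_s being the Hessian of s = sum_c log(p_c + 1) at the logits.
rrr_batch <- function(model, fw, probs, annotations, variant = "squared") {
  N <- dim(fw$acts[[1L]])[4]
  gy <- log1p_softmax_grad(probs)
  bpass <- net_backward(model, fw, gy, to_layer = 0L, param_grads = FALSE,
                        record = TRUE)
  gx <- bpass$g
  d <- dim(gx)
  B <- d[3]
  ann4 <- array(0, d)
  for (b in seq_len(B)) ann4[, , b, ] <- annotations
  rloss <- if (variant == "squared") {
    sum(ann4 * gx^2) / N
  } else {
    sum(ann4 * gx) / N
  }
  ghat <- if (variant == "squared") (2 / N) * ann4 * gx else ann4 / N
  L <- length(model$layers)
  gW <- vector("list", L)
  gb <- vector("list", L)
  g <- ghat
  for (l in seq_len(L)) {
    lay <- model$layers[[l]]
    if (lay$type == "conv") {
      gW[[l]] <- conv_backward_weight(im2col(g, lay$ci), bpass$gs[[l + 1L]],
                                      lay$kdim)$gW
      gb[[l]] <- numeric(length(lay$b))   # bias absent from the backward map
      g <- conv_forward(g, lay$W, numeric(dim(lay$W)[4]), lay$ci,
                        keep_col = FALSE)$out
    } else if (lay$type == "center") {
      g <- center_map(g)
    } else if (lay$type == "relu") {
      g <- g * (fw$acts[[l + 1L]] > 0)
    } else if (lay$type == "pool") {
      g <- maxpool_doublebp(g, fw$caches[[l]], dim(fw$acts[[l + 1L]]))
    } else if (lay$type == "flatten") {
      dim(g) <- c(lay$n, N)
    } else if (lay$type == "gap") {
      dg <- dim(g)
      dim(g) <- c(lay$PQ, dg[3] * dg[4])
      g <- matrix(colSums(g) / lay$PQ, dg[3], dg[4])
    } else { # dense
      gW[[l]] <- bpass$gs[[l + 1L]] %*% t(g)
      gb[[l]] <- numeric(length(lay$b))
      g <- lay$W %*% g
    }
  }
  yhat <- log1p_softmax_hvp(probs, g)
  head_bp <- net_backward(model, fw, yhat, to_layer = 0L, param_grads = TRUE)
  for (l in seq_len(L)) {
    if (!is.null(head_bp$gW[[l]])) {
      gW[[l]] <- (gW[[l]] %||% 0) + head_bp$gW[[l]]
      gb[[l]] <- (gb[[l]] %||% 0) + head_bp$gb[[l]]
    }
  }
  list(rloss = rloss, gW = gW, gb = gb)
}
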