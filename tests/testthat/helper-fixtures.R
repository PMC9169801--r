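# Shared fixtures, all generated in code.

relerr <- function(a, b) max(abs(a - b)) / max(1e-12, max(abs(b)))

# A trivially separable two-class image set (bright square patch vs none),
# in the same container the simulator produces.
make_patch_dataset <- function(n = 20L, size = 32L, seed = 1L,
                               test_frac = 0) {
  set.seed(seed)
  imgs <- array(stats::runif(size * size * 3 * n, 0, 0.3),
                c(size, size, 3L, n))
  labs <- rep(1:2, length.out = n)
  for (i in which(labs == 2L)) {
    imgs[8:16, 8:16, , i] <- 0.95
  }
  ntest <- round(test_frac * n)
  idx <- sample(n)
  structure(list(
    images = imgs, labels = labs,
    annotations = array(0L, c(size, size, n)),
    assessments = array(1L, c(size, size, n)),
    splits = list(train = sort(idx[seq_len(n - ntest)]),
                  validation = integer(0),
                  test = if (ntest) sort(idx[(n - ntest + 1L):n]) else
                    sort(idx[seq_len(n - ntest)])),
    class_names = c("plain", "patch"), task = "toy", cfg = NULL, seed = seed),
    class = "leaf_dataset")
}

# Tiny trained-ish network on a small input, for gradient oracles.
make_small_net <- function(seed = 7L, size = 32L, n_classes = 3L) {
  build_network(network_spec("tiny", n_classes = n_classes,
                             input_size = c(size, size, 3L)), seed = seed)
}

# Forward pass of the layers above the Grad-CAM stage only, starting from a
# given CAM activation; used as the function under finite differencing.
tail_from_cam <- function(model, a, class_index) {
  for (l in (model$cam_layer + 1L):length(model$layers)) {
    lay <- model$layers[[l]]
    a <- switch(lay$type,
      pool = rightreasons:::maxpool_forward(a, lay$k, lay$s)$out,
      flatten = { dim(a) <- c(lay$n, 1L); a },
      gap = { da <- dim(a); dim(a) <- c(lay$PQ, da[3])
              matrix(colSums(a) / lay$PQ, da[3], 1L) },
      dense = lay$W %*% a + lay$b,
      relu = a * (a > 0),
      center = rightreasons:::center_map(a))
  }
  a[class_index, 1L]
}

# Whole-model scalar objective s(x) = sum_c log(p_c + 1), for input-gradient
# finite differences.
log1p_objective <- function(model, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  fw <- rightreasons:::net_forward(model, x, keep = FALSE)
  p <- rightreasons:::softmax_cols(fw$logits)
  sum(log(p + 1))
}
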