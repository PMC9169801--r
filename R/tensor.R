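# Batched tensor primitives on arrays laid out (H, W, C, N), column-major.
# Convolution is implemented as an im2col gather followed by one BLAS matrix
# product; the gather indices depend only on the layer geometry and are
# precomputed once per layer at network-build time.

# Geometry + gather indices for a conv (or pooling) window.
# idx[r, p] is the 1-based linear index into a single padded (Hp, Wp, Cin)
# volume of the r-th unrolled kernel element for the p-th output position.
# Row order: kernel row fastest, then kernel col, then input channel.
# Column order: output row fastest, then output col.
conv_index <- function(H, W, Cin, k, stride = 1L, pad = 0L) {
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  P <- (Hp - k) %/% stride + 1L
  Q <- (Wp - k) %/% stride + 1L
  if (P < 1L || Q < 1L) {
    stop("kernel of size ", k, " does not fit a ", H, "x", W, " input")
  }
  off <- as.vector(outer(0:(k - 1L), Hp * (0:(k - 1L)), "+"))
  off <- as.vector(outer(off, Hp * Wp * (0:(Cin - 1L)), "+"))
  base <- as.vector(outer(stride * (0:(P - 1L)), Hp * stride * (0:(Q - 1L)), "+"))
  idx <- outer(off, base, "+") + 1L
  storage.mode(idx) <- "integer"
  list(idx = idx, H = H, W = W, Cin = Cin, k = k, stride = stride, pad = pad,
       Hp = Hp, Wp = Wp, P = P, Q = Q)
}

pad_input <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), , ] <- x
  out
}

# im2col over the batch: returns (k*k*Cin, P*Q*N).
im2col <- function(x, ci) {
  N <- dim(x)[4]
  xp <- pad_input(x, ci$pad)
  vol <- ci$Hp * ci$Wp * ci$Cin
  .Call(C_im2col, as.double(xp), ci$idx, as.integer(N), as.double(vol))
}

# Forward convolution.  W: (k, k, Cin, Cout); b: length Cout.
# Returns list(out = (P, Q, Cout, N), col) -- col is kept for the weight
# gradient and for the double-backprop sweep.
conv_forward <- function(x, W, b, ci, keep_col = TRUE) {
  N <- dim(x)[4]
  Cout <- dim(W)[4]
  col <- im2col(x, ci)
  Wm <- matrix(W, nrow = prod(dim(W)[1:3]), ncol = Cout)
  out <- crossprod(col, Wm)                       # (PQ*N, Cout)
  out <- sweep(out, 2L, b, "+")
  dim(out) <- c(ci$P * ci$Q, N, Cout)
  out <- aperm(out, c(1L, 3L, 2L))
  dim(out) <- c(ci$P, ci$Q, Cout, N)
  list(out = out, col = if (keep_col) col else NULL)
}

# Reshape an output-shaped gradient (P, Q, Cout, N) to (PQ*N, Cout).
.gout_mat <- function(gout) {
  d <- dim(gout)
  g <- aperm(gout, c(1L, 2L, 4L, 3L))
  dim(g) <- c(d[1] * d[2] * d[4], d[3])
  g
}

# Gradient wrt the conv input: scatter-add of W %*% gout through the
# im2col map.  Each idx row maps output positions to distinct padded pixels,
# so per-row indexed addition is safe.
conv_backward_input <- function(gout, W, ci, N) {
  Cout <- dim(W)[4]
  Wm <- matrix(W, nrow = prod(dim(W)[1:3]), ncol = Cout)
  gm <- .gout_mat(gout)                            # (PQ*N, Cout)
  gcol <- tcrossprod(Wm, gm)                       # (KKC, PQ*N)
  vol <- ci$Hp * ci$Wp * ci$Cin
  gpad <- .Call(C_col2im, gcol, ci$idx, as.integer(N), as.double(vol))
  dim(gpad) <- c(ci$Hp, ci$Wp, ci$Cin, N)
  if (ci$pad > 0L) {
    p <- ci$pad
    gpad <- gpad[(p + 1L):(p + ci$H), (p + 1L):(p + ci$W), , , drop = FALSE]
  }
  gpad
}

# Gradient wrt conv weights/bias given the stored col matrix.
conv_backward_weight <- function(col, gout, kdim) {
  gm <- .gout_mat(gout)
  gW <- col %*% gm                                 # (KKC, Cout)
  dim(gW) <- kdim
  list(gW = gW, gb = colSums(gm))
}

# Max pooling, window k x k, given stride.  Returns pooled output plus the
# argmax bookkeeping needed by backward (scatter) and double-backprop (gather).
maxpool_forward <- function(x, k, stride) {
  d <- dim(x)
  ci <- conv_index(d[1], d[2], 1L, k, stride, 0L)
  planes <- d[3] * d[4]
  res <- .Call(C_maxpool, as.double(x), ci$idx, as.integer(planes),
               as.double(d[1] * d[2]))
  out <- res[[1L]]
  dim(out) <- c(ci$P, ci$Q, d[3], d[4])
  list(out = out, argidx = res[[2L]], argoff = res[[3L]], kk = k * k,
       in_dim = d)
}

maxpool_backward <- function(gout, cache) {
  gin <- .Call(C_maxpool_bw, as.double(gout), cache$argidx,
               as.double(prod(cache$in_dim)))
  dim(gin) <- cache$in_dim
  gin
}

# Adjoint of maxpool_backward wrt its input gradient: a pure gather.
maxpool_doublebp <- function(gin_adj, cache, out_dim) {
  g <- as.vector(gin_adj)[cache$argidx]
  dim(g) <- out_dim
  g
}

#' Bilinear upsampling of a heatmap to a target size
#'
#' Resizes a `P x Q` map to `U x V` by corner-aligned bilinear interpolation:
#' the four corner samples of the source map straddle the four corners of the
#' target grid.  Constant maps are preserved exactly, and every output value
#' lies between the input minimum and maximum (interpolation weights are a
#' convex combination).  This is the `Trans()` step that brings a class
#' activation map from feature-map resolution up to input resolution.
#'
#' @param map numeric matrix, `P x Q`, `P, Q >= 1`.
#' @param target integer vector `c(U, V)`, the output size.
#' @return a `U x V` numeric matrix.
#' @examples
#' upsample(matrix(c(0, 1, 1, 0), 2, 2), c(4, 4))
#' @export
upsample <- function(map, target) {
  if (!is.matrix(map) || !is.numeric(map)) stop("`map` must be a numeric matrix")
  U <- as.integer(target[1]); V <- as.integer(target[2])
  if (is.na(U) || is.na(V) || U < 1L || V < 1L) {
    stop("target size must be at least 1 x 1")
  }
  interp_matrix(nrow(map), U) %*% map %*% t(interp_matrix(ncol(map), V))
}

# (U x P) sparse-pattern interpolation weights, corner-aligned.
interp_matrix <- function(P, U) {
  M <- matrix(0, U, P)
  if (P == 1L) {
    M[, 1L] <- 1
    return(M)
  }
  src <- if (U == 1L) 0 else (seq_len(U) - 1) * (P - 1) / (U - 1)
  lo <- pmin(floor(src), P - 2)
  w <- src - lo
  for (i in seq_len(U)) {
    M[i, lo[i] + 1L] <- 1 - w[i]
    M[i, lo[i] + 2L] <- w[i]
  }
  M
}
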