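# Grad-CAM explanations: feature maps of the last convolutional stage are
# weighted by the spatial average of the class-score gradient, summed,
# rectified, and upsampled to input resolution.

#' Grad-CAM channel weights
#'
#' For class `c`, the weight of feature-map channel `k` is the global average
#' of the gradient of the pre-softmax class score over the spatial positions
#' of the last convolutional stage:
#' `w_k = (1 / (P * Q)) * sum_ij d y_c / d A_k[i, j]`.
#' Gradients are taken on the pre-softmax score, not the probability.
#'
#' @param model a `"leafnet"`.
#' @param x a single image `(U, V, B)`.
#' @param class_index class to explain, `1..n_classes`.
#' @return numeric vector of length `K` (channels of the CAM layer).
#' @export
gradcam_weights <- function(model, x, class_index) {
  gc <- .gradcam_core(model, .as_batch(x), as.integer(class_index))
  gc$weights[, 1L]
}

#' Grad-CAM explanation heatmap
#'
#' `G(M, X, c) = Trans(ReLU(sum_k w_k A_k))`: the weighted feature-map sum is
#' rectified (only channels with positive influence on the class score
#' contribute) and bilinearly upsampled to the input size.  Heatmaps are
#' returned unnormalized; assessment metrics normalize by the maximum.
#'
#' @inheritParams gradcam_weights
#' @return an object of class `"gradcam"`: list with `heatmap` (nonnegative
#'   `U x V` matrix), `class_index`, `weights`, and the raw feature-map-sized
#'   `cam`.
#' @export
gradcam_explain <- function(model, x, class_index) {
  class_index <- as.integer(class_index)
  gc <- .gradcam_core(model, .as_batch(x), class_index)
  structure(list(heatmap = gc$heatmaps[, , 1L],
                 cam = gc$cams[, , 1L],
                 weights = gc$weights[, 1L],
                 class_index = class_index,
                 variant = model$spec$variant),
            class = "gradcam")
}

.as_batch <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

# Batched Grad-CAM; classes may differ per sample.  Backpropagates the
# one-hot pre-softmax seed only down to the CAM layer.
.gradcam_core <- function(model, x, classes) {
  n <- model$spec$n_classes
  N <- dim(x)[4]
  classes <- rep_len(as.integer(classes), N)
  if (any(classes < 1L | classes > n)) {
    stop("class_index out of range 1..", n)
  }
  fw <- net_forward(model, x)
  seed <- matrix(0, n, N)
  seed[cbind(classes, seq_len(N))] <- 1
  gA <- net_backward(model, fw, seed, to_layer = model$cam_layer,
                     param_grads = FALSE)$g          # (P, Q, K, N)
  A <- fw$acts[[model$cam_layer + 1L]]
  d <- dim(A)
  P <- d[1]; Q <- d[2]; K <- d[3]
  w <- apply(gA, c(3L, 4L), mean)                    # (K, N) spatial GAP
  dim(w) <- c(K, N)
  Af <- A; dim(Af) <- c(P * Q, K, N)
  U <- model$spec$input_size[1]; V <- model$spec$input_size[2]
  cams <- array(0, c(P, Q, N))
  heat <- array(0, c(U, V, N))
  for (i in seq_len(N)) {
    cam <- matrix(matrix(Af[, , i], P * Q, K) %*% w[, i, drop = FALSE], P, Q)
    cam[cam < 0] <- 0
    cams[, , i] <- cam
    heat[, , i] <- upsample(cam, c(U, V))
  }
  heat[heat < 0] <- 0   # clamp interpolation round-off
  list(heatmaps = heat, cams = cams, weights = w)
}

#' @export
print.gradcam <- function(x, ...) {
  cat(sprintf("<gradcam> class %d, heatmap %dx%d, max %.4g\n",
              x$class_index, nrow(x$heatmap), ncol(x$heatmap),
              max(x$heatmap)))
  invisible(x)
}

#' @export
plot.gradcam <- function(x, ...) {
  hm <- x$heatmap
  # image() draws column-major from bottom-left; flip rows for raster order
  graphics::image(t(hm[nrow(hm):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Inferno"), axes = FALSE,
                  asp = nrow(hm) / ncol(hm), ...)
  invisible(x)
}

#' Persist an explanation as a portable raster with a JSON sidecar
#'
#' Writes the heatmap as a single-channel 16-bit PNG (values scaled by the
#' recorded maximum) plus a `.json` sidecar holding the class index, scale
#' and provenance, and optionally a colour-mapped preview PNG.
#'
#' @param x a `"gradcam"`.
#' @param path output path (`.png`).
#' @param preview also write `<path>_preview.png` colour-mapped for viewing.
#' @return `path`, invisibly.
#' @export
write_gradcam <- function(x, path, preview = FALSE) {
  stopifnot(inherits(x, "gradcam"))
  mx <- max(x$heatmap)
  scaled <- if (mx > 0) x$heatmap / mx else x$heatmap
  png::writePNG(scaled, path, dpi = NULL)
  jsonlite::write_json(
    list(class_index = x$class_index, max_value = mx, variant = x$variant),
    paste0(sub("\\.png$", "", path), ".json"), auto_unbox = TRUE, digits = NA)
  if (preview) {
    cols <- grDevices::hcl.colors(256, "Inferno")
    idx <- pmin(255L, pmax(0L, round(scaled * 255))) + 1L
    rgb <- grDevices::col2rgb(cols[idx]) / 255
    arr <- array(0, c(nrow(scaled), ncol(scaled), 3L))
    for (b in 1:3) arr[, , b] <- matrix(rgb[b, ], nrow(scaled))
    png::writePNG(arr, paste0(sub("\\.png$", "", path), "_preview.png"))
  }
  invisible(path)
}
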