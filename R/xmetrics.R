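# Explanation assessment against reference masks: absolute difference
# (RMSE), relative difference (cosine similarity), and overlap of the
# top-ranked pixels with the useful region (PIP).

#' Normalize an explanation heatmap to the unit interval
#'
#' Divides by the maximum value when it is positive; all-zero heatmaps pass
#' through unchanged.  Normalization is monotone, so pixel rankings (and
#' hence PIP) are unaffected.
#'
#' @param e a `"gradcam"` object or a nonnegative numeric matrix/vector.
#' @return numeric vector in `[0, 1]`, flattened column-major.
#' @export
normalize_explanation <- function(e) {
  v <- if (inherits(e, "gradcam")) e$heatmap else e
  v <- as.vector(v)
  if (any(!is.finite(v))) stop("explanation contains non-finite values")
  if (any(v < 0)) stop("explanation must be nonnegative")
  mx <- max(v)
  if (mx > 0) v / mx else v
}

.chk_pair <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  if (length(a) != length(b)) {
    stop("explanation and mask lengths differ (", length(a), " vs ",
         length(b), ")")
  }
  list(a = a, b = b)
}

#' Root-mean-square error between an explanation and a reference mask
#'
#' `sqrt(sum((a_i - b_i)^2) / N)`.  With `a` in `[0, 1]` and a binary mask
#' the value lies in `[0, 1]`; 0 iff the explanation equals the mask.
#'
#' @param a normalized explanation (vector or matrix).
#' @param b binary reference mask of the same length (1 = useful pixel).
#' @return nonnegative scalar.
#' @export
rmse <- function(a, b) {
  p <- .chk_pair(a, b)
  sqrt(mean((p$a - p$b)^2))
}

#' Cosine similarity between an explanation and a reference mask
#'
#' `sum(a_i b_i) / (||a|| ||b||)`.  Undefined when either vector has zero
#' norm; callers aggregating over samples should exclude (and count) such
#' cases rather than impute them.
#'
#' @inheritParams rmse
#' @return scalar in `[0, 1]` for nonnegative inputs, or `NA` with a warning
#'   when a norm is zero.
#' @export
cosine_similarity <- function(a, b) {
  p <- .chk_pair(a, b)
  na <- sqrt(sum(p$a^2)); nb <- sqrt(sum(p$b^2))
  if (na == 0 || nb == 0) {
    warning("zero-norm input: cosine similarity undefined")
    return(NA_real_)
  }
  sum(p$a * p$b) / (na * nb)
}

#' Proportion of important pixels inside the reference mask
#'
#' The important-pixel set IP holds the `ceiling(N * percent / 100)` pixels
#' with the highest explanation values, ties broken by lowest flat
#' (column-major) index.  Returns `Num(IP intersect RM) / Num(IP)` where RM
#' is the set of mask-1 pixels.
#'
#' @inheritParams rmse
#' @param percent top percentage of pixels to keep, in `(0, 100]`; a warning
#'   is issued when `percent/100 >= Num(RM)/N` (the proportion can then no
#'   longer reach 1).
#' @return fraction in `[0, 1]`.
#' @export
pip <- function(a, b, percent) {
  p <- .chk_pair(a, b)
  if (!is.numeric(percent) || length(percent) != 1L || percent <= 0 ||
      percent > 100) {
    stop("percent must be a single value in (0, 100]")
  }
  N <- length(p$a)
  nmask <- sum(p$b == 1)
  if (percent / 100 >= nmask / N) {
    warning("percent/100 >= Num(RM)/N: the important-pixel set cannot fit ",
            "inside the reference mask")
  }
  k <- ceiling(N * percent / 100)
  ip <- order(-p$a, seq_len(N))[seq_len(k)]
  sum(p$b[ip] == 1) / k
}

#' Assess a model's explanations over a dataset split
#'
#' For every sample of the split, computes the Grad-CAM explanation for the
#' chosen class, max-normalizes it, and evaluates RMSE, cosine similarity and
#' PIP at each requested percentage against the sample's assessment mask
#' (1 = useful-region pixel).  Samples whose assessment mask is empty are
#' excluded from the cosine and PIP means (they are undefined there) and
#' counted; RMSE is always defined and averaged over all samples.
#'
#' @param model a trained `"leafnet"`.
#' @param data a `"leaf_dataset"` with assessment masks.
#' @param split `"train"`, `"validation"` or `"test"`.
#' @param percents PIP percentages; default `c(1, 5, 10)`.
#' @param class_choice explain the sample's `"true"` class (default) or the
#'   model's `"predicted"` class.
#' @param chunk samples per forward/backward batch.
#' @return an object of class `"assessment_report"`: a one-row data frame
#'   with `accuracy_pct`, `rmse`, `cosines`, one `pip_<p>` column per
#'   percentage (PIP reported in percent), `n_samples` and
#'   `n_cosine_excluded`, plus attribute `"per_sample"` with the raw values.
#' @export
assess_model <- function(model, data, split = "test", percents = c(1, 5, 10),
                         class_choice = c("true", "predicted"), chunk = 64L) {
  stopifnot(inherits(model, "leafnet"), inherits(data, "leaf_dataset"))
  class_choice <- match.arg(class_choice)
  idx <- data$splits[[split]]
  if (is.null(idx) || !length(idx)) stop("split '", split, "' is empty")
  if (is.null(data$assessments)) stop("dataset has no assessment masks")
  n <- length(idx)
  per <- data.frame(sample = idx, rmse = NA_real_, cosines = NA_real_)
  for (p in percents) per[[sprintf("pip_%g", p)]] <- NA_real_
  correct <- logical(n)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    sub <- idx[rows]
    x <- data$images[, , , sub, drop = FALSE]
    cls <- if (class_choice == "true") {
      data$labels[sub]
    } else {
      predict(model, x, type = "class")
    }
    correct[rows] <- predict(model, x, type = "class") == data$labels[sub]
    gc <- .gradcam_core(model, x, cls)
    for (j in seq_along(rows)) {
      a <- normalize_explanation(gc$heatmaps[, , j])
      b <- as.vector(data$assessments[, , sub[j]])
      per$rmse[rows[j]] <- rmse(a, b)
      if (sum(b) > 0) {
        if (sum(a^2) > 0) {
          per$cosines[rows[j]] <- cosine_similarity(a, b)
        }
        for (p in percents) {
          per[[sprintf("pip_%g", p)]][rows[j]] <-
            suppressWarnings(pip(a, b, p))
        }
      }
    }
  }
  rep <- data.frame(accuracy_pct = 100 * mean(correct),
                    rmse = mean(per$rmse),
                    cosines = mean(per$cosines, na.rm = TRUE))
  for (p in percents) {
    rep[[sprintf("pip_%g", p)]] <-
      100 * mean(per[[sprintf("pip_%g", p)]], na.rm = TRUE)
  }
  rep$n_samples <- n
  rep$n_cosine_excluded <- sum(is.na(per$cosines))
  attr(rep, "per_sample") <- per
  attr(rep, "percents") <- percents
  class(rep) <- c("assessment_report", "data.frame")
  rep
}

#' Write an assessment or comparison report as CSV
#'
#' @param report an `"assessment_report"` or comparison data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
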