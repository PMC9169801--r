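# Synthetic leaf scenes with exact ground-truth masks.  Scenes are procedural
# stand-ins for leaf photographs: an ellipse-union leaf with low-amplitude
# colour texture on a contrasting background.  Lesions are transparent
# circles that alpha-blend the image toward the background colour, emulating
# the thinning of diseased tissue; their union is known pixel-exactly, so the
# annotation matrices used for right-reason training and the reference masks
# used for explanation assessment carry no labelling error.

#' Scene generator configuration
#'
#' @param image_size integer `c(U, V)`, both `>= 32`.
#' @param n_circles_range integer interval, number of transparent circles.
#' @param radius_range circle radius as a fraction of `min(U, V)`.
#' @param alpha_range circle opacity interval, within `(0, 1]`; at opacity 1
#'   the circle equals the background colour.
#' @param allow_background_circles may circles fall outside the leaf?
#' @param background_style `"textured"` (low-amplitude smooth noise) or
#'   `"flat"`.
#' @return an object of class `"scene_config"`.
#' @export
scene_config <- function(image_size = c(64L, 64L),
                         n_circles_range = c(1L, 5L),
                         radius_range = c(0.05, 0.15),
                         alpha_range = c(0.3, 0.7),
                         allow_background_circles = TRUE,
                         background_style = c("textured", "flat")) {
  background_style <- match.arg(background_style)
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(is.na(image_size)) ||
      any(image_size < 32L)) {
    stop("image_size must be two integers, each >= 32")
  }
  n_circles_range <- as.integer(n_circles_range)
  if (length(n_circles_range) != 2L || n_circles_range[1] > n_circles_range[2] ||
      n_circles_range[1] < 0L) {
    stop("n_circles_range must be a nonnegative, non-empty integer interval")
  }
  .chk_interval <- function(x, name, lo, hi) {
    if (length(x) != 2L || !is.numeric(x) || x[1] > x[2] ||
        x[1] < lo || x[2] > hi) {
      stop(name, " must be a non-empty interval within [", lo, ", ", hi, "]")
    }
  }
  .chk_interval(radius_range, "radius_range", 0, 0.5)
  .chk_interval(alpha_range, "alpha_range", 0, 1)
  if (alpha_range[1] <= 0) stop("alpha_range must be within (0, 1]")
  structure(list(image_size = image_size,
                 n_circles_range = n_circles_range,
                 radius_range = radius_range,
                 alpha_range = alpha_range,
                 allow_background_circles = isTRUE(allow_background_circles),
                 background_style = background_style),
            class = "scene_config")
}

#' Serialize / restore a scene configuration as JSON
#'
#' @param cfg a [scene_config()].
#' @param json a JSON string or file path produced by `scene_config_to_json`.
#' @return `scene_config_to_json` returns a JSON string;
#'   `scene_config_from_json` a `"scene_config"`.
#' @export
scene_config_to_json <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  jsonlite::toJSON(unclass(cfg), auto_unbox = FALSE, digits = NA)
}

#' @rdname scene_config_to_json
#' @export
scene_config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  scene_config(image_size = x$image_size,
               n_circles_range = x$n_circles_range,
               radius_range = x$radius_range,
               alpha_range = x$alpha_range,
               allow_background_circles = x$allow_background_circles,
               background_style = x$background_style)
}

# Smooth low-amplitude noise field via bilinear upsampling of a coarse grid.
.smooth_noise <- function(U, V, amplitude, grid = 8L) {
  coarse <- matrix(stats::runif(grid * grid, -1, 1), grid, grid)
  amplitude * upsample(coarse, c(U, V))
}

# Pixel-centre coordinate grids (1-based row/col indices).
.coord_grid <- function(U, V) {
  list(r = matrix(seq_len(U), U, V), c = matrix(seq_len(V), U, V, byrow = TRUE))
}

# Rasterize a rotated ellipse: centre (cr, cc), semi-axes (a, b), angle th.
.ellipse_mask <- function(U, V, cr, cc, a, b, th) {
  g <- .coord_grid(U, V)
  dr <- g$r - cr; dc <- g$c - cc
  x <- cos(th) * dc + sin(th) * dr
  y <- -sin(th) * dc + cos(th) * dr
  (x / a)^2 + (y / b)^2 <= 1
}

#' Generate a synthetic leaf scene
#'
#' Draws a leaf-like foreground (union of rotated ellipses, green-dominant
#' with low-amplitude texture) on a contrasting brownish background and
#' returns the exact foreground mask.  Deterministic given `(cfg, seed)`.
#'
#' @param cfg a [scene_config()].
#' @param seed integer seed.
#' @param shape leaf silhouette: `"broad"`, `"narrow"`, `"lobed"` or
#'   `"round"`; the shapes are procedurally distinct (used as species in
#'   [build_dataset()]).
#' @param lesions add brown blotches inside the leaf (diseased tissue).
#' @param leaf_scale multiplier on the leaf size; the scene is rejected if
#'   the resulting foreground covers no pixel.
#' @return list with `image` (`U x V x 3` array in `[0, 1]`, carrying the
#'   scene background colour and foreground as attributes) and `foreground`
#'   (binary `U x V` matrix, 1 = leaf).
#' @export
generate_leaf_scene <- function(cfg, seed = 1L,
                                shape = c("broad", "narrow", "lobed", "round"),
                                lesions = FALSE, leaf_scale = 1) {
  stopifnot(inherits(cfg, "scene_config"))
  shape <- match.arg(shape)
  U <- cfg$image_size[1]; V <- cfg$image_size[2]
  m <- min(U, V)
  set.seed(as.integer(seed))

  bg_color <- c(0.45, 0.36, 0.26) + stats::runif(3, -0.04, 0.04)
  img <- array(rep(bg_color, each = U * V), c(U, V, 3))
  if (cfg$background_style == "textured") {
    for (b in 1:3) img[, , b] <- img[, , b] + .smooth_noise(U, V, 0.06)
  }

  cr <- U / 2 + stats::runif(1, -0.05, 0.05) * U
  cc <- V / 2 + stats::runif(1, -0.05, 0.05) * V
  th <- stats::runif(1, 0, pi)
  axes <- switch(shape,
    broad  = c(stats::runif(1, 0.30, 0.40), stats::runif(1, 0.24, 0.34)),
    narrow = c(stats::runif(1, 0.34, 0.44), stats::runif(1, 0.10, 0.16)),
    lobed  = c(stats::runif(1, 0.22, 0.28), stats::runif(1, 0.16, 0.22)),
    round  = rep(stats::runif(1, 0.26, 0.33), 2L))
  axes <- axes * m * leaf_scale
  fg <- .ellipse_mask(U, V, cr, cc, axes[1], axes[2], th)
  if (shape == "lobed") {
    # two side lobes along the main axis
    for (s in c(-1, 1)) {
      lr <- cr + s * sin(th) * axes[1] * 0.9
      lc <- cc + s * cos(th) * axes[1] * 0.9
      fg <- fg | .ellipse_mask(U, V, lr, lc, axes[1] * 0.7, axes[2] * 0.8,
                               th + s * 0.5)
    }
  }
  if (!any(fg)) stop("configuration yields an empty leaf foreground")

  leaf_color <- c(0.20, 0.52, 0.20) + stats::runif(3, -0.05, 0.05)
  tex <- .smooth_noise(U, V, 0.05)
  for (b in 1:3) {
    plane <- img[, , b]
    plane[fg] <- leaf_color[b] + tex[fg]
    img[, , b] <- plane
  }

  if (lesions) {
    lesion_color <- c(0.48, 0.30, 0.10)
    n_les <- 2L + sample.int(4L, 1L)
    for (i in seq_len(n_les)) {
      inside <- which(fg)
      pick <- inside[sample.int(length(inside), 1L)]
      pr <- (pick - 1L) %% U + 1L
      pc <- (pick - 1L) %/% U + 1L
      la <- stats::runif(1, 0.03, 0.08) * m
      lm <- .ellipse_mask(U, V, pr, pc, la, la * stats::runif(1, 0.6, 1),
                          stats::runif(1, 0, pi)) & fg
      alpha <- stats::runif(1, 0.5, 0.8)
      for (b in 1:3) {
        plane <- img[, , b]
        plane[lm] <- (1 - alpha) * plane[lm] + alpha * lesion_color[b]
        img[, , b] <- plane
      }
    }
  }

  img[img < 0] <- 0
  img[img > 1] <- 1
  fg <- matrix(as.integer(fg), U, V)
  attr(img, "background_color") <- bg_color
  attr(img, "foreground") <- fg
  list(image = img, foreground = fg)
}

#' Inject transparent circles into a scene
#'
#' Each circle alpha-blends the image toward the scene background colour with
#' opacity drawn from `cfg$alpha_range`, emulating the thinning of diseased
#' leaf tissue.  A pixel at integer centre `(r, c)` belongs to a circle with
#' centre `(cr, cc)` and radius `rad` iff `(r-cr)^2 + (c-cc)^2 <= rad^2`.
#' Deterministic given `(img, cfg, seed)`.
#'
#' @param img a leaf image from [generate_leaf_scene()] (or any `U x V x 3`
#'   array in `[0, 1]`).
#' @param cfg a [scene_config()]; circle count, radius fraction and opacity
#'   are drawn from its ranges.  When `allow_background_circles` is `FALSE`
#'   circle centres are drawn from the foreground mask.
#' @param seed integer seed.
#' @param background_color length-3 colour the circles blend toward; defaults
#'   to the colour recorded by the scene generator, else mid-grey.
#' @param foreground optional binary mask used to place circles when
#'   background circles are disallowed; defaults to the mask recorded by the
#'   scene generator.
#' @return list with `image` (modified copy), `circle_region` (binary
#'   `U x V` matrix marking exactly the union of circle disks) and `circles`
#'   (data frame of sampled centre row/col, radius and opacity).
#' @export
add_transparent_circles <- function(img, cfg, seed = 1L,
                                    background_color = NULL,
                                    foreground = NULL) {
  stopifnot(inherits(cfg, "scene_config"))
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) stop("img must be a U x V x 3 array")
  U <- d[1]; V <- d[2]
  background_color <- background_color %||%
    attr(img, "background_color") %||% rep(0.5, 3)
  foreground <- foreground %||% attr(img, "foreground")
  set.seed(as.integer(seed))
  lo <- cfg$n_circles_range[1]; hi <- cfg$n_circles_range[2]
  n <- lo + if (hi > lo) sample.int(hi - lo + 1L, 1L) - 1L else 0L
  region <- matrix(0L, U, V)
  circles <- data.frame(row = numeric(n), col = numeric(n),
                        radius = numeric(n), alpha = numeric(n))
  out <- img
  g <- .coord_grid(U, V)
  for (i in seq_len(n)) {
    rad <- stats::runif(1, cfg$radius_range[1], cfg$radius_range[2]) * min(U, V)
    if (cfg$allow_background_circles || is.null(foreground)) {
      ctr <- c(stats::runif(1, 1, U), stats::runif(1, 1, V))
    } else {
      inside <- which(foreground == 1L)
      if (!length(inside)) stop("no foreground pixels to place circles on")
      pick <- inside[sample.int(length(inside), 1L)]
      ctr <- c((pick - 1L) %% U + 1L, (pick - 1L) %/% U + 1L)
    }
    alpha <- stats::runif(1, cfg$alpha_range[1], cfg$alpha_range[2])
    circles[i, ] <- c(ctr[1], ctr[2], rad, alpha)
    disk <- (g$r - ctr[1])^2 + (g$c - ctr[2])^2 <= rad^2
    region[disk] <- 1L
    for (b in 1:3) {
      plane <- out[, , b]
      plane[disk] <- (1 - alpha) * plane[disk] + alpha * background_color[b]
      out[, , b] <- plane
    }
  }
  attr(out, "background_color") <- background_color
  attr(out, "foreground") <- foreground
  list(image = out, circle_region = region, circles = circles)
}

#' Annotation matrices from ground-truth masks
#'
#' Annotation matrices are binary `U x V` masks in which 1 marks pixels that
#' are *useless* for the task at hand (the convention of the right-reason
#' penalty).  Three automatic constructions are provided:
#' `annotation_from_circles` marks everything outside the lesion circles
#' (fake-vs-real task); `annotation_from_background` marks the scene
#' background (diseased-vs-healthy task; exact for synthetic scenes, an
#' external segmenter can supply `foreground` for photographs);
#' `annotation_from_bounding_rect` marks everything strictly outside the
#' minimum axis-aligned bounding rectangle of the leaf (species task, which
#' keeps leaf-shape information usable).
#'
#' @param circle_region,foreground binary `U x V` matrices.
#' @return a binary `U x V` annotation matrix.
#' @export
annotation_from_circles <- function(circle_region) {
  .chk_binary(circle_region, "circle_region")
  1L - circle_region
}

#' @rdname annotation_from_circles
#' @export
annotation_from_background <- function(foreground) {
  .chk_binary(foreground, "foreground")
  1L - foreground
}

#' @rdname annotation_from_circles
#' @export
annotation_from_bounding_rect <- function(foreground) {
  .chk_binary(foreground, "foreground")
  ones <- which(foreground == 1L, arr.ind = TRUE)
  if (!nrow(ones)) stop("foreground is empty: no bounding rectangle defined")
  rr <- range(ones[, 1]); cc <- range(ones[, 2])
  ann <- matrix(1L, nrow(foreground), ncol(foreground))
  ann[rr[1]:rr[2], cc[1]:cc[2]] <- 0L
  ann
}

# Small per-sample photometric variation (global brightness shift plus iid
# pixel noise), standing in for shot-to-shot variation between photographs
# of the same leaf.
.photometric_jitter <- function(img, seed, brightness_sd = 0.02,
                                noise_sd = 0.01) {
  at <- attributes(img)
  set.seed(as.integer(seed))
  out <- img + stats::rnorm(1, 0, brightness_sd) +
    array(stats::rnorm(length(img), 0, noise_sd), dim(img))
  out[out < 0] <- 0
  out[out > 1] <- 1
  attributes(out) <- at
  out
}

.chk_binary <- function(m, name) {
  if (!is.matrix(m) || !all(m %in% c(0L, 1L))) {
    stop(name, " must be a binary (0/1) matrix")
  }
}

# Largest-remainder allocation of n items to fractions f (sums to n exactly).
.allocate <- function(n, f) {
  raw <- n * f
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Build a complete labelled synthetic dataset
#'
#' Generates `n_samples` scenes for one of three tasks and packages images,
#' integer labels, per-sample annotation matrices, assessment masks
#' (elementwise complement of the annotation: 1 = useful-region pixel) and
#' seed-deterministic stratified splits.
#'
#' * `"fake_vs_real"`: a pool of `n_base` base scenes is reused across
#'   samples (emulating a study design where a few leaf photographs are
#'   augmented many times) with small per-sample photometric jitter; half
#'   the samples stay unmodified (class `real`), half have transparent
#'   circles injected (class `fake`).  Fake samples get their annotation via
#'   [annotation_from_circles()]; real samples carry the zero annotation
#'   matrix (the opt-out that leaves them unguided during right-reason
#'   training).
#' * `"diseased_vs_healthy"`: clean versus lesion-textured leaves;
#'   annotations via [annotation_from_background()].
#' * `"species"`: `n_species` procedurally distinct leaf shapes with equal
#'   per-class counts (`n_samples` must be divisible by `n_species`);
#'   annotations via [annotation_from_bounding_rect()].
#'
#' @param task one of `"fake_vs_real"`, `"diseased_vs_healthy"`, `"species"`.
#' @param cfg a [scene_config()].
#' @param n_samples total number of samples, `>= 10`.
#' @param split_fracs fractions `c(train, validation, test)` summing to 1.
#' @param seed integer master seed; all per-sample and split randomness is
#'   derived from it.
#' @param n_species number of classes for the `"species"` task (2 to 4).
#' @param n_base size of the reused base-scene pool for `"fake_vs_real"`.
#' @return an object of class `"leaf_dataset"`: list with `images`
#'   (`U x V x 3 x N`), `labels` (integers `1..n_classes`), `annotations` and
#'   `assessments` (`U x V x N`), `splits` (disjoint index sets), and
#'   `class_names`.
#' @export
build_dataset <- function(task = c("fake_vs_real", "diseased_vs_healthy",
                                   "species"),
                          cfg = scene_config(), n_samples = 100L,
                          split_fracs = c(0.6, 0.2, 0.2), seed = 1L,
                          n_species = 3L, n_base = 8L) {
  task <- match.arg(task)
  stopifnot(inherits(cfg, "scene_config"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 10L) stop("n_samples must be >= 10")
  if (length(split_fracs) != 3L || abs(sum(split_fracs) - 1) > 1e-8) {
    stop("split_fracs must be three fractions summing to 1")
  }
  U <- cfg$image_size[1]; V <- cfg$image_size[2]
  set.seed(as.integer(seed))
  scene_seeds <- sample.int(2147483646L, n_samples)
  circle_seeds <- sample.int(2147483646L, n_samples)
  split_seed <- sample.int(2147483646L, 1L)

  if (task == "species") {
    n_species <- as.integer(n_species)
    if (n_species < 2L || n_species > 4L) {
      stop("n_species must be between 2 and 4 (distinct procedural shapes)")
    }
    if (n_samples %% n_species != 0L) {
      stop("n_samples must be divisible by n_species for equal class counts")
    }
    class_names <- c("broad", "narrow", "lobed", "round")[seq_len(n_species)]
    labels <- rep(seq_len(n_species), each = n_samples %/% n_species)
  } else if (task == "fake_vs_real") {
    class_names <- c("real", "fake")
    n_fake <- n_samples %/% 2L
    labels <- c(rep(1L, n_samples - n_fake), rep(2L, n_fake))
  } else {
    class_names <- c("healthy", "diseased")
    n_dis <- n_samples %/% 2L
    labels <- c(rep(1L, n_samples - n_dis), rep(2L, n_dis))
  }

  base_pool <- NULL
  if (task == "fake_vs_real") {
    n_base <- as.integer(n_base)
    if (n_base < 1L) stop("n_base must be >= 1")
    base_pool <- lapply(seq_len(n_base),
                        function(b) generate_leaf_scene(cfg, scene_seeds[b]))
  }

  images <- array(0, c(U, V, 3L, n_samples))
  annotations <- array(0L, c(U, V, n_samples))
  for (i in seq_len(n_samples)) {
    if (task == "species") {
      sc <- generate_leaf_scene(cfg, scene_seeds[i],
                                shape = class_names[labels[i]])
      img <- sc$image
      ann <- annotation_from_bounding_rect(sc$foreground)
    } else if (task == "diseased_vs_healthy") {
      sc <- generate_leaf_scene(cfg, scene_seeds[i],
                                lesions = labels[i] == 2L)
      img <- sc$image
      ann <- annotation_from_background(sc$foreground)
    } else {
      sc <- base_pool[[(i - 1L) %% length(base_pool) + 1L]]
      img <- .photometric_jitter(sc$image, scene_seeds[i])
      if (labels[i] == 2L) {
        aug <- add_transparent_circles(img, cfg, circle_seeds[i])
        img <- aug$image
        ann <- annotation_from_circles(aug$circle_region)
      } else {
        ann <- matrix(0L, U, V)   # unmodified sample: no guidance (opt-out)
      }
    }
    images[, , , i] <- img
    annotations[, , i] <- ann
  }
  assessments <- 1L - annotations

  set.seed(split_seed)
  splits <- list(train = integer(0), validation = integer(0),
                 test = integer(0))
  for (k in seq_along(class_names)) {
    idx <- sample(which(labels == k))
    sizes <- .allocate(length(idx), split_fracs)
    splits$train <- c(splits$train, idx[seq_len(sizes[1])])
    splits$validation <- c(splits$validation,
                           idx[sizes[1] + seq_len(sizes[2])])
    splits$test <- c(splits$test, idx[sizes[1] + sizes[2] + seq_len(sizes[3])])
  }
  splits <- lapply(splits, sort)

  structure(list(images = images, labels = labels,
                 annotations = annotations, assessments = assessments,
                 splits = splits, class_names = class_names,
                 task = task, cfg = cfg, seed = as.integer(seed)),
            class = "leaf_dataset")
}

#' @export
print.leaf_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<leaf_dataset> task '%s': %d samples of %dx%dx%d\n",
              x$task, d[4], d[1], d[2], d[3]))
  cat(sprintf("  classes: %s\n", paste(x$class_names, collapse = ", ")))
  cat(sprintf("  splits: train %d / validation %d / test %d\n",
              length(x$splits$train), length(x$splits$validation),
              length(x$splits$test)))
  invisible(x)
}

#' Plant a label-correlated corner watermark (Clever Hans benchmark)
#'
#' Stamps a bright square into one corner of every train- and
#' validation-split image of the given class, leaving the test split clean:
#' the watermark is perfectly predictive during training but absent at test
#' time, the classic spurious-correlation setup.  All annotation matrices are
#' replaced by the watermark region (1 = useless there), so right-reason
#' training is told to ignore exactly the spurious cue; assessment masks are
#' set to the complement.
#'
#' @param data a `"leaf_dataset"`.
#' @param class_index class whose train/validation images receive the stamp.
#' @param size_frac side of the square as a fraction of `min(U, V)`.
#' @param corner one of `"tl"`, `"tr"`, `"bl"`, `"br"`.
#' @param color length-3 stamp colour.
#' @return the modified `"leaf_dataset"`, with the watermark region attached
#'   as attribute `"watermark_region"`.
#' @export
watermark_bias_dataset <- function(data, class_index = 2L, size_frac = 0.15,
                                   corner = c("tl", "tr", "bl", "br"),
                                   color = c(1, 1, 0.2)) {
  stopifnot(inherits(data, "leaf_dataset"))
  corner <- match.arg(corner)
  d <- dim(data$images)
  U <- d[1]; V <- d[2]
  s <- max(2L, round(size_frac * min(U, V)))
  rows <- if (corner %in% c("tl", "tr")) 1:s else (U - s + 1L):U
  cols <- if (corner %in% c("tl", "bl")) 1:s else (V - s + 1L):V
  region <- matrix(0L, U, V)
  region[rows, cols] <- 1L
  biased <- c(data$splits$train, data$splits$validation)
  biased <- biased[data$labels[biased] == class_index]
  for (i in biased) {
    for (b in 1:3) data$images[rows, cols, b, i] <- color[b]
  }
  for (i in seq_len(d[4])) data$annotations[, , i] <- region
  data$assessments <- 1L - data$annotations
  attr(data, "watermark_region") <- region
  data
}
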