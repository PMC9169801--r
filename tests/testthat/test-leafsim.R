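# Synthetic scene generator: determinism, mask exactness, annotation
# constructions, dataset assembly.

cfg32 <- scene_config(image_size = c(32, 32))

test_that("scene generation is bit-identical for identical (cfg, seed)", {
  a <- generate_leaf_scene(cfg32, seed = 11)
  b <- generate_leaf_scene(cfg32, seed = 11)
  expect_identical(a$image, b$image)
  expect_identical(a$foreground, b$foreground)
  c2 <- generate_leaf_scene(cfg32, seed = 12)
  expect_false(identical(a$image, c2$image))
})

test_that("scenes satisfy the image invariants", {
  sc <- generate_leaf_scene(scene_config(), seed = 3)
  expect_true(all(sc$image >= 0 & sc$image <= 1))
  expect_true(all(is.finite(sc$image)))
  expect_true(all(sc$foreground %in% c(0L, 1L)))
  expect_identical(dim(sc$foreground), dim(sc$image)[1:2])
})

test_that("degenerate configurations are rejected", {
  expect_error(scene_config(image_size = c(16, 64)), ">= 32")
  expect_error(generate_leaf_scene(cfg32, seed = 1, leaf_scale = 0),
               "empty leaf foreground")
})

test_that("foreground coverage at defaults stays in a plausible band", {
  cov <- vapply(1:200, function(s) {
    mean(generate_leaf_scene(cfg32, seed = s)$foreground)
  }, numeric(1))
  expect_gt(min(cov), 0.2)
  expect_lt(max(cov), 0.8)
})

test_that("zero circles leave the image untouched", {
  sc <- generate_leaf_scene(cfg32, seed = 5)
  cfg0 <- scene_config(image_size = c(32, 32), n_circles_range = c(0, 0))
  aug <- add_transparent_circles(sc$image, cfg0, seed = 6)
  expect_identical(aug$image, sc$image)
  expect_identical(aug$circle_region, matrix(0L, 32, 32))
})

test_that("circle region equals the brute-force pixel-distance disk", {
  sc <- generate_leaf_scene(cfg32, seed = 5)
  cfg1 <- scene_config(image_size = c(32, 32), n_circles_range = c(1, 1),
                       radius_range = c(0.2, 0.2))
  aug <- add_transparent_circles(sc$image, cfg1, seed = 8)
  ci <- aug$circles
  expected <- matrix(0L, 32, 32)
  for (r in 1:32) for (cc in 1:32) {
    if ((r - ci$row)^2 + (cc - ci$col)^2 <= ci$radius^2) {
      expected[r, cc] <- 1L
    }
  }
  expect_identical(aug$circle_region, expected)
})

test_that("fully opaque circles equal the background colour exactly", {
  flat <- array(0.2, c(32, 32, 3))
  cfg1 <- scene_config(image_size = c(32, 32), n_circles_range = c(1, 1),
                       radius_range = c(0.15, 0.15), alpha_range = c(1, 1))
  bg <- c(0.7, 0.6, 0.5)
  aug <- add_transparent_circles(flat, cfg1, seed = 2, background_color = bg)
  inside <- aug$circle_region == 1L
  for (b in 1:3) {
    plane <- aug$image[, , b]
    expect_true(all(plane[inside] == bg[b]))
    expect_true(all(plane[!inside] == 0.2))
  }
})

test_that("pixels changed by augmentation lie inside the circle region", {
  sc <- generate_leaf_scene(scene_config(), seed = 21)
  aug <- add_transparent_circles(sc$image, scene_config(), seed = 22)
  changed <- apply(aug$image != sc$image, c(1, 2), any)
  expect_true(all(aug$circle_region[changed] == 1L))
})

test_that("annotation constructions are exact complements", {
  r <- matrix(0L, 5, 5)
  expect_identical(annotation_from_circles(r), matrix(1L, 5, 5))
  expect_identical(annotation_from_circles(matrix(1L, 5, 5)), matrix(0L, 5, 5))
  r[2, 3] <- 1L; r[4, 4] <- 1L
  ann <- annotation_from_circles(r)
  expect_equal(sum(ann) + sum(r), 25)

  checker <- matrix(as.integer((outer(1:6, 1:6, "+")) %% 2L), 6, 6)
  expect_identical(annotation_from_background(checker), 1L - checker)
  expect_identical(annotation_from_background(matrix(1L, 4, 4)),
                   matrix(0L, 4, 4))
})

test_that("bounding-rectangle annotation matches a brute-force scan", {
  fg <- matrix(0L, 6, 6)
  fg[2, 2] <- 1L; fg[4, 5] <- 1L   # rows 2..4, cols 2..5
  ann <- annotation_from_bounding_rect(fg)
  brute <- matrix(1L, 6, 6)
  for (r in 1:6) for (cc in 1:6) {
    if (r >= 2 && r <= 4 && cc >= 2 && cc <= 5) brute[r, cc] <- 0L
  }
  expect_identical(ann, brute)
  expect_equal(sum(ann), 36 - 12)

  single <- matrix(0L, 5, 5); single[3, 4] <- 1L
  ann1 <- annotation_from_bounding_rect(single)
  expect_equal(sum(ann1 == 0L), 1)
  expect_equal(ann1[3, 4], 0L)

  expect_identical(annotation_from_bounding_rect(matrix(1L, 4, 4)),
                   matrix(0L, 4, 4))
  expect_error(annotation_from_bounding_rect(matrix(0L, 4, 4)), "empty")
})

test_that("datasets are deterministic, balanced and correctly split", {
  d1 <- build_dataset("fake_vs_real", cfg32, n_samples = 24, seed = 7)
  d2 <- build_dataset("fake_vs_real", cfg32, n_samples = 24, seed = 7)
  expect_identical(d1$images, d2$images)
  expect_identical(d1$splits, d2$splits)

  d <- build_dataset("fake_vs_real", cfg32, n_samples = 100, seed = 1)
  expect_equal(lengths(d$splits[c("train", "validation", "test")]),
               c(train = 60L, validation = 20L, test = 20L))
  expect_equal(sum(d$labels == 1), 50)
  expect_equal(sum(d$labels == 2), 50)
  # class balance within every split
  for (s in names(d$splits)) {
    counts <- table(d$labels[d$splits[[s]]])
    expect_lte(max(counts) - min(counts), 1)
  }
  # splits partition the indices
  expect_identical(sort(unname(unlist(d$splits))), 1:100)
})

test_that("annotation and assessment masks partition every pixel", {
  for (task in c("fake_vs_real", "diseased_vs_healthy", "species")) {
    n <- if (task == "species") 12 else 10
    d <- build_dataset(task, cfg32, n_samples = n, seed = 3)
    expect_true(all(d$annotations + d$assessments == 1L))
  }
})

test_that("species datasets have equal per-class counts and shape-based masks", {
  d <- build_dataset("species", cfg32, n_samples = 12, seed = 2,
                     n_species = 3)
  expect_equal(as.vector(table(d$labels)), rep(4L, 3))
  expect_error(build_dataset("species", cfg32, n_samples = 10, seed = 2,
                             n_species = 3), "divisible")
})

test_that("invalid split fractions are rejected", {
  expect_error(build_dataset("fake_vs_real", cfg32, n_samples = 20,
                             split_fracs = c(0.5, 0.2, 0.2), seed = 1),
               "summing to 1")
})

test_that("scene configs survive a JSON round trip", {
  cfg <- scene_config(image_size = c(48, 40), n_circles_range = c(2, 3),
                      radius_range = c(0.1, 0.2), alpha_range = c(0.4, 0.6),
                      allow_background_circles = FALSE,
                      background_style = "flat")
  cfg2 <- scene_config_from_json(scene_config_to_json(cfg))
  expect_equal(cfg2, cfg)
})

test_that("the watermark biases train/validation but never test", {
  d <- build_dataset("fake_vs_real", cfg32, n_samples = 20, seed = 4)
  before <- d$images
  wb <- watermark_bias_dataset(d, class_index = 2, size_frac = 0.2)
  region <- attr(wb, "watermark_region")
  expect_equal(sum(region), round(0.2 * 32)^2)
  for (i in wb$splits$test) {
    expect_identical(wb$images[, , , i], before[, , , i])
  }
  stamped <- intersect(c(wb$splits$train, wb$splits$validation),
                       which(wb$labels == 2))
  for (i in stamped) {
    expect_false(identical(wb$images[, , , i], before[, , , i]))
  }
  expect_true(all(apply(wb$annotations, 3, identical, y = region)))
})
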