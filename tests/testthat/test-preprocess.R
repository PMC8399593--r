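test_that("green extraction selects exactly the second channel", {
  img <- array(0, c(4, 5, 3))
  img[, , 1] <- 10; img[, , 2] <- 200; img[, , 3] <- 30
  expect_equal(extract_green(img), matrix(200, 4, 5))
  expect_equal(extract_green(array(0, c(3, 3, 3))), matrix(0, 3, 3))

  set.seed(4)
  rnd <- array(sample(0:255, 6 * 7 * 3, TRUE), c(6, 7, 3))
  # brute-force per-pixel loop oracle
  oracle <- matrix(0, 6, 7)
  for (r in 1:6) for (c in 1:7) oracle[r, c] <- rnd[r, c, 2]
  expect_equal(extract_green(rnd), oracle)

  expect_error(extract_green(matrix(0, 4, 4)), "3")
})

test_that("CLAHE enhances contrast, fixes constants, reduces to global equalization", {
  const <- matrix(120, 32, 32)
  out <- apply_clahe(const)
  expect_equal(length(unique(as.vector(out))), 1L)  # constant in, constant out

  # two-level raster: spread must not shrink
  two <- matrix(rep(c(100, 140), each = 128), 16, 16)
  eq <- apply_clahe(two, clip_limit = 1, tile_rows = 1, tile_cols = 1)
  expect_gte(sd(eq), sd(two))
  expect_true(all(eq >= 0 & eq <= 255))

  # 1x1 tile grid with no clipping == plain histogram equalization
  set.seed(9)
  toy <- matrix(sample(40:90, 256, TRUE), 16, 16)
  expect_equal(apply_clahe(toy, clip_limit = 1, tile_rows = 1, tile_cols = 1),
               global_hist_eq(toy))

  expect_error(apply_clahe(toy, clip_limit = 0), "clip_limit")
  expect_error(apply_clahe(toy, tile_rows = 0), "tile")
})

test_that("patch grids reproduce the published tiling arithmetic", {
  g <- patch_grid(400, 1184, 2000, 2368)
  expect_equal(c(g$n_rows, g$n_cols), c(5, 2))
  expect_equal(g$n_rows * g$n_cols, 10)            # 10 patches per image

  g224 <- patch_grid(224, 224, 2000, 2368, mode = "floor")
  expect_equal(g224$n_rows * g224$n_cols, 80)       # 80 floor tiles per image

  gt <- patch_grid(200, 296, 400, 1184)
  expect_equal(gt$n_rows * gt$n_cols, 8)            # 8 evaluation tiles

  expect_error(patch_grid(224, 224, 2000, 2368, mode = "exact"), "divisible")

  # index <-> position round trip is bijective
  for (i in seq_len(10)) {
    pos <- patch_position(g, i)
    expect_equal(patch_index(g, pos["row"], pos["col"]), i)
  }
})

test_that("split/stitch are exact inverses and conserve mask content", {
  set.seed(2)
  x <- matrix(rnorm(40 * 24), 40, 24)
  g <- patch_grid(10, 8, 40, 24)
  ps <- split_patches(x, g)
  expect_length(ps, 12)
  expect_equal(stitch_patches(ps, g), x)

  # row-major order on a 2x2 grid of 1x1 patches
  g11 <- patch_grid(1, 1, 2, 2)
  expect_equal(stitch_patches(list(matrix(1), matrix(2), matrix(3), matrix(4)), g11),
               matrix(c(1, 3, 2, 4), 2, 2))

  mask <- matrix(rbinom(40 * 24, 1, 0.1), 40, 24)
  mp <- split_patches(mask, g)
  expect_equal(sum(stitch_patches(mp, g)), sum(mask))
  expect_error(stitch_patches(mp[-1], g), "count")
})

test_that("cropping follows offset semantics and validates bounds", {
  src <- matrix(1:100, 10, 10)
  out <- crop_background(src, 4, 4, 3, 3)
  expect_equal(out, src[4:7, 4:7])                  # offset = skipped pixels
  expect_equal(crop_background(src, 10, 10, 0, 0), src)
  # centered crop of the clinical raster geometry: 3008 -> 2368 skips 320
  expect_equal((3008 - 2368) %/% 2, 320)
  wide <- matrix(0, 20, 3008)
  expect_silent(crop_background(wide, 20, 2368))
  expect_error(crop_background(src, 8, 8, 5, 5), "outside")
})

test_that("per-patch normalization rescales to the full 8-bit range", {
  expect_equal(sort(unique(as.vector(normalize_patch(matrix(c(50, 150), 1))))),
               c(0, 255))
  full <- matrix(c(0, 255, 17, 101), 2, 2)
  expect_equal(normalize_patch(full), full)         # already full range
  expect_equal(as.vector(normalize_patch(matrix(c(10, 20, 30), 1))),
               c(0, 128, 255))                      # round half up
  expect_equal(normalize_patch(matrix(7, 3, 3)), matrix(0, 3, 3))
})

test_that("flip augmentation triples counts and transforms masks identically", {
  set.seed(6)
  ps <- replicate(5, matrix(sample(0:255, 12), 3, 4), simplify = FALSE)
  ms <- replicate(5, matrix(rbinom(12, 1, 0.3), 3, 4), simplify = FALSE)
  aug <- augment_flips(ps, ms)
  expect_length(aug$patches, 15)
  expect_length(aug$masks, 15)
  # order: originals, horizontal, vertical
  expect_equal(aug$patches[[6]], ps[[1]][, 4:1])
  expect_equal(aug$patches[[11]], ps[[1]][3:1, ])
  expect_equal(aug$masks[[6]], ms[[1]][, 4:1])
  # flips are permutations: Neo counts conserved
  expect_equal(vapply(aug$masks, sum, numeric(1)), rep(vapply(ms, sum, numeric(1)), 3))
  # symmetric patch -> three identical copies
  sym <- matrix(5, 4, 4)
  a2 <- augment_flips(list(sym), list(sym * 0))
  expect_equal(a2$patches[[1]], a2$patches[[2]])
  expect_equal(a2$patches[[2]], a2$patches[[3]])
  expect_error(augment_flips(ps, ms[-1]), "aligned")
})

test_that("dataset splitting is exhaustive, disjoint and seed-reproducible", {
  s <- split_dataset(1:200, c(0.5, 0.25, 0.25), seed = 3)
  expect_equal(lengths(s[c("train", "validation", "test")]),
               c(train = 100L, validation = 50L, test = 50L))
  expect_equal(sort(c(s$train, s$validation, s$test)), 1:200)
  expect_identical(split_dataset(1:200, seed = 3), s)
  expect_false(identical(split_dataset(1:200, seed = 4), s))

  s4 <- split_dataset(1:4)
  expect_equal(lengths(s4[c("train", "validation", "test")]),
               c(train = 2L, validation = 1L, test = 1L))
  expect_error(split_dataset(1:10, c(0.5, 0.3, 0.3)), "sum to 1")
})

test_that("the preprocessing chain applies CLAHE before patching and spares masks", {
  cfg <- tiny_phantom(seed = 8)
  ph <- render_phantom(cfg)
  g <- patch_grid(48, 48, 96, 96)
  ps <- preprocess_image(ph$image, g)
  expect_length(ps, 4)
  expect_true(all(vapply(ps, function(p) min(p) == 0 && max(p) == 255, logical(1))))
  ms <- preprocess_mask(ph$mask, g)
  expect_equal(stitch_patches(ms, g), ph$mask, ignore_attr = TRUE)
  # masks keep raw 0/1 values: no intensity transform was applied
  expect_true(all(unlist(ms) %in% c(0L, 1L)))
})
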