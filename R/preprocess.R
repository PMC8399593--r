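# Preprocessing: green-channel extraction, CLAHE, cropping, deterministic
# patch tiling, per-patch normalization, flip augmentation and dataset
# splitting. The canonical order for images is green -> CLAHE -> crop/patch ->
# normalize; masks undergo only crop/patch/flip, never intensity transforms.

#' Extract the green channel from an RGB image
#'
#' Retinal vessels, including neovascular ones, have their highest contrast
#' against the fundus background in the green channel, which is why the
#' pipeline segments on it.
#'
#' @param image height x width x 3 array (RGB channel order).
#' @return height x width matrix (values unmodified).
#' @export
extract_green <- function(image) {
  assert_that(is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L,
              "image must be a height x width x 3 array")
  image[, , 2]
}

#' Define a deterministic patch grid
#'
#' A grid tiles a raster into non-overlapping `patch_height` x `patch_width`
#' rectangles in row-major order. In `exact` mode the patches must cover the
#' raster exactly; in `floor` mode the grid keeps
#' `floor(height / patch_height)` x `floor(width / patch_width)` tiles and
#' discards the remainder at the bottom/right.
#'
#' @param patch_height,patch_width tile size in pixels.
#' @param image_height,image_width raster size in pixels.
#' @param mode `"exact"` or `"floor"`.
#' @return An object of class `patch_grid` with fields `patch_height`,
#'   `patch_width`, `n_rows`, `n_cols`, `mode`.
#' @export
#' @examples
#' g <- patch_grid(400, 1184, 2000, 2368)  # 5 x 2 = 10 patches
#' g$n_rows * g$n_cols
patch_grid <- function(patch_height, patch_width, image_height, image_width,
                       mode = c("exact", "floor")) {
  mode <- match.arg(mode)
  assert_that(patch_height >= 1 && patch_width >= 1, "patch size must be positive")
  if (mode == "exact") {
    if (image_height %% patch_height != 0 || image_width %% patch_width != 0) {
      stop(sprintf("exact grid: %d x %d is not divisible by %d x %d",
                   image_height, image_width, patch_height, patch_width),
           call. = FALSE)
    }
    n_rows <- image_height %/% patch_height
    n_cols <- image_width %/% patch_width
  } else {
    n_rows <- image_height %/% patch_height
    n_cols <- image_width %/% patch_width
    assert_that(n_rows >= 1 && n_cols >= 1, "raster smaller than one patch")
  }
  structure(list(patch_height = as.integer(patch_height),
                 patch_width = as.integer(patch_width),
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 mode = mode),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("patch grid: %d x %d tiles of %d x %d px (%s mode, %d patches)\n",
              x$n_rows, x$n_cols, x$patch_height, x$patch_width, x$mode,
              x$n_rows * x$n_cols))
  invisible(x)
}

#' Map a row-major patch index to its (row, col) grid position and back
#'
#' @param grid a [patch_grid()].
#' @param index patch index in 1..n_rows*n_cols.
#' @return `patch_position()`: integer `c(row, col)`; `patch_index()`: the
#'   row-major index.
#' @export
patch_position <- function(grid, index) {
  n <- grid$n_rows * grid$n_cols
  assert_that(all(index >= 1 & index <= n), "patch index out of range")
  i <- as.integer(index) - 1L
  c(row = i %/% grid$n_cols + 1L, col = i %% grid$n_cols + 1L)
}

#' @rdname patch_position
#' @param row,col grid position, 1-based.
#' @export
patch_index <- function(grid, row, col) {
  assert_that(row >= 1 && row <= grid$n_rows && col >= 1 && col <= grid$n_cols,
              "patch position out of range")
  (as.integer(row) - 1L) * grid$n_cols + as.integer(col)
}

#' Crop a window out of a raster
#'
#' Removes background around the retina (and is applied identically to
#' ground-truth masks). Offsets count skipped pixels (0-based): the crop keeps
#' rows `row_offset + 1 .. row_offset + target_height`. When an offset is
#' `NULL` the window is centered along that axis.
#'
#' @param raster matrix or height x width x channels array.
#' @param target_height,target_width crop size in pixels.
#' @param row_offset,col_offset number of leading rows/columns to skip;
#'   `NULL` centers the window.
#' @return The cropped raster (same number of channels as the input).
#' @export
crop_background <- function(raster, target_height, target_width,
                            row_offset = NULL, col_offset = NULL) {
  d <- dim(raster)
  H <- d[1]; W <- d[2]
  if (is.null(row_offset)) row_offset <- (H - target_height) %/% 2
  if (is.null(col_offset)) col_offset <- (W - target_width) %/% 2
  if (row_offset < 0 || col_offset < 0 ||
      row_offset + target_height > H || col_offset + target_width > W) {
    stop("crop window falls outside the source raster", call. = FALSE)
  }
  rows <- (row_offset + 1):(row_offset + target_height)
  cols <- (col_offset + 1):(col_offset + target_width)
  if (length(d) == 2L) raster[rows, cols, drop = FALSE]
  else raster[rows, cols, , drop = FALSE]
}

#' Split a raster into patches / reassemble patches into a raster
#'
#' `split_patches()` tiles a raster into the grid's non-overlapping patches in
#' row-major order; in `exact` mode every pixel is covered exactly once and
#' `stitch_patches()` is its exact inverse.
#'
#' @param raster height x width matrix.
#' @param grid a [patch_grid()] valid for the raster under its mode.
#' @return `split_patches()`: list of `n_rows * n_cols` matrices;
#'   `stitch_patches()`: the reassembled matrix.
#' @export
split_patches <- function(raster, grid) {
  d <- dim(raster)
  need_h <- grid$n_rows * grid$patch_height
  need_w <- grid$n_cols * grid$patch_width
  if (grid$mode == "exact") {
    assert_that(d[1] == need_h && d[2] == need_w,
                "exact grid does not match raster dimensions")
  } else {
    assert_that(d[1] >= need_h && d[2] >= need_w, "grid larger than raster")
  }
  out <- vector("list", grid$n_rows * grid$n_cols)
  k <- 0L
  for (r in seq_len(grid$n_rows)) {
    for (c in seq_len(grid$n_cols)) {
      k <- k + 1L
      out[[k]] <- raster[((r - 1) * grid$patch_height + 1):(r * grid$patch_height),
                         ((c - 1) * grid$patch_width + 1):(c * grid$patch_width),
                         drop = FALSE]
    }
  }
  out
}

#' @rdname split_patches
#' @param patches list of equally-sized matrices, row-major order.
#' @export
stitch_patches <- function(patches, grid) {
  assert_that(length(patches) == grid$n_rows * grid$n_cols,
              "patch count does not match grid")
  ph <- grid$patch_height; pw <- grid$patch_width
  assert_that(all(vapply(patches, function(p) all(dim(p) == c(ph, pw)), logical(1))),
              "all patches must match the grid patch size")
  out <- matrix(0, grid$n_rows * ph, grid$n_cols * pw)
  k <- 0L
  for (r in seq_len(grid$n_rows)) {
    for (c in seq_len(grid$n_cols)) {
      k <- k + 1L
      out[((r - 1) * ph + 1):(r * ph), ((c - 1) * pw + 1):(c * pw)] <- patches[[k]]
    }
  }
  out
}

#' Min-max normalize a patch to the full 8-bit range
#'
#' Linearly rescales the patch so its minimum maps to 0 and its maximum to
#' 255 (rounded half-up); a constant patch maps to all zeros. Applied per
#' patch, after CLAHE, to images only.
#'
#' @param patch single-channel matrix.
#' @return Matrix of integers in \[0, 255\].
#' @export
normalize_patch <- function(patch) {
  assert_that(length(patch) > 0, "patch must be non-empty")
  lo <- min(patch); hi <- max(patch)
  if (hi == lo) return(matrix(0, nrow(patch), ncol(patch)))
  round_half_up((patch - lo) / (hi - lo) * 255)
}

#' Augment a patch set with horizontal and vertical flips
#'
#' Returns originals, then all horizontal flips (columns reversed), then all
#' vertical flips (rows reversed); masks are transformed identically, so a
#' training set of 100 patches becomes 300.
#'
#' @param patches list of image patches (matrices).
#' @param masks aligned list of mask patches.
#' @return list with `patches` and `masks`, each of length `3 * length(patches)`.
#' @export
augment_flips <- function(patches, masks) {
  assert_that(length(patches) == length(masks), "patches and masks must be aligned")
  assert_that(all(mapply(function(p, m) all(dim(p) == dim(m)), patches, masks)),
              "each mask must match its patch dimensions")
  hflip <- function(x) x[, rev(seq_len(ncol(x))), drop = FALSE]
  vflip <- function(x) x[rev(seq_len(nrow(x))), , drop = FALSE]
  list(patches = c(patches, lapply(patches, hflip), lapply(patches, vflip)),
       masks = c(masks, lapply(masks, hflip), lapply(masks, vflip)))
}

#' Randomly partition items into train / validation / test sets
#'
#' Uniform random partition without replacement, reproducible by seed. Set
#' sizes follow the largest-remainder rule, so 200 items at (0.5, 0.25, 0.25)
#' give exactly 100/50/50.
#'
#' @param items vector or list of items (typically patch indices).
#' @param fractions length-3 numeric summing to 1: train, validation, test.
#' @param seed integer seed.
#' @return An object of class `dataset_split`: list with `train`,
#'   `validation`, `test` and `seed`. The three sets are disjoint and their
#'   union is `items`.
#' @export
split_dataset <- function(items, fractions = c(0.5, 0.25, 0.25), seed = 1L) {
  assert_that(length(fractions) == 3 && all(fractions >= 0),
              "fractions must be three non-negative numbers")
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  n <- length(items)
  sizes <- floor(n * fractions)
  rem <- n * fractions - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    for (j in order(rem, decreasing = TRUE)[seq_len(short)]) sizes[j] <- sizes[j] + 1
  }
  perm <- with_seed(seed, sample.int(n))
  idx <- list(train = perm[seq_len(sizes[1])],
              validation = perm[sizes[1] + seq_len(sizes[2])],
              test = perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
  pick <- function(i) if (is.list(items)) items[i] else items[i]
  structure(list(train = pick(idx$train), validation = pick(idx$validation),
                 test = pick(idx$test), seed = as.integer(seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset split: %d train / %d validation / %d test (seed %d)\n",
              length(x$train), length(x$validation), length(x$test), x$seed))
  invisible(x)
}

#' Run the full image preprocessing chain on one fundus image
#'
#' Applies, in order: green-channel extraction, CLAHE on the full image,
#' optional background crop, patch tiling, and per-patch min-max
#' normalization. `preprocess_mask()` applies only the geometric steps (crop
#' and tiling) to the paired ground-truth mask.
#'
#' @param image height x width x 3 RGB array.
#' @param grid a [patch_grid()] for the (cropped) image.
#' @param clip_limit,tile_rows,tile_cols CLAHE parameters, see [apply_clahe()].
#' @param crop optional list `(target_height, target_width, row_offset,
#'   col_offset)` passed to [crop_background()]; `NULL` skips cropping.
#' @return List of normalized single-channel patches.
#' @export
preprocess_image <- function(image, grid, clip_limit = 0.01, tile_rows = 8L,
                             tile_cols = 8L, crop = NULL) {
  g <- extract_green(image)
  g <- apply_clahe(g, clip_limit = clip_limit, tile_rows = tile_rows,
                   tile_cols = tile_cols)
  if (!is.null(crop)) {
    g <- crop_background(g, crop$target_height, crop$target_width,
                         crop$row_offset, crop$col_offset)
  }
  lapply(split_patches(g, grid), normalize_patch)
}

#' @rdname preprocess_image
#' @param mask height x width 0/1 matrix aligned to `image`.
#' @export
preprocess_mask <- function(mask, grid, crop = NULL) {
  if (!is.null(crop)) {
    mask <- crop_background(mask, crop$target_height, crop$target_width,
                            crop$row_offset, crop$col_offset)
  }
  split_patches(mask, grid)
}
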