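#' Configuration for a synthetic fundus phantom
#'
#' A phantom emulates the appearance of a color fundus photograph at desk
#' scale: a dark background, a circular retinal field of view, one bright
#' elliptical optic disk, a branching tree of normal vessels drawn in all
#' three channels with the strongest contrast against background in the green
#' channel, and zero or more neovascularization lesions, each a dense tangle
#' of thin, highly tortuous strokes confined to a small disk. The ground-truth
#' mask marks exactly the lesion stroke pixels as `Neo`.
#'
#' Default dimensions are 400 x 592: one-fifth linear scale of a 2000 x 2368
#' cropped clinical fundus image, rounded so that both the network's 8-fold
#' downsampling path and the 5 x 2 patch grid (patches of 80 x 296) still
#' apply after scaling.
#'
#' @param image_height,image_width phantom size in pixels, each >= 64.
#' @param n_lesions number of neovascularization lesions (>= 0).
#' @param vessel_branching_depth depth of the recursive binary vessel tree
#'   (>= 1; depth 1 is a single unbranched trunk).
#' @param vessel_base_width trunk width in pixels.
#' @param lesion_radius_range length-2 numeric, pixel radius interval from
#'   which each lesion's confining disk radius is drawn.
#' @param lesion_vessel_count number of tangle strokes per lesion.
#' @param background_level green-channel background intensity inside the field
#'   of view (0-255); red and blue backgrounds are derived from it to mimic
#'   the reddish-orange fundus hue.
#' @param noise_sd standard deviation of additive Gaussian sensor noise, in
#'   intensity units (applied per channel, then clipped to \[0, 255\]).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return An object of class `phantom_config` (a validated list).
#' @seealso [render_phantom()], [emit_dataset()]
#' @export
#' @examples
#' cfg <- phantom_config(n_lesions = 1, seed = 42)
#' ph <- render_phantom(cfg)
#' dim(ph$image)
phantom_config <- function(image_height = 400L, image_width = 592L,
                           n_lesions = 2L, vessel_branching_depth = 5L,
                           vessel_base_width = 4, lesion_radius_range = c(18, 30),
                           lesion_vessel_count = 12L, background_level = 90,
                           noise_sd = 5, seed = 1L) {
  assert_that(image_height >= 64 && image_width >= 64,
              "image_height and image_width must be >= 64")
  assert_that(n_lesions >= 0, "n_lesions must be >= 0")
  assert_that(vessel_base_width >= 1, "vessel_base_width must be >= 1")
  assert_that(length(lesion_radius_range) == 2 &&
                lesion_radius_range[1] <= lesion_radius_range[2] &&
                lesion_radius_range[1] > 0,
              "lesion_radius_range must be a positive increasing interval")
  assert_that(lesion_vessel_count >= 1, "lesion_vessel_count must be >= 1")
  assert_that(background_level >= 0 && background_level <= 255,
              "background_level must be in [0, 255]")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    n_lesions = as.integer(n_lesions),
    vessel_branching_depth = as.integer(vessel_branching_depth),
    vessel_base_width = as.numeric(vessel_base_width),
    lesion_radius_range = as.numeric(lesion_radius_range),
    lesion_vessel_count = as.integer(lesion_vessel_count),
    background_level = as.numeric(background_level),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("fundus phantom config: %d x %d, %d lesion(s), vessel depth %d, seed %d\n",
              x$image_height, x$image_width, x$n_lesions,
              x$vessel_branching_depth, x$seed))
  invisible(x)
}

#' Grow a recursive binary vessel tree
#'
#' Grows a branching vessel skeleton by recursive bifurcation starting from
#' `origin`. Each branch point spawns two children with jittered headings,
#' shortened length and narrower caliber; widths never fall below 1 pixel and
#' a child is never wider than its parent. Endpoints are clipped to the image
#' bounds.
#'
#' Consumes the R random stream; wrap in a fixed seed (or pass `seed`) for
#' reproducible trees.
#'
#' @param config a [phantom_config()].
#' @param origin numeric `c(x, y)` starting coordinate, inside the retinal
#'   field of view.
#' @param heading initial direction in radians (default: sampled).
#' @param seed optional integer; when given, the tree is grown under this seed
#'   without disturbing the caller's random stream.
#' @return A data.frame of segments with columns `x0, y0, x1, y1, width,
#'   depth`; at most `2^depth - 1` rows.
#' @export
grow_vessel_tree <- function(config, origin, heading = NULL, seed = NULL) {
  assert_that(inherits(config, "phantom_config"), "config must be a phantom_config")
  if (config$vessel_branching_depth < 1) {
    stop("vessel_branching_depth must be >= 1", call. = FALSE)
  }
  if (!is.null(seed)) {
    return(with_seed(seed, grow_vessel_tree(config, origin, heading)))
  }
  H <- config$image_height; W <- config$image_width
  if (is.null(heading)) heading <- stats::runif(1, 0, 2 * pi)
  base_len <- 0.22 * min(H, W)
  segs <- vector("list", 2^config$vessel_branching_depth)
  k <- 0L
  recurse <- function(p, ang, len, width, depth) {
    ang <- ang + stats::rnorm(1, 0, 0.08)
    q <- p + len * c(cos(ang), sin(ang))
    q <- c(clip(q[1], 1, W), clip(q[2], 1, H))
    k <<- k + 1L
    segs[[k]] <<- c(p[1], p[2], q[1], q[2], width,
                    config$vessel_branching_depth - depth + 1)
    if (depth > 1) {
      spread <- stats::runif(2, 0.25, 0.7)
      shrink <- stats::runif(2, 0.68, 0.8)
      w_child <- pmax(1, width * stats::runif(2, 0.62, 0.78))
      recurse(q, ang - spread[1], len * shrink[1], min(w_child[1], width), depth - 1)
      recurse(q, ang + spread[2], len * shrink[2], min(w_child[2], width), depth - 1)
    }
  }
  p0 <- c(clip(origin[1], 1, W), clip(origin[2], 1, H))
  recurse(p0, heading, base_len, max(1, config$vessel_base_width),
          config$vessel_branching_depth)
  out <- as.data.frame(do.call(rbind, segs[seq_len(k)]))
  names(out) <- c("x0", "y0", "x1", "y1", "width", "depth")
  out
}

# Linear pixel indices (into an H x W matrix) covered when a polyline point
# set is stamped with a disk of the given width. xs/ys are continuous coords.
stamp_points <- function(xs, ys, width, H, W) {
  r <- max(width / 2, 0.5)
  ri <- floor(r)
  off <- expand.grid(dx = -ri:ri, dy = -ri:ri)
  off <- off[off$dx^2 + off$dy^2 <= r^2 + 1e-9, , drop = FALSE]
  cx <- round(xs); cy <- round(ys)
  px <- as.vector(outer(cx, off$dx, `+`))
  py <- as.vector(outer(cy, off$dy, `+`))
  keep <- px >= 1 & px <= W & py >= 1 & py <= H
  unique(py[keep] + (px[keep] - 1) * H)
}

# Pixels covered by one segment drawn at its width.
segment_pixels <- function(x0, y0, x1, y1, width, H, W) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  n <- max(2L, ceiling(len / 0.5) + 1L)
  t <- seq(0, 1, length.out = n)
  stamp_points(x0 + t * (x1 - x0), y0 + t * (y1 - y0), width, H, W)
}

# One tortuous lesion stroke: a bounded random walk radiating from the lesion
# center, reflected back when it wanders past the confining radius. Returns
# the covered pixel indices. All strokes start at the center so each lesion
# forms a single connected tangle.
lesion_stroke <- function(cx, cy, radius, H, W) {
  n_steps <- max(10L, round(3 * radius))
  step <- 0.6
  heading <- stats::runif(1, 0, 2 * pi)
  xs <- numeric(n_steps + 1); ys <- numeric(n_steps + 1)
  xs[1] <- cx; ys[1] <- cy
  x <- cx; y <- cy
  for (i in seq_len(n_steps)) {
    heading <- heading + stats::rnorm(1, 0, 0.55)
    x2 <- x + step * cos(heading); y2 <- y + step * sin(heading)
    if ((x2 - cx)^2 + (y2 - cy)^2 > radius^2) {
      heading <- atan2(cy - y, cx - x) + stats::rnorm(1, 0, 0.3)
      x2 <- x + step * cos(heading); y2 <- y + step * sin(heading)
    }
    x <- x2; y <- y2
    xs[i + 1] <- x; ys[i + 1] <- y
  }
  width <- sample(c(1, 2), 1, prob = c(0.7, 0.3))
  stamp_points(xs, ys, width, H, W)
}

#' Render a fundus phantom and its ground-truth mask
#'
#' Deterministically renders the phantom described by `config`: circular field
#' of view on a dark background, bright elliptical optic disk, a normal vessel
#' tree rooted at the disk (drawn darker than background in all channels, with
#' the largest contrast magnitude in green), `n_lesions` disjoint
#' neovascularization tangles, then additive Gaussian noise clipped to
#' \[0, 255\]. Lesion centers are drawn with a non-overlap constraint and are
#' rejected when they intersect the optic disk, so ground truth is never
#' ambiguous. The mask marks exactly the lesion stroke pixels.
#'
#' @param config a [phantom_config()].
#' @return A list with `image` (height x width x 3 array, integers 0-255, RGB
#'   channel order) and `mask` (height x width integer matrix, 1 = Neo,
#'   0 = NotNeo).
#' @export
render_phantom <- function(config) {
  assert_that(inherits(config, "phantom_config"), "config must be a phantom_config")
  with_seed(config$seed, render_phantom_impl(config))
}

render_phantom_impl <- function(config) {
  H <- config$image_height; W <- config$image_width
  fov_r <- 0.47 * min(H, W)
  fov_c <- c(W / 2, H / 2)          # (x, y)
  if (config$n_lesions > 0 && config$lesion_radius_range[2] > fov_r / 2) {
    stop("lesion radius exceeds half the field-of-view radius", call. = FALSE)
  }

  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  in_fov <- (xs - fov_c[1])^2 + (ys - fov_c[2])^2 <= fov_r^2

  bg <- config$background_level
  red <- matrix(8, H, W); green <- matrix(6, H, W); blue <- matrix(4, H, W)
  red[in_fov] <- clip(2.0 * bg); green[in_fov] <- bg; blue[in_fov] <- clip(0.45 * bg)

  # optic disk: bright ellipse offset from the field-of-view center
  disk_c <- fov_c + c(0.55 * fov_r, -0.08 * fov_r)
  disk_ax <- 0.16 * fov_r; disk_ay <- 0.13 * fov_r
  in_disk <- ((xs - disk_c[1]) / disk_ax)^2 + ((ys - disk_c[2]) / disk_ay)^2 <= 1
  red[in_disk] <- 235; green[in_disk] <- 205; blue[in_disk] <- 130

  # normal vasculature: two trees rooted at the disk, heading into the retina
  vessel_idx <- integer(0)
  for (h0 in c(pi - 0.5, pi + 0.5)) {
    tree <- grow_vessel_tree(config, origin = disk_c,
                             heading = h0 + stats::rnorm(1, 0, 0.15))
    for (i in seq_len(nrow(tree))) {
      vessel_idx <- c(vessel_idx, segment_pixels(tree$x0[i], tree$y0[i],
                                                 tree$x1[i], tree$y1[i],
                                                 tree$width[i], H, W))
    }
  }
  vessel_idx <- unique(vessel_idx)
  vessel_idx <- vessel_idx[in_fov[vessel_idx] & !in_disk[vessel_idx]]
  # dark vessels; contrast magnitude largest in the green channel
  red[vessel_idx] <- clip(red[vessel_idx] - 25)
  green[vessel_idx] <- clip(green[vessel_idx] - 60)
  blue[vessel_idx] <- clip(blue[vessel_idx] - 10)

  # neovascular lesions: disjoint tangles of thin tortuous strokes
  mask <- matrix(0L, H, W)
  if (config$n_lesions > 0) {
    centers <- matrix(numeric(0), 0, 3)  # x, y, radius
    tries <- 0L
    while (nrow(centers) < config$n_lesions) {
      tries <- tries + 1L
      if (tries > 2000L) {
        stop("could not place lesions without overlap; reduce n_lesions or radius",
             call. = FALSE)
      }
      r <- stats::runif(1, config$lesion_radius_range[1], config$lesion_radius_range[2])
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, fov_r - r - 6)
      cx <- fov_c[1] + rad * cos(ang); cy <- fov_c[2] + rad * sin(ang)
      # keep off the optic disk and away from other lesions
      if (sqrt((cx - disk_c[1])^2 + (cy - disk_c[2])^2) < r + disk_ax + 4) next
      if (nrow(centers) > 0 &&
          any(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) <
                centers[, 3] + r + 6)) next
      centers <- rbind(centers, c(cx, cy, r))
    }
    for (j in seq_len(config$n_lesions)) {
      les_idx <- integer(0)
      for (k in seq_len(config$lesion_vessel_count)) {
        les_idx <- c(les_idx, lesion_stroke(centers[j, 1], centers[j, 2],
                                            centers[j, 3], H, W))
      }
      les_idx <- unique(les_idx)
      mask[les_idx] <- 1L
      red[les_idx] <- clip(red[les_idx] - 20)
      green[les_idx] <- clip(green[les_idx] - 50)
      blue[les_idx] <- clip(blue[les_idx] - 8)
    }
  }

  img <- array(0, c(H, W, 3))
  img[, , 1] <- red; img[, , 2] <- green; img[, , 3] <- blue
  if (config$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, config$noise_sd)
  }
  img <- round(clip(img))
  list(image = img, mask = mask)
}

#' Write a phantom dataset to disk
#'
#' Renders `n_images` phantoms and writes each as an 8-bit RGB PNG with a
#' matching 8-bit grayscale mask PNG (0 = NotNeo, 255 = Neo), plus a
#' tab-separated manifest listing file pairs and the per-image seeds. Image
#' `i` uses seed `config$seed + (i - 1) * 1000`, so any single file can be
#' regenerated from the master seed alone.
#'
#' @param config a [phantom_config()]; its `seed` acts as the master seed.
#' @param n_images number of image/mask pairs to write (>= 0).
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the manifest data.frame (`image`, `mask`, `seed`).
#' @export
emit_dataset <- function(config, n_images, out_dir) {
  assert_that(inherits(config, "phantom_config"), "config must be a phantom_config")
  assert_that(n_images >= 0, "n_images must be >= 0")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  }
  manifest <- data.frame(image = character(0), mask = character(0),
                         seed = integer(0), stringsAsFactors = FALSE)
  for (i in seq_len(n_images)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + (i - 1L) * 1000L
    ph <- render_phantom(cfg_i)
    img_file <- sprintf("phantom_%03d.png", i)
    mask_file <- sprintf("phantom_%03d_mask.png", i)
    write_image_png(ph$image, file.path(out_dir, img_file))
    write_mask_png(ph$mask, file.path(out_dir, mask_file))
    manifest <- rbind(manifest, data.frame(image = img_file, mask = mask_file,
                                           seed = cfg_i$seed,
                                           stringsAsFactors = FALSE))
  }
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
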