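#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Local contrast enhancement used to make retinal vessels stand out from the
#' background before patching. The raster is divided into a `tile_rows` x
#' `tile_cols` grid; each tile's histogram is clipped so that no bin holds
#' more than `clip_limit` of the tile's pixels (the excess is redistributed
#' uniformly over all bins), an equalization lookup table is built per tile
#' from the clipped cumulative histogram, and every pixel is remapped by
#' bilinear interpolation between the four surrounding tile tables. The clip
#' limit bounds how much a near-uniform region can be amplified, which keeps
#' sensor noise from being stretched to full contrast.
#'
#' With a single 1 x 1 tile and a clip limit of 1 no clipping occurs and the
#' operation reduces to plain global histogram equalization.
#'
#' @param gray height x width matrix of integer intensities 0-255.
#' @param clip_limit normalized clip limit in (0, 1\]: the maximum fraction of
#'   a tile's pixels a single histogram bin may hold. Default 0.01.
#' @param tile_rows,tile_cols contextual tile grid (positive counts).
#'   Default 8 x 8.
#' @param nbins number of histogram bins (default 256, one per 8-bit level).
#' @return height x width matrix of integers in \[0, 255\].
#' @export
#' @examples
#' x <- matrix(rep(c(100, 140), each = 128), 16, 16)
#' y <- apply_clahe(x, clip_limit = 1, tile_rows = 1, tile_cols = 1)
#' sd(y) >= sd(x)
apply_clahe <- function(gray, clip_limit = 0.01, tile_rows = 8L, tile_cols = 8L,
                        nbins = 256L) {
  assert_that(is.matrix(gray), "gray must be a single-channel matrix")
  check_intensities(gray, "gray raster")
  assert_that(clip_limit > 0, "clip_limit must be > 0")
  assert_that(tile_rows >= 1 && tile_cols >= 1, "tile counts must be positive")
  H <- nrow(gray); W <- ncol(gray)

  # pad bottom/right by edge replication so tiles are equal-sized
  tile_h <- ceiling(H / tile_rows); tile_w <- ceiling(W / tile_cols)
  Hp <- tile_h * tile_rows; Wp <- tile_w * tile_cols
  g <- gray[c(seq_len(H), rep(H, Hp - H)), c(seq_len(W), rep(W, Wp - W)), drop = FALSE]

  npix <- tile_h * tile_w
  clip_count <- max(1, clip_limit * npix)
  bin_of <- function(v) pmin(floor(v * nbins / 256), nbins - 1) + 1

  # per-tile equalization lookup tables
  lut <- array(0, c(tile_rows, tile_cols, nbins))
  for (tr in seq_len(tile_rows)) {
    for (tc in seq_len(tile_cols)) {
      tile <- g[((tr - 1) * tile_h + 1):(tr * tile_h),
                ((tc - 1) * tile_w + 1):(tc * tile_w)]
      h <- tabulate(bin_of(tile), nbins)
      # clip and redistribute; a few passes are enough for the residual excess
      for (it in 1:8) {
        excess <- sum(pmax(h - clip_count, 0))
        if (excess < 1e-9) break
        h <- pmin(h, clip_count) + excess / nbins
      }
      cdf <- cumsum(h)
      first <- which(h > 0)[1]
      cdfmin <- cdf[first]
      denom <- npix - cdfmin
      if (denom <= 0) {
        lut[tr, tc, ] <- round(seq(0, nbins - 1) * 255 / (nbins - 1))  # degenerate: identity ramp
      } else {
        lut[tr, tc, ] <- round((cdf - cdfmin) / denom * 255)
      }
    }
  }

  # bilinear blend between the four surrounding tile tables
  py <- matrix(rep(seq_len(H), W), H, W)
  px <- matrix(rep(seq_len(W), each = H), H, W)
  ty <- (py - 0.5) / tile_h + 0.5
  tx <- (px - 0.5) / tile_w + 0.5
  i0 <- floor(ty); j0 <- floor(tx)
  wy <- clip(ty - i0, 0, 1); wx <- clip(tx - j0, 0, 1)
  r1 <- clip(i0, 1, tile_rows); r2 <- clip(i0 + 1, 1, tile_rows)
  c1 <- clip(j0, 1, tile_cols); c2 <- clip(j0 + 1, 1, tile_cols)
  b <- bin_of(gray)
  look <- function(r, c) lut[r + tile_rows * (c - 1) + tile_rows * tile_cols * (b - 1)]
  out <- (1 - wy) * ((1 - wx) * look(r1, c1) + wx * look(r1, c2)) +
    wy * ((1 - wx) * look(r2, c1) + wx * look(r2, c2))
  matrix(clip(round(out)), H, W)
}
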