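# Independent oracles used across tests. These deliberately use the dumbest
# possible algorithms (per-pixel loops, flood fill, closed forms) so they
# stay independent of the implementation paths they check.

# Direct per-pixel convolution by explicit summation.
naive_conv2d <- function(x, w, b, stride, pad) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; N <- dim(x)[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Co <- dim(w)[4]
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  y <- array(0, c(Ho, Wo, Co, N))
  for (n in 1:N) for (co in 1:Co) for (ho in 1:Ho) for (wo in 1:Wo) {
    s <- b[co]
    for (c in 1:C) for (ki in 1:kh) for (kj in 1:kw) {
      hi <- (ho - 1) * stride - pad + ki
      wi <- (wo - 1) * stride - pad + kj
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        s <- s + x[hi, wi, c, n] * w[ki, kj, c, co]
      }
    }
    y[ho, wo, co, n] <- s
  }
  y
}

# Count 8-connected components of a 0/1 mask by flood fill.
count_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  n_comp <- 0L
  for (start in which(mask == 1 & !seen)) {
    if (seen[start]) next
    n_comp <- n_comp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1) %% H + 1
      c <- (cur - 1) %/% H + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) {
          idx <- rr + (cc - 1) * H
          if (mask[idx] == 1 && !seen[idx]) {
            seen[idx] <- TRUE
            queue <- c(queue, idx)
          }
        }
      }
    }
  }
  n_comp
}

# Classic global histogram equalization on an 8-bit raster.
global_hist_eq <- function(gray) {
  counts <- tabulate(as.vector(gray) + 1, 256)
  cdf <- cumsum(counts)
  cdfmin <- cdf[which(counts > 0)[1]]
  n <- length(gray)
  lut <- round((cdf - cdfmin) / (n - cdfmin) * 255)
  matrix(lut[gray + 1], nrow(gray), ncol(gray))
}

# Brute-force confusion tally by an explicit double loop.
naive_confusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (r in seq_len(nrow(pred))) for (c in seq_len(ncol(pred))) {
    if (pred[r, c] == 1 && truth[r, c] == 1) tp <- tp + 1L
    else if (pred[r, c] == 0 && truth[r, c] == 0) tn <- tn + 1L
    else if (pred[r, c] == 1) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Small phantom config used by several suites.
tiny_phantom <- function(seed = 1, n_lesions = 1L, noise_sd = 0) {
  phantom_config(image_height = 96L, image_width = 96L, n_lesions = n_lesions,
                 vessel_branching_depth = 3L, lesion_radius_range = c(8, 12),
                 lesion_vessel_count = 6L, noise_sd = noise_sd, seed = seed)
}
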