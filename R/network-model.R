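# Model construction and the forward/backward executor. Activations are base
# arrays with dims (H, W, C, N); the heavy convolution kernels live in
# compiled code (see src/conv_ops.cpp), batch norm / ReLU / softmax are
# vectorized R. Backpropagation walks the declarative layer plan in reverse,
# which keeps the topology (residual additions, the depth-concatenation skip)
# in one place: build_reference_spec().

same_pad <- function(k) (k - 1L) %/% 2L

as_batch <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  x
}

#' Initialize network parameters from a layer plan
#'
#' Convolution and transposed-convolution weights use scaled (He) random
#' initialization, `sd = init_gain * sqrt(2 / fan_in)`, biases start at zero;
#' batch-norm scale/shift start at (1, 0) with running statistics (0, 1).
#'
#' The gain (default 0.3) applies to every convolution except the final
#' classification layer. Because all of those convolutions are followed
#' (directly or after the concatenation) by batch normalization, their
#' weights are scale-invariant: shrinking the initial norm leaves the
#' network function unchanged but raises the weights' effective learning
#' rate, which scales as `lr / ||W||^2`. Under the fixed small learning rate
#' of the training regime this makes convergence markedly faster without
#' touching the optimizer.
#'
#' With `init = "zero"` all weights are zero, which is useful for symmetry
#' tests: the softmax output is then exactly 0.5 for both classes everywhere.
#'
#' @param spec a [build_reference_spec()] plan.
#' @param seed integer seed for the weight draw (recorded in the model).
#' @param init `"he"` or `"zero"`.
#' @param init_gain multiplier on the He standard deviation for all
#'   batch-normalized convolutions.
#' @return An object of class `neovaseg_model`: list with `spec`, `params`
#'   (named per layer) and `seed`.
#' @export
init_network <- function(spec, seed = 1L, init = c("he", "zero"),
                         init_gain = 0.3) {
  assert_that(inherits(spec, "network_spec"), "spec must be a network_spec")
  init <- match.arg(init)
  params <- with_seed(seed, {
    p <- list()
    for (ly in spec$layer_plan) {
      if (ly$kind %in% c("conv", "tconv")) {
        kh <- ly$kernel[1]; kw <- ly$kernel[2]
        # tconv kernels are stored in the layout of the matching strided
        # convolution: (kh, kw, out_channels, in_channels)
        dims <- if (ly$kind == "conv") c(kh, kw, ly$in_channels, ly$out_channels)
                else c(kh, kw, ly$out_channels, ly$in_channels)
        fan_in <- kh * kw * ly$in_channels
        gain <- if (ly$name == "final_conv") 1 else init_gain
        w <- if (init == "he") {
          array(stats::rnorm(prod(dims), 0, gain * sqrt(2 / fan_in)), dims)
        } else array(0, dims)
        p[[ly$name]] <- list(w = w, b = numeric(ly$out_channels))
      } else if (ly$kind == "bn") {
        c_out <- ly$out_channels
        p[[ly$name]] <- list(gamma = rep(1, c_out), beta = numeric(c_out),
                             running_mean = numeric(c_out), running_var = rep(1, c_out))
      }
    }
    p
  })
  structure(list(spec = spec, params = params, seed = as.integer(seed)),
            class = "neovaseg_model")
}

#' @export
print.neovaseg_model <- function(x, ...) {
  cat(sprintf("neovaseg model: %d x %d input, %d layers, %s parameters (seed %d)\n",
              x$spec$input_height, x$spec$input_width, length(x$spec$layer_plan),
              format(count_parameters(x$spec), big.mark = ","), x$seed))
  invisible(x)
}

# ---- batch norm -------------------------------------------------------------

bn_eps <- 1e-5

# x: (H,W,C,N). Training mode uses batch statistics over (H,W,N) per channel
# and returns updated running stats; inference uses the stored running stats.
# The heavy per-pixel work happens in compiled code.
bn_forward <- function(x, par, training) {
  r <- cpp_bn_fwd(x, par$gamma, par$beta, par$running_mean, par$running_var,
                  training, bn_eps)
  par$running_mean <- r$running_mean
  par$running_var <- r$running_var
  list(y = r$y, cache = list(xhat = r$xhat, invstd = r$invstd), par = par)
}

bn_backward <- function(dy, par, cache) {
  cpp_bn_bwd(dy, cache$xhat, cache$invstd, par$gamma)
}

# ---- conv / tconv wrappers --------------------------------------------------

conv_forward <- function(x, par, kernel, stride) {
  cpp_conv2d_fwd(x, par$w, par$b, stride, same_pad(kernel[1]))
}

conv_backward <- function(x, dy, par, kernel, stride) {
  pad <- same_pad(kernel[1])
  d <- dim(x)
  dwdb <- cpp_conv2d_bwd_dwdb(x, dy, kernel[1], kernel[2], stride, pad)
  dx <- cpp_conv2d_bwd_dx(par$w, dy, stride, pad, d[1], d[2])
  list(dx = dx, dw = dwdb$dw, db = dwdb$db)
}

# Transposed convolution (x2 upsampling, kernel 4, stride 2, pad 1): its
# forward pass is the data-gradient of the matching strided convolution.
tconv_forward <- function(x, par, stride) {
  d <- dim(x)
  y <- cpp_conv2d_bwd_dx(par$w, x, stride, 1L, d[1] * stride, d[2] * stride)
  dy_dims <- dim(y)
  y + rep(rep(par$b, each = dy_dims[1] * dy_dims[2]), times = dy_dims[4])
}

tconv_backward <- function(x, dy, par, stride) {
  kh <- dim(par$w)[1]; kw <- dim(par$w)[2]
  dx <- cpp_conv2d_fwd(dy, par$w, numeric(dim(par$w)[4]), stride, 1L)
  dwdb <- cpp_conv2d_bwd_dwdb(dy, x, kh, kw, stride, 1L)
  d <- dim(dy)
  db <- .rowSums(matrix(.colSums(as.vector(dy), d[1] * d[2], d[3] * d[4]),
                        d[3], d[4]), d[3], d[4])
  list(dx = dx, dw = dwdb$dw, db = db)
}

# ---- softmax ----------------------------------------------------------------

# Per-pixel softmax over the channel dimension (2 classes).
softmax2 <- function(z) {
  d <- dim(z)
  z1 <- z[, , 1, , drop = FALSE]; z2 <- z[, , 2, , drop = FALSE]
  m <- pmax(z1, z2)
  e1 <- exp(z1 - m); e2 <- exp(z2 - m)
  s <- e1 + e2
  p <- array(0, d)
  p[, , 1, ] <- e1 / s; p[, , 2, ] <- e2 / s
  p
}

# ---- executor ---------------------------------------------------------------

# Runs the layer plan on a batch. Inputs are 8-bit intensities; the executor
# rescales them to [0, 1]. Returns every layer's activation when
# keep_cache = TRUE (needed for backprop).
net_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  x <- as_batch(x) / 255
  outs <- list()
  caches <- list()
  for (ly in model$spec$layer_plan) {
    out <- switch(ly$kind,
      input = x,
      conv = conv_forward(outs[[ly$inputs]], model$params[[ly$name]], ly$kernel, ly$stride),
      bn = {
        r <- bn_forward(outs[[ly$inputs]], model$params[[ly$name]], training)
        if (training) model$params[[ly$name]] <- r$par
        caches[[ly$name]] <- r$cache
        r$y
      },
      relu = cpp_relu_fwd(outs[[ly$inputs]]),
      maxpool = {
        r <- cpp_maxpool_fwd(outs[[ly$inputs]])
        caches[[ly$name]] <- r$idx
        r$y
      },
      tconv = tconv_forward(outs[[ly$inputs]], model$params[[ly$name]], ly$stride),
      add = outs[[ly$inputs[1]]] + outs[[ly$inputs[2]]],
      concat = {
        a <- outs[[ly$inputs[1]]]; b <- outs[[ly$inputs[2]]]
        da <- dim(a); db_ <- dim(b)
        if (any(da[c(1, 2, 4)] != db_[c(1, 2, 4)])) {
          stop("concat inputs must match spatially", call. = FALSE)
        }
        out <- array(0, c(da[1], da[2], da[3] + db_[3], da[4]))
        out[, , seq_len(da[3]), ] <- a
        out[, , da[3] + seq_len(db_[3]), ] <- b
        out
      },
      softmax = softmax2(outs[[ly$inputs]]),
      stop(sprintf("unknown layer kind '%s'", ly$kind)))
    outs[[ly$name]] <- out
  }
  res <- list(probs = outs[["softmax"]], logits = outs[["final_conv"]], model = model)
  if (keep_cache) { res$outs <- outs; res$caches <- caches }
  res
}

# Backpropagate from d(loss)/d(logits). Returns gradients named like params.
net_backward <- function(model, fwd, dlogits) {
  plan <- model$spec$layer_plan
  grads_out <- list(final_conv = dlogits)
  pgrads <- list()
  for (i in rev(seq_along(plan))) {
    ly <- plan[[i]]
    if (ly$kind %in% c("softmax", "input")) next
    g <- grads_out[[ly$name]]
    if (is.null(g)) next
    acc <- function(name, d) {
      grads_out[[name]] <<- if (is.null(grads_out[[name]])) d else grads_out[[name]] + d
    }
    switch(ly$kind,
      conv = {
        par <- model$params[[ly$name]]
        pad <- same_pad(ly$kernel[1])
        dwdb <- cpp_conv2d_bwd_dwdb(fwd$outs[[ly$inputs]], g,
                                    ly$kernel[1], ly$kernel[2], ly$stride, pad)
        pgrads[[ly$name]] <- list(w = dwdb$dw, b = dwdb$db)
        if (ly$inputs != "input") {  # no data gradient needed at the image
          d <- dim(fwd$outs[[ly$inputs]])
          acc(ly$inputs, cpp_conv2d_bwd_dx(par$w, g, ly$stride, pad, d[1], d[2]))
        }
      },
      tconv = {
        r <- tconv_backward(fwd$outs[[ly$inputs]], g, model$params[[ly$name]], ly$stride)
        pgrads[[ly$name]] <- list(w = r$dw, b = r$db)
        acc(ly$inputs, r$dx)
      },
      bn = {
        r <- bn_backward(g, model$params[[ly$name]], fwd$caches[[ly$name]])
        pgrads[[ly$name]] <- list(gamma = r$dgamma, beta = r$dbeta)
        acc(ly$inputs, r$dx)
      },
      relu = acc(ly$inputs, cpp_relu_bwd(g, fwd$outs[[ly$name]])),
      maxpool = acc(ly$inputs, cpp_maxpool_bwd(g, fwd$caches[[ly$name]],
                                               dim(fwd$outs[[ly$inputs]]))),
      add = { acc(ly$inputs[1], g); acc(ly$inputs[2], g) },
      concat = {
        ca <- dim(fwd$outs[[ly$inputs[1]]])[3]
        acc(ly$inputs[1], g[, , seq_len(ca), , drop = FALSE])
        acc(ly$inputs[2], g[, , (ca + 1):dim(g)[3], , drop = FALSE])
      })
    grads_out[[ly$name]] <- NULL  # release
  }
  pgrads
}

#' Per-pixel class probabilities for a patch
#'
#' Runs the fully-convolutional network on a single-channel patch (or a batch)
#' and returns per-pixel softmax probabilities over the two classes
#' (NotNeo, Neo). For every pixel the probabilities are non-negative and sum
#' to 1; output spatial size equals input spatial size.
#'
#' @param model a `neovaseg_model`.
#' @param patch height x width matrix of 8-bit intensities (dimensions
#'   divisible by 8), or an (H, W, 1, N) array for a batch.
#' @param ... unused.
#' @return For a single patch, an H x W x 2 array; for a batch, H x W x 2 x N.
#'   Channel 1 is NotNeo, channel 2 is Neo.
#' @export
forward <- function(model, patch, ...) UseMethod("forward")

#' @rdname forward
#' @export
forward.neovaseg_model <- function(model, patch, ...) {
  single <- is.matrix(patch)
  d <- dim(as_batch(patch))
  if (d[1] %% 8 != 0 || d[2] %% 8 != 0) {
    stop("patch dimensions must be divisible by 8", call. = FALSE)
  }
  p <- net_forward(model, patch, training = FALSE)$probs
  if (single) array(p, dim(p)[1:3]) else p
}

# ---- standalone residual block ----------------------------------------------

#' Residual block with simultaneous addition and downsampling
#'
#' The building block of the encoder: main path = 3 x 3 convolution (stride
#' per spec) + batch norm + ReLU + 3 x 3 convolution (stride 1) + batch norm;
#' skip path = identity when stride is 1 and channels match, otherwise a
#' 1 x 1 convolution (stride per spec) + batch norm so that the two paths
#' agree in shape at the element-wise addition; output =
#' `relu(main + skip)`. The 1 x 1 skip kernel downsamples without heavy
#' filtering, preserving the information carried around the main path.
#'
#' @param in_filters,out_filters channel counts.
#' @param stride 1 or 2.
#' @return `residual_block_spec()`: a spec object. `init_residual_block()`:
#'   a parameter list. `residual_block_forward()`: the (H/stride, W/stride,
#'   out_filters, N) output array.
#' @export
residual_block_spec <- function(in_filters, out_filters, stride = 2L) {
  assert_that(stride %in% c(1L, 2L), "stride must be 1 or 2")
  structure(list(in_filters = as.integer(in_filters),
                 out_filters = as.integer(out_filters),
                 stride = as.integer(stride),
                 identity_skip = stride == 1L && in_filters == out_filters),
            class = "residual_block_spec")
}

#' @rdname residual_block_spec
#' @param spec a `residual_block_spec`.
#' @param seed integer seed.
#' @param init `"he"` or `"zero"` (zero main-path weights make the block an
#'   identity-plus-activation, handy for tests).
#' @export
init_residual_block <- function(spec, seed = 1L, init = c("he", "zero")) {
  init <- match.arg(init)
  draw <- function(dims) {
    if (init == "zero") return(array(0, dims))
    array(stats::rnorm(prod(dims), 0, sqrt(2 / (dims[1] * dims[2] * dims[3]))), dims)
  }
  with_seed(seed, {
    p <- list(
      conv1 = list(w = draw(c(3, 3, spec$in_filters, spec$out_filters)),
                   b = numeric(spec$out_filters)),
      bn1 = list(gamma = rep(1, spec$out_filters), beta = numeric(spec$out_filters),
                 running_mean = numeric(spec$out_filters), running_var = rep(1, spec$out_filters)),
      conv2 = list(w = draw(c(3, 3, spec$out_filters, spec$out_filters)),
                   b = numeric(spec$out_filters)),
      bn2 = list(gamma = rep(1, spec$out_filters), beta = numeric(spec$out_filters),
                 running_mean = numeric(spec$out_filters), running_var = rep(1, spec$out_filters))
    )
    if (!spec$identity_skip) {
      p$skip_conv <- list(w = draw(c(1, 1, spec$in_filters, spec$out_filters)),
                          b = numeric(spec$out_filters))
      p$skip_bn <- list(gamma = rep(1, spec$out_filters), beta = numeric(spec$out_filters),
                        running_mean = numeric(spec$out_filters),
                        running_var = rep(1, spec$out_filters))
    }
    p
  })
}

#' @rdname residual_block_spec
#' @param x input feature maps, (H, W, in_filters, N) array.
#' @param params parameters from [init_residual_block()].
#' @param training logical; batch-norm mode.
#' @export
residual_block_forward <- function(x, spec, params, training = FALSE) {
  x <- as_batch(x)
  assert_that(dim(x)[3] == spec$in_filters, "input channels must equal spec$in_filters")
  main <- conv_forward(x, params$conv1, c(3L, 3L), spec$stride)
  main <- bn_forward(main, params$bn1, training)$y
  main <- pmax(main, 0)
  main <- conv_forward(main, params$conv2, c(3L, 3L), 1L)
  main <- bn_forward(main, params$bn2, training)$y
  skip <- if (spec$identity_skip) x else {
    s <- conv_forward(x, params$skip_conv, c(1L, 1L), spec$stride)
    bn_forward(s, params$skip_bn, training)$y
  }
  if (!all(dim(main) == dim(skip))) {
    stop("residual block: main and skip path shapes differ at the addition",
         call. = FALSE)
  }
  pmax(main + skip, 0)
}
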