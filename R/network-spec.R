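#' Build the reference 42-layer segmentation network plan
#'
#' Constructs the declarative layer plan of the encoder-decoder semantic
#' segmentation network. Counting input through softmax (the per-pixel
#' classification loss is not a layer), the plan has exactly 42 layers:
#'
#' * stem: 7 x 7 convolution (32 filters, stride 1, same padding) +
#'   batch norm + ReLU — a wide first receptive field suited to
#'   high-resolution fundus images;
#' * 2 x 2 max-pool, stride 2;
#' * two residual downsampling blocks (64 then 128 filters): 3 x 3 stride-2
#'   convolution in the main path, 1 x 1 stride-2 convolution in the skip
#'   path so that addition and downsampling happen simultaneously;
#' * bottleneck 1 x 1 convolution (128 filters) at the lowest resolution,
#'   where few pixels remain for larger kernels;
#' * three x2 transposed-convolution upsampling stages (64, 64, 32 filters),
#'   the first two followed by batch norm + ReLU;
#' * depth concatenation of the final upsampled maps with the stem ReLU
#'   output (32 + 32 = 64 channels at full resolution);
#' * two 3 x 3 convolution + batch norm + ReLU trios (32 filters each);
#' * final 1 x 1 convolution to 2 channels and per-pixel softmax over the
#'   classes (NotNeo, Neo).
#'
#' The encoder reduces the spatial size to 1/8 (one pool + two strided
#' blocks), matched by the three x2 upsampling stages, so output spatial size
#' equals input spatial size.
#'
#' @param input_height,input_width input patch size in pixels; each must be
#'   divisible by 8.
#' @return An object of class `network_spec`: list with `input_height`,
#'   `input_width`, `stem_filters`, `stage_filters`, `n_classes` (fixed at 2)
#'   and `layer_plan`, an ordered list of layer descriptors (`name`, `kind`,
#'   `kernel`, `stride`, `in_channels`, `out_channels`, `inputs`).
#' @seealso [init_network()], [count_parameters()]
#' @export
#' @examples
#' spec <- build_reference_spec(80, 296)
#' length(spec$layer_plan)  # 42
build_reference_spec <- function(input_height, input_width) {
  if (input_height %% 8 != 0 || input_width %% 8 != 0) {
    stop("input dimensions must be divisible by 8", call. = FALSE)
  }
  L <- function(name, kind, kernel = c(NA_integer_, NA_integer_), stride = 1L,
                in_ch = NA_integer_, out_ch = NA_integer_, inputs = character(0)) {
    list(name = name, kind = kind, kernel = as.integer(kernel),
         stride = as.integer(stride), in_channels = as.integer(in_ch),
         out_channels = as.integer(out_ch), inputs = inputs)
  }
  res_block <- function(prefix, in_ch, out_ch, input) {
    list(
      L(paste0(prefix, "_conv1"), "conv", c(3, 3), 2L, in_ch, out_ch, input),
      L(paste0(prefix, "_bn1"), "bn", in_ch = out_ch, out_ch = out_ch,
        inputs = paste0(prefix, "_conv1")),
      L(paste0(prefix, "_relu1"), "relu", in_ch = out_ch, out_ch = out_ch,
        inputs = paste0(prefix, "_bn1")),
      L(paste0(prefix, "_conv2"), "conv", c(3, 3), 1L, out_ch, out_ch,
        paste0(prefix, "_relu1")),
      L(paste0(prefix, "_bn2"), "bn", in_ch = out_ch, out_ch = out_ch,
        inputs = paste0(prefix, "_conv2")),
      L(paste0(prefix, "_skip_conv"), "conv", c(1, 1), 2L, in_ch, out_ch, input),
      L(paste0(prefix, "_skip_bn"), "bn", in_ch = out_ch, out_ch = out_ch,
        inputs = paste0(prefix, "_skip_conv")),
      L(paste0(prefix, "_add"), "add", in_ch = out_ch, out_ch = out_ch,
        inputs = c(paste0(prefix, "_bn2"), paste0(prefix, "_skip_bn"))),
      L(paste0(prefix, "_relu2"), "relu", in_ch = out_ch, out_ch = out_ch,
        inputs = paste0(prefix, "_add"))
    )
  }
  plan <- c(
    list(
      L("input", "input", in_ch = 1L, out_ch = 1L),
      L("stem_conv", "conv", c(7, 7), 1L, 1L, 32L, "input"),
      L("stem_bn", "bn", in_ch = 32L, out_ch = 32L, inputs = "stem_conv"),
      L("stem_relu", "relu", in_ch = 32L, out_ch = 32L, inputs = "stem_bn"),
      L("pool", "maxpool", c(2, 2), 2L, 32L, 32L, "stem_relu")
    ),
    res_block("rb1", 32L, 64L, "pool"),
    res_block("rb2", 64L, 128L, "rb1_relu2"),
    list(
      L("bott_conv", "conv", c(1, 1), 1L, 128L, 128L, "rb2_relu2"),
      L("bott_bn", "bn", in_ch = 128L, out_ch = 128L, inputs = "bott_conv"),
      L("bott_relu", "relu", in_ch = 128L, out_ch = 128L, inputs = "bott_bn"),
      L("up1_tconv", "tconv", c(4, 4), 2L, 128L, 64L, "bott_relu"),
      L("up1_bn", "bn", in_ch = 64L, out_ch = 64L, inputs = "up1_tconv"),
      L("up1_relu", "relu", in_ch = 64L, out_ch = 64L, inputs = "up1_bn"),
      L("up2_tconv", "tconv", c(4, 4), 2L, 64L, 64L, "up1_relu"),
      L("up2_bn", "bn", in_ch = 64L, out_ch = 64L, inputs = "up2_tconv"),
      L("up2_relu", "relu", in_ch = 64L, out_ch = 64L, inputs = "up2_bn"),
      L("up3_tconv", "tconv", c(4, 4), 2L, 64L, 32L, "up2_relu"),
      L("concat", "concat", in_ch = 64L, out_ch = 64L,
        inputs = c("up3_tconv", "stem_relu")),
      L("head1_conv", "conv", c(3, 3), 1L, 64L, 32L, "concat"),
      L("head1_bn", "bn", in_ch = 32L, out_ch = 32L, inputs = "head1_conv"),
      L("head1_relu", "relu", in_ch = 32L, out_ch = 32L, inputs = "head1_bn"),
      L("head2_conv", "conv", c(3, 3), 1L, 32L, 32L, "head2_input_placeholder"),
      L("head2_bn", "bn", in_ch = 32L, out_ch = 32L, inputs = "head2_conv"),
      L("head2_relu", "relu", in_ch = 32L, out_ch = 32L, inputs = "head2_bn"),
      L("final_conv", "conv", c(1, 1), 1L, 32L, 2L, "head2_relu"),
      L("softmax", "softmax", in_ch = 2L, out_ch = 2L, inputs = "final_conv")
    )
  )
  # fix the head2 input reference
  for (i in seq_along(plan)) {
    if (plan[[i]]$name == "head2_conv") plan[[i]]$inputs <- "head1_relu"
  }
  names(plan) <- vapply(plan, `[[`, character(1), "name")
  structure(list(input_height = as.integer(input_height),
                 input_width = as.integer(input_width),
                 stem_filters = 32L, stage_filters = c(64L, 128L),
                 n_classes = 2L, layer_plan = plan),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("segmentation network spec: %d x %d input, %d layers, %s parameters\n",
              x$input_height, x$input_width, length(x$layer_plan),
              format(count_parameters(x), big.mark = ",")))
  for (ly in x$layer_plan) {
    kern <- if (!is.na(ly$kernel[1])) sprintf(" %dx%d", ly$kernel[1], ly$kernel[2]) else ""
    cat(sprintf("  %-14s %-8s%s stride %d  %s -> %s ch%s\n", ly$name, ly$kind,
                kern, ly$stride, ly$in_channels, ly$out_channels,
                if (length(ly$inputs)) paste0("  (from ", paste(ly$inputs, collapse = ", "), ")") else ""))
  }
  invisible(x)
}

#' Count learnable parameters of a network plan
#'
#' Deterministic closed-form total of weights and biases: convolution and
#' transposed-convolution layers contribute `kh * kw * in * out + out`, batch
#' norm layers contribute `2 * channels` (scale and shift). Independent of
#' input size (convolutional weight sharing).
#'
#' @param spec a [build_reference_spec()] plan.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  assert_that(inherits(spec, "network_spec"), "spec must be a network_spec")
  total <- 0
  for (ly in spec$layer_plan) {
    total <- total + switch(ly$kind,
      conv = ,
      tconv = prod(ly$kernel) * ly$in_channels * ly$out_channels + ly$out_channels,
      bn = 2 * ly$out_channels,
      0)
  }
  as.integer(total)
}

#' Serialize / restore a network spec as structured text
#'
#' @param spec a `network_spec`.
#' @param path YAML file path.
#' @return `write_network_spec()` returns `path` invisibly;
#'   `read_network_spec()` returns the restored `network_spec`.
#' @export
write_network_spec <- function(spec, path) {
  assert_that(inherits(spec, "network_spec"), "spec must be a network_spec")
  yaml::write_yaml(list(input_height = spec$input_height,
                        input_width = spec$input_width), path)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  v <- yaml::read_yaml(path)
  build_reference_spec(v$input_height, v$input_width)
}
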