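#' Network configuration
#'
#' @param input_side square input side in pixels; must be divisible by 16 so
#'   the bottleneck at side/16 is integral.  384 for disc segmentation,
#'   256 for cup segmentation by default.
#' @param base_width channels at the finest level; doubled at each of the four
#'   downsamplings.  16 for real use; 4 gives a fast test-scale network.
#' @param seed integer seed for weight initialisation.
#' @return a list of class `msmku_config`.
#' @export
msmku_config <- function(input_side = 384L, base_width = 16L, seed = 1L) {
  if (input_side %% 16 != 0)
    stop("input_side must be divisible by 16")
  if (base_width < 2) stop("base_width must be >= 2")
  structure(list(input_side = as.integer(input_side),
                 base_width = as.integer(base_width),
                 pyramid_levels = 4L,
                 seed = as.integer(seed)),
            class = "msmku_config")
}

#' Image pyramid for the multi-scale contracting path
#'
#' Level 1 is the input unchanged; levels 2-4 are bilinear reductions to
#' 1/2, 1/4 and 1/8 of the side.
#'
#' @param X image array `H x W x 3` with `H`, `W` divisible by 8.
#' @return list of four image arrays.
#' @export
build_image_pyramid <- function(X) {
  d <- dim(X)
  if (d[1] %% 8 != 0 || d[2] %% 8 != 0)
    stop("pyramid input sides must be divisible by 8")
  X2 <- downsample2(X)
  X3 <- downsample2(X2)
  list(X, X2, X3, downsample2(X3))
}

# bilinear x1/2 reduction; with half-pixel-centre sampling this is exactly
# the mean of each 2x2 block
downsample2 <- function(x) {
  d <- dim(x)
  ro <- seq(1, d[1], by = 2)
  re <- seq(2, d[1], by = 2)
  x <- (x[ro, , , drop = FALSE] + x[re, , , drop = FALSE]) / 2
  co <- seq(1, d[2], by = 2)
  ce <- seq(2, d[2], by = 2)
  (x[, co, , drop = FALSE] + x[, ce, , drop = FALSE]) / 2
}

# multi-kernel residual module: three parallel 3x3 branches and one branch of
# two successive 4x4 convolutions, channel-concatenated, fused by a 1x1
# convolution + ReLU + batch norm, with an additive short connection from the
# module input (1x1 projection when depths differ).
new_mk_module <- function(cin, cout) {
  list(b1 = new_conv(3, 3, cin, cout, act = "none"),
       b2 = new_conv(3, 3, cin, cout, act = "none"),
       b3 = new_conv(3, 3, cin, cout, act = "none"),
       b4a = new_conv(4, 4, cin, cout, act = "none"),
       b4b = new_conv(4, 4, cout, cout, act = "none"),
       fuse = new_conv(1, 1, 4 * cout, cout, act = "relu"),
       bn = new_bn(cout),
       proj = if (cin != cout) new_conv(1, 1, cin, cout, act = "none"))
}

mk_forward <- function(M, xs, training) {
  y1 <- conv_forward(M$b1, xs, training)
  y2 <- conv_forward(M$b2, xs, training)
  y3 <- conv_forward(M$b3, xs, training)
  y4 <- conv_forward(M$b4b, conv_forward(M$b4a, xs, training), training)
  z <- conv_forward(M$fuse, concat_channels(list(y1, y2, y3, y4)), training)
  o <- bn_forward(M$bn, z, training)
  short <- if (is.null(M$proj)) xs else conv_forward(M$proj, xs, training)
  batch_add(o, short)
}

mk_backward <- function(M, dys) {
  dshort <- if (is.null(M$proj)) dys else conv_backward(M$proj, dys)
  dz <- bn_backward(M$bn, dys)
  dcat <- conv_backward(M$fuse, dz)
  cout <- M$bn$c
  parts <- split_channels(dcat, rep(cout, 4))
  dx <- conv_backward(M$b1, parts[[1]])
  dx <- batch_add(dx, conv_backward(M$b2, parts[[2]]))
  dx <- batch_add(dx, conv_backward(M$b3, parts[[3]]))
  dx <- batch_add(dx, conv_backward(M$b4a, conv_backward(M$b4b, parts[[4]])))
  batch_add(dx, dshort)
}

#' Build the multi-scale multi-kernel U-shaped segmentation network
#'
#' Contracting path: the four pyramid levels enter through convolution stems
#' `f1..f4`; features are fused hierarchically by addition,
#' `F3(F2(F1(f1(X1)+f2(X2))+f3(X3))+f4(X4))`, where each `F_i` is a
#' multi-kernel module followed by a strided convolution (no pooling
#' anywhere), giving a bottleneck of side `input_side/16`.  Expanding path:
#' four stages of convolution + linear x2 up-sampling with additive skip
#' connections from the pre-strided module outputs, then a 1x1 convolution
#' and sigmoid producing a probability map at full input size.
#'
#' @param config an [msmku_config()].
#' @return an object of class `msmku` (environment with layers and config).
#' @export
build_msmku <- function(config = msmku_config()) {
  stopifnot(inherits(config, "msmku_config"))
  set.seed(config$seed)
  b <- config$base_width
  w1 <- b; w2 <- 2L * b; w3 <- 4L * b; w4 <- 8L * b
  layers <- list(
    f1c = new_conv(3, 3, 3, w1),
    f1s = new_conv(3, 3, w1, w1, stride = 2L),
    f2c = new_conv(3, 3, 3, w1),
    mk1 = new_mk_module(w1, w1),
    F1s = new_conv(3, 3, w1, w2, stride = 2L),
    f3c = new_conv(3, 3, 3, w2),
    mk2 = new_mk_module(w2, w2),
    F2s = new_conv(3, 3, w2, w3, stride = 2L),
    f4c = new_conv(3, 3, 3, w3),
    mk3 = new_mk_module(w3, w3),
    F3s = new_conv(3, 3, w3, w4, stride = 2L),
    u3c = new_conv(3, 3, w4, w3),
    u2c = new_conv(3, 3, w3, w2),
    u1c = new_conv(3, 3, w2, w1),
    u0c = new_conv(3, 3, w1, w1),
    head = new_conv(1, 1, w1, 1, act = "none"))
  net <- new.env(parent = emptyenv())
  net$config <- config
  net$layers <- layers
  net$param_refs <- collect_param_refs(layers)
  class(net) <- "msmku"
  net
}

# Forward pass over a batch (list of side x side x 3 arrays).  Returns a list
# of probability matrices.  With training = TRUE all caches needed by
# msmku_backward are retained and batch-norm uses batch statistics.
# Precomputed pyramids (list per sample, from build_image_pyramid) may be
# passed to avoid rebuilding them for unchanged training images.
msmku_forward <- function(net, xs, training = FALSE, pyramids = NULL) {
  side <- net$config$input_side
  if (is.null(pyramids)) {
    for (x in xs) {
      d <- dim(x)
      if (d[1] != side || d[2] != side || d[3] != 3)
        stop(sprintf("input must be %d x %d x 3", side, side))
    }
    pyramids <- lapply(xs, build_image_pyramid)
  }
  L <- net$layers
  X <- lapply(1:4, function(k) lapply(pyramids, `[[`, k))

  S0 <- conv_forward(L$f1c, X[[1]], training)
  A1 <- batch_add(conv_forward(L$f1s, S0, training),
                  conv_forward(L$f2c, X[[2]], training))
  M1 <- mk_forward(L$mk1, A1, training)
  A2 <- batch_add(conv_forward(L$F1s, M1, training),
                  conv_forward(L$f3c, X[[3]], training))
  M2 <- mk_forward(L$mk2, A2, training)
  A3 <- batch_add(conv_forward(L$F2s, M2, training),
                  conv_forward(L$f4c, X[[4]], training))
  M3 <- mk_forward(L$mk3, A3, training)
  B <- conv_forward(L$F3s, M3, training)

  # expanding path; net$no_skips (inference-only diagnostic) severs the
  # additive skip connections so their contribution can be inspected
  sk <- if (isTRUE(net$no_skips)) function(a, b) a else batch_add
  D3 <- sk(upsample2_fwd(conv_forward(L$u3c, B, training)), M3)
  D2 <- sk(upsample2_fwd(conv_forward(L$u2c, D3, training)), M2)
  D1 <- sk(upsample2_fwd(conv_forward(L$u1c, D2, training)), M1)
  D0 <- sk(upsample2_fwd(conv_forward(L$u0c, D1, training)), S0)
  Z <- conv_forward(L$head, D0, training)
  P <- lapply(Z, function(z) 1 / (1 + exp(-z[, , 1])))
  if (training) net$P <- P
  P
}

# Backward pass; dPs is a list of matrices dLoss/dP.  Accumulates parameter
# gradients in the layers.  Must follow msmku_forward(..., training = TRUE).
msmku_backward <- function(net, dPs) {
  L <- net$layers
  dZ <- Map(function(dp, p) {
    g <- dp * p * (1 - p)
    array(g, c(dim(g), 1L))
  }, dPs, net$P)
  dD0 <- conv_backward(L$head, dZ)
  dD1 <- conv_backward(L$u0c, upsample2_bwd(dD0))
  dM1_skip <- dD1
  dD2 <- conv_backward(L$u1c, upsample2_bwd(dD1))
  dM2_skip <- dD2
  dD3 <- conv_backward(L$u2c, upsample2_bwd(dD2))
  dM3_skip <- dD3
  dB <- conv_backward(L$u3c, upsample2_bwd(dD3))
  dM3 <- batch_add(conv_backward(L$F3s, dB), dM3_skip)
  dA3 <- mk_backward(L$mk3, dM3)
  conv_backward(L$f4c, dA3)
  dM2 <- batch_add(conv_backward(L$F2s, dA3), dM2_skip)
  dA2 <- mk_backward(L$mk2, dM2)
  conv_backward(L$f3c, dA2)
  dM1 <- batch_add(conv_backward(L$F1s, dA2), dM1_skip)
  dA1 <- mk_backward(L$mk1, dM1)
  conv_backward(L$f2c, dA1)
  dS0 <- batch_add(conv_backward(L$f1s, dA1), dD0)
  conv_backward(L$f1c, dS0)
  invisible(NULL)
}

#' Multi-kernel module as a standalone operation
#'
#' Applies a freshly initialised multi-kernel residual module to a feature
#' grid; mainly useful for inspecting the module's shape contract.
#'
#' @param x feature array `H x W x C`.
#' @param out_depth output channels.
#' @param seed initialisation seed.
#' @return array `H x W x out_depth`.
#' @export
multi_kernel_module <- function(x, out_depth, seed = 1L) {
  set.seed(seed)
  M <- new_mk_module(dim(x)[3], out_depth)
  mk_forward(M, list(x), training = FALSE)[[1]]
}

#' @export
print.msmku <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "MSMKU segmentation network: input %d x %d, base width %d, %d parameters\n",
    cfg$input_side, cfg$input_side, cfg$base_width, n_params(x)))
  invisible(x)
}

n_params <- function(net) {
  sum(vapply(net$param_refs,
             function(r) length(r$layer[[r$name]]), numeric(1)))
}

#' Predict a probability map or binary mask for one image
#'
#' @param object an `msmku` network.
#' @param image array `side x side x 3` matching the configured input side.
#' @param type `"prob"` for the probability map, `"mask"` for its 0.5
#'   binarisation.
#' @param ... unused.
#' @return matrix `side x side`.
#' @export
predict.msmku <- function(object, image, type = c("prob", "mask"), ...) {
  type <- match.arg(type)
  P <- msmku_forward(object, list(image), training = FALSE)[[1]]
  if (type == "mask") binarize(P) else P
}

# deep copy of all parameters (used to snapshot/restore during training)
get_params <- function(net) lapply(net$param_refs, function(r) r$layer[[r$name]])

set_params <- function(net, params) {
  for (i in seq_along(net$param_refs)) {
    r <- net$param_refs[[i]]
    r$layer[[r$name]] <- params[[i]]
  }
  invisible(net)
}
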