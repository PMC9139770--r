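#' Standardize wave-parameter targets
#'
#' Maps (lambda, v) to z-scores using the theoretical mean \code{(a+b)/2}
#' and standard deviation \code{(b-a)/sqrt(12)} of the uniform sampling
#' distributions, so both regression targets share scale.
#'
#' @param lambda,v parameter values (vectorized).
#' @param ranges a \code{\link{sampling_ranges}}.
#' @return matrix with columns \code{z_lambda}, \code{z_v}.
#' @export
standardize_targets <- function(lambda, v, ranges = sampling_ranges()) {
  st <- target_standardization(ranges)
  cbind(z_lambda = (lambda - st$mean[1]) / st$sd[1],
        z_v = (v - st$mean[2]) / st$sd[2])
}

#' Invert the target standardization
#' @param z matrix or vector of standardized (z_lambda, z_v).
#' @param ranges a \code{\link{sampling_ranges}}.
#' @return matrix with columns \code{lambda}, \code{v}.
#' @export
destandardize_targets <- function(z, ranges = sampling_ranges()) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 2)
  st <- target_standardization(ranges)
  cbind(lambda = z[, 1] * st$sd[1] + st$mean[1],
        v = z[, 2] * st$sd[2] + st$mean[2])
}

target_standardization <- function(ranges) {
  widths <- c(diff(ranges$lambda), diff(ranges$v))
  if (any(widths <= 0)) stop("degenerate sampling range")
  list(mean = c((ranges$lambda[1] + ranges$lambda[2]) / 2,
                (ranges$v[1] + ranges$v[2]) / 2),
       sd = widths / sqrt(12))
}

# ---- layer primitives -------------------------------------------------------

# kernel extent / stride / pad are 1 / 1 / 0 along singleton spatial axes
axis_extents <- function(spatial, k, stride, pad) {
  act <- spatial > 1
  list(k = ifelse(act, k, 1L), stride = ifelse(act, stride, 1L),
       pad = ifelse(act, pad, 0L))
}

new_conv <- function(spatial, cin, cout, k, stride, pad, relu, transposed = FALSE) {
  ax <- axis_extents(spatial, k, stride, pad)
  fan_in <- prod(ax$k) * cin
  w <- array(stats::rnorm(prod(ax$k) * cin * cout, sd = sqrt(2 / fan_in)),
             dim = c(ax$k, cin, cout))
  list(type = if (transposed) "tconv" else "conv", w = w, b = numeric(cout),
       stride = as.integer(ax$stride), pad = as.integer(ax$pad), relu = relu)
}

new_dense <- function(nin, nout) {
  list(type = "dense",
       w = matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout),
       b = numeric(nout), relu = FALSE)
}

layer_forward <- function(layer, x, keep_col = FALSE) {
  if (layer$type == "dense") {
    y <- drop(crossprod(layer$w, x)) + layer$b
    return(list(y = y, x = x))
  }
  cache <- list(x = x, xdim = dim(x))
  if (layer$type == "conv") {
    if (keep_col) {
      res <- conv_fwd_col_cpp(x, dim(x), layer$w, dim(layer$w), layer$b,
                              layer$stride, layer$pad)
      y <- res$y
      cache$col <- res$col
      cache$x <- NULL     # the im2col matrix replaces the input in the cache
    } else {
      y <- conv_fwd_cpp(x, dim(x), layer$w, dim(layer$w), layer$b,
                        layer$stride, layer$pad)
    }
  } else {
    y <- tconv_fwd_cpp(x, dim(x), layer$w, dim(layer$w), layer$b,
                       layer$stride)
  }
  if (layer$relu) {
    cache$pre <- y
    y <- pmax(y, 0)
    dim(y) <- dim(cache$pre)
  }
  cache$y <- y
  cache
}

layer_backward <- function(layer, cache, dy) {
  if (layer$type == "dense") {
    return(list(dx = as.vector(layer$w %*% dy),
                dw = outer(cache$x, dy), db = dy))
  }
  if (layer$relu) {
    dy <- dy * (cache$pre > 0)
    dim(dy) <- dim(cache$pre)
  }
  if (layer$type == "conv") {
    if (!is.null(cache$col))
      g <- conv_bwd_col_cpp(cache$col, cache$xdim, layer$w, dim(layer$w),
                            layer$stride, layer$pad, dy)
    else
      g <- conv_bwd_cpp(cache$x, cache$xdim, layer$w, dim(layer$w),
                        layer$stride, layer$pad, dy)
  } else {
    g <- tconv_bwd_cpp(cache$x, cache$xdim, layer$w, dim(layer$w),
                       layer$stride, dy)
  }
  g
}

# ---- parameter-estimation network ------------------------------------------

#' Specification of the parameter-estimation network
#'
#' A convolutional encoder: \code{n_blocks} down-sampling blocks (two 3x3
#' stride-1 convolutions with bias and ReLU, then a 2x2 stride-2
#' convolution), whose terminal feature map is flattened and concatenated
#' with the scalar imaging interval dt2 before a fully connected layer
#' merges it into 2 outputs (standardized lambda and v). At the full scale
#' of 192 x 192 x 128 input with 6 blocks ending in 8 channels, the
#' pre-output vector has 3*3*2*8 + 1 = 145 components.
#'
#' @param input_shape spatial input dimensions (2 or 3 values; 2D inputs
#'   get a singleton third axis).
#' @param channels input channels (3 contours + 6 tensor components).
#' @param widths convolution width per block; the last entry is the
#'   terminal channel count (8 at full scale).
#' @return list of class \code{parameter_network_spec}; element
#'   \code{pre_output_length} gives the flattened-plus-interval vector
#'   length.
#' @export
parameter_network_spec <- function(input_shape = c(192, 192, 128),
                                   channels = 9,
                                   widths = c(32, 32, 16, 16, 8, 8)) {
  if (length(input_shape) == 2) input_shape <- c(input_shape, 1L)
  input_shape <- as.integer(input_shape)
  n_blocks <- length(widths)
  act <- input_shape > 1
  div <- 2^n_blocks
  if (any(input_shape[act] %% div != 0))
    stop("spatial dims must be divisible by 2^", n_blocks, " = ", div)
  terminal <- ifelse(act, input_shape %/% div, 1L)
  structure(list(input_shape = input_shape, channels = channels,
                 widths = as.integer(widths), n_blocks = n_blocks,
                 terminal_shape = terminal,
                 pre_output_length = as.integer(prod(terminal) *
                                                  widths[n_blocks] + 1L)),
            class = "parameter_network_spec")
}

#' Build the parameter-estimation network
#'
#' @param spec a \code{\link{parameter_network_spec}}.
#' @param seed RNG seed for weight initialization.
#' @return model of class \code{parameter_network}.
#' @export
build_parameter_network <- function(spec = parameter_network_spec(),
                                    seed = 0) {
  with_seed(seed, {
    layers <- list()
    spatial <- spec$input_shape
    cin <- spec$channels
    for (b in seq_len(spec$n_blocks)) {
      w <- spec$widths[b]
      layers[[length(layers) + 1]] <- new_conv(spatial, cin, w, 3L, 1L, 1L, TRUE)
      layers[[length(layers) + 1]] <- new_conv(spatial, w, w, 3L, 1L, 1L, TRUE)
      layers[[length(layers) + 1]] <- new_conv(spatial, w, w, 2L, 2L, 0L, FALSE)
      spatial <- ifelse(spatial > 1, spatial %/% 2L, 1L)
      cin <- w
    }
    layers[[length(layers) + 1]] <- new_dense(spec$pre_output_length, 2L)
    structure(list(spec = spec, layers = layers),
              class = "parameter_network")
  })
}

#' @export
print.parameter_network <- function(x, ...) {
  cat("Parameter-estimation network: input ",
      paste(x$spec$input_shape, collapse = " x "), " x ", x$spec$channels,
      " channels, ", x$spec$n_blocks, " down blocks, pre-output vector of ",
      x$spec$pre_output_length, " components, ",
      sum(vapply(x$layers, function(l) length(l$w) + length(l$b), 0)),
      " weights\n", sep = "")
  invisible(x)
}

forward_parameter_network <- function(model, x, dt2, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  n <- length(model$layers)
  h <- x
  for (i in seq_len(n - 1)) {
    cc <- layer_forward(model$layers[[i]], h, keep_col = keep_cache)
    h <- cc$y
    if (keep_cache) caches[[i]] <- cc
  }
  flat <- c(as.vector(h), dt2)
  cc <- layer_forward(model$layers[[n]], flat)
  if (keep_cache) caches[[n]] <- cc
  list(y = cc$y, caches = caches, feat_dim = dim(h))
}

backward_parameter_network <- function(model, fwd, dy) {
  n <- length(model$layers)
  grads <- vector("list", n)
  g <- layer_backward(model$layers[[n]], fwd$caches[[n]], dy)
  grads[[n]] <- g[c("dw", "db")]
  dflat <- g$dx
  dh <- dflat[-length(dflat)]          # drop the dt2 slot
  dim(dh) <- fwd$feat_dim
  for (i in rev(seq_len(n - 1))) {
    g <- layer_backward(model$layers[[i]], fwd$caches[[i]], dh)
    grads[[i]] <- g[c("dw", "db")]
    dh <- g$dx
  }
  grads
}

# ---- density-estimation network --------------------------------------------

#' Specification of the density-reconstruction U-Net
#'
#' Encoder-decoder with skip connections: \code{depth} down-sampling blocks
#' (two 3x3 stride-1 convolutions with ReLU, then a 2x2 stride-2
#' convolution), \code{depth} up-sampling blocks (two convolutions, then a
#' 2x2 stride-2 transposed convolution with ReLU), and an output block (two
#' convolutions and a 1x1 convolution with no activation merging the last
#' \code{base_width} feature maps into one density channel). The output of
#' each down block's second ReLU is concatenated to the input of the
#' decoder stage with matching spatial dimensions.
#'
#' @param input_shape spatial dimensions, divisible by \code{2^depth} along
#'   non-singleton axes.
#' @param channels input channels (2 contours + 6 tensor components).
#' @param depth number of down/up block pairs.
#' @param base_width channels of the first block, doubling per level.
#' @return list of class \code{density_network_spec}.
#' @export
density_network_spec <- function(input_shape = c(192, 192, 128),
                                 channels = 8, depth = 4, base_width = 32) {
  if (length(input_shape) == 2) input_shape <- c(input_shape, 1L)
  input_shape <- as.integer(input_shape)
  act <- input_shape > 1
  if (any(input_shape[act] %% (2^depth) != 0))
    stop("spatial dims must be divisible by 2^", depth, " = ", 2^depth)
  structure(list(input_shape = input_shape, channels = channels,
                 depth = depth, base_width = as.integer(base_width)),
            class = "density_network_spec")
}

#' Build the density-reconstruction U-Net
#' @param spec a \code{\link{density_network_spec}}.
#' @param seed RNG seed for weight initialization.
#' @return model of class \code{density_network}.
#' @export
build_density_network <- function(spec = density_network_spec(), seed = 0) {
  with_seed(seed, {
    d <- spec$depth
    wd <- spec$base_width * 2^(0:(d - 1))     # down widths per level
    down <- vector("list", d)
    spatial <- spec$input_shape
    cin <- spec$channels
    for (b in seq_len(d)) {
      down[[b]] <- list(
        new_conv(spatial, cin, wd[b], 3L, 1L, 1L, TRUE),
        new_conv(spatial, wd[b], wd[b], 3L, 1L, 1L, TRUE),
        new_conv(spatial, wd[b], wd[b], 2L, 2L, 0L, FALSE))
      spatial <- ifelse(spatial > 1, spatial %/% 2L, 1L)
      cin <- wd[b]
    }
    up <- vector("list", d)
    for (b in seq_len(d)) {
      # up block b runs at the resolution of down level d - b + 1's output
      wu <- spec$base_width * 2^(d - b + 1)   # conv width (bottleneck 2^d w)
      wout <- wu / 2                          # channels after up-sampling
      up[[b]] <- list(
        new_conv(spatial, cin, wu, 3L, 1L, 1L, TRUE),
        new_conv(spatial, wu, wu, 3L, 1L, 1L, TRUE),
        new_conv(spatial, wu, wout, 2L, 2L, 0L, TRUE, transposed = TRUE))
      spatial <- ifelse(spec$input_shape > 1, spatial * 2L, 1L)
      cin <- wout + wd[d - b + 1]             # concat with the skip
    }
    out_block <- list(
      new_conv(spatial, cin, spec$base_width, 3L, 1L, 1L, TRUE),
      new_conv(spatial, spec$base_width, spec$base_width, 3L, 1L, 1L, TRUE),
      new_conv(spatial, spec$base_width, 1L, 1L, 1L, 0L, FALSE))
    structure(list(spec = spec, down = down, up = up, out = out_block),
              class = "density_network")
  })
}

#' @export
print.density_network <- function(x, ...) {
  np <- 0
  for (blk in c(x$down, x$up, list(x$out)))
    for (l in blk) np <- np + length(l$w) + length(l$b)
  cat("Density-reconstruction U-Net: input ",
      paste(x$spec$input_shape, collapse = " x "), " x ", x$spec$channels,
      " channels, depth ", x$spec$depth, ", base width ", x$spec$base_width,
      ", ", np, " weights\n", sep = "")
  invisible(x)
}

forward_density_network <- function(model, x, keep_cache = FALSE) {
  d <- model$spec$depth
  caches <- list(down = vector("list", d), up = vector("list", d),
                 out = NULL, skips = vector("list", d))
  h <- x
  for (b in seq_len(d)) {
    c1 <- layer_forward(model$down[[b]][[1]], h, keep_col = keep_cache)
    c2 <- layer_forward(model$down[[b]][[2]], c1$y, keep_col = keep_cache)
    caches$skips[[b]] <- dim(c2$y)
    skip <- c2$y
    c3 <- layer_forward(model$down[[b]][[3]], skip, keep_col = keep_cache)
    h <- c3$y
    if (keep_cache) caches$down[[b]] <- list(c1, c2, c3)
    else caches$down[[b]] <- list(skip = skip)
    caches$down[[b]]$skip <- skip
  }
  for (b in seq_len(d)) {
    c1 <- layer_forward(model$up[[b]][[1]], h, keep_col = keep_cache)
    c2 <- layer_forward(model$up[[b]][[2]], c1$y, keep_col = keep_cache)
    c3 <- layer_forward(model$up[[b]][[3]], c2$y)
    skip <- caches$down[[d - b + 1]]$skip
    h <- abind4(c3$y, skip)
    if (keep_cache) caches$up[[b]] <- list(c1, c2, c3, nup = dim(c3$y)[4])
  }
  c1 <- layer_forward(model$out[[1]], h, keep_col = keep_cache)
  c2 <- layer_forward(model$out[[2]], c1$y, keep_col = keep_cache)
  c3 <- layer_forward(model$out[[3]], c2$y, keep_col = keep_cache)
  if (keep_cache) caches$out <- list(c1, c2, c3)
  list(y = c3$y, caches = caches)
}

# concatenate two (x, y, z, c) arrays along channels
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

backward_density_network <- function(model, fwd, dy) {
  d <- model$spec$depth
  caches <- fwd$caches
  grads <- list(down = vector("list", d), up = vector("list", d), out = NULL)
  g3 <- layer_backward(model$out[[3]], caches$out[[3]], dy)
  g2 <- layer_backward(model$out[[2]], caches$out[[2]], g3$dx)
  g1 <- layer_backward(model$out[[1]], caches$out[[1]], g2$dx)
  grads$out <- list(g1[c("dw", "db")], g2[c("dw", "db")], g3[c("dw", "db")])
  dh <- g1$dx
  dskip <- vector("list", d)    # gradient flowing into each down skip
  for (b in rev(seq_len(d))) {
    cc <- caches$up[[b]]
    nup <- cc$nup
    dup <- dh[, , , seq_len(nup), drop = FALSE]
    dskip[[d - b + 1]] <- dh[, , , -seq_len(nup), drop = FALSE]
    g3 <- layer_backward(model$up[[b]][[3]], cc[[3]], dup)
    g2 <- layer_backward(model$up[[b]][[2]], cc[[2]], g3$dx)
    g1 <- layer_backward(model$up[[b]][[1]], cc[[1]], g2$dx)
    grads$up[[b]] <- list(g1[c("dw", "db")], g2[c("dw", "db")],
                          g3[c("dw", "db")])
    dh <- g1$dx
  }
  for (b in rev(seq_len(d))) {
    cc <- caches$down[[b]]
    g3 <- layer_backward(model$down[[b]][[3]], cc[[3]], dh)
    dskip_b <- g3$dx + dskip[[b]]
    g2 <- layer_backward(model$down[[b]][[2]], cc[[2]], dskip_b)
    g1 <- layer_backward(model$down[[b]][[1]], cc[[1]], g2$dx)
    grads$down[[b]] <- list(g1[c("dw", "db")], g2[c("dw", "db")],
                            g3[c("dw", "db")])
    dh <- g1$dx
  }
  grads
}
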