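# Architecture contracts: a compact 2D U-net segmentation generator and a
# shallow residual encoder-decoder (U-ResNet style) discriminator with a
# voxel-wise two-class softmax head. Forward and backward passes are written
# out explicitly per architecture.

#' Generator architecture specification
#'
#' A 2D U-net with eight convolutional layers (two per resolution level on
#' the way down, a bottleneck, two decoder convolutions with skip
#' connections, and a 1x1 softmax head), batch normalisation, relu and
#' dropout. Input spatial dimensions must be divisible by 4 (two pooling
#' levels).
#'
#' @param out_classes K + 1 output classes (K organs + background).
#' @param in_channels Number of image channels (default 1).
#' @param base_filters Filters in the first level; deeper levels double it.
#' @param dropout_rate Dropout rate on the two decoder blocks.
#' @param norm Use batch normalisation.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(out_classes, in_channels = 1L, base_filters = 16L,
                           dropout_rate = 0.2, norm = TRUE) {
  stopifnot(out_classes >= 2, in_channels >= 1, base_filters >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(
    in_channels = as.integer(in_channels),
    out_classes = as.integer(out_classes),
    n_conv_layers = 8L,
    base_filters = as.integer(base_filters),
    dropout_rate = dropout_rate,
    norm = isTRUE(norm)
  ), class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' A shallow two-level encoder-decoder with residual blocks and a voxel-wise
#' two-class softmax output (correct vs error). Input channels are the K
#' organ masks followed by the image as the final channel.
#'
#' @param in_channels K + 1 (K organ masks + image last).
#' @param base_filters Filters per level.
#' @param n_residual_blocks Residual blocks (one per level; default 2).
#' @param norm Use batch normalisation inside residual blocks (default
#'   FALSE; keeps mixed gold-standard/generated batches stable).
#' @return A `discriminator_spec` list.
#' @export
discriminator_spec <- function(in_channels, base_filters = 16L,
                               n_residual_blocks = 2L, norm = FALSE) {
  stopifnot(in_channels >= 2, base_filters >= 1, n_residual_blocks == 2L)
  structure(list(
    in_channels = as.integer(in_channels),
    out_classes = 2L,
    base_filters = as.integer(base_filters),
    n_residual_blocks = 2L,
    depth = 2L,
    norm = isTRUE(norm)
  ), class = "discriminator_spec")
}

new_bn_params <- function(model, name, c_out) {
  bn <- bn_init(c_out)
  model$params[[paste0(name, ".gamma")]] <- bn$gamma
  model$params[[paste0(name, ".beta")]] <- bn$beta
  model$bn[[name]] <- list(run_mean = bn$run_mean, run_var = bn$run_var)
  model
}

new_conv_params <- function(model, name, c_in, c_out, k) {
  par <- conv_init(c_in, c_out, k)
  model$params[[paste0(name, ".W")]] <- par$W
  model$params[[paste0(name, ".b")]] <- par$b
  model
}

conv_par <- function(model, name) {
  list(W = model$params[[paste0(name, ".W")]],
       b = model$params[[paste0(name, ".b")]])
}

bn_par <- function(model, name) {
  list(gamma = model$params[[paste0(name, ".gamma")]],
       beta = model$params[[paste0(name, ".beta")]],
       run_mean = model$bn[[name]]$run_mean,
       run_var = model$bn[[name]]$run_var)
}

#' Build a generator model with randomly initialised weights
#'
#' @param spec [generator_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return A `generator_model`.
#' @export
build_generator <- function(spec, seed = 1L) {
  f <- spec$base_filters
  k1 <- spec$out_classes
  model <- structure(list(spec = spec, params = list(), bn = list(),
                          type = "generator"),
                     class = "generator_model")
  with_seed(seed, {
    model <- new_conv_params(model, "c1", spec$in_channels, f, 3L)
    model <- new_conv_params(model, "c2", f, f, 3L)
    model <- new_conv_params(model, "c3", f, 2L * f, 3L)
    model <- new_conv_params(model, "c4", 2L * f, 2L * f, 3L)
    model <- new_conv_params(model, "c5", 4L * f, 2L * f, 3L)
    model <- new_conv_params(model, "c6", 3L * f, f, 3L)
    model <- new_conv_params(model, "c7", f, f, 3L)
    model <- new_conv_params(model, "c8", f, k1, 1L)
  })
  if (spec$norm) {
    widths <- c(f, f, 2L * f, 2L * f, 2L * f, f, f)
    for (i in seq_along(widths)) {
      model <- new_bn_params(model, paste0("bn", i), widths[i])
    }
  }
  model
}

# conv (+ optional bn) + relu block used by both networks.
cbr_fwd <- function(x, model, cname, bname, train, k = 3L, act = TRUE) {
  cv <- conv_fwd(x, conv_par(model, cname), k)
  cache <- list(conv = cv$cache, bn = NULL, relu = NULL)
  y <- cv$y
  if (!is.null(bname) && model$spec$norm) {
    bn <- bn_fwd(y, bn_par(model, bname), train)
    if (!is.null(bn$running)) model$bn[[bname]] <- bn$running
    y <- bn$y
    cache$bn <- bn$cache
  }
  if (act) {
    rl <- relu_fwd(y)
    y <- rl$y
    cache$relu <- rl$cache
  }
  list(y = y, cache = cache, model = model)
}

cbr_bwd <- function(dy, cache, model, cname, bname, grads) {
  if (!is.null(cache$relu)) dy <- relu_bwd(dy, cache$relu)
  if (!is.null(cache$bn)) {
    bb <- bn_bwd(dy, cache$bn, bn_par(model, bname))
    grads[[paste0(bname, ".gamma")]] <- bb$dgamma
    grads[[paste0(bname, ".beta")]] <- bb$dbeta
    dy <- bb$dx
  }
  cb <- conv_bwd(dy, cache$conv, conv_par(model, cname))
  grads[[paste0(cname, ".W")]] <- cb$dW
  grads[[paste0(cname, ".b")]] <- cb$db
  cb$dx
}

check_spatial <- function(x, divisor = 4L) {
  d <- dim(x)
  if (d[1] %% divisor != 0 || d[2] %% divisor != 0) {
    abort(sprintf("spatial size %dx%d must be divisible by %d.",
                  d[1], d[2], divisor))
  }
}

# x: (H, W, N, in_channels). Returns probs (H, W, N, K+1) plus caches.
generator_forward <- function(model, x, train = FALSE) {
  check_spatial(x)
  spec <- model$spec
  ca <- list()
  s1 <- cbr_fwd(x, model, "c1", "bn1", train); model <- s1$model
  s2 <- cbr_fwd(s1$y, model, "c2", "bn2", train); model <- s2$model
  p1 <- pool_fwd(s2$y)
  s3 <- cbr_fwd(p1$y, model, "c3", "bn3", train); model <- s3$model
  p2 <- pool_fwd(s3$y)
  s4 <- cbr_fwd(p2$y, model, "c4", "bn4", train); model <- s4$model
  u1 <- up_fwd(s4$y)
  cat1 <- concat_channels(u1$y, s3$y)
  s5 <- cbr_fwd(cat1, model, "c5", "bn5", train); model <- s5$model
  d5 <- dropout_fwd(s5$y, spec$dropout_rate, train)
  u2 <- up_fwd(d5$y)
  cat2 <- concat_channels(u2$y, s2$y)
  s6 <- cbr_fwd(cat2, model, "c6", "bn6", train); model <- s6$model
  d6 <- dropout_fwd(s6$y, spec$dropout_rate, train)
  s7 <- cbr_fwd(d6$y, model, "c7", "bn7", train); model <- s7$model
  s8 <- conv_fwd(s7$y, conv_par(model, "c8"), 1L)
  probs <- softmax_fwd(s8$y)
  list(
    probs = probs, model = model,
    cache = list(s1 = s1$cache, s2 = s2$cache, p1 = p1$cache, s3 = s3$cache,
                 p2 = p2$cache, s4 = s4$cache, u1d = dim(s4$y),
                 s5 = s5$cache, d5 = d5$cache, u2d = dim(d5$y),
                 s6 = s6$cache, d6 = d6$cache, s7 = s7$cache, s8 = s8$cache,
                 f = spec$base_filters)
  )
}

# dz: gradient at the softmax logits, (H, W, N, K+1). Returns named grads.
generator_backward <- function(model, cache, dz) {
  grads <- new.env(parent = emptyenv())
  f <- cache$f
  cb8 <- conv_bwd(dz, cache$s8, conv_par(model, "c8"))
  grads[["c8.W"]] <- cb8$dW; grads[["c8.b"]] <- cb8$db
  da7 <- cb8$dx
  da6 <- cbr_bwd(da7, cache$s7, model, "c7", "bn7", grads)
  da6 <- dropout_bwd(da6, cache$d6)
  dcat2 <- cbr_bwd(da6, cache$s6, model, "c6", "bn6", grads)
  sp2 <- split_channels(dcat2, 2L * f)
  da5 <- up_bwd(sp2[[1]], cache$u2d)
  da5 <- dropout_bwd(da5, cache$d5)
  dcat1 <- cbr_bwd(da5, cache$s5, model, "c5", "bn5", grads)
  sp1 <- split_channels(dcat1, 2L * f)
  da4 <- up_bwd(sp1[[1]], cache$u1d)
  dp2 <- cbr_bwd(da4, cache$s4, model, "c4", "bn4", grads)
  da3 <- pool_bwd(dp2, cache$p2) + sp1[[2]]
  dp1 <- cbr_bwd(da3, cache$s3, model, "c3", "bn3", grads)
  da2 <- pool_bwd(dp1, cache$p1) + sp2[[2]]
  da1 <- cbr_bwd(da2, cache$s2, model, "c2", "bn2", grads)
  cbr_bwd(da1, cache$s1, model, "c1", "bn1", grads)
  as.list(grads)
}

#' Build a discriminator model with randomly initialised weights
#'
#' @param spec [discriminator_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return A `discriminator_model`.
#' @export
build_discriminator <- function(spec, seed = 1L) {
  f <- spec$base_filters
  model <- structure(list(spec = spec, params = list(), bn = list(),
                          type = "discriminator"),
                     class = "discriminator_model")
  with_seed(seed, {
    model <- new_conv_params(model, "d0", spec$in_channels, f, 3L)
    model <- new_conv_params(model, "r1a", f, f, 3L)
    model <- new_conv_params(model, "r1b", f, f, 3L)
    model <- new_conv_params(model, "r2a", f, f, 3L)
    model <- new_conv_params(model, "r2b", f, f, 3L)
    model <- new_conv_params(model, "fuse", 2L * f, f, 3L)
    model <- new_conv_params(model, "out", f, 2L, 1L)
  })
  # both residual blocks operate at the pooled level; full resolution
  # carries the stem and the skip-fusion convolution only (cost-driven
  # reading of "shallow")
  if (spec$norm) {
    for (nm in c("bnr1a", "bnr1b", "bnr2a", "bnr2b")) {
      model <- new_bn_params(model, nm, f)
    }
  }
  model
}

res_fwd <- function(x, model, a, b, train) {
  sa <- cbr_fwd(x, model, a, paste0("bn", a), train); model <- sa$model
  sb <- cbr_fwd(sa$y, model, b, paste0("bn", b), train, act = FALSE)
  model <- sb$model
  rl <- relu_fwd(x + sb$y)
  list(y = rl$y, model = model,
       cache = list(a = sa$cache, b = sb$cache, relu = rl$cache))
}

res_bwd <- function(dy, cache, model, a, b, grads) {
  dy <- relu_bwd(dy, cache$relu)
  dt <- cbr_bwd(dy, cache$b, model, b, paste0("bn", b), grads)
  dx_branch <- cbr_bwd(dt, cache$a, model, a, paste0("bn", a), grads)
  dy + dx_branch
}

# x: (H, W, N, K+1) with organ-mask channels first and the image last.
discriminator_forward <- function(model, x, train = FALSE) {
  check_spatial(x, 2L)
  if (dim(x)[4] != model$spec$in_channels) {
    abort(sprintf("discriminator expects %d input channels (K masks + image), got %d.",
                  model$spec$in_channels, dim(x)[4]))
  }
  s0 <- cbr_fwd(x, model, "d0", NULL, train); model <- s0$model
  p <- pool_fwd(s0$y)
  r1 <- res_fwd(p$y, model, "r1a", "r1b", train); model <- r1$model
  r2 <- res_fwd(r1$y, model, "r2a", "r2b", train); model <- r2$model
  u <- up_fwd(r2$y)
  catd <- concat_channels(u$y, s0$y)
  s3 <- cbr_fwd(catd, model, "fuse", NULL, train); model <- s3$model
  s4 <- conv_fwd(s3$y, conv_par(model, "out"), 1L)
  probs <- softmax_fwd(s4$y)
  list(probs = probs, model = model,
       cache = list(s0 = s0$cache, p = p$cache, r1 = r1$cache,
                    r2 = r2$cache, ud = dim(r2$y), s3 = s3$cache,
                    s4 = s4$cache, f = model$spec$base_filters))
}

# Returns grads plus the gradient w.r.t. the input tensor (used for the
# generator's adversarial update).
discriminator_backward <- function(model, cache, dz) {
  grads <- new.env(parent = emptyenv())
  f <- cache$f
  cb4 <- conv_bwd(dz, cache$s4, conv_par(model, "out"))
  grads[["out.W"]] <- cb4$dW; grads[["out.b"]] <- cb4$db
  dcat <- cbr_bwd(cb4$dx, cache$s3, model, "fuse", NULL, grads)
  sp <- split_channels(dcat, f)
  db2 <- up_bwd(sp[[1]], cache$ud)
  dr1 <- res_bwd(db2, cache$r2, model, "r2a", "r2b", grads)
  dp <- res_bwd(dr1, cache$r1, model, "r1a", "r1b", grads)
  db0 <- pool_bwd(dp, cache$p) + sp[[2]]
  dx <- cbr_bwd(db0, cache$s0, model, "d0", NULL, grads)
  list(grads = as.list(grads), dx = dx)
}

# Single-sample convenience wrappers -----------------------------------------

as_batch1 <- function(...) {
  mats <- list(...)
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])
  array(unlist(mats, use.names = FALSE), c(h, w, 1L, length(mats)))
}

# Stack one (image, masks) pair into the discriminator input layout:
# K mask channels then the image as the final channel.
stack_disc_input <- function(image, masks) {
  check_same_shape(image, masks[, , 1], "`image` and mask channels")
  k <- dim(masks)[3]
  h <- nrow(image); w <- ncol(image)
  out <- array(0, c(h, w, 1L, k + 1L))
  for (j in seq_len(k)) out[, , 1L, j] <- masks[, , j]
  out[, , 1L, k + 1L] <- image
  out
}
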