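# Differentiable layer primitives on (H, W, N, C) tensors, with explicit
# caches for hand-derived backward passes, plus Adam. Matrix views with
# H*W*N rows and C columns share storage with the tensors, so the heavy
# lifting happens in BLAS.

as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}

as_tensor <- function(m, d3) {
  dim(m) <- c(d3, ncol(m))
  m
}

conv_init <- function(c_in, c_out, k, seed_rnorm = rnorm) {
  # He-normal initialisation for relu stacks
  w <- matrix(seed_rnorm(k * k * c_in * c_out) * sqrt(2 / (k * k * c_in)),
              k * k * c_in, c_out)
  list(W = w, b = rep(0, c_out))
}

# The backward pass rebuilds the patch matrix from the cached input (a
# reference to the previous layer's activation, so no extra memory).
conv_fwd <- function(x, par, k, pad = (k - 1L) %/% 2L) {
  d <- dim(x)
  y <- conv_fwd_cpp(x, par$W, par$b, as.integer(d), k, pad)
  list(y = y, cache = list(x = x, dims = d, k = k, pad = pad))
}

sweep_add_bias <- function(y, b) {
  y + matrix(b, nrow(y), length(b), byrow = TRUE)
}

conv_bwd <- function(dy, cache, par) {
  conv_bwd_cpp(dy, cache$x, par$W, as.integer(cache$dims), cache$k,
               cache$pad)
}

# The relu mask is recovered from the output (y > 0), so no cache array is
# carried.
relu_fwd <- function(x) {
  y <- relu_cpp(x)
  list(y = y, cache = y)
}

relu_bwd <- function(dy, cache) relu_grad_cpp(dy, cache)

bn_init <- function(c_out) {
  list(gamma = rep(1, c_out), beta = rep(0, c_out),
       run_mean = rep(0, c_out), run_var = rep(1, c_out))
}

# Batch normalisation over (H, W, N) per channel. In training mode the batch
# statistics are used and running statistics updated in place via the
# returned `running` element; in evaluation mode the running statistics make
# the layer deterministic.
bn_fwd <- function(x, par, train, momentum = 0.9, eps = 1e-5) {
  d <- dim(x)
  m <- as_mat(x)
  if (train) {
    mu <- colMeans(m)
    xc <- sweep_add_bias(m, -mu)
    v <- colMeans(xc * xc)
    invstd <- 1 / sqrt(v + eps)
    xhat <- xc * matrix(invstd, nrow(m), ncol(m), byrow = TRUE)
    running <- list(
      run_mean = momentum * par$run_mean + (1 - momentum) * mu,
      run_var = momentum * par$run_var + (1 - momentum) * v
    )
  } else {
    invstd <- 1 / sqrt(par$run_var + eps)
    xhat <- sweep_add_bias(m, -par$run_mean) *
      matrix(invstd, nrow(m), ncol(m), byrow = TRUE)
    running <- NULL
  }
  y <- xhat * matrix(par$gamma, nrow(m), ncol(m), byrow = TRUE)
  y <- sweep_add_bias(y, par$beta)
  list(y = as_tensor(y, d[1:3]),
       cache = list(xhat = xhat, invstd = invstd, dims = d, train = train),
       running = running)
}

bn_bwd <- function(dy, cache, par) {
  d <- cache$dims
  dym <- as_mat(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  gm <- matrix(par$gamma, nrow(dym), ncol(dym), byrow = TRUE)
  dxhat <- dym * gm
  if (cache$train) {
    n <- nrow(dym)
    ism <- matrix(cache$invstd, n, ncol(dym), byrow = TRUE)
    t1 <- sweep_add_bias(dxhat, -colMeans(dxhat))
    t2 <- xhat * matrix(colMeans(dxhat * xhat), n, ncol(dym), byrow = TRUE)
    dx <- ism * (t1 - t2)
  } else {
    dx <- dxhat * matrix(cache$invstd, nrow(dym), ncol(dym), byrow = TRUE)
  }
  list(dx = as_tensor(dx, d[1:3]), dgamma = dgamma, dbeta = dbeta)
}

# Inverted dropout; identity in evaluation mode. Draws from the session RNG,
# which the training loop seeds explicitly.
dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, cache = NULL))
  keep <- array(runif(length(x)) >= rate, dim(x)) / (1 - rate)
  list(y = x * keep, cache = keep)
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

pool_fwd <- function(x) {
  d <- dim(x)
  out <- maxpool2_fwd(x, d[1], d[2], d[3], d[4])
  list(y = out$y, cache = list(idx = out$idx, dims = d))
}

pool_bwd <- function(dy, cache) {
  d <- cache$dims
  maxpool2_bwd(dy, cache$idx, d[1], d[2], d[3], d[4])
}

up_fwd <- function(x) {
  d <- dim(x)
  list(y = upsample2_fwd(x, d[1], d[2], d[3], d[4]), cache = d)
}

up_bwd <- function(dy, cache) {
  upsample2_bwd(dy, cache[1], cache[2], cache[3], cache[4])
}

# Channel concatenation is free in the (H, W, N, C) layout.
concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- c(a, b)
  dim(y) <- c(da[1:3], da[4] + db[4])
  y
}

split_channels <- function(dy, c_first) {
  d <- dim(dy)
  n <- prod(d[1:3])
  da <- dy[seq_len(n * c_first)]
  dbv <- dy[(n * c_first + 1L):length(dy)]
  dim(da) <- c(d[1:3], c_first)
  dim(dbv) <- c(d[1:3], d[4] - c_first)
  list(da, dbv)
}

# Row-wise softmax on the matrix view; returns probabilities (H, W, N, C).
softmax_fwd <- function(logits) {
  d <- dim(logits)
  m <- as_mat(logits)
  rowmax <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) rowmax <- pmax(rowmax, m[, j])
  e <- exp(m - rowmax)
  p <- e / rowSums(e)
  as_tensor(p, d[1:3])
}

# Gradient of mean focal log loss w.r.t. the softmax logits.
# probs: (H, W, N, C); target: integer vector (length H*W*N) of 1-based
# target classes; weight: optional per-voxel weights (defaults to uniform
# mean reduction).
focal_softmax_logit_grad <- function(probs, target, params) {
  d <- dim(probs)
  pm <- as_mat(probs)
  n <- nrow(pm)
  ind <- cbind(seq_len(n), target)
  pt <- pm[ind]
  coef <- focal_log_loss_grad(pt, params) * pt / n
  dz <- pm * (-coef)
  dz[ind] <- dz[ind] + coef
  as_tensor(dz, d[1:3])
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr = 2e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
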