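ac <- asNamespace("autoconfidence")

test_that("generator emits a valid softmax of the right shape, deterministically", {
  gen <- build_generator(generator_spec(out_classes = 4, base_filters = 4),
                         seed = 1)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  fw1 <- ac$generator_forward(gen, x, train = FALSE)
  fw2 <- ac$generator_forward(gen, x, train = FALSE)
  expect_equal(dim(fw1$probs), c(32, 32, 1, 4))
  sums <- apply(fw1$probs, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_identical(fw1$probs, fw2$probs) # evaluation-mode determinism
  expect_error(ac$generator_forward(gen, array(0, c(30, 30, 1, 1))),
               "divisible")
})

test_that("discriminator is a voxel-wise two-class softmax with image-last input", {
  disc <- build_discriminator(discriminator_spec(in_channels = 4,
                                                 base_filters = 4), seed = 2)
  x <- array(runif(32 * 32 * 4), c(32, 32, 1, 4))
  fw <- ac$discriminator_forward(disc, x, train = FALSE)
  expect_equal(dim(fw$probs), c(32, 32, 1, 2))
  p_err <- fw$probs[, , 1, 2]
  expect_true(all(p_err >= 0 & p_err <= 1))
  expect_identical(ac$discriminator_forward(disc, x, train = FALSE)$probs,
                   fw$probs)
  expect_error(ac$discriminator_forward(disc, array(0, c(32, 32, 1, 3))),
               "channels")
})

test_that("both networks are fully convolutional (size transfers)", {
  gen <- build_generator(generator_spec(out_classes = 3, base_filters = 4),
                         seed = 3)
  big <- ac$generator_forward(gen, array(runif(64 * 48), c(64, 48, 1, 1)),
                              train = FALSE)
  expect_equal(dim(big$probs), c(64, 48, 1, 3))
  disc <- build_discriminator(discriminator_spec(in_channels = 3,
                                                 base_filters = 4), seed = 3)
  bigd <- ac$discriminator_forward(disc,
                                   array(runif(64 * 48 * 3),
                                         c(64, 48, 1, 3)), train = FALSE)
  expect_equal(dim(bigd$probs), c(64, 48, 1, 2))
})

test_that("analytic gradients match finite differences on a tiny model", {
  set.seed(42)
  H <- 8; W <- 8; N <- 2; K <- 2
  params <- loss_params()
  gen <- build_generator(generator_spec(out_classes = K + 1,
                                        base_filters = 2,
                                        dropout_rate = 0, norm = TRUE),
                         seed = 7)
  x <- array(runif(H * W * N), c(H, W, N, 1))
  target <- sample(1:(K + 1), H * W * N, replace = TRUE)
  loss_fn <- function(model) {
    fw <- ac$generator_forward(model, x, train = TRUE)
    pm <- ac$as_mat(fw$probs)
    focal_log_loss(pm[cbind(seq_len(nrow(pm)), target)], params)$mean
  }
  fw <- ac$generator_forward(gen, x, train = TRUE)
  dz <- ac$focal_softmax_logit_grad(fw$probs, target, params)
  grads <- ac$generator_backward(gen, fw$cache, dz)
  for (nm in c("c1.W", "c4.W", "c5.W", "c8.W", "bn3.gamma", "bn6.beta")) {
    g <- grads[[nm]]
    idx <- sample(length(g), min(3, length(g)))
    for (i in idx) {
      eps <- 1e-5
      m1 <- gen; m1$params[[nm]][i] <- m1$params[[nm]][i] + eps
      m2 <- gen; m2$params[[nm]][i] <- m2$params[[nm]][i] - eps
      num <- (loss_fn(m1) - loss_fn(m2)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4,
                   info = sprintf("%s[%d]", nm, i))
    }
  }
  # discriminator parameter and input gradients
  disc <- build_discriminator(discriminator_spec(in_channels = K + 1,
                                                 base_filters = 2), seed = 9)
  xd <- array(runif(H * W * N * (K + 1)), c(H, W, N, K + 1))
  td <- sample(1:2, H * W * N, replace = TRUE)
  dloss <- function(model, xin = xd) {
    fw <- ac$discriminator_forward(model, xin, train = TRUE)
    pm <- ac$as_mat(fw$probs)
    focal_log_loss(pm[cbind(seq_len(nrow(pm)), td)], params)$mean
  }
  fwd <- ac$discriminator_forward(disc, xd, train = TRUE)
  dzd <- ac$focal_softmax_logit_grad(fwd$probs, td, params)
  bk <- ac$discriminator_backward(disc, fwd$cache, dzd)
  for (nm in c("d0.W", "r1b.W", "fuse.W", "out.b")) {
    g <- bk$grads[[nm]]
    i <- sample(length(g), 1)
    eps <- 1e-5
    m1 <- disc; m1$params[[nm]][i] <- m1$params[[nm]][i] + eps
    m2 <- disc; m2$params[[nm]][i] <- m2$params[[nm]][i] - eps
    expect_equal(g[i], (dloss(m1) - dloss(m2)) / (2 * eps),
                 tolerance = 1e-4, info = nm)
  }
  for (i in sample(length(xd), 4)) {
    eps <- 1e-5
    x1 <- xd; x1[i] <- x1[i] + eps
    x2 <- xd; x2[i] <- x2[i] - eps
    expect_equal(bk$dx[i], (dloss(disc, x1) - dloss(disc, x2)) / (2 * eps),
                 tolerance = 1e-4)
  }
})
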