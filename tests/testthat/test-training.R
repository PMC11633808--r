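# Lightweight contracts of the training loop; the statistical training
# properties run in the acceptance suite on the scaled-down benchmark.

tiny_data <- function(n = 6, seed = 31) {
  generate_slices(n, phantom_config(seed = seed))
}

test_that("zero epochs returns initial weights and an empty history", {
  data <- tiny_data(2)
  fit <- train(data, train_config(epochs = 0L, base_filters = 2L, seed = 1L))
  expect_s3_class(fit, "aco_fit")
  expect_equal(nrow(fit$history), 0)
  expect_equal(fit$k, 3)
  expect_equal(fit$threshold, 0.5) # untrained: no calibration
})

test_that("one short adversarial run is reproducible and logs all losses", {
  data <- tiny_data(4)
  cfg <- train_config(epochs = 2L, batch_size = 2L, base_filters = 2L,
                      seed = 7L)
  f1 <- train(data, cfg)
  f2 <- train(data, cfg)
  expect_equal(f1$history, f2$history, tolerance = 1e-12)
  expect_identical(f1$generator$params, f2$generator$params)
  expect_equal(nrow(f1$history), 4) # 2 epochs x 2 batches
  expect_true(all(is.finite(f1$history$fl_g)))
  expect_true(all(is.finite(f1$history$fl_d)))
  expect_true(all(is.finite(f1$history$l_gen)))
  # broom-style accessors
  expect_identical(tidy(f1), f1$history)
  g <- glance(f1)
  expect_equal(g$n_updates, 4)
  expect_true(g$adversarial)
})

test_that("sequential baseline trains generator first, then discriminator", {
  data <- tiny_data(4)
  cfg <- train_config(epochs = 1L, batch_size = 2L, base_filters = 2L,
                      seed = 3L)
  fit <- train_sequential_baseline(data, cfg)
  expect_false(fit$adversarial)
  phases <- unique(fit$history$phase)
  expect_equal(phases, c("adversarial", "discriminator"))
  # generator phase logs no discriminator loss; phase 2 no generator loss
  p1 <- fit$history[fit$history$phase == "adversarial", ]
  expect_true(all(is.na(p1$fl_d)))
  p2 <- fit$history[fit$history$phase == "discriminator", ]
  expect_true(all(is.na(p2$fl_g)))
})

test_that("predict_confidence and predict_segmentation satisfy their contracts", {
  data <- tiny_data(4)
  fit <- train(data, train_config(epochs = 1L, batch_size = 2L,
                                  base_filters = 2L, seed = 5L))
  s <- data[[1]]
  conf <- predict_confidence(s$image, s$masks, fit)
  expect_equal(dim(conf), dim(s$image))
  expect_true(all(conf >= 0 & conf <= 1))
  expect_identical(conf, predict_confidence(s$image, s$masks, fit))
  # works on externally supplied (corrupted) masks without a gold standard
  corrupted <- remove_oar(s$masks, 1)
  conf2 <- predict_confidence(s$image, corrupted, fit)
  expect_equal(dim(conf2), dim(s$image))
  expect_error(predict_confidence(s$image, random_mask_set(64, 64, 5), fit),
               "channels")
  probs <- predict_segmentation(s$image, fit)
  expect_equal(dim(probs), c(64, 64, 4))
  sums <- apply(probs, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
})

test_that("checkpointing writes a reloadable fit", {
  dir <- withr::local_tempdir()
  data <- tiny_data(2)
  fit <- train(data, train_config(epochs = 1L, batch_size = 2L,
                                  base_filters = 2L, seed = 2L,
                                  checkpoint_dir = dir))
  path <- file.path(dir, "aco_fit.rds")
  expect_true(file.exists(path))
  back <- readRDS(path)
  expect_identical(back$generator$params, fit$generator$params)
})
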