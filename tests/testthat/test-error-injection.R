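test_that("zero-magnitude rigid and TPS transforms are identities", {
  m <- random_disjoint_mask_set(32, 32, 3, seed = 4)
  expect_identical(apply_rigid(m, 0, c(0, 0)), m)
  expect_identical(apply_tps(m, sigma_mm = 0, seed = 1), m)
})

test_that("translation moves voxels exactly as stated", {
  m <- oar_masks(matrix(0, 32, 32))
  m[10, 10, 1] <- 1
  out <- apply_rigid(m, 0, c(3, 0))
  expect_equal(which(out[, , 1] == 1, arr.ind = TRUE)[1, ],
               c(row = 13, col = 10))
  out2 <- apply_rigid(m, 0, c(-2, 5))
  expect_equal(which(out2[, , 1] == 1, arr.ind = TRUE)[1, ],
               c(row = 8, col = 15))
})

test_that("90-degree rotation matches per-voxel coordinate remapping", {
  set.seed(7)
  m <- oar_masks(matrix(rbinom(32 * 32, 1, 0.2), 32, 32))
  out <- apply_rigid(m, 90, c(0, 0))
  ctr <- (32 + 1) / 2
  ref <- matrix(0, 32, 32)
  for (r in 1:32) for (c in 1:32) {
    # inverse map: rotate output coordinate by -90 degrees about centre
    src_r <- round(cos(pi / 2) * (r - ctr) + sin(pi / 2) * (c - ctr) + ctr)
    src_c <- round(-sin(pi / 2) * (r - ctr) + cos(pi / 2) * (c - ctr) + ctr)
    if (src_r >= 1 && src_r <= 32 && src_c >= 1 && src_c <= 32) {
      ref[r, c] <- m[src_r, src_c, 1]
    }
  }
  expect_equal(unclass(out)[, , 1], ref)
})

test_that("rigid transforms keep masks binary and move channels jointly", {
  m <- random_disjoint_mask_set(32, 32, 3, seed = 9)
  out <- apply_rigid(m, 17.3, c(2.2, -1.7))
  expect_true(all(out %in% c(0, 1)))
  # all channels experience the same displacement: the union transforms
  # like any single channel
  u_in <- oar_masks(pmin(apply(unclass(m), c(1, 2), sum), 1))
  u_out <- apply_rigid(u_in, 17.3, c(2.2, -1.7))
  expect_equal(unclass(u_out)[, , 1],
               pmin(apply(unclass(out), c(1, 2), sum), 1),
               ignore_attr = TRUE)
})

test_that("TPS deformation is seed-deterministic and sigma-monotone", {
  m <- oar_masks(disc_mask(48, 48, c(24, 24), 10))
  a <- apply_tps(m, 20, 3, seed = 11)
  b <- apply_tps(m, 20, 3, seed = 11)
  expect_identical(a, b)
  expect_true(all(a %in% c(0, 1)))
  # mean displacement magnitude grows with sigma (Monte-Carlo over seeds)
  mean_disp <- function(sigma) {
    mean(vapply(1:200, function(s) {
      f <- autoconfidence:::tps_field(32, 32, 20, sigma, 1, seed = s)
      mean(sqrt(f$dr^2 + f$dc^2))
    }, numeric(1)))
  }
  d1 <- mean_disp(1); d2 <- mean_disp(2); d4 <- mean_disp(4)
  expect_lt(d1, d2)
  expect_lt(d2, d4)
})

test_that("perturb_class relabels the target organ to its runner-up class", {
  probs <- random_softmax(12, 12, 4, seed = 5)
  out <- perturb_class(probs, 2)
  lab_in <- oracle_argmax(probs)
  lab_out <- oracle_argmax(probs) # recompute, then apply rule
  for (r in 1:12) for (c in 1:12) {
    if (lab_in[r, c] == 3) { # target organ 2 = class 3
      lab_out[r, c] <- oracle_second_argmax(probs[r, c, ], 3)
    }
  }
  for (j in 1:3) {
    expect_equal(out[, , j], (lab_out == j + 1) + 0, ignore_attr = TRUE)
  }
  # runner-up equal to background empties the channel
  hot <- array(0, c(4, 4, 3))
  hot[, , 1] <- 0.4; hot[, , 2] <- 0.6
  emptied <- perturb_class(hot, 1)
  expect_equal(sum(emptied), 0)
  # empty target channel is a warning no-op
  bgonly <- array(0, c(4, 4, 3)); bgonly[, , 1] <- 1
  expect_warning(perturb_class(bgonly, 2), "no-op")
})

test_that("remove_oar empties exactly one channel", {
  m <- random_disjoint_mask_set(16, 16, 3, seed = 6)
  out <- remove_oar(m, 2)
  expect_true(all(out[, , 2] == 0))
  expect_equal(out[, , 1], m[, , 1])
  expect_equal(out[, , 3], m[, , 3])
  expect_identical(unclass(remove_oar(out, 2)), unclass(out))
  expect_error(remove_oar(m, 5), "1..3")
  # d2GS of (removed vs original) equals the removed channel
  d <- compute_d2gs(out, m)
  expect_equal(unclass(d), unclass(m)[, , 2], ignore_attr = TRUE)
})

test_that("inject applies families per configured probabilities with a log", {
  m <- random_disjoint_mask_set(32, 32, 3, seed = 8)
  sm <- random_softmax(32, 32, 4, seed = 8)
  off <- error_config(p_geometric = 0, p_class_perturb = 0, p_removal = 0)
  res <- inject(m, sm, off, seed = 1)
  expect_identical(unclass(res$masks), unclass(m))
  expect_equal(nrow(res$log), 0)

  rem <- error_config(p_geometric = 0, p_class_perturb = 0, p_removal = 1)
  res <- inject(m, NULL, rem, seed = 2)
  emptied <- which(vapply(1:3, function(j) all(res$masks[, , j] == 0) &&
                            any(m[, , j] == 1), logical(1)))
  expect_length(emptied, 1)
  expect_equal(res$log$family, "removal")
  expect_equal(res$log$channels, organ_names(m)[emptied])

  # determinism of the full pipeline
  all_on <- error_config(p_geometric = 1, p_class_perturb = 1, p_removal = 1)
  r1 <- inject(m, sm, all_on, seed = 33)
  r2 <- inject(m, sm, all_on, seed = 33)
  expect_identical(r1$masks, r2$masks)
  expect_identical(r1$log, r2$log)
  expect_error(inject(m, NULL, error_config(p_class_perturb = 0.5), seed = 1),
               "softmax")
})

test_that("corruption severity grows with magnitude_scale (DSC decreases)", {
  m <- oar_masks(disc_mask(64, 64, c(32, 32), 12))
  mean_dsc <- function(scale) {
    cfg <- error_config(p_geometric = 1, p_class_perturb = 0, p_removal = 0,
                        rotation_range = 6, translation_range = 3,
                        tps_sigma = 2, magnitude_scale = scale)
    mean(vapply(1:40, function(s) {
      dsc(inject(m, NULL, cfg, seed = s)$masks[, , 1], m[, , 1])
    }, numeric(1)))
  }
  d_small <- mean_dsc(0.5)
  d_large <- mean_dsc(2)
  expect_gt(d_small, d_large)
})
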