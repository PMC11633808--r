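test_that("generate_phantom is deterministic and honours the organ count", {
  cfg <- small_phantom_config(seed = 5)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a, b)
  expect_equal(dim(a$masks)[3], 3)
  expect_true(all(apply(a$masks, 3, sum) > 0))
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_true(all(is.finite(a$image)))
})

test_that("gold-standard organ masks are pairwise disjoint", {
  for (seed in 1:6) {
    ph <- generate_phantom(small_phantom_config(seed = seed))
    expect_lte(max(apply(unclass(ph$masks), c(1, 2), sum)), 1)
  }
})

test_that("organ contrast is recovered from the image when noise is off", {
  cfg <- phantom_config(n_organs = 1, contrast_levels = 0.5,
                        noise_sigma = 0, shading_amplitude = 0,
                        include_tiny_organ = FALSE,
                        include_low_contrast_organ = FALSE, seed = 3)
  ph <- generate_phantom(cfg)
  inside <- mean(ph$image[ph$masks[, , 1] == 1])
  outside <- mean(ph$image[ph$masks[, , 1] == 0])
  expect_equal(inside - outside, 0.5, tolerance = 1e-8)
  # with shading on, the offset survives within a tolerance
  cfg2 <- phantom_config(n_organs = 1, contrast_levels = 0.5,
                         noise_sigma = 0, shading_amplitude = 0.08,
                         include_tiny_organ = FALSE,
                         include_low_contrast_organ = FALSE, seed = 3)
  ph2 <- generate_phantom(cfg2)
  offset <- mean(ph2$image[ph2$masks[, , 1] == 1]) -
    mean(ph2$image[ph2$masks[, , 1] == 0])
  expect_equal(offset, 0.5, tolerance = 0.1)
})

test_that("difficulty flags produce a tiny organ and a low-CNR organ", {
  for (seed in 1:5) {
    cfg <- small_phantom_config(seed = seed)
    ph <- generate_phantom(cfg)
    areas <- apply(ph$masks, 3, sum)
    expect_lt(min(areas), 10) # lens-like structure
    # designated low-contrast organ: measured CNR <= 1 (plus shading slack)
    noise_free <- phantom_config(n_organs = 3, seed = seed,
                                 noise_sigma = 0, shading_amplitude = 0)
    ph0 <- generate_phantom(noise_free)
    contrasts <- vapply(1:3, function(j) {
      mean(ph0$image[ph0$masks[, , j] == 1]) -
        mean(ph0$image[apply(unclass(ph0$masks), c(1, 2), sum) == 0])
    }, numeric(1))
    expect_lte(min(contrasts), cfg$noise_sigma + 1e-9)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(height = 16), "32x32")
  expect_error(phantom_config(n_organs = 0), "n_organs")
  # an impossible packing fails with a placement error
  cfg <- phantom_config(height = 32, width = 32, n_organs = 20,
                        organ_size_range = c(8, 9),
                        include_tiny_organ = FALSE, seed = 1)
  expect_error(generate_phantom(cfg), "place organ")
})

test_that("generate_dataset writes a reloadable, reproducible manifest", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- small_phantom_config(seed = 10)
  man1 <- generate_dataset(5, cfg, dir1)
  expect_equal(nrow(man1), 5)
  expect_true(all(file.exists(man1$image_path)))
  expect_true(all(file.exists(man1$masks_path)))
  # round trip is bit-identical
  slices <- read_dataset(man1)
  ref <- generate_slices(5, cfg)
  for (i in 1:5) {
    expect_equal(unclass(slices[[i]]$image), unclass(ref[[i]]$image),
                 ignore_attr = TRUE)
    expect_identical(unclass(slices[[i]]$masks), unclass(ref[[i]]$masks))
  }
  # same master seed -> identical data in a fresh directory
  man2 <- generate_dataset(5, cfg, dir2)
  expect_equal(man2$seed, man1$seed)
  s2 <- read_dataset(man2)
  expect_identical(unclass(s2[[3]]$masks), unclass(slices[[3]]$masks))
})
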