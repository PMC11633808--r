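test_that("IER removes thin boundary ribbons entirely", {
  seg <- oar_masks(disc_mask(32, 32, c(16, 16), 7))
  # 1-voxel ribbon exactly on the mask boundary
  er <- unclass(seg[, , 1] - disc_mask(32, 32, c(16, 16), 6))
  out <- intelligent_edge_removal(er, seg, ier_params(k = 3))
  expect_true(all(out == 0))
})

test_that("IER preserves interior errors and never creates error voxels", {
  seg <- oar_masks(disc_mask(32, 32, c(16, 16), 8))
  block <- matrix(0, 32, 32); block[14:18, 14:18] <- 1 # deep inside
  out <- intelligent_edge_removal(block, seg, ier_params(k = 3))
  expect_equal(out, block)
  # output is always a subset of the input error map
  for (seed in 1:5) {
    set.seed(seed)
    er <- matrix(rbinom(32 * 32, 1, 0.2), 32, 32)
    out <- intelligent_edge_removal(er, seg)
    expect_true(all(out <= er))
  }
})

test_that("IER leaves errors farther than k from every boundary untouched", {
  seg <- oar_masks(disc_mask(48, 48, c(24, 24), 8))
  far <- matrix(0, 48, 48); far[40:44, 40:44] <- 1
  expect_equal(intelligent_edge_removal(far, seg), far)
})

test_that("IER matches the brute-force morphological oracle", {
  # constructed straddling blob: part inside, part on the boundary band
  seg <- oar_masks(disc_mask(32, 32, c(16, 16), 7))
  blob <- matrix(0, 32, 32); blob[10:16, 20:26] <- 1
  expect_equal(intelligent_edge_removal(blob, seg, ier_params(3)),
               oracle_ier(blob, seg, 3))
  # random fixtures over random segmentations
  for (seed in 1:50) {
    set.seed(seed)
    k_org <- sample(1:2, 1)
    m <- array(0, c(24, 24, k_org))
    for (j in seq_len(k_org)) {
      m[, , j] <- disc_mask(24, 24, c(sample(6:18, 1), sample(6:18, 1)),
                            sample(3:6, 1))
    }
    seg <- oar_masks(pmin(m, 1))
    er <- matrix(rbinom(24 * 24, 1, 0.25), 24, 24)
    expect_equal(intelligent_edge_removal(er, seg, ier_params(3)),
                 oracle_ier(er, seg, 3),
                 info = sprintf("seed %d", seed))
  }
})

test_that("GDC handles the canonical proximity cases", {
  # no TP anywhere: identity
  lab <- random_labels(16, 16, seed = 2, p = c(TN = .8, FP = .1, FN = .1, TP = 0))
  cm <- cm_from_labels(lab)
  out <- geometric_distance_correction(cm)
  expect_identical(out$labels, cm$labels)
  expect_false(any(out$gdc_modified))

  # FP adjacent to a 9x9 TP block is reclassified (flag set)
  lab <- matrix("TN", 31, 31)
  lab[11:19, 11:19] <- "TP"
  lab[15, 20] <- "FP"
  out <- geometric_distance_correction(cm_from_labels(lab), gdc_params(31))
  expect_equal(cm_labels_chr(out)[15, 20], "TP")
  expect_true(out$gdc_modified[15, 20])

  # isolated FP at distance 10 from a single TP voxel stays FP
  lab <- matrix("TN", 31, 31)
  lab[15, 3] <- "TP"
  lab[15, 13] <- "FP"
  out <- geometric_distance_correction(cm_from_labels(lab), gdc_params(31))
  expect_equal(cm_labels_chr(out)[15, 13], "FP")

  # FN near a large TP region becomes TN
  lab <- matrix("TN", 31, 31)
  lab[11:19, 11:19] <- "TP"
  lab[15, 21] <- "FN"
  out <- geometric_distance_correction(cm_from_labels(lab), gdc_params(31))
  expect_equal(cm_labels_chr(out)[15, 21], "TN")
})

test_that("GDC matches the exhaustive brute-force oracle on random maps", {
  for (seed in 1:12) {
    lab <- random_labels(32, 32, seed = seed,
                         p = c(TN = .62, FP = .12, FN = .12, TP = .14))
    cm <- cm_from_labels(lab)
    out <- geometric_distance_correction(cm, gdc_params(15))
    ref <- oracle_gdc(lab, 15)
    expect_equal(cm_labels_chr(out), ref$labels,
                 info = sprintf("seed %d", seed))
    expect_equal(out$gdc_modified, ref$modified,
                 info = sprintf("seed %d", seed))
  }
})

test_that("GDC only removes FP/FN: rates never increase, TP/TN never change", {
  for (seed in 1:8) {
    lab <- random_labels(24, 24, seed = seed + 50)
    cm <- cm_from_labels(lab)
    before <- compute_metrics(cm)
    out <- geometric_distance_correction(cm, gdc_params(11))
    after <- compute_metrics(out)
    expect_lte(after$fpr, before$fpr)
    expect_lte(after$fnr, before$fnr)
    keep <- lab == "TP" | lab == "TN"
    expect_equal(cm_labels_chr(out)[keep], lab[keep])
    # decisions are made on the original labels only (no cascading):
    # every modified voxel must satisfy the rule w.r.t. the input map
    expect_true(all(out$gdc_modified == (cm_labels_chr(out) != lab)))
  }
})
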