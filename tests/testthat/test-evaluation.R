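test_that("metrics match hand-computed values across count tuples", {
  grid <- expand.grid(tp = c(0, 1, 40), tn = c(0, 5, 900),
                      fp = c(0, 2, 10), fn = c(0, 3, 50))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    m <- autoconfidence:::metrics_from_counts(g$tp, g$tn, g$fp, g$fn)
    expect_equal(m$mcc, oracle_mcc(g$tp, g$tn, g$fp, g$fn))
    expect_equal(m$fpr,
                 if (g$fp + g$tn > 0) g$fp / (g$fp + g$tn) else NA_real_)
    expect_equal(m$fnr,
                 if (g$fn + g$tp > 0) g$fn / (g$fn + g$tp) else NA_real_)
    expect_equal(m$fp_fn_ratio,
                 if (g$fn > 0) g$fp / g$fn else NA_real_)
    if (!is.na(m$fpr)) expect_true(m$fpr >= 0 && m$fpr <= 1)
    if (!is.na(m$fnr)) expect_true(m$fnr >= 0 && m$fnr <= 1)
  }
  # perfect and inverted predictions
  expect_equal(autoconfidence:::metrics_from_counts(10, 90, 0, 0)$mcc, 1)
  expect_equal(autoconfidence:::metrics_from_counts(0, 0, 10, 90)$mcc, -1)
  # specific worked example
  m <- autoconfidence:::metrics_from_counts(40, 900, 10, 50)
  expect_equal(m$fpr, 10 / 910)
  expect_equal(m$fnr, 50 / 90)
  expect_equal(m$mcc, (40 * 900 - 10 * 50) /
                 sqrt((40 + 10) * (40 + 50) * (900 + 10) * (900 + 50)))
})

test_that("MCC is symmetric under the TP/TN with FP/FN swap", {
  set.seed(1)
  for (i in 1:20) {
    v <- sample(0:50, 4, replace = TRUE)
    expect_equal(oracle_mcc(v[1], v[2], v[3], v[4]),
                 autoconfidence:::metrics_from_counts(v[2], v[1], v[4],
                                                      v[3])$mcc)
  }
})

test_that("compute_metrics counts match the confusion map and regions", {
  lab <- random_labels(16, 16, seed = 3)
  cm <- cm_from_labels(lab)
  m <- compute_metrics(cm)
  expect_equal(m$tp, sum(lab == "TP"))
  expect_equal(m$fn, sum(lab == "FN"))
  region <- matrix(FALSE, 16, 16); region[1:8, ] <- TRUE
  mr <- compute_metrics(cm, region)
  expect_equal(mr$tp + mr$tn + mr$fp + mr$fn, 128)
})

test_that("evaluate_case reduces to plain confusion metrics when options are off", {
  set.seed(12)
  gs <- oar_masks(array(c(disc_mask(32, 32, c(10, 10), 5),
                          disc_mask(32, 32, c(23, 22), 6)), c(32, 32, 2)))
  # translation plus a removed organ: boundary errors and a large interior
  # error region that survives edge removal
  pred <- remove_oar(apply_rigid(gs, 0, c(2, 1)), 1)
  conf <- matrix(runif(32 * 32), 32, 32)
  ev <- evaluate_case(conf, pred, gs, configurations = "baseline")
  ov <- ev[ev$oar == "overall", ]
  ref <- compute_metrics(confusion_map(binarize_confidence(conf),
                                       unclass(compute_d2gs(pred, gs))))
  expect_equal(ov$mcc, ref$mcc)
  expect_equal(ov$tp, ref$tp)
  # oracle confidence (= d2GS) scores perfectly in every configuration
  d2 <- unclass(compute_d2gs(pred, gs))
  ev2 <- evaluate_case(d2, pred, gs)
  expect_true(all(ev2$mcc[ev2$oar == "overall"] == 1))
  # all-zero confidence with pred == gs: no positives anywhere, FPR = 0
  ev3 <- evaluate_case(matrix(0, 32, 32), gs, gs,
                       configurations = "baseline")
  expect_true(all(is.na(ev3$mcc)))
  expect_true(all(ev3$fpr[!is.na(ev3$fpr)] == 0))
})

test_that("evaluate_case reports every organ in every configuration", {
  gs <- random_disjoint_mask_set(32, 32, 3, seed = 21)
  pred <- apply_rigid(gs, 5, c(1, 0))
  conf <- matrix(runif(32 * 32), 32, 32)
  ev <- evaluate_case(conf, pred, gs)
  expect_setequal(unique(ev$oar), c("overall", organ_names(gs)))
  expect_setequal(unique(ev$configuration),
                  c("baseline", "ier", "gdc", "ier_gdc"))
  expect_equal(nrow(ev), 4 * 4)
})

test_that("four-colour map paints each labelled voxel exactly one colour", {
  img <- matrix(0.5, 8, 8)
  lab <- matrix("TN", 8, 8)
  lab[2, 2] <- "TP"; lab[3, 3] <- "FP"; lab[4, 4] <- "FN"
  cm <- cm_from_labels(lab)
  cm$labels[5, 5] <- autoconfidence:::CONFUSION_LEVELS[["TP"]]
  cm$gdc_modified[5, 5] <- TRUE
  rgb <- render_four_colour_map(cm, img, alpha = 1)
  expect_equal(dim(rgb), c(8, 8, 3))
  expect_equal(rgb[2, 2, ], c(0, 0.8, 0))        # TP green
  expect_equal(rgb[3, 3, ], c(1, 0.45, 0.7))     # FP pink
  expect_equal(rgb[4, 4, ], c(0.15, 0.35, 1))    # FN blue
  expect_equal(rgb[5, 5, ], c(1, 0.9, 0))        # GDC-modified yellow
  expect_equal(rgb[1, 1, ], rep(0.5, 3))         # TN keeps the image
  # all-TN map stays pure grayscale
  plain <- render_four_colour_map(cm_from_labels(matrix("TN", 8, 8)), img)
  expect_true(all(plain == 0.5))
  # colour counts match label counts
  painted <- apply(rgb, c(1, 2), function(v) !all(v == 0.5))
  expect_equal(sum(painted), 4)
})
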