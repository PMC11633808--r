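# Scaled-down end-to-end benchmark: train on synthetic phantoms, corrupt
# held-out gold standards to emulate an external segmentation model, score
# confidence maps against d2GS in all four reporting configurations, and
# replicate the input/training ablation protocol.

#' Benchmark study conditions
#'
#' The fixed conditions of the scaled-down phantom study: slice geometry and
#' difficulty, training length, and the test-time error injection that
#' emulates an external auto-segmentation model. Sizes are chosen so a full
#' variant set trains in minutes on one CPU while leaving enough signal for
#' the directional comparisons.
#'
#' @param n_train,n_test Training and held-out slice counts.
#' @param epochs Training epochs per variant.
#' @param base_filters Network width.
#' @param threshold Error-probability threshold for binarizing confidence
#'   maps; `NULL` (default) uses each fit's training-calibrated threshold.
#' @param phantom [phantom_config()] template (its seed is re-derived).
#' @param train_error [error_config()] used during training.
#' @param test_error [error_config()] applied to held-out gold standards
#'   (class perturbation off: an external model exposes no softmax). The
#'   mix of displacement and removal keeps error locations unpredictable
#'   from either input alone; cases that draw no error carry an empty d2GS
#'   and drop out of MCC averages as undefined.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(n_train = 160L, n_test = 40L, epochs = 6L,
                             base_filters = 8L, threshold = NULL,
                             phantom = phantom_config(),
                             train_error = error_config(),
                             test_error = error_config(
                               p_geometric = 0.6, p_class_perturb = 0,
                               p_removal = 0.5, rotation_range = 8,
                               translation_range = 4, tps_sigma = 3
                             )) {
  structure(list(
    n_train = as.integer(n_train), n_test = as.integer(n_test),
    epochs = as.integer(epochs), base_filters = as.integer(base_filters),
    threshold = threshold, phantom = phantom,
    train_error = train_error, test_error = test_error
  ), class = "benchmark_config")
}

BENCHMARK_VARIANTS <- c("adversarial", "no_synthetic_errors", "zero_image",
                        "zero_segmentation", "sequential")

train_variant <- function(variant, data, cfg, seed) {
  base <- train_config(
    epochs = cfg$epochs, base_filters = cfg$base_filters,
    use_synthetic_errors = variant != "no_synthetic_errors",
    error_config = cfg$train_error,
    ablation = switch(variant, zero_image = "zero_image",
                      zero_segmentation = "zero_segmentation", "none"),
    seed = seed
  )
  if (variant == "sequential") {
    train_sequential_baseline(data, base)
  } else {
    train(data, base)
  }
}

#' Run the end-to-end phantom benchmark
#'
#' Generates training and held-out phantom slices, trains the requested
#' variants, corrupts each held-out gold standard with the test-time error
#' injection (so every case carries known errors), predicts confidence maps
#' and evaluates them against d2GS in the four configurations (baseline,
#' IER, GDC, IER+GDC). Also reports the internal generator's DSC on the
#' held-out slices.
#'
#' @param seed Master seed; everything (phantoms, weights, injections) is
#'   derived from it.
#' @param config [benchmark_config()].
#' @param variants Subset of `r toString(BENCHMARK_VARIANTS)`.
#' @return List with `summary` (tibble: variant, configuration, mean/sd of
#'   MCC, FPR, FNR over held-out slices), `per_case` (tibble of overall
#'   metrics per case), `dsc` (tibble of generator DSC per variant), and
#'   `fits` (named list of `aco_fit`s).
#' @export
run_benchmark <- function(seed = 1L, config = benchmark_config(),
                          variants = BENCHMARK_VARIANTS) {
  variants <- match.arg(variants, BENCHMARK_VARIANTS, several.ok = TRUE)
  seeds <- derive_seeds(seed, 4L + length(variants))
  ph_train <- config$phantom; ph_train$seed <- seeds[1]
  ph_test <- config$phantom; ph_test$seed <- seeds[2]
  train_data <- generate_slices(config$n_train, ph_train)
  test_data <- generate_slices(config$n_test, ph_test)

  # held-out segmentations under test: gold standards corrupted at known
  # error magnitude, emulating an external model
  inj_seeds <- derive_seeds(seeds[3], config$n_test)
  test_segs <- lapply(seq_len(config$n_test), function(i) {
    inject(test_data[[i]]$masks, softmax = NULL,
           config = config$test_error, seed = inj_seeds[i])$masks
  })

  fits <- list()
  per_case <- list()
  dsc_rows <- list()
  for (vi in seq_along(variants)) {
    variant <- variants[vi]
    fit <- train_variant(variant, train_data, config, seeds[4L + vi])
    fits[[variant]] <- fit
    for (i in seq_len(config$n_test)) {
      slice <- test_data[[i]]
      conf <- predict_confidence(slice$image, test_segs[[i]], fit)
      ev <- evaluate_case(conf, test_segs[[i]], slice$masks,
                          threshold = config$threshold %||% fit$threshold,
                          per_oar = FALSE)
      ov <- dplyr::filter(ev, .data$oar == "overall")
      ov$variant <- variant
      ov$case <- i
      per_case[[length(per_case) + 1L]] <- ov
      sm <- predict_segmentation(slice$image, fit)
      pred_masks <- softmax_to_masks(sm, organ_names(slice$masks))
      dsc_rows[[length(dsc_rows) + 1L]] <- tibble(
        variant = variant, case = i,
        organ = organ_names(slice$masks),
        dsc = vapply(seq_len(fit$k), function(j) {
          dsc(pred_masks[, , j], slice$masks[, , j])
        }, numeric(1))
      )
    }
  }
  per_case <- dplyr::bind_rows(per_case)
  summary <- per_case |>
    dplyr::group_by(.data$variant, .data$configuration) |>
    dplyr::summarise(
      mean_mcc = mean(.data$mcc, na.rm = TRUE),
      sd_mcc = stats::sd(.data$mcc, na.rm = TRUE),
      mean_fpr = mean(.data$fpr, na.rm = TRUE),
      mean_fnr = mean(.data$fnr, na.rm = TRUE),
      n_cases = dplyr::n(),
      .groups = "drop"
    )
  dsc_tbl <- dplyr::bind_rows(dsc_rows) |>
    dplyr::group_by(.data$variant, .data$organ) |>
    dplyr::summarise(mean_dsc = mean(.data$dsc, na.rm = TRUE),
                     .groups = "drop")
  list(summary = summary, per_case = per_case, dsc = dsc_tbl, fits = fits)
}
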