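# Umbrella pipeline: configuration, provenance, and the simulate -> train ->
# inject -> predict -> postprocess -> evaluate run bound into one artifact
# directory.

#' Run configuration
#'
#' @param out_dir Artifact directory.
#' @param n_train,n_test Slice counts.
#' @param phantom [phantom_config()].
#' @param train [train_config()].
#' @param test_error [error_config()] for held-out corruption.
#' @param threshold Confidence binarization threshold.
#' @param ier,gdc Post-processing parameter objects.
#' @param stages Character vector of stages to run, in order; any of
#'   `"simulate"`, `"train"`, `"evaluate"`. Later stages consume the
#'   artifacts of earlier ones from `out_dir` when a stage is skipped.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, n_train = 60L, n_test = 12L,
                       phantom = phantom_config(),
                       train = train_config(epochs = 2L, base_filters = 8L),
                       test_error = error_config(p_geometric = 1,
                                                 p_class_perturb = 0,
                                                 p_removal = 0.3),
                       threshold = 0.5, ier = ier_params(),
                       gdc = gdc_params(),
                       stages = c("simulate", "train", "evaluate"),
                       seed = 1L) {
  stages <- match.arg(stages, c("simulate", "train", "evaluate"),
                      several.ok = TRUE)
  structure(list(
    out_dir = out_dir, n_train = as.integer(n_train),
    n_test = as.integer(n_test), phantom = phantom, train = train,
    test_error = test_error, threshold = threshold, ier = ier, gdc = gdc,
    stages = stages, seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; the nested
#' `phantom`, `train`, `test_error`, `ier` and `gdc` blocks mirror the
#' corresponding constructor arguments. Missing keys keep their defaults.
#'
#' @param path YAML file.
#' @param out_dir Overrides the configured output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, args %||% list())
  cfg <- run_config(
    out_dir = out_dir %||% y$out_dir %||% ".",
    n_train = y$n_train %||% 60L,
    n_test = y$n_test %||% 12L,
    phantom = build(phantom_config, y$phantom),
    train = build(train_config, y$train),
    test_error = build(error_config, y$test_error),
    threshold = y$threshold %||% 0.5,
    ier = build(ier_params, y$ier),
    gdc = build(gdc_params, y$gdc),
    stages = y$stages %||% c("simulate", "train", "evaluate"),
    seed = y$seed %||% 1L
  )
  cfg
}

#' Execute the full pipeline
#'
#' Runs the configured stages, writing phantom data (NIfTI + manifest),
#' model checkpoints, per-case confidence maps, a tidy metrics CSV,
#' four-colour map PNGs (when the `png` package is available) and a
#' provenance record (`provenance.json` with config hash, seeds, package
#' version and per-stage wall time).
#'
#' @param config A [run_config()].
#' @return `config$out_dir`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 4L)
  timings <- list()
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  if ("simulate" %in% config$stages) {
    timed("simulate", {
      ph_train <- config$phantom; ph_train$seed <- seeds[1]
      ph_test <- config$phantom; ph_test$seed <- seeds[2]
      generate_dataset(config$n_train, ph_train, file.path(out, "train"))
      generate_dataset(config$n_test, ph_test, file.path(out, "test"))
    })
  }
  if ("train" %in% config$stages) {
    timed("train", {
      data <- read_dataset(file.path(out, "train", "manifest.csv"))
      cfg <- config$train
      cfg$seed <- seeds[3]
      cfg$checkpoint_dir <- file.path(out, "checkpoints")
      fit <- train(data, cfg)
      hist_path <- file.path(out, "history.csv")
      utils::write.csv(fit$history, hist_path, row.names = FALSE)
    })
  }
  if ("evaluate" %in% config$stages) {
    timed("evaluate", {
      fit <- readRDS(file.path(out, "checkpoints", "aco_fit.rds"))
      test_data <- read_dataset(file.path(out, "test", "manifest.csv"))
      inj_seeds <- derive_seeds(seeds[4], length(test_data))
      map_dir <- file.path(out, "maps")
      dir.create(map_dir, showWarnings = FALSE)
      rows <- list()
      for (i in seq_along(test_data)) {
        slice <- test_data[[i]]
        seg <- inject(slice$masks, softmax = NULL,
                      config = config$test_error, seed = inj_seeds[i])$masks
        conf <- predict_confidence(slice$image, seg, fit)
        write_volume(conf, file.path(map_dir, sprintf("conf_%03d.nii.gz", i)))
        ev <- evaluate_case(conf, seg, slice$masks,
                            threshold = config$threshold,
                            ier = config$ier, gdc = config$gdc)
        ev$case <- i
        rows[[i]] <- ev
        if (requireNamespace("png", quietly = TRUE)) {
          pe <- binarize_confidence(conf, config$threshold)
          cm <- geometric_distance_correction(
            confusion_map(pe, unclass(compute_d2gs(seg, slice$masks))),
            config$gdc
          )
          fc <- render_four_colour_map(cm, slice$image)
          png::writePNG(aperm(unclass(fc), c(1, 2, 3)),
                        file.path(map_dir, sprintf("fourcolour_%03d.png", i)))
        }
      }
      metrics <- dplyr::bind_rows(rows)
      metrics_long <- tidyr::pivot_longer(
        metrics, c("tp", "tn", "fp", "fn", "mcc", "fpr", "fnr",
                   "fp_fn_ratio", "dsc"),
        names_to = "metric", values_to = "value"
      )
      utils::write.csv(metrics_long, file.path(out, "metrics.csv"),
                       row.names = FALSE)
    })
  }

  prov <- list(
    package_version = as.character(utils::packageVersion("autoconfidence")),
    r_version = R.version.string,
    master_seed = config$seed,
    derived_seeds = as.list(setNames(seeds, c("simulate_train",
                                              "simulate_test", "train",
                                              "inject"))),
    config_hash = rlang::hash(config),
    stages = config$stages,
    wall_time_s = timings,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(prov, file.path(out, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    saveRDS(prov, file.path(out, "provenance.rds"))
  }
  invisible(out)
}
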