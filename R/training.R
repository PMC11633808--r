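# Alternating adversarial training of the segmentation generator and the
# confidence discriminator, the sequential (non-adversarial) baseline, and
# the inference entry points.

#' Training configuration
#'
#' @param epochs Passes over the training slices.
#' @param batch_size Slices per batch.
#' @param lr_generator,lr_discriminator Adam learning rates.
#' @param loss_params [loss_params()] (gamma, eps, alpha, beta).
#' @param use_synthetic_errors Corrupt generated segmentations with
#'   [inject()] before the discriminator sees them.
#' @param error_config [error_config()] for the synthetic errors.
#' @param base_filters Base filter count for both networks.
#' @param dropout_rate Generator dropout.
#' @param norm_generator,norm_discriminator Batch-normalisation flags.
#' @param ablation `"none"`, `"zero_image"` (discriminator's image channel
#'   zeroed at train and test) or `"zero_segmentation"` (mask channels
#'   zeroed) — the input-ablation protocol.
#' @param seed Master seed; training is reproducible from it.
#' @param checkpoint_dir Optional directory; the fitted object is saved
#'   there as `aco_fit.rds`.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 6L, batch_size = 8L, lr_generator = 1e-3,
                         lr_discriminator = 1e-3,
                         loss_params = autoconfidence::loss_params(),
                         use_synthetic_errors = TRUE,
                         error_config = autoconfidence::error_config(),
                         base_filters = 16L, dropout_rate = 0.2,
                         norm_generator = TRUE, norm_discriminator = FALSE,
                         ablation = c("none", "zero_image", "zero_segmentation"),
                         seed = 1L, checkpoint_dir = NULL) {
  stopifnot(epochs >= 0, batch_size >= 1)
  structure(list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    lr_generator = lr_generator, lr_discriminator = lr_discriminator,
    loss_params = loss_params,
    use_synthetic_errors = isTRUE(use_synthetic_errors),
    error_config = error_config,
    base_filters = as.integer(base_filters), dropout_rate = dropout_rate,
    norm_generator = isTRUE(norm_generator),
    norm_discriminator = isTRUE(norm_discriminator),
    ablation = match.arg(ablation),
    seed = as.integer(seed), checkpoint_dir = checkpoint_dir
  ), class = "train_config")
}

# Stack a list of slices into (H, W, N, 1) images and (H, W, N, K) masks.
stack_batch <- function(slices) {
  h <- nrow(slices[[1]]$image); w <- ncol(slices[[1]]$image)
  n <- length(slices)
  k <- dim(slices[[1]]$masks)[3]
  x <- array(0, c(h, w, n, 1L))
  g <- array(0, c(h, w, n, k))
  for (i in seq_len(n)) {
    x[, , i, 1L] <- slices[[i]]$image
    g[, , i, ] <- slices[[i]]$masks
  }
  list(x = x, gs = g)
}

# Per-voxel 1-based target classes from disjoint gold-standard channels
# (1 = background, j + 1 = organ j), flattened to length H*W*N.
gs_target_classes <- function(gs) {
  d <- dim(gs)
  t <- array(1, d[1:3])
  for (j in seq_len(d[4])) t <- t + j * gs[, , , j] * (t == 1)
  as.integer(t)
}

# Discriminator input for a batch: mask channels then image, with the
# configured ablation applied.
disc_input <- function(masks_hwnk, image_hwn1, ablation = "none") {
  d <- dim(masks_hwnk)
  x <- array(0, c(d[1], d[2], d[3], d[4] + 1L))
  if (ablation != "zero_segmentation") x[, , , seq_len(d[4])] <- masks_hwnk
  if (ablation != "zero_image") x[, , , d[4] + 1L] <- image_hwn1[, , , 1L]
  x
}

# Target classes for the discriminator from a d2GS batch (H, W, N):
# class 1 = correct, class 2 = error.
d2gs_target_classes <- function(d2gs_hwn) {
  as.integer(1L + d2gs_hwn)
}

disc_step_tensors <- function(disc, x_in, target, params, train = TRUE) {
  fw <- discriminator_forward(disc, x_in, train = train)
  disc <- fw$model
  pm <- as_mat(fw$probs)
  pt <- pm[cbind(seq_len(nrow(pm)), target)]
  fl <- focal_log_loss(pt, params)
  dz <- focal_softmax_logit_grad(fw$probs, target, params)
  bk <- discriminator_backward(disc, fw$cache, dz)
  list(disc = disc, fl = fl$mean, grads = bk$grads, dx = bk$dx,
       probs = fw$probs)
}

#' Train AutoConfidence adversarially
#'
#' Per batch: (1) the generator proposes segmentations for the batch
#' images; (2) proposals are argmax-binarized (and optionally corrupted
#' with synthetic errors); (3) the discriminator takes one Adam step on the
#' interleaved gold-standard inputs (d2GS = all zeros) and generated inputs
#' (d2GS computed against the gold standard), under focal log loss; (4) the
#' generator takes one Adam step on
#' `alpha * FL_G + beta * (1 - FL_D on the generated sample)`, receiving
#' the adversarial gradient through the discriminator via its softmax organ
#' channels. Exactly one update of each network per batch.
#'
#' @param data List of slices (`list(image =, masks =)`), e.g. from
#'   [generate_slices()] or [read_dataset()].
#' @param config [train_config()].
#' @return An `aco_fit` with elements `generator`, `discriminator`,
#'   `history` (tibble of per-batch loss curves), `config`, `organ_names`.
#' @export
train <- function(data, config = train_config()) {
  fit <- with_seed(config$seed, train_impl(data, config, adversarial = TRUE))
  maybe_checkpoint(fit, config)
}

#' Train generator and discriminator sequentially (ablation baseline)
#'
#' The generator is first trained to convergence on its supervised focal
#' loss alone, then frozen; the discriminator is subsequently trained on
#' the frozen generator's raw outputs (no synthetic-error corruption: the
#' baseline discriminator sees only the fixed internal segmentations).
#' Used as the non-adversarial comparator.
#'
#' @inheritParams train
#' @return An `aco_fit`.
#' @export
train_sequential_baseline <- function(data, config = train_config()) {
  fit <- with_seed(config$seed, train_impl(data, config, adversarial = FALSE))
  maybe_checkpoint(fit, config)
}

maybe_checkpoint <- function(fit, config) {
  if (!is.null(config$checkpoint_dir)) {
    dir.create(config$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(fit, file.path(config$checkpoint_dir, "aco_fit.rds"))
  }
  fit
}

train_impl <- function(data, config, adversarial = TRUE) {
  stopifnot(length(data) >= 1)
  k <- dim(data[[1]]$masks)[3]
  nms <- organ_names(data[[1]]$masks)
  params <- config$loss_params
  gen <- build_generator(
    generator_spec(out_classes = k + 1L, base_filters = config$base_filters,
                   dropout_rate = config$dropout_rate,
                   norm = config$norm_generator),
    seed = sample.int(.Machine$integer.max, 1)
  )
  disc <- build_discriminator(
    discriminator_spec(in_channels = k + 1L,
                       base_filters = config$base_filters,
                       norm = config$norm_discriminator),
    seed = sample.int(.Machine$integer.max, 1)
  )
  opt_g <- adam_init(gen$params)
  opt_d <- adam_init(disc$params)
  history <- list()

  generator_step <- function(batch, adversarial) {
    fw <- generator_forward(gen, batch$x, train = TRUE)
    gen <<- fw$model
    t_gs <- gs_target_classes(batch$gs)
    pm <- as_mat(fw$probs)
    pt <- pm[cbind(seq_len(nrow(pm)), t_gs)]
    fl_g <- focal_log_loss(pt, params)$mean
    dz <- focal_softmax_logit_grad(fw$probs, t_gs, params) * params$alpha
    fl_d_gen <- NA_real_
    if (adversarial && params$beta > 0) {
      hard <- hard_masks_batch(fw$probs)
      d2gs_gen <- d2gs_batch(hard, batch$gs)
      soft_in <- disc_input(fw$probs[, , , -1L, drop = FALSE], batch$x,
                            config$ablation)
      dfw <- discriminator_forward(disc, soft_in, train = FALSE)
      t_d <- d2gs_target_classes(d2gs_gen)
      dpm <- as_mat(dfw$probs)
      dpt <- dpm[cbind(seq_len(nrow(dpm)), t_d)]
      fl_d_gen <- focal_log_loss(dpt, params)$mean
      dzd <- focal_softmax_logit_grad(dfw$probs, t_d, params) * (-params$beta)
      dbk <- discriminator_backward(disc, dfw$cache, dzd)
      dmask <- dbk$dx[, , , seq_len(k), drop = FALSE]
      if (config$ablation == "zero_segmentation") dmask[] <- 0
      dprobs <- array(0, dim(fw$probs))
      dprobs[, , , -1L] <- dmask
      # probability-space gradient -> logit-space through the softmax
      pmat <- as_mat(fw$probs)
      dpmat <- as_mat(dprobs)
      inner <- rowSums(dpmat * pmat)
      dz <- dz + as_tensor(pmat * (dpmat - inner), dim(fw$probs)[1:3])
    }
    grads <- generator_backward(gen, fw$cache, dz)
    st <- adam_step(gen$params, grads, opt_g, lr = config$lr_generator)
    gen$params <<- st$params
    opt_g <<- st$state
    list(fl_g = fl_g, fl_d_gen = fl_d_gen)
  }

  discriminator_step <- function(batch, use_errors = config$use_synthetic_errors) {
    fw_eval <- generator_forward(gen, batch$x, train = FALSE)
    hard <- hard_masks_batch(fw_eval$probs)
    n <- dim(batch$x)[3]
    corrupted <- hard
    if (use_errors) {
      for (i in seq_len(n)) {
        res <- inject(
          oar_masks(array(hard[, , i, ], dim(hard)[c(1, 2, 4)]), nms),
          softmax = array(fw_eval$probs[, , i, ], dim(fw_eval$probs)[c(1, 2, 4)]),
          config = config$error_config,
          seed = sample.int(.Machine$integer.max, 1)
        )
        corrupted[, , i, ] <- res$masks
      }
    }
    d2gs_fake <- d2gs_batch(corrupted, batch$gs)
    x_real <- disc_input(batch$gs, batch$x, config$ablation)
    x_fake <- disc_input(corrupted, batch$x, config$ablation)
    x_in <- abind4(x_real, x_fake)
    t_real <- rep(1L, prod(dim(batch$x)[1:3]))
    t_fake <- d2gs_target_classes(d2gs_fake)
    target <- c(t_real, t_fake)
    # interleaving is along the batch axis: (real block, fake block), one
    # combined update
    st <- disc_step_tensors(disc, x_in, target, params, train = TRUE)
    disc <<- st$disc
    upd <- adam_step(disc$params, st$grads, opt_d,
                     lr = config$lr_discriminator)
    disc$params <<- upd$params
    opt_d <<- upd$state
    st$fl
  }

  n <- length(data)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bi in seq_along(batches)) {
      batch <- stack_batch(data[batches[[bi]]])
      if (adversarial) {
        fl_d <- discriminator_step(batch)
        gstep <- generator_step(batch, adversarial = TRUE)
      } else {
        fl_d <- NA_real_
        gstep <- generator_step(batch, adversarial = FALSE)
      }
      l_gen <- if (is.na(gstep$fl_d_gen)) params$alpha * gstep$fl_g else
        generator_total_loss(gstep$fl_g, gstep$fl_d_gen, params)
      if (!is.finite(gstep$fl_g) || (adversarial && !is.finite(fl_d))) {
        abort(sprintf("training diverged at epoch %d batch %d (non-finite loss).",
                      epoch, bi))
      }
      history[[length(history) + 1L]] <- tibble(
        phase = "adversarial", epoch = epoch, batch = bi,
        fl_g = gstep$fl_g, fl_d = fl_d, l_gen = l_gen
      )
    }
  }

  if (!adversarial) {
    # phase 2: discriminator on the frozen generator's raw outputs (no
    # synthetic corruption -- the baseline sees only the fixed IAS)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (bi in seq_along(batches)) {
        batch <- stack_batch(data[batches[[bi]]])
        fl_d <- discriminator_step(batch, use_errors = FALSE)
        history[[length(history) + 1L]] <- tibble(
          phase = "discriminator", epoch = epoch, batch = bi,
          fl_g = NA_real_, fl_d = fl_d, l_gen = NA_real_
        )
      }
    }
  }

  fit <- structure(list(
    generator = gen, discriminator = disc,
    history = if (length(history)) dplyr::bind_rows(history) else
      tibble(phase = character(), epoch = integer(), batch = integer(),
             fl_g = double(), fl_d = double(), l_gen = double()),
    config = config, organ_names = nms, k = k,
    adversarial = adversarial, threshold = 0.5
  ), class = "aco_fit")
  if (config$epochs > 0) {
    fit$threshold <- calibrate_threshold(fit, data, config)
  }
  fit
}

# Operating-point selection: focal-loss-trained softmax outputs are
# systematically under-confident, so a fixed 0.5 cut can sit above every
# predicted error probability. The threshold is chosen by maximizing pooled
# MCC on error-injected *training* slices (held-out data is never touched).
calibrate_threshold <- function(fit, data, config, n_cal = 16L,
                                grid = seq(0.05, 0.95, by = 0.05)) {
  idx <- seq_len(min(n_cal, length(data)))
  cal_cfg <- config$error_config
  cal_cfg$p_class_perturb <- 0 # corrupted gold standards expose no softmax
  cal_cfg$p_geometric <- max(cal_cfg$p_geometric, 0.9)
  scores <- vector("list", length(idx))
  labels <- vector("list", length(idx))
  for (i in idx) {
    s <- data[[i]]
    seg <- inject(s$masks, softmax = NULL, config = cal_cfg,
                  seed = sample.int(.Machine$integer.max, 1))$masks
    conf <- predict_confidence(s$image, seg, fit$discriminator,
                               ablation = config$ablation)
    scores[[i]] <- as.vector(conf)
    labels[[i]] <- as.vector(unclass(compute_d2gs(seg, s$masks)))
  }
  sc <- unlist(scores)
  lb <- unlist(labels)
  best <- 0.5
  best_mcc <- -Inf
  for (th in grid) {
    pred <- sc >= th
    m <- metrics_from_counts(sum(pred & lb == 1), sum(!pred & lb == 0),
                             sum(pred & lb == 0), sum(!pred & lb == 1))
    if (!is.na(m$mcc) && m$mcc > best_mcc) {
      best_mcc <- m$mcc
      best <- th
    }
  }
  best
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Argmax-binarized organ channels of a softmax batch: (H, W, N, K).
hard_masks_batch <- function(probs) {
  d <- dim(probs)
  k <- d[4] - 1L
  pm <- as_mat(probs)
  lab <- max.col(pm, ties.method = "first")
  out <- array(0, c(d[1:3], k))
  for (j in seq_len(k)) {
    out[, , , j] <- array((lab == j + 1L) + 0, d[1:3])
  }
  out
}

# Batch d2GS: (H, W, N) binary array from (H, W, N, K) mask batches.
d2gs_batch <- function(pred, gs) {
  d <- dim(pred)
  out <- array(0, d[1:3])
  for (j in seq_len(d[4])) out <- pmax(out, abs(pred[, , , j] - gs[, , , j]))
  array(out, d[1:3])
}

#' @export
print.aco_fit <- function(x, ...) {
  cat(sprintf(
    "<aco_fit> %s training, %d organ channels (%s)\n",
    if (x$adversarial) "adversarial" else "sequential",
    x$k, paste(x$organ_names, collapse = ", ")
  ))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  %d batch updates; final FL_G %.4f, FL_D %.4f\n",
                nrow(x$history), last$fl_g, last$fl_d))
  } else {
    cat("  untrained (0 epochs)\n")
  }
  invisible(x)
}

#' Predict a voxel-wise confidence map for any segmentation
#'
#' Runs the trained discriminator in evaluation mode on an (image,
#' segmentation) pair from any source — the internal generator, an external
#' model, or manual contours. No gold standard is needed.
#'
#' @param image `H x W` intensity matrix in `[0, 1]`.
#' @param seg [oar_masks()] with the K channels the model was trained on.
#' @param fit An `aco_fit` (or a bare `discriminator_model`).
#' @param ablation Input-ablation override; defaults to the fit's training
#'   ablation so train and test are consistent.
#' @return `H x W` matrix of error-class probabilities (`p_error`);
#'   confidence is `1 - p_error`.
#' @export
predict_confidence <- function(image, seg, fit, ablation = NULL) {
  disc <- if (inherits(fit, "aco_fit")) fit$discriminator else fit
  ablation <- ablation %||%
    (if (inherits(fit, "aco_fit")) fit$config$ablation else "none")
  k <- disc$spec$in_channels - 1L
  if (dim(seg)[3] != k) {
    abort(sprintf("segmentation has %d channels but the model was trained with %d.",
                  dim(seg)[3], k))
  }
  masks4 <- array(seg, c(dim(seg)[1:2], 1L, k))
  img4 <- array(image, c(dim(image), 1L, 1L))
  x <- disc_input(masks4, img4, ablation)
  fw <- discriminator_forward(disc, x, train = FALSE)
  fw$probs[, , 1L, 2L]
}

#' Predict a softmax segmentation from the trained generator
#'
#' @param image `H x W` intensity matrix.
#' @param fit An `aco_fit` (or a bare `generator_model`).
#' @return `H x W x (K+1)` softmax stack (channel 1 = background).
#' @export
predict_segmentation <- function(image, fit) {
  gen <- if (inherits(fit, "aco_fit")) fit$generator else fit
  x <- array(image, c(dim(image), 1L, 1L))
  fw <- generator_forward(gen, x, train = FALSE)
  array(fw$probs[, , 1L, ], dim(fw$probs)[c(1, 2, 4)])
}
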