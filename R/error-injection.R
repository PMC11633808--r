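# Synthetic segmentation corruption: rigid misregistration, smooth
# thin-plate-spline deformation, organ class perturbation and whole-organ
# removal. Used both as training-time hard examples and to emulate external
# auto-segmentation models of low/high quality at test time.

#' Error injection configuration
#'
#' @param p_geometric,p_class_perturb,p_removal Per-slice application
#'   probabilities of each error family.
#' @param rotation_range Max |rotation| in degrees (drawn uniformly).
#' @param translation_range Max |translation| per axis in voxels.
#' @param tps_grid_spacing Control-grid spacing of the thin-plate-spline
#'   deformation, in mm (default 20 = 2 cm; at 1 mm in-plane spacing this
#'   is 20 voxels).
#' @param tps_sigma Standard deviation (mm) of the Normal control-point
#'   displacement vectors.
#' @param magnitude_scale Multiplier on rotation/translation/tps_sigma;
#'   values > 1 emulate a low-quality external model, values < 1 a
#'   high-quality one.
#' @param seed Integer seed used by [inject()].
#' @return An `error_config` list.
#' @export
error_config <- function(p_geometric = 0.9, p_class_perturb = 0.2,
                         p_removal = 0.3, rotation_range = 10,
                         translation_range = 4, tps_grid_spacing = 20,
                         tps_sigma = 3, magnitude_scale = 1, seed = 1L) {
  probs <- c(p_geometric, p_class_perturb, p_removal)
  if (any(probs < 0) || any(probs > 1)) {
    abort("application probabilities must lie in [0, 1].")
  }
  stopifnot(tps_grid_spacing > 0, tps_sigma >= 0, magnitude_scale >= 0,
            rotation_range >= 0, translation_range >= 0)
  structure(list(
    p_geometric = p_geometric, p_class_perturb = p_class_perturb,
    p_removal = p_removal, rotation_range = rotation_range,
    translation_range = translation_range,
    tps_grid_spacing = tps_grid_spacing, tps_sigma = tps_sigma,
    magnitude_scale = magnitude_scale, seed = as.integer(seed)
  ), class = "error_config")
}

# Resample all channels with nearest-neighbour at source coordinates given
# by (src_r, src_c) matrices; out-of-bounds voxels become 0.
warp_masks_nn <- function(masks, src_r, src_c) {
  h <- dim(masks)[1]; w <- dim(masks)[2]; k <- dim(masks)[3]
  ri <- round(src_r); ci <- round(src_c)
  ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
  out <- array(0, dim(masks))
  lin <- cbind(ri[ok], ci[ok])
  for (j in seq_len(k)) {
    plane <- matrix(0, h, w)
    src <- masks[, , j]
    plane[ok] <- src[lin]
    out[, , j] <- plane
  }
  oar_masks(out, organ_names(masks))
}

#' Rigid transformation of a mask set
#'
#' Rotates about the image centre and translates, applying the identical
#' transform to every channel with nearest-neighbour resampling (so masks
#' stay binary). Voxels mapped from outside the grid become 0.
#'
#' @param masks [oar_masks()].
#' @param rotation Rotation angle in degrees (counter-clockwise in
#'   (row, col) coordinates).
#' @param translation Length-2 voxel shift `(dr, dc)`: a mask voxel at
#'   `(r, c)` moves to `(r + dr, c + dc)`.
#' @return Transformed `oar_masks`.
#' @export
apply_rigid <- function(masks, rotation = 0, translation = c(0, 0)) {
  stopifnot(length(translation) == 2)
  h <- dim(masks)[1]; w <- dim(masks)[2]
  if (rotation == 0 && all(translation == 0)) return(masks)
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  th <- rotation * pi / 180
  rc <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  # inverse mapping: undo translation, then rotate by -theta about centre
  r1 <- rc - translation[1] - ctr[1]
  c1 <- cc - translation[2] - ctr[2]
  src_r <- cos(th) * r1 + sin(th) * c1 + ctr[1]
  src_c <- -sin(th) * r1 + cos(th) * c1 + ctr[2]
  warp_masks_nn(masks, src_r, src_c)
}

# Dense displacement field interpolated by a thin-plate spline from Normal
# control vectors on a regular grid. Returns list(dr, dc) in voxels.
tps_field <- function(h, w, grid_spacing, sigma, spacing = 1, seed = NULL) {
  with_seed(seed, {
    step <- max(2, grid_spacing / spacing) # voxels between control points
    gr <- unique(c(seq(1, h, by = step), h))
    gc <- unique(c(seq(1, w, by = step), w))
    if (length(gr) < 2 || length(gc) < 2) abort("degenerate TPS control grid.")
    pts <- as.matrix(expand.grid(r = gr, c = gc))
    disp <- matrix(rnorm(nrow(pts) * 2, 0, sigma / spacing), ncol = 2)
    if (sigma == 0) {
      return(list(dr = matrix(0, h, w), dc = matrix(0, h, w)))
    }
    # thin-plate spline system: [K P; t(P) 0] [w; a] = [v; 0]
    n <- nrow(pts)
    d2 <- as.matrix(stats::dist(pts))^2
    K <- ifelse(d2 == 0, 0, 0.5 * d2 * log(d2)) # r^2 log r = d2/2 * log(d2)
    P <- cbind(1, pts)
    A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
    rhs <- rbind(disp, matrix(0, 3, 2))
    coef <- solve(A + diag(1e-8, n + 3), rhs)
    rc <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    q <- cbind(as.vector(rc), as.vector(cc))
    d2q <- outer(q[, 1], pts[, 1], `-`)^2 + outer(q[, 2], pts[, 2], `-`)^2
    U <- ifelse(d2q == 0, 0, 0.5 * d2q * log(d2q))
    B <- cbind(U, 1, q)
    f <- B %*% coef
    list(dr = matrix(f[, 1], h, w), dc = matrix(f[, 2], h, w))
  })
}

#' Thin-plate-spline deformation of a mask set
#'
#' A smooth non-rigid deformation field is interpolated from independent
#' Normal(0, `sigma_mm`) displacement vectors placed on a regular control
#' grid of the stated spacing; all channels share the field and are warped
#' with nearest-neighbour resampling.
#'
#' @param masks [oar_masks()].
#' @param grid_spacing_mm Control-grid spacing in mm (default 20 = 2 cm).
#' @param sigma_mm Std of control displacement vectors in mm; 0 is the
#'   identity.
#' @param spacing In-plane voxel spacing in mm/voxel (default 1).
#' @param seed Integer seed (field is reproducible from it).
#' @return Deformed `oar_masks`.
#' @export
apply_tps <- function(masks, grid_spacing_mm = 20, sigma_mm = 3,
                      spacing = 1, seed = NULL) {
  if (sigma_mm == 0) return(masks)
  h <- dim(masks)[1]; w <- dim(masks)[2]
  fld <- tps_field(h, w, grid_spacing_mm, sigma_mm, spacing, seed)
  rc <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  # backward mapping: sample the source at x + d(x)
  warp_masks_nn(masks, rc + fld$dr, cc + fld$dc)
}

#' Organ class perturbation
#'
#' Relabels every voxel whose argmax class is the target organ to its
#' second-most-likely class under the softmax, mimicking a whole-organ
#' labelling error. All other voxels are unchanged.
#'
#' @param softmax `H x W x (K+1)` softmax stack (channel 1 = background).
#' @param target_channel Organ index in `1..K`.
#' @param names Optional organ names for the output masks.
#' @return `oar_masks` with K channels reflecting the perturbed labelling.
#' @export
perturb_class <- function(softmax, target_channel, names = NULL) {
  validate_softmax(softmax)
  d <- dim(softmax)
  k <- d[3] - 1L
  stopifnot(target_channel >= 1, target_channel <= k)
  lab <- argmax_classes(softmax)
  target_class <- target_channel + 1L
  sel <- lab == target_class
  if (!any(sel)) {
    warn("target channel is empty under argmax; class perturbation is a no-op.")
  } else {
    m <- matrix(softmax, d[1] * d[2], d[3])
    msel <- m[which(sel), , drop = FALSE]
    msel[, target_class] <- -Inf
    second <- max.col(msel, ties.method = "first")
    lab[sel] <- as.integer(second)
  }
  out <- array(0, c(d[1], d[2], k))
  for (j in seq_len(k)) out[, , j] <- (lab == j + 1L) + 0
  oar_masks(out, names)
}

#' Remove an entire organ mask
#'
#' @param masks [oar_masks()].
#' @param channel Organ channel to empty.
#' @return `oar_masks` with that channel all-zero and all others
#'   bit-identical.
#' @export
remove_oar <- function(masks, channel) {
  k <- dim(masks)[3]
  if (channel < 1 || channel > k) {
    abort(sprintf("`channel` must be in 1..%d.", k))
  }
  masks[, , channel] <- 0
  oar_masks(unclass(masks), organ_names(masks))
}

#' Inject synthetic errors into a segmentation
#'
#' Applies each error family independently with its configured probability:
#' geometric (a rigid rotation/translation plus a thin-plate-spline
#' deformation applied jointly to all channels, emulating misregistration),
#' class perturbation of one random organ (requires the softmax), and
#' removal of one random organ. Magnitudes scale with
#' `config$magnitude_scale`. Deterministic given `seed`.
#'
#' @param seg_masks [oar_masks()].
#' @param softmax Optional softmax stack; required when
#'   `p_class_perturb > 0`.
#' @param config [error_config()].
#' @param seed Overrides `config$seed` when given.
#' @param spacing Voxel spacing in mm (default 1).
#' @return List with `masks` (corrupted `oar_masks`) and `log` (tibble:
#'   `family`, `params`, `channels`).
#' @export
inject <- function(seg_masks, softmax = NULL, config = error_config(),
                   seed = NULL, spacing = 1) {
  seed <- seed %||% config$seed
  if (config$p_class_perturb > 0 && is.null(softmax)) {
    abort("`softmax` is required when `p_class_perturb` > 0.")
  }
  with_seed(seed, {
    masks <- seg_masks
    nms <- organ_names(seg_masks)
    k <- dim(seg_masks)[3]
    sc <- config$magnitude_scale
    log_rows <- list()
    if (runif(1) < config$p_class_perturb) {
      present <- which(vapply(seq_len(k), function(j) {
        any(argmax_classes(softmax) == j + 1L)
      }, logical(1)))
      if (length(present) > 0) {
        ch <- if (length(present) == 1) present else sample(present, 1)
        masks <- perturb_class(softmax, ch, nms)
        log_rows[[length(log_rows) + 1L]] <- tibble(
          family = "class_perturb", params = "second-argmax relabel",
          channels = nms[ch]
        )
      }
    }
    if (runif(1) < config$p_geometric) {
      rot <- runif(1, -config$rotation_range, config$rotation_range) * sc
      tr <- runif(2, -config$translation_range, config$translation_range) * sc
      masks <- apply_rigid(masks, rot, tr)
      tps_seed <- sample.int(.Machine$integer.max, 1)
      masks <- apply_tps(masks, config$tps_grid_spacing,
                         config$tps_sigma * sc, spacing, tps_seed)
      log_rows[[length(log_rows) + 1L]] <- tibble(
        family = "geometric",
        params = sprintf("rot=%.2fdeg tr=(%.2f,%.2f)vox tps_sigma=%.2fmm",
                         rot, tr[1], tr[2], config$tps_sigma * sc),
        channels = "all"
      )
    }
    if (runif(1) < config$p_removal) {
      ch <- sample.int(k, 1)
      masks <- remove_oar(masks, ch)
      log_rows[[length(log_rows) + 1L]] <- tibble(
        family = "removal", params = "channel emptied", channels = nms[ch]
      )
    }
    log <- if (length(log_rows)) dplyr::bind_rows(log_rows) else
      tibble(family = character(), params = character(), channels = character())
    list(masks = masks, log = log)
  })
}
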