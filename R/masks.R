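# Binary-mask algebra: d2GS construction, softmax binarization, Dice and
# voxel-wise confusion labelling.

#' Construct a multi-organ mask set
#'
#' Bundles K aligned per-organ binary masks into a single `H x W x K` array
#' with organ names attached along the channel dimension. Channel order is
#' meaningful everywhere in the package (it must match between a prediction
#' and its gold standard).
#'
#' @param channels An `H x W x K` array (or an `H x W` matrix for K = 1) of
#'   0/1 values, one channel per organ.
#' @param names Optional character vector of K organ labels.
#' @return An `oar_masks` array.
#' @export
oar_masks <- function(channels, names = NULL) {
  if (is.matrix(channels)) channels <- array(channels, c(dim(channels), 1L))
  if (length(dim(channels)) != 3L) {
    abort("`channels` must be an H x W x K array.")
  }
  stop_if_not_binary(channels, "channels")
  storage.mode(channels) <- "double"
  k <- dim(channels)[3]
  names <- names %||% dimnames(channels)[[3]] %||% paste0("organ_", seq_len(k))
  if (length(names) != k) abort("`names` must have one label per channel.")
  dimnames(channels) <- list(NULL, NULL, names)
  structure(channels, class = c("oar_masks", "array"))
}

#' @export
print.oar_masks <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<oar_masks> %dx%d voxels, %d organ channel(s): %s\n", d[1], d[2], d[3],
    paste(dimnames(x)[[3]], collapse = ", ")
  ))
  cat(sprintf("  foreground voxels per channel: %s\n",
              paste(apply(x, 3, sum), collapse = ", ")))
  invisible(x)
}

organ_names <- function(masks) dimnames(masks)[[3]]

#' Difference-to-gold-standard error mask
#'
#' The binary d2GS label: the channel-wise maximum of the absolute difference
#' between a predicted mask set and the gold-standard mask set. A voxel is 1
#' (error class) wherever any organ channel disagrees — i.e. wherever the
#' proposed segmentation over- or under-segments any structure.
#'
#' @param pred,gs `oar_masks` (or plain binary arrays) with identical shape
#'   and channel order.
#' @return An `H x W` binary matrix of class `d2gs_mask`.
#' @examples
#' gs <- oar_masks(array(0, c(8, 8, 2)))
#' pr <- gs; pr[3, 3, 1] <- 1
#' sum(compute_d2gs(pr, gs)) # 1
#' @export
compute_d2gs <- function(pred, gs) {
  check_same_shape(pred, gs, "`pred` and `gs`")
  stop_if_not_binary(pred, "pred")
  stop_if_not_binary(gs, "gs")
  if (is.matrix(pred)) {
    d <- abs(pred - gs)
  } else {
    d <- apply(abs(pred - gs), c(1, 2), max)
  }
  structure(d, class = c("d2gs_mask", class(matrix())))
}

#' Binarize a softmax segmentation by per-voxel argmax
#'
#' Converts a `H x W x (K+1)` softmax stack (channel 1 = background, channels
#' 2..K+1 = organs) into K binary organ masks. Ties are broken toward the
#' lowest class index, so an all-uniform voxel lands in background.
#'
#' @param probs Softmax array; per-voxel probabilities must sum to 1
#'   (tolerance 1e-6).
#' @param names Optional organ names for the K foreground channels.
#' @return `oar_masks` with K channels.
#' @export
softmax_to_masks <- function(probs, names = NULL) {
  validate_softmax(probs)
  d <- dim(probs)
  k <- d[3] - 1L
  lab <- argmax_classes(probs)
  out <- array(0, c(d[1], d[2], k))
  for (j in seq_len(k)) out[, , j] <- (lab == j + 1L) + 0
  oar_masks(out, names)
}

validate_softmax <- function(probs, tol = 1e-6) {
  if (length(dim(probs)) != 3L || dim(probs)[3] < 2L) {
    abort("softmax stack must be H x W x (K+1) with K >= 1.")
  }
  if (any(probs < -tol) || any(probs > 1 + tol)) {
    abort("softmax probabilities must lie in [0, 1].")
  }
  s <- apply(probs, c(1, 2), sum)
  if (max(abs(s - 1)) > tol) {
    abort("softmax probabilities must sum to 1 per voxel (tolerance 1e-6).")
  }
  invisible(probs)
}

# Per-voxel argmax with lowest-index tie-break; returns H x W integer labels
# in 1..(K+1) where 1 is background.
argmax_classes <- function(probs) {
  d <- dim(probs)
  m <- matrix(probs, d[1] * d[2], d[3])
  lab <- max.col(m, ties.method = "first")
  matrix(as.integer(lab), d[1], d[2])
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`. When both masks are empty the score is
#' undefined and `NA` is returned, so degenerate organs can be excluded from
#' averages instead of scoring a silent 1.
#'
#' @param pred,gs Binary matrices of identical shape.
#' @return A number in `[0, 1]`, or `NA` for the empty-vs-empty case.
#' @export
dsc <- function(pred, gs) {
  check_same_shape(pred, gs, "`pred` and `gs`")
  stop_if_not_binary(pred, "pred")
  stop_if_not_binary(gs, "gs")
  denom <- sum(pred) + sum(gs)
  if (denom == 0) return(NA_real_)
  2 * sum(pred * gs) / denom
}

# Confusion labels are stored as an integer matrix with this fixed coding.
CONFUSION_LEVELS <- c(TN = 1L, FP = 2L, FN = 3L, TP = 4L)

#' Voxel-wise confusion map of an error prediction against d2GS
#'
#' Positive class = error voxel. `TP` where prediction and d2GS are both 1,
#' `FP` where predicted-only, `FN` where label-only, `TN` elsewhere. The
#' `gdc_modified` flag starts all-FALSE and is set only by
#' [geometric_distance_correction()].
#'
#' @param pred_error Binary matrix of predicted error voxels (e.g. a
#'   thresholded confidence map).
#' @param d2gs Binary d2GS matrix, same shape.
#' @return A `confusion_map`: list with `labels` (integer matrix coded
#'   TN=1, FP=2, FN=3, TP=4) and `gdc_modified` (logical matrix).
#' @export
confusion_map <- function(pred_error, d2gs) {
  check_same_shape(pred_error, d2gs, "`pred_error` and `d2gs`")
  stop_if_not_binary(pred_error, "pred_error")
  stop_if_not_binary(d2gs, "d2gs")
  lab <- matrix(CONFUSION_LEVELS[["TN"]], nrow(pred_error), ncol(pred_error))
  lab[pred_error == 1 & d2gs == 1] <- CONFUSION_LEVELS[["TP"]]
  lab[pred_error == 1 & d2gs == 0] <- CONFUSION_LEVELS[["FP"]]
  lab[pred_error == 0 & d2gs == 1] <- CONFUSION_LEVELS[["FN"]]
  new_confusion_map(lab, matrix(FALSE, nrow(lab), ncol(lab)))
}

new_confusion_map <- function(labels, gdc_modified) {
  structure(
    list(labels = labels, gdc_modified = gdc_modified),
    class = "confusion_map"
  )
}

#' @export
print.confusion_map <- function(x, ...) {
  counts <- confusion_counts(x)
  cat(sprintf(
    "<confusion_map> %dx%d voxels | TP %d  FP %d  FN %d  TN %d | GDC-modified %d\n",
    nrow(x$labels), ncol(x$labels),
    counts[["tp"]], counts[["fp"]], counts[["fn"]], counts[["tn"]],
    sum(x$gdc_modified)
  ))
  invisible(x)
}

# Named tp/tn/fp/fn counts, optionally restricted to a logical region mask.
confusion_counts <- function(cm, region = NULL) {
  lab <- cm$labels
  if (!is.null(region)) lab <- lab[region]
  c(
    tp = sum(lab == CONFUSION_LEVELS[["TP"]]),
    tn = sum(lab == CONFUSION_LEVELS[["TN"]]),
    fp = sum(lab == CONFUSION_LEVELS[["FP"]]),
    fn = sum(lab == CONFUSION_LEVELS[["FN"]])
  )
}

#' Threshold a confidence map into a binary predicted-error mask
#'
#' @param p_error Matrix of per-voxel error-class probabilities in `[0, 1]`.
#' @param threshold Error-class probability at or above which a voxel is
#'   called an error. Default 0.5.
#' @return Binary matrix.
#' @export
binarize_confidence <- function(p_error, threshold = 0.5) {
  if (any(p_error < 0) || any(p_error > 1)) {
    abort("`p_error` must lie in [0, 1].")
  }
  (p_error >= threshold) + 0
}
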