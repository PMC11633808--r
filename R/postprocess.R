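# Post-processing: Intelligent Edge Removal on error maps and Geometric
# Distance Correction on evaluation confusion maps. Morphology and distance
# transforms are delegated to EBImage with explicitly constructed kernels.

# Structuring elements ------------------------------------------------------

# Odd-sided k x k box kernel.
box_kernel <- function(k) {
  stopifnot(k >= 1)
  side <- if (k %% 2 == 1) k else k + 1
  matrix(1, side, side)
}

# Euclidean disc of the given radius (voxels with dr^2 + dc^2 <= r^2).
disc_kernel <- function(radius) {
  r <- ceiling(radius)
  off <- -r:r
  d2 <- outer(off^2, off^2, `+`)
  (d2 <= radius^2 + 1e-9) + 0
}

dilate_binary <- function(x, kern) {
  if (sum(x) == 0) return(x * 0)
  y <- EBImage::dilate(x, kern)
  (y > 0) + 0
}

# Sobel gradient-magnitude edge of a binary mask (nonzero gradient voxels).
sobel_edge <- function(mask) {
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- EBImage::filter2(mask, sx, boundary = 0)
  gy <- EBImage::filter2(mask, t(sx), boundary = 0)
  (abs(gx) + abs(gy) > 1e-9) + 0
}

#' Intelligent Edge Removal parameters
#'
#' @param k Edge-mask width in voxels (default 3, the minimum width found to
#'   remove thin boundary errors).
#' @param regrow_radius Euclidean radius used to regrow surviving errors
#'   back into the boundary band; defaults to `k / 2`.
#' @return An `ier_params` list.
#' @export
ier_params <- function(k = 3L, regrow_radius = k / 2) {
  stopifnot(k >= 1, regrow_radius >= 0)
  structure(list(k = as.integer(k), regrow_radius = regrow_radius),
            class = "ier_params")
}

#' Intelligent Edge Removal
#'
#' Removes "thin" error predictions hugging organ boundaries (partial-volume
#' artefacts of binary masks) while keeping substantial errors that merely
#' touch a boundary: (1) Sobel edges of every organ channel are united and
#' dilated to a width of `k` voxels; (2) errors inside the dilated edge band
#' are deleted; (3) surviving errors are regrown into the band by a
#' Euclidean radius of `k/2`, restricted to the original error map. Applied
#' identically to predicted error maps and to d2GS maps before metrics.
#'
#' @param error_map Binary matrix of error voxels.
#' @param seg [oar_masks()] whose boundaries define the edge band.
#' @param params [ier_params()].
#' @return Binary matrix; always a subset of `error_map`.
#' @export
intelligent_edge_removal <- function(error_map, seg, params = ier_params()) {
  check_same_shape(error_map, seg[, , 1], "`error_map` and `seg` channels")
  stop_if_not_binary(error_map, "error_map")
  edge <- matrix(0, nrow(error_map), ncol(error_map))
  for (j in seq_len(dim(seg)[3])) {
    edge <- pmax(edge, sobel_edge(seg[, , j]))
  }
  edge_band <- dilate_binary(edge, box_kernel(params$k))
  kept <- error_map * (1 - edge_band)
  regrown <- dilate_binary(kept, disc_kernel(params$regrow_radius)) *
    edge_band * error_map
  pmin(kept + regrown, 1)
}

#' Geometric Distance Correction parameters
#'
#' @param patch_size Odd side length (voxels) of the local window within
#'   which the true-positive region size and distances are measured.
#'   Default 31.
#' @return A `gdc_params` list.
#' @export
gdc_params <- function(patch_size = 31L) {
  stopifnot(patch_size >= 3, patch_size %% 2 == 1)
  structure(list(patch_size = as.integer(patch_size)), class = "gdc_params")
}

#' Geometric Distance Correction
#'
#' Evaluation-only reclassification that credits predictions of low
#' confidence near genuine error regions: for every FP or FN voxel, within
#' the local patch centred on it, the maximum dimension of the TP region is
#' taken as the inscribed-disc diameter (twice the maximum Euclidean
#' distance transform value inside the TP region), and the Euclidean
#' distance from the voxel to the nearest TP voxel is computed. If the
#' distance is smaller than the TP region dimension, FP becomes TP and FN
#' becomes TN, with the `gdc_modified` flag set. All decisions are made on
#' the original labels (no cascading); TP and TN voxels never change. The
#' correction never touches confidence maps — only confusion maps.
#'
#' @param cm A [confusion_map()].
#' @param params [gdc_params()].
#' @return A corrected `confusion_map`.
#' @export
geometric_distance_correction <- function(cm, params = gdc_params()) {
  stopifnot(inherits(cm, "confusion_map"))
  lab <- cm$labels
  h <- nrow(lab); w <- ncol(lab)
  tp <- lab == CONFUSION_LEVELS[["TP"]]
  if (!any(tp)) return(cm)
  cand <- which(lab == CONFUSION_LEVELS[["FP"]] |
                  lab == CONFUSION_LEVELS[["FN"]], arr.ind = TRUE)
  if (nrow(cand) == 0) return(cm)
  half <- (params$patch_size - 1L) %/% 2L
  new_lab <- lab
  modified <- cm$gdc_modified
  tp_idx <- which(tp, arr.ind = TRUE)
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    r0 <- max(1L, r - half); r1 <- min(h, r + half)
    c0 <- max(1L, c - half); c1 <- min(w, c + half)
    sel <- tp_idx[, 1] >= r0 & tp_idx[, 1] <= r1 &
      tp_idx[, 2] >= c0 & tp_idx[, 2] <= c1
    if (!any(sel)) next
    prows <- tp_idx[sel, 1]; pcols <- tp_idx[sel, 2]
    d_x_tp <- sqrt(min((prows - r)^2 + (pcols - c)^2))
    patch_tp <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
    patch_tp[cbind(prows - r0 + 1L, pcols - c0 + 1L)] <- 1
    d_tp_max <- 2 * max(EBImage::distmap(patch_tp, metric = "euclidean"))
    if (d_x_tp < d_tp_max) {
      if (lab[r, c] == CONFUSION_LEVELS[["FP"]]) {
        new_lab[r, c] <- CONFUSION_LEVELS[["TP"]]
      } else {
        new_lab[r, c] <- CONFUSION_LEVELS[["TN"]]
      }
      modified[r, c] <- TRUE
    }
  }
  new_confusion_map(new_lab, modified)
}
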