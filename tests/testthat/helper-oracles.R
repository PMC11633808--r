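# Brute-force reference implementations used as independent oracles. These
# deliberately use plain loops and first-principles definitions, never the
# package's own code paths.

oracle_d2gs <- function(pred, gs) {
  h <- dim(pred)[1]; w <- dim(pred)[2]; k <- dim(pred)[3]
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    v <- 0
    for (j in seq_len(k)) v <- max(v, abs(pred[r, c, j] - gs[r, c, j]))
    out[r, c] <- v
  }
  out
}

oracle_argmax <- function(probs) {
  h <- dim(probs)[1]; w <- dim(probs)[2]
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    v <- probs[r, c, ]
    out[r, c] <- which(v == max(v))[1]
  }
  out
}

oracle_second_argmax <- function(v, exclude) {
  v[exclude] <- -Inf
  which(v == max(v))[1]
}

oracle_confusion <- function(pred, lab) {
  h <- nrow(pred); w <- ncol(pred)
  out <- matrix("", h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    out[r, c] <- if (pred[r, c] == 1 && lab[r, c] == 1) "TP"
      else if (pred[r, c] == 1) "FP"
      else if (lab[r, c] == 1) "FN"
      else "TN"
  }
  out
}

# Sobel gradient magnitude by direct correlation (zero padding).
oracle_sobel_nonzero <- function(m) {
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  h <- nrow(m); w <- ncol(m)
  gx <- matrix(0, h, w); gy <- gx
  at <- function(r, c) if (r >= 1 && r <= h && c >= 1 && c <= w) m[r, c] else 0
  for (r in seq_len(h)) for (c in seq_len(w)) {
    for (dr in -1:1) for (dc in -1:1) {
      gx[r, c] <- gx[r, c] + sx[dr + 2, dc + 2] * at(r + dr, c + dc)
      gy[r, c] <- gy[r, c] + sx[dc + 2, dr + 2] * at(r + dr, c + dc)
    }
  }
  (abs(gx) + abs(gy) > 1e-9) + 0
}

# Binary dilation with an explicit offset set.
oracle_dilate <- function(m, offsets) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  on <- which(m == 1, arr.ind = TRUE)
  for (i in seq_len(nrow(on))) {
    for (o in seq_len(nrow(offsets))) {
      r <- on[i, 1] + offsets[o, 1]; c <- on[i, 2] + offsets[o, 2]
      if (r >= 1 && r <= h && c >= 1 && c <= w) out[r, c] <- 1
    }
  }
  out
}

box_offsets <- function(k) {
  half <- k %/% 2
  as.matrix(expand.grid(-half:half, -half:half))
}

disc_offsets <- function(radius) {
  r <- ceiling(radius)
  o <- as.matrix(expand.grid(-r:r, -r:r))
  o[o[, 1]^2 + o[, 2]^2 <= radius^2 + 1e-9, , drop = FALSE]
}

oracle_ier <- function(error_map, seg, k = 3) {
  h <- nrow(error_map); w <- ncol(error_map)
  edge <- matrix(0, h, w)
  for (j in seq_len(dim(seg)[3])) {
    edge <- pmax(edge, oracle_sobel_nonzero(seg[, , j]))
  }
  band <- oracle_dilate(edge, box_offsets(k))
  kept <- error_map * (1 - band)
  regrown <- matrix(0, h, w)
  kept_pos <- which(kept == 1, arr.ind = TRUE)
  cand <- which(band == 1 & error_map == 1, arr.ind = TRUE)
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept_pos) == 0) break
    d2 <- (kept_pos[, 1] - cand[i, 1])^2 + (kept_pos[, 2] - cand[i, 2])^2
    if (min(d2) <= (k / 2)^2 + 1e-9) regrown[cand[i, 1], cand[i, 2]] <- 1
  }
  pmin(kept + regrown, 1)
}

# GDC by exhaustive per-voxel distance computation.
oracle_gdc <- function(labels, patch_size) {
  h <- nrow(labels); w <- ncol(labels)
  half <- (patch_size - 1) %/% 2
  out <- labels
  mod <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    lv <- labels[r, c]
    if (lv != "FP" && lv != "FN") next
    r0 <- max(1, r - half); r1 <- min(h, r + half)
    c0 <- max(1, c - half); c1 <- min(w, c + half)
    tp <- NULL
    for (pr in r0:r1) for (pc in c0:c1) {
      if (labels[pr, pc] == "TP") tp <- rbind(tp, c(pr, pc))
    }
    if (is.null(tp)) next
    d_x_tp <- sqrt(min((tp[, 1] - r)^2 + (tp[, 2] - c)^2))
    # in-patch EDT of each TP voxel: distance to the nearest in-patch
    # non-TP voxel (patch borders are not background)
    edt_max <- 0
    for (i in seq_len(nrow(tp))) {
      best <- Inf
      for (pr in r0:r1) for (pc in c0:c1) {
        if (labels[pr, pc] != "TP") {
          best <- min(best, sqrt((pr - tp[i, 1])^2 + (pc - tp[i, 2])^2))
        }
      }
      edt_max <- max(edt_max, best)
    }
    d_tp_max <- 2 * edt_max
    if (d_x_tp < d_tp_max) {
      out[r, c] <- if (lv == "FP") "TP" else "TN"
      mod[r, c] <- TRUE
    }
  }
  list(labels = out, modified = mod)
}

# Labels of a package confusion_map as a character matrix.
cm_labels_chr <- function(cm) {
  lv <- c("TN", "FP", "FN", "TP")
  matrix(lv[cm$labels], nrow(cm$labels), ncol(cm$labels))
}

oracle_mcc <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(NA_real_)
  (tp * tn - fp * fn) / sqrt(den)
}
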