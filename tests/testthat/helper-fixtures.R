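# Programmatic fixtures shared across test files.

random_mask_set <- function(h = 16, w = 16, k = 3, p = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  oar_masks(array(rbinom(h * w * k, 1, p), c(h, w, k)))
}

random_disjoint_mask_set <- function(h = 16, w = 16, k = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lab <- matrix(sample(0:k, h * w, replace = TRUE), h, w)
  m <- array(0, c(h, w, k))
  for (j in seq_len(k)) m[, , j] <- (lab == j) + 0
  oar_masks(m)
}

random_softmax <- function(h = 8, w = 8, classes = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- array(rexp(h * w * classes), c(h, w, classes))
  s <- apply(a, c(1, 2), sum)
  for (j in seq_len(classes)) a[, , j] <- a[, , j] / s
  a
}

# A single-organ mask: filled disc at the given centre/radius.
disc_mask <- function(h, w, centre, radius) {
  rc <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((rc - centre[1])^2 + (cc - centre[2])^2 <= radius^2) + 0
}

small_phantom_config <- function(seed = 1, ...) {
  phantom_config(height = 64, width = 64, n_organs = 3, seed = seed, ...)
}

# Labels matrix (character) -> confusion_map object, for GDC tests.
cm_from_labels <- function(lab_chr) {
  code <- c(TN = 1L, FP = 2L, FN = 3L, TP = 4L)
  pred <- (lab_chr == "TP" | lab_chr == "FP") + 0
  d2 <- (lab_chr == "TP" | lab_chr == "FN") + 0
  cm <- confusion_map(pred, d2)
  stopifnot(all(code[lab_chr] == cm$labels))
  cm
}

random_labels <- function(h = 32, w = 32, seed = 1,
                          p = c(TN = 0.7, FP = 0.1, FN = 0.1, TP = 0.1)) {
  set.seed(seed)
  matrix(sample(names(p), h * w, replace = TRUE, prob = p), h, w)
}
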