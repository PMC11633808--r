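# Volume I/O: NIfTI via RNifti (single-slice volumes for images,
# multi-channel volumes for mask stacks with a channel-name sidecar) and
# PNG for 2D fixtures.

channels_sidecar <- function(path) paste0(path, ".channels")

#' Write an image slice or mask stack to disk
#'
#' NIfTI (`.nii` / `.nii.gz`) volumes are written with double precision so
#' reads round-trip bit-identically; mask stacks are stored as one
#' multi-channel volume with organ names in a `<path>.channels` sidecar.
#' `.png` is supported for 2D fixtures (grayscale, values in `[0, 1]`).
#'
#' @param x `H x W` matrix or [oar_masks()] array.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  is_masks <- inherits(x, "oar_masks") || length(dim(x)) == 3L
  if (grepl("\\.png$", path)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("the 'png' package is required for PNG output.")
    }
    png::writePNG(aperm_if_masks(x), path)
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    arr <- unclass(x)
    attributes(arr) <- list(dim = dim(arr) %||% c(dim(x)))
    ok <- tryCatch({
      RNifti::writeNifti(arr, path, datatype = "double")
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) abort(sprintf("failed to write '%s': %s", path,
                                   conditionMessage(ok)))
  } else {
    abort(sprintf("unknown volume format for '%s' (use .nii, .nii.gz or .png).",
                  path))
  }
  if (is_masks && !is.null(dimnames(x)[[3]])) {
    writeLines(dimnames(x)[[3]], channels_sidecar(path))
  }
  invisible(path)
}

aperm_if_masks <- function(x) {
  x <- if (length(dim(x)) == 3L) unclass(x) else unclass(as.matrix(x))
  storage.mode(x) <- "double"
  x
}

#' Read an image slice or mask stack
#'
#' Inverse of [write_volume()]: a 2D volume returns a plain matrix; a 3D
#' volume with a channel sidecar returns [oar_masks()].
#'
#' @param path `.nii`, `.nii.gz` or `.png` path.
#' @return Matrix or `oar_masks`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: '%s'.", path))
  if (grepl("\\.png$", path)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("the 'png' package is required for PNG input.")
    }
    arr <- png::readPNG(path)
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    arr <- as.array(RNifti::readNifti(path))
    attributes(arr) <- list(dim = dim(arr))
  } else {
    abort(sprintf("unknown volume format for '%s'.", path))
  }
  d <- dim(arr)
  if (length(d) > 2 && d[length(d)] == 1) {
    dim(arr) <- d[-length(d)]
    d <- dim(arr)
  }
  if (length(d) == 3L) {
    nm <- if (file.exists(channels_sidecar(path))) {
      readLines(channels_sidecar(path))
    }
    if (all(arr %in% c(0, 1))) return(oar_masks(arr, nm))
    dimnames(arr) <- if (!is.null(nm)) list(NULL, NULL, nm)
    return(arr)
  }
  arr
}

#' Load a phantom dataset from its manifest
#'
#' @param manifest Tibble from [generate_dataset()] or a path to a
#'   `manifest.csv`.
#' @return List of slices (`list(image =, masks =)`), ready for [train()].
#' @export
read_dataset <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- tibble::as_tibble(utils::read.csv(manifest,
                                                  stringsAsFactors = FALSE))
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    image <- read_volume(manifest$image_path[i])
    masks <- read_volume(manifest$masks_path[i])
    check_same_shape(image, masks[, , 1],
                     sprintf("image/masks pair in row %d", i))
    list(image = image, masks = masks)
  })
}
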