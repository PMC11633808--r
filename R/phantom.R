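# Synthetic multi-organ phantom slices standing in for clinical MRI data:
# elliptical/blob organs of varying size and contrast on a shaded, noisy
# background, with non-overlapping gold-standard masks.

#' Phantom simulation configuration
#'
#' Describes one family of 2D "MRI-like" slices: organ count, sizes,
#' organ-to-background contrasts, noise level and the difficulty flags that
#' reproduce the statistically hard features of clinical data (sub-10-voxel
#' lens-like structures, organs whose contrast is at or below the noise
#' floor).
#'
#' @param height,width Slice size in voxels (>= 32).
#' @param n_organs Number of organs (>= 1).
#' @param organ_size_range Min/max equivalent radius in voxels.
#' @param contrast_levels Organ-to-background intensity offsets in `[0, 1]`,
#'   recycled across organs.
#' @param noise_sigma Standard deviation of the additive Gaussian noise, in
#'   normalized intensity units.
#' @param include_tiny_organ Force one organ below 10 voxels of area.
#' @param include_low_contrast_organ Force one organ's contrast at or below
#'   `noise_sigma` (contrast-to-noise ratio <= 1).
#' @param shading_amplitude Amplitude of the low-frequency multiplicative
#'   shading field (0 disables it).
#' @param spacing In-plane voxel spacing in mm (default 1, so a 2 cm
#'   deformation grid spans 20 voxels).
#' @param seed Integer seed; the full phantom is reproducible from it.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(height = 64L, width = 64L, n_organs = 3L,
                           organ_size_range = c(3, 9),
                           contrast_levels = c(0.45, 0.3, 0.2),
                           noise_sigma = 0.05,
                           include_tiny_organ = TRUE,
                           include_low_contrast_organ = TRUE,
                           shading_amplitude = 0.08,
                           spacing = 1,
                           seed = 1L) {
  if (height < 32 || width < 32) abort("phantom slices must be at least 32x32.")
  if (n_organs < 1) abort("`n_organs` must be >= 1.")
  stopifnot(length(organ_size_range) == 2, organ_size_range[1] > 0,
            organ_size_range[2] >= organ_size_range[1],
            all(contrast_levels >= 0), all(contrast_levels <= 1),
            noise_sigma >= 0, shading_amplitude >= 0, spacing > 0)
  structure(list(
    height = as.integer(height), width = as.integer(width),
    n_organs = as.integer(n_organs),
    organ_size_range = as.numeric(organ_size_range),
    contrast_levels = as.numeric(contrast_levels),
    noise_sigma = noise_sigma,
    include_tiny_organ = isTRUE(include_tiny_organ),
    include_low_contrast_organ = isTRUE(include_low_contrast_organ),
    shading_amplitude = shading_amplitude,
    spacing = spacing,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

# Smooth blob mask: an ellipse whose radius is modulated by low-order
# angular harmonics, rasterised on the voxel grid.
rasterize_blob <- function(height, width, centre, radii, angle, wobble) {
  rc <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  dr <- rc - centre[1]
  dc <- cc - centre[2]
  ca <- cos(angle); sa <- sin(angle)
  u <- ca * dr + sa * dc
  v <- -sa * dr + ca * dc
  theta <- atan2(v / radii[2], u / radii[1])
  mod <- 1 + wobble[1] * cos(2 * theta + wobble[3]) +
    wobble[2] * cos(3 * theta + wobble[4])
  r2 <- (u / radii[1])^2 + (v / radii[2])^2
  (r2 <= mod^2) + 0
}

draw_organ_geometry <- function(cfg, radius) {
  margin <- ceiling(radius * 1.6) + 2
  if (2 * margin >= min(cfg$height, cfg$width)) margin <- floor(min(cfg$height, cfg$width) / 2) - 1
  list(
    centre = c(runif(1, margin + 1, cfg$height - margin),
               runif(1, margin + 1, cfg$width - margin)),
    radii = radius * runif(2, 0.75, 1.25),
    angle = runif(1, 0, pi),
    wobble = c(runif(2, 0, 0.12), runif(2, 0, 2 * pi))
  )
}

# Low-frequency multiplicative shading field in [1 - a, 1 + a].
shading_field <- function(height, width, amplitude) {
  if (amplitude <= 0) return(matrix(1, height, width))
  rc <- matrix(seq_len(height) / height, height, width)
  cc <- matrix(seq_len(width) / width, height, width, byrow = TRUE)
  ph <- runif(4, 0, 2 * pi)
  f <- sin(2 * pi * rc * runif(1, 0.5, 1.2) + ph[1]) +
    sin(2 * pi * cc * runif(1, 0.5, 1.2) + ph[2]) +
    0.5 * sin(2 * pi * (rc + cc) * runif(1, 0.8, 1.6) + ph[3])
  f <- f / max(abs(f))
  1 + amplitude * f
}

#' Generate one phantom slice with gold-standard masks
#'
#' Builds `n_organs` non-overlapping smooth blob organs (with at least one
#' tiny and one low-contrast organ when the corresponding flags are set),
#' composes the image as background + per-organ contrast offsets, multiplies
#' by a low-frequency shading field, adds i.i.d. Gaussian noise and clips to
#' `[0, 1]`. Deterministic given `config$seed`.
#'
#' @param config A [phantom_config()].
#' @return List with `image` (`H x W` matrix in `[0, 1]`, `spacing`
#'   attribute in mm) and `masks` ([oar_masks()] with `n_organs` channels).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, generate_phantom_impl(config))
}

generate_phantom_impl <- function(cfg, max_tries = 200L) {
  k <- cfg$n_organs
  contrasts <- rep_len(cfg$contrast_levels, k)
  radii <- runif(k, cfg$organ_size_range[1], cfg$organ_size_range[2])
  if (cfg$include_tiny_organ) {
    radii[k] <- runif(1, 1.1, 1.6) # area < 10 voxels
  }
  if (cfg$include_low_contrast_organ) {
    idx <- if (cfg$include_tiny_organ && k >= 2) max(1L, k - 1L) else k
    contrasts[idx] <- min(contrasts[idx], cfg$noise_sigma)
  }
  occupied <- matrix(0, cfg$height, cfg$width)
  masks <- array(0, c(cfg$height, cfg$width, k))
  for (j in seq_len(k)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      geo <- draw_organ_geometry(cfg, radii[j])
      m <- rasterize_blob(cfg$height, cfg$width, geo$centre, geo$radii,
                          geo$angle, geo$wobble)
      if (sum(m) == 0) next
      # require a 2-voxel separation so organs stay clearly distinct
      halo <- dilate_binary(m, disc_kernel(2))
      if (sum(halo * occupied) == 0) {
        masks[, , j] <- m
        occupied <- occupied + halo
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf("could not place organ %d without overlap after %d tries.",
                    j, max_tries))
    }
  }
  background <- 0.25
  img <- matrix(background, cfg$height, cfg$width)
  for (j in seq_len(k)) img <- img + contrasts[j] * masks[, , j]
  img <- img * shading_field(cfg$height, cfg$width, cfg$shading_amplitude)
  if (cfg$noise_sigma > 0) {
    img <- img + matrix(rnorm(length(img), 0, cfg$noise_sigma),
                        cfg$height, cfg$width)
  }
  img <- pmin(pmax(img, 0), 1)
  image <- structure(img, spacing = cfg$spacing)
  list(image = image, masks = oar_masks(masks))
}

#' Write a phantom dataset to disk
#'
#' Generates `n_slices` image/mask pairs (per-slice seeds derived from
#' `config$seed`), writes them as single-slice NIfTI volumes (masks as one
#' multi-channel volume) and returns a manifest tibble.
#'
#' @param n_slices Number of slices.
#' @param config [phantom_config()]; its `seed` is the master seed.
#' @param out_dir Writable output directory (created if missing).
#' @return Tibble with columns `slice`, `seed`, `image_path`, `masks_path`,
#'   `organ_names`; also written to `manifest.csv` in `out_dir`.
#' @export
generate_dataset <- function(n_slices, config, out_dir) {
  stopifnot(n_slices >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create directory '%s'.", out_dir))
  seeds <- derive_seeds(config$seed, n_slices)
  rows <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    ph <- generate_phantom(cfg_i)
    image_path <- file.path(out_dir, sprintf("slice_%03d_image.nii.gz", i))
    masks_path <- file.path(out_dir, sprintf("slice_%03d_masks.nii.gz", i))
    write_volume(ph$image, image_path)
    write_volume(ph$masks, masks_path)
    rows[[i]] <- tibble(
      slice = i, seed = seeds[i],
      image_path = image_path, masks_path = masks_path,
      organ_names = paste(organ_names(ph$masks), collapse = ";")
    )
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Generate an in-memory phantom dataset
#'
#' List-of-slices variant of [generate_dataset()] (no I/O): per-slice seeds
#' are derived from `config$seed`, so the dataset is reproducible.
#'
#' @param n_slices Number of slices.
#' @param config [phantom_config()].
#' @return List of `list(image =, masks =)` pairs, ready for [train()].
#' @export
generate_slices <- function(n_slices, config) {
  seeds <- derive_seeds(config$seed, n_slices)
  lapply(seq_len(n_slices), function(i) {
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    generate_phantom(cfg_i)
  })
}
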