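# Synthetic modality-flavored phantoms with exact ground-truth masks and
# patient grouping. Phantoms exist to exercise every code path and the
# statistical protocols (patient-level splitting, class imbalance,
# bootstrap CIs) without any clinical download; they make no claim to
# photorealism.

#' Phantom generation configuration
#'
#' Describes a synthetic dataset: the imaging modality whose statistical
#' character is emulated, lesion geometry, contrast, noise level, and the
#' patient structure. Lesions of one synthetic "patient" share a base shape
#' with per-image jitter, so patient-level splitting is a meaningful
#' leakage test.
#'
#' @param modality one of "ultrasound", "histology", "mammogram", "mri".
#' @param image_size side length in pixels (default 256).
#' @param lesions_per_image integer range (min, max) of lesions per image
#'   (histology uses its own nuclei count range).
#' @param radius_range lesion radius range in pixels.
#' @param foreground_contrast absolute intensity offset of lesions from the
#'   background, in [0, 1].
#' @param noise_level noise amplitude (speckle strength for ultrasound,
#'   additive sd otherwise).
#' @param patients number of synthetic patients.
#' @param images_per_patient images per patient.
#' @param seed dataset-level RNG seed.
#' @return object of class \code{phantom_config}.
#' @export
phantom_config <- function(modality = c("ultrasound", "histology",
                                        "mammogram", "mri"),
                           image_size = 256L,
                           lesions_per_image = c(1L, 2L),
                           radius_range = NULL,
                           foreground_contrast = 0.35,
                           noise_level = 0.15,
                           patients = 20L, images_per_patient = 4L,
                           seed = 0L) {
  modality <- match.arg(modality)
  if (is.null(radius_range)) {
    radius_range <- if (modality == "histology") {
      c(max(2L, round(image_size / 64)), max(3L, round(image_size / 32)))
    } else {
      c(round(image_size / 10), round(image_size / 5))
    }
  }
  if (max(radius_range) >= image_size / 2)
    stop_config("radius_range exceeds image bounds")
  stopifnot(is_count(image_size), is_count(patients),
            is_count(images_per_patient), all(lesions_per_image >= 0))
  structure(list(modality = modality, image_size = as.integer(image_size),
                 lesions_per_image = as.integer(lesions_per_image),
                 radius_range = radius_range,
                 foreground_contrast = foreground_contrast,
                 noise_level = noise_level, patients = as.integer(patients),
                 images_per_patient = as.integer(images_per_patient),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Rotated-ellipse indicator on the pixel grid (pixel centers at integers).
ellipse_mask <- function(n, cx, cy, rx, ry, theta = 0) {
  x <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  y <- matrix(rep(seq_len(n), n), n, n)          # row index
  xr <- (x - cx) * cos(theta) + (y - cy) * sin(theta)
  yr <- -(x - cx) * sin(theta) + (y - cy) * cos(theta)
  (xr / rx)^2 + (yr / ry)^2 <= 1
}

smooth_field <- function(n, scale = 4L) {
  coarse <- matrix(stats::rnorm(scale * scale), scale, scale)
  up <- bilinear_resize(array(coarse, c(scale, scale, 1, 1)), n, n)
  matrix(up, n, n)
}

# Draw one patient's base lesion geometry; per-image calls jitter it.
patient_geometry <- function(cfg) {
  n <- cfg$image_size
  rr <- cfg$radius_range
  k <- if (cfg$lesions_per_image[1] == cfg$lesions_per_image[2])
    cfg$lesions_per_image[1] else
    sample(cfg$lesions_per_image[1]:cfg$lesions_per_image[2], 1)
  if (cfg$modality == "histology") k <- sample(20:80, 1)
  if (k == 0) return(list(k = 0))
  margin <- rr[2] + 2
  list(k = k,
       cx = stats::runif(k, margin, n - margin),
       cy = stats::runif(k, margin, n - margin),
       rx = stats::runif(k, rr[1], rr[2]),
       ry = stats::runif(k, rr[1], rr[2]),
       theta = stats::runif(k, 0, pi))
}

render_mask <- function(geom, n, jitter = 0) {
  mask <- matrix(FALSE, n, n)
  if (geom$k == 0) return(mask)
  for (i in seq_len(geom$k)) {
    mask <- mask | ellipse_mask(n, geom$cx[i] + jitter * stats::rnorm(1),
                                geom$cy[i] + jitter * stats::rnorm(1),
                                geom$rx[i] * stats::runif(1, 1 - 0.05 * jitter,
                                                          1 + 0.05 * jitter),
                                geom$ry[i], geom$theta[i])
  }
  mask
}

#' Generate one phantom image with its exact mask
#'
#' Renders the modality-specific appearance: ultrasound -- dark elliptical
#' lesion(s) on a mid-gray background with multiplicative gamma speckle and
#' mild depth shading; histology -- many small dark "nuclei" on a pale
#' textured background; mammogram -- a bright soft-edged mass on a smooth
#' intensity gradient; mri -- a hyperintense region on a noisy dark
#' background. The mask is the generating geometry rendered before any
#' noise, so mask/image registration is exact. Deterministic given
#' \code{seed}.
#'
#' @param cfg a \code{\link{phantom_config}}.
#' @param seed RNG seed for this draw.
#' @param geom optional precomputed patient geometry (internal use for
#'   patient grouping).
#' @param jitter geometry jitter amplitude when reusing a patient geometry.
#' @return list with \code{image} ((n, n) matrix in [0, 1]) and
#'   \code{mask} ((n, n) 0/1 matrix).
#' @export
generate_phantom <- function(cfg, seed = 0L, geom = NULL, jitter = 0) {
  with_seed(seed, {
    n <- cfg$image_size
    if (is.null(geom)) geom <- patient_geometry(cfg)
    mask <- render_mask(geom, n, jitter)
    con <- cfg$foreground_contrast
    img <- switch(cfg$modality,
      ultrasound = {
        depth <- matrix(rep(seq(1, 0.75, length.out = n), n), n, n)
        base <- 0.5 * depth
        base[mask] <- base[mask] - con
        base <- pmax(base, 0.02)
        sp <- matrix(stats::rgamma(n * n, shape = 4, rate = 4), n, n)
        base * (1 + cfg$noise_level * (sp - 1) / 0.5)
      },
      histology = {
        base <- 0.85 + 0.05 * smooth_field(n, 8L)
        base[mask] <- base[mask] - con
        base + cfg$noise_level * 0.3 * stats::rnorm(n * n)
      },
      mammogram = {
        base <- 0.35 + 0.15 * smooth_field(n, 3L)
        soft <- matrix(0, n, n)
        soft[mask] <- con
        softimg <- ebi_to_arr(EBImage::gblur(arr_to_ebi(soft),
                                             sigma = max(1, n / 64)))
        base + softimg + cfg$noise_level * 0.2 * stats::rnorm(n * n)
      },
      mri = {
        base <- matrix(0.2, n, n)
        base[mask] <- base[mask] + con
        base + cfg$noise_level * stats::rnorm(n * n)
      })
    list(image = pmin(pmax(img, 0), 1),
         mask = matrix(as.integer(mask), n, n))
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes \code{patients x images_per_patient} 8-bit PNG image/mask pairs
#' (mask values 0/255) plus a manifest CSV with patient ids, consumable by
#' \code{\link{read_manifest}} / \code{\link{load_pair}}. Images of one
#' patient share a base lesion geometry with small jitter.
#'
#' @param cfg a \code{\link{phantom_config}}.
#' @param out_dir output directory (created if missing).
#' @return the manifest data.frame (invisibly also written to
#'   \code{manifest.csv} in \code{out_dir}).
#' @export
generate_dataset <- function(cfg, out_dir) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_io("cannot create directory: ", out_dir)
  rows <- vector("list", cfg$patients * cfg$images_per_patient)
  idx <- 1L
  for (p in seq_len(cfg$patients)) {
    geom <- with_seed(cfg$seed * 10007L + p, patient_geometry(cfg))
    pid <- sprintf("P%03d", p)
    for (i in seq_len(cfg$images_per_patient)) {
      ph <- generate_phantom(cfg, seed = cfg$seed * 10007L + p * 131L + i,
                             geom = geom, jitter = 1)
      imgf <- file.path(out_dir, sprintf("%s_img%02d.png", pid, i))
      mskf <- file.path(out_dir, sprintf("%s_msk%02d.png", pid, i))
      EBImage::writeImage(arr_to_ebi(ph$image), imgf, bits.per.sample = 8L)
      EBImage::writeImage(arr_to_ebi(ph$mask * 1.0), mskf,
                          bits.per.sample = 8L)
      rows[[idx]] <- data.frame(image_path = basename(imgf),
                                mask_path = basename(mskf),
                                patient_id = pid, modality = cfg$modality)
      idx <- idx + 1L
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  read_manifest(file.path(out_dir, "manifest.csv"))
}

# In-memory dataset (no disk round trip): list of loaded pairs, used by the
# fast training paths and tests.
generate_memory_dataset <- function(cfg, n_images = NULL) {
  total <- cfg$patients * cfg$images_per_patient
  if (!is.null(n_images)) total <- n_images
  out <- vector("list", total)
  idx <- 1L
  for (p in seq_len(cfg$patients)) {
    geom <- with_seed(cfg$seed * 10007L + p, patient_geometry(cfg))
    for (i in seq_len(cfg$images_per_patient)) {
      if (idx > total) break
      ph <- generate_phantom(cfg, seed = cfg$seed * 10007L + p * 131L + i,
                             geom = geom, jitter = 1)
      out[[idx]] <- list(
        image = array(rep(ph$image, 3L), c(dim(ph$image), 3L)),
        mask = ph$mask, patient_id = sprintf("P%03d", p))
      idx <- idx + 1L
    }
    if (idx > total) break
  }
  out
}
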