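# Reading image/mask pairs via EBImage, RGB mask decoding, manifests.
# Internal array convention is (H, W, C) / (H, W); EBImage stores (W, H, C),
# so the two helpers below transpose at the boundary.

ebi_to_arr <- function(img) {
  m <- EBImage::imageData(img)
  d <- dim(m)
  if (length(d) == 2L) t(m) else aperm(m, c(2, 1, 3))
}

arr_to_ebi <- function(a, color = FALSE) {
  d <- dim(a)
  m <- if (length(d) == 2L) t(a) else aperm(a, c(2, 1, 3))
  EBImage::Image(m, colormode = if (color) "Color" else "Grayscale")
}

#' Decode an RGB-coded ground-truth mask to binary
#'
#' Clinical masks may encode lesion classes as colors (black background,
#' red malignant, green benign). A pixel is foreground iff its color is
#' closer to pure red or pure green than to black, which for channel values
#' in [0, 1] reduces to \code{R > 0.5 | G > 0.5}. Grayscale masks pass
#' through a mid-scale threshold (> 127 on the 8-bit scale).
#'
#' @param mask (H, W, 3) array in [0, 1], or (H, W) grayscale.
#' @return binary (H, W) matrix of 0/1.
#' @export
decode_rgb_mask <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) {
    return(matrix(as.integer(mask > 127 / 255), d[1], d[2]))
  }
  if (length(d) != 3L || !(d[3] %in% c(3L, 4L)))
    stop_io("mask has unexpected channel count: ",
            paste(d, collapse = "x"))
  fg <- (mask[, , 1] > 0.5) | (mask[, , 2] > 0.5)
  matrix(as.integer(fg), d[1], d[2])
}

#' Load and standardize an image/mask pair
#'
#' Reads both files (PNG/JPEG/TIFF via EBImage), resizes the image to
#' \code{target_size} with bilinear resampling, scales it to [0, 1] and
#' replicates grayscale to 3 channels; the mask is resized with
#' nearest-neighbor resampling (so it stays binary) and decoded from RGB or
#' grayscale to 0/1.
#'
#' @param record a one-row data.frame (or list) with \code{image_path} and
#'   \code{mask_path}.
#' @param target_size output side length in pixels (default 256).
#' @return list with \code{image} (target x target x 3, in [0, 1]) and
#'   \code{mask} (target x target, 0/1).
#' @export
load_pair <- function(record, target_size = 256L) {
  for (f in c(record$image_path, record$mask_path)) {
    if (!file.exists(f)) stop_io("cannot read file: ", f)
  }
  img <- tryCatch(EBImage::readImage(record$image_path),
                  error = function(e) stop_io("unreadable image: ",
                                              record$image_path))
  msk <- tryCatch(EBImage::readImage(record$mask_path),
                  error = function(e) stop_io("unreadable mask: ",
                                              record$mask_path))
  img <- EBImage::resize(img, w = target_size, h = target_size,
                         filter = "bilinear")
  msk <- EBImage::resize(msk, w = target_size, h = target_size,
                         filter = "none")
  a <- ebi_to_arr(img)
  if (length(dim(a)) == 2L) {
    a <- array(rep(a, 3L), c(dim(a), 3L))
  } else if (dim(a)[3] == 4L) {
    a <- a[, , 1:3]                      # drop alpha
  } else if (dim(a)[3] == 1L) {
    a <- array(rep(a[, , 1], 3L), c(dim(a)[1:2], 3L))
  }
  a <- pmin(pmax(a, 0), 1)
  m <- decode_rgb_mask(ebi_to_arr(msk))
  list(image = a, mask = m)
}

#' Read / write a dataset manifest
#'
#' The manifest CSV (columns \code{image_path}, \code{mask_path},
#' \code{patient_id}, \code{modality}) is the canonical interchange format
#' between the data generator, the splitter and the training driver.
#' Relative paths are resolved against the manifest's own directory.
#'
#' @param path manifest CSV path.
#' @return data.frame of image records.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_io("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "mask_path", "patient_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_io("manifest missing columns: ",
                            paste(miss, collapse = ", "))
  if (is.null(df$modality)) df$modality <- "synthetic"
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  df$image_path <- fix(df$image_path)
  df$mask_path <- fix(df$mask_path)
  if (any(!nzchar(df$patient_id)))
    stop_io("manifest contains empty patient_id values")
  df
}

#' @rdname read_manifest
#' @param records data.frame of image records.
#' @export
write_manifest <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Patient-level 70/15/15 split
#'
#' Shuffles patients with the given seed and assigns them to train,
#' validation and test splits by the cumulative ratios over patient counts
#' (floor rounding, remainders going to train, so 20 patients give exactly
#' 14/3/3). All images of a patient follow the patient, so the three
#' patient-id sets are pairwise disjoint by construction.
#'
#' @param records data.frame of image records with \code{patient_id}.
#' @param ratios train/val/test proportions summing to 1.
#' @param seed RNG seed for the patient shuffle.
#' @return list with \code{train}, \code{val}, \code{test} (data.frames),
#'   the \code{ratios} and the \code{seed}.
#' @export
split_by_patient <- function(records, ratios = c(0.70, 0.15, 0.15),
                             seed = 0L) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("split ratios must sum to 1")
  pats <- unique(records$patient_id)
  P <- length(pats)
  if (P < 3L) stop("need at least 3 patients to form three non-empty splits")
  pats <- with_seed(seed, sample(pats))
  n_val <- max(1L, floor(ratios[2] * P))
  n_test <- max(1L, floor(ratios[3] * P))
  n_train <- P - n_val - n_test
  if (n_train < 1L) stop("split ratios leave no training patients")
  assign_of <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  names(assign_of) <- pats
  grp <- assign_of[records$patient_id]
  out <- list(train = records[grp == "train", , drop = FALSE],
              val = records[grp == "val", , drop = FALSE],
              test = records[grp == "test", , drop = FALSE])
  out$ratios <- ratios
  out$seed <- seed
  out
}
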