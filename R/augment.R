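# Joint image/mask augmentation. Geometric transforms are applied
# identically to image and mask (mask with nearest-neighbor resampling and
# re-binarization); intensity jitter touches the image only.

#' Augmentation configuration
#'
#' Two augmentation families are supported behind one config: the default
#' set (random horizontal/vertical flips, small continuous rotations within
#' \code{max_rotation_deg}, multiplicative intensity jitter) and an
#' alternative right-angle set (0/90/180/270 degree rotations plus scale
#' jitter). Setting \code{enabled = FALSE} makes \code{\link{augment}} the
#' identity.
#'
#' @param hflip_prob,vflip_prob flip probabilities in [0, 1].
#' @param max_rotation_deg maximum absolute continuous rotation (degrees,
#'   default 15); 0 disables continuous rotation.
#' @param right_angle_rotations draw a rotation from (0, 90, 180, 270)
#'   instead of a continuous angle.
#' @param intensity_jitter relative amplitude a of the multiplicative
#'   intensity factor drawn from [1-a, 1+a] (default 0.1).
#' @param scale_jitter relative amplitude of the uniform zoom (0 disables).
#' @param enabled master switch.
#' @return object of class \code{augment_config}.
#' @export
augment_config <- function(hflip_prob = 0.5, vflip_prob = 0.5,
                           max_rotation_deg = 15, right_angle_rotations = FALSE,
                           intensity_jitter = 0.1, scale_jitter = 0,
                           enabled = TRUE) {
  stopifnot(hflip_prob >= 0, hflip_prob <= 1, vflip_prob >= 0,
            vflip_prob <= 1, max_rotation_deg >= 0, intensity_jitter >= 0,
            scale_jitter >= 0)
  structure(list(hflip_prob = hflip_prob, vflip_prob = vflip_prob,
                 max_rotation_deg = max_rotation_deg,
                 right_angle_rotations = isTRUE(right_angle_rotations),
                 intensity_jitter = intensity_jitter,
                 scale_jitter = scale_jitter, enabled = isTRUE(enabled)),
            class = "augment_config")
}

rot90k <- function(a, k) {
  k <- k %% 4L
  if (k == 0L) return(a)
  for (i in seq_len(k)) {
    a <- if (length(dim(a)) == 2L) t(a[nrow(a):1, , drop = FALSE]) else
      aperm(a[dim(a)[1]:1, , , drop = FALSE], c(2, 1, 3))
  }
  a
}

rotate_pair <- function(image, mask, angle) {
  d <- dim(mask)
  imgr <- ebi_to_arr(EBImage::rotate(arr_to_ebi(image, color = TRUE), angle,
                                     filter = "bilinear",
                                     output.dim = c(d[2], d[1]), bg.col = 0))
  mskr <- ebi_to_arr(EBImage::rotate(arr_to_ebi(mask), angle,
                                     filter = "none",
                                     output.dim = c(d[2], d[1]), bg.col = 0))
  list(image = pmin(pmax(imgr, 0), 1),
       mask = matrix(as.integer(mskr > 0.5), d[1], d[2]))
}

scale_pair <- function(image, mask, factor) {
  d <- dim(mask)
  H <- d[1]; W <- d[2]
  Hn <- max(1L, round(H * factor)); Wn <- max(1L, round(W * factor))
  imgs <- ebi_to_arr(EBImage::resize(arr_to_ebi(image, color = TRUE),
                                     w = Wn, h = Hn, filter = "bilinear"))
  msks <- ebi_to_arr(EBImage::resize(arr_to_ebi(mask), w = Wn, h = Hn,
                                     filter = "none"))
  if (factor >= 1) {                      # center crop back
    r0 <- (Hn - H) %/% 2L; c0 <- (Wn - W) %/% 2L
    img <- imgs[r0 + seq_len(H), c0 + seq_len(W), , drop = FALSE]
    msk <- msks[r0 + seq_len(H), c0 + seq_len(W), drop = FALSE]
  } else {                                # reflection-pad back
    pr <- H - Hn; pc <- W - Wn
    top <- pr %/% 2L; left <- pc %/% 2L
    ridx <- c(rev(seq_len(top)), seq_len(Hn), Hn - seq_len(pr - top) + 1L)
    cidx <- c(rev(seq_len(left)), seq_len(Wn), Wn - seq_len(pc - left) + 1L)
    img <- imgs[ridx, cidx, , drop = FALSE]
    msk <- msks[ridx, cidx, drop = FALSE]
  }
  list(image = img, mask = matrix(as.integer(msk > 0.5), H, W))
}

#' Apply joint augmentation to an image/mask pair
#'
#' Draws the transforms from the current RNG stream (seed it with
#' \code{set.seed} or wrap in a seeded context for reproducibility).
#' Geometry is shared between image and mask; the mask goes through
#' nearest-neighbor resampling and is re-binarized, so it stays 0/1.
#' A disabled config returns the inputs bit-identically.
#'
#' @param image (H, W, 3) array in [0, 1].
#' @param mask (H, W) binary matrix.
#' @param cfg an \code{\link{augment_config}}.
#' @return list with augmented \code{image} and \code{mask}.
#' @export
augment <- function(image, mask, cfg = augment_config()) {
  if (!cfg$enabled) return(list(image = image, mask = mask))
  if (!identical(dim(image)[1:2], dim(mask)[1:2]))
    stop_shape("augment: image and mask sizes differ")
  if (stats::runif(1) < cfg$hflip_prob) {      # flip left-right
    image <- image[, dim(image)[2]:1, , drop = FALSE]
    mask <- mask[, ncol(mask):1, drop = FALSE]
  }
  if (stats::runif(1) < cfg$vflip_prob) {      # flip up-down
    image <- image[dim(image)[1]:1, , , drop = FALSE]
    mask <- mask[nrow(mask):1, , drop = FALSE]
  }
  if (cfg$right_angle_rotations) {
    k <- sample(0:3, 1)
    if (k > 0) { image <- rot90k(image, k); mask <- rot90k(mask, k) }
  } else if (cfg$max_rotation_deg > 0) {
    ang <- stats::runif(1, -cfg$max_rotation_deg, cfg$max_rotation_deg)
    r <- rotate_pair(image, mask, ang)
    image <- r$image; mask <- r$mask
  }
  if (cfg$scale_jitter > 0) {
    f <- stats::runif(1, 1 - cfg$scale_jitter, 1 + cfg$scale_jitter)
    r <- scale_pair(image, mask, f)
    image <- r$image; mask <- r$mask
  }
  if (cfg$intensity_jitter > 0) {
    image <- pmin(pmax(image * stats::runif(1, 1 - cfg$intensity_jitter,
                                            1 + cfg$intensity_jitter), 0), 1)
  }
  list(image = image, mask = mask)
}
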