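#' Rotation-invariant uniform LBP signature of a seed patch
#'
#' An 18-bin texture descriptor: the rotation-invariant uniform local binary
#' pattern with `P = 16` circular neighbours (radius `R = 2`, bilinear
#' interpolation) has `P + 2 = 18` histogram bins -- one per uniform-pattern
#' one-count (0..16) plus a non-uniform catch-all. Computed on the BT.601
#' grayscale patch, accumulated over masked pixels only (pixels whose
#' neighbourhood crosses the mask boundary are skipped), and L1-normalized.
#'
#' @param patch a [seed_patch].
#' @param P number of sampling points.
#' @param R sampling radius in pixels.
#' @return numeric vector of length `P + 2` summing to 1.
#' @export
lbp_descriptor <- function(patch, P = 16, R = 2) {
  stopifnot(inherits(patch, "seed_patch"))
  if (sum(patch$mask) < 100)
    stop("insufficient region: masked area below 100 pixels")
  gray <- rgb_to_gray(patch$pixels)
  counts <- lbp_hist_cpp(gray, patch$mask, as.integer(P), R)
  tot <- sum(counts)
  if (tot == 0) stop("insufficient region: no pixel has a full in-mask neighbourhood")
  counts / tot
}

#' Per-channel colour histogram of a seed patch
#'
#' 60 equal-width bins per RGB channel over `[0, 255]`, counts over masked
#' pixels only, each channel block L1-normalized, concatenated R || G || B.
#'
#' @param patch a [seed_patch].
#' @param bins bins per channel.
#' @return numeric vector of length `3 * bins`.
#' @export
color_histogram <- function(patch, bins = 60) {
  stopifnot(inherits(patch, "seed_patch"), any(patch$mask))
  out <- numeric(0)
  for (k in 1:3) {
    v <- patch$pixels[, , k][patch$mask]
    idx <- pmin(floor(v / 256 * bins), bins - 1) + 1
    h <- tabulate(idx, nbins = bins)
    out <- c(out, h / sum(h))
  }
  out
}

#' The 198-item seed descriptor
#'
#' Concatenates the 18-bin LBP signature and the 180-bin colour histogram
#' into the per-seed feature vector used by the texture classifier.
#'
#' @inheritParams lbp_descriptor
#' @param bins colour bins per channel.
#' @return named numeric vector `f000..f197` of length `P + 2 + 3 * bins`
#'   (198 at the defaults).
#' @export
feature_vector <- function(patch, P = 16, R = 2, bins = 60) {
  v <- c(lbp_descriptor(patch, P, R), color_histogram(patch, bins))
  names(v) <- sprintf("f%03d", seq_along(v) - 1)
  v
}

#' Feature matrix for a list of patches
#'
#' @param patches list of [seed_patch] objects.
#' @inheritParams feature_vector
#' @return numeric matrix, one row per patch.
#' @export
feature_matrix <- function(patches, P = 16, R = 2, bins = 60) {
  do.call(rbind, lapply(patches, feature_vector, P = P, R = R, bins = bins))
}
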