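#' Locate the graph-paper strip
#'
#' The calibration strip is the bright band across the top of the frame; rows
#' whose mean luma exceeds 60% of the brightest row's mean, taken as a
#' contiguous run from the top, delimit it.
#'
#' @param image RGB array or grayscale matrix.
#' @return `c(x, y, w, h)` (0-based, pixels) or `NULL` when no strip-like top
#'   band exists.
#' @export
locate_strip_roi <- function(image) {
  gray <- rgb_to_gray(image)
  rm_ <- rowMeans(gray)
  bright <- rm_ > 0.6 * max(rm_)
  if (!any(bright[1:min(5, length(bright))])) return(NULL)
  # strip height: up to the first run of >= 3 consecutive non-bright rows
  # (isolated dark rows are the horizontal grid lines themselves)
  dark_run <- !bright & !c(bright[-1], TRUE) & !c(bright[-(1:2)], TRUE, TRUE)
  h <- if (any(dark_run)) which(dark_run)[1] - 1L else nrow(gray)
  if (h < 5) return(NULL)
  c(x = 0L, y = 0L, w = ncol(gray), h = as.integer(h))
}

# Ramer-Douglas-Peucker simplification of an open polyline (n x 2 matrix).
dp_simplify <- function(pts, eps) {
  n <- nrow(pts)
  keep <- logical(n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    len <- sqrt(sum(ab^2))
    mid <- (i + 1):(j - 1)
    if (len < 1e-9) {
      d <- sqrt((pts[mid, 1] - a[1])^2 + (pts[mid, 2] - a[2])^2)
    } else {
      d <- abs(ab[2] * (pts[mid, 1] - a[1]) - ab[1] * (pts[mid, 2] - a[2])) / len
    }
    k <- which.max(d)
    if (d[k] > eps) {
      m <- mid[k]
      keep[m] <- TRUE
      stack <- c(stack, list(c(i, m), c(m, j)))
    }
  }
  pts[keep, , drop = FALSE]
}

# Approximate a closed contour by a polygon: split at the two mutually
# farthest-ish anchor points, simplify each chain, and merge.
approx_polygon <- function(contour, eps) {
  n <- nrow(contour)
  if (n < 4) return(contour)
  d0 <- (contour[, 1] - contour[1, 1])^2 + (contour[, 2] - contour[1, 2])^2
  k <- which.max(d0)
  c1 <- contour[1:k, , drop = FALSE]
  c2 <- contour[c(k:n, 1), , drop = FALSE]
  v1 <- dp_simplify(c1, eps)
  v2 <- dp_simplify(c2, eps)
  v <- rbind(v1, v2[-1, , drop = FALSE])
  v[-nrow(v), , drop = FALSE]        # drop duplicated closing vertex
}

#' Detect graph-paper squares
#'
#' Finds the individual grid cells of the 1 mm graph paper: the region of
#' interest is binarized with Otsu's threshold (light paper vs dark grid
#' lines), cell interiors are labelled as 4-connected components, each
#' component's outer contour is followed and simplified to a polygon, and
#' only 4-vertex polygons with near-equal sides (max/min <= 1.3) and
#' near-right corners are kept. Each polygon side is compensated by +2 px
#' (half the separating grid-line width at both ends) so the reported side
#' measures the line-centre-to-line-centre pitch. Partial grids are fine; a
#' quorum of squares is all the scale estimate needs.
#'
#' @param image RGB array or grayscale matrix.
#' @param roi `c(x, y, w, h)` (0-based) or `NULL` to auto-locate the strip
#'   (falling back to the full image).
#' @param min_area_px smallest cell interior considered.
#' @return data frame with one row per detected square: `cx, cy` (0-based
#'   centre within the image), `side_a..side_d`, `mean_side_px`. Contours are
#'   attached as the `contours` attribute.
#' @export
detect_squares <- function(image, roi = NULL, min_area_px = 9) {
  gray <- rgb_to_gray(image)
  if (is.null(roi)) roi <- locate_strip_roi(image)
  if (is.null(roi)) roi <- c(x = 0L, y = 0L, w = ncol(gray), h = nrow(gray))
  rows <- (roi[2] + 1):(roi[2] + roi[4])
  cols <- (roi[1] + 1):(roi[1] + roi[3])
  g <- gray[rows, cols, drop = FALSE]
  if (diff(range(g)) < 1)
    stop("calibration unavailable: no graph-paper squares detected")
  th <- otsu_threshold(g)
  bright <- g >= th
  lab <- label_cpp(bright, 4L)
  if (lab$n == 0)
    stop("calibration unavailable: no graph-paper squares detected")

  res <- list()
  contours <- list()
  areas <- tabulate(lab$labels[lab$labels > 0], nbins = lab$n)
  nr <- nrow(g); nc <- ncol(g)
  for (id in seq_len(lab$n)) {
    if (areas[id] < min_area_px) next
    ij <- which(lab$labels == id, arr.ind = TRUE)
    # a cell cut by the ROI border is not a full square
    if (min(ij[, 1]) == 1 || max(ij[, 1]) == nr ||
        min(ij[, 2]) == 1 || max(ij[, 2]) == nc) next
    ct <- trace_contour_cpp(lab$labels, id)      # x, y 0-based within ROI
    if (nrow(ct) < 4) next
    per <- sum(sqrt(rowSums((ct - ct[c(2:nrow(ct), 1), ])^2)))
    v <- approx_polygon(ct, max(1.5, 0.05 * per))
    if (nrow(v) != 4) next
    nxt <- v[c(2, 3, 4, 1), , drop = FALSE]
    sides <- sqrt(rowSums((v - nxt)^2)) + 2      # line-width compensation
    if (max(sides) / min(sides) > 1.3) next
    prv <- v[c(4, 1, 2, 3), , drop = FALSE]
    a <- prv - v; b <- nxt - v
    cosang <- abs(rowSums(a * b)) /
      pmax(1e-9, sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
    if (any(cosang >= 0.3)) next
    res[[length(res) + 1]] <- data.frame(
      cx = mean(v[, 1]) + roi[1], cy = mean(v[, 2]) + roi[2],
      side_a = sides[1], side_b = sides[2], side_c = sides[3],
      side_d = sides[4], mean_side_px = mean(sides))
    contours[[length(contours) + 1]] <- ct
  }
  if (!length(res))
    stop("calibration unavailable: no graph-paper squares detected")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "contours") <- contours
  out
}

#' Scale estimate from graph-paper squares
#'
#' `S = ADV / EDV`: `EDV` is the estimated average square side in pixels,
#' `ADV` the a-priori known side in mm (1 mm for standard graph paper), so
#' `S` is the real-world extent, in mm, of one pixel.
#'
#' @param EDV estimated square side, pixels (> 0).
#' @param ADV known square side, mm.
#' @param n_squares number of squares behind the estimate.
#' @param side_histogram optional `list(breaks, counts)` of side lengths.
#' @return object of class `scale_estimate` with fields `EDV`, `ADV`, `S`,
#'   `n_squares`, `side_histogram`.
#' @export
scale_estimate <- function(EDV, ADV = 1, n_squares = NA_integer_,
                           side_histogram = NULL) {
  stopifnot(EDV > 0, ADV > 0)
  structure(list(EDV = EDV, ADV = ADV, S = ADV / EDV, n_squares = n_squares,
                 side_histogram = side_histogram),
            class = "scale_estimate")
}

#' @export
print.scale_estimate <- function(x, ...) {
  cat(sprintf("scale estimate: EDV = %.2f px, ADV = %g mm, S = %.5f mm/px (n = %s squares)\n",
              x$EDV, x$ADV, x$S, x$n_squares))
  invisible(x)
}

#' Estimate EDV from detected squares
#'
#' All 4n side lengths are histogrammed (1 px bins by default); the peak bin
#' corresponds to the true 1 mm pitch, and `EDV` is the mean of the sides
#' falling in the modal bin +/- one bin -- robust to the occasional merged or
#' broken contour.
#'
#' @param squares data frame from [detect_squares()].
#' @param adv_mm known square side in mm.
#' @param bin_width histogram bin width in px.
#' @param quorum minimum number of squares required for a reliable estimate.
#' @return a [scale_estimate].
#' @export
estimate_edv <- function(squares, adv_mm = 1, bin_width = 1, quorum = 10) {
  n <- nrow(squares)
  if (is.null(n) || n < quorum)
    stop("calibration unavailable: only ", n %||% 0,
         " squares detected (quorum ", quorum, ")")
  sides <- c(squares$side_a, squares$side_b, squares$side_c, squares$side_d)
  breaks <- seq(floor(min(sides)), ceiling(max(sides)) + bin_width, by = bin_width)
  hh <- graphics::hist(sides, breaks = breaks, plot = FALSE, right = FALSE)
  k <- which.max(hh$counts)
  lo <- breaks[max(1, k - 1)]
  hi <- breaks[min(length(breaks), k + 2)]
  sel <- sides >= lo & sides < hi
  scale_estimate(mean(sides[sel]), ADV = adv_mm, n_squares = n,
                 side_histogram = list(breaks = hh$breaks, counts = hh$counts))
}

#' Seed size in millimetres
#'
#' Converts a mean seed radius in pixels to the real-world seed size. The
#' reported size is the seed *diameter*: `2 * mean_radius_px * S` with
#' `ADV = 1` mm graph paper (e.g. a 146 px mean radius at 56.64 px/mm gives
#' `2 * 146 / 56.64 = 5.16` mm).
#'
#' @param mean_radius_px mean detected radius, pixels (> 0).
#' @param scale a [scale_estimate].
#' @return seed size (diameter) in mm; rounding is left to presentation.
#' @export
seed_size_mm <- function(mean_radius_px, scale) {
  if (is.null(scale)) stop("calibration unavailable: no scale estimate")
  stopifnot(inherits(scale, "scale_estimate"), mean_radius_px > 0)
  2 * mean_radius_px * scale$S
}

#' Absolute size error
#'
#' @param measured_mm,estimated_mm nonnegative sizes in mm.
#' @return `|measured - estimated|`, vectorized.
#' @export
absolute_error <- function(measured_mm, estimated_mm) {
  stopifnot(all(measured_mm >= 0), all(estimated_mm >= 0))
  abs(measured_mm - estimated_mm)
}
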