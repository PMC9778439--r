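#' Canny edge map with adaptive thresholds
#'
#' Edges drive both the seed (circle) detector and the graph-paper square
#' detector. Hysteresis thresholds follow the standard adaptive rule
#' `lower/upper = 0.66/1.33 x median(gray)`, floored at 1/2 gray levels so a
#' constant image yields an empty map rather than a full one.
#'
#' @param image RGB array or grayscale matrix.
#' @param sigma Gaussian smoothing scale in pixels.
#' @return an `edge_map`: `raster` (logical matrix) and `coords`, an `n x 2`
#'   matrix of 0-based `(x = col, y = row)` edge-pixel coordinates.
#' @export
edge_map <- function(image, sigma = 1.4) {
  gray <- rgb_to_gray(image)
  stopifnot(length(gray) > 0)
  med <- stats::median(gray)
  low <- max(0.66 * med, 1)
  high <- max(1.33 * med, 2)
  raster <- canny_cpp(gray, low, high, sigma)
  ij <- which(raster, arr.ind = TRUE)
  coords <- cbind(x = ij[, 2] - 1, y = ij[, 1] - 1)
  # unit intensity-gradient direction at each edge pixel (radial on a true
  # circular rim); consumed by the detector's consistency check
  sb <- sobel_cpp(gray, sigma)
  gx <- sb$gx[ij]; gy <- sb$gy[ij]
  gn <- pmax(sqrt(gx^2 + gy^2), 1e-9)
  structure(list(raster = raster, coords = coords,
                 grad = cbind(gx = gx / gn, gy = gy / gn)),
            class = "edge_map")
}

#' Circle through three points
#'
#' The geometric primitive of the randomized detector: three sampled edge
#' pixels determine a unique circle unless they are (near) collinear.
#'
#' @param p1,p2,p3 numeric length-2 points `(x, y)`.
#' @return list with `center`, `radius_px` and `support_fraction` (0, unset).
#' @export
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  scale2 <- max(abs(c(ax, ay, bx, by, cx, cy)), 1)^2
  if (abs(d) < 1e-9 * scale2)
    stop("degenerate geometry: points are collinear")
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius_px = sqrt((ax - ux)^2 + (ay - uy)^2),
       support_fraction = 0)
}

# Kasa algebraic least-squares circle fit; sub-pixel refinement of an
# accepted candidate from its inlier edge pixels.
fit_circle_ls <- function(pts) {
  A <- cbind(2 * pts[, 1], 2 * pts[, 2], 1)
  b <- pts[, 1]^2 + pts[, 2]^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  c(x = sol[1], y = sol[2], r = sqrt(r2))
}

#' Randomized circle detector parameters
#'
#' @param min_edge_pixels stop searching when fewer edge pixels remain; also
#'   the minimum evidence to attempt a detection.
#' @param min_support_fraction fraction of the circumference that must be
#'   covered by edge pixels to accept a candidate; 0.6 tolerates a missing
#'   quarter-arc plus occlusions while random alignments stay far below it.
#' @param sample_budget number of random 3-point samples.
#' @param inlier_tolerance_px distance tolerance for an edge pixel to count as
#'   circumference support.
#' @param radius_sd_multiplier width of the per-image radius plausibility band
#'   in standard deviations (2 = discard radii outside mean +/- 2 sd).
#' @param background_fraction_max maximum tolerated fraction of background
#'   pixels inside a circle (0.10 = discard above 10%).
#' @param rng_seed seed making the randomized search reproducible.
#' @param min_radius_px,max_radius_px practical guards on candidate radii.
#' @param neighborhood_k the second and third sample points are drawn from
#'   this many nearest neighbours of the first, concentrating triples on a
#'   single edge structure; larger than the edge count means uniform
#'   sampling.
#' @return a `detector_params` list.
#' @export
detector_params <- function(min_edge_pixels = 50, min_support_fraction = 0.6,
                            sample_budget = 2000, inlier_tolerance_px = 1.5,
                            radius_sd_multiplier = 2,
                            background_fraction_max = 0.10, rng_seed = 0,
                            min_radius_px = 5, max_radius_px = Inf,
                            neighborhood_k = 500) {
  p <- list(min_edge_pixels = min_edge_pixels,
            min_support_fraction = min_support_fraction,
            sample_budget = sample_budget,
            inlier_tolerance_px = inlier_tolerance_px,
            radius_sd_multiplier = radius_sd_multiplier,
            background_fraction_max = background_fraction_max,
            rng_seed = as.integer(rng_seed),
            min_radius_px = min_radius_px, max_radius_px = max_radius_px,
            neighborhood_k = as.integer(neighborhood_k))
  stopifnot(p$min_support_fraction > 0, p$min_support_fraction <= 1,
            p$sample_budget >= 1, p$inlier_tolerance_px > 0,
            p$min_edge_pixels >= 3)
  class(p) <- "detector_params"
  p
}

#' Detect circles by randomized 3-point sampling
#'
#' Repeatedly samples three remaining edge pixels, forms their circumcircle,
#' and counts edge pixels within `inlier_tolerance_px` of the circumference.
#' A candidate whose circumference support reaches `min_support_fraction` is
#' refined by a least-squares fit on its inliers (sub-pixel accuracy), merged
#' with any accepted circle whose centre lies within half a radius (the higher
#' support wins), and its supporting pixels are removed so the remaining
#' budget is spent on undiscovered seeds. No prior knowledge of the radius is
#' needed, so differently sized seeds in one image are all found.
#'
#' @param edges an [edge_map()].
#' @param params a [detector_params()].
#' @return data frame of accepted candidates, in acceptance order:
#'   `x, y, radius_px, support, n_inliers`.
#' @export
detect_circles <- function(edges, params = detector_params()) {
  stopifnot(inherits(edges, "edge_map"))
  empty <- data.frame(x = numeric(0), y = numeric(0), radius_px = numeric(0),
                      support = numeric(0), n_inliers = integer(0))
  coords <- edges$coords
  if (is.null(coords) || nrow(coords) < 3) return(empty)

  # support = fraction of the circumference covered by edge pixels, measured
  # as occupancy of ~3 px arc sectors; robust against dense point clusters
  # and chords that would inflate a simple inlier count
  arc_support <- function(ix, iy, cx, cy, r) {
    if (!length(ix)) return(0)
    nb <- max(16L, as.integer(round(2 * pi * r / 3)))
    ang <- atan2(iy - cy, ix - cx)
    bin <- pmin(nb, floor((ang + pi) / (2 * pi) * nb) + 1L)
    mean(tabulate(bin, nbins = nb) > 0)
  }

  withr::with_seed(params$rng_seed, {
    px <- coords[, 1]; py <- coords[, 2]
    grad <- edges$grad                      # may be NULL for point-set maps
    # inliers must lie near the circumference and, when gradient directions
    # are known, have their gradient pointing inward within ~45 degrees of
    # the radial line: seeds are bright objects on a dark surface, so on a
    # true rim the intensity gradient always points toward the centre
    inliers_of <- function(cx, cy, r) {
      rx <- px[idx] - cx; ry <- py[idx] - cy
      rn <- pmax(sqrt(rx^2 + ry^2), 1e-9)
      ok <- abs(rn - r) < tol
      if (!is.null(grad)) {
        cosang <- (grad[idx, 1] * rx + grad[idx, 2] * ry) / rn
        ok <- ok & cosang < -0.7
      }
      ok
    }
    alive <- rep(TRUE, length(px))
    idx <- which(alive)
    acc <- list()
    tol <- params$inlier_tolerance_px
    iter <- 0
    while (iter < params$sample_budget && length(idx) >= params$min_edge_pixels) {
      iter <- iter + 1
      i1 <- idx[sample.int(length(idx), 1L)]
      d2n <- (px[idx] - px[i1])^2 + (py[idx] - py[i1])^2
      k <- min(params$neighborhood_k, length(idx) - 1L)
      if (k < 2) break
      thr <- sort(d2n, partial = k + 1L)[k + 1L]
      neigh <- idx[d2n <= thr & idx != i1]
      pick <- c(i1, neigh[sample.int(length(neigh), 2L)])
      cc <- tryCatch(circumcircle(c(px[pick[1]], py[pick[1]]),
                                  c(px[pick[2]], py[pick[2]]),
                                  c(px[pick[3]], py[pick[3]])),
                     error = function(e) NULL)
      if (is.null(cc)) next
      r <- cc$radius_px
      if (r < params$min_radius_px || r > params$max_radius_px) next
      cx <- cc$center[1]; cy <- cc$center[2]
      # a candidate centred inside an accepted seed is a texture artefact
      dup <- FALSE
      for (j in seq_along(acc))
        if ((acc[[j]]$x - cx)^2 + (acc[[j]]$y - cy)^2 < acc[[j]]$radius_px^2) {
          dup <- TRUE
          break
        }
      if (dup) next
      inl <- inliers_of(cx, cy, r)
      support <- arc_support(px[idx[inl]], py[idx[inl]], cx, cy, r)
      if (support < params$min_support_fraction) next

      # iterated least-squares refinement on the inliers (sub-pixel accuracy);
      # repeated refits let a candidate locked onto part of the true rim
      # converge to the full circle
      for (pass in 1:3) {
        fit <- fit_circle_ls(cbind(px[idx[inl]], py[idx[inl]]))
        if (is.null(fit) || fit["r"] < params$min_radius_px ||
            fit["r"] > params$max_radius_px) break
        inl2 <- inliers_of(fit["x"], fit["y"], fit["r"])
        if (sum(inl2) < sum(inl)) break       # keep refinement only if it helps
        cx <- unname(fit["x"]); cy <- unname(fit["y"]); r <- unname(fit["r"])
        no_change <- identical(inl2, inl)
        inl <- inl2
        if (no_change) break
      }
      support <- arc_support(px[idx[inl]], py[idx[inl]], cx, cy, r)
      if (support < params$min_support_fraction) next
      # the minimum-edge-pixel threshold that keeps false circles out
      if (sum(inl) < params$min_edge_pixels) next

      new_circ <- list(x = cx, y = cy, radius_px = r, support = support,
                       n_inliers = sum(inl))
      merged <- FALSE
      for (j in seq_along(acc)) {
        dc <- sqrt((acc[[j]]$x - new_circ$x)^2 + (acc[[j]]$y - new_circ$y)^2)
        if (dc < 0.5 * acc[[j]]$radius_px) {
          if (new_circ$support > acc[[j]]$support) acc[[j]] <- new_circ
          merged <- TRUE
          break
        }
      }
      if (!merged) {
        # retroactive duplicate suppression: an earlier, smaller acceptance
        # whose centre falls inside this circle was a texture artefact
        contained <- vapply(acc, function(a)
          (a$x - cx)^2 + (a$y - cy)^2 < r^2 && a$radius_px < r, logical(1))
        if (any(contained)) acc <- acc[!contained]
        acc[[length(acc) + 1]] <- new_circ
      }
      # remove circumference support and interior points: texture edges
      # inside an accepted seed must not seed further candidates
      inside <- sqrt((px[idx] - cx)^2 + (py[idx] - cy)^2) < r + tol
      alive[idx[inl | inside]] <- FALSE
      idx <- which(alive)
    }
    if (!length(acc)) return(empty)
    do.call(rbind, lapply(acc, as.data.frame))
  })
}

#' Promote circle candidates to detected circles
#'
#' @param candidates output of [detect_circles()].
#' @return data frame with `background_fraction` (NA until the radiometric
#'   check runs) and `status` (`retained`) columns added.
#' @export
as_detected <- function(candidates) {
  candidates$background_fraction <- NA_real_
  candidates$status <- rep("retained", nrow(candidates))
  candidates
}

#' Statistical check on detected radii
#'
#' Within one image, radii outside `mean +/- multiplier * sd` are marked
#' `discarded_radius`; a lone circle is retained unconditionally (no spread
#' can be estimated from one sample). Note that with very few circles a gross
#' outlier inflates the standard deviation enough to pass its own band; the
#' check is effective at realistic per-image seed counts.
#'
#' @param circles data frame from [as_detected()].
#' @param multiplier band width in standard deviations (2 by default).
#' @return the data frame with updated `status`.
#' @export
radius_filter <- function(circles, multiplier = 2) {
  stopifnot(nrow(circles) >= 1)
  if (nrow(circles) == 1) return(circles)
  mu <- mean(circles$radius_px)
  sig <- stats::sd(circles$radius_px)
  out <- circles$radius_px < mu - multiplier * sig |
         circles$radius_px > mu + multiplier * sig
  circles$status[out & circles$status == "retained"] <- "discarded_radius"
  circles
}

#' Radiometric check on circle interiors
#'
#' A detected circle containing too much dark background is a false positive
#' (an alignment of unrelated edges). The interior background fraction is the
#' share of pixels whose gray value falls below a threshold -- Otsu's
#' threshold on the whole image by default, separating the dark surface from
#' the bright seeds. Circles above `max_bg` are marked
#' `discarded_radiometric`; already-discarded circles keep their status but
#' still get their `background_fraction` measured.
#'
#' @param circles data frame from [as_detected()].
#' @param image the source image.
#' @param max_bg maximum tolerated background fraction (0.10 by default).
#' @param threshold optional explicit background threshold. By default a
#'   two-stage Otsu rule: a first Otsu split separates the bright content
#'   (seeds, graph paper) from the dark class, and a second Otsu split
#'   *within* the dark class separates the acquisition surface from dark
#'   testa patterns -- a single global split would count the dark patterns of
#'   dotted/complex/marbled seeds as background and discard valid seeds.
#' @return the data frame with `background_fraction` and `status` updated.
#' @export
radiometric_filter <- function(circles, image, max_bg = 0.10, threshold = NULL) {
  gray <- rgb_to_gray(image)
  if (is.null(threshold)) {
    t1 <- otsu_threshold(gray)
    dark <- gray[gray < t1]
    threshold <- if (length(dark) >= 100 && diff(range(dark)) >= 8)
      otsu_threshold(dark) else t1
  }
  h <- nrow(gray); w <- ncol(gray)
  for (i in seq_len(nrow(circles))) {
    cx <- circles$x[i]; cy <- circles$y[i]; r <- circles$radius_px[i]
    if (cx + r < 0 || cx - r > w - 1 || cy + r < 0 || cy - r > h - 1)
      stop("circle ", i, " lies fully outside the image")
    cols <- max(0, floor(cx - r)):min(w - 1, ceiling(cx + r))
    rows <- max(0, floor(cy - r)):min(h - 1, ceiling(cy + r))
    dx <- matrix(rep(cols - cx, each = length(rows)), length(rows))
    dy <- matrix(rep(rows - cy, times = length(cols)), length(rows))
    inside <- dx^2 + dy^2 <= r^2
    if (!any(inside)) stop("circle ", i, " has no interior pixels in the image")
    vals <- gray[rows + 1, cols + 1, drop = FALSE][inside]
    bg <- mean(vals < threshold)
    circles$background_fraction[i] <- bg
    if (bg > max_bg && circles$status[i] == "retained")
      circles$status[i] <- "discarded_radiometric"
  }
  circles
}

#' Seed patch container
#'
#' A square crop around a detected circle, side equal to the circle diameter,
#' with the circular-interior mask used by all texture operations.
#'
#' @param pixels RGB array.
#' @param mask logical matrix of identical spatial dimensions, marking the
#'   disc interior; must be nonempty.
#' @param label optional known testa-pattern class (synthetic patches).
#' @param source_image,source_circle provenance identifiers.
#' @param clipped was the crop clipped at an image border?
#' @return object of class `seed_patch`.
#' @export
seed_patch <- function(pixels, mask, label = NA_character_,
                       source_image = NA_character_, source_circle = NULL,
                       clipped = FALSE) {
  stopifnot(dim(pixels)[1] == nrow(mask), dim(pixels)[2] == ncol(mask),
            any(mask))
  structure(list(pixels = pixels, mask = mask, label = label,
                 source_image = source_image, source_circle = source_circle,
                 clipped = clipped),
            class = "seed_patch")
}

#' Extract the square patch around a retained circle
#'
#' @param image the source image.
#' @param circle one-row data frame (or list) with `x`, `y`, `radius_px`.
#' @return a [seed_patch]; `clipped` records whether an image border cut the
#'   crop, and the mask stays consistent with the true circle geometry.
#' @export
extract_patch <- function(image, circle) {
  cx <- circle$x; cy <- circle$y; r <- circle$radius_px
  h <- dim(image)[1]; w <- dim(image)[2]
  s <- max(2L, as.integer(round(2 * r)))
  x0 <- as.integer(round(cx)) - (s - 1L) %/% 2L
  y0 <- as.integer(round(cy)) - (s - 1L) %/% 2L
  x1 <- x0 + s - 1L; y1 <- y0 + s - 1L
  cx0 <- max(0L, x0); cy0 <- max(0L, y0)
  cx1 <- min(w - 1L, x1); cy1 <- min(h - 1L, y1)
  clipped <- cx0 != x0 || cy0 != y0 || cx1 != x1 || cy1 != y1
  rows <- (cy0:cy1) + 1L; cols <- (cx0:cx1) + 1L
  pixels <- image[rows, cols, , drop = FALSE]
  dx <- matrix(rep((cx0:cx1) - cx, each = length(rows)), length(rows))
  dy <- matrix(rep((cy0:cy1) - cy, times = length(cols)), length(rows))
  mask <- dx^2 + dy^2 <= r^2
  seed_patch(pixels, mask, source_circle = circle, clipped = clipped)
}
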