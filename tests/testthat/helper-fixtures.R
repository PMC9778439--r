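# Shared fixtures, all generated in code.

# A clean bright disc (no texture) on a dark background.
make_disc_image <- function(size = 128, cx = NULL, cy = NULL, r = 40,
                            fg = 200, bg = 10) {
  if (is.null(cx)) cx <- (size - 1) / 2
  if (is.null(cy)) cy <- (size - 1) / 2
  xs <- matrix(rep(0:(size - 1), each = size), size)
  ys <- matrix(rep(0:(size - 1), times = size), size)
  d <- sqrt((xs - cx)^2 + (ys - cy)^2)
  alpha <- pmin(pmax(r + 0.5 - d, 0), 1)
  g <- bg * (1 - alpha) + fg * alpha
  img <- array(0, c(size, size, 3))
  for (k in 1:3) img[, , k] <- g
  list(image = img, cx = cx, cy = cy, r = r)
}

# Point-set edge map (no raster/gradient): exercises pure geometry paths.
ring_edge_map <- function(cx, cy, r, n = 360, arc = c(0, 2 * pi),
                          jitter = 0, seed = 1) {
  withr::with_seed(seed, {
    th <- seq(arc[1], arc[2], length.out = n + 1)[-1]
    coords <- cbind(x = cx + (r + rnorm(n, 0, jitter)) * cos(th),
                    y = cy + (r + rnorm(n, 0, jitter)) * sin(th))
    structure(list(raster = NULL, coords = coords, grad = NULL),
              class = "edge_map")
  })
}

# Exhaustive Hough-style oracle: best (center, radius) on a grid by inlier
# count, independent of the randomized detector's code path.
hough_oracle <- function(coords, cx0, cy0, r0, span = 2, step = 0.5, tol = 1.5) {
  best <- NULL
  for (cx in seq(cx0 - span, cx0 + span, by = step))
    for (cy in seq(cy0 - span, cy0 + span, by = step))
      for (r in seq(r0 - span, r0 + span, by = step)) {
        d <- abs(sqrt((coords[, 1] - cx)^2 + (coords[, 2] - cy)^2) - r)
        n <- sum(d < tol)
        if (is.null(best) || n > best$n) best <- list(x = cx, y = cy, r = r, n = n)
      }
  best
}

# Match detections against truth circles; returns per-truth center/radius errors.
match_truth <- function(det, truth) {
  t(vapply(seq_len(nrow(truth)), function(i) {
    dd <- sqrt((det$x - truth$x[i])^2 + (det$y - truth$y[i])^2)
    j <- which.min(dd)
    c(center = dd[j], radius = abs(det$radius_px[j] - truth$radius_px[i]))
  }, c(center = 0, radius = 0)))
}

# Scene edge map with the calibration strip masked out, as run_image does.
scene_edges_sans_strip <- function(image) {
  em <- edge_map(image)
  roi <- locate_strip_roi(image)
  if (!is.null(roi)) {
    keep <- em$coords[, 2] >= roi[4]
    em$coords <- em$coords[keep, , drop = FALSE]
    em$grad <- em$grad[keep, , drop = FALSE]
    em$raster[seq_len(roi[4]), ] <- FALSE
  }
  em
}

# One small texture model shared across test files (built on first use).
.fixture_env <- new.env(parent = emptyenv())
shared_patch_model <- function() {
  if (is.null(.fixture_env$model)) {
    classes <- rep(pattern_classes(), each = 10)
    patches <- lapply(seq_along(classes), function(i)
      generate_patch(classes[i], 96, rng_seed = 9000 + i))
    X <- feature_matrix(patches)
    .fixture_env$model <- texture_train(X, texture_group(classes),
                                        train_config(nrounds = 60))
  }
  .fixture_env$model
}
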