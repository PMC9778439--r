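#' Parameters of the morphological subclass step
#'
#' @param significant_area_fraction minimum region area, as a fraction of the
#'   masked seed area, for a region to count as significant (0.5%).
#' @param spotted_min_regions significant regions needed to call a
#'   rare-textured seed spotted (any significant region, by default, since
#'   absent requires none).
#' @param complex_coverage_threshold coverage above which a sparse-textured
#'   seed is complex (strict inequality; "more than 50% of the surface").
#' @param closing_kernel rectangular structuring element `(rows, cols)` at the
#'   reference resolution; scaled proportionally to the patch side.
#' @param ref_patch_side patch side (px) at which `closing_kernel` applies.
#' @param mask_erosion_frac fraction of the patch side eroded off the mask rim
#'   before edge detection, so the disc boundary itself contributes no
#'   regions.
#' @return a `subclass_params` list.
#' @export
subclass_params <- function(significant_area_fraction = 0.005,
                            spotted_min_regions = 1,
                            complex_coverage_threshold = 0.5,
                            closing_kernel = c(3, 5), ref_patch_side = 300,
                            mask_erosion_frac = 0.04) {
  p <- list(significant_area_fraction = significant_area_fraction,
            spotted_min_regions = as.integer(spotted_min_regions),
            complex_coverage_threshold = complex_coverage_threshold,
            closing_kernel = as.integer(closing_kernel),
            ref_patch_side = ref_patch_side,
            mask_erosion_frac = mask_erosion_frac)
  stopifnot(p$significant_area_fraction > 0, p$significant_area_fraction < 1,
            p$complex_coverage_threshold > 0, p$complex_coverage_threshold < 1,
            p$spotted_min_regions >= 1, all(p$closing_kernel >= 1))
  class(p) <- "subclass_params"
  p
}

#' Morphological region analysis of a seed patch
#'
#' Separates testa pattern (foreground) from the uniform coat: Canny edges
#' with adaptive thresholds (0.66/1.33 x the masked median), restricted to an
#' eroded mask so the seed rim is excluded; closing (dilation then erosion
#' with the same rectangular structuring element); contour following of the
#' connected components with hole filling; and area computation of the filled
#' regions. Regions at least `significant_area_fraction` of the masked seed
#' area are significant; `coverage_fraction` is their total area over the
#' masked area.
#'
#' @param patch a [seed_patch].
#' @param params a [subclass_params()].
#' @return object of class `region_stats`: `regions` (data frame `area_px`,
#'   bounding box), `contours`, `n_significant`, `coverage_fraction`,
#'   `mask_area`.
#' @export
region_analysis <- function(patch, params = subclass_params()) {
  stopifnot(inherits(patch, "seed_patch"))
  gray <- rgb_to_gray(patch$pixels)
  side <- max(dim(gray))
  mask_area <- sum(patch$mask)

  # adaptive thresholds relative to the masked median: inside a seed the
  # median is the bright coat itself, so the whole-scene 0.66/1.33 rule
  # (where the median is the dark surface) would sit above every pattern
  # edge; 0.2/0.4 x median clears sensor noise yet keeps pattern boundaries
  med <- stats::median(gray[patch$mask])
  low <- max(0.2 * med, 1)
  high <- max(0.4 * med, 2)
  edges <- canny_cpp(gray, low, high, 1.4)

  er <- max(3L, as.integer(round(params$mask_erosion_frac * side)))
  mask_in <- erode_rect_cpp(patch$mask, 2L * er + 1L, 2L * er + 1L)
  edges <- edges & mask_in

  k <- pmax(1L, as.integer(round(params$closing_kernel * side / params$ref_patch_side)))
  closed <- erode_rect_cpp(dilate_rect_cpp(edges, k[1], k[2]), k[1], k[2])
  filled <- fill_holes_cpp(closed)

  lab <- label_cpp(filled, 8L)
  regions <- data.frame(area_px = numeric(0), x0 = numeric(0), y0 = numeric(0),
                        x1 = numeric(0), y1 = numeric(0))
  contours <- list()
  if (lab$n > 0) {
    for (id in seq_len(lab$n)) {
      ij <- which(lab$labels == id, arr.ind = TRUE)
      regions <- rbind(regions, data.frame(
        area_px = nrow(ij), x0 = min(ij[, 2]) - 1, y0 = min(ij[, 1]) - 1,
        x1 = max(ij[, 2]) - 1, y1 = max(ij[, 1]) - 1))
      contours[[id]] <- trace_contour_cpp(lab$labels, id)
    }
  }
  sig <- regions$area_px >= params$significant_area_fraction * mask_area
  structure(list(regions = regions, contours = contours,
                 n_significant = sum(sig),
                 coverage_fraction = min(1, sum(regions$area_px[sig]) / mask_area),
                 mask_area = mask_area),
            class = "region_stats")
}

#' Disambiguate rare-textured seeds: absent vs spotted
#'
#' No significant region means a plain coat (`absent`); at least
#' `spotted_min_regions` significant regions mean localized blobs
#' (`spotted`).
#'
#' @param stats a `region_stats`.
#' @param params a [subclass_params()].
#' @return `"absent"` or `"spotted"`.
#' @export
subclass_rare <- function(stats, params = subclass_params()) {
  if (stats$n_significant >= params$spotted_min_regions) "spotted" else "absent"
}

#' Disambiguate sparse-textured seeds: dotted vs complex
#'
#' Coverage strictly above the threshold (default 50% of the seed surface)
#' means large merged patterns (`complex`); otherwise uniformly spread small
#' dots (`dotted`).
#'
#' @inheritParams subclass_rare
#' @return `"dotted"` or `"complex"`.
#' @export
subclass_sparse <- function(stats, params = subclass_params()) {
  if (stats$coverage_fraction > params$complex_coverage_threshold) "complex" else "dotted"
}

#' Final five-class testa-pattern label
#'
#' The two-step decision: densely textured seeds are marbled unconditionally;
#' rare goes through [subclass_rare()], sparse through [subclass_sparse()].
#' There is no recovery path between groups.
#'
#' @param texture one of [texture_levels()].
#' @param stats a `region_stats`.
#' @param params a [subclass_params()].
#' @return one of [pattern_classes()].
#' @export
final_label <- function(texture, stats, params = subclass_params()) {
  switch(as.character(texture),
         dense = "marbled",
         rare = subclass_rare(stats, params),
         sparse = subclass_sparse(stats, params),
         stop("unknown texture group: ", texture))
}
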