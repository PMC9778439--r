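#' Pipeline configuration
#'
#' One nested configuration object covering every stage; serializable to a
#' single JSON file for the command-line interface.
#'
#' @param detector a [detector_params()].
#' @param subclass a [subclass_params()].
#' @param training a [train_config()].
#' @param features list: LBP `P`, `R` and colour `bins`.
#' @param scale list: `adv_mm` (known square side), histogram `bin_width`,
#'   square `quorum`.
#' @param quality list: `dark_luma` (abort below this mean luma) and
#'   `saturated_frac` (abort above this fraction of clipped pixels).
#' @param rng_seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(detector = detector_params(),
                            subclass = subclass_params(),
                            training = train_config(),
                            features = list(P = 16, R = 2, bins = 60),
                            scale = list(adv_mm = 1, bin_width = 1, quorum = 10),
                            quality = list(dark_luma = 25, saturated_frac = 0.02),
                            rng_seed = 0) {
  cfg <- list(detector = detector, subclass = subclass, training = training,
              features = features, scale = scale, quality = quality,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

#' @rdname pipeline_config
#' @param cfg a configuration list to validate.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg$detector), is.list(cfg$subclass), is.list(cfg$training),
            cfg$features$P >= 4, cfg$features$R > 0, cfg$features$bins >= 2,
            cfg$scale$adv_mm > 0, cfg$scale$quorum >= 1,
            cfg$quality$dark_luma >= 0, cfg$quality$saturated_frac > 0)
  # re-run the component validators
  do.call(detector_params, unclass(cfg$detector)[names(formals(detector_params))[
    names(formals(detector_params)) %in% names(cfg$detector)]])
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  jsonlite::write_json(strip(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config(
    detector = do.call(detector_params, raw$detector),
    subclass = do.call(subclass_params, raw$subclass[names(raw$subclass) %in%
                                                       names(formals(subclass_params))]),
    training = do.call(train_config, raw$training),
    features = raw$features, scale = raw$scale, quality = raw$quality,
    rng_seed = raw$rng_seed %||% 0)
  cfg
}

#' Image quality gate
#'
#' Dark or saturated frames cannot be analysed and abort early; a frame whose
#' graph paper yields no square quorum is flagged unfocused downstream
#' (advisory).
#'
#' @param image RGB array or grayscale matrix.
#' @param config a [pipeline_config()].
#' @return list `flags` (character vector), `abort` (logical).
#' @export
quality_gate <- function(image, config = pipeline_config()) {
  luma <- rgb_to_gray(image)
  flags <- character(0)
  if (mean(luma) < config$quality$dark_luma) flags <- c(flags, "dark")
  if (mean(luma >= 250) > config$quality$saturated_frac) flags <- c(flags, "saturated")
  list(flags = flags, abort = length(flags) > 0)
}

#' Run the full pipeline on one image
#'
#' Quality gate, edge map, randomized circle detection, radius and
#' radiometric checks, patch extraction, scale calibration from the graph
#' paper, mean seed size in mm, and (given a trained model) texture
#' classification plus morphological subclassing into the five testa-pattern
#' classes. The located calibration strip is masked out of the edge map
#' before circle detection so grid edges cannot seed false circles.
#'
#' @param image RGB array, or a path to a PNM image.
#' @param config a [pipeline_config()].
#' @param model optional trained `lentil_gbt`; without it seeds are measured
#'   but not classified.
#' @param image_id identifier recorded in the report.
#' @return an `image_report`: `image`, `scale` (or NULL), `seeds` (one row
#'   per detected circle), `counts` (detection funnel), `mean_radius_px`,
#'   `size_mm`, `warnings`.
#' @export
run_image <- function(image, config = pipeline_config(), model = NULL,
                      image_id = NULL) {
  if (is.character(image)) {
    if (!file.exists(image)) stop("unreadable file: ", image)
    if (is.null(image_id)) image_id <- basename(image)
    image <- read_pnm(image)
  }
  if (is.null(image_id)) image_id <- "image"
  empty_seeds <- data.frame(x = numeric(0), y = numeric(0),
                            radius_px = numeric(0), support = numeric(0),
                            background_fraction = numeric(0),
                            status = character(0), texture_group = character(0),
                            n_significant = integer(0),
                            coverage_fraction = numeric(0),
                            pattern_class = character(0))
  report <- function(seeds, counts, scale, warnings, mean_r = NA_real_,
                     size = NA_real_) {
    structure(list(image = image_id, scale = scale, seeds = seeds,
                   counts = counts, mean_radius_px = mean_r, size_mm = size,
                   warnings = warnings), class = "image_report")
  }
  zero_counts <- list(detected = 0L, after_radius = 0L, retained = 0L,
                      discarded_radius = 0L, discarded_radiometric = 0L)

  qg <- quality_gate(image, config)
  if (qg$abort)
    return(report(empty_seeds, zero_counts, NULL, qg$flags))

  warnings <- character(0)
  roi <- locate_strip_roi(image)
  scale <- tryCatch(
    estimate_edv(detect_squares(image, roi), adv_mm = config$scale$adv_mm,
                 bin_width = config$scale$bin_width,
                 quorum = config$scale$quorum),
    error = function(e) NULL)
  if (is.null(scale)) warnings <- c(warnings, "unfocused_or_no_calibration")

  em <- edge_map(image)
  if (!is.null(roi)) {
    keep <- em$coords[, 2] >= roi[4]          # drop edges inside the strip
    em$coords <- em$coords[keep, , drop = FALSE]
    em$grad <- em$grad[keep, , drop = FALSE]
    em$raster[seq_len(roi[4]), ] <- FALSE
  }
  cands <- detect_circles(em, config$detector)
  if (nrow(cands) == 0)
    return(report(empty_seeds, zero_counts, scale, warnings))

  det <- as_detected(cands)
  det <- radius_filter(det, config$detector$radius_sd_multiplier)
  after_radius <- sum(det$status == "retained")
  det <- radiometric_filter(det, image, config$detector$background_fraction_max)
  retained <- det$status == "retained"
  counts <- list(detected = nrow(det), after_radius = after_radius,
                 retained = sum(retained),
                 discarded_radius = sum(det$status == "discarded_radius"),
                 discarded_radiometric = sum(det$status == "discarded_radiometric"))

  det$texture_group <- NA_character_
  det$n_significant <- NA_integer_
  det$coverage_fraction <- NA_real_
  det$pattern_class <- NA_character_
  for (i in which(retained)) {
    patch <- extract_patch(image, det[i, ])
    stats <- region_analysis(patch, config$subclass)
    det$n_significant[i] <- stats$n_significant
    det$coverage_fraction[i] <- stats$coverage_fraction
    if (!is.null(model)) {
      fv <- feature_vector(patch, P = config$features$P, R = config$features$R,
                           bins = config$features$bins)
      tex <- predict(model, fv)
      det$texture_group[i] <- tex
      det$pattern_class[i] <- final_label(tex, stats, config$subclass)
    }
  }
  mean_r <- if (any(retained)) mean(det$radius_px[retained]) else NA_real_
  size <- if (!is.null(scale) && !is.na(mean_r)) seed_size_mm(mean_r, scale) else NA_real_
  report(det[, names(empty_seeds)], counts, scale, warnings, mean_r, size)
}

#' @export
print.image_report <- function(x, ...) {
  cat(sprintf("image %s: %d detected -> %d after radius check -> %d retained",
              x$image, x$counts$detected, x$counts$after_radius,
              x$counts$retained))
  if (!is.na(x$size_mm)) cat(sprintf("; mean size %.2f mm", x$size_mm))
  if (length(x$warnings)) cat(" [", paste(x$warnings, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' Run the pipeline over a dataset manifest
#'
#' @param manifest data frame with `image_path` and optionally
#'   `measured_size_mm` (per-image ground-truth mean seed size).
#' @param config a [pipeline_config()].
#' @param model optional trained classifier.
#' @return a `dataset_report`: per-image reports, the aggregate detection
#'   funnel in pipeline order (detected, after radius check, after
#'   radiometric check), a per-image size table, a [size_error_report] when
#'   measured sizes were supplied, and the list of missing files (missing
#'   files are reported, the run continues).
#' @export
run_dataset <- function(manifest, config = pipeline_config(), model = NULL) {
  stopifnot(is.data.frame(manifest), "image_path" %in% names(manifest))
  reports <- list()
  missing <- character(0)
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$image_path[i]
    if (!file.exists(p)) {
      missing <- c(missing, p)
      next
    }
    reports[[length(reports) + 1]] <- run_image(p, config, model)
  }
  counts <- list(detected = 0L, after_radius = 0L, retained = 0L)
  sizes <- data.frame(image = character(0), size_mm = numeric(0),
                      measured_mm = numeric(0))
  keep_meas <- "measured_size_mm" %in% names(manifest)
  present <- which(file.exists(manifest$image_path))
  for (j in seq_along(reports)) {
    r <- reports[[j]]
    counts$detected <- counts$detected + r$counts$detected
    counts$after_radius <- counts$after_radius + r$counts$after_radius
    counts$retained <- counts$retained + r$counts$retained
    sizes <- rbind(sizes, data.frame(
      image = r$image, size_mm = r$size_mm,
      measured_mm = if (keep_meas) manifest$measured_size_mm[present[j]] else NA_real_))
  }
  errors <- NULL
  ok <- !is.na(sizes$size_mm) & !is.na(sizes$measured_mm)
  if (sum(ok) >= 2)
    errors <- size_error_report(sizes$measured_mm[ok], sizes$size_mm[ok])
  structure(list(images = reports, counts = counts, sizes = sizes,
                 size_errors = errors, missing = missing),
            class = "dataset_report")
}

#' @export
print.dataset_report <- function(x, ...) {
  cat(sprintf("dataset: %d images, funnel %d -> %d -> %d\n",
              length(x$images), x$counts$detected, x$counts$after_radius,
              x$counts$retained))
  if (!is.null(x$size_errors)) print(x$size_errors)
  if (length(x$missing)) cat("missing files:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}
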