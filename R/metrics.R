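#' Confusion matrix with fixed class order
#'
#' Rows are ground truth (GT), columns predictions (P) -- the convention of
#' the published benchmark tables this package reproduces.
#'
#' @param true_labels,predicted_labels aligned label vectors.
#' @param class_names ordered class vocabulary; labels outside it are an
#'   error. Defaults to the classes in order of first appearance in
#'   `true_labels` then `predicted_labels`.
#' @return integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(true_labels, predicted_labels, class_names = NULL) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  stopifnot(length(true_labels) == length(predicted_labels))
  if (is.null(class_names))
    class_names <- unique(c(true_labels, predicted_labels))
  bad <- setdiff(unique(c(true_labels, predicted_labels)), class_names)
  if (length(bad)) stop("label outside class_names: ", paste(bad, collapse = ", "))
  t_ <- factor(true_labels, levels = class_names)
  p_ <- factor(predicted_labels, levels = class_names)
  m <- as.matrix(table(t_, p_))
  dimnames(m) <- list(GT = class_names, P = class_names)
  confusion_matrix(m, class_names)
}

#' @rdname confusion
#' @param counts square matrix of counts (rows GT, columns P), e.g. a
#'   published table.
#' @export
confusion_matrix <- function(counts, class_names = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0),
            all(counts == round(counts)))
  if (!is.null(class_names))
    dimnames(counts) <- list(GT = class_names, P = class_names)
  structure(counts, class = c("confusion_matrix", class(counts)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (rows = ground truth, columns = prediction)\n")
  print(unclass(x))
  invisible(x)
}

#' Overall accuracy
#'
#' `trace / total`: the fraction of correctly classified examples.
#'
#' @param cm a [confusion_matrix].
#' @return scalar in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  sum(diag(cm)) / tot
}

#' Balanced accuracy
#'
#' Mean of per-class recalls, robust to class imbalance. With
#' `round_recalls_first = TRUE` each recall is rounded to two decimals before
#' averaging, reproducing how such benchmarks are commonly printed
#' (e.g. `(0.98 + 0.69 + 0.96 + 0.76 + 0.94)/5 = 0.87`).
#'
#' @param cm a [confusion_matrix].
#' @param round_recalls_first round each recall to 2 decimals first.
#' @return scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(cm, round_recalls_first = FALSE) {
  supports <- rowSums(cm)
  zero <- supports == 0
  if (any(zero))
    stop("zero-support class: ", paste(rownames(cm)[zero], collapse = ", "))
  recalls <- diag(cm) / supports
  if (round_recalls_first) recalls <- round_half_up(recalls, 2)
  mean(recalls)
}

#' Support-weighted F1 score
#'
#' Per class, precision is the column-wise and recall the row-wise fraction
#' of the diagonal; their harmonic mean (0 when both are 0) is averaged with
#' weights equal to class supports.
#'
#' @param cm a [confusion_matrix].
#' @return scalar in `[0, 1]`.
#' @export
weighted_f1 <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  sum(f1 * rowSums(cm)) / tot
}

#' Half-up presentation rounding
#'
#' `round()` in R rounds half to even and is subject to binary representation
#' quirks; printed benchmark numbers use conventional half-up rounding, so
#' metric regression tests need it explicitly.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Seed-size error report
#'
#' Per-image absolute errors `E_i = |x_i - xhat_i|` between measured and
#' estimated seed sizes (mm), with the summary statistics: mean absolute
#' error, RMSD, the coefficient of determination `R^2 = 1 - RSS/TSS`, and the
#' mean relative accuracy `cc = mean((x_i - |x_i - xhat_i|) / x_i)`.
#'
#' @param measured_mm,estimated_mm aligned positive size vectors, `N >= 2`.
#' @return object of class `size_error_report` with `per_image`, `E_bar`,
#'   `RMSD`, `R2` (with `RSS`, `TSS`), `cc`, `N`.
#' @export
size_error_report <- function(measured_mm, estimated_mm) {
  stopifnot(length(measured_mm) == length(estimated_mm),
            length(measured_mm) >= 2)
  if (any(measured_mm <= 0)) stop("measured sizes must be positive (cc undefined at 0)")
  E <- abs(measured_mm - estimated_mm)
  rss <- sum((measured_mm - estimated_mm)^2)
  tss <- sum((measured_mm - mean(measured_mm))^2)
  r2 <- if (rss == 0) 1 else if (tss == 0) NA_real_ else 1 - rss / tss
  structure(list(
    per_image = data.frame(measured_mm = measured_mm,
                           estimated_mm = estimated_mm, E = E),
    E_bar = mean(E),
    RMSD = sqrt(mean((measured_mm - estimated_mm)^2)),
    R2 = r2, RSS = rss, TSS = tss,
    cc = mean((measured_mm - E) / measured_mm),
    N = length(measured_mm)), class = "size_error_report")
}

#' @export
print.size_error_report <- function(x, ...) {
  cat(sprintf("size errors over %d images: E_bar = %.3f mm, RMSD = %.3f mm, R2 = %.3f, cc = %.3f\n",
              x$N, x$E_bar, x$RMSD, x$R2, x$cc))
  invisible(x)
}

#' Seed-retrieval rate
#'
#' Percentage of pictured seeds that survive the full detection funnel.
#'
#' @param retained number of definitively retained seeds.
#' @param pictured number of seeds pictured in the dataset.
#' @return percentage on `[0, 100]`.
#' @export
retrieval_rate <- function(retained, pictured) {
  stopifnot(pictured > 0, retained >= 0)
  retained * 100 / pictured
}

#' Published benchmark inputs
#'
#' The confusion matrices and funnel counts printed by the original
#' evaluation of this pipeline on a 64-image collection of pigmented lentil
#' genotypes (940 annotated seed patches), bundled as regression-test and
#' acceptance inputs: `texture3` (rare/sparse/dense step), `rare2`
#' (absent/spotted), `sparse2` (dotted/complex), `overall5` (final
#' five-class result), the detection funnel counts, and the worked
#' scale-calibration example.
#'
#' @return list with elements `tables` (four [confusion_matrix] objects),
#'   `counts` and `scale_example`.
#' @export
reference_benchmarks <- function() {
  t1 <- confusion_matrix(matrix(c(631, 4, 0,
                                  9, 270, 1,
                                  1, 6, 18), 3, byrow = TRUE),
                         c("rare", "sparse", "dense"))
  t2 <- confusion_matrix(matrix(c(502, 9,
                                  38, 86), 2, byrow = TRUE),
                         c("absent", "spotted"))
  t3 <- confusion_matrix(matrix(c(215, 32,
                                  12, 21), 2, byrow = TRUE),
                         c("dotted", "complex"))
  t4 <- confusion_matrix(matrix(c(500, 9, 2, 0, 0,
                                  38, 85, 1, 0, 0,
                                  0, 9, 236, 0, 2,
                                  0, 1, 1, 19, 4,
                                  0, 0, 0, 2, 31), 5, byrow = TRUE),
                         c("absent", "spotted", "dotted", "marbled", "complex"))
  list(tables = list(texture3 = t1, rare2 = t2, sparse2 = t3, overall5 = t4),
       counts = c(detected = 1549, after_radius = 1136, retained = 940,
                  pictured = 1270),
       scale_example = list(EDV = 56.64, ADV = 1, mean_radius_px = 146,
                            measured_mm = 5))
}
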