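#' Image containers and basic radiometry
#'
#' Images are plain numeric arrays: an RGB image is an `h x w x 3` array and a
#' grayscale image an `h x w` matrix, both with intensities on `[0, 255]`.
#' Pixel coordinates exposed by the detection functions are 0-based with
#' `x = column`, `y = row`, matching the convention of most imaging tools.
#'
#' @param image RGB array (`h x w x 3`) or grayscale matrix.
#' @return `rgb_to_gray()` returns an `h x w` matrix of luma values.
#' @details Grayscale conversion uses ITU-R BT.601 luma weights
#'   (0.299, 0.587, 0.114).
#' @export
rgb_to_gray <- function(image) {
  if (is.matrix(image)) return(image)
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Otsu's automatic intensity threshold
#'
#' Used to separate the dark acquisition surface from bright seeds (and dark
#' grid lines from light graph paper) without a fixed threshold.
#'
#' @param gray grayscale matrix with values in `[0, 255]`.
#' @return scalar threshold; pixels strictly below it are "background".
#' @export
otsu_threshold <- function(gray) {
  v <- pmin(pmax(round(as.numeric(gray)), 0), 255)
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  # the criterion is flat across an empty histogram gap: take the middle of
  # the maximizing plateau rather than its left edge
  at_max <- which(sigma_b >= max(sigma_b) - 1e-9)
  round(mean(at_max)) - 1L  # threshold t: classes [0,t) vs [t,255]
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

#' Read and write portable anymap (PNM) images
#'
#' Self-contained PGM/PPM support (ASCII `P2`/`P3` and binary `P5`/`P6`,
#' 8-bit). PNM is the interchange format of this package: it is trivially
#' inspectable, needs no external decoder, and round-trips the integer
#' intensities exactly.
#'
#' @param path file path.
#' @param image RGB array or grayscale matrix, values `[0, 255]`.
#' @param ascii write the ASCII variant (`P2`/`P3`) instead of binary.
#' @return `read_pnm()` returns an `h x w x 3` array (PPM) or matrix (PGM).
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P3", "P5", "P6")) stop("not an 8-bit PGM/PPM file: ", path)
  ascii <- magic %in% c("P2", "P3")
  color <- magic %in% c("P3", "P6")

  # header tokens (width, height, maxval), '#' comments allowed
  toks <- integer(0)
  buf <- character(0)
  while (length(toks) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PNM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf)) {
      toks <- c(toks, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- toks[1]; h <- toks[2]; maxv <- toks[3]
  if (maxv > 255) stop("only 8-bit PNM supported")
  n <- w * h * if (color) 3L else 1L
  vals <- if (ascii) scan(con, integer(), n = n, quiet = TRUE)
          else as.integer(readBin(con, "raw", n = n))
  if (length(vals) < n) stop("truncated PNM data")
  if (color) {
    arr <- array(0, c(h, w, 3))
    m <- matrix(vals, nrow = 3)          # interleaved RGB, row-major pixels
    for (k in 1:3) arr[, , k] <- matrix(m[k, ], nrow = h, byrow = TRUE)
    arr
  } else {
    matrix(vals, nrow = h, byrow = TRUE)
  }
}

#' @rdname read_pnm
#' @export
write_pnm <- function(image, path, ascii = FALSE) {
  color <- !is.matrix(image)
  if (color) stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  v <- round(clamp255(image))
  h <- dim(v)[1]; w <- dim(v)[2]
  if (color) {
    px <- rbind(as.numeric(t(v[, , 1])), as.numeric(t(v[, , 2])), as.numeric(t(v[, , 3])))
    flat <- as.integer(px)
  } else {
    flat <- as.integer(t(v))
  }
  magic <- if (ascii) { if (color) "P3" else "P2" } else { if (color) "P6" else "P5" }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n255\n", magic, w, h), con, eos = NULL)
  if (ascii) writeChar(paste(flat, collapse = "\n"), con, eos = NULL)
  else writeBin(as.raw(flat), con)
  invisible(path)
}
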