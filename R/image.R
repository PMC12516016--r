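# Image I/O and resampling --------------------------------------------------

#' Read an image file as an M x N x 3 array in [0, 1]
#'
#' PNG via the png package, JPEG via the jpeg package (if installed), and
#' binary PPM/PGM (P6/P5) natively.  Grayscale inputs are replicated to
#' three channels; alpha channels are dropped.
#'
#' @param path Image file path.
#' @return Numeric `M x N x 3` array with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("the 'jpeg' package is required to read JPEG files")
      }
      jpeg::readJPEG(path)
    },
    ppm = ,
    pgm = read_pnm(path),
    stop("unsupported image format: .", ext))
  as_rgb_array(x)
}

as_rgb_array <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  C <- dim(x)[3]
  if (C == 1L) {
    x <- array(rep(x, 3L), c(dim(x)[1:2], 3L))
  } else if (C == 2L) {          # gray + alpha
    x <- array(rep(x[, , 1L], 3L), c(dim(x)[1:2], 3L))
  } else if (C >= 4L) {          # drop alpha
    x <- x[, , 1:3, drop = FALSE]
  }
  x
}

#' Write an image array to PNG
#'
#' @param image Numeric array `M x N x C` (or matrix); values are clamped to
#'   `[0, 1]` unless `normalise = TRUE`, in which case they are min-max
#'   rescaled first (how signed detail subbands are displayed).
#' @param path Output file path.
#' @param normalise Min-max rescale before writing.
#' @export
write_image_png <- function(image, path, normalise = FALSE) {
  if (normalise) image <- normalise01(image)
  image[image < 0] <- 0
  image[image > 1] <- 1
  png::writePNG(image, path)
  invisible(path)
}

# Binary PPM (P6) / PGM (P5), 8-bit.
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P5", "P6")) stop("unsupported PNM magic: ", magic)
  vals <- integer(0)
  while (length(vals) < 3L) {
    line <- readLines(con, 1L)
    line <- sub("#.*", "", line)
    vals <- c(vals, as.integer(strsplit(trimws(line), "\\s+")[[1]]))
  }
  w <- vals[1]; h <- vals[2]; maxval <- vals[3]
  nch <- if (magic == "P6") 3L else 1L
  raw <- as.integer(readBin(con, "raw", n = w * h * nch))
  # stored row-major, channel-interleaved
  arr <- array(0, c(h, w, nch))
  for (c in seq_len(nch)) {
    arr[, , c] <- matrix(raw[seq(c, length(raw), by = nch)],
                         nrow = h, ncol = w, byrow = TRUE)
  }
  arr / maxval
}

write_pnm <- function(image, path) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  nch <- dim(image)[3]
  stopifnot(nch %in% c(1L, 3L))
  image[image < 0] <- 0
  image[image > 1] <- 1
  v <- round(image * 255)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n255\n", if (nch == 3L) "P6" else "P5",
                    ncol(image), nrow(image)), con, eos = NULL)
  # channel-interleaved, row-major: channel varies fastest, then column, row
  writeBin(as.raw(as.vector(aperm(v, c(3L, 2L, 1L)))), con)
  invisible(path)
}

#' Min-max rescale to [0, 1]
#'
#' Zero-range inputs map to all zeros (the convention used both for display
#' of signed detail subbands and for degenerate Grad-CAM maps).
#'
#' @param x Numeric array.
#' @return Rescaled array of the same shape.
#' @export
normalise01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(array(0, dim(x) %||% length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resize an image to a target size
#'
#' Bilinear interpolation; when shrinking, the source is first box-filtered
#' (area averaging) so the result is anti-aliased.
#'
#' @param image `M x N x C` array or matrix.
#' @param size Target `c(height, width)` (a single number is used for both).
#' @return Resized array.
#' @export
resize_image <- function(image, size = c(128L, 128L)) {
  if (length(size) == 1L) size <- c(size, size)
  was_matrix <- is.matrix(image)
  if (was_matrix) image <- array(image, c(dim(image), 1L))
  out <- array(0, c(size, dim(image)[3]))
  for (c in seq_len(dim(image)[3])) {
    out[, , c] <- resize_channel(image[, , c], size[1], size[2])
  }
  if (was_matrix) out[, , 1] else out
}

resize_channel <- function(x, H, W) {
  h <- nrow(x); w <- ncol(x)
  # area-average prefilter for integer shrink factors (anti-aliasing)
  if (h >= 2 * H) {
    f <- floor(h / H)
    x <- box_reduce_rows(x, f); h <- nrow(x)
  }
  if (w >= 2 * W) {
    f <- floor(w / W)
    x <- t(box_reduce_rows(t(x), f)); w <- ncol(x)
  }
  if (h == H && w == W) return(x)
  # bilinear with pixel-centre alignment
  yi <- (seq_len(H) - 0.5) * h / H + 0.5
  xi <- (seq_len(W) - 0.5) * w / W + 0.5
  y0 <- pmin(pmax(floor(yi), 1L), h); y1 <- pmin(y0 + 1L, h)
  x0 <- pmin(pmax(floor(xi), 1L), w); x1 <- pmin(x0 + 1L, w)
  wy <- pmin(pmax(yi - y0, 0), 1); wx <- pmin(pmax(xi - x0, 0), 1)
  a <- x[y0, x0, drop = FALSE] * (1 - wy) + x[y1, x0, drop = FALSE] * wy
  b <- x[y0, x1, drop = FALSE] * (1 - wy) + x[y1, x1, drop = FALSE] * wy
  sweep(a, 2L, 1 - wx, `*`) + sweep(b, 2L, wx, `*`)
}

box_reduce_rows <- function(x, f) {
  if (f < 2) return(x)
  n <- floor(nrow(x) / f) * f
  x <- x[seq_len(n), , drop = FALSE]
  g <- matrix(0, n / f, ncol(x))
  for (i in seq_len(f)) g <- g + x[seq(i, n, by = f), , drop = FALSE]
  g / f
}
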