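#' Image stacks in the IDX container format
#'
#' `read_idx_images()` reads an IDX3 unsigned-byte image file (the
#' container used by the classic handwritten-digit datasets): a big-endian
#' int32 magic number 2051 (0x00000803), three big-endian int32 dimension
#' fields (n, rows, cols), then `n * rows * cols` pixel bytes, one image at
#' a time in row-major order. `write_idx_images()` is the exact inverse.
#'
#' @param path file path.
#' @return An `image_sample`: list with `images`, an integer array
#'   `[n, rows, cols]` of intensities in \[0, 255\], and `source`.
#' @export
read_idx_images <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, integer(), 1, size = 4, endian = "big")
  if (length(magic) == 0 || magic != 2051L) {
    stop_sigceiling("sigceiling_format_error",
                    "not an IDX3 unsigned-byte image file (bad magic number)")
  }
  dims <- readBin(con, integer(), 3, size = 4, endian = "big")
  if (length(dims) < 3 || any(dims <= 0)) {
    stop_sigceiling("sigceiling_format_error", "corrupt IDX dimension fields")
  }
  n <- dims[1]; nr <- dims[2]; nc <- dims[3]
  raw_px <- readBin(con, integer(), n * nr * nc, size = 1, signed = FALSE)
  if (length(raw_px) != n * nr * nc) {
    stop_sigceiling("sigceiling_format_error",
                    sprintf("truncated IDX file: expected %d pixels, got %d",
                            n * nr * nc, length(raw_px)))
  }
  # stored order: image-major, then row-major within an image
  images <- aperm(array(raw_px, dim = c(nc, nr, n)), c(3, 2, 1))
  image_sample(images, source = "idx_file")
}

#' @rdname read_idx_images
#' @param sample an `image_sample` (or bare `[n, rows, cols]` array).
#' @export
write_idx_images <- function(sample, path) {
  images <- if (inherits(sample, "image_sample")) sample$images else sample
  d <- dim(images)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(2051L, con, size = 4, endian = "big")
  writeBin(as.integer(d), con, size = 4, endian = "big")
  px <- as.integer(aperm(images, c(3, 2, 1)))
  writeBin(as.raw(px), con)
  invisible(path)
}

#' @rdname read_idx_images
#' @param images integer array `[n, rows, cols]` with values in \[0, 255\].
#' @param source provenance tag, `"idx_file"` or `"synthetic"`.
#' @export
image_sample <- function(images, source = c("synthetic", "idx_file")) {
  source <- match.arg(source)
  d <- dim(images)
  if (length(d) != 3 || d[1] < 2) {
    stop_sigceiling("sigceiling_validation_error",
                    "images must be an [n, rows, cols] array with n >= 2")
  }
  if (min(images) < 0 || max(images) > 255) {
    stop_sigceiling("sigceiling_validation_error",
                    "intensities must lie in [0, 255]")
  }
  structure(list(images = images, source = source), class = "image_sample")
}

#' @export
print.image_sample <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<image_sample> %d images of %dx%d pixels (%s)\n",
              d[1], d[2], d[3], x$source))
  invisible(x)
}
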