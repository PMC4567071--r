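# File round-tripping: grayscale PNG/TIFF images mapped linearly to [0,1],
# and plain-text formats for masks and complex measurement vectors so every
# artifact of a run is human-inspectable and diff-able.

#' Read a grayscale image
#'
#' Reads PNG or TIFF (by extension), averaging channels of color inputs,
#' and returns intensities in `[0, 1]` (8/16-bit files map linearly).
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return A numeric matrix with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image extension: ", ext)
  )
  if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3L, dim(img)[3L])), drop = FALSE], c(1, 2), mean)
  img
}

#' Write a grayscale image
#'
#' Writes PNG (8-bit) or TIFF (16-bit, preferred when quantization matters
#' in round-trips). Values are clipped to `[0, 1]` first.
#'
#' @param img numeric matrix.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    stop("unsupported image extension: ", ext)
  )
  invisible(path)
}

#' Read and write sampling masks as plain text
#'
#' Masks are stored as tab-separated 0/1 matrices: lossless, versionable,
#' and independent of any binary container.
#'
#' @param mask a [fourier_mask()].
#' @param path file path.
#' @return `write_mask()`: `path` invisibly; `read_mask()`: a
#'   [fourier_mask()].
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  utils::write.table(matrix(as.integer(mask), nrow(mask), ncol(mask)),
                     path, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(m) <- NULL
  fourier_mask(m != 0L)
}

#' Read and write complex measurement vectors as plain text
#'
#' Measurements are stored as a two-column CSV (`re`, `im`) in the mask's
#' column-major scan order; full double precision is kept.
#'
#' @param meas complex vector.
#' @param path file path.
#' @return `write_measurements()`: `path` invisibly;
#'   `read_measurements()`: a complex vector.
#' @export
write_measurements <- function(meas, path) {
  df <- data.frame(re = format(Re(meas), digits = 17),
                   im = format(Im(meas), digits = 17))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path)
  complex(real = df$re, imaginary = df$im)
}
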