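#' Read a grayscale image from PNG, TIFF or JPEG
#'
#' Returns the image as a numeric matrix with values scaled to `[0, 1]`
#' (8-bit samples are divided by 255, 16-bit by 65535). RGB input is reduced
#' to a single channel with the Rec. 709 luminance weights
#' (0.2126 R + 0.7152 G + 0.0722 B) and a message is emitted; alpha channels
#' are dropped. The original bit depth is recorded in the `"bit_depth"`
#' attribute.
#'
#' @param path Path to an existing `.png`, `.tif(f)`, `.jpg` or `.jpeg` file.
#' @return Numeric matrix (rows x cols) with values in `[0, 1]` and a
#'   `"bit_depth"` attribute.
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  depth <- 8L
  a <- switch(ext,
    png = {
      depth <- png_bit_depth(path)
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path, info = TRUE)
      bps <- attr(x, "bits.per.sample")
      if (!is.null(bps)) depth <- as.integer(bps[1])
      x
    },
    jpg = ,
    jpeg = {
      img <- EBImage::readImage(path)
      d <- EBImage::imageData(img)
      # EBImage stores (x, y[, channel]); transpose to (row, col)
      if (length(dim(d)) == 2L) t(d) else aperm(d, c(2, 1, 3))
    },
    stop("unsupported image format: '", ext, "' (", path, ")")
  )
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L) {
      message("read_image: RGB input '", basename(path),
              "' converted to luminance")
      a <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  if (length(a) == 0L) stop("empty image: ", path)
  out <- clip01(matrix(as.numeric(a), nrow(a), ncol(a)))
  attr(out, "bit_depth") <- depth
  out
}

# PNG bit depth lives in byte 25 of the file (IHDR)
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) >= 25L) as.integer(hdr[25]) else 8L
}

#' Write a binary mask as an 8-bit grayscale image
#'
#' Foreground pixels are written as 255, background as 0, so that
#' `read_image()` recovers exactly 1 and 0 and the mask round-trips.
#'
#' @param path Output path ending in `.png` or `.tif(f)`; the parent
#'   directory must exist.
#' @param mask Logical (or strictly 0/1 numeric) matrix.
#' @return `path`, invisibly.
#' @export
write_mask <- function(path, mask) {
  if (!dir.exists(dirname(path)))
    stop("cannot write mask: directory does not exist: ", dirname(path))
  m <- check_masks(mask, mask)$x
  img <- matrix(as.numeric(m), nrow(m), ncol(m))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, target = path),
    tif = ,
    tiff = tiff::writeTIFF(img, where = path, bits.per.sample = 8L),
    stop("unsupported mask format: '", ext, "'")
  )
  invisible(path)
}

#' Write a membership (or any unit-range) grid as an image
#'
#' PNG output quantizes to 8 bits; TIFF output stores 32-bit floats.
#'
#' @param path Output path ending in `.png` or `.tif(f)`.
#' @param z Numeric matrix with values in `[0, 1]`.
#' @return `path`, invisibly.
#' @export
write_membership <- function(path, z) {
  stopifnot(is.matrix(z), all(z >= 0 & z <= 1))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(z, target = path),
    tif = ,
    tiff = tiff::writeTIFF(z, where = path, bits.per.sample = 32L,
                           reduce = FALSE),
    stop("unsupported membership format: '", ext, "'")
  )
  invisible(path)
}
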