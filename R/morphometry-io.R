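#' Load a brightfield image as 8-bit grayscale
#'
#' Reads PNG, JPEG or ASCII PGM (P2). RGB(A) images are converted to
#' luminance with Rec. 601 weights (0.299 R + 0.587 G + 0.114 B); 16-bit PNG
#' is rescaled to 8-bit. TIFF is not supported in this build (no TIFF reader
#' available); convert to PNG upstream.
#'
#' @param path image file path.
#' @param pixel_size pixel size in um/px, > 0.
#' @return A [gray_image()] with `source_path = path`.
#' @export
load_grayscale <- function(path, pixel_size) {
  assert_pos(pixel_size, "pixel_size")
  if (!file.exists(path)) stop_io("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop_io("cannot read PNG '", path,
                                               "': ", conditionMessage(e))),
    jpg = ,
    jpeg = tryCatch(jpeg::readJPEG(path),
                    error = function(e) stop_io("cannot read JPEG '", path,
                                                "': ", conditionMessage(e))),
    pgm = read_pgm_ascii(path) / 255,
    tif = ,
    tiff = stop_io("TIFF is not supported in this build; convert '", path,
                   "' to PNG"),
    stop_io("unsupported image format '", ext, "' for: ", path))
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc >= 3L) {
      arr <- 0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    } else {
      arr <- arr[, , 1L]
    }
  }
  # readPNG/readJPEG scale to [0,1] regardless of bit depth; one round trip
  # through round-half-up lands both 8- and 16-bit inputs on 0..255.
  vals <- round_half_up(arr * 255)
  gray_image(matrix(as.integer(vals), nrow(arr), ncol(arr)),
             pixel_size = pixel_size, source_path = path)
}

# Minimal ASCII PGM (magic "P2") reader: plain-text fixture format.
read_pgm_ascii <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (length(toks) < 4L || toks[1L] != "P2") {
    stop_io("not an ASCII PGM (P2) file: ", path)
  }
  w <- as.integer(toks[2L]); h <- as.integer(toks[3L])
  maxval <- as.numeric(toks[4L])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) {
    stop_io("PGM pixel count mismatch in ", path, ": expected ", w * h,
            ", found ", length(vals))
  }
  matrix(round_half_up(vals / maxval * 255), nrow = h, ncol = w, byrow = TRUE)
}

#' Write a grayscale image to PNG
#'
#' @param image a [gray_image()].
#' @param path output path (.png).
#' @return Invisibly, `path`.
#' @export
write_grayscale_png <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  png::writePNG(image$intensities / 255, path)
  invisible(path)
}
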