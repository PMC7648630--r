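#' Construct a grayscale image object
#'
#' A `gray_image` is the unit of morphometric analysis: an H x W matrix of
#' 8-bit intensities (0-255) with a physical pixel size in micrometres per
#' pixel attached.
#'
#' @param intensities numeric or integer matrix, values in 0..255.
#' @param pixel_size pixel size in um/px, > 0.
#' @param source_path optional path the image was read from.
#' @return An object of class `gray_image` with fields `intensities`
#'   (integer matrix), `pixel_size` and `source_path`.
#' @export
gray_image <- function(intensities, pixel_size, source_path = NA_character_) {
  if (!is.matrix(intensities) || nrow(intensities) < 1L ||
      ncol(intensities) < 1L) {
    stop_validation("intensities must be a non-empty matrix")
  }
  assert_pos(pixel_size, "pixel_size")
  v <- as.vector(intensities)
  if (anyNA(v) || any(v < 0) || any(v > 255)) {
    stop_validation("intensities must lie in [0, 255]")
  }
  storage.mode(intensities) <- "integer"
  structure(list(intensities = intensities,
                 pixel_size = as.numeric(pixel_size),
                 source_path = source_path),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.4g um/px, range [%d, %d]\n",
              nrow(x$intensities), ncol(x$intensities), x$pixel_size,
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Construct a binary phase mask
#'
#' Phase convention is explicit and carried through all operations:
#' `"airspace0_wall1"` encodes airspace (alveolar lumen) pixels as 0 and
#' tissue wall pixels as 1.
#'
#' @param phase matrix of 0/1 (or logical, TRUE = wall).
#' @param pixel_size um/px, > 0.
#' @param convention phase convention string; only `"airspace0_wall1"` is
#'   defined.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(phase, pixel_size, convention = "airspace0_wall1") {
  if (!is.matrix(phase)) stop_validation("phase must be a matrix")
  if (is.logical(phase)) phase <- phase + 0L
  v <- as.vector(phase)
  if (anyNA(v) || !all(v %in% c(0L, 1L))) {
    stop_validation("phase must contain only 0 (airspace) and 1 (wall)")
  }
  if (!identical(convention, "airspace0_wall1")) {
    stop_validation("unknown phase convention: ", convention)
  }
  assert_pos(pixel_size, "pixel_size")
  storage.mode(phase) <- "integer"
  structure(list(phase = phase, convention = convention,
                 pixel_size = as.numeric(pixel_size)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %.4g um/px, wall fraction %.3f (%s)\n",
              nrow(x$phase), ncol(x$phase), x$pixel_size,
              mean(x$phase), x$convention))
  invisible(x)
}
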