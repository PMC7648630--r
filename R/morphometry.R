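#' Otsu binarization of a grayscale image
#'
#' Chooses the global threshold maximizing the between-class intensity
#' variance over the 256-bin histogram; ties are broken toward the lowest
#' maximizing threshold. Pixels with intensity strictly above the threshold
#' are assigned to the bright (airspace) class, pixels at or below it to the
#' dark (wall) class — under brightfield polarity this directly yields the
#' airspace = 0 / wall = 1 mask on which intercepts are measured.
#'
#' @param image a [gray_image()] with at least two distinct intensities.
#' @return List with `threshold` (integer in 0..254) and `mask` (a
#'   [binary_mask()], convention `airspace0_wall1`).
#' @export
binarize_otsu <- function(image) {
  stopifnot(inherits(image, "gray_image"))
  v <- as.vector(image$intensities)
  if (length(unique(v)) < 2L) {
    stop_validation("constant image: Otsu threshold undefined")
  }
  counts <- tabulate(v + 1L, nbins = 256L)
  thr <- otsu_threshold(counts)
  mask <- binary_mask((image$intensities <= thr) + 0L, image$pixel_size)
  list(threshold = thr, mask = mask)
}

# Between-class variance maximization over candidate thresholds t = 0..254:
# class 0 = {intensity <= t}, class 1 = {intensity > t}. Cumulative-moment
# formulation; the test suite checks it against a direct brute-force oracle.
otsu_threshold <- function(counts) {
  stopifnot(length(counts) == 256L)
  n <- sum(counts)
  p <- counts / n
  levels <- 0:255
  w0 <- cumsum(p)
  m0 <- cumsum(p * levels)
  mt <- m0[256L]
  w0c <- w0[1:255]; m0c <- m0[1:255]
  valid <- w0c > 0 & w0c < 1
  bcv <- rep(-Inf, 255L)
  bcv[valid] <- (mt * w0c[valid] - m0c[valid])^2 /
    (w0c[valid] * (1 - w0c[valid]))
  as.integer(which.max(bcv) - 1L)  # which.max takes the first (lowest) tie
}

#' Fill capillary lumens by morphological closing of the wall phase
#'
#' Dilation followed by erosion of the wall phase with a disk structuring
#' element. Airspace holes inside walls of diameter up to `2 * radius_px`
#' become wall; the image border is padded with airspace so genuine border
#' airspace is never spuriously closed.
#'
#' @param mask a [binary_mask()] (airspace = 0, wall = 1).
#' @param radius_px disk radius in pixels; 0 is the identity.
#' @return The closed [binary_mask()].
#' @export
fill_lumens <- function(mask, radius_px) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.numeric(radius_px) || length(radius_px) != 1L || radius_px < 0 ||
      radius_px != floor(radius_px)) {
    stop_validation("radius_px must be a non-negative integer")
  }
  if (radius_px == 0) return(mask)
  # Dilation pads with airspace (only real walls grow); erosion pads with
  # wall (border walls are not shaved away). Border airspace is therefore
  # never spuriously closed and hole-free walls keep their thickness.
  closed <- erode_disk(dilate_disk(mask$phase, radius_px, pad_value = 0L),
                       radius_px, pad_value = 1L)
  binary_mask(closed, mask$pixel_size)
}

#' Build the equally spaced horizontal line grid
#'
#' `n_lines` horizontal test lines placed from the image's vertical
#' dimension with centred equal spacing: 0-based rows
#' `floor((i + 0.5) * height_px / n_lines)`, i = 0..n_lines-1, so no line
#' falls on the extreme border rows. Returned rows are 1-based (R indexing).
#'
#' @param height_px image height in pixels.
#' @param n_lines number of lines (default 20).
#' @return A `line_grid` list with fields `rows` (1-based, strictly
#'   increasing) and `n_lines`.
#' @export
make_line_grid <- function(height_px, n_lines = 20L) {
  height_px <- assert_count(height_px, "height_px", min = 1L)
  n_lines <- assert_count(n_lines, "n_lines", min = 1L)
  if (height_px < n_lines) {
    stop_validation("height_px (", height_px, ") must be >= n_lines (",
                    n_lines, ")")
  }
  rows0 <- floor((seq_len(n_lines) - 0.5) * height_px / n_lines)
  structure(list(rows = as.integer(rows0) + 1L, n_lines = n_lines),
            class = "line_grid")
}

#' Measure airspace and wall intercepts along a line grid
#'
#' Along each grid line, maximal runs of airspace pixels are chords. A chord
#' bounded by wall on both ends is complete (length = run length x pixel
#' size); chords touching the image border are truncated and excluded from
#' the sample by default (they bias the mean downward). Wall chords are
#' measured identically on the wall phase. `wall_intersections` counts
#' airspace-to-wall transitions over all lines.
#'
#' @param mask a [binary_mask()], convention `airspace0_wall1`.
#' @param grid a [make_line_grid()] result with rows inside the mask.
#' @param include_truncated include border-truncated airspace chords in the
#'   sample (default FALSE).
#' @return An `intercept_set` list: `airspace_chords`, `wall_chords` (um),
#'   `wall_intersections`, `n_truncated`, `per_line_counts`,
#'   `total_line_length` (um), `pixel_size`.
#' @export
measure_intercepts <- function(mask, grid, include_truncated = FALSE) {
  stopifnot(inherits(mask, "binary_mask"), inherits(grid, "line_grid"))
  if (grid$n_lines < 1L) stop_validation("empty line grid")
  if (any(grid$rows < 1L) || any(grid$rows > nrow(mask$phase))) {
    stop_validation("grid rows outside mask")
  }
  px <- mask$pixel_size
  air <- vector("list", grid$n_lines)
  wall <- vector("list", grid$n_lines)
  per_line <- integer(grid$n_lines)
  n_trunc <- 0L
  n_intersections <- 0L
  for (i in seq_len(grid$n_lines)) {
    v <- mask$phase[grid$rows[i], ]
    n_intersections <- n_intersections + sum(diff(v) == 1L)
    r <- rle(v)
    n <- length(r$lengths)
    is_air <- r$values == 0L
    border <- seq_len(n) %in% c(1L, n)
    complete_air <- is_air & !border
    trunc_air <- is_air & border
    n_trunc <- n_trunc + sum(trunc_air)
    keep <- if (include_truncated) is_air else complete_air
    air[[i]] <- r$lengths[keep] * px
    wall[[i]] <- r$lengths[!is_air & !border] * px
    per_line[i] <- sum(complete_air)
  }
  structure(list(airspace_chords = unlist(air),
                 wall_chords = unlist(wall),
                 wall_intersections = n_intersections,
                 n_truncated = n_trunc,
                 per_line_counts = per_line,
                 total_line_length = grid$n_lines * ncol(mask$phase) * px,
                 pixel_size = px),
            class = "intercept_set")
}

#' Compute MLI, AST and dispersion statistics from an intercept set
#'
#' The MLI is the arithmetic mean of the complete airspace chord lengths
#' (the mean of the intercept-length histogram); its SD is the sample
#' (n - 1) standard deviation. The dispersion index is, by default, the
#' variance-to-mean ratio of the chord lengths (in um); the coefficient of
#' variation is available as an alternative. AST statistics are the same
#' quantities on the wall-phase chords. The classic count-based estimator
#' (total test-line length / wall intersections) is reported alongside as
#' `mli_intersection` for cross-checking.
#'
#' @param intercepts an [measure_intercepts()] result with at least one
#'   complete airspace chord.
#' @param dispersion `"variance_over_mean"` (default) or `"cv"`.
#' @param image_id identifier carried into the result.
#' @return A `morphometry_result` list: `mli`, `mli_sd`, `dispersion_index`,
#'   `ast`, `ast_sd`, `n_chords`, `n_wall_chords`, `n_truncated`,
#'   `wall_intersections`, `mli_intersection`, `image_id`.
#' @export
compute_mli <- function(intercepts,
                        dispersion = c("variance_over_mean", "cv"),
                        image_id = NA_character_) {
  stopifnot(inherits(intercepts, "intercept_set"))
  dispersion <- match.arg(dispersion)
  ch <- intercepts$airspace_chords
  if (length(ch) == 0L) {
    stop_validation("no complete airspace chords: cannot compute MLI ",
                    "(image ", image_id, ")")
  }
  mli <- mean(ch)
  mli_sd <- if (length(ch) > 1L) sd(ch) else 0
  disp <- if (length(ch) > 1L) {
    if (dispersion == "variance_over_mean") var(ch) / mli else mli_sd / mli
  } else 0
  wc <- intercepts$wall_chords
  ast <- if (length(wc) > 0L) mean(wc) else NA_real_
  ast_sd <- if (length(wc) > 1L) sd(wc) else if (length(wc) == 1L) 0
            else NA_real_
  mli_int <- if (intercepts$wall_intersections > 0L) {
    intercepts$total_line_length / intercepts$wall_intersections
  } else NA_real_
  structure(list(mli = mli, mli_sd = mli_sd, dispersion_index = disp,
                 ast = ast, ast_sd = ast_sd,
                 n_chords = length(ch), n_wall_chords = length(wc),
                 n_truncated = intercepts$n_truncated,
                 wall_intersections = intercepts$wall_intersections,
                 mli_intersection = mli_int,
                 image_id = image_id),
            class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf(paste0("<morphometry_result> %s\n  MLI %.2f um (SD %.2f, ",
                     "dispersion %.3f, n = %d chords)\n  AST %.2f um (SD ",
                     "%.2f)\n"),
              ifelse(is.na(x$image_id), "<unnamed>", x$image_id),
              x$mli, x$mli_sd, x$dispersion_index, x$n_chords, x$ast,
              x$ast_sd))
  invisible(x)
}

#' @export
as.data.frame.morphometry_result <- function(x, ...) {
  data.frame(image_id = x$image_id, mli = x$mli, mli_sd = x$mli_sd,
             dispersion_index = x$dispersion_index, ast = x$ast,
             ast_sd = x$ast_sd, n_chords = x$n_chords,
             n_truncated = x$n_truncated,
             wall_intersections = x$wall_intersections,
             mli_intersection = x$mli_intersection,
             stringsAsFactors = FALSE)
}

#' Morphometry pipeline configuration
#'
#' @param pixel_size um/px (required).
#' @param n_lines test lines in the grid (default 20).
#' @param closing_radius disk radius (px) for lumen filling (default 3).
#' @param min_chord drop airspace chords shorter than this many um
#'   (default 0 = off).
#' @param keep_truncated include border-truncated chords (default FALSE).
#' @param dispersion `"variance_over_mean"` or `"cv"`.
#' @return A `morphometry_config` list.
#' @export
morphometry_config <- function(pixel_size, n_lines = 20L, closing_radius = 3L,
                               min_chord = 0,
                               keep_truncated = FALSE,
                               dispersion = c("variance_over_mean", "cv")) {
  assert_pos(pixel_size, "pixel_size")
  n_lines <- assert_count(n_lines, "n_lines", min = 1L)
  closing_radius <- assert_count(closing_radius, "closing_radius")
  if (!is.numeric(min_chord) || min_chord < 0) {
    stop_validation("min_chord must be >= 0")
  }
  structure(list(pixel_size = pixel_size, n_lines = n_lines,
                 closing_radius = closing_radius, min_chord = min_chord,
                 keep_truncated = isTRUE(keep_truncated),
                 dispersion = match.arg(dispersion)),
            class = "morphometry_config")
}

#' Run the full morphometry pipeline on an in-memory image
#'
#' Binarize (Otsu, bright phase = airspace), fill capillary lumens by
#' closing the wall phase, lay the horizontal line grid, measure intercepts
#' and compute MLI/AST statistics. The inversion step of the original
#' procedure (airspaces one class, walls the other) is realized by the
#' explicit `airspace0_wall1` mask convention.
#'
#' @param image a [gray_image()].
#' @param config a [morphometry_config()] (its `pixel_size` is ignored in
#'   favour of the image's own).
#' @param image_id identifier for the result row.
#' @param keep_intermediates return intermediate masks for audit.
#' @return A `morphometry_result` (see [compute_mli()]); with
#'   `keep_intermediates = TRUE`, a list
#'   `(result, threshold, raw_mask, filled_mask, grid, intercepts)`.
#' @export
analyze_gray_image <- function(image, config, image_id = NA_character_,
                               keep_intermediates = FALSE) {
  stopifnot(inherits(image, "gray_image"),
            inherits(config, "morphometry_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_validation("morphometry stage '", name, "' failed: ",
                      conditionMessage(e))
    })
  }
  bin <- stage("binarize", binarize_otsu(image))
  filled <- stage("fill_lumens", fill_lumens(bin$mask, config$closing_radius))
  grid <- stage("line_grid",
                make_line_grid(nrow(image$intensities), config$n_lines))
  ints <- stage("intercepts",
                measure_intercepts(filled, grid,
                                   include_truncated = config$keep_truncated))
  if (config$min_chord > 0) {
    ints$airspace_chords <-
      ints$airspace_chords[ints$airspace_chords >= config$min_chord]
  }
  res <- stage("statistics",
               compute_mli(ints, dispersion = config$dispersion,
                           image_id = image_id))
  res$threshold <- bin$threshold
  if (!keep_intermediates) return(res)
  list(result = res, threshold = bin$threshold, raw_mask = bin$mask,
       filled_mask = filled, grid = grid, intercepts = ints)
}

#' Run the full morphometry pipeline on an image file
#'
#' @param path image path (PNG/JPEG/ASCII-PGM; see [load_grayscale()]).
#' @param config a [morphometry_config()] supplying `pixel_size` and the
#'   pipeline parameters.
#' @param image_id identifier; defaults to the file name.
#' @inheritParams analyze_gray_image
#' @return See [analyze_gray_image()].
#' @export
analyze_image <- function(path, config, image_id = basename(path),
                          keep_intermediates = FALSE) {
  img <- load_grayscale(path, config$pixel_size)
  analyze_gray_image(img, config, image_id = image_id,
                     keep_intermediates = keep_intermediates)
}

#' Aggregate per-image morphometry to per-subject statistics
#'
#' Per-lung averaging of per-image values: each subject's MLI/AST are the
#' mean and SD over its images.
#'
#' @param results a list of `morphometry_result` objects or a data frame
#'   with columns `image_id`, `mli`, `ast`.
#' @param subject_map data frame with columns `image_id`, `subject_id` and
#'   optionally `group`; every image must map to exactly one subject.
#' @return Data frame with one row per subject: `subject_id`, `group` (if
#'   supplied), `n_images`, `mli_mean`, `mli_sd`, `ast_mean`, `ast_sd`.
#' @export
aggregate_by_subject <- function(results, subject_map) {
  df <- if (is.data.frame(results)) results else {
    do.call(rbind, lapply(results, as.data.frame))
  }
  if (!all(c("image_id", "subject_id") %in% names(subject_map))) {
    stop_validation("subject_map needs columns image_id, subject_id")
  }
  if (anyDuplicated(subject_map$image_id)) {
    stop_validation("subject_map maps some image to multiple subjects: ",
                    paste(unique(subject_map$image_id[
                      duplicated(subject_map$image_id)]), collapse = ", "))
  }
  missing <- setdiff(df$image_id, subject_map$image_id)
  if (length(missing) > 0L) {
    stop_validation("images without subject mapping: ",
                    paste(missing, collapse = ", "))
  }
  df$subject_id <- subject_map$subject_id[match(df$image_id,
                                                subject_map$image_id)]
  has_group <- "group" %in% names(subject_map)
  if (has_group) {
    df$group <- subject_map$group[match(df$image_id, subject_map$image_id)]
  }
  sd0 <- function(x) if (length(x) > 1L) sd(x) else 0
  agg <- do.call(rbind, lapply(split(df, df$subject_id), function(d) {
    data.frame(subject_id = d$subject_id[1L],
               group = if (has_group) d$group[1L] else NA_character_,
               n_images = nrow(d),
               mli_mean = mean(d$mli), mli_sd = sd0(d$mli),
               ast_mean = mean(d$ast), ast_sd = sd0(d$ast),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  if (!has_group) agg$group <- NULL
  agg
}
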