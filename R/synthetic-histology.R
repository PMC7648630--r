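#' Specification of a square-lattice synthetic parenchyma
#'
#' A stand-in for lung parenchyma with perfectly known geometry: axis-aligned
#' square airspaces of side `airspace_side` separated by walls of uniform
#' thickness `wall_thickness`. Every horizontal chord through an airspace has
#' length exactly `airspace_side`, so the mean airspace chord (the MLI ground
#' truth) is analytic.
#'
#' @param airspace_side side of each square airspace, um.
#' @param wall_thickness wall thickness, um.
#' @param pixel_size raster pixel size, um/px. `airspace_side / pixel_size`
#'   must be >= 4 so airspaces are resolvable.
#' @param n_cells_x,n_cells_y number of airspaces along x and y.
#' @return A `lattice_spec` list.
#' @export
lattice_spec <- function(airspace_side, wall_thickness, pixel_size,
                         n_cells_x, n_cells_y) {
  assert_pos(airspace_side, "airspace_side")
  assert_pos(wall_thickness, "wall_thickness")
  assert_pos(pixel_size, "pixel_size")
  n_cells_x <- assert_count(n_cells_x, "n_cells_x", min = 1L)
  n_cells_y <- assert_count(n_cells_y, "n_cells_y", min = 1L)
  if (airspace_side / pixel_size < 4) {
    stop_validation("airspace_side/pixel_size must be >= 4 ",
                    "(airspace must span at least 4 px)")
  }
  structure(list(airspace_side = airspace_side,
                 wall_thickness = wall_thickness,
                 pixel_size = pixel_size,
                 n_cells_x = n_cells_x, n_cells_y = n_cells_y),
            class = "lattice_spec")
}

#' Specification of a Voronoi-tessellation synthetic parenchyma
#'
#' Airspaces are Voronoi cells of uniformly random seeds; walls are the
#' tessellation ridges dilated to `wall_thickness`. A point p belongs to the
#' wall iff `d2(p) - d1(p) <= wall_thickness` where d1, d2 are the distances
#' from p to its nearest and second-nearest seed. There is no closed form for
#' the chord-length distribution of this geometry, so ground truth is
#' obtained by brute-force horizontal-line sampling of the continuous
#' (pre-rasterization) geometry.
#'
#' @param n_seeds number of Voronoi seeds (>= 2).
#' @param field_width,field_height field extent, um.
#' @param wall_thickness um.
#' @param pixel_size um/px.
#' @param rng_seed integer seed; generation is a pure function of the spec.
#' @return A `voronoi_spec` list.
#' @export
voronoi_spec <- function(n_seeds, field_width, field_height, wall_thickness,
                         pixel_size, rng_seed) {
  n_seeds <- assert_count(n_seeds, "n_seeds", min = 2L)
  assert_pos(field_width, "field_width")
  assert_pos(field_height, "field_height")
  assert_pos(wall_thickness, "wall_thickness")
  assert_pos(pixel_size, "pixel_size")
  rng_seed <- assert_count(rng_seed, "rng_seed")
  structure(list(n_seeds = n_seeds, field_width = field_width,
                 field_height = field_height,
                 wall_thickness = wall_thickness, pixel_size = pixel_size,
                 rng_seed = rng_seed),
            class = "voronoi_spec")
}

#' Specification of brightfield rendering
#'
#' Brightfield polarity is fixed: stained tissue (walls) dark, airspace
#' bright, as in H&E sections, so `airspace_intensity > wall_intensity` is
#' required.
#'
#' @param airspace_intensity,wall_intensity mean 8-bit intensities (0-255).
#' @param noise_sd additive Gaussian noise SD in intensity units, >= 0.
#' @param rng_seed integer seed.
#' @return A `render_spec` list.
#' @export
render_spec <- function(airspace_intensity, wall_intensity, noise_sd = 0,
                        rng_seed = 0L) {
  for (v in list(airspace_intensity, wall_intensity)) {
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 255) {
      stop_validation("intensities must be scalars in [0, 255]")
    }
  }
  if (airspace_intensity <= wall_intensity) {
    stop_validation("brightfield convention requires airspace_intensity > ",
                    "wall_intensity (airspace bright, walls dark)")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop_validation("noise_sd must be >= 0")
  }
  rng_seed <- assert_count(rng_seed, "rng_seed")
  structure(list(airspace_intensity = airspace_intensity,
                 wall_intensity = wall_intensity,
                 noise_sd = noise_sd, rng_seed = rng_seed),
            class = "render_spec")
}

#' Chord-length ground truth of a synthetic geometry
#'
#' @param true_mean_airspace_chord mean horizontal airspace chord, um.
#' @param true_mean_wall_chord mean horizontal wall chord, um.
#' @param chord_sample airspace chord lengths (um) backing the mean; for
#'   `provenance = "analytic"` the mean must equal the closed form.
#' @param provenance `"analytic"` or `"brute_force_sampled"`.
#' @param wall_chord_sample optional wall chord sample, um.
#' @return A `ground_truth_geometry` list.
#' @export
ground_truth_geometry <- function(true_mean_airspace_chord,
                                  true_mean_wall_chord,
                                  chord_sample,
                                  provenance = c("analytic",
                                                 "brute_force_sampled"),
                                  wall_chord_sample = numeric()) {
  provenance <- match.arg(provenance)
  assert_pos(true_mean_airspace_chord, "true_mean_airspace_chord")
  assert_pos(true_mean_wall_chord, "true_mean_wall_chord")
  if (length(chord_sample) == 0L || any(chord_sample <= 0)) {
    stop_validation("chord_sample must be non-empty and positive")
  }
  if (provenance == "brute_force_sampled" &&
      abs(mean(chord_sample) - true_mean_airspace_chord) > 1e-9) {
    stop_validation("sampled ground truth must satisfy mean(chord_sample) ",
                    "== true_mean_airspace_chord")
  }
  structure(list(true_mean_airspace_chord = true_mean_airspace_chord,
                 true_mean_wall_chord = true_mean_wall_chord,
                 chord_sample = as.numeric(chord_sample),
                 wall_chord_sample = as.numeric(wall_chord_sample),
                 provenance = provenance),
            class = "ground_truth_geometry")
}

#' Generate a square-lattice parenchyma mask with analytic ground truth
#'
#' @param spec a [lattice_spec()].
#' @return List with `mask` (a [binary_mask()], airspace = 0, wall = 1) and
#'   `ground_truth` (a [ground_truth_geometry()], `provenance = "analytic"`,
#'   mean airspace chord = `airspace_side` exactly).
#' @examples
#' g <- generate_lattice(lattice_spec(50, 5, 1, 10, 10))
#' dim(g$mask$phase)  # 555 x 555
#' @export
generate_lattice <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  a_px <- as.integer(round(spec$airspace_side / spec$pixel_size))
  w_px <- as.integer(round(spec$wall_thickness / spec$pixel_size))
  if (a_px < 4L) stop_validation("airspace must span at least 4 px")
  if (w_px < 1L) stop_validation("wall must span at least 1 px")
  h <- spec$n_cells_y * a_px + (spec$n_cells_y + 1L) * w_px
  w <- spec$n_cells_x * a_px + (spec$n_cells_x + 1L) * w_px
  phase <- matrix(1L, h, w)
  for (i in seq_len(spec$n_cells_y)) {
    r0 <- w_px + (i - 1L) * (a_px + w_px)
    for (j in seq_len(spec$n_cells_x)) {
      c0 <- w_px + (j - 1L) * (a_px + w_px)
      phase[(r0 + 1L):(r0 + a_px), (c0 + 1L):(c0 + a_px)] <- 0L
    }
  }
  mask <- binary_mask(phase, spec$pixel_size)
  gt <- ground_truth_geometry(
    true_mean_airspace_chord = spec$airspace_side,
    true_mean_wall_chord = spec$wall_thickness,
    chord_sample = rep(spec$airspace_side, spec$n_cells_x * spec$n_cells_y),
    provenance = "analytic")
  list(mask = mask, ground_truth = gt, spec = spec)
}

# Distances to the nearest and second-nearest seed for arbitrary points,
# updated one seed at a time so memory stays O(n_points).
.nearest_two <- function(px, py, seeds) {
  d1 <- rep(Inf, length(px)); d2 <- d1
  for (k in seq_len(nrow(seeds))) {
    d <- (px - seeds[k, 1L])^2 + (py - seeds[k, 2L])^2
    d2 <- pmin(d2, pmax(d1, d))
    d1 <- pmin(d1, d)
  }
  list(d1 = sqrt(d1), d2 = sqrt(d2))
}

# Extract complete (wall-bounded) airspace and wall run lengths from a
# logical wall vector sampled along one horizontal line. Border runs are
# truncated and excluded.
.complete_runs <- function(wall_logical, step) {
  r <- rle(wall_logical)
  n <- length(r$lengths)
  if (n < 3L) return(list(air = numeric(), wall = numeric()))
  interior <- seq_len(n)[-c(1L, n)]
  list(air = r$lengths[interior][!r$values[interior]] * step,
       wall = r$lengths[interior][r$values[interior]] * step)
}

#' Generate a Voronoi parenchyma mask with brute-force sampled ground truth
#'
#' The continuous geometry (see [voronoi_spec()]) is rasterized at pixel
#' centres; ground truth is obtained from the same continuous geometry by
#' horizontal-line sampling at `gt_line_factor` times the analysis line
#' density (default 10 x 20 lines) and a sub-pixel marching step, so the
#' oracle never sees the raster.
#'
#' @param spec a [voronoi_spec()].
#' @param n_analysis_lines line count of the downstream analysis grid
#'   (default 20).
#' @param gt_line_factor ground-truth line density multiplier (>= 10).
#' @return List with `mask`, `ground_truth`
#'   (`provenance = "brute_force_sampled"`) and `seeds` (n x 2 matrix, um).
#' @export
generate_voronoi <- function(spec, n_analysis_lines = 20L,
                             gt_line_factor = 10L) {
  stopifnot(inherits(spec, "voronoi_spec"))
  gt_line_factor <- assert_count(gt_line_factor, "gt_line_factor", min = 10L)
  seeds <- with_rng_seed(spec$rng_seed, {
    s <- cbind(runif(spec$n_seeds) * spec$field_width,
               runif(spec$n_seeds) * spec$field_height)
    # Degenerate (coincident) seeds make the ridge set ill-defined;
    # regenerate by perturbation and report it.
    for (tries in 1:10) {
      dmin <- min(dist(s))
      if (dmin > 1e-6) break
      message("degenerate Voronoi seeds (min distance ", format(dmin),
              "); perturbing")
      s <- s + matrix(rnorm(length(s), sd = spec$pixel_size), ncol = 2L)
      s[, 1L] <- pmin(pmax(s[, 1L], 0), spec$field_width)
      s[, 2L] <- pmin(pmax(s[, 2L], 0), spec$field_height)
    }
    s
  })

  h <- as.integer(round(spec$field_height / spec$pixel_size))
  w <- as.integer(round(spec$field_width / spec$pixel_size))
  cx <- (seq_len(w) - 0.5) * spec$pixel_size
  cy <- (seq_len(h) - 0.5) * spec$pixel_size
  px <- rep(cx, each = h)
  py <- rep(cy, times = w)
  nd <- .nearest_two(px, py, seeds)
  wall <- matrix((nd$d2 - nd$d1) <= spec$wall_thickness, h, w)
  mask <- binary_mask(wall + 0L, spec$pixel_size)

  n_gt <- n_analysis_lines * gt_line_factor
  step <- spec$pixel_size / 4
  xs <- seq(step / 2, spec$field_width - step / 2, by = step)
  ys <- ((seq_len(n_gt) - 0.5) / n_gt) * spec$field_height
  gx <- rep(xs, times = n_gt)
  gy <- rep(ys, each = length(xs))
  gd <- .nearest_two(gx, gy, seeds)
  gwall <- (gd$d2 - gd$d1) <= spec$wall_thickness
  air <- vector("list", n_gt); wal <- vector("list", n_gt)
  for (i in seq_len(n_gt)) {
    idx <- ((i - 1L) * length(xs) + 1L):(i * length(xs))
    runs <- .complete_runs(gwall[idx], step)
    air[[i]] <- runs$air; wal[[i]] <- runs$wall
  }
  chords <- unlist(air); wchords <- unlist(wal)
  if (length(chords) == 0L) {
    stop_validation("ground-truth sampling produced no complete chords; ",
                    "field too small for the requested tessellation")
  }
  gt <- ground_truth_geometry(
    true_mean_airspace_chord = mean(chords),
    true_mean_wall_chord = mean(wchords),
    chord_sample = chords,
    provenance = "brute_force_sampled",
    wall_chord_sample = wchords)
  list(mask = mask, ground_truth = gt, spec = spec, seeds = seeds)
}

#' Punch capillary-like lumens into the walls of a mask
#'
#' Emulates the capillary lumens that the morphometry pipeline must remove by
#' morphological closing. Hole centres are drawn only from wall pixels whose
#' distance to the airspace phase exceeds `hole_radius_px`, so every hole is
#' strictly interior to a wall and the correct post-filling geometry is the
#' input mask itself.
#'
#' @param mask a [binary_mask()] (airspace = 0, wall = 1).
#' @param n_holes number of holes requested.
#' @param hole_radius_px hole radius in pixels (disk of offsets with
#'   `dy^2 + dx^2 <= r^2`).
#' @param rng_seed integer seed.
#' @return The punched [binary_mask()]; attribute `n_placed` records how many
#'   holes were actually placed (fewer than requested if interior wall pixels
#'   run out, with a warning).
#' @export
punch_lumens <- function(mask, n_holes, hole_radius_px, rng_seed) {
  stopifnot(inherits(mask, "binary_mask"))
  n_holes <- assert_count(n_holes, "n_holes")
  hole_radius_px <- assert_count(hole_radius_px, "hole_radius_px")
  rng_seed <- assert_count(rng_seed, "rng_seed")
  if (n_holes == 0L) {
    out <- mask
    attr(out, "n_placed") <- 0L
    return(out)
  }
  # Pixels at distance > r from airspace: erosion of the wall phase by a
  # disk of radius r, with the outside of the image counting as airspace.
  eligible <- erode_disk(mask$phase, hole_radius_px, pad_value = 0L)
  cand <- which(eligible == 1L)
  n_place <- min(n_holes, length(cand))
  if (n_place < n_holes) {
    warning(sprintf("only %d of %d holes placed: insufficient interior wall",
                    n_place, n_holes))
  }
  phase <- mask$phase
  if (n_place > 0L) {
    centers <- with_rng_seed(rng_seed,
                             cand[sample.int(length(cand), n_place)])
    off <- disk_offsets(hole_radius_px)
    h <- nrow(phase)
    rows <- ((centers - 1L) %% h) + 1L
    cols <- ((centers - 1L) %/% h) + 1L
    for (k in seq_len(nrow(off))) {
      phase[cbind(rows + off$dy[k], cols + off$dx[k])] <- 0L
    }
  }
  out <- binary_mask(phase, mask$pixel_size)
  attr(out, "n_placed") <- n_place
  out
}

#' Render a phase mask as an 8-bit brightfield grayscale image
#'
#' Airspace pixels are drawn Normal(`airspace_intensity`, `noise_sd`), wall
#' pixels Normal(`wall_intensity`, `noise_sd`), clipped to \[0, 255\] and
#' quantized to 8 bits with round-half-up. Geometry is untouched.
#'
#' @param mask a [binary_mask()].
#' @param spec a [render_spec()].
#' @return A [gray_image()] with the mask's pixel size.
#' @export
render_grayscale <- function(mask, spec) {
  stopifnot(inherits(mask, "binary_mask"), inherits(spec, "render_spec"))
  base <- ifelse(mask$phase == 0L, spec$airspace_intensity,
                 spec$wall_intensity)
  vals <- if (spec$noise_sd > 0) {
    with_rng_seed(spec$rng_seed,
                  base + rnorm(length(base), sd = spec$noise_sd))
  } else base
  vals <- round_half_up(pmin(pmax(vals, 0), 255))
  gray_image(matrix(as.integer(vals), nrow(mask$phase), ncol(mask$phase)),
             pixel_size = mask$pixel_size)
}

#' Write a synthetic fixture to disk
#'
#' Writes the rendered image as 8-bit grayscale PNG, the ground-truth chord
#' sample as CSV (one chord per row) and a JSON sidecar holding the
#' generating spec, seed and true means.
#'
#' @param image a [gray_image()].
#' @param ground_truth a [ground_truth_geometry()].
#' @param dir output directory (created if missing).
#' @param spec the generating spec list (serialized into the sidecar).
#' @param name fixture base name.
#' @return Invisibly, the paths written (named list).
#' @export
write_synthetic_fixture <- function(image, ground_truth, dir, spec = NULL,
                                    name = "fixture") {
  stopifnot(inherits(image, "gray_image"),
            inherits(ground_truth, "ground_truth_geometry"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, ".png"))
  png::writePNG(image$intensities / 255, img_path)
  csv_path <- file.path(dir, paste0(name, "_chords.csv"))
  write.csv(data.frame(chord_um = ground_truth$chord_sample), csv_path,
            row.names = FALSE)
  json_path <- file.path(dir, paste0(name, ".json"))
  sidecar <- list(
    spec = if (is.null(spec)) NULL else unclass(spec),
    pixel_size = image$pixel_size,
    true_mean_airspace_chord = ground_truth$true_mean_airspace_chord,
    true_mean_wall_chord = ground_truth$true_mean_wall_chord,
    provenance = ground_truth$provenance)
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(image = img_path, chords = csv_path, sidecar = json_path))
}
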