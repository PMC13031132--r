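# Synthetic zonated tissue scenes: two vein lumens, exponential marker
# gradients, and a field of non-overlapping polygonal "cells". These emulate
# the four-channel immunofluorescence input of the mapping workflow
# (pericentral marker, periportal marker, cell-boundary stain, nuclei) with
# fully known ground truth, so vein detection, trajectory building and cell
# selection can be tested without microscope data.

#' Specify a synthetic tissue scene
#'
#' Coordinates are in pixels, origin at the top-left corner, x to the right
#' (columns) and y down (rows); the pixel in matrix row r, column c has centre
#' (x = c, y = r).
#'
#' @param image_shape integer (H, W) image size in pixels.
#' @param vein_central,vein_portal lists with `center = c(x, y)` and `radius`
#'   (pixels) describing the two vein lumens.
#' @param cell_grid_pitch spacing of the cell seed grid in pixels.
#' @param cell_jitter maximal per-axis displacement of a seed from its grid
#'   node (pixels); must be below `cell_grid_pitch / 4` so cells cannot
#'   overlap.
#' @param marker_decay_length exponential decay constant (pixels) of the two
#'   vein-marker channels.
#' @param noise_sd s.d. of additive Gaussian pixel noise (intensity units on a
#'   [0, 1] scale).
#' @param seed integer; fully determines the generated scene.
#' @return an object of class `tissue_spec`.
#' @export
tissue_spec <- function(image_shape = c(256L, 512L),
                        vein_central = list(center = c(56, 128), radius = 24),
                        vein_portal = list(center = c(456, 128), radius = 24),
                        cell_grid_pitch = 16,
                        cell_jitter = 3,
                        marker_decay_length = 60,
                        noise_sd = 0.02,
                        seed = 1L) {
  if (length(image_shape) != 2L || any(image_shape < 32))
    zn_stop("image_shape must be (H, W) with both >= 32 px")
  for (v in list(vein_central, vein_portal)) {
    if (!is.list(v) || length(v$center) != 2L || !is.numeric(v$radius) ||
        v$radius <= 0)
      zn_stop("veins need center = c(x, y) and a positive radius")
  }
  gap <- euclid(vein_central$center, vein_portal$center)
  if (gap <= vein_central$radius + vein_portal$radius)
    zn_stop("vein lumens overlap: move anchors apart or shrink radii")
  if (cell_jitter >= cell_grid_pitch / 4)
    zn_stop("cell_jitter must be < cell_grid_pitch / 4 to keep cells disjoint")
  structure(list(image_shape = as.integer(image_shape),
                 vein_central = vein_central, vein_portal = vein_portal,
                 cell_grid_pitch = cell_grid_pitch, cell_jitter = cell_jitter,
                 marker_decay_length = marker_decay_length,
                 noise_sd = noise_sd, seed = seed),
            class = "tissue_spec")
}

#' A segmented cell contour
#'
#' @param id character id.
#' @param vertices n x 2 numeric matrix (x, y) in pixels, >= 3 rows, implicit
#'   closure (last vertex is not repeated).
#' @return object of class `cell_contour` with centroid and area computed by
#'   polygon moments.
#' @export
cell_contour <- function(id, vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) zn_stop("a contour needs at least 3 vertices")
  area <- polygon_area(vertices)
  if (area <= 0) zn_stop("degenerate contour: zero area")
  structure(list(id = as.character(id), vertices = unname(vertices),
                 centroid = polygon_centroid(vertices), area = area),
            class = "cell_contour")
}

#' @export
print.cell_contour <- function(x, ...) {
  cat(sprintf("<cell_contour %s: %d vertices, area %.1f px^2, centroid (%.1f, %.1f)>\n",
              x$id, nrow(x$vertices), x$area, x$centroid[1], x$centroid[2]))
  invisible(x)
}

dist_field <- function(shape, center) {
  H <- shape[1]; W <- shape[2]
  dx <- matrix(rep(seq_len(W), each = H), H, W) - center[1]
  dy <- matrix(rep(seq_len(H), W), H, W) - center[2]
  sqrt(dx^2 + dy^2)
}

#' Generate a synthetic zonated tissue scene
#'
#' Produces four single-channel images and a set of polygonal cell contours.
#' The pericentral-marker channel decays exponentially with distance from the
#' central-vein anchor and the periportal channel with distance from the
#' portal anchor (emulating GS / ASS1 staining); the boundary channel is
#' uniformly bright except inside the two vein lumens, where it is exactly
#' zero (veins carry no cells); the nuclei channel holds a small disc at every
#' cell centroid. Cells are star-convex radial-jitter polygons around jittered
#' grid seeds; the maximal polygon radius is below half the minimal seed
#' distance, so cells never overlap, and seeds falling inside or within one
#' polygon radius of a lumen are dropped.
#'
#' @param spec a [tissue_spec()].
#' @return list with `channels` (named list of H x W matrices: pericentral,
#'   periportal, boundary, nuclei), `contours` (list of [cell_contour()]) and
#'   `anchors` (list with `central` and `portal` (x, y) points).
#' @export
generate_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  with_rng(spec$seed, {
    H <- spec$image_shape[1]; W <- spec$image_shape[2]
    dc <- dist_field(spec$image_shape, spec$vein_central$center)
    dp <- dist_field(spec$image_shape, spec$vein_portal$center)
    noise <- function() matrix(abs(stats::rnorm(H * W, 0, spec$noise_sd)), H, W)

    pericentral <- exp(-dc / spec$marker_decay_length) + noise()
    periportal <- exp(-dp / spec$marker_decay_length) + noise()
    boundary <- 0.8 + noise()
    lumen <- dc <= spec$vein_central$radius | dp <= spec$vein_portal$radius
    boundary[lumen] <- 0

    # cell seeds: jittered grid clear of the borders and the lumens
    pitch <- spec$cell_grid_pitch
    r_max <- 0.5 * (pitch - 2 * spec$cell_jitter) * 0.96
    gx <- seq(pitch, W - pitch, by = pitch)
    gy <- seq(pitch, H - pitch, by = pitch)
    seeds <- expand.grid(x = gx, y = gy)
    seeds$x <- seeds$x + stats::runif(nrow(seeds), -spec$cell_jitter, spec$cell_jitter)
    seeds$y <- seeds$y + stats::runif(nrow(seeds), -spec$cell_jitter, spec$cell_jitter)
    d_c <- sqrt((seeds$x - spec$vein_central$center[1])^2 +
                  (seeds$y - spec$vein_central$center[2])^2)
    d_p <- sqrt((seeds$x - spec$vein_portal$center[1])^2 +
                  (seeds$y - spec$vein_portal$center[2])^2)
    keep <- d_c > spec$vein_central$radius + r_max &
      d_p > spec$vein_portal$radius + r_max
    seeds <- seeds[keep, , drop = FALSE]

    nv <- 12L
    contours <- vector("list", nrow(seeds))
    for (i in seq_len(nrow(seeds))) {
      ang <- 2 * pi * (seq_len(nv) - 1) / nv +
        stats::runif(nv, -0.12, 0.12) * 2 * pi / nv
      rad <- r_max * stats::runif(nv, 0.62, 0.98)
      contours[[i]] <- cell_contour(
        sprintf("cell_%04d", i),
        cbind(seeds$x[i] + rad * cos(ang), seeds$y[i] + rad * sin(ang)))
    }

    nuclei <- noise() * 0.2
    for (ct in contours) {
      dn <- (row(nuclei) - ct$centroid[2])^2 + (col(nuclei) - ct$centroid[1])^2
      nuclei[dn <= 2.5^2] <- 1
    }

    list(channels = list(pericentral = pericentral, periportal = periportal,
                         boundary = boundary, nuclei = nuclei),
         contours = contours,
         anchors = list(central = spec$vein_central$center,
                        portal = spec$vein_portal$center))
  })
}

#' Write tissue channels as single-channel TIFF files
#'
#' Intensities are clipped to [0, 1] before writing (32-bit float TIFF).
#'
#' @param tissue result of [generate_tissue()].
#' @param dir output directory; files are named `<channel>.tif`.
#' @return invisibly, the written paths.
#' @export
write_tissue_channels <- function(tissue, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(tissue$channels), function(ch) {
    img <- pmin(pmax(tissue$channels[[ch]], 0), 1)
    p <- file.path(dir, paste0(ch, ".tif"))
    tiff::writeTIFF(img, p, bits.per.sample = 32L)
    p
  }, character(1))
  invisible(paths)
}

#' Read a single-channel TIFF as an H x W matrix
#' @param path file path.
#' @export
read_channel <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Write / read cell contours as a plain CSV of vertices
#'
#' Long format with columns `cell_id, vertex, x, y`.
#' @param contours list of [cell_contour()].
#' @param path CSV path.
#' @export
write_contours_csv <- function(contours, path) {
  df <- data.table::rbindlist(lapply(contours, function(ct) {
    data.table::data.table(cell_id = ct$id, vertex = seq_len(nrow(ct$vertices)),
                           x = ct$vertices[, 1], y = ct$vertices[, 2])
  }))
  data.table::fwrite(df, path, sep = ",")
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  df <- data.table::fread(path)
  need <- c("cell_id", "vertex", "x", "y")
  if (!all(need %in% names(df)))
    zn_stop(paste("contour CSV must have columns", paste(need, collapse = ", ")))
  ids <- unique(df$cell_id)
  lapply(ids, function(id) {
    sub <- df[df$cell_id == id, ]
    sub <- sub[order(sub$vertex), ]
    cell_contour(id, cbind(sub$x, sub$y))
  })
}
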