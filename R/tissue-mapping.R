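# Vein detection and classification, trajectory ROIs, strategic cell
# selection by farthest-first traversal, and spatial-ratio assignment.

#' Minimum-valley histogram threshold
#'
#' Finds the threshold at the valley between the two modes of a bimodal
#' intensity histogram: the histogram is smoothed with a width-3 moving
#' average until exactly two local maxima remain, and the threshold is the
#' minimum between them.
#'
#' @param x numeric vector or matrix of intensities.
#' @param nbins number of histogram bins.
#' @return threshold value (intensity units).
#' @export
threshold_minimum <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= 0)
    zn_stop("no histogram valley: image is constant", class = "zn_numeric_error")
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = nbins + 1L),
                      plot = FALSE)
  counts <- as.numeric(h$counts)
  n_max <- function(y) {
    n <- length(y)
    sum(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n])
  }
  for (i in seq_len(10000L)) {
    if (n_max(counts) <= 2L) break
    counts <- stats::filter(c(counts[1], counts, counts[length(counts)]),
                            rep(1 / 3, 3))[2:(length(counts) + 1L)]
    counts <- as.numeric(counts)
  }
  if (n_max(counts) != 2L)
    zn_stop("no histogram valley: intensity distribution is not bimodal",
            class = "zn_numeric_error")
  n <- length(counts)
  inner <- 2:(n - 1)
  peaks <- inner[counts[inner] > counts[inner - 1] & counts[inner] >= counts[inner + 1]]
  between <- (peaks[1] + 1):(peaks[2] - 1)
  valley <- between[which.min(counts[between])]
  # sanity check on the raw histogram: a true inter-mode valley is nearly
  # empty next to the dominant mode; a ripple inside a single mode is not
  nb <- max(1L, valley - 2L):min(length(h$counts), valley + 2L)
  if (mean(h$counts[nb]) > 0.05 * max(h$counts))
    zn_stop("no histogram valley: intensity distribution is not bimodal",
            class = "zn_numeric_error")
  h$mids[valley]
}

as_ebimage <- function(mat) EBImage::Image(t(mat))

#' Detect vein lumens as signal voids in the cell-boundary channel
#'
#' Veins carry no cells, so their lumens appear as connected low-intensity
#' regions in the boundary (e.g. phalloidin) channel. The image is Gaussian
#' blurred and grayscale-dilated (removing small voids), thresholded at the
#' histogram minimum, and connected components of the below-threshold region
#' are returned, filtered by area.
#'
#' @param boundary H x W matrix, the cell-boundary channel.
#' @param min_vein_area minimal region area in px^2 after dilation.
#' @param blur_sigma Gaussian blur s.d. in pixels.
#' @param dilation_radius radius of the disc structuring element in pixels.
#' @return list of candidate regions, each with `mask` (H x W logical),
#'   `centroid` (x, y) and `area` (px^2); empty if the histogram is unimodal
#'   (no voids). A constant image raises a no-threshold error.
#' @export
detect_veins <- function(boundary, min_vein_area = 50, blur_sigma = 5,
                         dilation_radius = 10) {
  if (length(dim(boundary)) != 2L) zn_stop("boundary must be a 2-D image matrix")
  img <- as_ebimage(boundary)
  img <- EBImage::gblur(img, sigma = blur_sigma)
  brush <- EBImage::makeBrush(2L * as.integer(dilation_radius) + 1L, shape = "disc")
  img <- EBImage::dilate(img, brush)
  th <- tryCatch(threshold_minimum(EBImage::imageData(img)),
                 zn_numeric_error = function(e) {
                   if (grepl("constant", conditionMessage(e))) stop(e)
                   NULL
                 })
  if (is.null(th)) return(list())
  mask <- img < th
  labels <- EBImage::bwlabel(mask)
  lab <- t(EBImage::imageData(labels))  # back to row = y orientation
  out <- list()
  for (l in seq_len(max(lab))) {
    m <- lab == l
    area <- sum(m)
    if (area < min_vein_area) next
    idx <- which(m, arr.ind = TRUE)
    out[[length(out) + 1L]] <- list(mask = m,
                                    centroid = c(mean(idx[, 2]), mean(idx[, 1])),
                                    area = area)
  }
  out
}

#' Classify vein regions as central or portal by marker expression
#'
#' Each marker channel is standardized image-wide, and the mean standardized
#' intensity of each channel is compared in an annulus around the region
#' (pixels within `annulus_width` of the region but outside it; clipped at
#' the image border). Higher pericentral-marker (e.g. GS) score gives type
#' "central", higher periportal-marker (e.g. ASS1) score gives "portal".
#'
#' @param regions list of regions from [detect_veins()].
#' @param pericentral,periportal marker channel matrices.
#' @param annulus_width annulus thickness in pixels.
#' @return list of veins: `mask`, `anchor` (x, y), `area`, `type`,
#'   `marker_score_central`, `marker_score_portal`.
#' @export
classify_veins <- function(regions, pericentral, periportal, annulus_width = 15) {
  zc <- (pericentral - mean(pericentral)) / stats::sd(pericentral)
  zp <- (periportal - mean(periportal)) / stats::sd(periportal)
  brush <- EBImage::makeBrush(2L * as.integer(annulus_width) + 1L, shape = "disc")
  lapply(seq_along(regions), function(i) {
    r <- regions[[i]]
    dil <- t(EBImage::imageData(EBImage::dilate(as_ebimage(r$mask * 1), brush))) > 0.5
    ann <- dil & !r$mask
    sc <- mean(zc[ann]); sp <- mean(zp[ann])
    if (isTRUE(all.equal(sc, sp)))
      zn_stop(sprintf("ambiguous vein %d: equal marker scores after standardization", i))
    list(mask = r$mask, anchor = r$centroid, area = r$area,
         type = if (sc > sp) "central" else "portal",
         marker_score_central = sc, marker_score_portal = sp)
  })
}

#' Pair central and portal veins into trajectories
#'
#' Greedy nearest-anchor matching: repeatedly take the globally closest
#' (central, portal) pair among unused veins. Pairs are returned sorted by
#' axis length (anchor distance), shortest first.
#'
#' @param veins list of classified veins from [classify_veins()] (or
#'   [point_vein()]s).
#' @return list of `list(central = , portal = )` pairs; empty if either type
#'   is absent.
#' @export
pair_trajectories <- function(veins) {
  types <- vapply(veins, `[[`, character(1), "type")
  cen <- which(types == "central"); por <- which(types == "portal")
  if (!length(cen) || !length(por)) return(list())
  D <- outer(cen, por, Vectorize(function(i, j)
    euclid(veins[[i]]$anchor, veins[[j]]$anchor)))
  pairs <- list()
  used_c <- logical(length(cen)); used_p <- logical(length(por))
  repeat {
    D2 <- D; D2[used_c, ] <- Inf; D2[, used_p] <- Inf
    if (all(!is.finite(D2))) break
    ij <- which(D2 == min(D2), arr.ind = TRUE)[1, ]
    used_c[ij[1]] <- TRUE; used_p[ij[2]] <- TRUE
    pairs[[length(pairs) + 1L]] <- list(central = veins[[cen[ij[1]]]],
                                        portal = veins[[por[ij[2]]]])
  }
  len <- vapply(pairs, function(p) euclid(p$central$anchor, p$portal$anchor),
                numeric(1))
  pairs[order(len)]
}

#' Construct a degenerate point vein from a manual anchor
#' @param point (x, y) anchor in pixels.
#' @param type "central" or "portal".
#' @export
point_vein <- function(point, type = c("central", "portal")) {
  type <- match.arg(type)
  list(mask = NULL, anchor = as.numeric(point), area = 0, type = type,
       marker_score_central = NA_real_, marker_score_portal = NA_real_)
}

#' Build a trajectory region of interest between a vein pair
#'
#' Keeps the cells lying between the two veins: the centroid must project
#' onto the open segment between the anchors, its angular deviation from the
#' axis -- the angle at the nearer anchor between the axis direction and the
#' anchor-to-centroid vector -- must not exceed `cone_half_angle`, and
#' centroids inside a vein mask are excluded.
#'
#' @param pair `list(central = , portal = )` as from [pair_trajectories()].
#' @param contours list of [cell_contour()].
#' @param cone_half_angle half-angle of the two-sided cone in degrees
#'   (default 65).
#' @return object of class `trajectory`: the pair, the axis length, the cone
#'   angle and `roi_cells`.
#' @export
build_trajectory_roi <- function(pair, contours, cone_half_angle = 65) {
  A <- pair$central$anchor; B <- pair$portal$anchor
  if (isTRUE(all.equal(A, B))) zn_stop("trajectory anchors must be distinct")
  ab <- B - A; len2 <- sum(ab^2)
  in_mask <- function(mask, p) {
    if (is.null(mask)) return(FALSE)
    r <- round(p[2]); c <- round(p[1])
    r >= 1 && c >= 1 && r <= nrow(mask) && c <= ncol(mask) && mask[r, c]
  }
  keep <- vapply(contours, function(ct) {
    p <- ct$centroid
    t <- sum((p - A) * ab) / len2
    if (t <= 0 || t >= 1) return(FALSE)
    if (t <= 0.5) { v <- p - A; axis <- ab } else { v <- p - B; axis <- -ab }
    ang <- acos(pmin(1, pmax(-1, sum(v * axis) / (sqrt(sum(v^2)) * sqrt(len2)))))
    if (ang * 180 / pi > cone_half_angle) return(FALSE)
    !in_mask(pair$central$mask, p) && !in_mask(pair$portal$mask, p)
  }, logical(1))
  if (!any(keep))
    zn_stop("empty trajectory: no cell centroid falls inside the cone ROI")
  structure(list(central = pair$central, portal = pair$portal,
                 axis_length = sqrt(len2), cone_half_angle = cone_half_angle,
                 roi_cells = contours[keep]),
            class = "trajectory")
}

#' Build a trajectory from two manually chosen anchor points
#'
#' The manual mode of trajectory definition: point A marks the central vein
#' and point B the portal vein (useful when marker staining fails, e.g. in
#' diseased tissue). Behaves exactly like the automatic mode with degenerate
#' point veins; anchors may lie outside the image bounds (the construction is
#' purely geometric).
#'
#' @param point_a central-vein anchor (x, y).
#' @param point_b portal-vein anchor (x, y).
#' @param contours list of [cell_contour()].
#' @param cone_half_angle cone half-angle in degrees.
#' @export
manual_trajectory <- function(point_a, point_b, contours, cone_half_angle = 65) {
  if (isTRUE(all.equal(as.numeric(point_a), as.numeric(point_b))))
    zn_stop("manual anchors A and B must differ")
  build_trajectory_roi(list(central = point_vein(point_a, "central"),
                            portal = point_vein(point_b, "portal")),
                       contours, cone_half_angle)
}

#' Strategic cell selection by farthest-first traversal
#'
#' Solves the max-min dispersion (remote-edge diversity maximization) problem
#' greedily: the selection is initialized with the exact diameter pair (the
#' two centroids at maximal distance, ties broken by lowest cell id) and each
#' subsequent pick maximizes its minimum centroid distance to the already
#' selected set. The greedy solution is a 2-approximation of the optimal
#' minimum pairwise distance. Cells spread this way cover the trajectory
#' between the veins approximately uniformly.
#'
#' @param roi_cells list of [cell_contour()] (pairwise non-overlapping).
#' @param k number of cells to select (default 44); if fewer cells are
#'   available all are returned.
#' @return list of selected [cell_contour()]s in selection order.
#' @export
select_cells_fft <- function(roi_cells, k = 44L) {
  if (k < 2) zn_stop("k must be >= 2")
  n <- length(roi_cells)
  if (n <= k) return(roi_cells)
  ids <- vapply(roi_cells, `[[`, character(1), "id")
  pts <- t(vapply(roi_cells, `[[`, numeric(2), "centroid"))
  D <- as.matrix(stats::dist(pts))
  # exact diameter pair, ties by lowest (id, id) lexicographically
  dmax <- max(D)
  cand <- which(D == dmax & upper.tri(D), arr.ind = TRUE)
  ord <- order(pmin(ids[cand[, 1]], ids[cand[, 2]]),
               pmax(ids[cand[, 1]], ids[cand[, 2]]))
  first <- sort(c(cand[ord[1], 1], cand[ord[1], 2]))
  sel <- first[order(ids[first])]
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < k) {
    mind[sel] <- -Inf
    best <- which(mind == max(mind))
    nxt <- best[order(ids[best])][1]
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  roi_cells[sel]
}

#' Spatial ratio of a cell along the porto-central axis
#'
#' Computes the Euclidean distances from the cell centroid to the central and
#' portal anchors and the normalized position
#' S = d_central / (d_central + d_portal), so that S = 0 at the central vein
#' and S = 1 at the portal vein. Set `orientation = "portal0"` for the
#' flipped convention S = d_portal / (d_central + d_portal).
#'
#' @param centroid cell centroid (x, y).
#' @param central,portal anchor points (x, y); must be distinct.
#' @param orientation which vein maps to S = 0.
#' @return list with `d_central`, `d_portal`, `S`.
#' @export
compute_spatial_ratio <- function(centroid, central, portal,
                                  orientation = c("central0", "portal0")) {
  orientation <- match.arg(orientation)
  central <- as.numeric(central); portal <- as.numeric(portal)
  if (isTRUE(all.equal(central, portal))) zn_stop("anchors must be distinct")
  dc <- euclid(centroid, central); dp <- euclid(centroid, portal)
  S <- if (orientation == "central0") dc / (dc + dp) else dp / (dc + dp)
  list(d_central = dc, d_portal = dp, S = S)
}

#' Select cells along a trajectory and tabulate their spatial metadata
#'
#' Composes [select_cells_fft()] and [compute_spatial_ratio()] over a
#' [build_trajectory_roi()] result.
#'
#' @param trajectory a `trajectory` object.
#' @param k number of cells to select.
#' @param patient_id label copied into every row.
#' @param orientation passed to [compute_spatial_ratio()].
#' @return data.frame with cell_id, patient_id, d_central, d_portal, S,
#'   area_px2, centroid_x, centroid_y, in selection order.
#' @export
spatial_cell_table <- function(trajectory, k = 44L, patient_id = "P01",
                               orientation = "central0") {
  sel <- select_cells_fft(trajectory$roi_cells, k = k)
  rows <- lapply(sel, function(ct) {
    r <- compute_spatial_ratio(ct$centroid, trajectory$central$anchor,
                               trajectory$portal$anchor, orientation)
    data.frame(cell_id = ct$id, patient_id = patient_id,
               d_central = r$d_central, d_portal = r$d_portal, S = r$S,
               area_px2 = ct$area, centroid_x = ct$centroid[1],
               centroid_y = ct$centroid[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simplify a cutting contour
#'
#' Reduces the vertex count to at most `max(3, ceiling(target_fraction * n))`
#' (i.e. removes at least 90% of the points at the default), as required for
#' efficient laser-microdissection cutting. Vertices are decimated uniformly
#' along the contour and the simplified polygon is then rescaled about its
#' centroid so its area equals the original area exactly, keeping the cut
#' shape size-faithful.
#'
#' @param contour a [cell_contour()].
#' @param target_fraction maximal retained fraction of vertices.
#' @return simplified [cell_contour()] (same id).
#' @export
simplify_contour <- function(contour, target_fraction = 0.10) {
  stopifnot(inherits(contour, "cell_contour"))
  n <- nrow(contour$vertices)
  m <- max(3L, as.integer(ceiling(target_fraction * n)))
  if (m >= n) return(contour)
  idx <- unique(floor(seq(0, n - 1, length.out = m + 1L))[seq_len(m)] + 1L)
  v <- contour$vertices[idx, , drop = FALSE]
  a_new <- polygon_area(v)
  if (a_new <= 0) zn_stop("simplification produced a degenerate polygon")
  ctr <- polygon_centroid(v)
  v <- sweep(sweep(v, 2, ctr), 2, rep(sqrt(contour$area / a_new), 2), `*`)
  v <- sweep(v, 2, ctr, `+`)
  cell_contour(contour$id, v)
}
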