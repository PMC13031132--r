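# Vein detection/classification, trajectory ROIs, farthest-first selection,
# spatial ratios, contour simplification and LMD XML export.

scene <- generate_tissue(tissue_spec(seed = 12))

test_that("vein lumens are detected near their true anchors", {
  regions <- detect_veins(scene$channels$boundary)
  expect_length(regions, 2L)
  cents <- t(vapply(regions, `[[`, numeric(2), "centroid"))
  err_c <- min(sqrt(rowSums(sweep(cents, 2, scene$anchors$central)^2)))
  err_p <- min(sqrt(rowSums(sweep(cents, 2, scene$anchors$portal)^2)))
  expect_lt(err_c, 3)
  expect_lt(err_p, 3)
})

test_that("uniform bright image yields no candidates; constant image errors", {
  set.seed(5)
  bright <- matrix(0.8 + abs(rnorm(96 * 96, 0, 0.02)), 96, 96)
  expect_length(detect_veins(bright), 0L)
  expect_error(detect_veins(matrix(0.5, 96, 96)), "constant")
})

test_that("the area filter dominates detection", {
  regions <- detect_veins(scene$channels$boundary, min_vein_area = 1e6)
  expect_length(regions, 0L)
})

test_that("marker classification matches ground truth and flips on swap", {
  regions <- detect_veins(scene$channels$boundary)
  veins <- classify_veins(regions, scene$channels$pericentral,
                          scene$channels$periportal)
  byx <- order(vapply(veins, function(v) v$anchor[1], numeric(1)))
  truth_first <- if (scene$anchors$central[1] < scene$anchors$portal[1])
    c("central", "portal") else c("portal", "central")
  expect_identical(vapply(veins[byx], `[[`, character(1), "type"), truth_first)
  swapped <- classify_veins(regions, scene$channels$periportal,
                            scene$channels$pericentral)
  expect_identical(vapply(swapped[byx], `[[`, character(1), "type"),
                   rev(truth_first))
})

test_that("annulus clipped at the image border still classifies", {
  edge_region <- list(list(
    mask = {m <- matrix(FALSE, nrow(scene$channels$boundary),
                        ncol(scene$channels$boundary)); m[1:10, 1:10] <- TRUE; m},
    centroid = c(5, 5), area = 100))
  v <- classify_veins(edge_region, scene$channels$pericentral,
                      scene$channels$periportal)
  expect_true(v[[1]]$type %in% c("central", "portal"))
})

test_that("greedy vein pairing matches the exhaustive matching on small cases", {
  mk <- function(x, y, type) list(anchor = c(x, y), type = type, mask = NULL)
  one <- pair_trajectories(list(mk(0, 0, "central"), mk(10, 0, "portal")))
  expect_length(one, 1L)
  # square: centrals at left corners, portals at right corners
  sq <- list(mk(0, 0, "central"), mk(0, 10, "central"),
             mk(10, 0, "portal"), mk(10, 10, "portal"))
  pairs <- pair_trajectories(sq)
  expect_length(pairs, 2L)
  used <- lapply(pairs, function(p) list(p$central$anchor, p$portal$anchor))
  expect_equal(length(unique(unlist(used, recursive = FALSE))), 4L)
  for (p in pairs)
    expect_equal(zonemap:::euclid(p$central$anchor, p$portal$anchor), 10)
  expect_length(pair_trajectories(list(mk(0, 0, "central"), mk(5, 5, "central"))),
                0L)
})

test_that("cone ROI keeps between-vein cells and respects the angle", {
  A <- c(0, 0); B <- c(100, 0)
  mid <- ngon("mid", c(50, 0), 2)
  behind <- ngon("behind", c(-10, 0), 2)
  wide <- ngon("wide", c(10, 40), 2)    # angle at A: atan(40/10) = 76 deg
  near <- ngon("near", c(30, 10), 2)    # angle 18.4 deg
  traj <- manual_trajectory(A, B, list(mid, behind, wide, near))
  ids <- vapply(traj$roi_cells, `[[`, character(1), "id")
  expect_setequal(ids, c("mid", "near"))
  traj90 <- manual_trajectory(A, B, list(mid, behind, wide, near),
                              cone_half_angle = 90)
  expect_setequal(vapply(traj90$roi_cells, `[[`, character(1), "id"),
                  c("mid", "near", "wide"))
  expect_error(manual_trajectory(A, B, list(behind)), "empty trajectory")
  expect_error(manual_trajectory(A, A, list(mid)), "differ")
})

test_that("widening the cone can only enlarge a generated ROI", {
  veins <- classify_veins(detect_veins(scene$channels$boundary),
                          scene$channels$pericentral, scene$channels$periportal)
  pair <- pair_trajectories(veins)[[1]]
  roi65 <- build_trajectory_roi(pair, scene$contours, 65)
  roi90 <- build_trajectory_roi(pair, scene$contours, 90)
  ids65 <- vapply(roi65$roi_cells, `[[`, character(1), "id")
  ids90 <- vapply(roi90$roi_cells, `[[`, character(1), "id")
  expect_true(all(ids65 %in% ids90))
  expect_gt(length(ids90), length(ids65))
})

test_that("farthest-first traversal attains the collinear optimum", {
  pts <- lapply(0:9, function(x) ngon(sprintf("c%02d", x), c(x, 0), 0.01))
  sel <- select_cells_fft(pts, k = 3)
  cents <- t(vapply(sel, `[[`, numeric(2), "centroid"))
  expect_equal(min_pairwise_dist(cents),
               dispersion_brute(t(vapply(pts, `[[`, numeric(2), "centroid")), 3),
               tolerance = 1e-6)
  expect_equal(min_pairwise_dist(cents), 4, tolerance = 0.05)
})

test_that("greedy dispersion is within half of the brute-force optimum", {
  for (rep in 1:40) {
    set.seed(rep)
    n <- sample(4:12, 1); k <- sample(2:4, 1)
    xy <- matrix(runif(2 * n, 0, 100), n, 2)
    cells <- lapply(seq_len(n), function(i)
      ngon(sprintf("c%02d", i), xy[i, ], 0.01))
    sel <- select_cells_fft(cells, k = k)
    got <- min_pairwise_dist(t(vapply(sel, `[[`, numeric(2), "centroid")))
    opt <- dispersion_brute(t(vapply(cells, `[[`, numeric(2), "centroid")), k)
    expect_gte(got, 0.5 * opt - 1e-9)
  }
})

test_that("selection is the identity when k covers the ROI, and k<2 errors", {
  cells <- lapply(1:5, function(i) ngon(sprintf("c%d", i), c(i * 10, 0), 1))
  expect_identical(select_cells_fft(cells, k = 5), cells)
  expect_identical(select_cells_fft(cells, k = 10), cells)
  expect_error(select_cells_fft(cells, k = 1), "k must be")
})

test_that("spatial ratio honours the 0 = central convention and flips on demand", {
  r <- compute_spatial_ratio(c(0, 0), central = c(0, 0), portal = c(10, 0))
  expect_equal(r$S, 0)
  r <- compute_spatial_ratio(c(10, 0), central = c(0, 0), portal = c(10, 0))
  expect_equal(r$S, 1)
  r <- compute_spatial_ratio(c(1, 0), central = c(0, 0), portal = c(4, 0))
  expect_equal(r$S, 0.25)
  expect_equal(r$d_central, 1); expect_equal(r$d_portal, 3)
  rf <- compute_spatial_ratio(c(1, 0), c(0, 0), c(4, 0), orientation = "portal0")
  expect_equal(rf$S, 0.75)
  expect_error(compute_spatial_ratio(c(1, 1), c(2, 2), c(2, 2)), "distinct")
})

test_that("spatial ratio is invariant under rigid transforms", {
  set.seed(77)
  for (i in 1:20) {
    p <- runif(2, -50, 50); A <- runif(2, -50, 50); B <- runif(2, -50, 50)
    if (isTRUE(all.equal(A, B))) next
    th <- runif(1, 0, 2 * pi); shift <- runif(2, -100, 100)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    tr <- function(q) as.numeric(R %*% q + shift)
    s0 <- compute_spatial_ratio(p, A, B)$S
    s1 <- compute_spatial_ratio(tr(p), tr(A), tr(B))$S
    expect_equal(s0, s1, tolerance = 1e-9)
  }
})

test_that("manual mode reproduces auto mode given the same anchors", {
  veins <- classify_veins(detect_veins(scene$channels$boundary),
                          scene$channels$pericentral, scene$channels$periportal)
  pair <- pair_trajectories(veins)[[1]]
  auto <- build_trajectory_roi(pair, scene$contours)
  man <- manual_trajectory(pair$central$anchor, pair$portal$anchor,
                           scene$contours)
  expect_identical(vapply(auto$roi_cells, `[[`, character(1), "id"),
                   vapply(man$roi_cells, `[[`, character(1), "id"))
  ta <- spatial_cell_table(auto, k = 30)
  tm <- spatial_cell_table(man, k = 30)
  expect_equal(ta$S, tm$S, tolerance = 1e-12)
  expect_identical(ta$cell_id, tm$cell_id)
})

test_that("selected spatial ratios cover the trajectory uniformly", {
  veins <- classify_veins(detect_veins(scene$channels$boundary),
                          scene$channels$pericentral, scene$channels$periportal)
  traj <- build_trajectory_roi(pair_trajectories(veins)[[1]], scene$contours)
  tab <- spatial_cell_table(traj, k = 44)
  expect_equal(nrow(tab), 44L)
  ks <- suppressWarnings(stats::ks.test(tab$S, "punif"))$statistic
  expect_lt(ks, 0.2)
})

test_that("contour simplification meets the vertex budget and conserves area", {
  a <- 2 * pi * (0:99) / 100
  circ <- cell_contour("circle", cbind(50 + 20 * cos(a), 50 + 20 * sin(a)))
  simp <- simplify_contour(circ)
  expect_lte(nrow(simp$vertices), 10L)
  expect_lt(abs(simp$area - circ$area) / circ$area, 0.05)
  tri <- cell_contour("tri", rbind(c(0, 0), c(4, 0), c(0, 3)))
  expect_identical(simplify_contour(tri), tri)
  a40 <- 2 * pi * (0:39) / 40
  poly40 <- cell_contour("p40", cbind(10 * cos(a40), 10 * sin(a40)))
  expect_lte(nrow(simplify_contour(poly40)$vertices), 4L)
})

test_that("LMD XML export round-trips losslessly", {
  cells <- list(ngon("shape_a", c(10.123456789, 20.5), 5, 12),
                ngon("shape_b", c(100, 200), 8, 7))
  refs <- list(c(0, 0), c(500, 0), c(0, 500))
  path <- withr::local_tempfile(fileext = ".xml")
  export_lmd_xml(cells, refs, path)
  back <- read_lmd_xml(path)
  expect_identical(vapply(back$contours, `[[`, character(1), "id"),
                   c("shape_a", "shape_b"))
  expect_equal(back$contours[[1]]$vertices, cells[[1]]$vertices)
  expect_equal(back$ref_points, refs)
  # empty contour list still gives a valid calibrated document
  export_lmd_xml(list(), refs, path)
  expect_length(read_lmd_xml(path)$contours, 0L)
  # count conservation at the full selection size
  many <- lapply(1:44, function(i) ngon(sprintf("s%02d", i), c(i, i), 1))
  export_lmd_xml(many, refs, path)
  expect_length(read_lmd_xml(path)$contours, 44L)
  expect_error(export_lmd_xml(cells, refs[1:2], path), "3 reference")
})
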