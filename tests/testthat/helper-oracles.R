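# Independent oracles and small fixture builders used across the suite.

# Polygon centroid by fan triangulation from the first vertex: area-weighted
# mean of triangle centroids (independent of the package's moment formula).
oracle_centroid <- function(v) {
  n <- nrow(v)
  tot_a <- 0; acc <- c(0, 0)
  for (i in 2:(n - 1)) {
    p1 <- v[1, ]; p2 <- v[i, ]; p3 <- v[i + 1, ]
    a <- ((p2[1] - p1[1]) * (p3[2] - p1[2]) -
            (p3[1] - p1[1]) * (p2[2] - p1[2])) / 2
    acc <- acc + a * (p1 + p2 + p3) / 3
    tot_a <- tot_a + a
  }
  acc / tot_a
}

min_pairwise_dist <- function(pts) min(stats::dist(pts))

# Exhaustive max-min dispersion optimum over all k-subsets.
dispersion_brute <- function(pts, k) {
  best <- -Inf
  combs <- utils::combn(nrow(pts), k)
  for (j in seq_len(ncol(combs))) {
    d <- min_pairwise_dist(pts[combs[, j], , drop = FALSE])
    if (d > best) best <- d
  }
  best
}

# One-way ANOVA F from explicit sums of squares.
oracle_anova_F <- function(y, g) {
  g <- factor(g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2)))
  dfb <- nlevels(g) - 1
  dfw <- length(y) - nlevels(g)
  (ssb / dfb) / (ssw / dfw)
}

# Compact intensity_matrix builder: values is proteins x samples; patients
# and S are per sample.
make_im <- function(values, patients, S, condition = "healthy",
                    proteins = NULL, samples = NULL) {
  values <- as.matrix(values)
  if (is.null(proteins)) proteins <- sprintf("prot%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%03d", seq_len(ncol(values)))
  dimnames(values) <- list(proteins, samples)
  condition <- rep_len(condition, ncol(values))
  intensity_matrix(values, data.frame(sample_id = samples,
                                      patient_id = rep_len(patients, ncol(values)),
                                      condition = condition, S = S,
                                      stringsAsFactors = FALSE))
}

# A small contour factory: regular n-gon around a centre.
ngon <- function(id, center, r, n = 8L) {
  a <- 2 * pi * (seq_len(n) - 1) / n
  cell_contour(id, cbind(center[1] + r * cos(a), center[2] + r * sin(a)))
}
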