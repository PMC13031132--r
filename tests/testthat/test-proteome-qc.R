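# Matrix IO, sample/protein filters, within-patient standardization,
# marker panels, contamination scoring and the PCA space association.

test_that("intensity tables round-trip with their missing mask", {
  sim <- generate_proteome(proteome_spec(n_patients = 3, cells_per_patient = 6,
                                         n_proteins = 12, seed = 5))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "m.tsv"); mp <- file.path(dir, "meta.tsv")
  write_intensity_table(sim$matrix, p, mp)
  back <- read_intensity_table(p, mp)
  expect_equal(back$values, sim$matrix$values, tolerance = 1e-12)
  expect_identical(is.na(back$values), is.na(sim$matrix$values))
  expect_equal(back$meta$S, sim$matrix$meta$S, tolerance = 1e-12)
})

test_that("constructor rejects inconsistent inputs", {
  v <- matrix(1:6, 2, 3, dimnames = list(c("p1", "p2"), c("a", "b", "c")))
  meta <- data.frame(sample_id = c("a", "b"), patient_id = "P1",
                     condition = "healthy", S = 0.5)
  expect_error(intensity_matrix(v, meta), "mismatch.*c")
  v2 <- rbind(v, v[1, , drop = FALSE])
  rownames(v2) <- c("p1", "p2", "p1")
  meta3 <- data.frame(sample_id = c("a", "b", "c"), patient_id = "P1",
                      condition = "healthy", S = 0.5)
  expect_error(intensity_matrix(v2, meta3), "duplicate protein")
  meta_bad <- transform(meta3, S = c(0.5, 2, 0.1))
  expect_error(intensity_matrix(v, meta_bad), "\\[0, 1\\]")
})

test_that("sample QC applies the asymmetric median fences exactly", {
  counts_to_im <- function(counts) {
    n <- length(counts)
    v <- matrix(NA_real_, max(counts), n,
                dimnames = list(sprintf("p%04d", seq_len(max(counts))),
                                sprintf("s%02d", seq_len(n))))
    for (j in seq_len(n)) v[seq_len(counts[j]), j] <- 1
    make_im(v, patients = "P1", S = runif(n),
            proteins = rownames(v), samples = colnames(v))
  }
  set.seed(1)
  # low side: 2100 vs nine 2500s -> median 2500, sd = sd of all ten
  counts <- c(rep(2500, 9), 2100)
  res <- filter_samples_by_id_count(counts_to_im(counts))
  med <- median(counts); s <- sd(counts)
  expect_true(2100 < med - 1.5 * s)  # arithmetic premise of this fixture
  expect_identical(res$report$reason[10], "low")
  expect_equal(ncol(res$matrix$values), 9L)
  # same low count, wider spread -> kept
  counts2 <- c(2500, 2400, 2600, 2300, 2700, 2200, 2800, 2900, 2450, 2100)
  res2 <- filter_samples_by_id_count(counts_to_im(counts2))
  expect_true(2100 >= median(counts2) - 1.5 * sd(counts2))
  expect_identical(res2$report$reason[10], "kept")
  # high side at +3 sd
  counts3 <- c(rep(2500, 9), 3400)
  res3 <- filter_samples_by_id_count(counts_to_im(counts3))
  expect_true(3400 > median(counts3) + 3 * sd(counts3))
  expect_identical(res3$report$reason[10], "high")
  # all equal -> sd 0, nothing excluded
  res4 <- filter_samples_by_id_count(counts_to_im(rep(2000, 5)))
  expect_false(any(res4$report$excluded))
})

test_that("completeness filter keeps 7/10 and drops 6/10 (inclusive bound)", {
  v <- matrix(1, 3, 10)
  v[1, 1:3] <- NA   # 7/10 observed
  v[2, 1:4] <- NA   # 6/10 observed
  v[3, ] <- NA      # fully missing
  im <- make_im(v, patients = "P1", S = seq(0, 1, length.out = 10))
  kept <- filter_protein_completeness(im, 0.70)
  expect_identical(rownames(kept$values), "prot01")
  # idempotence
  expect_identical(filter_protein_completeness(kept, 0.70)$values, kept$values)
})

test_that("within-patient Z-scoring centres and scales each group", {
  sim <- generate_proteome(proteome_spec(n_patients = 4, cells_per_patient = 20,
                                         n_proteins = 15, seed = 6))
  z <- zscore_within_patient(sim$matrix)
  expect_identical(is.na(z$values) | is.na(sim$matrix$values),
                   is.na(z$values))  # missing entries stay missing
  for (p in unique(z$meta$patient_id)) {
    cols <- z$meta$patient_id == p
    for (i in c(1, 8, 15)) {
      vals <- z$values[i, cols]
      vals <- vals[!is.na(vals)]
      if (length(vals) >= 2) {
        expect_lt(abs(mean(vals)), 1e-9)
        expect_lt(abs(sd(vals) - 1), 1e-9)
      }
    }
  }
  # constant within a patient -> missing
  v <- matrix(c(rep(5, 4), 1, 2, 3, 4), 2, 4, byrow = TRUE)
  im <- make_im(v, patients = "P1", S = c(0.1, 0.4, 0.6, 0.9))
  zc <- zscore_within_patient(im)
  expect_true(all(is.na(zc$values[1, ])))
  expect_false(anyNA(zc$values[2, ]))
})

test_that("marker panels require both the absolute and fold thresholds", {
  ref <- rbind(a = c(2e8, 3e7), b = c(9e7, 9e7), c = c(2e8, 5e7))
  colnames(ref) <- c("hep", "kupffer")
  panels <- build_marker_panel(ref)
  expect_identical(panels$hep$protein_id, "a")  # c fails fold: 2e8 < 5*5e7
  expect_length(panels$kupffer$protein_id, 0L)
  # truncation to the 20 most intense of 25 qualifying
  ref2 <- cbind(hep = seq(2e8, 4.4e8, length.out = 25), other = 1)
  rownames(ref2) <- sprintf("m%02d", 1:25)
  p2 <- build_marker_panel(ref2)
  expect_length(p2$hep$protein_id, 20L)
  expect_identical(p2$hep$protein_id[1], "m25")
  expect_false("m01" %in% p2$hep$protein_id)
})

test_that("contamination scores follow median-rank arithmetic", {
  n <- 100
  v <- matrix(seq_len(n), n, 2,
              dimnames = list(sprintf("p%03d", seq_len(n)), c("s1", "s2")))
  im <- make_im(v, patients = "P1", S = c(0.2, 0.8),
                proteins = rownames(v), samples = colnames(v))
  hep <- sprintf("p%03d", (n - 19):n)     # the top-20 intensities
  absent <- sprintf("x%03d", 1:10)        # never detected
  sc <- contamination_score(im, list(hep = hep, ghost = absent))
  expect_equal(unname(sc[, "hep"]), rep(n - 9.5, 2))
  expect_equal(unname(sc[, "ghost"]), c(0, 0))
  # invariance under strictly monotone transforms
  im_log <- make_im(log1p(v), patients = "P1", S = c(0.2, 0.8),
                    proteins = rownames(v), samples = colnames(v))
  expect_equal(contamination_score(im_log, list(hep = hep)),
               sc[, "hep", drop = FALSE])
})

test_that("PC1 tracks S when space drives the shared variance", {
  set.seed(9)
  n <- 60
  S <- runif(n)
  # several features carry the spatial signal (features are standardized
  # before PCA, so a lone high-variance feature cannot dominate PC1)
  signal <- t(outer(S, c(1, -0.8, 1.2, 0.9, -1.1))) +
    matrix(rnorm(5 * n, sd = 0.05), 5, n)
  v <- rbind(signal, matrix(rnorm(5 * n, sd = 0.05), 5, n))
  im <- make_im(v, patients = rep(c("P1", "P2"), each = n / 2), S = S)
  res <- pca_space_association(im)
  expect_gte(abs(res$rho), 0.95)
  expect_lt(res$p, 1e-6)
  # determinism incl. the fixed sign convention
  res2 <- pca_space_association(im)
  expect_identical(res$rho, res2$rho)
  expect_identical(res$scores, res2$scores)
})

test_that("pure noise shows no PC1/space association", {
  hits <- vapply(1:60, function(i) {
    set.seed(1000 + i)
    n <- 40
    v <- matrix(rnorm(10 * n), 10, n)
    im <- make_im(v, patients = "P1", S = runif(n))
    pca_space_association(im)$p > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("PCA excludes |Z| > 3 outlier samples", {
  set.seed(10)
  n <- 30
  v <- matrix(rnorm(6 * n), 6, n)
  v[, 1] <- v[, 1] + 50
  im <- make_im(v, patients = "P1", S = runif(n))
  res <- pca_space_association(im)
  expect_true("s001" %in% res$excluded_samples)
  expect_equal(nrow(res$scores), n - length(res$excluded_samples))
})

test_that("the pipeline's filter order (samples, then completeness) matters", {
  # protein A is observed in 7 of 10 samples, one of them the failed
  # low-count sample: dropping that sample first leaves A at 6/9 (< 70%),
  # while filtering completeness first would keep A at 7/10.
  nprot <- 400
  v <- matrix(1, nprot, 10,
              dimnames = list(sprintf("p%03d", seq_len(nprot)),
                              sprintf("s%02d", 1:10)))
  v[1, c(1, 2, 3)] <- NA                # protein A: observed 7/10, incl. s10
  v[150:nprot, 10] <- NA                # s10 fails the count fence
  im <- make_im(v, patients = "P1", S = seq(0, 1, length.out = 10),
                proteins = rownames(v), samples = colnames(v))
  pipeline_order <- filter_protein_completeness(
    filter_samples_by_id_count(im)$matrix, 0.70)
  expect_false("p001" %in% rownames(pipeline_order$values))
  reversed <- filter_protein_completeness(im, 0.70)
  expect_true("p001" %in% rownames(reversed$values))
})

test_that("sample filter is idempotent on crafted counts", {
  set.seed(2)
  counts <- c(rep(2500, 9), 2100)
  v <- matrix(NA_real_, 2500, 10,
              dimnames = list(sprintf("p%04d", 1:2500), sprintf("s%02d", 1:10)))
  for (j in 1:10) v[seq_len(counts[j]), j] <- 1
  im <- make_im(v, patients = "P1", S = runif(10),
                proteins = rownames(v), samples = colnames(v))
  once <- filter_samples_by_id_count(im)$matrix
  twice <- filter_samples_by_id_count(once)$matrix
  expect_identical(colnames(twice$values), colnames(once$values))
})
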