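# Quality control for single-cell proteome matrices: table IO, sample- and
# protein-level filters, within-patient standardization, cell-type
# contamination scoring, and the PCA / spatial-ratio association check.
# "Detected" throughout means a finite positive intensity; zeros, empty
# fields and NaN are treated as missing (DIA-NN/directLFQ exports use both
# conventions). No imputation is performed anywhere.

#' Read a protein intensity table with sample metadata
#'
#' Expects a TSV with protein ids in the first column and one column per
#' sample (the layout of directLFQ-style `protein_intensities` exports), plus
#' a metadata TSV with columns `sample_id`, `patient_id`, `condition`, `S`.
#' Zeros, empty fields and NaN parse as missing.
#'
#' @param path intensity TSV path.
#' @param meta_path metadata TSV path.
#' @return an [intensity_matrix()].
#' @export
read_intensity_table <- function(path, meta_path) {
  dt <- data.table::fread(path, sep = "\t")
  ids <- as.character(dt[[1L]])
  vals <- as.matrix(dt[, -1L, with = FALSE])
  storage.mode(vals) <- "double"
  vals[is.nan(vals)] <- NA_real_
  rownames(vals) <- ids
  meta <- as.data.frame(data.table::fread(meta_path, sep = "\t"))
  intensity_matrix(vals, meta)
}

#' Write an intensity matrix and its metadata as TSV files
#'
#' Missing entries are written as empty fields.
#'
#' @param im an [intensity_matrix()].
#' @param path,meta_path output TSV paths.
#' @export
write_intensity_table <- function(im, path, meta_path) {
  dt <- data.table::data.table(protein_id = rownames(im$values))
  dt <- cbind(dt, data.table::as.data.table(im$values))
  data.table::fwrite(dt, path, sep = "\t", na = "")
  data.table::fwrite(im$meta, meta_path, sep = "\t", na = "")
  invisible(path)
}

#' Exclude samples by identified-protein count
#'
#' A sample (shape) is excluded when its number of detected proteins lies
#' more than 1.5 s.d. below or more than 3 s.d. above the median count; the
#' asymmetric fences drop failed collections on the low side and likely
#' doublets/contaminated wells on the high side. Median and sample s.d.
#' (n - 1) are computed once over all samples before any exclusion.
#'
#' @param im an [intensity_matrix()].
#' @param k_low,k_high s.d. multiples for the low and high fence.
#' @return list with `matrix` (filtered) and `report`, a data.frame with
#'   sample_id, n_proteins, excluded, reason ("kept", "low", "high") plus
#'   attributes `median` and `sd`.
#' @export
filter_samples_by_id_count <- function(im, k_low = 1.5, k_high = 3) {
  counts <- colSums(!is.na(im$values))
  if (length(counts) < 3L) zn_stop("sample QC needs at least 3 samples")
  med <- stats::median(counts); s <- stats::sd(counts)
  low <- counts < med - k_low * s
  high <- counts > med + k_high * s
  report <- data.frame(sample_id = colnames(im$values),
                       n_proteins = as.integer(counts),
                       excluded = low | high,
                       reason = ifelse(low, "low", ifelse(high, "high", "kept")),
                       stringsAsFactors = FALSE)
  attr(report, "median") <- med; attr(report, "sd") <- s
  keep <- !report$excluded
  list(matrix = im_subset(im, samples = keep), report = report)
}

#' Filter proteins by data completeness
#'
#' Keeps proteins detected in at least `min_fraction` of the samples
#' (inclusive: 7 of 10 passes at 0.70, 6 of 10 does not).
#'
#' @param im an [intensity_matrix()].
#' @param min_fraction minimal observed fraction (default 0.70).
#' @export
filter_protein_completeness <- function(im, min_fraction = 0.70) {
  frac <- rowMeans(!is.na(im$values))
  im_subset(im, proteins = frac >= min_fraction)
}

#' Z-score normalize protein intensities within each patient
#'
#' Per protein and per patient, observed entries are centred on their mean
#' and scaled to unit (sample, n - 1) variance. Groups with fewer than two
#' observed values or zero variance become missing; missing entries stay
#' missing.
#'
#' @param im an [intensity_matrix()].
#' @export
zscore_within_patient <- function(im) {
  v <- im$values
  for (p in unique(im$meta$patient_id)) {
    cols <- which(im$meta$patient_id == p)
    sub <- v[, cols, drop = FALSE]
    m <- rowMeans(sub, na.rm = TRUE)
    s <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    n <- rowSums(!is.na(sub))
    z <- (sub - m) / s
    z[n < 2L | !is.finite(s) | s == 0, ] <- NA_real_
    v[, cols] <- z
  }
  intensity_matrix(v, im$meta)
}

#' Build cell-type marker panels from a reference intensity table
#'
#' A protein is a cell-type-specific marker when its reference intensity in
#' that cell type exceeds `abs_threshold` (default 1e8) and is at least
#' `fold` times (default 5) its intensity in every other cell type; the top
#' `top_n` qualifying proteins by intensity form the panel (fewer if fewer
#' qualify).
#'
#' @param reference numeric matrix, proteins x cell types (NA treated as 0).
#' @param abs_threshold absolute reference-intensity threshold.
#' @param fold minimal fold change over every other cell type.
#' @param top_n panel size cap (default 20).
#' @return named list (one element per cell type) of data.frames with
#'   `protein_id` and `intensity`.
#' @export
build_marker_panel <- function(reference, abs_threshold = 1e8, fold = 5,
                               top_n = 20L) {
  reference <- as.matrix(reference)
  if (ncol(reference) < 2L) zn_stop("reference table needs >= 2 cell types")
  reference[is.na(reference)] <- 0
  out <- lapply(seq_len(ncol(reference)), function(j) {
    other_max <- apply(reference[, -j, drop = FALSE], 1L, max)
    ok <- reference[, j] > abs_threshold & reference[, j] >= fold * other_max
    qual <- data.frame(protein_id = rownames(reference)[ok],
                       intensity = reference[ok, j],
                       stringsAsFactors = FALSE)
    utils::head(qual[order(-qual$intensity), , drop = FALSE], top_n)
  })
  names(out) <- colnames(reference)
  out
}

#' Cell-type contamination score by median marker rank
#'
#' Within each sample, detected proteins are ranked by intensity in ascending
#' order (average ranks on ties, the most intense protein getting rank
#' n_detected); undetected marker proteins receive rank 0, the lowest
#' possible. The score of a cell-type panel in a sample is the median rank of
#' its markers: near n_detected means the panel dominates the proteome,
#' near 0 means it is absent. Because only ranks are used, the score is
#' invariant under any strictly monotone transform of a sample's intensities.
#'
#' @param im an [intensity_matrix()].
#' @param panels marker panels from [build_marker_panel()] (or a named list
#'   of protein-id vectors).
#' @return numeric matrix, samples x cell types, of median marker ranks.
#' @export
contamination_score <- function(im, panels) {
  panel_ids <- lapply(panels, function(p)
    if (is.data.frame(p)) p$protein_id else as.character(p))
  out <- matrix(NA_real_, ncol(im$values), length(panel_ids),
                dimnames = list(colnames(im$values), names(panel_ids)))
  for (s in seq_len(ncol(im$values))) {
    v <- im$values[, s]
    obs <- !is.na(v)
    rk <- stats::setNames(rep(0, nrow(im$values)), rownames(im$values))
    rk[obs] <- rank(v[obs])
    for (p in seq_along(panel_ids)) {
      ids <- panel_ids[[p]]
      r <- ifelse(ids %in% names(rk), rk[ids], 0)
      out[s, p] <- stats::median(r)
    }
  }
  out
}

#' PCA of single-cell proteomes and association of PC1 with space
#'
#' Uses only proteins with no missing values across samples (no imputation),
#' standardizes each protein to zero mean / unit variance, excludes samples
#' with any feature |Z| > 3, and computes principal components. The sign of
#' each PC is fixed deterministically (first nonzero loading positive). The
#' association between the first component and the spatial ratio S is
#' reported as a two-sided Spearman correlation.
#'
#' @param im an [intensity_matrix()].
#' @param z_cut sample-exclusion threshold on |Z| (default 3).
#' @return list with `scores` (samples x PCs), `rotation`,
#'   `explained_variance` (ratios), `rho`, `p` (Spearman PC1 vs S),
#'   `excluded_samples` (ids), `n_features`.
#' @export
pca_space_association <- function(im, z_cut = 3) {
  complete <- rowSums(is.na(im$values)) == 0L
  X <- t(im$values[complete, , drop = FALSE])
  if (ncol(X) < 2L) zn_stop("fewer than 2 complete proteins: cannot run PCA")
  sds <- apply(X, 2L, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  Z <- scale(X)
  bad <- apply(abs(Z) > z_cut, 1L, any)
  excluded <- rownames(X)[bad]
  Zk <- Z[!bad, , drop = FALSE]
  pca <- stats::prcomp(Zk, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pca$rotation))) {
    lead <- pca$rotation[which(pca$rotation[, j] != 0)[1L], j]
    if (!is.na(lead) && lead < 0) {
      pca$rotation[, j] <- -pca$rotation[, j]
      pca$x[, j] <- -pca$x[, j]
    }
  }
  S <- im$meta$S[match(rownames(Zk), im$meta$sample_id)]
  ct <- suppressWarnings(stats::cor.test(pca$x[, 1L], S, method = "spearman",
                                         alternative = "two.sided"))
  list(scores = pca$x, rotation = pca$rotation,
       explained_variance = pca$sdev^2 / sum(pca$sdev^2),
       rho = unname(ct$estimate), p = ct$p.value,
       excluded_samples = excluded, n_features = ncol(Zk))
}
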