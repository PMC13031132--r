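# Discrete comparator for the continuous gradient model: 20 equal-width
# spatial bins along the porto-central axis, bin Z-scores, heatmap ordering,
# per-protein one-way ANOVA across bins, and pathway median-Z profiles.

#' Bin cells by spatial ratio and average protein expression
#'
#' Bins are equal-width on [0, 1], left-closed / right-open with the last bin
#' right-closed, so S = 0 falls in bin 1, S = 0.05 in bin 2 (at 20 bins) and
#' S = 1 in the last bin. Means are over observed values only; an empty
#' (protein, bin) cell is missing.
#'
#' @param im an [intensity_matrix()].
#' @param n_bins number of bins (default 20).
#' @return object of class `binned_matrix`: list with `means` (proteins x
#'   bins), `counts` (cells per bin), `edges`, `bin` (per-sample bin index).
#' @export
bin_by_spatial_ratio <- function(im, n_bins = 20L) {
  S <- im$meta$S
  if (any(S < 0 | S > 1)) zn_stop("S must lie in [0, 1]")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- findInterval(S, edges, rightmost.closed = TRUE)
  means <- matrix(NA_real_, nrow(im$values), n_bins,
                  dimnames = list(rownames(im$values),
                                  sprintf("bin_%02d", seq_len(n_bins))))
  for (b in seq_len(n_bins)) {
    cols <- which(bin == b)
    if (!length(cols)) next
    m <- rowMeans(im$values[, cols, drop = FALSE], na.rm = TRUE)
    means[, b] <- ifelse(is.nan(m), NA_real_, m)
  }
  structure(list(means = means, counts = tabulate(bin, n_bins),
                 edges = edges, bin = bin),
            class = "binned_matrix")
}

#' Z-score binned profiles along the bin axis
#'
#' Per protein, the non-missing bin means are centred and scaled to unit
#' sample (n - 1) variance; proteins with fewer than two non-missing bins or
#' zero variance become all-missing. Missing bins stay missing.
#'
#' @param binned a [bin_by_spatial_ratio()] result.
#' @return a `binned_matrix` with Z-scored `means`.
#' @export
zscore_bins <- function(binned) {
  z <- t(apply(binned$means, 1L, function(x) {
    obs <- is.finite(x)
    if (sum(obs) < 2L) return(rep(NA_real_, length(x)))
    s <- stats::sd(x[obs])
    if (s == 0) return(rep(NA_real_, length(x)))
    (x - mean(x[obs])) / s
  }))
  dimnames(z) <- dimnames(binned$means)
  out <- binned; out$means <- z
  out
}

#' Order proteins by expression difference along the trajectory
#'
#' Heatmap row order: sort key is the mean of the last three bins minus the
#' mean of the first three bins (portal minus central end), descending, so
#' portally rising proteins sort to the top and centrally rising proteins to
#' the bottom. Ties are broken by protein id.
#'
#' @param binned a (typically Z-scored) `binned_matrix`.
#' @param n_edge number of bins averaged at each end (default 3).
#' @return character vector of protein ids in display order.
#' @export
order_by_gradient <- function(binned, n_edge = 3L) {
  nb <- ncol(binned$means)
  lo <- rowMeans(binned$means[, seq_len(n_edge), drop = FALSE], na.rm = TRUE)
  hi <- rowMeans(binned$means[, (nb - n_edge + 1L):nb, drop = FALSE], na.rm = TRUE)
  key <- hi - lo
  ids <- rownames(binned$means)
  ids[order(-key, ids)]
}

#' One-way ANOVA of a protein across spatial bins
#'
#' Fixed-effects one-way ANOVA of the cell-level values on the bin factor
#' (for a single factor the Type II decomposition coincides with the
#' ordinary one-way sums of squares). Constant data give F = 0, p = 1.
#'
#' @param y cell-level values for one protein.
#' @param bin bin labels, same length as `y`.
#' @return list with `F` and `p`.
#' @export
anova_bins <- function(y, bin) {
  keep <- is.finite(y) & !is.na(bin)
  y <- y[keep]; bin <- factor(bin[keep])
  if (nlevels(bin) < 2L || length(y) <= nlevels(bin))
    return(list(F = NA_real_, p = NA_real_))
  if (stats::var(y) == 0) return(list(F = 0, p = 1))
  a <- stats::anova(stats::lm(y ~ bin))
  list(F = a$`F value`[1L], p = a$`Pr(>F)`[1L])
}

#' Per-protein ANOVA across spatial bins with BH correction
#'
#' Runs [anova_bins()] for every protein of a matrix using the bin labels of
#' [bin_by_spatial_ratio()] and adjusts p values with Benjamini-Hochberg.
#'
#' @param im an [intensity_matrix()].
#' @param n_bins number of bins (default 20).
#' @return data.frame with protein_id, F, p, Q.
#' @export
anova_gradients <- function(im, n_bins = 20L) {
  bin <- bin_by_spatial_ratio(im, n_bins)$bin
  res <- t(vapply(seq_len(nrow(im$values)), function(i) {
    a <- anova_bins(im$values[i, ], bin)
    c(a$F, a$p)
  }, numeric(2)))
  out <- data.frame(protein_id = rownames(im$values), F = res[, 1],
                    p = res[, 2], Q = NA_real_, stringsAsFactors = FALSE)
  ok <- is.finite(out$p)
  out$Q[ok] <- bh_adjust(out$p[ok])
  out
}

#' Pathway median-Z spatial profiles
#'
#' Per pathway and bin, the median Z-score over the member proteins present
#' in the matrix (missing values omitted). Pathways with no member protein
#' available give an all-missing row with a warning.
#'
#' @param binned_z a Z-scored `binned_matrix` (see [zscore_bins()]).
#' @param pathways named list of protein-id vectors (e.g. from
#'   [read_gmt()]).
#' @return numeric matrix, pathways x bins, of median Z-scores.
#' @export
pathway_profile <- function(binned_z, pathways) {
  out <- matrix(NA_real_, length(pathways), ncol(binned_z$means),
                dimnames = list(names(pathways), colnames(binned_z$means)))
  for (p in seq_along(pathways)) {
    members <- intersect(pathways[[p]], rownames(binned_z$means))
    if (!length(members)) {
      warning(sprintf("pathway '%s' has no member protein in the matrix",
                      names(pathways)[p]))
      next
    }
    sub <- binned_z$means[members, , drop = FALSE]
    out[p, ] <- apply(sub, 2L, function(col) {
      obs <- is.finite(col)
      if (!any(obs)) NA_real_ else stats::median(col[obs])
    })
  }
  out
}

#' Read pathway membership from a GMT file
#'
#' Uses `fgsea::gmtPathways()` when fgsea is installed, else a minimal
#' tab-split fallback (GMT: name, description, member ids per line).
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[[`, character(1), 1L))
}

#' Compare continuous and binned significance per protein
#'
#' Pairs the Q values of the continuous (LMM Wald) and discrete (20-bin
#' ANOVA) analyses on their shared protein set, reports -log10 Q for both,
#' the counts significant in both/either at Q < `alpha`, and the Spearman
#' correlation between the two significance scales.
#'
#' @param fits a `gradient_fits` (continuous analysis).
#' @param anova_res result of [anova_gradients()].
#' @param alpha significance threshold (default 0.05).
#' @return list with `table` (protein_id, q_continuous, q_anova,
#'   neglog_q_continuous, neglog_q_anova, sig_continuous, sig_anova), `rho`,
#'   `n_both`, `n_either`.
#' @export
method_comparison <- function(fits, anova_res, alpha = 0.05) {
  shared <- intersect(fits$protein_id[!is.na(fits$Q)],
                      anova_res$protein_id[!is.na(anova_res$Q)])
  qa <- fits$Q[match(shared, fits$protein_id)]
  qb <- anova_res$Q[match(shared, anova_res$protein_id)]
  tab <- data.frame(protein_id = shared, q_continuous = qa, q_anova = qb,
                    neglog_q_continuous = -log10(qa),
                    neglog_q_anova = -log10(qb),
                    sig_continuous = qa < alpha, sig_anova = qb < alpha,
                    stringsAsFactors = FALSE)
  rho <- suppressWarnings(stats::cor(tab$neglog_q_continuous,
                                     tab$neglog_q_anova,
                                     method = "spearman"))
  list(table = tab, rho = rho,
       n_both = sum(tab$sig_continuous & tab$sig_anova),
       n_either = sum(tab$sig_continuous | tab$sig_anova))
}
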