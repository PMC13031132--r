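# Variable-width DIA isolation-window design: windows sized to the precursor
# density so that dense m/z regions get narrow windows and sparse regions
# wide ones, emulating a sample-tailored acquisition scheme.

#' Compute variable-width DIA isolation windows
#'
#' Partitions the precursor selection range into `n_windows` contiguous
#' isolation windows whose edges sit at type-1 (inverse-ECDF) empirical
#' quantiles of the in-range precursor m/z values, so per-window precursor
#' counts differ by at most one (for distinct m/z values) and window width
#' adapts inversely to precursor density. The first and last edges are
#' clamped to the range. Windows are half-open [low, high) with the last one
#' right-closed. Edge duplicates (arising from heavily tied m/z lists) and
#' windows narrower than `min_width` are merged, which can reduce the window
#' count and trade off the equal-count property; `min_width = 0` (default)
#' merges exact duplicates only.
#'
#' @param mz numeric vector of precursor m/z values (e.g. from a survey
#'   run); values outside `range` are ignored.
#' @param n_windows number of windows (default 60).
#' @param range precursor selection range, default c(380, 980) m/z.
#' @param min_width minimal window width in m/z (default 0 = off).
#' @return data.frame of class `window_scheme` with columns index, low,
#'   high, width, count; attribute `n_precursors` holds the in-range count.
#' @export
compute_variable_windows <- function(mz, n_windows = 60L, range = c(380, 980),
                                     min_width = 0) {
  if (length(range) != 2L || diff(range) <= 0)
    zn_stop("range must be an increasing (low, high) pair")
  x <- sort(mz[is.finite(mz) & mz >= range[1] & mz <= range[2]])
  n <- length(x)
  if (n < n_windows)
    zn_stop(sprintf(
      "only %d precursors in range for %d windows: use a smaller n_windows",
      n, n_windows))
  a <- seq_len(n_windows - 1L) * n / n_windows
  inner <- vapply(a, function(ai) {
    if (abs(ai - round(ai)) < 1e-9) (x[round(ai)] + x[round(ai) + 1L]) / 2
    else x[ceiling(ai)]
  }, numeric(1))
  edges <- c(range[1], inner, range[2])
  if (min_width > 0) {
    for (i in 2:length(edges))
      edges[i] <- max(edges[i], edges[i - 1] + min_width)
    edges <- pmin(edges, range[2])
  }
  edges <- unique(edges)
  if (length(edges) < 2L) zn_stop("degenerate window scheme")
  w <- length(edges) - 1L
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  out <- data.frame(index = seq_len(w), low = edges[-length(edges)],
                    high = edges[-1L])
  out$width <- out$high - out$low
  out$count <- tabulate(idx, w)
  attr(out, "n_precursors") <- n
  class(out) <- c("window_scheme", "data.frame")
  out
}

#' Write a window scheme as TSV
#' @param scheme a `window_scheme`.
#' @param path output path.
#' @export
write_window_scheme <- function(scheme, path) {
  data.table::fwrite(as.data.frame(scheme), path, sep = "\t")
  invisible(path)
}

#' Read a one-column m/z list (plain text or TSV)
#' @param path file with one m/z value per line (header optional).
#' @export
read_mz_list <- function(path) {
  dt <- data.table::fread(path, header = "auto")
  as.numeric(dt[[1L]])
}
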