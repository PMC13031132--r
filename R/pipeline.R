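# End-to-end workflows tying the modules together, plus YAML configuration.
# These are the programmatic counterparts of the command-line entry points
# in inst/cli/zonemap.R.

#' Assemble a pipeline configuration
#'
#' All tunables of every stage with their standard defaults: 44 cells per
#' trajectory, a 65 degree cone half-angle, 70% protein completeness, 20
#' spatial bins, strong-zonation thresholds |beta1| > 1 & Q < 0.05, loss
#' thresholds |delta_beta1| > 1 & Q < 0.05, and 60 DIA windows over
#' 380-980 m/z.
#'
#' @param ... overrides of any default field.
#' @return a named list of class `zonemap_config`.
#' @export
zonemap_config <- function(...) {
  cfg <- list(k = 44L, cone_angle = 65, completeness = 0.70, n_bins = 20L,
              strong_beta = 1, alpha = 0.05, loss_delta = 1,
              n_windows = 60L, window_low = 380, window_high = 980,
              min_vein_area = 50, blur_sigma = 5, dilation_radius = 10,
              annulus_width = 15, orientation = "central0", tukey_k = 1.5,
              mode = "auto", anchor_a = NULL, anchor_b = NULL,
              patient_id = "P01", seed = 1L,
              channels_dir = NULL, contours_csv = NULL,
              matrix_tsv = NULL, meta_tsv = NULL, out_dir = ".")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    zn_stop(paste("unknown config fields:", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  if (cfg$k < 2) zn_stop("k must be >= 2")
  if (cfg$cone_angle <= 0 || cfg$cone_angle > 90)
    zn_stop("cone_angle must be in (0, 90] degrees")
  if (cfg$completeness < 0 || cfg$completeness > 1)
    zn_stop("completeness must be in [0, 1]")
  structure(cfg, class = c("zonemap_config", "list"))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; fields as in [zonemap_config()].
#' @param ... overrides applied after the file.
#' @export
read_zonemap_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  do.call(zonemap_config, utils::modifyList(vals, list(...)))
}

#' Run the cell-selection workflow
#'
#' Detects and classifies veins (auto mode) or uses two manual anchor points,
#' builds the trajectory ROI, selects cells by farthest-first traversal,
#' computes spatial ratios, and writes the spatial-cell table (TSV) and the
#' LMD cutting contours (XML, calibrated on three image-corner reference
#' points).
#'
#' @param config a [zonemap_config()]; either `channels_dir` + `contours_csv`
#'   must point to inputs, or `tissue` must be given.
#' @param tissue optional in-memory scene from [generate_tissue()] (used
#'   instead of reading files).
#' @return invisibly, a list with `table` (the spatial-cell data.frame),
#'   `trajectory` and the output paths.
#' @export
run_select <- function(config, tissue = NULL) {
  stopifnot(inherits(config, "zonemap_config"))
  if (is.null(tissue)) {
    if (is.null(config$channels_dir) || is.null(config$contours_csv))
      zn_stop("run_select needs channels_dir and contours_csv (or a tissue object)")
    tissue <- list(
      channels = list(
        pericentral = read_channel(file.path(config$channels_dir, "pericentral.tif")),
        periportal = read_channel(file.path(config$channels_dir, "periportal.tif")),
        boundary = read_channel(file.path(config$channels_dir, "boundary.tif"))),
      contours = read_contours_csv(config$contours_csv))
  }
  if (config$mode == "manual") {
    if (is.null(config$anchor_a) || is.null(config$anchor_b))
      zn_stop("manual mode needs anchor_a and anchor_b")
    traj <- manual_trajectory(config$anchor_a, config$anchor_b,
                              tissue$contours, config$cone_angle)
    message(sprintf("manual trajectory: axis %.1f px, %d cells in ROI",
                    traj$axis_length, length(traj$roi_cells)))
  } else {
    regions <- detect_veins(tissue$channels$boundary, config$min_vein_area,
                            config$blur_sigma, config$dilation_radius)
    if (!length(regions)) zn_stop("no vein candidates detected")
    veins <- classify_veins(regions, tissue$channels$pericentral,
                            tissue$channels$periportal, config$annulus_width)
    message(sprintf("detected %d vein(s): %s", length(veins),
                    paste(vapply(veins, `[[`, character(1), "type"),
                          collapse = ", ")))
    pairs <- pair_trajectories(veins)
    if (!length(pairs)) zn_stop("no central/portal vein pair found")
    traj <- build_trajectory_roi(pairs[[1L]], tissue$contours, config$cone_angle)
    message(sprintf("trajectory: axis %.1f px, %d cells in ROI",
                    traj$axis_length, length(traj$roi_cells)))
  }
  tab <- spatial_cell_table(traj, k = config$k, patient_id = config$patient_id,
                            orientation = config$orientation)
  message(sprintf("selected %d cells (k = %d)", nrow(tab), config$k))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  tsv <- file.path(config$out_dir, "spatial_cells.tsv")
  data.table::fwrite(tab, tsv, sep = "\t")
  sel <- tissue$contours[match(tab$cell_id,
                               vapply(tissue$contours, `[[`, character(1), "id"))]
  sel <- lapply(sel, simplify_contour)
  ref <- list(c(0, 0),
              c(max(tab$centroid_x) + 10, 0),
              c(0, max(tab$centroid_y) + 10))
  xml <- file.path(config$out_dir, "contours_lmd.xml")
  export_lmd_xml(sel, ref, xml)
  invisible(list(table = tab, trajectory = traj, tsv = tsv, xml = xml))
}

#' Run the zonation analysis workflow
#'
#' Sample QC (identification-count fences), protein completeness filter,
#' continuous gradient fits with zonation calls, the 20-bin discrete
#' comparator, and the method comparison; writes fits, bins and a QC report
#' (TSV + JSON).
#'
#' @param config a [zonemap_config()].
#' @param im optional in-memory [intensity_matrix()] (instead of
#'   `matrix_tsv` / `meta_tsv`).
#' @return invisibly, list with `fits`, `binned`, `anova`, `comparison`,
#'   `qc_report`, and output paths.
#' @export
run_zonation <- function(config, im = NULL) {
  stopifnot(inherits(config, "zonemap_config"))
  if (is.null(im)) {
    if (is.null(config$matrix_tsv) || is.null(config$meta_tsv))
      zn_stop("run_zonation needs matrix_tsv and meta_tsv (or an intensity_matrix)")
    im <- read_intensity_table(config$matrix_tsv, config$meta_tsv)
  }
  if (!nrow(im$values) || !ncol(im$values)) zn_stop("empty intensity matrix")
  qc <- filter_samples_by_id_count(im)
  message(sprintf("sample QC: %d of %d samples kept (median %d ids, sd %.1f)",
                  sum(!qc$report$excluded), nrow(qc$report),
                  attr(qc$report, "median"), attr(qc$report, "sd")))
  imf <- filter_protein_completeness(qc$matrix, config$completeness)
  message(sprintf("completeness >= %d%%: %d of %d proteins kept",
                  round(100 * config$completeness), nrow(imf$values),
                  nrow(qc$matrix$values)))
  fits <- fit_gradients(imf, strong_beta = config$strong_beta,
                        alpha = config$alpha, tukey_k = config$tukey_k)
  message(sprintf("gradients: %d fits, %d significant, %d strong",
                  sum(fits$converged), sum(fits$significant), sum(fits$strong)))
  binned <- bin_by_spatial_ratio(imf, config$n_bins)
  anova_res <- anova_gradients(imf, config$n_bins)
  comparison <- method_comparison(fits, anova_res, config$alpha)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  paths <- list(fits = file.path(config$out_dir, "gradient_fits.tsv"),
                bins = file.path(config$out_dir, "binned_means.tsv"),
                qc = file.path(config$out_dir, "sample_qc.tsv"),
                qc_json = file.path(config$out_dir, "qc_summary.json"))
  data.table::fwrite(as.data.frame(fits), paths$fits, sep = "\t")
  bins_df <- data.frame(protein_id = rownames(binned$means),
                        as.data.frame(binned$means))
  data.table::fwrite(bins_df, paths$bins, sep = "\t")
  data.table::fwrite(qc$report, paths$qc, sep = "\t")
  jsonlite::write_json(list(
    n_samples_in = nrow(qc$report),
    n_samples_kept = sum(!qc$report$excluded),
    median_ids = attr(qc$report, "median"), sd_ids = attr(qc$report, "sd"),
    n_proteins_in = nrow(qc$matrix$values), n_proteins_kept = nrow(imf$values),
    n_significant = sum(fits$significant), n_strong = sum(fits$strong)),
    paths$qc_json, auto_unbox = TRUE, digits = NA)
  invisible(list(fits = fits, binned = binned, anova = anova_res,
                 comparison = comparison, qc_report = qc$report,
                 paths = paths))
}

#' Run the condition-contrast workflow
#'
#' Splits the matrix by condition label, fits gradients per condition,
#' contrasts the zonation coefficients of the reference condition's strongly
#' zonated proteins against the other condition, and writes the contrast
#' table and direction summary.
#'
#' @param config a [zonemap_config()].
#' @param im an [intensity_matrix()] holding both conditions (or use
#'   `matrix_tsv`/`meta_tsv`).
#' @param condition_a,condition_b condition labels; A is the reference.
#' @return invisibly, list with `contrasts`, `summary`, `fits_a`, `fits_b`.
#' @export
run_contrast <- function(config, im = NULL, condition_a = "healthy",
                         condition_b = "disease") {
  stopifnot(inherits(config, "zonemap_config"))
  if (is.null(im)) {
    if (is.null(config$matrix_tsv) || is.null(config$meta_tsv))
      zn_stop("run_contrast needs matrix_tsv and meta_tsv (or an intensity_matrix)")
    im <- read_intensity_table(config$matrix_tsv, config$meta_tsv)
  }
  for (cond in c(condition_a, condition_b))
    if (!cond %in% im$meta$condition)
      zn_stop(sprintf("condition label '%s' not present in metadata", cond))
  fit_cond <- function(cond) {
    sub <- im_subset(im, samples = im$meta$condition == cond)
    sub <- filter_protein_completeness(sub, config$completeness)
    fit_gradients(sub, strong_beta = config$strong_beta, alpha = config$alpha,
                  tukey_k = config$tukey_k)
  }
  fits_a <- fit_cond(condition_a)
  fits_b <- fit_cond(condition_b)
  contrasts <- contrast_conditions(fits_a, fits_b,
                                   loss_delta = config$loss_delta,
                                   alpha = config$alpha)
  summ <- zonation_summary(contrasts)
  message(sprintf("contrast %s vs %s: %d proteins in scope, %d loss calls",
                  condition_a, condition_b, nrow(contrasts),
                  sum(contrasts$loss)))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  data.table::fwrite(as.data.frame(contrasts),
                     file.path(config$out_dir, "contrasts.tsv"), sep = "\t")
  data.table::fwrite(summ$table,
                     file.path(config$out_dir, "contrast_summary.tsv"),
                     sep = "\t")
  invisible(list(contrasts = contrasts, summary = summ, fits_a = fits_a,
                 fits_b = fits_b))
}
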