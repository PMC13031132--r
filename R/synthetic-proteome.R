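# Synthetic single-cell proteome matrices generated from the same
# random-intercept model that the gradient fitter estimates:
#   y_ij = beta0 + beta1 * S_ij + u_i + e_ij,  u_i ~ N(0, sigma_u^2),
#   e_ij ~ N(0, sigma_e^2),
# with per-protein slopes, per-patient random intercepts and logistic
# intensity-dependent (MNAR) dropout on the standardized latent value.

#' Specify a synthetic proteome cohort
#'
#' Defaults mirror the study design the package targets: 14 patients with 44
#' cells each along one trajectory, a few hundred proteins of which roughly a
#' third carry a spatial gradient, patient baseline shifts of s.d. 0.5 and
#' residual noise of s.d. 0.3 on the normalized intensity scale.
#'
#' @param n_patients number of patients (trajectories).
#' @param cells_per_patient cells selected per trajectory (default 44).
#' @param n_proteins number of proteins.
#' @param frac_zonated fraction of proteins with a true nonzero slope.
#' @param beta1_range range of |beta1| for zonated proteins; the sign is
#'   drawn at random (positive = portal-enriched under the 0 = central
#'   orientation).
#' @param beta0_mean,beta0_sd distribution of the fixed intercepts.
#' @param sigma_u s.d. of the patient random intercepts.
#' @param sigma_e residual s.d.
#' @param dropout_midpoint,dropout_slope logistic MNAR parameters acting on
#'   the per-protein standardized latent intensity: an entry with standardized
#'   value z is observed with probability `plogis((z - midpoint) * slope)`.
#'   `dropout_midpoint = -Inf` disables dropout entirely (every entry
#'   observed). The default (-2, 1) gives ~88% observed with missingness
#'   concentrated in low-intensity entries.
#' @param attenuation multiplicative factor applied to beta1 for patients in
#'   the "disease" condition (1 = no change, 0 = complete gradient loss).
#' @param n_disease number of patients (the last ones) labelled "disease";
#'   the rest are "healthy".
#' @param seed integer seed; fully determines the cohort.
#' @return object of class `proteome_spec`.
#' @export
proteome_spec <- function(n_patients = 14L, cells_per_patient = 44L,
                          n_proteins = 200L, frac_zonated = 0.3,
                          beta1_range = c(0.5, 2), beta0_mean = 20,
                          beta0_sd = 1, sigma_u = 0.5, sigma_e = 0.3,
                          dropout_midpoint = -2, dropout_slope = 1,
                          attenuation = 1, n_disease = 0L, seed = 1L) {
  if (frac_zonated < 0 || frac_zonated > 1) zn_stop("frac_zonated must be in [0, 1]")
  if (sigma_u < 0 || sigma_e < 0) zn_stop("sigma_u and sigma_e must be >= 0")
  if (n_disease > n_patients) zn_stop("n_disease cannot exceed n_patients")
  if (length(beta1_range) != 2L || any(beta1_range < 0) || diff(beta1_range) < 0)
    zn_stop("beta1_range must be an increasing nonnegative pair")
  structure(as.list(environment()), class = "proteome_spec")
}

#' Generate a synthetic intensity matrix with ground truth
#'
#' @param spec a [proteome_spec()].
#' @param S optional vector of spatial ratios, either one per cell
#'   (`n_patients * cells_per_patient`) or one per within-trajectory position
#'   (`cells_per_patient`, reused for every patient). Default: uniform draws
#'   on [0, 1].
#' @return list with `matrix` (an [intensity_matrix()]) and `truth`, a list
#'   holding per-protein `beta0`, `beta1` (pre-attenuation), `zonated`,
#'   per-(protein, patient) random intercepts `u`, the per-cell `S`, patient
#'   `conditions`, and the full pre-dropout `latent` matrix. Every observed
#'   matrix entry equals its latent value; missing entries are NA.
#' @export
generate_proteome <- function(spec, S = NULL) {
  stopifnot(inherits(spec, "proteome_spec"))
  n_cells <- spec$n_patients * spec$cells_per_patient
  with_rng(spec$seed, {
    if (is.null(S)) S <- stats::runif(n_cells)
    if (length(S) == spec$cells_per_patient) S <- rep(S, spec$n_patients)
    if (length(S) != n_cells) zn_stop("S must have one value per cell")
    if (any(S < 0 | S > 1)) zn_stop("S values must lie in [0, 1]")

    patient <- rep(sprintf("P%02d", seq_len(spec$n_patients)),
                   each = spec$cells_per_patient)
    condition <- rep(c(rep("healthy", spec$n_patients - spec$n_disease),
                       rep("disease", spec$n_disease)),
                     each = spec$cells_per_patient)

    P <- spec$n_proteins
    zonated <- seq_len(P) <= round(spec$frac_zonated * P)
    beta1 <- numeric(P)
    beta1[zonated] <- sample(c(-1, 1), sum(zonated), replace = TRUE) *
      stats::runif(sum(zonated), spec$beta1_range[1], spec$beta1_range[2])
    beta0 <- stats::rnorm(P, spec$beta0_mean, spec$beta0_sd)
    u <- matrix(stats::rnorm(P * spec$n_patients, 0, spec$sigma_u),
                P, spec$n_patients,
                dimnames = list(NULL, unique(patient)))

    slope_eff <- outer(beta1, ifelse(condition == "disease", spec$attenuation, 1))
    latent <- beta0 + slope_eff * rep(S, each = P) + u[, patient] +
      matrix(stats::rnorm(P * n_cells, 0, spec$sigma_e), P, n_cells)

    observed <- latent
    if (is.finite(spec$dropout_midpoint)) {
      z <- t(scale(t(latent)))
      p_obs <- stats::plogis((z - spec$dropout_midpoint) * spec$dropout_slope)
      drop <- matrix(stats::runif(length(p_obs)) > p_obs, P, n_cells)
      observed[drop] <- NA_real_
    } else if (spec$dropout_midpoint > 0) {
      observed[] <- NA_real_
    }

    protein_ids <- sprintf("PROT_%04d", seq_len(P))
    sample_ids <- sprintf("%s_c%02d", patient,
                          rep(seq_len(spec$cells_per_patient), spec$n_patients))
    dimnames(observed) <- list(protein_ids, sample_ids)
    dimnames(latent) <- dimnames(observed)
    meta <- data.frame(sample_id = sample_ids, patient_id = patient,
                       condition = condition, S = S,
                       stringsAsFactors = FALSE)
    list(matrix = intensity_matrix(observed, meta),
         truth = list(beta0 = beta0, beta1 = beta1, zonated = zonated,
                      u = u, S = S, conditions = condition, latent = latent,
                      protein_ids = protein_ids))
  })
}

#' Protein intensity matrix with per-sample metadata
#'
#' The central data container: a proteins x samples numeric matrix (NA =
#' missing / not detected) plus a metadata table carrying, for every sample,
#' the patient it came from, its condition label and its spatial ratio S
#' along the porto-central axis.
#'
#' @param values numeric matrix with protein row names and sample column
#'   names; zeros are recoded to NA (not detected).
#' @param meta data.frame with columns `sample_id`, `patient_id`,
#'   `condition`, `S`; must cover exactly the matrix columns.
#' @return object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, meta) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    zn_stop("values must have protein row names and sample column names")
  if (anyDuplicated(rownames(values)))
    zn_stop(paste("duplicate protein ids:",
                  paste(unique(rownames(values)[duplicated(rownames(values))]),
                        collapse = ", ")))
  if (anyDuplicated(colnames(values))) zn_stop("duplicate sample ids")
  need <- c("sample_id", "patient_id", "condition", "S")
  miss <- setdiff(need, names(meta))
  if (length(miss)) zn_stop(paste("metadata lacks columns:", paste(miss, collapse = ", ")))
  only_m <- setdiff(colnames(values), meta$sample_id)
  only_d <- setdiff(meta$sample_id, colnames(values))
  if (length(only_m) || length(only_d))
    zn_stop(paste0("matrix/metadata sample mismatch;",
                   if (length(only_m)) paste0(" missing metadata for: ",
                                              paste(only_m, collapse = ", ")),
                   if (length(only_d)) paste0(" metadata without matrix column: ",
                                              paste(only_d, collapse = ", "))))
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (any(!is.na(meta$S) & (meta$S < 0 | meta$S > 1)))
    zn_stop("spatial ratio S must lie in [0, 1]")
  if (any(is.na(meta$patient_id) | !nzchar(meta$patient_id)))
    zn_stop("patient_id must be non-empty for every sample")
  values[!is.na(values) & values == 0] <- NA_real_
  structure(list(values = values, meta = meta), class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  obs <- mean(!is.na(x$values))
  cat(sprintf("<intensity_matrix: %d proteins x %d samples, %d patients, %.1f%% observed>\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$meta$patient_id)), 100 * obs))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Subset an intensity matrix by proteins and/or samples
#' @param x an [intensity_matrix()].
#' @param proteins,samples character or logical/integer index vectors.
#' @export
im_subset <- function(x, proteins = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(proteins)) v <- v[proteins, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  intensity_matrix(v, x$meta[match(colnames(v), x$meta$sample_id), , drop = FALSE])
}
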