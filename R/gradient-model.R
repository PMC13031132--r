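# Continuous gradient mapping: per-protein preprocessing (Tukey fences,
# robust scaling), random-intercept linear mixed model
#   y_ij = beta0 + beta1 * S_ij + u_i + e_ij
# fitted per protein with the spatial ratio S as predictor and a random
# intercept u_i per patient, Wald inference on the zonation coefficient
# beta1, Benjamini-Hochberg correction, zonation classification, and
# cross-condition delta-beta1 contrasts.

#' Remove outliers by Tukey's fences
#'
#' Drops values outside [Q1 - k IQR, Q3 + k IQR]. Quartiles use linear
#' interpolation (R's default type-7 convention); with zero IQR the fences
#' collapse onto the quartiles and nothing beyond ties is removed.
#'
#' @param x numeric vector with at least 4 finite values.
#' @param k fence multiplier (default 1.5).
#' @return the values inside the fences, preserving names and order.
#' @export
tukey_fence_filter <- function(x, k = 1.5) {
  fin <- is.finite(x)
  if (sum(fin) < 4L) zn_stop("Tukey fences need at least 4 finite values")
  q <- stats::quantile(x[fin], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  x[fin & x >= q[1] - k * iqr & x <= q[2] + k * iqr]
}

#' Robust scaling: centre on the median, divide by the IQR
#'
#' @param x numeric vector; the interquartile range must be positive.
#' @return (x - median) / IQR.
#' @export
robust_scale <- function(x) {
  fin <- is.finite(x)
  med <- stats::median(x[fin])
  iqr <- diff(stats::quantile(x[fin], c(0.25, 0.75), type = 7, names = FALSE))
  if (iqr <= 0)
    zn_stop("zero interquartile range: cannot robust-scale",
            class = "zn_numeric_error")
  (x - med) / iqr
}

#' Fit the random-intercept gradient model for one protein
#'
#' Fits y ~ S with a random intercept per patient by REML (lme4), falling
#' back to ML and finally flagging the fit on non-convergence. The Wald
#' statistic z = beta1 / SE(beta1) is referred to the standard normal for a
#' two-sided p value. A boundary fit with zero patient variance is a valid
#' result. With a single patient the model degenerates to ordinary least
#' squares.
#'
#' @param y response values (e.g. robust-scaled intensities).
#' @param S spatial ratios, same length as `y`.
#' @param patient patient ids, same length as `y`.
#' @param reml use REML (default) or ML.
#' @return one-row data.frame: beta0, beta1, se_beta1, sigma_u2, sigma2,
#'   n_cells, n_patients, z, p, converged.
#' @export
fit_lmm <- function(y, S, patient, reml = TRUE) {
  keep <- is.finite(y) & is.finite(S) & !is.na(patient)
  y <- y[keep]; S <- S[keep]; patient <- factor(patient[keep])
  n <- length(y); npat <- nlevels(patient)
  fail <- function() data.frame(beta0 = NA_real_, beta1 = NA_real_,
                                se_beta1 = NA_real_, sigma_u2 = NA_real_,
                                sigma2 = NA_real_, n_cells = n,
                                n_patients = npat, z = NA_real_, p = NA_real_,
                                converged = FALSE)
  if (n < 3L || length(unique(S)) < 2L) return(fail())
  if (npat == 1L) {
    m <- stats::lm(y ~ S)
    cf <- summary(m)$coefficients
    beta1 <- cf["S", "Estimate"]; se <- cf["S", "Std. Error"]
    z <- beta1 / se
    return(data.frame(beta0 = cf["(Intercept)", "Estimate"], beta1 = beta1,
                      se_beta1 = se, sigma_u2 = 0,
                      sigma2 = summary(m)$sigma^2, n_cells = n,
                      n_patients = 1L, z = z, p = 2 * stats::pnorm(-abs(z)),
                      converged = TRUE))
  }
  fit_once <- function(use_reml) {
    tryCatch(
      suppressMessages(lme4::lmer(
        y ~ S + (1 | patient), REML = use_reml,
        control = lme4::lmerControl(calc.derivs = FALSE))),
      error = function(e) NULL, warning = function(w) NULL)
  }
  m <- fit_once(reml)
  if (is.null(m)) m <- fit_once(!reml)
  if (is.null(m)) return(fail())
  fe <- lme4::fixef(m)
  se <- sqrt(diag(as.matrix(stats::vcov(m))))
  vc <- lme4::VarCorr(m)
  z <- fe[["S"]] / se[["S"]]
  data.frame(beta0 = fe[["(Intercept)"]], beta1 = fe[["S"]],
             se_beta1 = se[["S"]],
             sigma_u2 = as.numeric(vc$patient[1L]),
             sigma2 = attr(vc, "sc")^2, n_cells = n, n_patients = npat,
             z = z, p = 2 * stats::pnorm(-abs(z)), converged = TRUE)
}

#' Benjamini-Hochberg adjusted Q values
#'
#' Step-up false-discovery-rate correction (a thin wrapper over
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p vector of p values in [0, 1].
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) zn_stop("p values must be finite in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fit zonation gradients for every protein of a matrix
#'
#' Per protein: observed cells are taken across the whole analyzed cohort,
#' outliers are removed by Tukey's fences, intensities are robust-scaled
#' (median removed, IQR divided), and the random-intercept model is fitted
#' on the scaled values against S. Q values are Benjamini-Hochberg adjusted
#' over all converged fits, and each protein is classified by direction and
#' strength. Proteins with zero IQR, degenerate S or too few cells are
#' skipped with a logged reason.
#'
#' @param im an [intensity_matrix()] (typically after sample QC and the
#'   completeness filter).
#' @param preprocess apply Tukey fences + robust scaling (default TRUE); set
#'   FALSE to fit raw values, e.g. for calibration studies on synthetic data.
#' @param reml passed to [fit_lmm()].
#' @param tukey_k fence multiplier.
#' @param strong_beta,alpha thresholds for the "strong" call
#'   (|beta1| > strong_beta and Q < alpha).
#' @return data.frame of class `gradient_fits`: one row per protein with the
#'   [fit_lmm()] fields plus protein_id, Q, direction, significant, strong,
#'   reason.
#' @export
fit_gradients <- function(im, preprocess = TRUE, reml = TRUE, tukey_k = 1.5,
                          strong_beta = 1, alpha = 0.05) {
  S_all <- im$meta$S; pat_all <- im$meta$patient_id
  rows <- lapply(seq_len(nrow(im$values)), function(i) {
    v <- im$values[i, ]
    obs <- which(is.finite(v))
    base <- data.frame(protein_id = rownames(im$values)[i], beta0 = NA_real_,
                       beta1 = NA_real_, se_beta1 = NA_real_,
                       sigma_u2 = NA_real_, sigma2 = NA_real_,
                       n_cells = length(obs), n_patients = NA_integer_,
                       z = NA_real_, p = NA_real_, converged = FALSE,
                       reason = "", stringsAsFactors = FALSE)
    if (length(obs) < 4L) { base$reason <- "too_few_cells"; return(base) }
    y <- v[obs]; S <- S_all[obs]; pat <- pat_all[obs]
    if (preprocess) {
      kept <- tukey_fence_filter(y, k = tukey_k)
      idx <- which(names(y) %in% names(kept))
      y <- y[idx]; S <- S[idx]; pat <- pat[idx]
      y <- tryCatch(robust_scale(y), zn_numeric_error = function(e) NULL)
      if (is.null(y)) { base$reason <- "zero_iqr"; return(base) }
    }
    if (length(unique(S)) < 2L) { base$reason <- "degenerate_S"; return(base) }
    ft <- fit_lmm(y, S, pat, reml = reml)
    out <- cbind(data.frame(protein_id = base$protein_id,
                            stringsAsFactors = FALSE), ft)
    out$reason <- if (ft$converged) "" else "non_convergence"
    out
  })
  fits <- do.call(rbind, rows)
  fits$Q <- NA_real_
  conv <- fits$converged & is.finite(fits$p)
  fits$Q[conv] <- bh_adjust(fits$p[conv])
  fits <- cbind(fits, classify_zonation(fits, strong_beta = strong_beta,
                                        alpha = alpha))
  class(fits) <- c("gradient_fits", "data.frame")
  fits
}

#' Classify zonation direction and strength
#'
#' Direction follows the sign of the zonation coefficient: negative beta1
#' means enrichment towards the central vein (S = 0), positive towards the
#' portal vein (S = 1). A protein is significant at Q < `alpha` and
#' "strongly zonated" when additionally |beta1| > `strong_beta`.
#'
#' @param fits data.frame with columns beta1 and Q (e.g. from
#'   [fit_gradients()]).
#' @param strong_beta,alpha call thresholds (defaults 1 and 0.05).
#' @return data.frame with columns direction ("central", "portal", "none"),
#'   significant, strong.
#' @export
classify_zonation <- function(fits, strong_beta = 1, alpha = 0.05) {
  direction <- ifelse(is.na(fits$beta1) | fits$beta1 == 0, "none",
                      ifelse(fits$beta1 < 0, "central", "portal"))
  significant <- !is.na(fits$Q) & fits$Q < alpha
  strong <- significant & !is.na(fits$beta1) & abs(fits$beta1) > strong_beta
  data.frame(direction = direction, significant = significant,
             strong = strong, stringsAsFactors = FALSE)
}

#' Contrast zonation coefficients between two conditions
#'
#' For each protein in scope, the difference of zonation coefficients
#' delta = beta1(A) - beta1(B) is tested against zero with a Wald test,
#' SE(delta) = sqrt(SE_A^2 + SE_B^2), z = delta / SE referred to the
#' standard normal; Q values are Benjamini-Hochberg adjusted over the scoped
#' set. A protein "loses" its gradient when |delta| > `loss_delta` and
#' Q < `alpha`. By default the scope is the strongly zonated proteins of
#' condition A (the reference/control condition); scoped proteins absent or
#' unconverged in B are reported as not detected.
#'
#' @param fits_a,fits_b `gradient_fits` for the two conditions.
#' @param scope protein ids to contrast; default: strong in A.
#' @param loss_delta,alpha loss-call thresholds (defaults 1 and 0.05).
#' @return data.frame of class `condition_contrast`: protein_id,
#'   direction_a, beta1_a, beta1_b, delta_beta1, se_delta, z, p, Q,
#'   detected, loss.
#' @export
contrast_conditions <- function(fits_a, fits_b, scope = NULL, loss_delta = 1,
                                alpha = 0.05) {
  if (is.null(scope)) scope <- fits_a$protein_id[fits_a$strong]
  if (!length(scope)) zn_stop("empty contrast scope: no proteins to compare")
  a <- fits_a[match(scope, fits_a$protein_id), , drop = FALSE]
  if (any(is.na(a$protein_id))) zn_stop("scope proteins missing from fits_a")
  bi <- match(scope, fits_b$protein_id)
  detected <- !is.na(bi) & fits_b$converged[pmax(bi, 1L)] %in% TRUE
  b <- fits_b[pmax(bi, 1L), , drop = FALSE]
  delta <- ifelse(detected, a$beta1 - b$beta1, NA_real_)
  se <- ifelse(detected, sqrt(a$se_beta1^2 + b$se_beta1^2), NA_real_)
  z <- delta / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(protein_id = scope, direction_a = a$direction,
                    beta1_a = a$beta1,
                    beta1_b = ifelse(detected, b$beta1, NA_real_),
                    delta_beta1 = delta, se_delta = se, z = z, p = p,
                    Q = NA_real_, detected = detected,
                    stringsAsFactors = FALSE)
  ok <- detected & is.finite(p)
  out$Q[ok] <- bh_adjust(p[ok])
  out$loss <- !is.na(out$Q) & out$Q < alpha & abs(out$delta_beta1) > loss_delta
  class(out) <- c("condition_contrast", "data.frame")
  out
}

#' Summarize gradient changes per zonation direction
#'
#' For the centrally and portally enriched proteins (direction in the
#' reference condition), reports the median absolute coefficient change, the
#' counts and fractions lost / maintained / not detected, and a two-sided
#' unpaired rank-sum (Wilcoxon) test comparing |delta_beta1| between the two
#' directions.
#'
#' @param contrasts a `condition_contrast` from [contrast_conditions()].
#' @return list with `table` (one row per direction) and `rank_sum_p`.
#' @export
zonation_summary <- function(contrasts) {
  dirs <- c("central", "portal")
  tab <- do.call(rbind, lapply(dirs, function(d) {
    sub <- contrasts[contrasts$direction_a == d, , drop = FALSE]
    det <- sub[sub$detected, , drop = FALSE]
    data.frame(direction = d, n = nrow(sub),
               n_detected = nrow(det),
               n_not_detected = sum(!sub$detected),
               n_loss = sum(det$loss),
               n_maintained = sum(!det$loss),
               median_abs_delta = if (nrow(det)) stats::median(abs(det$delta_beta1)) else NA_real_,
               frac_loss = if (nrow(sub)) sum(det$loss) / nrow(sub) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  xc <- abs(contrasts$delta_beta1[contrasts$direction_a == "central" & contrasts$detected])
  xp <- abs(contrasts$delta_beta1[contrasts$direction_a == "portal" & contrasts$detected])
  rank_sum_p <- if (!length(xc) || !length(xp)) {
    NA_real_
  } else if (length(unique(c(xc, xp))) == 1L) {
    1  # all absolute changes identical: no evidence of asymmetry
  } else {
    suppressWarnings(stats::wilcox.test(xc, xp, alternative = "two.sided",
                                        paired = FALSE)$p.value)
  }
  list(table = tab, rank_sum_p = rank_sum_p)
}
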