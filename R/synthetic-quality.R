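# Synthetic per-scan quality metrics with a configured standardized
# regression structure on the cohort covariates.

#' Standardized covariate design matrix
#'
#' Builds the seven-column predictor matrix used throughout the regression
#' analyses: age, sex, education, BMI, diabetes status, CVD history, and
#' log10-transformed relative WMH volume, each z-scored against the sample.
#'
#' @param cohort a cohort data.frame (see [generate_cohort()]).
#' @return numeric matrix with columns `age, sex, education, bmi, diabetes,
#'   cvd, log_wmh`.
#' @export
covariate_zmatrix <- function(cohort) {
  need <- c("age", "sex", "education", "bmi", "diabetes", "cvd", "wmh_rel")
  if (!all(need %in% names(cohort))) {
    stop("cohort is missing columns: ",
         paste(setdiff(need, names(cohort)), collapse = ", "), call. = FALSE)
  }
  if (any(cohort$wmh_rel <= 0)) {
    stop("wmh_rel must be positive (log10-transformed before modelling)",
         call. = FALSE)
  }
  z <- cbind(
    age = zscore(cohort$age, "age"),
    sex = zscore(cohort$sex, "sex"),
    education = zscore(cohort$education, "education"),
    bmi = zscore(cohort$bmi, "bmi"),
    diabetes = zscore(cohort$diabetes, "diabetes"),
    cvd = zscore(cohort$cvd, "cvd"),
    log_wmh = zscore(log10(cohort$wmh_rel), "log_wmh")
  )
  z
}

#' Generate synthetic quality metrics
#'
#' For each modality (dMRI, rs-fMRI) and each quality metric (iSNR, head
#' motion, atlas mismatch), the standardized metric is generated as
#' `sum_k beta_k * z(covariate_k) + residual`, with the residual SD chosen
#' so the standardized outcome has unit variance; the metric is then
#' rescaled linearly to its configured observed mean and SD. Residuals are
#' drawn jointly across the six metrics: for each configured target
#' correlation (`quality_cor_targets`, e.g. the rs-fMRI iSNR-motion
#' correlation), the generator solves for the residual correlation that --
#' combined with the covariate-induced covariance -- produces the target on
#' the observed scale.
#'
#' A positive `noise_scales$motion_skew` applies a mean/SD-preserving
#' exponential tilt to the motion metrics, giving them the right-skewed tail
#' seen in real realignment data (used by the high-motion exclusion
#' analysis); the default of 0 keeps the metrics Gaussian so that refitted
#' coefficients are unattenuated.
#'
#' @param cohort a cohort data.frame from [generate_cohort()].
#' @param config the [qc_config()] that generated the cohort.
#' @return data.frame with `participant_id` and columns
#'   `{dmri,fmri}_{isnr,motion,mismatch}` on their observed scales (mm for
#'   motion; unitless otherwise; iSNR is negative).
#' @export
generate_quality <- function(cohort, config) {
  stopifnot(inherits(config, "qc_config"))
  if (nrow(cohort) < 2) stop("cohort must be nonempty (n >= 2)", call. = FALSE)
  z <- covariate_zmatrix(cohort)
  n <- nrow(z)
  metrics <- quality_metric_names()
  # linear predictors and unit-variance-completing residual SDs
  lin <- matrix(0, n, length(metrics), dimnames = list(NULL, metrics))
  sd_e <- setNames(numeric(length(metrics)), metrics)
  for (mod in MODALITIES) {
    for (met in QUALITY_NAMES) {
      key <- paste0(mod, "_", met)
      beta <- config$quality_coeffs[[mod]][[met]]
      lin[, key] <- z %*% beta
      s2 <- stats::var(lin[, key])
      if (s2 >= 1) {
        stop("quality coefficient set ", mod, "/", met, " implies explained ",
             "variance ", round(s2, 3), " >= 1 under the covariate ",
             "correlation structure; residual variance would be negative",
             call. = FALSE)
      }
      rs <- config$noise_scales$quality_resid
      sd_e[key] <- if (identical(rs, "auto")) sqrt(1 - s2) else as.numeric(rs)
    }
  }
  # residual correlation matrix solving for the target observed correlations
  R <- diag(length(metrics))
  dimnames(R) <- list(metrics, metrics)
  tg <- config$quality_cor_targets
  for (i in seq_len(nrow(tg))) {
    m1 <- tg$metric1[i]; m2 <- tg$metric2[i]
    if (sd_e[m1] == 0 || sd_e[m2] == 0) next
    cov_lin <- stats::cov(lin[, m1], lin[, m2])
    rho <- (tg$r[i] - cov_lin) / (sd_e[m1] * sd_e[m2])
    if (abs(rho) > 0.999) {
      warning("residual correlation for ", m1, "-", m2,
              " clamped to +/-0.999", call. = FALSE)
      rho <- sign(rho) * 0.999
    }
    R[m1, m2] <- R[m2, m1] <- rho
  }
  with_seed(split_seed(config$seed, 2L), {
    eps <- matrix(rnorm(n * length(metrics)), n)
    eps <- eps %*% chol(R)   # unit-variance residuals with correlation R
    out <- data.frame(participant_id = cohort$participant_id,
                      stringsAsFactors = FALSE)
    skew <- config$noise_scales$motion_skew
    for (key in metrics) {
      x <- lin[, key] + sd_e[key] * eps[, match(key, metrics)]
      if (grepl("_motion$", key) && skew > 0) x <- skew_tilt(x, skew)
      parts <- strsplit(key, "_")[[1]]
      sc <- config$quality_scale[[parts[1]]][[parts[2]]]
      out[[key]] <- sc[["mean"]] + sc[["sd"]] * x
    }
    attr(out, "residual_sd") <- sd_e
    attr(out, "residual_cor") <- R
    out
  })
}

# mean/SD-preserving exponential tilt of a ~N(0,1) variable; returns a
# right-skewed variable with mean 0 and SD 1 (exact for exactly standard
# normal input)
skew_tilt <- function(x, s) {
  m <- exp(s^2 / 2)
  v <- sqrt((exp(s^2) - 1) * exp(s^2))
  (exp(s * x) - m) / v
}
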