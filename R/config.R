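# Generator configuration: covariate distributions, standardized
# coefficient sets, calibration targets, and noise scales. The default
# values are calibrated to the published characteristics of a large
# population-based brain-MRI cohort (ages 40-75, type 2 diabetes
# oversampled), so that data generated from the default preset reproduces
# the printed covariate distributions and quality-metric regression
# structure of that study.

COVARIATE_NAMES <- c("age", "sex", "education", "bmi", "diabetes", "cvd",
                     "log_wmh")
QUALITY_NAMES <- c("isnr", "motion", "mismatch")
MODALITIES <- c("dmri", "fmri")

# modality-major column names: dmri_isnr, dmri_motion, ..., fmri_mismatch
quality_metric_names <- function() {
  paste0(rep(MODALITIES, each = length(QUALITY_NAMES)), "_",
         rep(QUALITY_NAMES, length(MODALITIES)))
}

#' Synthetic-cohort generator configuration
#'
#' Builds the configuration object consumed by [generate_cohort()],
#' [generate_quality()] and [generate_connectomes()]. All randomness flows
#' from the single `seed` via a fixed stream-splitting scheme
#' ([split_seed()]), so identical configurations give byte-identical
#' outputs.
#'
#' The coefficient sets are *standardized* regression coefficients: each
#' quality metric (and each modality's overall connectivity) is generated on
#' the z-scale as a linear combination of the z-scored covariates (plus, for
#' connectivity, the z-scored quality metrics) with independent Gaussian
#' noise whose variance completes the outcome to unit variance. Refitting
#' the same regression on generated data therefore recovers the configured
#' coefficients up to sampling error.
#'
#' @param n number of participants.
#' @param seed root seed (integer).
#' @param preset `"maastricht"` (default; calibrated to the published cohort
#'   values) or `"null"` (all coefficients zero, degenerate template -- every
#'   generated outcome is independent of the covariates).
#' @param ... named overrides of top-level config fields (e.g.
#'   `covariate_params`, `quality_coeffs`, `noise_scales`).
#' @return an object of class `qc_config`.
#' @examples
#' cfg <- qc_config(n = 100, seed = 7)
#' cohort <- generate_cohort(cfg)
#' @export
qc_config <- function(n = 5110, seed = 1L,
                      preset = c("maastricht", "null"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    n = as.integer(n),
    seed = as.integer(seed),
    preset = preset,
    covariate_params = list(
      age = list(mean = 59.4, sd = 8.7, min = 40, max = 75),
      sex = list(p_female = 0.494),           # coding: 0 = male, 1 = female
      education = list(p = c(low = 0.320, middle = 0.284, high = 0.397)),
      bmi = list(mean = 26.6, sd = 4.2),
      diabetes = list(p = c(no = 0.641, prediabetes = 0.147,
                            t2dm = 0.206, other = 0.006)),
      cvd = list(p_yes = 0.126),
      wmh = list(median = 0.016, q25 = 0.005, q75 = 0.050),  # % of ICV
      age_wmh_cor = 0.4
    ),
    # standardized coefficients of each quality metric on the seven
    # covariates (order: age, sex, education, bmi, diabetes, cvd, log_wmh)
    quality_coeffs = list(
      dmri = list(
        isnr     = c(0.117, -0.071, -0.017, 0.067, 0.032, 0.004, -0.038),
        motion   = c(0.368, -0.279,  0.001, 0.028, 0.095, 0.020,  0.048),
        mismatch = c(0.056, -0.303, -0.009, 0.093, -0.023, 0.009, 0.017)
      ),
      fmri = list(
        isnr     = c(0.170, -0.027, -0.044, 0.408, 0.096, -0.012, 0.030),
        motion   = c(0.079, -0.071, -0.010, 0.321, 0.024, -0.004, -0.016),
        mismatch = c(-0.088, 0.317, -0.003, -0.113, -0.020, 0.004, 0.013)
      )
    ),
    # observed-scale location/spread each standardized metric is mapped to
    # (iSNR is the negative of the SNR, hence the negative means)
    quality_scale = list(
      dmri = list(isnr = c(mean = -22, sd = 6.5),
                  motion = c(mean = 0.64, sd = 0.16),
                  mismatch = c(mean = 0.087, sd = 0.0092)),
      fmri = list(isnr = c(mean = -39, sd = 11),
                  motion = c(mean = 0.13, sd = 0.088),
                  mismatch = c(mean = 0.089, sd = 0.0086))
    ),
    # target observed correlations between quality metrics; the generator
    # solves for the residual correlation that, combined with the
    # covariate-induced covariance, yields these values
    quality_cor_targets = data.frame(
      metric1 = c("dmri_isnr", "fmri_isnr"),
      metric2 = c("dmri_motion", "fmri_motion"),
      r = c(0.298, 0.522),
      stringsAsFactors = FALSE
    ),
    # standardized Model-2 coefficients driving each participant's overall
    # connectivity (7 covariates then the modality's isnr, motion, mismatch)
    connectivity_coeffs = list(
      sc = c(-0.074, 0.213, -0.045, 0.109, 0.003, -0.010, 0.048,
             -0.120, -0.249, 0.021),
      fc = c(0.015, -0.062, 0.014, -0.008, -0.030, -0.017, -0.027,
             -0.082, 0.048, 0.027)
    ),
    connectivity_scale = list(
      sc = c(mean = 5.3e-3, sd = 0.6e-3),
      fc = c(mean = 0.32, sd = 0.03)
    ),
    noise_scales = list(
      # residual SDs: "auto" completes each standardized outcome to unit
      # variance given the configured coefficients
      quality_resid = "auto",
      connectivity_resid = "auto",
      sc_edge_sdlog = 0.4,   # log-normal multiplicative edge noise (SC)
      fc_edge_sd = 0.04,     # additive clipped edge noise (FC)
      motion_skew = 0        # right-skew knob for the motion metrics
    ),
    template = list(
      seed = 42L,
      n_regions = 94L,
      presence = "stochastic",
      # logistic distance-decay of edge probability; intra-hemispheric
      # connections decay later than inter-hemispheric ones
      d0_intra = 0.495, d0_inter = 0.455, slope = 0.036,
      weight_tau = 0.35
    )
  )
  if (preset == "null") {
    cfg$quality_coeffs <- lapply(cfg$quality_coeffs, function(m)
      lapply(m, function(b) b * 0))
    cfg$connectivity_coeffs <- lapply(cfg$connectivity_coeffs,
                                      function(b) b * 0)
    cfg$quality_cor_targets$r <- c(0, 0)
    cfg$covariate_params$age_wmh_cor <- 0
    cfg$noise_scales$sc_edge_sdlog <- 0
    cfg$noise_scales$fc_edge_sd <- 0
    cfg$noise_scales$connectivity_resid <- 0
    cfg$template$presence <- "deterministic"
  }
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm, call. = FALSE)
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]], keep.null = TRUE)
  }
  validate_qc_config(structure(cfg, class = "qc_config"))
}

validate_qc_config <- function(cfg) {
  cp <- cfg$covariate_params
  for (p in list(cp$sex$p_female, cp$cvd$p_yes)) stop_if_not_prob(p, "proportion")
  for (pr in list(cp$education$p, cp$diabetes$p)) {
    stop_if_not_prob(pr, "proportions")
    if (abs(sum(pr) - 1) > 0.01) {
      stop("category proportions must sum to 1 (got ", sum(pr), ")",
           call. = FALSE)
    }
  }
  stopifnot(cp$age$min < cp$age$max, cp$wmh$median > 0,
            cp$wmh$q25 > 0, cp$wmh$q75 >= cp$wmh$q25)
  for (mod in MODALITIES) {
    for (met in QUALITY_NAMES) {
      b <- cfg$quality_coeffs[[mod]][[met]]
      if (length(b) != length(COVARIATE_NAMES)) {
        stop("quality coefficient set ", mod, "/", met,
             " must name exactly the ", length(COVARIATE_NAMES),
             " covariates", call. = FALSE)
      }
    }
  }
  for (mod in c("sc", "fc")) {
    b <- cfg$connectivity_coeffs[[mod]]
    if (length(b) != length(COVARIATE_NAMES) + 3) {
      stop("connectivity coefficient set '", mod, "' must name the ",
           length(COVARIATE_NAMES), " covariates plus 3 quality metrics",
           call. = FALSE)
    }
  }
  cfg
}

#' @export
print.qc_config <- function(x, ...) {
  cat("<qc_config> preset '", x$preset, "', n = ", x$n, ", seed = ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Read / write generator configurations as YAML
#'
#' Round-trips a [qc_config()] through a plain-text YAML file. Two presets
#' ship with the package: `maastricht.cfg` (the calibrated cohort) and
#' `null.cfg` (all coefficients zero); see
#' `system.file("extdata", package = "connqc")`.
#'
#' @param cfg a `qc_config`.
#' @param path file path.
#' @return `read_qc_config` returns a `qc_config`.
#' @export
write_qc_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "qc_config"))
  out <- unclass(cfg)
  out$quality_cor_targets <- as.list(out$quality_cor_targets)
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' @rdname write_qc_config
#' @export
read_qc_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$quality_cor_targets <- as.data.frame(raw$quality_cor_targets,
                                           stringsAsFactors = FALSE)
  for (mod in MODALITIES) raw$quality_coeffs[[mod]] <-
    lapply(raw$quality_coeffs[[mod]], as.numeric)
  raw$connectivity_coeffs <- lapply(raw$connectivity_coeffs, as.numeric)
  for (mod in MODALITIES) raw$quality_scale[[mod]] <-
    lapply(raw$quality_scale[[mod]], function(v)
      setNames(as.numeric(v), c("mean", "sd")))
  raw$connectivity_scale <- lapply(raw$connectivity_scale, function(v)
    setNames(as.numeric(v), c("mean", "sd")))
  for (f in c("p")) {
    raw$covariate_params$education[[f]] <-
      unlist(raw$covariate_params$education[[f]])
    raw$covariate_params$diabetes[[f]] <-
      unlist(raw$covariate_params$diabetes[[f]])
  }
  validate_qc_config(structure(raw, class = "qc_config"))
}
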