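# Regression analyses: standardized coefficients, the Model 1 / Model 2
# confounder-adjustment comparison with percent-change bookkeeping, quality
# determinants, quality cross-correlations, the motion-aging equivalence,
# and the high-motion sensitivity exclusion.

#' Standardized multiple linear regression
#'
#' Z-scores the outcome and every predictor, fits ordinary least squares,
#' and reports standardized coefficients with two-sided t-test p-values and
#' the model R-squared. Standardized coefficients are invariant under affine
#' rescaling of the outcome or any predictor.
#'
#' @param outcome numeric vector.
#' @param predictors data.frame or matrix of numeric predictors (columns
#'   named). Transform skewed variables (e.g. log10 of relative WMH volume)
#'   before calling; [covariate_zmatrix()] builds the standard covariate set.
#' @param alpha significance level (default 0.05).
#' @param outcome_name label stored in the result.
#' @return data.frame of class `regression_result` with columns `term`,
#'   `beta`, `p`, `significant`; attributes `r2`, `n`, `outcome`.
#' @export
standardized_regression <- function(outcome, predictors, alpha = 0.05,
                                    outcome_name = "outcome") {
  x <- as.matrix(predictors)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- length(outcome)
  if (nrow(x) != n) stop("outcome and predictors differ in length", call. = FALSE)
  if (n <= ncol(x) + 1) stop("need n > number of predictors + 1", call. = FALSE)
  consts <- colnames(x)[apply(x, 2, function(v) stats::sd(v) == 0)]
  if (length(consts) > 0) {
    stop("constant predictor(s): ", paste(consts, collapse = ", "),
         call. = FALSE)
  }
  zx <- scale(x)
  zy <- as.vector(scale(outcome))
  if (anyNA(zy)) stop("outcome is constant; cannot standardize", call. = FALSE)
  if (qr(zx)$rank < ncol(zx)) {
    # name the offending predictors via aliasing against the rest
    offenders <- colnames(zx)[is.na(coef(lm(zy ~ zx))[-1])]
    stop("perfectly collinear predictor(s): ",
         paste(offenders, collapse = ", "), call. = FALSE)
  }
  fit <- lm(zy ~ zx)
  sm <- summary(fit)
  tab <- sm$coefficients[-1, , drop = FALSE]
  res <- data.frame(term = colnames(zx),
                    beta = unname(tab[, "Estimate"]),
                    p = unname(tab[, "Pr(>|t|)"]),
                    stringsAsFactors = FALSE)
  res$significant <- res$p < alpha
  attr(res, "r2") <- sm$r.squared
  attr(res, "n") <- n
  attr(res, "outcome") <- outcome_name
  class(res) <- c("regression_result", "data.frame")
  res
}

#' Signed percent change between two coefficients
#'
#' The change of a coefficient after additional adjustment, relative to the
#' unadjusted model: `(beta2 - beta1) / beta1 * 100`. Signed, so a
#' sign-flipping adjustment (e.g. 0.058 to -0.081) reports -240, and an
#' adjustment that strengthens a negative effect reports a positive change.
#' The same formula applies to R-squared pairs.
#'
#' @param beta1 coefficient (or R-squared) in the unadjusted model.
#' @param beta2 coefficient in the adjusted model.
#' @return signed percent change; `NA` where `beta1 == 0`.
#' @export
percent_change <- function(beta1, beta2) {
  ifelse(beta1 == 0, NA_real_, (beta2 - beta1) / beta1 * 100)
}

#' Model 1 / Model 2 confounder comparison
#'
#' For each connectivity measure, fits Model 1 (measure on the seven
#' demographic/clinical covariates) and Model 2 (Model 1 plus the three
#' modality-matched image-quality metrics), both fully standardized, and
#' tabulates the signed percent change of each covariate's coefficient. A
#' change is flagged `relevant` when the coefficient is significant (in
#' either model) and moves by more than `change_threshold` percent. A final
#' row per outcome carries the R-squared pair through the same formula.
#'
#' @param connectivity data.frame with `participant_id` and one column per
#'   connectivity measure (e.g. `overall`, `nu`, `gamma`, `e_global`).
#' @param cohort cohort data.frame.
#' @param quality quality data.frame with `{modality}_{metric}` columns.
#' @param modality `"dmri"` (for SC measures) or `"fmri"` (for FC measures);
#'   selects the quality metrics entering Model 2.
#' @param measures which connectivity columns to analyse (default: all
#'   non-id numeric columns).
#' @param alpha significance level.
#' @param change_threshold relevance threshold in percent (default 10).
#' @return data.frame of class `change_ledger`: one row per
#'   (outcome, covariate) with `beta1`, `p1`, `beta2`, `p2`, `delta_pct`,
#'   `relevant`, plus the Model-2-only quality terms (with `beta1 = NA`) and
#'   an `(R2)` row per outcome.
#' @export
fit_model1_model2 <- function(connectivity, cohort, quality,
                              modality = c("dmri", "fmri"),
                              measures = NULL, alpha = 0.05,
                              change_threshold = 10) {
  modality <- match.arg(modality)
  qcols <- paste0(modality, "_", QUALITY_NAMES)
  if (!all(qcols %in% names(quality))) {
    stop("quality table lacks the ", modality, " metrics (",
         paste(qcols, collapse = ", "), "); modality mismatch?", call. = FALSE)
  }
  df <- merge(merge(connectivity, cohort, by = "participant_id"),
              quality, by = "participant_id")
  if (nrow(df) < 2) stop("no joinable participants", call. = FALSE)
  z <- covariate_zmatrix(df)
  zq <- as.matrix(df[qcols])
  colnames(zq) <- QUALITY_NAMES
  if (is.null(measures)) {
    measures <- setdiff(names(connectivity), "participant_id")
    measures <- measures[vapply(connectivity[measures], is.numeric, TRUE)]
  }
  rows <- lapply(measures, function(ms) {
    if (stats::sd(df[[ms]]) == 0) {
      # e.g. a node-degree measure pinned at its ceiling in simulated data
      warning("outcome '", ms, "' is constant; skipped", call. = FALSE)
      return(NULL)
    }
    m1 <- standardized_regression(df[[ms]], z, alpha, ms)
    m2 <- standardized_regression(df[[ms]], cbind(z, zq), alpha, ms)
    m2cov <- m2[match(m1$term, m2$term), ]
    delta <- percent_change(m1$beta, m2cov$beta)
    covrows <- data.frame(
      outcome = ms, term = m1$term,
      beta1 = m1$beta, p1 = m1$p,
      beta2 = m2cov$beta, p2 = m2cov$p,
      delta_pct = delta,
      relevant = (m1$significant | m2cov$significant) & !is.na(delta) &
        abs(delta) > change_threshold,
      stringsAsFactors = FALSE
    )
    qrows <- m2[m2$term %in% QUALITY_NAMES, ]
    qrows <- data.frame(outcome = ms, term = qrows$term,
                        beta1 = NA_real_, p1 = NA_real_,
                        beta2 = qrows$beta, p2 = qrows$p,
                        delta_pct = NA_real_, relevant = NA,
                        stringsAsFactors = FALSE)
    r2row <- data.frame(outcome = ms, term = "(R2)",
                        beta1 = attr(m1, "r2"), p1 = NA_real_,
                        beta2 = attr(m2, "r2"), p2 = NA_real_,
                        delta_pct = percent_change(attr(m1, "r2"),
                                                   attr(m2, "r2")),
                        relevant = NA, stringsAsFactors = FALSE)
    rbind(covrows, qrows, r2row)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    stop("all connectivity measures are constant; nothing to compare",
         call. = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "modality") <- modality
  attr(out, "alpha") <- alpha
  attr(out, "change_threshold") <- change_threshold
  attr(out, "n") <- nrow(df)
  class(out) <- c("change_ledger", "data.frame")
  out
}

#' Determinants of the quality metrics
#'
#' One standardized regression per quality metric (six in total: two
#' modalities by three metrics) of the metric on the seven
#' demographic/clinical covariates. By default the full model is fitted;
#' `selection = "forward"` instead adds covariates stepwise while the best
#' candidate's p-value is below `entry_alpha` (coefficients of unselected
#' covariates are reported as 0 with p = NA).
#'
#' @param cohort cohort data.frame.
#' @param quality quality data.frame.
#' @param alpha significance level.
#' @param selection `"full"` or `"forward"`.
#' @param entry_alpha forward-selection entry threshold.
#' @return named list of `regression_result` objects, one per
#'   `{modality}_{metric}` column present in `quality`.
#' @export
quality_determinants <- function(cohort, quality, alpha = 0.05,
                                 selection = c("full", "forward"),
                                 entry_alpha = 0.05) {
  selection <- match.arg(selection)
  df <- merge(cohort, quality, by = "participant_id")
  z <- covariate_zmatrix(df)
  metrics <- intersect(quality_metric_names(), names(quality))
  res <- lapply(metrics, function(met) {
    y <- df[[met]]
    if (selection == "full") {
      return(standardized_regression(y, z, alpha, met))
    }
    chosen <- character(0)
    remaining <- colnames(z)
    while (length(remaining) > 0) {
      pvals <- vapply(remaining, function(cand) {
        fit <- standardized_regression(y, z[, c(chosen, cand), drop = FALSE],
                                       alpha, met)
        fit$p[fit$term == cand]
      }, numeric(1))
      best <- names(which.min(pvals))
      if (pvals[best] >= entry_alpha) break
      chosen <- c(chosen, best)
      remaining <- setdiff(remaining, best)
    }
    if (length(chosen) == 0) {
      out <- data.frame(term = colnames(z), beta = 0, p = NA_real_,
                        significant = FALSE, stringsAsFactors = FALSE)
      attr(out, "r2") <- 0
      attr(out, "n") <- length(y)
      attr(out, "outcome") <- met
      class(out) <- c("regression_result", "data.frame")
      return(out)
    }
    fit <- standardized_regression(y, z[, chosen, drop = FALSE], alpha, met)
    full <- data.frame(term = colnames(z), beta = 0, p = NA_real_,
                       significant = FALSE, stringsAsFactors = FALSE)
    idx <- match(fit$term, full$term)
    full$beta[idx] <- fit$beta
    full$p[idx] <- fit$p
    full$significant[idx] <- fit$significant
    attr(full, "r2") <- attr(fit, "r2")
    attr(full, "n") <- attr(fit, "n")
    attr(full, "outcome") <- met
    class(full) <- c("regression_result", "data.frame")
    full
  })
  names(res) <- metrics
  res
}

#' Cross-correlations of the quality metrics
#'
#' Pearson correlations (with two-sided p-values) between every pair of the
#' six quality metrics.
#'
#' @param quality quality data.frame.
#' @return list with matrices `r` and `p`, and `n`.
#' @export
quality_cross_correlations <- function(quality) {
  metrics <- intersect(quality_metric_names(), names(quality))
  x <- as.matrix(quality[metrics])
  x <- x[complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 3) stop("need at least 3 complete rows", call. = FALSE)
  consts <- metrics[apply(x, 2, function(v) stats::sd(v) == 0)]
  if (length(consts) > 0) {
    stop("constant quality metric column(s): ",
         paste(consts, collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(x)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  list(r = r, p = p, n = n)
}

#' Motion-aging equivalence
#'
#' Converts a head-motion increment into the age change that produces the
#' same shift in the standardized outcome, via the ratio of standardized
#' effects: `|beta_motion / beta_age| * (delta_motion / sd_motion) * sd_age`.
#' With the adjusted-model coefficients for overall structural connectivity
#' and the cohort SDs, a 0.1 mm increase in dMRI head motion is equivalent
#' to roughly two decades of aging.
#'
#' @param beta_motion,beta_age standardized coefficients of motion and age
#'   for the same outcome.
#' @param sd_motion cohort SD of head motion (mm).
#' @param sd_age cohort SD of age (years).
#' @param delta_motion motion increment to convert (mm; default 0.1).
#' @return equivalent years of aging (nonnegative).
#' @examples
#' motion_age_equivalence(-0.249, -0.074, sd_motion = 0.16, sd_age = 8.7)
#' @export
motion_age_equivalence <- function(beta_motion, beta_age, sd_motion, sd_age,
                                   delta_motion = 0.1) {
  if (beta_age == 0) {
    stop("beta_age is zero; equivalence undefined", call. = FALSE)
  }
  stopifnot(sd_motion > 0, sd_age > 0)
  abs(beta_motion / beta_age) * (delta_motion / sd_motion) * sd_age
}

#' High-motion sensitivity exclusion
#'
#' Excludes participants whose dMRI (or rs-fMRI) head motion exceeds the
#' threshold and reruns the Model 1 / Model 2 comparison on the subset.
#'
#' @param cohort,quality,connectivity as in [fit_model1_model2()].
#' @param threshold motion threshold in mm (default 1.0).
#' @param modality which motion metric gates the exclusion (also the quality
#'   modality used in the refit).
#' @param ... passed to [fit_model1_model2()].
#' @return list with `included` (participant ids), `n_excluded`, and
#'   `ledger` (the refit `change_ledger`).
#' @export
exclude_high_motion <- function(cohort, quality, connectivity,
                                threshold = 1.0,
                                modality = c("dmri", "fmri"), ...) {
  modality <- match.arg(modality)
  stopifnot(threshold > 0)
  mcol <- paste0(modality, "_motion")
  keep <- quality$participant_id[quality[[mcol]] <= threshold]
  if (length(keep) == 0) {
    stop("threshold ", threshold, " mm excludes every participant",
         call. = FALSE)
  }
  sub <- function(df) df[df$participant_id %in% keep, , drop = FALSE]
  ledger <- fit_model1_model2(sub(connectivity), sub(cohort), sub(quality),
                              modality = modality, ...)
  list(included = keep,
       n_excluded = nrow(quality) - length(keep),
       ledger = ledger)
}
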