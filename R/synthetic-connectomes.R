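# Synthetic individual connectomes: a fixed geometric base template whose
# edge probabilities and weights decay with inter-region distance (denser
# intra-hemispheric than inter-hemispheric blocks), scaled per participant
# so that overall connectivity follows the configured standardized linear
# model in the covariates and quality metrics.

#' Base connectome template
#'
#' Deterministically builds (from `config$template$seed`) a 94-region
#' geometric template: region coordinates are drawn uniformly inside two
#' hemisphere blocks (odd labels left, even labels right); the probability
#' that an edge is present in an individual follows a logistic decay in
#' inter-region distance with a later decay for intra-hemispheric pairs, and
#' the edge weight template decays exponentially with distance (short
#' intra-hemispheric connections are the strongest, mirroring the dominance
#' of short association tracts in tractography).
#'
#' @param config a [qc_config()].
#' @return list with `p` (edge-presence probability matrix), `w_sc` and
#'   `w_fc` (weight templates), `coords`, `hemisphere`.
#' @export
connectome_template <- function(config) {
  tp <- config$template
  n <- tp$n_regions
  with_seed(split_seed(tp$seed, 0L), {
    hemi <- ifelse(seq_len(n) %% 2 == 1, "L", "R")
    nl <- sum(hemi == "L")
    coords <- matrix(0, n, 3)
    coords[hemi == "L", ] <- cbind(runif(nl, 0, 0.45), runif(nl), runif(nl))
    coords[hemi == "R", ] <- cbind(runif(n - nl, 0.55, 1),
                                   runif(n - nl), runif(n - nl))
    d <- as.matrix(stats::dist(coords))
    intra <- outer(hemi, hemi, "==")
    d0 <- ifelse(intra, tp$d0_intra, tp$d0_inter)
    p <- stats::plogis((d0 - d) / tp$slope)
    w <- exp(-d / tp$weight_tau)
    diag(p) <- 0
    diag(w) <- 0
    # FC weights decay more gently than SC weights and sit well inside
    # (0, 1), so per-subject rescaling plus edge noise rarely hits the clip
    # bounds (which would bias the calibrated overall connectivity)
    w_fc <- 0.15 + 0.55 * exp(-d / 0.5)
    diag(w_fc) <- 0
    list(p = p, w_sc = w, w_fc = w_fc, coords = coords,
         hemisphere = hemi)
  })
}

#' Generate synthetic individual connectomes
#'
#' Each participant's connectome starts from the base template: edges are
#' present with the template probability (SC; or always, FC), carry the
#' template weight perturbed by edge-level noise (log-normal multiplicative
#' for SC, which preserves nonnegativity; additive clipped for FC), and the
#' whole matrix is then rescaled so the participant's overall connectivity
#' equals `mean + sd * u_i`, where `u_i` is the standardized subject score
#' `sum_k beta_k z_k + residual` over the seven covariates and the
#' modality-matched quality metrics (Model-2 structure). Overall
#' connectivity of the generated set is therefore linear in the configured
#' predictors by construction.
#'
#' FC weights are clipped to `[0, 1]` after noise; any weight driven
#' negative and clipped is counted in the `n_clipped` attribute.
#'
#' @param cohort cohort data.frame.
#' @param quality quality data.frame from [generate_quality()].
#' @param config the [qc_config()].
#' @param modalities subset of `c("SC", "FC")` to generate.
#' @return list with elements `sc` and/or `fc` (lists of [connectome()]
#'   keyed by participant id), `template`, and attribute `n_clipped`.
#' @export
generate_connectomes <- function(cohort, quality, config,
                                 modalities = c("SC", "FC")) {
  stopifnot(inherits(config, "qc_config"))
  modalities <- match.arg(modalities, several.ok = TRUE)
  tmpl <- connectome_template(config)
  z <- covariate_zmatrix(cohort)
  n <- nrow(cohort)
  ut <- upper.tri(tmpl$p)
  out <- list(template = tmpl)
  n_clipped <- 0L
  for (modality in modalities) {
    key <- tolower(modality)
    qmod <- if (modality == "SC") "dmri" else "fmri"
    zq <- cbind(
      isnr = zscore(quality[[paste0(qmod, "_isnr")]], "isnr"),
      motion = zscore(quality[[paste0(qmod, "_motion")]], "motion"),
      mismatch = zscore(quality[[paste0(qmod, "_mismatch")]], "mismatch")
    )
    beta <- config$connectivity_coeffs[[key]]
    lin <- cbind(z, zq) %*% beta
    s2 <- stats::var(as.vector(lin))
    if (s2 >= 1) {
      stop("connectivity coefficient set '", key, "' implies explained ",
           "variance >= 1; residual variance would be negative",
           call. = FALSE)
    }
    rs <- config$noise_scales$connectivity_resid
    sd_e <- if (identical(rs, "auto")) sqrt(1 - s2) else as.numeric(rs)
    scale_par <- config$connectivity_scale[[key]]
    conns <- with_seed(split_seed(config$seed, if (modality == "SC") 3L else 4L), {
      u <- as.vector(lin) + sd_e * rnorm(n)
      target <- scale_par[["mean"]] + scale_par[["sd"]] * u
      lapply(seq_len(n), function(i) {
        if (modality == "SC") {
          present <- if (config$template$presence == "deterministic") {
            (tmpl$p[ut] >= 0.5) + 0
          } else {
            rbinom(sum(ut), 1, tmpl$p[ut])
          }
          sdlog <- config$noise_scales$sc_edge_sdlog
          noise <- if (sdlog > 0) {
            rlnorm(sum(ut), meanlog = -sdlog^2 / 2, sdlog = sdlog)
          } else 1
          wu <- tmpl$w_sc[ut] * present * noise
        } else {
          wu <- tmpl$w_fc[ut]
        }
        oc <- mean(wu)
        if (oc > 0 && target[i] > 0) wu <- wu * (target[i] / oc)
        if (modality == "FC") {
          esd <- config$noise_scales$fc_edge_sd
          if (esd > 0) wu <- wu + rnorm(sum(ut), 0, esd)
          nneg <- sum(wu < 0)
          if (nneg > 0) n_clipped <<- n_clipped + nneg
          wu <- pmin(pmax(wu, 0), 1)
        } else if (any(wu < 0)) {
          n_clipped <<- n_clipped + sum(wu < 0)
          wu <- pmax(wu, 0)
        }
        w <- matrix(0, nrow(tmpl$p), nrow(tmpl$p))
        w[ut] <- wu
        w <- w + t(w)
        connectome(w, modality, hemisphere = tmpl$hemisphere)
      })
    })
    names(conns) <- cohort$participant_id
    out[[key]] <- conns
  }
  attr(out, "n_clipped") <- n_clipped
  out
}
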