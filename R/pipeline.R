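# Config-driven orchestration: simulate -> quality -> connectomes ->
# mask/graph measures -> statistics -> report, with a provenance manifest.
# Every stage writes plain CSV; re-running with the same configuration
# reproduces the outputs byte-identically.

#' Run the full synthetic-cohort pipeline
#'
#' Generates a cohort, quality metrics and individual connectomes from the
#' configuration; builds the group-averaged consensus connectome per
#' modality and thresholds it at `sparsity`; computes per-participant graph
#' measures with per-participant seeded null ensembles; and runs the
#' statistical stage (Model 1 / Model 2 ledgers for both modalities, quality
#' determinants, quality cross-correlations, the motion-aging equivalence
#' from the fitted coefficients, and the high-motion exclusion refit). All
#' outputs are written to `out_dir` together with a manifest recording the
#' configuration, its hash, and the seeds used.
#'
#' @param config a [qc_config()].
#' @param out_dir output directory.
#' @param sparsity consensus sparsity (default 0.80).
#' @param n_null null networks per participant (default 100).
#' @param swaps_per_edge rewiring intensity.
#' @param alpha significance level for the statistical stage.
#' @param change_threshold relevance threshold in percent.
#' @param motion_threshold high-motion exclusion threshold in mm.
#' @param modalities which modalities to process.
#' @return (invisibly) a list with all stage results (`cohort`, `quality`,
#'   `measures`, `ledgers`, `determinants`, `cross_cor`,
#'   `motion_age_years`, `exclusion`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, sparsity = 0.80, n_null = 100L,
                         swaps_per_edge = 10L, alpha = 0.05,
                         change_threshold = 10, motion_threshold = 1.0,
                         modalities = c("SC", "FC")) {
  stopifnot(inherits(config, "qc_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- generate_cohort(config)
  quality <- generate_quality(cohort, config)
  conns <- generate_connectomes(cohort, quality, config,
                                modalities = modalities)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  write_cohort(quality, file.path(out_dir, "quality.csv"))

  measures <- list()
  ledgers <- list()
  for (modality in modalities) {
    key <- tolower(modality)
    qmod <- if (modality == "SC") "dmri" else "fmri"
    cs <- conns[[key]]
    group <- group_average(cs)
    mask <- proportional_threshold(group, sparsity)
    write_edge_list(mask, file.path(out_dir, paste0("consensus_", key, ".tsv")))
    rows <- lapply(seq_along(cs), function(i) {
      gm <- graph_measures(cs[[i]], mask, n_null = n_null,
                           seed = split_seed(config$seed, c(5L, i)),
                           swaps_per_edge = swaps_per_edge)
      cbind(participant_id = names(cs)[i], modality = modality, gm,
            null_seed = split_seed(config$seed, c(5L, i)),
            stringsAsFactors = FALSE)
    })
    mtab <- do.call(rbind, rows)
    measures[[key]] <- mtab
    write_cohort(mtab, file.path(out_dir, paste0("measures_", key, ".csv")))
    conn_tab <- data.frame(participant_id = mtab$participant_id,
                           overall = mtab$overall, nu = mtab$nu,
                           gamma = mtab$gamma, e_global = mtab$e_global,
                           stringsAsFactors = FALSE)
    ledgers[[key]] <- fit_model1_model2(conn_tab, cohort, quality,
                                        modality = qmod, alpha = alpha,
                                        change_threshold = change_threshold)
    write_cohort(as.data.frame(ledgers[[key]]),
                 file.path(out_dir, paste0("model_comparison_", key, ".csv")))
  }

  determinants <- quality_determinants(cohort, quality, alpha = alpha)
  det_tab <- do.call(rbind, lapply(names(determinants), function(met) {
    d <- determinants[[met]]
    cbind(metric = met, as.data.frame(d), r2 = attr(d, "r2"),
          stringsAsFactors = FALSE)
  }))
  write_cohort(det_tab, file.path(out_dir, "quality_determinants.csv"))

  cross <- quality_cross_correlations(quality)
  write_cohort(as.data.frame(cross$r), file.path(out_dir, "quality_cross_cor.csv"))

  motion_age <- NA_real_
  exclusion <- NULL
  if ("SC" %in% modalities) {
    led <- ledgers$sc
    bm <- led$beta2[led$outcome == "overall" & led$term == "motion"]
    ba <- led$beta2[led$outcome == "overall" & led$term == "age"]
    if (length(bm) == 1 && length(ba) == 1 && ba != 0) {
      motion_age <- motion_age_equivalence(
        bm, ba, sd_motion = stats::sd(quality$dmri_motion),
        sd_age = stats::sd(cohort$age), delta_motion = 0.1)
    }
    conn_tab <- data.frame(participant_id = measures$sc$participant_id,
                           overall = measures$sc$overall,
                           stringsAsFactors = FALSE)
    exclusion <- exclude_high_motion(cohort, quality, conn_tab,
                                     threshold = motion_threshold,
                                     modality = "dmri", alpha = alpha,
                                     change_threshold = change_threshold)
    write_cohort(as.data.frame(exclusion$ledger),
                 file.path(out_dir, "model_comparison_sc_lowmotion.csv"))
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  write_qc_config(config, cfg_path)
  manifest <- list(
    package = "connqc",
    version = as.character(utils::packageVersion("connqc")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    n = config$n,
    sparsity = sparsity,
    n_null = n_null,
    swaps_per_edge = swaps_per_edge,
    alpha = alpha,
    change_threshold = change_threshold,
    motion_threshold = motion_threshold,
    motion_age_years = motion_age,
    n_excluded_high_motion = if (is.null(exclusion)) NA else exclusion$n_excluded
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"),
                   precision = 12)

  invisible(list(cohort = cohort, quality = quality, measures = measures,
                 ledgers = ledgers, determinants = determinants,
                 cross_cor = cross, motion_age_years = motion_age,
                 exclusion = exclusion, manifest = manifest))
}

#' Graph measures over a sparsity grid
#'
#' Thresholds the group-averaged connectome at each sparsity in the grid and
#' recomputes the masked graph measures for every participant, summarizing
#' each measure by its mean and 5th-95th percentiles. Overall connectivity
#' is sparsity-independent (computed pre-masking) and joined to every row.
#'
#' @param cs list of individual [connectome()] objects (one modality).
#' @param sparsities numeric grid in (0, 1); the structural default is
#'   0.60-0.90 in steps of 0.05, the functional default 0.10-0.90 in steps
#'   of 0.10.
#' @param n_null,swaps_per_edge null-ensemble settings per participant and
#'   sparsity.
#' @param seed root seed for the null ensembles.
#' @return list with `measures` (long data.frame: participant, sparsity,
#'   overall, nu, gamma, e_global) and `summary` (per sparsity: mean and
#'   5th/95th percentile of each measure).
#' @export
sparsity_sweep <- function(cs, sparsities = seq(0.60, 0.90, by = 0.05),
                           n_null = 100L, swaps_per_edge = 10L, seed = 1L) {
  if (length(sparsities) < 2) stop("need at least two sparsity values", call. = FALSE)
  stopifnot(all(sparsities > 0 & sparsities < 1))
  group <- group_average(cs)
  rows <- list()
  for (s in sparsities) {
    mask <- proportional_threshold(group, s)
    for (i in seq_along(cs)) {
      gm <- graph_measures(cs[[i]], mask, n_null = n_null,
                           seed = split_seed(seed, c(6L, round(1000 * s), i)),
                           swaps_per_edge = swaps_per_edge)
      gm$sparsity <- s   # nominal grid value (realized value may differ in
                         # the last decimals through rounding of the count)
      rows[[length(rows) + 1L]] <-
        cbind(participant_id = names(cs)[i] %||% as.character(i), gm,
              stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(long, long$sparsity), function(d) {
    data.frame(
      sparsity = d$sparsity[1],
      nu_mean = mean(d$nu), nu_p5 = quantile(d$nu, 0.05),
      nu_p95 = quantile(d$nu, 0.95),
      gamma_mean = mean(d$gamma), gamma_p5 = quantile(d$gamma, 0.05),
      gamma_p95 = quantile(d$gamma, 0.95),
      e_global_mean = mean(d$e_global),
      e_global_p5 = quantile(d$e_global, 0.05),
      e_global_p95 = quantile(d$e_global, 0.95),
      overall_mean = mean(d$overall),
      row.names = NULL
    )
  }))
  summ <- summ[order(summ$sparsity), ]
  rownames(summ) <- NULL
  list(measures = long, summary = summ)
}
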