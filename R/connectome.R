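# Structural and functional connectome construction, consensus averaging,
# proportional thresholding and group masking.

N_REGIONS <- 94L
N_PAIRS <- N_REGIONS * (N_REGIONS - 1L) / 2L  # 4371

#' Construct a connectome object
#'
#' A connectome is a symmetric nonnegative `n x n` edge-weight matrix with a
#' zero diagonal over atlas regions. For structural connectomes (`"SC"`),
#' weights are relative tract volumes (tract volume / intracranial volume);
#' for functional connectomes (`"FC"`), weights are nuisance-adjusted Pearson
#' correlations with negative values clipped to zero, so weights lie in
#' `[0, 1]`.
#'
#' @param weights symmetric numeric matrix, nonnegative, zero diagonal.
#' @param modality `"SC"` or `"FC"`.
#' @param region_labels integer region labels (default `1:n`); by convention
#'   odd labels are left-hemisphere and even labels right-hemisphere regions.
#' @param hemisphere optional character vector `"L"`/`"R"` overriding the
#'   odd/even convention.
#' @return an object of class `connectome`.
#' @export
connectome <- function(weights, modality = c("SC", "FC"),
                       region_labels = seq_len(nrow(weights)),
                       hemisphere = NULL) {
  modality <- match.arg(modality)
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weights must be square", call. = FALSE)
  if (any(!is.finite(weights))) stop("weights must be finite", call. = FALSE)
  if (max(abs(weights - t(weights))) > 1e-12) {
    stop("weights must be symmetric", call. = FALSE)
  }
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (modality == "FC" && any(weights > 1 + 1e-12)) {
    stop("FC weights must lie in [0, 1]", call. = FALSE)
  }
  if (length(region_labels) != n) {
    stop("region_labels length must match matrix size", call. = FALSE)
  }
  hemi <- hemisphere %||% ifelse(region_labels %% 2 == 1, "L", "R")
  stopifnot(all(hemi %in% c("L", "R")))
  dimnames(weights) <- list(region_labels, region_labels)
  structure(list(weights = weights, modality = modality,
                 region_labels = as.integer(region_labels),
                 hemisphere = hemi),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", x$modality, ", ", nrow(x$weights), " regions, ",
      sum(upper_tri_values(x$weights) > 0), " nonzero edges, overall = ",
      format(overall_connectivity(x), digits = 4), "\n", sep = "")
  invisible(x)
}

upper_tri_values <- function(w) w[upper.tri(w)]

as_weight_matrix <- function(c) {
  if (inherits(c, "connectome")) c$weights else as.matrix(c)
}

#' Build a structural connectome from tract volumes
#'
#' Edge strength between two regions is the tract volume (number of voxels
#' visited by the tracts multiplied by the voxel volume) relative to the
#' intracranial volume (ICV). Pairs connected by fewer than two tracts are
#' considered spurious and receive weight zero.
#'
#' @param tract_volumes data.frame with columns `region_i`, `region_j`,
#'   `n_tracts`, `total_tract_voxels` (one row per region pair; pairs not
#'   listed get weight 0).
#' @param voxel_volume voxel volume in mm^3.
#' @param icv intracranial volume in mm^3.
#' @param n_regions number of atlas regions (default 94).
#' @param min_tracts minimum tract count for a pair to count as connected
#'   (default 2).
#' @return an `"SC"` [connectome()].
#' @export
build_sc <- function(tract_volumes, voxel_volume, icv,
                     n_regions = N_REGIONS, min_tracts = 2L) {
  stopifnot(icv > 0, voxel_volume > 0)
  w <- matrix(0, n_regions, n_regions)
  if (nrow(tract_volumes) > 0) {
    need <- c("region_i", "region_j", "n_tracts", "total_tract_voxels")
    if (!all(need %in% names(tract_volumes))) {
      stop("tract_volumes must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    tv <- tract_volumes
    if (any(tv$n_tracts < 0) || any(tv$total_tract_voxels < 0)) {
      stop("negative tract counts or voxel counts", call. = FALSE)
    }
    bad <- tv$region_i == tv$region_j & tv$total_tract_voxels > 0
    if (any(bad)) stop("self-connections with nonzero tract volume", call. = FALSE)
    keep <- tv$n_tracts >= min_tracts & tv$region_i != tv$region_j
    tv <- tv[keep, , drop = FALSE]
    if (nrow(tv) > 0) {
      idx <- cbind(tv$region_i, tv$region_j)
      w[idx] <- tv$total_tract_voxels * voxel_volume / icv
      w[idx[, 2:1, drop = FALSE]] <- w[idx]
    }
  }
  connectome(w, "SC")
}

#' Build a functional connectome from regional time-series
#'
#' Each region's mean BOLD series is residualized on the nuisance design
#' (six rigid-body motion parameters plus the mean CSF and WM signals, with
#' an intercept); the edge weight is the Pearson correlation of the
#' residual series, with negative correlations set to zero (negative edges
#' are not considered meaningful connections). Edges whose residual series
#' are constant have undefined correlation; they are set to 0 and counted in
#' the `n_undefined` attribute.
#'
#' @param ts numeric T x R matrix of regional mean time-series (columns =
#'   regions).
#' @param nuisance numeric T x 8 matrix: six motion parameters, CSF mean,
#'   WM mean. May have fewer/more columns; an intercept is always added.
#' @return an `"FC"` [connectome()]; attribute `n_undefined` counts edges
#'   zeroed because of constant residuals.
#' @export
build_fc <- function(ts, nuisance) {
  ts <- as.matrix(ts)
  nuisance <- as.matrix(nuisance)
  if (nrow(ts) != nrow(nuisance)) {
    stop("time-series and nuisance series must have equal length", call. = FALSE)
  }
  tlen <- nrow(ts)
  if (tlen <= ncol(nuisance) + 1 + 1) {
    stop("too few time points for the nuisance design", call. = FALSE)
  }
  design <- cbind(1, nuisance)
  resid <- qr.resid(qr(design), ts)
  sds <- apply(resid, 2, stats::sd)
  ok <- sds > 0
  r <- matrix(0, ncol(ts), ncol(ts))
  if (any(ok)) {
    r[ok, ok] <- stats::cor(resid[, ok, drop = FALSE])
  }
  n_undef <- sum(!ok) * ncol(ts) - sum(!ok) * (sum(!ok) + 1) / 2
  if (n_undef > 0) {
    warning(n_undef, " edge(s) had constant residual series; set to 0",
            call. = FALSE)
  }
  r[r < 0] <- 0
  diag(r) <- 0
  fc <- connectome(pmin(r, 1), "FC", region_labels = seq_len(ncol(ts)))
  attr(fc, "n_undefined") <- n_undef
  fc
}

#' Overall connectivity of a connectome
#'
#' The mean over all region pairs (upper triangle, zeros included) of the
#' edge weights. Computed on the unmasked individual connectome, so it does
#' not depend on the consensus sparsity.
#'
#' @param c a [connectome()] or weight matrix.
#' @return mean edge weight over all `n(n-1)/2` pairs.
#' @export
overall_connectivity <- function(c) {
  mean(upper_tri_values(as_weight_matrix(c)))
}

#' Group-average connectome
#'
#' For structural connectomes the individual matrices are binarized
#' (weight > 0) and averaged, giving the group prevalence of each edge in
#' `[0, 1]`; for functional connectomes the weights are averaged as such.
#'
#' @param cs list of [connectome()] objects (same size and modality).
#' @param binarize `TRUE` for the SC prevalence mode, `FALSE` for the FC
#'   mean-weight mode. Defaults to `TRUE` when the first element is SC.
#' @return a [connectome()] holding the group values.
#' @export
group_average <- function(cs, binarize = NULL) {
  if (length(cs) < 1) stop("need at least one connectome", call. = FALSE)
  ws <- lapply(cs, as_weight_matrix)
  dims <- vapply(ws, nrow, 1L)
  if (length(unique(dims)) != 1) stop("connectome shape mismatch", call. = FALSE)
  modality <- if (inherits(cs[[1]], "connectome")) cs[[1]]$modality else "SC"
  if (is.null(binarize)) binarize <- modality == "SC"
  acc <- matrix(0, dims[1], dims[1])
  for (w in ws) acc <- acc + if (binarize) (w > 0) + 0 else w
  g <- acc / length(ws)
  connectome(pmin(g, 1), if (modality == "SC") "SC" else "FC",
             region_labels = if (inherits(cs[[1]], "connectome"))
               cs[[1]]$region_labels else seq_len(dims[1]))
}

#' Proportionally threshold a group connectome
#'
#' Retains the `K = round((1 - sparsity) * n(n-1)/2)` edges with the largest
#' group values. For 94 regions at the default sparsity of 0.80 this keeps
#' exactly 874 edges. Ties are broken deterministically: larger group value
#' first, then lexicographic (row, column) order of the upper triangle.
#'
#' @param group a group-average [connectome()] (or matrix).
#' @param sparsity fraction in (0, 1) of region pairs to *drop*.
#' @param mode `"proportional"` (default, rank-based) or `"prevalence"`: the
#'   alternative literal cut keeping edges with group value >= `1 - sparsity`
#'   (e.g. present in at least 80% of participants). The rank-based mode is
#'   the default because it fixes the edge count exactly.
#' @return an object of class `edge_mask` with fields `edges` (logical
#'   matrix), `sparsity` (realized), `n_edges`.
#' @export
proportional_threshold <- function(group, sparsity = 0.80,
                                   mode = c("proportional", "prevalence")) {
  mode <- match.arg(mode)
  w <- as_weight_matrix(group)
  n <- nrow(w)
  npair <- n * (n - 1) / 2
  if (!(sparsity > 0 && sparsity < 1)) {
    stop("sparsity must lie in (0, 1)", call. = FALSE)
  }
  ut <- which(upper.tri(w), arr.ind = TRUE)
  vals <- w[upper.tri(w)]
  if (mode == "prevalence") {
    keep_idx <- which(vals >= 1 - sparsity)
    if (length(keep_idx) == 0) stop("prevalence cut retains no edges", call. = FALSE)
  } else {
    k <- round(npair * (1 - sparsity))
    if (k < 1) stop("sparsity too high: no edges retained", call. = FALSE)
    # order: value descending, then row, then column (lexicographic tie-break)
    o <- order(-vals, ut[, 1], ut[, 2])
    keep_idx <- o[seq_len(k)]
  }
  edges <- matrix(FALSE, n, n)
  edges[ut[keep_idx, , drop = FALSE]] <- TRUE
  edges <- edges | t(edges)
  structure(list(edges = edges,
                 sparsity = 1 - length(keep_idx) / npair,
                 n_edges = length(keep_idx)),
            class = "edge_mask")
}

#' @export
print.edge_mask <- function(x, ...) {
  cat("<edge_mask> ", x$n_edges, " edges, sparsity ",
      format(x$sparsity, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Mask an individual connectome by the group consensus
#'
#' Sets all weights outside the consensus edge mask to zero; weights inside
#' the mask are preserved (they may still be zero for that individual, so
#' the masked individual network has sparsity at or above the mask's).
#'
#' @param c a [connectome()].
#' @param m an `edge_mask` from [proportional_threshold()].
#' @return a masked [connectome()].
#' @export
apply_group_mask <- function(c, m) {
  stopifnot(inherits(m, "edge_mask"))
  w <- as_weight_matrix(c)
  if (!all(dim(w) == dim(m$edges))) stop("shape mismatch", call. = FALSE)
  w[!m$edges] <- 0
  if (inherits(c, "connectome")) {
    connectome(w, c$modality, c$region_labels, c$hemisphere)
  } else {
    connectome(w)
  }
}

#' Fraction of interhemispheric edges in a mask
#'
#' @param m an `edge_mask`.
#' @param hemisphere character vector `"L"`/`"R"` per region; default is the
#'   odd-left / even-right labeling convention.
#' @return retained edges joining opposite hemispheres divided by all
#'   retained edges.
#' @export
interhemispheric_fraction <- function(m, hemisphere = NULL) {
  stopifnot(inherits(m, "edge_mask"))
  n <- nrow(m$edges)
  hemi <- hemisphere %||% ifelse(seq_len(n) %% 2 == 1, "L", "R")
  ut <- which(upper.tri(m$edges) & m$edges, arr.ind = TRUE)
  if (nrow(ut) == 0) return(NaN)
  mean(hemi[ut[, 1]] != hemi[ut[, 2]])
}

# --- I/O ------------------------------------------------------------------

#' Read / write connectomes as dense CSV
#'
#' The on-disk format is a plain dense numeric CSV with a header row of
#' region labels.
#'
#' @param c a [connectome()].
#' @param path file path.
#' @param modality modality tag used when reading.
#' @return `write_connectome` returns `path` invisibly; `read_connectome`
#'   returns a [connectome()].
#' @export
write_connectome <- function(c, path) {
  stopifnot(inherits(c, "connectome"))
  write.csv(as.data.frame(c$weights), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path, modality = c("SC", "FC")) {
  modality <- match.arg(modality)
  m <- as.matrix(read.csv(path, check.names = FALSE))
  connectome(unname(m), modality)
}

#' Write a connectome or mask as an edge list
#'
#' Tab-separated columns `i`, `j`, `weight` (upper triangle, nonzero edges
#' only).
#'
#' @param x a [connectome()] or `edge_mask`.
#' @param path file path.
#' @export
write_edge_list <- function(x, path) {
  w <- if (inherits(x, "edge_mask")) x$edges + 0 else as_weight_matrix(x)
  ut <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  df <- data.frame(i = ut[, 1], j = ut[, 2], weight = w[ut])
  df <- df[order(df$i, df$j), ]
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
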