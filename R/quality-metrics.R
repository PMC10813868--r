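# Per-scan image-quality metrics, each on a "lower is better" scale:
# inverse SNR, mean volume-to-volume head translation, and atlas mismatch.

#' Inverse signal-to-noise ratio from two back-to-back volumes
#'
#' Estimates the (negated) signal-to-noise ratio from two volumes acquired
#' immediately after each other, using the difference-image method:
#' \deqn{iSNR = - mean(I_1, I_2) / (sd(I_1 - I_2) / \sqrt{2})}
#' The mean is taken over the masked voxels of both volumes pooled, and the
#' standard deviation of the voxelwise difference uses the sample (n - 1)
#' denominator. More negative values indicate better SNR, so the metric is
#' on the same "lower is better" scale as the other quality metrics.
#'
#' @param vol1,vol2 numeric arrays of identical shape (typically 3D volumes);
#'   for dMRI the two trailing b = 0 volumes, for rs-fMRI two volumes after
#'   magnetization stabilization (see `isnr_volume_pair` in [run_pipeline()]
#'   configs).
#' @param mask logical or 0/1 array of the same shape selecting brain voxels.
#' @return a single negative number (for any physically sensible scan).
#' @examples
#' v1 <- array(10, c(2, 1, 1)); v2 <- array(c(10, 14), c(2, 1, 1))
#' isnr(v1, v2, array(TRUE, c(2, 1, 1)))  # -5.5
#' @export
isnr <- function(vol1, vol2, mask) {
  mask <- as_mask_array(mask)
  if (!all(dim(vol1) == dim(vol2)) || !all(dim(vol1) == dim(mask))) {
    stop("vol1, vol2 and mask must have identical dimensions", call. = FALSE)
  }
  idx <- which(mask)
  if (length(idx) < 2) {
    stop("mask must contain at least two voxels", call. = FALSE)
  }
  x1 <- as.numeric(vol1[idx])
  x2 <- as.numeric(vol2[idx])
  noise <- stats::sd(x1 - x2) / sqrt(2)
  if (!is.finite(noise) || noise == 0) {
    stop("difference image has zero variance within the mask; ",
         "iSNR is undefined", call. = FALSE)
  }
  -mean(c(x1, x2)) / noise
}

#' Mean volume-to-volume head translation
#'
#' Summarizes a rigid-body motion trace as the mean Euclidean displacement
#' between consecutive volumes:
#' \deqn{\sum_{i=2}^{N} \sqrt{\Delta X_i^2 + \Delta Y_i^2 + \Delta Z_i^2} / (N - 1)}
#' where \eqn{X_i, Y_i, Z_i} are the translations (mm) of volume *i* along
#' the left-right, anterior-posterior and longitudinal axes. The result is
#' invariant to a constant offset of the whole trace.
#'
#' @param trace a `motion_trace` from [motion_trace()] or
#'   [read_motion_parameters()], or an N x 3 numeric matrix of translations
#'   in mm.
#' @return mean volume-to-volume translation in mm (nonnegative).
#' @examples
#' head_motion(cbind(c(0, 1, 1), 0, 0))      # 0.5
#' head_motion(cbind(c(0, 3), c(0, 4), 0))   # 5
#' @export
head_motion <- function(trace) {
  xyz <- as_translation_matrix(trace)
  n <- nrow(xyz)
  if (n < 2) stop("motion trace must contain at least two volumes", call. = FALSE)
  d <- diff(xyz)
  sum(sqrt(rowSums(d^2))) / (n - 1)
}

#' Mismatch between two brain masks (one minus Dice coefficient)
#'
#' Quantifies the spatial mismatch between a scan's brain mask and the brain
#' atlas mask as \eqn{1 - 2|A \cap B| / (|A| + |B|)}, i.e. one minus the Dice
#' similarity coefficient on voxel counts. Ranges from 0 (identical masks)
#' to 1 (disjoint masks); symmetric in its arguments. Voxel dimensions are
#' ignored: the metric is a pure count-based overlap.
#'
#' @param brain,atlas logical or 0/1 arrays of the same shape.
#' @return mismatch in `[0, 1]`.
#' @examples
#' a <- array(c(1, 1, 0), c(3, 1, 1)); b <- array(c(0, 1, 1), c(3, 1, 1))
#' atlas_mismatch(a, b)  # 1 - 2*1/(2+2) = 0.5
#' @export
atlas_mismatch <- function(brain, atlas) {
  brain <- as_mask_array(brain)
  atlas <- as_mask_array(atlas)
  if (!all(dim(brain) == dim(atlas))) {
    stop("brain and atlas masks must have identical dimensions", call. = FALSE)
  }
  a <- sum(brain)
  b <- sum(atlas)
  if (a + b == 0) stop("both masks are empty; Dice is undefined", call. = FALSE)
  1 - 2 * sum(brain & atlas) / (a + b)
}

#' Construct a motion trace
#'
#' @param translations N x 3 numeric matrix of per-volume translations (mm)
#'   along the left-right, anterior-posterior and longitudinal axes.
#' @param rotations optional N x 3 matrix of rotations (rad); parsed from
#'   realignment files and retained, but not used by [head_motion()], which
#'   is defined on translations only.
#' @return an object of class `motion_trace`.
#' @export
motion_trace <- function(translations, rotations = NULL) {
  translations <- as.matrix(translations)
  if (ncol(translations) != 3 || !is.numeric(translations)) {
    stop("translations must be an N x 3 numeric matrix", call. = FALSE)
  }
  if (!is.null(rotations)) {
    rotations <- as.matrix(rotations)
    stopifnot(ncol(rotations) == 3, nrow(rotations) == nrow(translations))
  }
  structure(list(translations = translations, rotations = rotations),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat("<motion_trace> ", nrow(x$translations), " volumes; mean |dT| = ",
      format(head_motion(x), digits = 4), " mm\n", sep = "")
  invisible(x)
}

#' Read rigid-body realignment parameters
#'
#' Reads a whitespace-delimited 6-column text file with one row per volume,
#' as written by common realignment tools. The default column convention is
#' three rotations (rad) followed by three translations (mm); set
#' `order = "trans_first"` for the opposite dialect.
#'
#' @param path path to the parameter file.
#' @param order `"rot_first"` (default) or `"trans_first"`.
#' @return a [motion_trace()].
#' @export
read_motion_parameters <- function(path, order = c("rot_first", "trans_first")) {
  order <- match.arg(order)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("motion parameter file is empty: ", path, call. = FALSE)
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) != 6 || anyNA(v)) {
      stop("malformed motion parameter row at line ", i, " of ", path,
           " (expected 6 numeric columns)", call. = FALSE)
    }
    v
  })
  m <- do.call(rbind, rows)
  if (order == "rot_first") {
    motion_trace(translations = m[, 4:6, drop = FALSE],
                 rotations = m[, 1:3, drop = FALSE])
  } else {
    motion_trace(translations = m[, 1:3, drop = FALSE],
                 rotations = m[, 4:6, drop = FALSE])
  }
}

#' Write rigid-body realignment parameters
#'
#' Counterpart of [read_motion_parameters()]; used by the fixture generator.
#'
#' @param trace a [motion_trace()].
#' @param path output path.
#' @param order column convention, as in [read_motion_parameters()].
#' @return `path`, invisibly.
#' @export
write_motion_parameters <- function(trace, path,
                                    order = c("rot_first", "trans_first")) {
  order <- match.arg(order)
  stopifnot(inherits(trace, "motion_trace"))
  rot <- trace$rotations %||% matrix(0, nrow(trace$translations), 3)
  m <- if (order == "rot_first") cbind(rot, trace$translations)
       else cbind(trace$translations, rot)
  write.table(format(m, digits = 12, trim = TRUE), path,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quality metrics for one scan
#'
#' Convenience wrapper computing the full quality triple for a 4D scan.
#'
#' @param volumes 4D array (x, y, z, t) of image intensities.
#' @param brain_mask 3D brain mask.
#' @param atlas_mask 3D atlas mask on the same grid.
#' @param trace a [motion_trace()] with one row per volume.
#' @param isnr_pair indices of the two back-to-back volumes used for the
#'   iSNR estimate (default the first two).
#' @return a one-row data.frame with columns `isnr`, `motion`, `mismatch`.
#' @export
quality_triple <- function(volumes, brain_mask, atlas_mask, trace,
                           isnr_pair = c(1L, 2L)) {
  stopifnot(length(dim(volumes)) == 4, length(isnr_pair) == 2)
  nt <- dim(volumes)[4]
  if (any(isnr_pair < 1 | isnr_pair > nt)) {
    stop("isnr_pair indices out of range", call. = FALSE)
  }
  if (nrow(as_translation_matrix(trace)) != nt) {
    stop("motion trace length does not match the number of volumes",
         call. = FALSE)
  }
  data.frame(
    isnr = isnr(volumes[, , , isnr_pair[1]], volumes[, , , isnr_pair[2]],
                brain_mask),
    motion = head_motion(trace),
    mismatch = atlas_mismatch(brain_mask, atlas_mask)
  )
}

# --- internal coercions ---------------------------------------------------

as_mask_array <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1, 1)
  if (is.logical(x)) return(x)
  if (!all(x %in% c(0, 1))) {
    stop("mask must be logical or contain only 0/1", call. = FALSE)
  }
  array(x > 0, dim(x))
}

as_translation_matrix <- function(trace) {
  if (inherits(trace, "motion_trace")) return(trace$translations)
  m <- as.matrix(trace)
  if (ncol(m) != 3 || !is.numeric(m)) {
    stop("expected a motion_trace or an N x 3 translation matrix",
         call. = FALSE)
  }
  m
}
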