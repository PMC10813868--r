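# Minimal 4D imaging fixtures with known ground-truth quality metrics, for
# exercising the quality-metric operations end to end (including file I/O).

#' Generate a synthetic 4D volume fixture
#'
#' Constructs a spherical "brain" of constant intensity plus white Gaussian
#' noise scaled so the expected SNR of the difference-image estimator equals
#' `snr_target`; shifts each volume according to a motion trace that
#' alternates between 0 and `motion_per_volume` mm along the left-right
#' axis (so the mean volume-to-volume translation is exactly
#' `motion_per_volume`); and derives the atlas mask from the brain mask by
#' erosion (keeping the innermost voxels) so that the mismatch hits
#' `mismatch_target` as closely as integer voxel counts allow -- the achieved
#' value, exact by construction, is stored in the ground truth.
#'
#' The brain mask is eroded relative to the intensity sphere by a safety
#' margin larger than any applied shift, so the masked signal stays constant
#' under motion and the iSNR estimator keeps its nominal expectation.
#'
#' @param n_volumes number of volumes (>= 2).
#' @param snr_target expected SNR (> 0); ground-truth iSNR is
#'   `-snr_target`.
#' @param motion_per_volume volume-to-volume displacement in mm (>= 0).
#' @param mismatch_target atlas mismatch in `[0, 1)`.
#' @param seed RNG seed for the noise.
#' @param grid_dim 3D grid size (default `c(32, 32, 32)`, 1 mm voxels).
#' @param brain_radius radius of the intensity sphere in voxels.
#' @param mask_margin erosion margin (voxels) between the intensity sphere
#'   and the brain mask.
#' @return an object of class `volume_fixture` with fields `volumes`
#'   (4D array), `brain_mask`, `atlas_mask`, `trace` ([motion_trace()]),
#'   and `truth` (list `isnr`, `motion`, `mismatch`).
#' @export
generate_volume_fixture <- function(n_volumes = 4L, snr_target = 22,
                                    motion_per_volume = 0,
                                    mismatch_target = 0.1, seed = 1L,
                                    grid_dim = c(32L, 32L, 32L),
                                    brain_radius = 13, mask_margin = 2) {
  stopifnot(n_volumes >= 2, snr_target > 0, motion_per_volume >= 0,
            mismatch_target >= 0, mismatch_target < 1)
  centre <- (grid_dim + 1) / 2
  ax <- lapply(1:3, function(k) seq_len(grid_dim[k]) - centre[k])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  sphere <- r2 <= brain_radius^2
  brain_mask <- r2 <= (brain_radius - mask_margin)^2

  # alternating trace: 0, m, 0, m, ... -> every volume-to-volume step is m
  x_shift <- rep(c(0, motion_per_volume), length.out = n_volumes)
  trace <- motion_trace(cbind(x_shift, 0, 0))
  if (max(abs(round(x_shift))) > mask_margin) {
    warning("motion shift exceeds the mask margin; the masked signal is no ",
            "longer constant and the iSNR truth degrades", call. = FALSE)
  }

  signal <- 100
  noise_sd <- signal / snr_target
  volumes <- with_seed(seed, {
    v <- array(0, c(grid_dim, n_volumes))
    for (t in seq_len(n_volumes)) {
      img <- array(0, grid_dim)
      img[shift_mask(sphere, round(x_shift[t]))] <- signal
      v[, , , t] <- img + array(rnorm(prod(grid_dim), 0, noise_sd), grid_dim)
    }
    v
  })

  atlas_mask <- erode_to_mismatch(brain_mask, r2, mismatch_target)
  truth <- list(
    isnr = -snr_target,
    motion = head_motion(trace),
    mismatch = atlas_mismatch(brain_mask, atlas_mask)
  )
  structure(list(volumes = volumes, brain_mask = brain_mask,
                 atlas_mask = atlas_mask, trace = trace, truth = truth,
                 voxel_dims = c(1, 1, 1)),
            class = "volume_fixture")
}

# integer shift of a logical mask along the first axis (zero fill)
shift_mask <- function(mask, k) {
  if (k == 0) return(mask)
  out <- array(FALSE, dim(mask))
  n <- dim(mask)[1]
  if (abs(k) >= n) return(out)
  if (k > 0) out[(k + 1):n, , ] <- mask[1:(n - k), , ]
  else out[1:(n + k), , ] <- mask[(1 - k):n, , ]
  out
}

# atlas mask as the innermost m voxels of the brain mask, m chosen so
# 1 - 2m/(a + m) is as close as integer counts allow to the target
erode_to_mismatch <- function(brain_mask, r2, target) {
  a <- sum(brain_mask)
  m <- round(a * (1 - target) / (1 + target))
  if (m < 1) {
    nearest <- 1 - 2 / (a + 1)
    stop("mismatch target ", target, " unreachable on this grid; nearest ",
         "achievable value is ", format(nearest, digits = 4), call. = FALSE)
  }
  idx <- which(brain_mask)
  keep <- idx[order(r2[idx])][seq_len(m)]
  atlas <- array(FALSE, dim(brain_mask))
  atlas[keep] <- TRUE
  atlas
}

#' @export
print.volume_fixture <- function(x, ...) {
  d <- dim(x$volumes)
  cat("<volume_fixture> ", paste(d[1:3], collapse = "x"), " grid, ", d[4],
      " volumes; truth: iSNR = ", x$truth$isnr, ", motion = ",
      format(x$truth$motion, digits = 4), " mm, mismatch = ",
      format(x$truth$mismatch, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write / read a volume fixture
#'
#' Volumes and masks are stored as NIfTI-1 (`.nii.gz`), the motion trace as
#' 6-column whitespace-delimited text (rotations then translations), and the
#' ground truth as YAML.
#'
#' @param fixture a `volume_fixture`.
#' @param dir output directory (created if needed).
#' @return `read_volume_fixture` returns a `volume_fixture`.
#' @export
write_volume_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "volume_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(fixture$volumes, file.path(dir, "volumes.nii.gz"))
  RNifti::writeNifti(fixture$brain_mask + 0L, file.path(dir, "brain_mask.nii.gz"))
  RNifti::writeNifti(fixture$atlas_mask + 0L, file.path(dir, "atlas_mask.nii.gz"))
  write_motion_parameters(fixture$trace, file.path(dir, "motion.par"))
  yaml::write_yaml(fixture$truth, file.path(dir, "truth.yaml"), precision = 12)
  invisible(dir)
}

#' @rdname write_volume_fixture
#' @export
read_volume_fixture <- function(dir) {
  vols <- as.array(RNifti::readNifti(file.path(dir, "volumes.nii.gz")))
  bm <- as.array(RNifti::readNifti(file.path(dir, "brain_mask.nii.gz"))) > 0
  am <- as.array(RNifti::readNifti(file.path(dir, "atlas_mask.nii.gz"))) > 0
  trace <- read_motion_parameters(file.path(dir, "motion.par"))
  truth_path <- file.path(dir, "truth.yaml")
  truth <- if (file.exists(truth_path)) yaml::read_yaml(truth_path) else NULL
  structure(list(volumes = vols, brain_mask = bm, atlas_mask = am,
                 trace = trace, truth = truth, voxel_dims = c(1, 1, 1)),
            class = "volume_fixture")
}

#' Quality metrics from a fixture directory
#'
#' The "from-files" entry point: reads NIfTI volumes, masks and the motion
#' parameter file from `dir` and computes the quality triple.
#'
#' @param dir a directory written by [write_volume_fixture()] (or with the
#'   same layout).
#' @param isnr_pair indices of the two volumes for the iSNR estimate.
#' @return one-row data.frame `isnr`, `motion`, `mismatch`.
#' @export
quality_from_files <- function(dir, isnr_pair = c(1L, 2L)) {
  fx <- read_volume_fixture(dir)
  quality_triple(fx$volumes, fx$brain_mask, fx$atlas_mask, fx$trace,
                 isnr_pair = isnr_pair)
}
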