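#' Motion trace container
#'
#' Per-volume rigid-body parameters (3 rotations in radians, 3 translations
#' in mm) together with the realignment reference index.
#'
#' @param params T x 6 numeric matrix (rot_x, rot_y, rot_z, trans_x,
#'   trans_y, trans_z).
#' @param reference_index index of the reference volume (1-based).
#' @return list of class `motion_trace`.
#' @export
motion_trace <- function(params, reference_index) {
  params <- as.matrix(params)
  stopifnot(ncol(params) == 6L, nrow(params) >= 1L,
            reference_index >= 1L, reference_index <= nrow(params))
  colnames(params) <- c("rot_x", "rot_y", "rot_z",
                        "trans_x", "trans_y", "trans_z")
  structure(list(params = params, reference_index = as.integer(reference_index)),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d volumes, reference %d, max |translation| %.2f mm\n",
              nrow(x$params), x$reference_index, max(abs(x$params[, 4:6]))))
  invisible(x)
}

#' Discard initial volumes
#'
#' Removes the first `n_discard` recorded volumes (signal equilibration)
#' and, when a paradigm is supplied, shifts its onsets back by
#' `n_discard * TR` so that time 0 remains the first retained volume.
#'
#' @param vol a [volume4d()].
#' @param n_discard number of initial volumes to drop (default 4).
#' @param paradigm optional [build_paradigm()] whose onsets are expressed
#'   relative to the first recorded volume.
#' @return the trimmed `volume4d`, or a list `(vol, paradigm)` when a
#'   paradigm is supplied.
#' @export
discard_initial <- function(vol, n_discard = 4L, paradigm = NULL) {
  Tn <- n_volumes(vol)
  if (n_discard >= Tn) stop("cannot discard ", n_discard, " of ", Tn, " volumes")
  if (n_discard > 0L) {
    vol$data <- vol$data[, , , -(seq_len(n_discard)), drop = FALSE]
  }
  if (is.null(paradigm)) return(vol)
  list(vol = vol,
       paradigm = shift_paradigm(paradigm, -n_discard * vol$tr_seconds))
}

# SSD between a candidate-shifted volume and the reference, in-bulk voxels.
.ssd_shift <- function(volume, reference, shift_vox) {
  diff <- shift_volume3d(volume, shift_vox) - reference
  sum(diff^2)
}

#' Translational realignment to the middle volume
#'
#' Estimates a per-volume rigid translation by minimizing the sum of
#' squared intensity differences to the reference (the middle volume):
#' an integer-voxel grid search (adaptively widened from +/-1 to +/-2
#' voxels) followed by per-axis parabolic sub-voxel refinement, then
#' resamples each volume by separable linear interpolation. Rotations are
#' reported as zero; the estimator is translation-only by design.
#'
#' @param vol a [volume4d()].
#' @return list `(vol, trace)`: the realigned volume and a
#'   [motion_trace()] whose translations are the estimated head offsets
#'   in mm (the applied correction is their negative).
#' @export
realign_translational <- function(vol) {
  Tn <- n_volumes(vol)
  if (Tn < 2L) stop("need at least two volumes to realign")
  ref_idx <- Tn %/% 2L + 1L
  reference <- vol$data[, , , ref_idx]
  if (all(reference == 0)) stop("reference volume is identically zero")
  est <- matrix(0, Tn, 3)
  out <- vol$data
  for (t in seq_len(Tn)) {
    if (t == ref_idx) next
    v <- vol$data[, , , t]
    d_hat <- .estimate_translation(v, reference)
    est[t, ] <- d_hat
    if (any(d_hat != 0)) out[, , , t] <- shift_volume3d(v, -d_hat)
  }
  vol$data <- out
  params <- cbind(matrix(0, Tn, 3), sweep(est, 2, vol$voxel_mm, `*`))
  list(vol = vol, trace = motion_trace(params, ref_idx))
}

# Integer search + parabolic refinement for one volume (shift in voxels,
# meaning: volume content = reference shifted by +d).
.estimate_translation <- function(volume, reference, max_shift = 2L) {
  best <- c(0L, 0L, 0L)
  # adaptive integer search: start with radius 1, widen while the optimum
  # sits on the search boundary
  radius <- 1L
  repeat {
    grid <- expand.grid(x = -radius:radius, y = -radius:radius, z = -radius:radius)
    ssd <- apply(grid, 1L, function(s) .ssd_shift(volume, reference, -as.numeric(s)))
    best <- as.integer(grid[which.min(ssd), ])
    if (all(abs(best) < radius) || radius >= max_shift) break
    radius <- radius + 1L
  }
  # parabolic sub-voxel refinement along each axis, two passes with a
  # shrinking step for interpolation-limited accuracy
  refine <- as.numeric(best)
  for (step in c(1, 0.25)) {
    for (ax in 1:3) {
      f <- function(delta) {
        s <- refine; s[ax] <- s[ax] + delta
        .ssd_shift(volume, reference, -s)
      }
      y_m <- f(-step); y_0 <- f(0); y_p <- f(step)
      denom <- y_m - 2 * y_0 + y_p
      delta <- if (denom > 0) 0.5 * step * (y_m - y_p) / denom else 0
      refine[ax] <- refine[ax] + max(-step / 2, min(step / 2, delta))
    }
  }
  refine
}

#' Displacement metrics and the motion-exclusion verdict
#'
#' Per-volume displacement combines the translation vector with the
#' rotational arc travelled on an 80 mm radius sphere (each rotation angle
#' times 80 mm, combined with the translations in quadrature). Absolute
#' displacement is measured against the reference volume, relative
#' displacement between consecutive volumes. A subject is excluded when
#' the mean relative displacement reaches `rel_limit_mm` or the mean
#' absolute displacement reaches `abs_limit_mm`.
#'
#' @param trace a [motion_trace()].
#' @param rel_limit_mm exclusion limit on mean relative displacement
#'   (default 1 mm).
#' @param abs_limit_mm exclusion limit on mean absolute displacement
#'   (default 3 mm).
#' @param sphere_radius_mm radius used to convert rotations to mm
#'   (default 80).
#' @return list with `abs_disp` (per volume, mm), `rel_disp` (per
#'   transition, length T-1), `abs_mean`, `rel_mean`, and `exclude`
#'   (logical verdict).
#' @export
displacement_and_exclusion <- function(trace, rel_limit_mm = 1,
                                       abs_limit_mm = 3,
                                       sphere_radius_mm = 80) {
  p <- trace$params
  if (nrow(p) == 0L) stop("empty motion trace")
  # 6-vector in mm: rotations as arc length on the sphere, translations as-is
  mm <- cbind(p[, 1:3] * sphere_radius_mm, p[, 4:6])
  ref <- mm[trace$reference_index, ]
  abs_disp <- sqrt(rowSums(sweep(mm, 2, ref, `-`)^2))
  rel_disp <- if (nrow(mm) > 1L) sqrt(rowSums(diff(mm)^2)) else numeric(0)
  abs_mean <- mean(abs_disp)
  rel_mean <- if (length(rel_disp)) mean(rel_disp) else 0
  list(abs_disp = abs_disp, rel_disp = rel_disp,
       abs_mean = abs_mean, rel_mean = rel_mean,
       exclude = (rel_mean >= rel_limit_mm) || (abs_mean >= abs_limit_mm),
       rel_limit_mm = rel_limit_mm, abs_limit_mm = abs_limit_mm)
}

#' Intensity-based brain mask
#'
#' Thresholds the temporal-mean volume at a fraction of its robust maximum
#' (98th percentile), keeps the largest 6-connected component and fills
#' interior holes. A simple intensity method adequate for synthetic heads
#' (bright ellipsoid on dark background); it is not a substitute for a
#' surface-based extraction on real data.
#'
#' @param vol a [volume4d()].
#' @param fraction threshold as a fraction of the robust maximum
#'   (default 0.25).
#' @return logical 3D array.
#' @export
brain_mask <- function(vol, fraction = 0.25) {
  mean_vol <- apply(vol$data, 1:3, mean)
  if (stats::sd(mean_vol) == 0) stop("mean volume is constant; cannot mask")
  robust_max <- stats::quantile(mean_vol, 0.98, names = FALSE)
  m <- mean_vol > fraction * robust_max
  if (!any(m)) stop("empty mask after thresholding")
  lab <- label_components(m, connectivity = 6L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  fill_holes3d(lab == keep)
}

#' Spatial smoothing and grand-mean intensity normalization
#'
#' Per-volume 3D Gaussian smoothing with `sigma = fwhm / (2.3548 *
#' voxel_mm)` voxels per axis, followed by a single multiplicative factor
#' scaling the entire 4D data set so that its in-mask grand mean equals
#' `target_grand_mean`.
#'
#' @param vol a [volume4d()] with a mask (see [brain_mask()]).
#' @param fwhm_mm smoothing kernel full width at half maximum in mm
#'   (default 5; 0 disables smoothing).
#' @param target_grand_mean grand-mean target (default 10000).
#' @return the smoothed, normalized `volume4d`.
#' @export
smooth_and_normalize <- function(vol, fwhm_mm = 5, target_grand_mean = 10000) {
  stopifnot(fwhm_mm >= 0, !is.null(vol$mask))
  if (fwhm_mm > 0) {
    sigma_vox <- fwhm_mm / (2.3548 * vol$voxel_mm)
    Tn <- n_volumes(vol)
    for (t in seq_len(Tn)) {
      vol$data[, , , t] <- smooth3d(vol$data[, , , t], sigma_vox)
    }
  }
  grand <- mean(vol_matrix(vol))
  if (abs(grand) < .Machine$double.eps) stop("zero in-mask grand mean")
  vol$data <- vol$data * (target_grand_mean / grand)
  vol
}

#' Write realignment parameters as TSV
#'
#' Six columns per volume: three rotations (radians) then three
#' translations (mm), matching the generator's dialect.
#' @param trace a [motion_trace()].
#' @param path output TSV path.
#' @export
write_motion_tsv <- function(trace, path) {
  utils::write.table(as.data.frame(trace$params), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read realignment parameters from TSV
#' @param path TSV with 6 columns (rotations rad, translations mm).
#' @param reference_index realignment reference volume (default: middle).
#' @export
read_motion_tsv <- function(path, reference_index = NULL) {
  tab <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  if (is.null(reference_index)) reference_index <- nrow(tab) %/% 2L + 1L
  motion_trace(tab, reference_index)
}
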