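#' AROMA-style component features
#'
#' Computes, for every component, the four temporal and spatial criteria
#' used to identify motion-related independent components:
#' \describe{
#'   \item{hfc}{high-frequency content: the frequency at which the
#'     cumulative periodogram reaches half of the total power, divided by
#'     the Nyquist frequency.}
#'   \item{max_rp_corr}{maximum absolute correlation between the component
#'     time course and an expanded realignment-parameter set (the 6
#'     parameters, their first differences, and one-volume forward and
#'     backward shifts of each).}
#'   \item{edge_frac}{fraction of the map's total absolute weight lying in
#'     brain-edge voxels.}
#'   \item{csf_frac}{fraction lying in CSF voxels.}
#' }
#'
#' @param components a [probabilistic_ica()] result.
#' @param motion_trace a [motion_trace()] with per-volume parameters.
#' @param mask logical 3D brain mask.
#' @param edge_mask logical 3D array of brain-edge voxels (see
#'   [edge_mask_from()]).
#' @param csf_mask logical 3D array of CSF voxels.
#' @param tr repetition time in seconds.
#' @return data.frame with one row per component: `component`, `hfc`,
#'   `max_rp_corr`, `edge_frac`, `csf_frac`.
#' @export
aroma_features <- function(components, motion_trace, mask, edge_mask,
                           csf_mask, tr = components$tr_seconds) {
  if (!any(edge_mask) || !any(csf_mask)) stop("empty edge or CSF mask")
  Tn <- nrow(components$timecourses)
  if (Tn < 20L) stop("need at least 20 timepoints for AROMA features")
  stopifnot(nrow(motion_trace$params) == Tn)
  rp <- expand_motion_regressors(motion_trace$params)
  edge_in <- edge_mask[mask]
  csf_in <- csf_mask[mask]
  out <- lapply(seq_len(components$K), function(k) {
    tc <- components$timecourses[, k]
    absmap <- abs(components$maps[k, ])
    total <- sum(absmap)
    data.frame(component = k,
               hfc = high_frequency_content(tc, tr),
               max_rp_corr = max_abs_correlation(tc, rp),
               edge_frac = if (total > 0) sum(absmap[edge_in]) / total else 0,
               csf_frac = if (total > 0) sum(absmap[csf_in]) / total else 0)
  })
  do.call(rbind, out)
}

# Fraction of Nyquist at which the cumulative periodogram reaches 50%.
high_frequency_content <- function(tc, tr) {
  x <- tc - mean(tc)
  n <- length(x)
  spec <- Mod(stats::fft(x))^2
  m <- n %/% 2L
  freq <- (seq_len(m)) / (n * tr)
  power <- spec[2:(m + 1L)]
  if (sum(power) == 0) return(0)
  cum <- cumsum(power) / sum(power)
  nyquist <- 1 / (2 * tr)
  freq[which(cum >= 0.5)[1]] / nyquist
}

# Expanded realignment-parameter set: params, first differences, and
# +/- one-volume shifts of both (zero-padded).
expand_motion_regressors <- function(params) {
  Tn <- nrow(params)
  d <- rbind(0, diff(params))
  base <- cbind(params, d)
  fwd <- rbind(0, base[-Tn, , drop = FALSE])
  bwd <- rbind(base[-1, , drop = FALSE], 0)
  cbind(base, fwd, bwd)
}

max_abs_correlation <- function(tc, regressors) {
  rs <- apply(regressors, 2, function(r) {
    v <- safe_cor(tc, r)
    if (is.na(v)) 0 else abs(v)
  })
  max(rs)
}

#' AROMA classification thresholds
#'
#' Defaults: CSF fraction 0.10, high-frequency content 0.35, and the
#' published AROMA linear decision boundary in the (max RP correlation,
#' edge fraction) plane.
#'
#' @param csf_threshold flag when `csf_frac` exceeds this (default 0.10).
#' @param hfc_threshold flag when `hfc` exceeds this (default 0.35).
#' @param hyperplane numeric triple (intercept, RP-correlation
#'   coefficient, edge-fraction coefficient); a component is flagged when
#'   the linear projection is positive.
#' @return list of class `aroma_thresholds`.
#' @export
aroma_thresholds <- function(csf_threshold = 0.10, hfc_threshold = 0.35,
                             hyperplane = c(-19.9751070082159,
                                            9.95127547670627,
                                            24.8333160239175)) {
  structure(list(csf_threshold = csf_threshold, hfc_threshold = hfc_threshold,
                 hyperplane = hyperplane),
            class = "aroma_thresholds")
}

#' Classify components as motion/noise
#'
#' A component is flagged as noise when its CSF fraction exceeds the CSF
#' threshold, OR its high-frequency content exceeds the HFC threshold, OR
#' the point (max RP correlation, edge fraction) lies above the linear
#' decision boundary.
#'
#' @param features data.frame from [aroma_features()].
#' @param thresholds an [aroma_thresholds()] object.
#' @return logical vector of per-component noise flags.
#' @export
classify_noise <- function(features, thresholds = aroma_thresholds()) {
  hp <- thresholds$hyperplane
  proj <- hp[1] + hp[2] * features$max_rp_corr + hp[3] * features$edge_frac
  features$csf_frac > thresholds$csf_threshold |
    features$hfc > thresholds$hfc_threshold |
    proj > 0
}

#' Non-aggressive removal of flagged components
#'
#' Regresses every voxel's time series on all `K` component time courses
#' jointly (plus an intercept) and subtracts only the fitted contribution
#' of the flagged components, leaving variance shared with unflagged
#' components untouched — the partial component regression of the
#' non-aggressive denoising option.
#'
#' @param vol a [volume4d()] with mask.
#' @param components a [probabilistic_ica()] result on the same grid.
#' @param noise_flags logical vector of length `K`.
#' @return the denoised `volume4d`.
#' @export
nonaggressive_regress <- function(vol, components, noise_flags) {
  stopifnot(length(noise_flags) == components$K, components$K >= 1L)
  if (!any(noise_flags)) return(vol)
  Y <- vol_matrix(vol)                              # T x V
  X <- cbind(1, components$timecourses)             # intercept + K
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("component time courses are rank deficient")
  beta <- qr.coef(qx, Y)                            # (K+1) x V
  noise_cols <- c(FALSE, noise_flags)
  cleaned <- Y - X[, noise_cols, drop = FALSE] %*% beta[noise_cols, , drop = FALSE]
  d <- dim(vol$data)
  m <- matrix(vol$data, prod(d[1:3]), d[4])
  m[as.vector(vol$mask), ] <- t(cleaned)
  vol$data <- array(m, d)
  vol
}

#' Aggressive removal of flagged components
#'
#' Full regression on the flagged components only; removes all variance
#' they can explain, including variance shared with signal components.
#' Provided for comparison with [nonaggressive_regress()].
#'
#' @inheritParams nonaggressive_regress
#' @return the denoised `volume4d`.
#' @export
aggressive_regress <- function(vol, components, noise_flags) {
  stopifnot(length(noise_flags) == components$K)
  if (!any(noise_flags)) return(vol)
  Y <- vol_matrix(vol)
  X <- cbind(1, components$timecourses[, noise_flags, drop = FALSE])
  qx <- qr(X)
  beta <- qr.coef(qx, Y)
  cleaned <- Y - X[, -1, drop = FALSE] %*% beta[-1, , drop = FALSE]
  d <- dim(vol$data)
  m <- matrix(vol$data, prod(d[1:3]), d[4])
  m[as.vector(vol$mask), ] <- t(cleaned)
  vol$data <- array(m, d)
  vol
}

#' Edge mask: voxels near the brain boundary
#'
#' Voxels within `rim_voxels` of the mask boundary (inside) plus a
#' one-voxel shell outside the mask. The default rim of two voxels
#' matches how far the 5 mm spatial smoothing spreads boundary signal on
#' a 3 mm grid; a narrower rim systematically under-counts the edge
#' weight of genuinely boundary-locked components.
#'
#' @param mask logical 3D brain mask.
#' @param rim_voxels width of the interior rim in voxels (default 2).
#' @return logical 3D array.
#' @export
edge_mask_from <- function(mask, rim_voxels = 2L) {
  eroded <- mask
  for (i in seq_len(rim_voxels)) eroded <- erode3d(eroded)
  inner <- mask & !eroded
  shell <- dilate3d(mask) & !mask
  inner | shell
}

#' Write the AROMA feature table as TSV
#'
#' @param features data.frame from [aroma_features()].
#' @param flags logical vector from [classify_noise()].
#' @param path output TSV path.
#' @export
write_feature_table <- function(features, flags, path) {
  out <- cbind(features, flagged = flags)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
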