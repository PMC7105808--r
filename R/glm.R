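#' Prewhitened voxel-wise first-level GLM
#'
#' Ordinary least squares fit of the design (plus intercept) at every
#' in-mask voxel, followed by AR(1) prewhitening: the lag-1 autocorrelation
#' of the OLS residuals is estimated per voxel, smoothed spatially
#' (Gaussian, 5 voxel FWHM by default), then data and design are
#' transformed by the AR(1) whitening filter and refit. For speed the
#' smoothed coefficients are discretized to a 0.005 grid so voxels sharing
#' a coefficient are solved in one batch; the discretization is far below
#' the estimation noise of the coefficients themselves.
#'
#' @param vol a [volume4d()] with mask.
#' @param design a [build_design_matrix()] result (or any numeric matrix
#'   via the `X` element).
#' @param ar_smooth_fwhm_vox FWHM (voxels) of the spatial smoothing of the
#'   AR(1) coefficient map (default 5; 0 disables smoothing).
#' @param prewhiten set `FALSE` to keep the plain OLS fit (for
#'   calibration comparisons).
#' @param ar_rho optional fixed AR(1) coefficient applied at every voxel
#'   in place of the estimated map (0 reduces the whitening transform to
#'   the identity, so the fit equals plain OLS).
#' @return a `first_level_fit`: list with `pe` (p x V parameter
#'   estimates), `sigma2` (V residual variances), `xtx_inv` (list of
#'   per-voxel (X'X)^-1, indexed by AR bin), `ar_bin` (V), `dof`,
#'   `residuals` (T x V, whitened), `design_names`, `mask`, `voxel_mm`.
#' @export
fit_first_level <- function(vol, design, ar_smooth_fwhm_vox = 5,
                            prewhiten = TRUE, ar_rho = NULL) {
  X0 <- if (inherits(design, "design_matrix")) design$X else design
  Y <- vol_matrix(vol)                               # T x V
  Tn <- nrow(Y); V <- ncol(Y)
  X <- cbind(X0, intercept = 1)
  p <- ncol(X)
  if (Tn <= p + 2L) stop("too few timepoints for the design")
  qx <- qr(X)
  if (qx$rank < p) stop("rank-deficient design matrix")
  beta0 <- qr.coef(qx, Y)
  res0 <- Y - X %*% beta0
  dof <- Tn - p
  if (!prewhiten) {
    xtx_inv <- solve(crossprod(X))
    sigma2 <- colSums(res0^2) / dof
    return(structure(list(pe = beta0, sigma2 = sigma2,
                          xtx_inv = list(xtx_inv), ar_bin = rep(1L, V),
                          dof = dof, residuals = res0,
                          design_names = colnames(X), mask = vol$mask,
                          voxel_mm = vol$voxel_mm),
                     class = "first_level_fit"))
  }
  # voxel-wise lag-1 autocorrelation of the OLS residuals
  num <- colSums(res0[-1, , drop = FALSE] * res0[-Tn, , drop = FALSE])
  den <- colSums(res0^2)
  rho <- ifelse(den > 0, num / den, 0)
  rho <- pmax(pmin(rho, 0.95), -0.95)
  if (!is.null(ar_rho)) rho <- rep(ar_rho, V)
  if (is.null(ar_rho) && ar_smooth_fwhm_vox > 0) {
    sigma_vox <- ar_smooth_fwhm_vox / 2.3548
    rho_map <- unmask(rho, vol$mask)
    w_map <- smooth3d(array(as.numeric(vol$mask), dim(vol$mask)),
                      rep(sigma_vox, 3))
    rho_s <- smooth3d(rho_map, rep(sigma_vox, 3))
    rho <- (rho_s / pmax(w_map, 1e-12))[vol$mask]   # mask-renormalized
  }
  # discretize and refit per AR bin
  bins <- round(rho / 0.005) * 0.005
  ulev <- sort(unique(bins))
  ar_bin <- match(bins, ulev)
  pe <- matrix(0, p, V, dimnames = list(colnames(X), NULL))
  sigma2 <- numeric(V)
  residuals <- matrix(0, Tn, V)
  xtx_inv <- vector("list", length(ulev))
  for (b in seq_along(ulev)) {
    a <- ulev[b]
    idx <- which(ar_bin == b)
    Xw <- ar1_whiten(X, a)
    Yw <- ar1_whiten(Y[, idx, drop = FALSE], a)
    qw <- qr(Xw)
    bet <- qr.coef(qw, Yw)
    rw <- Yw - Xw %*% bet
    pe[, idx] <- bet
    sigma2[idx] <- colSums(rw^2) / dof
    residuals[, idx] <- rw
    xtx_inv[[b]] <- solve(crossprod(Xw))
  }
  structure(list(pe = pe, sigma2 = sigma2, xtx_inv = xtx_inv, ar_bin = ar_bin,
                 dof = dof, residuals = residuals, design_names = colnames(X),
                 mask = vol$mask, voxel_mm = vol$voxel_mm),
            class = "first_level_fit")
}

# AR(1) whitening transform: y*_1 = sqrt(1-a^2) y_1, y*_t = y_t - a y_{t-1}.
ar1_whiten <- function(M, a) {
  M <- as.matrix(M)
  if (a == 0) return(M)
  Tn <- nrow(M)
  out <- M
  out[1, ] <- sqrt(1 - a^2) * M[1, ]
  out[2:Tn, ] <- M[2:Tn, , drop = FALSE] - a * M[1:(Tn - 1), , drop = FALSE]
  out
}

#' The nine condition contrasts
#'
#' Registry of the contrasts computed for the three movement conditions:
#' each condition against rest and all pairwise comparisons.
#'
#' @param conditions condition labels (default F, H, V).
#' @return named list of contrast vectors over the primary regressors
#'   (derivative and intercept entries are implied zero).
#' @export
contrast_registry <- function(conditions = c("F", "H", "V")) {
  stopifnot(length(conditions) == 3L)
  cn <- conditions
  unit <- function(i) { v <- numeric(3); v[i] <- 1; v }
  out <- list()
  long <- c(F = "frontal", H = "horizontal", V = "vertical")[cn]
  if (any(is.na(long))) long <- cn
  for (i in 1:3) out[[paste0(long[i], " > rest")]] <- unit(i)
  pairs <- list(c(2, 1), c(3, 1), c(1, 3), c(2, 3), c(1, 2), c(3, 2))
  for (pr in pairs) {
    out[[paste0(long[pr[1]], " > ", long[pr[2]])]] <- unit(pr[1]) - unit(pr[2])
  }
  out
}

#' Contrast of parameter estimates with t and z maps
#'
#' `cope = c'beta`, `varcope = sigma^2 c'(X'X)^-1 c`, `t = cope /
#' sqrt(varcope)`, and `z` via the probability transform of the t
#' distribution at the fit's degrees of freedom.
#'
#' @param fit a [fit_first_level()] result.
#' @param contrast numeric contrast vector; shorter vectors are
#'   zero-padded over derivative and intercept columns.
#' @return a `stat_map`: list with in-mask vectors `cope`, `varcope`,
#'   `tstat`, `zstat`, plus `dof` and `mask`.
#' @export
contrast_to_z <- function(fit, contrast) {
  p <- nrow(fit$pe)
  cvec <- numeric(p)
  cvec[seq_along(contrast)] <- contrast
  cope <- drop(crossprod(cvec, fit$pe))
  quad <- vapply(fit$xtx_inv, function(M) drop(crossprod(cvec, M %*% cvec)),
                 numeric(1))
  varcope <- fit$sigma2 * quad[fit$ar_bin]
  tstat <- ifelse(varcope > 0, cope / sqrt(varcope),
                  ifelse(cope == 0, 0, sign(cope) * Inf))
  zstat <- t_to_z(ifelse(is.finite(tstat), tstat, sign(tstat) * 1e6), fit$dof)
  structure(list(cope = cope, varcope = varcope, tstat = tstat, zstat = zstat,
                 dof = fit$dof, mask = fit$mask, voxel_mm = fit$voxel_mm),
            class = "stat_map")
}

#' Simplified mixed-effects group map
#'
#' One-sample group analysis across subjects on a common grid: the
#' between-subject variance is estimated per voxel by method of moments
#' (clamped at zero), each subject is weighted by the inverse of
#' `varcope + sigma2_between`, and the weighted mean over its standard
#' error gives a t statistic on `n - 1` degrees of freedom, converted to
#' z. A deliberate simplification of two-stage Bayesian mixed-effects
#' estimation, adequate at desk scale.
#'
#' @param copes list (or V x n matrix) of per-subject contrast estimates.
#' @param varcopes matching list/matrix of per-subject variances.
#' @param mask logical 3D mask carried through to the result (optional).
#' @param voxel_mm voxel size carried through (optional).
#' @return a `stat_map` with `cope`, `varcope`, `tstat`, `zstat`, `dof`.
#' @export
group_level <- function(copes, varcopes, mask = NULL, voxel_mm = c(3, 3, 3)) {
  C <- if (is.list(copes)) do.call(cbind, copes) else as.matrix(copes)
  S <- if (is.list(varcopes)) do.call(cbind, varcopes) else as.matrix(varcopes)
  n <- ncol(C)
  if (n < 3L) stop("group analysis needs at least 3 subjects")
  stopifnot(identical(dim(C), dim(S)))
  cbar <- rowMeans(C)
  samp_var <- rowSums((C - cbar)^2) / (n - 1)
  sigma2_between <- pmax(samp_var - rowMeans(S), 0)
  W <- 1 / pmax(S + sigma2_between, 1e-12)
  sw <- rowSums(W)
  mu <- rowSums(W * C) / sw
  se <- sqrt(1 / sw)
  tstat <- mu / se
  dof <- n - 1
  structure(list(cope = mu, varcope = se^2, tstat = tstat,
                 zstat = t_to_z(tstat, dof), dof = dof, mask = mask,
                 voxel_mm = voxel_mm),
            class = "stat_map")
}

#' Residual smoothness of a statistic image
#'
#' Estimates the per-axis FWHM of the underlying Gaussian random field
#' from the spatial derivatives of the normalized residuals, and the
#' resel count of the search mask.
#'
#' @param residuals T x V matrix of (whitened) residuals.
#' @param mask logical 3D mask with V `TRUE` voxels.
#' @return list with `fwhm_vox` (per axis, voxels, clamped at 1.01) and
#'   `resels`.
#' @export
estimate_smoothness <- function(residuals, mask) {
  d <- dim(mask)
  Tn <- nrow(residuals)
  # normalize residual images to unit variance per voxel
  sdv <- apply(residuals, 2, stats::sd)
  sdv[sdv == 0] <- 1
  R <- sweep(residuals, 2, sdv, `/`)
  lambda <- numeric(3)
  counts <- numeric(3)
  idx_arr <- array(0L, d)
  idx_arr[mask] <- seq_len(sum(mask))
  for (ax in 1:3) {
    sel <- slice.index(idx_arr, ax) < d[ax]
    a <- idx_arr[sel]
    # neighbour along +ax
    nb <- array(0L, d)
    take <- lapply(d, seq_len)
    take[[ax]] <- c(2:d[ax], d[ax])
    nb <- do.call(`[`, c(list(idx_arr), take))
    dim(nb) <- d
    b <- nb[sel]
    ok <- a > 0L & b > 0L & a != b
    if (!any(ok)) next
    dr <- R[, b[ok], drop = FALSE] - R[, a[ok], drop = FALSE]
    lambda[ax] <- mean(dr^2) / 2          # var of derivative / var (unit)
    counts[ax] <- sum(ok)
  }
  lambda[lambda <= 0 | counts == 0] <- NA
  fwhm <- sqrt(4 * log(2) / lambda)
  if (any(is.na(fwhm))) {
    warning("degenerate smoothness estimate; clamping FWHM")
    fwhm[is.na(fwhm)] <- 1.01
  }
  if (any(fwhm < 1.01)) {
    warning("sub-voxel smoothness estimate; clamping FWHM at 1.01 voxels")
    fwhm <- pmax(fwhm, 1.01)
  }
  list(fwhm_vox = fwhm, resels = sum(mask) / prod(fwhm))
}

# Expected number of clusters above z under Gaussian-random-field theory
# (3D expected Euler characteristic times the resel count).
expected_clusters_grf <- function(z, resels) {
  resels * (4 * log(2))^1.5 * (2 * pi)^(-2) * (z^2 - 1) * exp(-z^2 / 2)
}

#' GRF cluster thresholding of a z map
#'
#' Thresholds the z image at `z_thresh`, labels 26-connected
#' supra-threshold clusters, and assigns each a corrected p-value from
#' Gaussian-random-field theory (Poisson clumping heuristic: expected
#' cluster count from the Euler characteristic density, cluster-extent
#' survival `exp(-beta k^(2/3))`). Clusters at or above `p_thresh` are
#' dropped.
#'
#' @param zstat in-mask z vector or a `stat_map`.
#' @param mask logical 3D mask.
#' @param residuals T x V residual matrix for smoothness estimation.
#' @param z_thresh cluster-forming threshold (default 3.1).
#' @param p_thresh corrected cluster significance threshold (default
#'   0.01).
#' @return a `cluster_table`: list with `clusters` (data.frame: id,
#'   size_voxels, p_cluster, peak_z), `label_map` (3D integer array,
#'   cluster ids), `smoothness`, `z_thresh`, `p_thresh`.
#' @export
grf_cluster_threshold <- function(zstat, mask, residuals, z_thresh = 3.1,
                                  p_thresh = 0.01) {
  z <- if (inherits(zstat, "stat_map")) zstat$zstat else zstat
  stopifnot(length(z) == sum(mask))
  sm <- estimate_smoothness(residuals, mask)
  zmap <- unmask(z, mask)
  supra <- zmap > z_thresh & mask
  lab <- label_components(supra, connectivity = 26L)
  n_clust <- max(lab)
  if (n_clust == 0L) {
    return(structure(list(clusters = data.frame(id = integer(0),
                                                size_voxels = integer(0),
                                                p_cluster = numeric(0),
                                                peak_z = numeric(0)),
                          label_map = lab, smoothness = sm,
                          z_thresh = z_thresh, p_thresh = p_thresh),
                     class = "cluster_table"))
  }
  sizes <- tabulate(lab[lab > 0L], n_clust)
  p <- vapply(sizes, function(k) {
    cluster_p_grf(k, z_thresh, sm$resels, sum(mask))
  }, numeric(1))
  peak <- vapply(seq_len(n_clust), function(i) max(zmap[lab == i]), numeric(1))
  keep <- which(p < p_thresh)
  # relabel surviving clusters by descending size
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  new_lab <- array(0L, dim(lab))
  for (j in seq_along(keep)) new_lab[lab == keep[j]] <- j
  structure(list(clusters = data.frame(id = seq_along(keep),
                                       size_voxels = sizes[keep],
                                       p_cluster = p[keep],
                                       peak_z = peak[keep]),
                 label_map = new_lab, smoothness = sm,
                 z_thresh = z_thresh, p_thresh = p_thresh),
            class = "cluster_table")
}

# Corrected cluster p-value: 1 - exp(-E[m] P(extent >= k)).
cluster_p_grf <- function(k_voxels, z_thresh, resels, n_mask_voxels) {
  Em <- max(expected_clusters_grf(z_thresh, resels), 1e-12)
  EN <- n_mask_voxels * stats::pnorm(z_thresh, lower.tail = FALSE)
  nbar <- max(EN / Em, 1e-12)
  beta <- (gamma(2.5) / nbar)^(2 / 3)
  p_extent <- exp(-beta * k_voxels^(2 / 3))
  1 - exp(-Em * p_extent)
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("<cluster_table> %d clusters above z > %.2f at p < %.2g (FWHM %s vox)\n",
              nrow(x$clusters), x$z_thresh, x$p_thresh,
              paste(sprintf("%.1f", x$smoothness$fwhm_vox), collapse = "x")))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Local maxima within significant clusters
#'
#' Within each cluster, voxels that are greater than or equal to all of
#' their 26-neighbours are candidate peaks; candidates are accepted in
#' descending z order (ties broken by lexicographic voxel index), each
#' suppressing later candidates within `min_dist_mm`, up to `max_n` peaks
#' overall. Peaks are annotated with the toy anatomical label volume.
#'
#' @param zstat in-mask z vector or a `stat_map`.
#' @param clusters a [grf_cluster_threshold()] result.
#' @param mask logical 3D mask.
#' @param voxel_mm voxel size in mm.
#' @param min_dist_mm minimum distance between accepted maxima
#'   (default 20).
#' @param max_n maximum number of maxima overall (default 100).
#' @param labels optional integer 3D label volume.
#' @param label_names optional character vector naming label codes.
#' @return data.frame: `cluster`, `x`, `y`, `z` (voxel indices), `Z`,
#'   `label`.
#' @export
local_maxima <- function(zstat, clusters, mask, voxel_mm = c(3, 3, 3),
                         min_dist_mm = 20, max_n = 100, labels = NULL,
                         label_names = NULL) {
  z <- if (inherits(zstat, "stat_map")) zstat$zstat else zstat
  zmap <- unmask(z, mask)
  lab <- clusters$label_map
  n_clust <- max(lab)
  if (n_clust == 0L) {
    return(data.frame(cluster = integer(0), x = integer(0), y = integer(0),
                      z = integer(0), Z = numeric(0), label = character(0)))
  }
  offs <- neighbour_offsets(26L)
  d <- dim(mask)
  cand <- list()
  for (ci in seq_len(n_clust)) {
    vox <- which(lab == ci, arr.ind = TRUE)
    is_peak <- vapply(seq_len(nrow(vox)), function(i) {
      v <- vox[i, ]
      zv <- zmap[v[1], v[2], v[3]]
      for (k in seq_len(nrow(offs))) {
        nx <- v[1] + offs[k, 1]; ny <- v[2] + offs[k, 2]; nz <- v[3] + offs[k, 3]
        if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2] || nz < 1 || nz > d[3]) next
        if (lab[nx, ny, nz] == ci && zmap[nx, ny, nz] > zv) return(FALSE)
      }
      TRUE
    }, logical(1))
    if (any(is_peak)) {
      vv <- vox[is_peak, , drop = FALSE]
      cand[[length(cand) + 1L]] <-
        data.frame(cluster = ci, x = vv[, 1], y = vv[, 2], z = vv[, 3],
                   Z = zmap[vv])
    }
  }
  if (!length(cand)) {
    return(data.frame(cluster = integer(0), x = integer(0), y = integer(0),
                      z = integer(0), Z = numeric(0), label = character(0)))
  }
  cand <- do.call(rbind, cand)
  # descending Z, lexicographic (x, y, z) tie-break
  cand <- cand[order(-cand$Z, cand$x, cand$y, cand$z), , drop = FALSE]
  accepted <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    if (nrow(accepted) >= max_n) break
    if (nrow(accepted)) {
      dist <- sqrt(((accepted$x - cand$x[i]) * voxel_mm[1])^2 +
                     ((accepted$y - cand$y[i]) * voxel_mm[2])^2 +
                     ((accepted$z - cand$z[i]) * voxel_mm[3])^2)
      if (any(dist < min_dist_mm)) next
    }
    accepted <- rbind(accepted, cand[i, ])
  }
  accepted$label <- if (is.null(labels)) {
    rep(NA_character_, nrow(accepted))
  } else {
    codes <- labels[cbind(accepted$x, accepted$y, accepted$z)]
    if (is.null(label_names)) as.character(codes) else {
      ifelse(codes > 0 & codes <= length(label_names),
             label_names[pmax(codes, 1)], "unlabelled")
    }
  }
  rownames(accepted) <- NULL
  accepted
}

#' Write cluster and peak tables as TSV
#'
#' @param clusters a [grf_cluster_threshold()] result.
#' @param peaks a [local_maxima()] result.
#' @param dir output directory.
#' @export
write_cluster_tables <- function(clusters, peaks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(clusters$clusters, file.path(dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(peaks, file.path(dir, "local_maxima.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
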