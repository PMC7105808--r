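#' Single-subject probabilistic spatial ICA
#'
#' Decomposes a pre-processed 4D series into `K` spatially independent
#' components: voxel-wise demeaning, PCA whitening to `K` dimensions in the
#' time domain, then fixed-point ICA with symmetric decorrelation and the
#' tanh contrast (restarted with fresh random rotations on
#' non-convergence). Component time courses are variance-normalized, maps
#' are scaled to z-like units by the residual-noise standard deviation,
#' signs are fixed so every map has positive skewness, and components are
#' ordered by explained variance.
#'
#' @param vol a [volume4d()].
#' @param mask logical 3D array (default: the volume's own mask).
#' @param K number of components (default 20).
#' @param seed seed for the random ICA initialization.
#' @param tol convergence tolerance of the fixed-point iteration
#'   (default 1e-6).
#' @param max_iter maximum fixed-point iterations per restart (default 500).
#' @param restarts maximum restarts on non-convergence (default 5).
#' @return a `component_set`: list with `maps` (K x V, z-scaled),
#'   `timecourses` (T x K, unit variance), `explained_var` (K shares),
#'   `voxel_means` (V), `sigma_res` (scalar residual SD), `mask`, `K`,
#'   `seed`, `tr_seconds`, `voxel_mm`.
#' @export
probabilistic_ica <- function(vol, mask = vol$mask, K = 20L, seed = 1L,
                              tol = 1e-6, max_iter = 500L, restarts = 5L) {
  stopifnot(!is.null(mask))
  X <- vol_matrix(vol, mask)                       # T x V
  Tn <- nrow(X); V <- ncol(X)
  if (K > min(Tn, V) - 1L) stop("K too large for ", Tn, " timepoints / ",
                                V, " voxels")
  if (V < 10L * K) stop("too few in-mask voxels (", V, ") for K = ", K)
  voxel_means <- colMeans(X)
  Xc <- sweep(X, 2, voxel_means)
  # remove the global (spatial-mean) time course as well, so the whitened
  # spatial rows are exactly zero-mean as the fixed-point update assumes
  row_means <- rowMeans(Xc)
  Xc <- Xc - row_means
  # PCA whitening in the time domain: C = Xc Xc' / V
  sv <- svd(Xc, nu = K, nv = 0)
  dK <- sv$d[seq_len(K)]
  if (any(dK < 1e-12 * sv$d[1])) {
    dK <- pmax(dK, 1e-12 * sv$d[1])               # rank-deficient guard
  }
  E <- sv$u                                       # T x K
  Z <- diag(1 / dK, K) %*% t(E) %*% Xc * sqrt(V)  # K x V, rows ~ unit var
  W <- .fastica_symm(Z, seed = seed, tol = tol, max_iter = max_iter,
                     restarts = restarts)
  S <- W %*% Z                                    # K x V spatial sources
  A <- E %*% diag(dK, K) %*% t(W) / sqrt(V)       # T x K mixing
  # reconstruction X ~ A S  (exactly the PCA-K reconstruction)
  resid <- Xc - A %*% S
  sigma_res <- stats::sd(as.vector(resid))
  sigma_res <- max(sigma_res, 1e-6 * stats::sd(as.vector(Xc)))
  # normalize: unit-variance time courses, amplitude absorbed into maps
  tc_sd <- apply(A, 2, stats::sd)
  tc_sd[tc_sd == 0] <- 1
  timecourses <- sweep(A, 2, tc_sd, `/`)
  maps <- sweep(S, 1, tc_sd, `*`) / sigma_res
  # sign convention: positive map skewness
  for (k in seq_len(K)) {
    if (.skewness(maps[k, ]) < 0) {
      maps[k, ] <- -maps[k, ]
      timecourses[, k] <- -timecourses[, k]
    }
  }
  # order by explained variance (S rows are orthogonal, so contributions add)
  total <- sum(Xc^2)
  expl <- colSums(A^2) * V / total
  ord <- order(expl, decreasing = TRUE)
  structure(list(maps = maps[ord, , drop = FALSE],
                 timecourses = timecourses[, ord, drop = FALSE],
                 explained_var = expl[ord], voxel_means = voxel_means,
                 row_means = row_means,
                 sigma_res = sigma_res, mask = mask, K = as.integer(K),
                 seed = as.integer(seed), tr_seconds = vol$tr_seconds,
                 voxel_mm = vol$voxel_mm),
            class = "component_set")
}

# Symmetric fixed-point FastICA with tanh contrast on whitened rows of Z.
# Stabilized: full fixed-point steps for the first half of the iteration
# budget; if not converged by then, the step size is damped geometrically.
# Directions with genuine non-Gaussian contrast reach their fixed point in
# the full-step phase; directions without contrast (noise subspace) have
# sampling-noise-driven updates with no fixed point, and the damping
# freezes them at the current rotation so the iteration terminates at a
# well-defined, seed-reproducible solution.
.fastica_symm <- function(Z, seed, tol, max_iter, restarts) {
  K <- nrow(Z); V <- ncol(Z)
  set.seed(seed)
  for (attempt in seq_len(restarts)) {
    W <- .sym_decorrelate(matrix(stats::rnorm(K * K), K, K))
    mu <- 1
    for (iter in seq_len(max_iter)) {
      WZ <- W %*% Z                               # K x V
      G <- tanh(WZ)
      gprime <- rowMeans(1 - G^2)
      W_upd <- (G %*% t(Z)) / V - diag(gprime, K) %*% W
      if (iter > max_iter / 2) mu <- mu * 0.93
      # align update signs row-wise before blending: fixed points of the
      # fast iteration are defined up to sign, and blending an unaligned
      # row (W_upd ~ -W) would cancel it and re-seed it randomly
      sgn <- sign(rowSums(W_upd * W))
      sgn[sgn == 0] <- 1
      W_new <- .sym_decorrelate((1 - mu) * W + mu * sgn * W_upd)
      delta <- max(abs(1 - abs(rowSums(W_new * W))))
      W <- W_new
      if (delta < tol) return(W)
    }
  }
  stop(sprintf(paste0("FastICA did not converge (%d restarts x %d iterations, ",
                      "tol %.1e); consider lowering K"),
               restarts, max_iter, tol))
}

# Symmetric decorrelation: W <- (W W')^{-1/2} W.
.sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  vals <- pmax(e$values, 1e-12)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors) %*% W
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> K = %d components over %d voxels, %d timepoints\n",
              x$K, ncol(x$maps), nrow(x$timecourses)))
  cat(sprintf("  explained variance: %s ...\n",
              paste(sprintf("%.3f", utils::head(x$explained_var, 5)), collapse = " ")))
  invisible(x)
}

#' @export
summary.component_set <- function(object, ...) {
  data.frame(component = seq_len(object$K),
             explained_var = object$explained_var,
             map_skewness = apply(object$maps, 1, .skewness))
}

# Reconstruct the in-mask data matrix (T x V) from a component set.
reconstruct_components <- function(cs, components = seq_len(cs$K)) {
  A <- cs$timecourses[, components, drop = FALSE]
  S <- cs$maps[components, , drop = FALSE] * cs$sigma_res
  sweep(A %*% S + cs$row_means, 2, cs$voxel_means, `+`)
}

#' Gaussian-mixture thresholding of a spatial map
#'
#' Fits a two-class Gaussian mixture (background + active) to the map
#' intensities by EM (deterministic k-means initialization, at most
#' `max_iter` iterations, tolerance `tol` on the log-likelihood) and
#' returns the posterior probability of the higher-mean class per voxel;
#' voxels with posterior above 0.5 form the active set. Degenerate fits
#' (either class weight below 1e-3, or no real separation between the
#' class means) yield an empty active set.
#'
#' @param map numeric vector of in-mask map intensities.
#' @param max_iter EM iteration cap (default 200).
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @return a `mixture_thresholded_map`: list with `posterior` (per voxel,
#'   in `[0,1]`), `active_set` (logical), `means`, `sds`, `weights`,
#'   `degenerate`.
#' @export
mixture_threshold <- function(map, max_iter = 200L, tol = 1e-6) {
  x <- as.numeric(map)
  n <- length(x)
  s_all <- stats::sd(x)
  if (!is.finite(s_all) || s_all == 0) stop("constant map cannot be thresholded")
  # near-constant guard: jitter at numerical-noise scale carries no classes
  if (s_all < 1e-8 * max(1, abs(mean(x)))) {
    return(structure(list(posterior = rep(0, n), active_set = rep(FALSE, n),
                          means = c(mean(x), mean(x)), sds = c(s_all, s_all),
                          weights = c(1, 0), degenerate = TRUE),
                     class = "mixture_thresholded_map"))
  }
  # deterministic k-means init: centres at the 25th and 97.5th percentiles
  init <- stats::quantile(x, c(0.25, 0.975), names = FALSE)
  if (init[1] >= init[2]) init <- c(mean(x) - s_all, mean(x) + s_all)
  km <- suppressWarnings(stats::kmeans(x, centers = matrix(init, 2, 1)))
  mu <- as.numeric(km$centers)
  sg <- vapply(1:2, function(k) {
    xs <- x[km$cluster == k]
    if (length(xs) < 2L) s_all / 10 else max(stats::sd(xs), s_all * 1e-3)
  }, numeric(1))
  w <- tabulate(km$cluster, 2) / n
  loglik_old <- -Inf
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    loglik <- sum(log(tot))
    if (is.finite(loglik) && abs(loglik - loglik_old) < tol) break
    loglik_old <- loglik
    w <- c(mean(1 - r2), mean(r2))
    if (min(w) < 1e-3) break
    mu[1] <- sum((1 - r2) * x) / sum(1 - r2)
    mu[2] <- sum(r2 * x) / sum(r2)
    sg[1] <- sqrt(sum((1 - r2) * (x - mu[1])^2) / sum(1 - r2))
    sg[2] <- sqrt(sum(r2 * (x - mu[2])^2) / sum(r2))
    sg <- pmax(sg, s_all * 1e-6)
  }
  # posterior of the higher-mean ("active") class
  hi <- which.max(mu)
  d_hi <- w[hi] * stats::dnorm(x, mu[hi], sg[hi])
  d_lo <- w[3 - hi] * stats::dnorm(x, mu[3 - hi], sg[3 - hi])
  tot <- d_hi + d_lo
  tot[tot == 0] <- .Machine$double.xmin
  posterior <- d_hi / tot
  degenerate <- min(w) < 1e-3 ||
    abs(diff(mu)) < 0.5 * max(sg)                  # classes not separated
  if (degenerate) posterior <- rep(0, n)
  structure(list(posterior = posterior, active_set = posterior > 0.5,
                 means = mu, sds = sg, weights = w, degenerate = degenerate),
            class = "mixture_thresholded_map")
}

#' Write a component set in a melodic-style layout
#'
#' Spatial maps as one 4D NIfTI (K volumes over the analysis grid) plus a
#' time-course TSV (one column per component).
#'
#' @param cs a [probabilistic_ica()] result.
#' @param dir output directory.
#' @export
write_component_set <- function(cs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(cs$mask)
  arr <- array(0, c(d, cs$K))
  for (k in seq_len(cs$K)) arr[, , , k] <- unmask(cs$maps[k, ], cs$mask)
  write_map_nifti(arr, file.path(dir, "melodic_IC.nii.gz"), cs$voxel_mm)
  tc <- as.data.frame(cs$timecourses)
  names(tc) <- paste0("IC", seq_len(cs$K))
  utils::write.table(tc, file.path(dir, "melodic_mix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
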