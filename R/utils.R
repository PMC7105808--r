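# Internal numerical helpers shared across pipeline stages.

#' @importFrom stats rnorm runif sd var cor coef lm pt qnorm pnorm dgamma
#'   quantile fft filter kmeans convolve
NULL

# Derive a reproducible child seed from a master seed and an index.
# Kept below 2^31 so it is always a valid integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 104729) %% 2147483647L)
}

# Sample variance with guard for length-1 input.
.svar <- function(x) if (length(x) < 2L) 0 else stats::var(x)

# Pearson correlation that tolerates constant inputs (returns NA).
safe_cor <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}

# One-dimensional Gaussian convolution matrix (rows renormalized to sum 1,
# so constants are preserved at the edges). sigma in sample units.
gauss_conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  K[abs(outer(idx, idx, "-")) > ceiling(4 * sigma)] <- 0
  K / rowSums(K)
}

# Separable 3D Gaussian smoothing of a 3D array; sigma_vox per axis (voxels).
smooth3d <- function(vol, sigma_vox) {
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3L)
  out <- vol
  if (sigma_vox[1] > 0) {
    K <- gauss_conv_matrix(d[1], sigma_vox[1])
    out <- array(K %*% matrix(out, d[1], d[2] * d[3]), d)
  }
  if (sigma_vox[2] > 0) {
    K <- gauss_conv_matrix(d[2], sigma_vox[2])
    tmp <- aperm(out, c(2, 1, 3))
    tmp <- array(K %*% matrix(tmp, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
    out <- aperm(tmp, c(2, 1, 3))
  }
  if (sigma_vox[3] > 0) {
    K <- gauss_conv_matrix(d[3], sigma_vox[3])
    tmp <- aperm(out, c(3, 1, 2))
    tmp <- array(K %*% matrix(tmp, d[3], d[1] * d[2]), c(d[3], d[1], d[2]))
    out <- aperm(tmp, c(2, 3, 1))
  }
  out
}

# Linear-interpolation matrix for a 1D fractional shift: out[i] = in[i - s],
# zero-filled outside the grid. Used both to inject and to correct motion.
shift1d_matrix <- function(n, s) {
  M <- matrix(0, n, n)
  src <- seq_len(n) - s
  i0 <- floor(src)
  w <- src - i0
  for (i in seq_len(n)) {
    a <- i0[i]; b <- a + 1L
    if (a >= 1 && a <= n) M[i, a] <- M[i, a] + (1 - w[i])
    if (w[i] > 0 && b >= 1 && b <= n) M[i, b] <- M[i, b] + w[i]
  }
  M
}

# Translate a 3D volume by shift_vox (fractional voxels, per axis) with
# separable linear interpolation; content moves in +shift direction.
shift_volume3d <- function(vol, shift_vox) {
  d <- dim(vol)
  out <- vol
  if (shift_vox[1] != 0) {
    out <- array(shift1d_matrix(d[1], shift_vox[1]) %*% matrix(out, d[1], d[2] * d[3]), d)
  }
  if (shift_vox[2] != 0) {
    tmp <- aperm(out, c(2, 1, 3))
    tmp <- array(shift1d_matrix(d[2], shift_vox[2]) %*% matrix(tmp, d[2], d[1] * d[3]),
                 c(d[2], d[1], d[3]))
    out <- aperm(tmp, c(2, 1, 3))
  }
  if (shift_vox[3] != 0) {
    tmp <- aperm(out, c(3, 1, 2))
    tmp <- array(shift1d_matrix(d[3], shift_vox[3]) %*% matrix(tmp, d[3], d[1] * d[2]),
                 c(d[3], d[1], d[2]))
    out <- aperm(tmp, c(2, 3, 1))
  }
  out
}

# Neighbour offsets for 3D connectivity (6 = faces, 26 = faces+edges+corners).
neighbour_offsets <- function(connectivity = 26L) {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), , drop = FALSE]
  if (connectivity == 6L) {
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1L, , drop = FALSE]
  } else if (connectivity != 26L) {
    stop("connectivity must be 6 or 26")
  }
  as.matrix(offs)
}

# Label connected components of a logical 3D array by breadth-first search.
# Returns an integer array; 0 = background. Labels are assigned in scan
# order of the first voxel encountered.
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  offs <- neighbour_offsets(connectivity)
  lab <- array(0L, d)
  active <- which(mask)
  if (length(active) == 0L) return(lab)
  nxt <- 0L
  queue <- integer(length(active))
  strides <- c(1L, d[1], d[1] * d[2])
  for (start in active) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    lab[start] <- nxt
    queue[1] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      v0 <- v - 1L
      x <- v0 %% d[1] + 1L
      y <- (v0 %/% d[1]) %% d[2] + 1L
      z <- v0 %/% (d[1] * d[2]) + 1L
      for (k in seq_len(nrow(offs))) {
        nx <- x + offs[k, 1]; ny <- y + offs[k, 2]; nz <- z + offs[k, 3]
        if (nx < 1L || nx > d[1] || ny < 1L || ny > d[2] || nz < 1L || nz > d[3]) next
        nv <- nx + (ny - 1L) * strides[2] + (nz - 1L) * strides[3]
        if (mask[nv] && lab[nv] == 0L) {
          lab[nv] <- nxt
          tail <- tail + 1L
          queue[tail] <- nv
        }
      }
    }
  }
  lab
}

# Binary erosion / dilation with a 6-connected structuring element.
erode3d <- function(mask) {
  d <- dim(mask)
  out <- mask
  pad <- function(a, ax, dir) {
    # shift logical array by one voxel, padding with FALSE
    idx <- lapply(d, seq_len)
    src <- idx
    src[[ax]] <- pmin(pmax(idx[[ax]] + dir, 1L), d[ax])
    shifted <- do.call(`[`, c(list(a), src))
    dim(shifted) <- d
    if (dir > 0) shifted[slice.index(shifted, ax) == d[ax]] <- FALSE
    else shifted[slice.index(shifted, ax) == 1L] <- FALSE
    shifted
  }
  for (ax in 1:3) for (dir in c(-1L, 1L)) out <- out & pad(mask, ax, dir)
  out
}

dilate3d <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (ax in 1:3) for (dir in c(-1L, 1L)) {
    idx <- lapply(d, seq_len)
    src <- idx
    src[[ax]] <- pmin(pmax(idx[[ax]] + dir, 1L), d[ax])
    shifted <- do.call(`[`, c(list(mask), src))
    dim(shifted) <- d
    if (dir > 0) shifted[slice.index(shifted, ax) == d[ax]] <- FALSE
    else shifted[slice.index(shifted, ax) == 1L] <- FALSE
    out <- out | shifted
  }
  out
}

# Fill interior holes of a binary mask: background components not touching
# the array border are absorbed into the mask.
fill_holes3d <- function(mask) {
  d <- dim(mask)
  bg <- label_components(!mask, connectivity = 6L)
  if (max(bg) == 0L) return(mask)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  touching <- unique(bg[border & bg > 0L])
  hole <- bg > 0L & !(bg %in% touching)
  mask | hole
}

# Convert a t statistic to a z score through the probability transform,
# stable in the far tails via log-scale cdf evaluation.
t_to_z <- function(t, dof) {
  z <- numeric(length(t))
  pos <- !is.na(t) & t >= 0
  z[pos] <- -stats::qnorm(stats::pt(t[pos], dof, lower.tail = FALSE, log.p = TRUE),
                          log.p = TRUE)
  z[!pos] <- stats::qnorm(stats::pt(t[!pos], dof, lower.tail = TRUE, log.p = TRUE),
                          log.p = TRUE)
  z[is.na(t)] <- NA_real_
  z
}

# Two-sided p-value for a Pearson correlation via the t transform (n-2 dof).
cor_p_value <- function(r, n) {
  if (is.na(r) || n < 3L) return(NA_real_)
  r <- max(min(r, 1 - 1e-15), -1 + 1e-15)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
}

# Skewness (biased moment estimator); used for the ICA sign convention.
.skewness <- function(x) {
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s == 0) return(0)
  mean(x^3) / s^3
}
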