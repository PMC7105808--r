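#' Build a pseudorandomized block paradigm
#'
#' Constructs the three-condition tongue-movement block timeline: movement
#' blocks of `block_s` seconds in pseudorandomized order (no condition more
#' than twice in a row), a long rest of `long_rest_s` after every third
#' movement block (including the final one), and short `short_rest_s` gaps
#' between the remaining blocks, preceded by a fixation lead-in.
#'
#' Onsets are expressed relative to the first retained volume (time 0 =
#' start of the analyzed series).
#'
#' @param conditions character vector of condition labels (default F, H, V
#'   for frontal/protrusion, horizontal/side-to-side, vertical/elevation).
#' @param blocks_per_condition movement blocks per condition (default 8).
#' @param block_s movement block duration, seconds (default 15).
#' @param long_rest_s rest after every third movement block (default 15).
#' @param short_rest_s gap between other blocks (default 3).
#' @param lead_in_s fixation period before the first block (default 15).
#' @param seed integer seed for the pseudorandomized condition order.
#' @return a `block_paradigm`: list with `events` (data.frame with columns
#'   `condition`, `onset`, `duration`; rest periods included as condition
#'   "rest") and `lead_in_s`.
#' @export
build_paradigm <- function(conditions = c("F", "H", "V"), blocks_per_condition = 8,
                           block_s = 15, long_rest_s = 15, short_rest_s = 3,
                           lead_in_s = 15, seed = 1L) {
  stopifnot(blocks_per_condition >= 1, block_s > 0, lead_in_s >= 0,
            length(conditions) >= 1)
  order <- pseudorandom_order(conditions, blocks_per_condition, seed)
  n_blocks <- length(order)
  events <- list()
  t <- lead_in_s
  if (lead_in_s > 0) {
    events[[length(events) + 1L]] <- data.frame(condition = "rest", onset = 0,
                                                duration = lead_in_s)
  }
  for (b in seq_len(n_blocks)) {
    events[[length(events) + 1L]] <- data.frame(condition = order[b], onset = t,
                                                duration = block_s)
    t <- t + block_s
    gap <- if (b %% 3L == 0L || b == n_blocks) long_rest_s else short_rest_s
    events[[length(events) + 1L]] <- data.frame(condition = "rest", onset = t,
                                                duration = gap)
    t <- t + gap
  }
  structure(list(events = do.call(rbind, events), lead_in_s = lead_in_s,
                 conditions = conditions),
            class = "block_paradigm")
}

# Seeded pseudorandomization: balanced condition counts with no condition
# appearing more than twice consecutively. Restarts on dead ends; errors
# if the constraint is unsatisfiable.
pseudorandom_order <- function(conditions, blocks_per_condition, seed,
                               max_restarts = 200L) {
  n_blocks <- length(conditions) * blocks_per_condition
  if (length(conditions) == 1L && blocks_per_condition > 2L) {
    stop("pseudorandomization impossible: a single condition cannot avoid ",
         "runs longer than 2")
  }
  set.seed(seed)
  for (restart in seq_len(max_restarts)) {
    remaining <- stats::setNames(rep(blocks_per_condition, length(conditions)),
                                 conditions)
    order <- character(0)
    ok <- TRUE
    for (b in seq_len(n_blocks)) {
      cand <- names(remaining)[remaining > 0]
      if (length(order) >= 2L) {
        last2 <- order[c(b - 1L, b - 2L)]
        if (last2[1] == last2[2]) cand <- setdiff(cand, last2[1])
      }
      if (length(cand) == 0L) { ok <- FALSE; break }
      pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
      order <- c(order, pick)
      remaining[pick] <- remaining[pick] - 1L
    }
    if (ok) return(order)
  }
  stop("pseudorandomization failed after ", max_restarts, " restarts")
}

#' @export
print.block_paradigm <- function(x, ...) {
  mv <- x$events[x$events$condition != "rest", ]
  cat(sprintf("<block_paradigm> %d movement blocks (%s), span %.1f s\n",
              nrow(mv), paste(unique(mv$condition), collapse = ", "),
              max(x$events$onset + x$events$duration)))
  invisible(x)
}

# Shift all onsets by delta_s (used for discard bookkeeping).
shift_paradigm <- function(paradigm, delta_s) {
  paradigm$events$onset <- paradigm$events$onset + delta_s
  paradigm
}

#' Gamma hemodynamic response kernel
#'
#' Samples the gamma-density HRF used throughout the pipeline. The
#' parameterization follows the convention of a mean lag and standard
#' deviation in seconds: shape `k = (lag/sd)^2`, scale `theta = sd^2/lag`,
#' shifted by `phase_s`. The kernel is normalized to unit sum so that
#' convolving a boxcar of height 1 yields a plateau of height 1.
#'
#' @param params list with `phase_s` (default 0), `sd_s` (default 3) and
#'   `mean_lag_s` (default 6); see [hrf_params()].
#' @param dt_s sampling interval in seconds.
#' @param support_s kernel support length in seconds (must cover
#'   `mean_lag + 5*sd`).
#' @return numeric vector of kernel samples at `seq(0, support_s, by = dt_s)`.
#' @export
gamma_hrf <- function(params = hrf_params(), dt_s = 0.05, support_s = 32) {
  stopifnot(dt_s > 0)
  if (params$sd_s <= 0 || params$mean_lag_s <= 0) {
    stop("HRF standard deviation and mean lag must be positive")
  }
  if (support_s < params$mean_lag_s + 5 * params$sd_s) {
    stop("support_s too short for the requested HRF")
  }
  shape <- (params$mean_lag_s / params$sd_s)^2
  scale <- params$sd_s^2 / params$mean_lag_s
  t <- seq(0, support_s, by = dt_s)
  h <- stats::dgamma(t - params$phase_s, shape = shape, scale = scale)
  h / sum(h)
}

#' HRF parameter set
#'
#' @param phase_s onset shift in seconds (default 0).
#' @param sd_s standard deviation of the gamma response, seconds (default 3).
#' @param mean_lag_s mean lag of the gamma response, seconds (default 6).
#' @return list of class `hrf_params`.
#' @export
hrf_params <- function(phase_s = 0, sd_s = 3, mean_lag_s = 6) {
  structure(list(phase_s = phase_s, sd_s = sd_s, mean_lag_s = mean_lag_s),
            class = "hrf_params")
}

# Convolve a set of (onset, duration) blocks with the HRF on a fine grid and
# sample at the volume acquisition times.
convolve_blocks <- function(blocks, hrf, dt_s, sample_times) {
  t_end <- max(sample_times) + 1
  fine_n <- ceiling(t_end / dt_s) + length(hrf) + 1L
  fine_t <- (seq_len(fine_n) - 1L) * dt_s
  box <- numeric(fine_n)
  if (nrow(blocks) > 0) {
    for (i in seq_len(nrow(blocks))) {
      on <- blocks$onset[i]; off <- on + blocks$duration[i]
      box[fine_t >= on & fine_t < off] <- 1
    }
  }
  resp <- stats::convolve(box, rev(hrf), type = "open")[seq_len(fine_n)]
  stats::approx(fine_t, resp, xout = sample_times, rule = 2)$y
}

# Central-difference gradient (forward/backward at the ends).
discrete_gradient <- function(x) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  g <- numeric(n)
  g[1] <- x[2] - x[1]
  g[n] <- x[n] - x[n - 1]
  if (n > 2L) g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  g
}

#' Build the first-level design matrix
#'
#' Each condition's block boxcar is convolved with the gamma HRF at fine
#' temporal resolution (`dt_s`, default 0.05 s), sampled at the volume
#' acquisition times `t = i * TR`, and paired with its temporal derivative
#' (a regressor of no interest absorbing small timing errors). The
#' `expected_response` column — the union of all movement blocks convolved
#' with the HRF — is the reference time course for the temporal filter.
#'
#' @param paradigm a [build_paradigm()] object (onsets relative to the first
#'   retained volume).
#' @param hrf_params_ HRF parameters, see [hrf_params()].
#' @param n_timepoints number of retained volumes.
#' @param tr_seconds repetition time in seconds.
#' @param dt_s fine convolution resolution (default 0.05 s).
#' @return a `design_matrix`: list with `X` (n_timepoints x 2*conditions
#'   matrix, EVs then derivatives), `expected_response`, `tr_seconds`,
#'   `n_timepoints`, `conditions`.
#' @export
build_design_matrix <- function(paradigm, hrf_params_ = hrf_params(),
                                n_timepoints, tr_seconds = 1.8, dt_s = 0.05) {
  ev <- paradigm$events
  span <- if (nrow(ev)) max(ev$onset + ev$duration) else 0
  scan_s <- n_timepoints * tr_seconds
  if (span > scan_s + 1e-9) {
    stop(sprintf("paradigm (%.1f s) longer than scan (%.1f s)", span, scan_s))
  }
  hrf <- gamma_hrf(hrf_params_, dt_s = dt_s,
                   support_s = max(32, hrf_params_$mean_lag_s + 5 * hrf_params_$sd_s))
  times <- (seq_len(n_timepoints) - 1L) * tr_seconds
  conds <- paradigm$conditions
  cols <- list()
  for (cn in conds) {
    blocks <- ev[ev$condition == cn, , drop = FALSE]
    cols[[cn]] <- convolve_blocks(blocks, hrf, dt_s, times)
  }
  movement <- ev[ev$condition != "rest", , drop = FALSE]
  expected <- convolve_blocks(movement, hrf, dt_s, times)
  X <- do.call(cbind, cols)
  D <- apply(X, 2, discrete_gradient)
  if (is.null(dim(D))) D <- matrix(D, ncol = ncol(X))
  colnames(D) <- paste0(conds, "_deriv")
  X <- cbind(X, D)
  structure(list(X = X, expected_response = expected, tr_seconds = tr_seconds,
                 n_timepoints = n_timepoints, conditions = conds),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d timepoints x %d regressors (%s) at TR %.3g s\n",
              x$n_timepoints, ncol(x$X), paste(colnames(x$X), collapse = ", "),
              x$tr_seconds))
  invisible(x)
}

#' Gaussian-weighted running-line high-pass filter
#'
#' At each time point a straight line is fitted to the series by weighted
#' least squares with Gaussian weights of standard deviation `sigma_s`
#' centred there; the fitted value is subtracted (removing drift and other
#' slow structure) and the series' global mean is re-added.
#'
#' @param series numeric vector (length >= 3).
#' @param sigma_s Gaussian weight SD in seconds (default 45).
#' @param tr_seconds sampling interval in seconds.
#' @return filtered series of the same length.
#' @export
highpass_filter <- function(series, sigma_s = 45, tr_seconds = 1.8) {
  n <- length(series)
  if (n < 3L) stop("series too short to high-pass filter")
  stopifnot(sigma_s > 0)
  t <- (seq_len(n) - 1L) * tr_seconds
  fitted <- numeric(n)
  for (i in seq_len(n)) {
    w <- exp(-(t - t[i])^2 / (2 * sigma_s^2))
    dt <- t - t[i]
    sw <- sum(w); swx <- sum(w * dt); swxx <- sum(w * dt^2)
    swy <- sum(w * series); swxy <- sum(w * dt * series)
    det <- sw * swxx - swx^2
    # weighted line a + b*dt evaluated at dt = 0
    fitted[i] <- (swxx * swy - swx * swxy) / det
  }
  series - fitted + mean(series)
}

#' Apply the running-line high-pass filter to every in-mask voxel
#'
#' Vectorized form of [highpass_filter()] for a whole 4D series: the
#' Gaussian-weighted running-line smoother is precomputed once as a
#' linear operator and applied to all in-mask voxel time series.
#'
#' @param vol a [volume4d()] with mask.
#' @param sigma_s Gaussian weight SD in seconds (default 45).
#' @return the filtered `volume4d`.
#' @export
highpass_volume <- function(vol, sigma_s = 45) {
  mask <- vol$mask
  stopifnot(!is.null(mask))
  Y <- vol_matrix(vol)                       # T x V
  n <- nrow(Y)
  t <- (seq_len(n) - 1L) * vol$tr_seconds
  # Precompute the linear smoother matrix once; filtering is linear.
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- exp(-(t - t[i])^2 / (2 * sigma_s^2))
    dt <- t - t[i]
    sw <- sum(w); swx <- sum(w * dt); swxx <- sum(w * dt^2)
    det <- sw * swxx - swx^2
    S[i, ] <- (swxx * w - swx * w * dt) / det
  }
  filtered <- Y - S %*% Y + matrix(colMeans(Y), n, ncol(Y), byrow = TRUE)
  d <- dim(vol$data)
  out <- array(0, d)
  m <- matrix(out, prod(d[1:3]), d[4])
  m[as.vector(mask), ] <- t(filtered)
  vol$data <- array(m, d)
  vol
}

#' Write paradigm events as a BIDS-style TSV
#'
#' Columns `onset`, `duration`, `trial_type`; rest periods are omitted.
#' @param paradigm a [build_paradigm()] object.
#' @param path output TSV path.
#' @export
write_events_tsv <- function(paradigm, path) {
  ev <- paradigm$events[paradigm$events$condition != "rest", ]
  out <- data.frame(onset = ev$onset, duration = ev$duration,
                    trial_type = ev$condition)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events TSV as a block paradigm
#'
#' @param path TSV with columns onset, duration, trial_type.
#' @param lead_in_s recorded for bookkeeping (default: first onset).
#' @export
read_events_tsv <- function(path, lead_in_s = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  if (is.null(lead_in_s)) lead_in_s <- min(tab$onset)
  events <- data.frame(condition = as.character(tab$trial_type),
                       onset = tab$onset, duration = tab$duration)
  events <- events[order(events$onset), ]
  structure(list(events = events, lead_in_s = lead_in_s,
                 conditions = unique(events$condition)),
            class = "block_paradigm")
}

#' Write a design matrix as TSV
#' @param design a [build_design_matrix()] object.
#' @param path output TSV path.
#' @export
write_design_tsv <- function(design, path) {
  out <- cbind(as.data.frame(design$X), expected_response = design$expected_response)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
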