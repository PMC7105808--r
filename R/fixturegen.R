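#' Acquisition protocol
#'
#' Bookkeeping for the synthetic scanner: TR, number of recorded volumes,
#' initial volumes to discard for signal equilibration, grid shape and voxel
#' size. The default records 308 volumes so that the four-volume discard
#' rule retains 304.
#'
#' @param tr_seconds repetition time, seconds (default 1.8).
#' @param n_recorded_volumes recorded volumes (default 308).
#' @param n_discard initial volumes discarded before analysis (default 4).
#' @param grid_shape integer triple (default 24 x 24 x 14).
#' @param voxel_mm voxel size triple in mm (default 3).
#' @return list of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(tr_seconds = 1.8, n_recorded_volumes = 308L,
                                 n_discard = 4L, grid_shape = c(24L, 24L, 14L),
                                 voxel_mm = c(3, 3, 3)) {
  stopifnot(tr_seconds > 0, n_recorded_volumes >= 1, n_discard >= 0,
            n_discard < n_recorded_volumes, length(grid_shape) == 3L,
            all(grid_shape >= 4L), all(voxel_mm > 0))
  structure(list(tr_seconds = tr_seconds,
                 n_recorded_volumes = as.integer(n_recorded_volumes),
                 n_discard = as.integer(n_discard),
                 grid_shape = as.integer(grid_shape),
                 voxel_mm = as.numeric(voxel_mm)),
            class = "acquisition_protocol")
}

# Ellipsoidal head mask centred in the grid (semi-axes 0.46 of each dim).
head_mask_for_grid <- function(grid_shape) {
  d <- grid_shape
  cx <- (d + 1) / 2
  ax <- 0.46 * d
  idx <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  r2 <- ((idx$x - cx[1]) / ax[1])^2 + ((idx$y - cx[2]) / ax[2])^2 +
    ((idx$z - cx[3]) / ax[3])^2
  array(r2 <= 1, d)
}

# Gaussian blob on the grid, centre in voxel coordinates, sd in voxels.
gaussian_blob <- function(grid_shape, centre, sigma) {
  d <- grid_shape
  gx <- exp(-(seq_len(d[1]) - centre[1])^2 / (2 * sigma^2))
  gy <- exp(-(seq_len(d[2]) - centre[2])^2 / (2 * sigma^2))
  gz <- exp(-(seq_len(d[3]) - centre[3])^2 / (2 * sigma^2))
  outer(outer(gx, gy), gz)
}

# Canonical blob layout: centres as fractions of the grid dimensions.
# Chosen once so that pairwise in-mask correlations stay below 0.3 on the
# default grid; verified at construction.
template_layout <- function() {
  list(
    visual_medial          = list(c(0.50, 0.24, 0.50)),
    visual_occipital_pole  = list(c(0.50, 0.08, 0.52)),
    visual_lateral         = list(c(0.24, 0.24, 0.46), c(0.76, 0.24, 0.46)),
    default_mode           = list(c(0.50, 0.38, 0.64), c(0.50, 0.84, 0.50)),
    cerebellum_stub        = list(c(0.50, 0.22, 0.24)),
    superior_sensorimotor  = list(c(0.50, 0.50, 0.88)),
    auditory               = list(c(0.18, 0.52, 0.42), c(0.82, 0.52, 0.42)),
    executive_control      = list(c(0.50, 0.64, 0.72)),
    left_frontoparietal    = list(c(0.24, 0.70, 0.58), c(0.28, 0.38, 0.66)),
    right_frontoparietal   = list(c(0.76, 0.70, 0.58), c(0.72, 0.38, 0.66))
  )
}

#' Build the ten-network template library
#'
#' Generates ten synthetic network surrogate maps (sums of Gaussian blobs,
#' zero outside the head mask) with the cardinality of the canonical
#' ten-network set used by the spatial filter: three visual networks,
#' default mode, a cerebellar stub, superior sensorimotor, auditory,
#' executive control and left/right fronto-parietal networks. Blob centres
#' receive a small seeded jitter; the construction errors if any pairwise
#' in-mask correlation reaches 0.3.
#'
#' @param grid_shape integer triple (default 24 x 24 x 14).
#' @param voxel_mm voxel size in mm.
#' @param seed integer seed for the centre jitter.
#' @param sigma_vox blob standard deviation in voxels; by default 1.3 on
#'   the reference 24 x 24 x 14 grid, scaled down proportionally on
#'   smaller grids so the ten blobs stay separable.
#' @return a `template_library`: list with `names`, `maps` (list of 3D
#'   arrays), `mask`, `labels` (integer label volume marking each
#'   template's peak blob), `voxel_mm`.
#' @export
build_template_library <- function(grid_shape = c(24L, 24L, 14L),
                                   voxel_mm = c(3, 3, 3), seed = 7L,
                                   sigma_vox = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(sigma_vox)) {
    sigma_vox <- 1.3 * min(1, min(grid_shape / c(24, 24, 14)))
  }
  mask <- head_mask_for_grid(grid_shape)
  layout <- template_layout()
  set.seed(seed)
  maps <- list()
  labels <- array(0L, grid_shape)
  for (i in seq_along(layout)) {
    m <- array(0, grid_shape)
    centres <- layout[[i]]
    for (j in seq_along(centres)) {
      ctr <- centres[[j]] * grid_shape + stats::runif(3, -0.3, 0.3)
      m <- m + gaussian_blob(grid_shape, ctr, sigma_vox)
      if (j == 1L) {
        # toy anatomical label: sphere of 2 voxels around the peak blob
        d2 <- (slice.index(labels, 1) - ctr[1])^2 +
          (slice.index(labels, 2) - ctr[2])^2 +
          (slice.index(labels, 3) - ctr[3])^2
        labels[d2 <= 4 & labels == 0L] <- i
      }
    }
    m[!mask] <- 0
    if (stats::sd(m[mask]) == 0) stop("template map constant within mask")
    maps[[names(layout)[i]]] <- m
  }
  cors <- template_cross_correlation(maps, mask)
  off <- abs(cors[upper.tri(cors)])
  if (max(off) >= 0.3) {
    stop(sprintf("grid too small for well-separated templates (max pairwise |r| = %.2f)",
                 max(off)))
  }
  structure(list(names = names(layout), maps = maps, mask = mask,
                 labels = labels, voxel_mm = as.numeric(voxel_mm)),
            class = "template_library")
}

# Pairwise in-mask Pearson correlation matrix of a list of maps.
template_cross_correlation <- function(maps, mask) {
  M <- sapply(maps, function(m) m[mask])
  stats::cor(M)
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("<template_library> %d templates on %s grid (%d in-mask voxels)\n",
              length(x$maps), paste(dim(x$mask), collapse = "x"), sum(x$mask)))
  cat(" ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Import user-supplied template maps from NIfTI files
#'
#' Replaces the synthetic surrogate library with maps read from disk (e.g.
#' resampled canonical network maps), keeping the library interface.
#'
#' @param paths named character vector of NIfTI paths (names become
#'   template names; exactly 10 expected by the spatial filter defaults,
#'   but any number is accepted).
#' @param mask_path NIfTI path of the analysis mask.
#' @return a `template_library`.
#' @export
import_template_library <- function(paths, mask_path) {
  stopifnot(length(names(paths)) == length(paths))
  mimg <- RNifti::readNifti(mask_path)
  mask <- array(as.array(mimg) > 0.5, dim(mimg))
  maps <- lapply(paths, function(p) {
    img <- RNifti::readNifti(p)
    arr <- array(as.array(img), dim(img))
    stopifnot(identical(dim(arr), dim(mask)))
    arr
  })
  structure(list(names = names(paths), maps = maps, mask = mask,
                 labels = array(0L, dim(mask)),
                 voxel_mm = RNifti::pixdim(mimg)[1:3]),
            class = "template_library")
}

# ---------------------------------------------------------------------------
# Scenario and planted components

#' Default simulation scenario
#'
#' Describes which components are planted in a synthetic subject, the noise
#' model, and the injected head-motion schedule. The defaults emulate the
#' signal structure the analysis assumes: one bilateral task-locked
#' sensorimotor component (target temporal correlation 0.7 with the expected
#' response), one canonical-network-like component (default mode, calibrated
#' spatial correlation 0.6 with its template, band-limited 0.01-0.1 Hz time
#' course), one edge-ring motion component tied to the injected motion, one
#' central CSF component with high-frequency time course, AR(1) voxel noise
#' (coefficient 0.3, innovation SD 1) and a low piecewise-constant motion
#' schedule.
#'
#' @param task_target_r temporal correlation target of the task plant
#'   (set negative for an anti-correlated plant; `NA` drops the plant).
#' @param task_amplitude amplitude of the task plant.
#' @param networks character vector of template names to plant (may be
#'   empty).
#' @param network_map_r calibrated in-mask spatial correlation between each
#'   planted network map and its template.
#' @param network_amplitude amplitude of network plants.
#' @param motion_component logical: plant an edge-ring motion component.
#' @param csf_component logical: plant a central CSF component.
#' @param noise_sd innovation SD of the AR(1) voxel noise.
#' @param ar_coef AR(1) coefficient of the voxel noise.
#' @param baseline_amplitude intensity of the static head (0 for pure
#'   signal-plus-noise fixtures).
#' @param motion one of "none", "low", "high", or a T x 3 matrix of
#'   translations in mm.
#' @param extra_task_r optional second task-locked plant's target
#'   correlation (e.g. -0.6 for the anti-correlated occipital-like plant);
#'   `NA` for none.
#' @return list of class `scenario`.
#' @export
default_scenario <- function(task_target_r = 0.7, task_amplitude = 3,
                             networks = "default_mode", network_map_r = 0.6,
                             network_amplitude = 3, motion_component = TRUE,
                             csf_component = TRUE, noise_sd = 1, ar_coef = 0.3,
                             baseline_amplitude = 100, motion = "low",
                             extra_task_r = NA) {
  structure(list(task_target_r = task_target_r, task_amplitude = task_amplitude,
                 networks = networks, network_map_r = network_map_r,
                 network_amplitude = network_amplitude,
                 motion_component = motion_component,
                 csf_component = csf_component, noise_sd = noise_sd,
                 ar_coef = ar_coef, baseline_amplitude = baseline_amplitude,
                 motion = motion, extra_task_r = extra_task_r),
            class = "scenario")
}

# Band-limited (f_lo..f_hi Hz) Gaussian time course via FFT masking.
bandlimited_noise <- function(n, tr, f_lo = 0.01, f_hi = 0.1) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) / (n * tr)
  f <- pmin(f, 1 / tr - f)            # two-sided frequency axis
  keep <- f >= f_lo & f <= f_hi
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  if (stats::sd(y) == 0) y <- stats::rnorm(n)
  (y - mean(y)) / stats::sd(y)
}

# Build a time course with exact correlation `target_r` with `reference`
# over the index set `idx` (the retained volumes).
correlated_timecourse <- function(reference, target_r, idx, tr,
                                  f_lo = 0.01, f_hi = 0.1) {
  n <- length(reference)
  g <- bandlimited_noise(n, tr, f_lo, f_hi)
  e <- reference
  es <- (e - mean(e[idx])) / stats::sd(e[idx])
  gs <- g - mean(g[idx])
  # orthogonalize the noise against the reference over the retained span
  gs <- gs - sum(gs[idx] * es[idx]) / sum(es[idx]^2) * es
  sg <- stats::sd(gs[idx])
  gs <- if (sg > 0) gs / sg else gs
  target_r * es + sqrt(max(0, 1 - target_r^2)) * gs
}

# Injected translation schedule (T x 3 mm).
motion_schedule <- function(kind, n) {
  if (is.matrix(kind)) {
    stopifnot(nrow(kind) == n, ncol(kind) == 3L)
    return(kind)
  }
  tr <- matrix(0, n, 3)
  if (identical(kind, "none")) return(tr)
  if (identical(kind, "low")) {
    # piecewise-constant drift with one brief spike; relative mean stays
    # far below the 1 mm exclusion limit
    pts <- sort(sample(seq(10L, n - 10L), 4L))
    lev <- matrix(stats::rnorm(15, 0, 0.25), 5, 3)
    bounds <- c(0L, pts, n)
    for (s in seq_len(5)) {
      tr[(bounds[s] + 1L):bounds[s + 1L], ] <-
        matrix(lev[s, ], bounds[s + 1L] - bounds[s], 3, byrow = TRUE)
    }
    spike <- sample(seq(20L, n - 20L), 1L)
    tr[spike, 1] <- tr[spike, 1] + 1.0
    return(tr)
  }
  if (identical(kind, "high")) {
    # incessant volume-to-volume jitter well above the 1 mm relative
    # limit (bounded, as a head in a coil is, rather than a drifting walk)
    return(matrix(stats::rnorm(n * 3, 0, 1.2), n, 3))
  }
  stop("unknown motion schedule: ", kind)
}

# Bilateral sensorimotor-like task map (lateral superior blob pair),
# placed away from every template centre.
task_plant_map <- function(grid_shape, mask, sigma_vox = 1.5) {
  m <- gaussian_blob(grid_shape, c(0.28, 0.56, 0.80) * grid_shape, sigma_vox) +
    gaussian_blob(grid_shape, c(0.72, 0.56, 0.80) * grid_shape, sigma_vox)
  m[!mask] <- 0
  m
}

# Occipital-like map for the anti-correlated plant; kept clearly interior
# to the head mask (boundary-adjacent placements are corrupted by the
# simulator's own motion edge artifacts, not by the component's signal).
occipital_plant_map <- function(grid_shape, mask, sigma_vox = 1.5) {
  m <- gaussian_blob(grid_shape, c(0.35, 0.20, 0.62) * grid_shape, sigma_vox) +
    gaussian_blob(grid_shape, c(0.65, 0.20, 0.62) * grid_shape, sigma_vox)
  m[!mask] <- 0
  m
}

# Central CSF blob and its mask.
csf_map <- function(grid_shape, mask, sigma_vox = 1.2) {
  m <- gaussian_blob(grid_shape, c(0.5, 0.5, 0.5) * grid_shape, sigma_vox)
  m[!mask] <- 0
  m
}

# Map with calibrated in-mask correlation `target_r` against `template`.
# The perturbation away from the template is itself sparse (extra blobs at
# individual-specific locations, plus mild smooth noise), mirroring how an
# individual's network differs from a canonical map by displaced or
# additional regions rather than by diffuse haze; blob centres keep at
# least 4 voxels from every template centre so the perturbation does not
# re-create another library network.
calibrated_network_map <- function(template, mask, target_r, sigma_vox = 1.3,
                                   n_extra_blobs = 3L) {
  d <- dim(template)
  # keep clear of template blobs AND the fixed plant sites (task,
  # occipital, CSF), so a perturbation never doubles another component
  avoid <- c(unlist(template_layout(), recursive = FALSE),
             list(c(0.28, 0.56, 0.80), c(0.72, 0.56, 0.80),
                  c(0.35, 0.20, 0.62), c(0.65, 0.20, 0.62),
                  c(0.50, 0.50, 0.50)))
  tmpl_centres <- do.call(rbind, lapply(avoid, function(f) f * d))
  pert <- array(0, d)
  placed <- 0L
  attempts <- 0L
  while (placed < n_extra_blobs && attempts < 200L) {
    attempts <- attempts + 1L
    ctr <- stats::runif(3, 0.15, 0.85) * d
    if (!mask[ceiling(ctr[1]), ceiling(ctr[2]), ceiling(ctr[3])]) next
    dist <- sqrt(rowSums(sweep(tmpl_centres, 2, ctr)^2))
    if (min(dist) < 4) next
    pert <- pert + gaussian_blob(d, ctr, sigma_vox)
    placed <- placed + 1L
  }
  pert <- pert + 0.3 * smooth3d(array(stats::rnorm(length(template)), d),
                                rep(sigma_vox, 3))
  tv <- template[mask]
  ts <- (tv - mean(tv)) / stats::sd(tv)
  nv <- pert[mask]
  nv <- nv - mean(nv)
  nv <- nv - sum(nv * ts) / sum(ts^2) * ts
  nv <- nv / stats::sd(nv)
  out <- array(0, dim(template))
  out[mask] <- target_r * ts + sqrt(max(0, 1 - target_r^2)) * nv
  out
}

#' Simulate one synthetic subject
#'
#' Builds a 4D series as baseline head + sum of planted components
#' (amplitude x spatial map x time course) + AR(1) voxel noise, then
#' resamples each volume under the injected per-volume head translations.
#' Ground truth for every plant is returned for downstream verification.
#'
#' @param protocol an [acquisition_protocol()].
#' @param paradigm a [build_paradigm()] object (onsets relative to the first
#'   retained volume).
#' @param scenario a [default_scenario()] object.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param template_library optional [build_template_library()] result;
#'   built with seed 7 on the protocol grid when omitted.
#' @return list with `raw` (a [volume4d()], no mask), `motion` (injected
#'   `motion_trace`), and `truth` (a `ground_truth` list: `planted`
#'   components, `motion_truth` T x 3 mm, `labels`, `networks_present`,
#'   `head_mask`, `csf_mask`, `template_library`).
#' @export
simulate_subject <- function(protocol = acquisition_protocol(),
                             paradigm = build_paradigm(),
                             scenario = default_scenario(), seed = 1L,
                             template_library = NULL) {
  if (is.null(template_library)) {
    template_library <- build_template_library(protocol$grid_shape,
                                               protocol$voxel_mm)
  }
  missing <- setdiff(scenario$networks, template_library$names)
  if (length(missing)) {
    stop("scenario requests networks absent from the library: ",
         paste(missing, collapse = ", "))
  }
  set.seed(seed)
  d <- protocol$grid_shape
  Tn <- protocol$n_recorded_volumes
  tr <- protocol$tr_seconds
  mask <- template_library$mask
  # expected response over recorded volumes; time 0 = first retained volume
  retained_idx <- (protocol$n_discard + 1L):Tn
  rec_times <- (seq_len(Tn) - 1L - protocol$n_discard) * tr
  hrf <- gamma_hrf()
  movement <- paradigm$events[paradigm$events$condition != "rest", , drop = FALSE]
  expected <- convolve_blocks(movement, hrf, 0.05, pmax(rec_times, 0))
  expected[rec_times < 0] <- 0

  plants <- list()
  add_plant <- function(name, map, tc, kind, amplitude, target_r = NA) {
    achieved <- if (is.na(target_r)) NA_real_ else
      stats::cor(tc[retained_idx], expected[retained_idx])
    if (!is.na(target_r) &&
        abs(achieved) < 0.9 * abs(target_r)) {
      stop("task-locked plant '", name, "' missed its target correlation")
    }
    plants[[length(plants) + 1L]] <<- list(
      name = name, map = map, timecourse = tc, timecourse_kind = kind,
      amplitude = amplitude, target_temporal_r = target_r,
      achieved_temporal_r = achieved)
  }
  if (!is.na(scenario$task_target_r)) {
    tc <- correlated_timecourse(expected, scenario$task_target_r, retained_idx, tr)
    add_plant("sensorimotor_task", task_plant_map(d, mask), tc, "task_locked",
              scenario$task_amplitude, scenario$task_target_r)
  }
  if (!is.na(scenario$extra_task_r)) {
    tc <- correlated_timecourse(expected, scenario$extra_task_r, retained_idx, tr)
    add_plant("occipital_anti", occipital_plant_map(d, mask), tc, "task_locked",
              scenario$task_amplitude, scenario$extra_task_r)
  }
  for (nw in scenario$networks) {
    map <- calibrated_network_map(template_library$maps[[nw]], mask,
                                  scenario$network_map_r)
    tc <- bandlimited_noise(Tn, tr, 0.01, 0.1)
    add_plant(paste0("network_", nw), map, tc, "network_structured",
              scenario$network_amplitude)
  }
  motion_mm <- motion_schedule(scenario$motion, Tn)
  if (isTRUE(scenario$motion_component)) {
    # one-voxel rim at the head boundary, the signature geometry of
    # residual motion; time course follows the signed volume-to-volume
    # translation change (what intensity at a fixed edge voxel sees)
    edge <- mask & !erode3d(mask)
    dtrans <- c(0, diff(motion_mm[, 1] + 0.5 * motion_mm[, 3]))
    if (stats::sd(dtrans) == 0) {
      dtrans[sample(seq_len(Tn), 6L)] <- stats::rnorm(6L)
    }
    tc <- dtrans + stats::rnorm(Tn, 0, 0.02 + stats::sd(dtrans) * 0.05)
    tc <- (tc - mean(tc)) / stats::sd(tc)
    m <- array(0, d); m[edge] <- 1
    add_plant("edge_motion", m, tc, "motion_spike", 2.5)
  }
  csf_mask_arr <- NULL
  if (isTRUE(scenario$csf_component)) {
    cm <- csf_map(d, mask)
    csf_mask_arr <- cm > 0.3 * max(cm)
    tc <- bandlimited_noise(Tn, tr, 0.15, 1 / (2 * tr))
    add_plant("csf", cm, tc, "csf", 2)
  }

  # assemble: baseline + plants + AR(1) noise
  V <- prod(d)
  data_mat <- matrix(0, V, Tn)
  if (scenario$baseline_amplitude > 0) {
    # near-binary head with a slightly soft edge, so intensity masking
    # recovers the true support
    profile <- smooth3d(array(as.numeric(mask), d), c(0.5, 0.5, 0.5))
    data_mat <- data_mat + as.vector(profile) * scenario$baseline_amplitude
  }
  for (p in plants) {
    data_mat <- data_mat + p$amplitude * outer(as.vector(p$map), p$timecourse)
  }
  if (scenario$noise_sd > 0) {
    wn <- matrix(stats::rnorm(V * Tn, 0, scenario$noise_sd), Tn, V)
    if (scenario$ar_coef != 0) {
      wn <- stats::filter(wn, scenario$ar_coef, method = "recursive")
      wn <- matrix(as.numeric(wn), Tn, V)
    }
    data_mat <- data_mat + t(wn)
  }
  arr <- array(data_mat, c(d, Tn))
  # inject rigid translations by resampling each volume
  if (any(motion_mm != 0)) {
    for (t in seq_len(Tn)) {
      if (any(motion_mm[t, ] != 0)) {
        arr[, , , t] <- shift_volume3d(arr[, , , t],
                                       motion_mm[t, ] / protocol$voxel_mm)
      }
    }
  }
  raw <- volume4d(arr, voxel_mm = protocol$voxel_mm, tr_seconds = tr)
  params <- cbind(matrix(0, Tn, 3), motion_mm)
  colnames(params) <- c("rot_x", "rot_y", "rot_z", "trans_x", "trans_y", "trans_z")
  motion <- motion_trace(params, reference_index = Tn %/% 2L + 1L)
  truth <- structure(list(planted = plants, motion_truth = motion_mm,
                          labels = template_library$labels,
                          networks_present = scenario$networks,
                          head_mask = mask, csf_mask = csf_mask_arr,
                          template_library = template_library,
                          expected_response = expected[retained_idx],
                          scenario = scenario, seed = seed),
                     class = "ground_truth")
  list(raw = raw, motion = motion, truth = truth)
}

#' Simulate a cohort of synthetic subjects
#'
#' @param protocol an [acquisition_protocol()].
#' @param paradigm a [build_paradigm()] object.
#' @param cohort_spec a [cohort_spec()] object.
#' @param seed master seed; per-subject seeds are derived deterministically.
#' @return list of per-subject `simulate_subject()` triples.
#' @export
simulate_cohort <- function(protocol = acquisition_protocol(),
                            paradigm = build_paradigm(),
                            cohort_spec = cohort_spec(), seed = 1L) {
  n <- cohort_spec$n
  if (n == 0L) return(list())
  lib <- build_template_library(protocol$grid_shape, protocol$voxel_mm)
  lapply(seq_len(n), function(i) {
    sc <- cohort_spec$scenario_for(i)
    simulate_subject(protocol, paradigm, sc, seed = derive_seed(seed, i),
                     template_library = lib)
  })
}

#' Cohort specification
#'
#' @param n number of subjects (default 17, the included-cohort size the
#'   generator mirrors).
#' @param scenario base [default_scenario()] applied to every subject.
#' @param network_subjects integer indices of subjects that receive the
#'   network plants (default: all); other subjects get the base scenario
#'   with `networks = character(0)`.
#' @param high_motion_subjects integer indices forced onto the "high"
#'   motion schedule (for exclusion tests).
#' @return list of class `cohort_spec` with a `scenario_for(i)` accessor.
#' @export
cohort_spec <- function(n = 17L, scenario = default_scenario(),
                        network_subjects = seq_len(n),
                        high_motion_subjects = integer(0)) {
  if (n < 0L) stop("cohort size must be non-negative")
  force(scenario); force(network_subjects); force(high_motion_subjects)
  structure(list(
    n = as.integer(n),
    scenario_for = function(i) {
      sc <- scenario
      if (!(i %in% network_subjects)) sc$networks <- character(0)
      if (i %in% high_motion_subjects) sc$motion <- "high"
      sc
    }),
    class = "cohort_spec")
}

#' Write a simulated subject to disk
#'
#' NIfTI for the 4D data, head mask, labels and templates; TSV for the
#' injected motion; JSON for the ground-truth manifest.
#'
#' @param subject result of [simulate_subject()].
#' @param dir output directory (created if needed).
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vol <- subject$raw
  vol$mask <- subject$truth$head_mask
  write_volume4d(vol, file.path(dir, "func.nii.gz"),
                 mask_path = file.path(dir, "mask.nii.gz"))
  write_map_nifti(subject$truth$labels, file.path(dir, "labels.nii.gz"),
                  vol$voxel_mm)
  write_motion_tsv(subject$motion, file.path(dir, "motion.tsv"))
  manifest <- list(
    seed = subject$truth$seed,
    networks_present = as.list(subject$truth$networks_present),
    planted = lapply(subject$truth$planted, function(p) {
      list(name = p$name, kind = p$timecourse_kind, amplitude = p$amplitude,
           target_temporal_r = p$target_temporal_r,
           achieved_temporal_r = p$achieved_temporal_r)
    }))
  jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
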