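# Shared fixtures, built in code at test time.

# A reduced protocol for unit tests where full size is not the point:
# same TR and discard rule, smaller grid and fewer volumes.
small_protocol <- function(n_recorded = 124L, grid = c(18L, 18L, 12L)) {
  acquisition_protocol(n_recorded_volumes = n_recorded, grid_shape = grid)
}

# Default design over the retained series (cached per session).
default_design <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_design_matrix(build_paradigm(), n_timepoints = 304L)
    }
    cache
  }
})

# Minimal component_set for feature/filter units that only need time
# courses and maps.
fake_component_set <- function(timecourses, maps, mask,
                               tr = 1.8, voxel_mm = c(3, 3, 3)) {
  timecourses <- as.matrix(timecourses)
  maps <- as.matrix(maps)
  K <- ncol(timecourses)
  structure(list(maps = maps, timecourses = timecourses,
                 explained_var = rep(1 / K, K),
                 voxel_means = rep(0, ncol(maps)),
                 row_means = rep(0, nrow(timecourses)),
                 sigma_res = 1, mask = mask, K = K, seed = 0L,
                 tr_seconds = tr, voxel_mm = voxel_mm),
            class = "component_set")
}

# Match recovered maps against planted sources: best |r| assignment by
# exhaustive permutation (small K only).
match_sources <- function(recovered, planted) {
  K <- nrow(planted)
  R <- abs(stats::cor(t(recovered), t(planted)))  # K x K
  perms <- .permutations(K)
  best <- -Inf; best_r <- NULL
  for (i in seq_len(nrow(perms))) {
    r <- R[cbind(seq_len(K), perms[i, ])]
    if (min(r) > best) { best <- min(r); best_r <- r }
  }
  best_r
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))
  }))
}

# Run the standard preprocessing chain (discard, realign, mask, smooth)
# on a simulated subject; returns list(vol, trace, truth).
preprocess_subject <- function(sub, protocol = acquisition_protocol()) {
  vol <- discard_initial(sub$raw, protocol$n_discard)
  re <- realign_translational(vol)
  vol <- re$vol
  vol$mask <- brain_mask(vol)
  vol <- smooth_and_normalize(vol)
  list(vol = vol, trace = re$trace, truth = sub$truth)
}

# Fully processed default-protocol subjects run through the complete
# pipeline (AROMA denoising, high-pass, filter-branch ICA), computed once
# and shared across acceptance-style tests.
processed_cohort <- local({
  cache <- list()
  function(n = 10L, scenario = NULL, tag = "default", run_glm = FALSE) {
    key <- paste0(tag, "_", n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    if (is.null(scenario)) {
      scenario <- default_scenario(extra_task_r = -0.6)
    }
    proto <- acquisition_protocol()
    paradigm <- build_paradigm()
    lib <- build_template_library(proto$grid_shape, proto$voxel_mm)
    out <- lapply(seq_len(n), function(i) {
      seed <- 1000L + i
      sub <- simulate_subject(proto, paradigm, scenario, seed = seed,
                              template_library = lib)
      cfg <- run_config(protocol = proto, paradigm = paradigm,
                        scenario = scenario, run_glm = run_glm, seed = seed)
      res <- run_subject(cfg, subject = sub, template_library = lib)
      list(sub = sub, res = res)
    })
    cache[[key]] <<- out
    out
  }
})

# Short paradigm fitting the reduced protocol (6 movement blocks, 147 s).
small_paradigm <- function(seed = 1L) {
  build_paradigm(blocks_per_condition = 2, seed = seed)
}
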