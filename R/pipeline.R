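#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis: acquisition
#' protocol, paradigm settings, thresholds, ICA dimensionality, branch
#' toggles and seeds. Serializes losslessly to JSON.
#'
#' @param protocol an [acquisition_protocol()].
#' @param paradigm a [build_paradigm()] object; by default the standard
#'   three-condition paradigm built with `paradigm_seed`.
#' @param paradigm_seed seed for the pseudorandomized block order.
#' @param scenario a [default_scenario()] describing the synthetic
#'   subject.
#' @param K ICA model order for the filter branch (default 20).
#' @param thresholds an [st_thresholds()] object.
#' @param aroma an [aroma_thresholds()] object.
#' @param z_thresh cluster-forming threshold (default 3.1).
#' @param p_thresh cluster significance threshold (default 0.01).
#' @param highpass_sigma_s high-pass sigma in seconds (default 45).
#' @param fwhm_mm smoothing kernel FWHM in mm (default 5).
#' @param rel_limit_mm,abs_limit_mm motion-exclusion limits (defaults 1
#'   and 3 mm).
#' @param run_glm,run_ica branch toggles.
#' @param seed master seed; stage seeds are derived deterministically.
#' @return list of class `run_config`.
#' @export
run_config <- function(protocol = acquisition_protocol(), paradigm = NULL,
                       paradigm_seed = 1L,
                       scenario = default_scenario(), K = 20L,
                       thresholds = st_thresholds(),
                       aroma = aroma_thresholds(), z_thresh = 3.1,
                       p_thresh = 0.01, highpass_sigma_s = 45, fwhm_mm = 5,
                       rel_limit_mm = 1, abs_limit_mm = 3, run_glm = TRUE,
                       run_ica = TRUE, seed = 1L) {
  if (is.null(paradigm)) paradigm <- build_paradigm(seed = paradigm_seed)
  structure(list(protocol = protocol, paradigm = paradigm,
                 paradigm_seed = as.integer(paradigm_seed),
                 scenario = scenario, K = as.integer(K),
                 thresholds = thresholds, aroma = aroma, z_thresh = z_thresh,
                 p_thresh = p_thresh, highpass_sigma_s = highpass_sigma_s,
                 fwhm_mm = fwhm_mm, rel_limit_mm = rel_limit_mm,
                 abs_limit_mm = abs_limit_mm, run_glm = run_glm,
                 run_ica = run_ica, seed = as.integer(seed)),
            class = "run_config")
}

#' Save / load a run configuration as JSON
#'
#' `load_config(save_config(cfg, path))` reproduces `cfg`.
#' @param config a [run_config()].
#' @param path JSON path.
#' @export
save_config <- function(config, path) {
  ser <- list(protocol = unclass(config$protocol),
              paradigm = list(events = config$paradigm$events,
                              lead_in_s = config$paradigm$lead_in_s,
                              conditions = config$paradigm$conditions),
              paradigm_seed = config$paradigm_seed,
              scenario = unclass(config$scenario),
              K = config$K,
              thresholds = unclass(config$thresholds),
              aroma = unclass(config$aroma),
              z_thresh = config$z_thresh, p_thresh = config$p_thresh,
              highpass_sigma_s = config$highpass_sigma_s,
              fwhm_mm = config$fwhm_mm,
              rel_limit_mm = config$rel_limit_mm,
              abs_limit_mm = config$abs_limit_mm,
              run_glm = config$run_glm, run_ica = config$run_ica,
              seed = config$seed)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- j$scenario
  scenario <- default_scenario(
    task_target_r = sc$task_target_r, task_amplitude = sc$task_amplitude,
    networks = as.character(unlist(sc$networks)),
    network_map_r = sc$network_map_r,
    network_amplitude = sc$network_amplitude,
    motion_component = sc$motion_component, csf_component = sc$csf_component,
    noise_sd = sc$noise_sd, ar_coef = sc$ar_coef,
    baseline_amplitude = sc$baseline_amplitude,
    motion = if (is.character(sc$motion)) sc$motion else as.matrix(sc$motion),
    extra_task_r = if (is.null(sc$extra_task_r)) NA else sc$extra_task_r)
  paradigm <- structure(list(events = as.data.frame(j$paradigm$events),
                             lead_in_s = j$paradigm$lead_in_s,
                             conditions = as.character(unlist(j$paradigm$conditions))),
                        class = "block_paradigm")
  run_config(
    paradigm = paradigm,
    protocol = acquisition_protocol(j$protocol$tr_seconds,
                                    j$protocol$n_recorded_volumes,
                                    j$protocol$n_discard,
                                    unlist(j$protocol$grid_shape),
                                    unlist(j$protocol$voxel_mm)),
    paradigm_seed = j$paradigm_seed, scenario = scenario, K = j$K,
    thresholds = st_thresholds(j$thresholds$r_temporal,
                               j$thresholds$p_temporal,
                               j$thresholds$r_spatial),
    aroma = aroma_thresholds(j$aroma$csf_threshold, j$aroma$hfc_threshold,
                             unlist(j$aroma$hyperplane)),
    z_thresh = j$z_thresh, p_thresh = j$p_thresh,
    highpass_sigma_s = j$highpass_sigma_s, fwhm_mm = j$fwhm_mm,
    rel_limit_mm = j$rel_limit_mm, abs_limit_mm = j$abs_limit_mm,
    run_glm = j$run_glm, run_ica = j$run_ica, seed = j$seed)
}

#' Run the full pipeline on one synthetic subject
#'
#' Stage order: simulate, discard initial volumes, realign to the middle
#' volume, motion exclusion check, brain mask, smooth and normalize,
#' ICA-AROMA denoising, high-pass filter, then the GLM branch and the
#' ICA + spatio-temporal filter branch. Subjects exceeding the motion
#' limits are marked excluded and downstream branches are skipped.
#'
#' @param config a [run_config()].
#' @param subject optional pre-simulated [simulate_subject()] triple
#'   (bypasses the simulate stage; used by [run_cohort()]).
#' @param template_library optional [build_template_library()].
#' @return a `subject_result`: list with `excluded`, `motion` (metrics +
#'   verdict), `aroma` (feature table + flags), `components` summary,
#'   `filter_report`, `cluster_table`, `peaks`, `log` (ordered stage
#'   data.frame), plus `skipped` markers for absent branches.
#' @export
run_subject <- function(config, subject = NULL, template_library = NULL) {
  stopifnot(inherits(config, "run_config"))
  proto <- config$protocol
  log <- list()
  note <- function(stage, ...) {
    params <- list(...)
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage,
      params = jsonlite::toJSON(params, auto_unbox = TRUE, digits = 10))
  }
  paradigm <- config$paradigm
  if (is.null(template_library)) {
    template_library <- build_template_library(proto$grid_shape, proto$voxel_mm)
  }
  if (is.null(subject)) {
    subject <- simulate_subject(proto, paradigm, config$scenario,
                                seed = derive_seed(config$seed, 1L),
                                template_library = template_library)
    note("simulate", seed = derive_seed(config$seed, 1L))
  }
  vol <- subject$raw
  vol <- discard_initial(vol, proto$n_discard)
  note("discard", n_discard = proto$n_discard)
  re <- realign_translational(vol)
  vol <- re$vol
  note("realign", reference = re$trace$reference_index)
  disp <- displacement_and_exclusion(re$trace, config$rel_limit_mm,
                                     config$abs_limit_mm)
  note("motion_check", rel_mean = disp$rel_mean, abs_mean = disp$abs_mean,
       exclude = disp$exclude)
  result <- list(excluded = disp$exclude, motion = disp,
                 motion_trace = re$trace,
                 aroma = "skipped", components = "skipped",
                 filter_report = "skipped", cluster_table = "skipped",
                 peaks = "skipped")
  if (disp$exclude) {
    result$log <- do.call(rbind, log)
    class(result) <- "subject_result"
    return(result)
  }
  vol$mask <- brain_mask(vol)
  note("brain_mask", n_voxels = sum(vol$mask))
  vol <- smooth_and_normalize(vol, config$fwhm_mm)
  note("smooth_normalize", fwhm_mm = config$fwhm_mm, grand_mean = 10000)
  # ICA-AROMA on the smoothed, normalized (not yet high-pass filtered) data
  aroma_K <- min(config$K, n_volumes(vol) %/% 4L)
  cs_aroma <- probabilistic_ica(vol, K = aroma_K,
                                seed = derive_seed(config$seed, 2L))
  edge <- edge_mask_from(vol$mask)
  csf <- if (!is.null(subject$truth$csf_mask)) subject$truth$csf_mask else
    csf_map(proto$grid_shape, vol$mask) > 0.3
  feats <- aroma_features(cs_aroma, re$trace, vol$mask, edge, csf,
                          tr = vol$tr_seconds)
  flags <- classify_noise(feats, config$aroma)
  vol <- nonaggressive_regress(vol, cs_aroma, flags)
  note("ica_aroma", K = aroma_K, n_flagged = sum(flags))
  result$aroma <- list(features = feats, flags = flags,
                       components = cs_aroma)
  # high-pass AFTER denoising
  vol <- highpass_volume(vol, config$highpass_sigma_s)
  note("highpass", sigma_s = config$highpass_sigma_s)
  design <- build_design_matrix(paradigm, hrf_params(),
                                n_timepoints = n_volumes(vol),
                                tr_seconds = vol$tr_seconds)
  if (isTRUE(config$run_glm)) {
    fit <- fit_first_level(vol, design)
    contrasts <- contrast_registry()
    stat <- contrast_to_z(fit, contrasts[[1]])
    ct <- grf_cluster_threshold(stat, vol$mask, fit$residuals,
                                config$z_thresh, config$p_thresh)
    peaks <- local_maxima(stat, ct, vol$mask, vol$voxel_mm,
                          labels = subject$truth$labels,
                          label_names = template_library$names)
    note("glm", contrast = names(contrasts)[1], z_thresh = config$z_thresh,
         p_thresh = config$p_thresh, n_clusters = nrow(ct$clusters))
    result$first_level <- fit
    result$stat_map <- stat
    result$cluster_table <- ct
    result$peaks <- peaks
  }
  if (isTRUE(config$run_ica)) {
    cs <- probabilistic_ica(vol, K = config$K,
                            seed = derive_seed(config$seed, 3L))
    note("ica", K = config$K)
    fr <- filter_report(cs, design$expected_response, template_library,
                        config$thresholds)
    note("st_filter", r_temporal = config$thresholds$r_temporal,
         p_temporal = config$thresholds$p_temporal,
         r_spatial = config$thresholds$r_spatial)
    result$components <- cs
    result$filter_report <- fr
  }
  result$design <- design
  result$log <- do.call(rbind, log)
  class(result) <- "subject_result"
  result
}

#' @export
print.subject_result <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("<subject_result> EXCLUDED (rel mean %.2f mm, abs mean %.2f mm)\n",
                x$motion$rel_mean, x$motion$abs_mean))
    return(invisible(x))
  }
  cat(sprintf("<subject_result> included (rel mean %.2f mm); stages: %s\n",
              x$motion$rel_mean, paste(x$log$stage, collapse = " -> ")))
  if (inherits(x$filter_report, "filter_report")) print(x$filter_report)
  invisible(x)
}

# Compact numeric manifest of a subject result (for determinism checks
# and JSON output).
subject_manifest <- function(result) {
  out <- list(excluded = result$excluded,
              rel_mean = result$motion$rel_mean,
              abs_mean = result$motion$abs_mean,
              stages = as.list(result$log$stage))
  if (inherits(result$filter_report, "filter_report")) {
    pc <- result$filter_report$per_component
    out$temporal_r <- pc$temporal_r
    out$temporal_flags <- pc$temporal_flag
    out$presence <- as.list(result$filter_report$presence)
  }
  if (inherits(result$cluster_table, "cluster_table")) {
    out$cluster_sizes <- result$cluster_table$clusters$size_voxels
    out$cluster_p <- result$cluster_table$clusters$p_cluster
  }
  if (is.list(result$aroma)) out$n_flagged <- sum(result$aroma$flags)
  out
}

#' Run a cohort of subjects through the pipeline
#'
#' @param configs list of [run_config()] objects (one per subject), or a
#'   single config plus `n` to replicate it with derived seeds.
#' @param n optional cohort size when a single config is given.
#' @param cohort_spec optional [cohort_spec()] controlling per-subject
#'   scenarios.
#' @return list with `results` (per-subject `subject_result`s),
#'   `summary` (network counts over included subjects), `n_excluded`.
#' @export
run_cohort <- function(configs, n = NULL, cohort_spec = NULL) {
  if (inherits(configs, "run_config")) {
    base <- configs
    stopifnot(!is.null(n))
    configs <- lapply(seq_len(n), function(i) {
      cfg <- base
      cfg$seed <- derive_seed(base$seed, 100L + i)
      if (!is.null(cohort_spec)) cfg$scenario <- cohort_spec$scenario_for(i)
      cfg
    })
  }
  stopifnot(length(configs) >= 1L)
  proto <- configs[[1]]$protocol
  lib <- build_template_library(proto$grid_shape, proto$voxel_mm)
  results <- lapply(configs, run_subject, template_library = lib)
  included <- Filter(function(r) !r$excluded, results)
  reports <- lapply(included, function(r) r$filter_report)
  reports <- Filter(function(f) inherits(f, "filter_report"), reports)
  summary <- cohort_summary(reports, template_names = lib$names)
  list(results = results, summary = summary,
       n_excluded = sum(vapply(results, `[[`, logical(1), "excluded")))
}

#' Write a subject result to a directory
#'
#' JSON manifest plus the stage tables (AROMA features, filter report,
#' cluster/peak tables) as TSV.
#'
#' @param result a [run_subject()] result.
#' @param dir output directory.
#' @export
write_subject_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(subject_manifest(result),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(result$log, file.path(dir, "stages.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (is.list(result$aroma)) {
    write_feature_table(result$aroma$features, result$aroma$flags,
                        file.path(dir, "aroma_features.tsv"))
  }
  if (inherits(result$filter_report, "filter_report")) {
    write_filter_report(result$filter_report, dir)
  }
  if (inherits(result$cluster_table, "cluster_table")) {
    write_cluster_tables(result$cluster_table,
                         if (is.data.frame(result$peaks)) result$peaks else
                           data.frame(),
                         dir)
  }
  invisible(dir)
}
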