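#' Spatio-temporal filter thresholds
#'
#' @param r_temporal absolute temporal correlation threshold (default 0.4).
#' @param p_temporal temporal significance level (default 0.05).
#' @param r_spatial spatial correlation threshold (default 0.4).
#' @return list of class `st_thresholds`.
#' @export
st_thresholds <- function(r_temporal = 0.4, p_temporal = 0.05,
                          r_spatial = 0.4) {
  stopifnot(r_temporal > 0, r_temporal < 1, p_temporal > 0, p_temporal < 1,
            r_spatial > 0, r_spatial < 1)
  structure(list(r_temporal = r_temporal, p_temporal = p_temporal,
                 r_spatial = r_spatial),
            class = "st_thresholds")
}

#' Temporal filter: correlation with the expected response
#'
#' Correlates every component time course with the expected hemodynamic
#' response (the union of all movement blocks convolved with the HRF).
#' A component is flagged `positive` when `r > r_temporal` with `p <
#' p_temporal` (two-sided, t transform at T-2 dof), `negative` when `r <
#' -r_temporal` with `p < p_temporal`, otherwise `none`. Constant time
#' courses yield an undefined correlation and flag `none` with a warning.
#'
#' @param components a [probabilistic_ica()] result (or a T x K matrix of
#'   time courses).
#' @param expected_response numeric vector, length T.
#' @param thresholds an [st_thresholds()] object.
#' @return data.frame: `component`, `temporal_r`, `temporal_p`,
#'   `temporal_flag`.
#' @export
temporal_filter <- function(components, expected_response,
                            thresholds = st_thresholds()) {
  tc <- if (inherits(components, "component_set")) components$timecourses
        else as.matrix(components)
  if (nrow(tc) != length(expected_response)) {
    stop("time course length (", nrow(tc), ") != expected response length (",
         length(expected_response), ")")
  }
  Tn <- nrow(tc)
  out <- lapply(seq_len(ncol(tc)), function(k) {
    r <- safe_cor(tc[, k], expected_response)
    if (is.na(r)) {
      warning("component ", k, " has a constant time course; flag set to none")
      return(data.frame(component = k, temporal_r = NA_real_,
                        temporal_p = NA_real_, temporal_flag = "none"))
    }
    p <- cor_p_value(r, Tn)
    flag <- if (r > thresholds$r_temporal && p < thresholds$p_temporal) {
      "positive"
    } else if (r < -thresholds$r_temporal && p < thresholds$p_temporal) {
      "negative"
    } else "none"
    data.frame(component = k, temporal_r = r, temporal_p = p,
               temporal_flag = flag)
  })
  do.call(rbind, out)
}

#' Spatial filter: cross-correlation with the template library
#'
#' Computes the in-mask Pearson correlation between every component map
#' and every template network map. All pairs exceeding `r_spatial` are
#' reported; each component is also assigned its best-matching template,
#' and a template counts as present for the subject when any component
#' exceeds the threshold. Spatial correlation uses the unthresholded
#' z-scaled maps by default; set `use_thresholded_maps` to correlate
#' mixture-thresholded maps (posterior-masked) instead.
#'
#' @param components a [probabilistic_ica()] result.
#' @param template_library a [build_template_library()] result on the
#'   same grid.
#' @param thresholds an [st_thresholds()] object.
#' @param use_thresholded_maps logical; apply [mixture_threshold()] to
#'   each map and correlate the map restricted to its active set
#'   (default FALSE).
#' @return list with `matches` (data.frame: component, template, r),
#'   `best_match` (data.frame: component, template, r), and
#'   `presence` (named logical over template names).
#' @export
spatial_filter <- function(components, template_library,
                           thresholds = st_thresholds(),
                           use_thresholded_maps = FALSE) {
  if (!identical(dim(components$mask), dim(template_library$mask))) {
    stop("component and template grids differ")
  }
  mask <- components$mask
  tmpl <- sapply(template_library$maps, function(m) m[mask])
  maps <- components$maps
  if (use_thresholded_maps) {
    maps <- t(apply(maps, 1, function(m) {
      thr <- mixture_threshold(m)
      ifelse(thr$active_set, m, 0)
    }))
  }
  R <- matrix(NA_real_, components$K, ncol(tmpl),
              dimnames = list(NULL, template_library$names))
  for (k in seq_len(components$K)) {
    for (j in seq_len(ncol(tmpl))) R[k, j] <- safe_cor(maps[k, ], tmpl[, j])
  }
  R[is.na(R)] <- 0
  hits <- which(R > thresholds$r_spatial, arr.ind = TRUE)
  matches <- data.frame(component = hits[, 1],
                        template = template_library$names[hits[, 2]],
                        r = R[hits])
  matches <- matches[order(-matches$r), , drop = FALSE]
  rownames(matches) <- NULL
  best_idx <- apply(R, 1, which.max)
  best_match <- data.frame(component = seq_len(components$K),
                           template = template_library$names[best_idx],
                           r = R[cbind(seq_len(components$K), best_idx)])
  presence <- apply(R > thresholds$r_spatial, 2, any)
  names(presence) <- template_library$names
  list(matches = matches, best_match = best_match, presence = presence,
       correlation_matrix = R)
}

#' Per-subject spatio-temporal filter report
#'
#' Runs both filters and combines them into one report; components
#' passing the temporal filter are not excluded from the spatial filter —
#' both statuses are recorded side by side.
#'
#' @param components a [probabilistic_ica()] result.
#' @param expected_response reference time course (length T).
#' @param template_library a [build_template_library()] result.
#' @param thresholds an [st_thresholds()] object.
#' @param use_thresholded_maps passed to [spatial_filter()].
#' @return a `filter_report`: list with `per_component` (data.frame:
#'   component, temporal_r, temporal_p, temporal_flag, best_template,
#'   best_spatial_r), `spatial_matches`, `presence`, `thresholds`.
#' @export
filter_report <- function(components, expected_response, template_library,
                          thresholds = st_thresholds(),
                          use_thresholded_maps = FALSE) {
  tf <- temporal_filter(components, expected_response, thresholds)
  sf <- spatial_filter(components, template_library, thresholds,
                       use_thresholded_maps)
  per_component <- cbind(tf,
                         best_template = sf$best_match$template,
                         best_spatial_r = sf$best_match$r)
  structure(list(per_component = per_component,
                 spatial_matches = sf$matches, presence = sf$presence,
                 thresholds = thresholds),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  pc <- x$per_component
  cat(sprintf("<filter_report> %d components: %d positive, %d negative temporal flags\n",
              nrow(pc), sum(pc$temporal_flag == "positive"),
              sum(pc$temporal_flag == "negative")))
  pres <- names(x$presence)[x$presence]
  cat("  networks present:",
      if (length(pres)) paste(pres, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Cohort summary of filter reports
#'
#' Counts, for every template network, the subjects in which it was
#' present, and per subject whether any component carried a positive
#' temporal flag. All template names are listed even at count zero.
#'
#' @param reports list of [filter_report()] results (possibly empty).
#' @param template_names template names for the schema; taken from the
#'   first report when omitted.
#' @return list with `network_counts` (data.frame: network,
#'   n_subjects_present, n_total) and `temporal_hits` (data.frame:
#'   subject, n_positive, n_negative).
#' @export
cohort_summary <- function(reports, template_names = NULL) {
  if (is.null(template_names)) {
    template_names <- if (length(reports)) names(reports[[1]]$presence)
                      else character(0)
  }
  n <- length(reports)
  counts <- vapply(template_names, function(nm) {
    sum(vapply(reports, function(r) isTRUE(r$presence[[nm]]), logical(1)))
  }, numeric(1))
  network_counts <- data.frame(network = template_names,
                               n_subjects_present = as.integer(counts),
                               n_total = n)
  temporal_hits <- if (n) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      pc <- reports[[i]]$per_component
      data.frame(subject = i,
                 n_positive = sum(pc$temporal_flag == "positive"),
                 n_negative = sum(pc$temporal_flag == "negative"))
    }))
  } else {
    data.frame(subject = integer(0), n_positive = integer(0),
               n_negative = integer(0))
  }
  list(network_counts = network_counts, temporal_hits = temporal_hits)
}

#' Write a filter report as TSV + JSON
#'
#' @param report a [filter_report()] result.
#' @param dir output directory.
#' @export
write_filter_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$per_component,
                     file.path(dir, "filter_components.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$spatial_matches,
                     file.path(dir, "spatial_matches.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(presence = as.list(report$presence),
                            thresholds = unclass(report$thresholds)),
                       file.path(dir, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a cohort summary as TSV
#' @param summary a [cohort_summary()] result.
#' @param path output TSV path.
#' @export
write_cohort_summary <- function(summary, path) {
  utils::write.table(summary$network_counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
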