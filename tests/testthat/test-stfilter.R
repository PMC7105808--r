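test_that("temporal filter flags components by correlation and significance", {
  des <- default_design()
  e <- des$expected_response
  Tn <- length(e)
  set.seed(1)
  tcs <- cbind(e,                                   # r = 1
               -e + rnorm(Tn, 0, 0.1 * sd(e)),      # strongly negative
               rnorm(Tn))                           # unrelated
  tf <- temporal_filter(tcs, e)
  expect_equal(tf$temporal_flag, c("positive", "negative", "none"))
  expect_equal(tf$temporal_r[1], 1)
  expect_lt(tf$temporal_p[2], 0.05)
  # defaults: |r| > 0.4 at p < 0.05
  th <- st_thresholds()
  expect_equal(th$r_temporal, 0.4)
  expect_equal(th$p_temporal, 0.05)
  expect_equal(th$r_spatial, 0.4)
  # sub-threshold correlation is not flagged even when significant
  weak <- 0.3 * e + rnorm(Tn, 0, sqrt(1 - 0.09) * sd(e))
  tfw <- temporal_filter(cbind(weak), e)
  expect_lt(tfw$temporal_p, 0.05)
  expect_equal(tfw$temporal_flag, "none")
  # constant time course warns and flags none
  expect_warning(tfc <- temporal_filter(cbind(rep(1, Tn)), e), "constant")
  expect_equal(tfc$temporal_flag, "none")
  expect_error(temporal_filter(tcs[1:100, ], e), "length")
})

test_that("temporal correlations match a brute-force oracle to 1e-12", {
  set.seed(2)
  Tn <- 120L
  e <- rnorm(Tn)
  tcs <- matrix(rnorm(Tn * 100), Tn, 100)
  tf <- temporal_filter(tcs, e)
  oracle <- apply(tcs, 2, function(x) {
    xm <- x - mean(x); em <- e - mean(e)
    sum(xm * em) / sqrt(sum(xm^2) * sum(em^2))
  })
  expect_lt(max(abs(tf$temporal_r - oracle)), 1e-12)
})

test_that("filter decisions are invariant to affine rescaling", {
  des <- default_design()
  e <- des$expected_response
  set.seed(3)
  Tn <- length(e)
  tcs <- cbind(0.8 * e + rnorm(Tn, 0, 0.5 * sd(e)), rnorm(Tn))
  tf1 <- temporal_filter(tcs, e)
  tf2 <- temporal_filter(sweep(tcs, 2, c(37, 0.01), `*`) + 5, e)
  expect_equal(tf1$temporal_r, tf2$temporal_r, tolerance = 1e-12)
  expect_identical(tf1$temporal_flag, tf2$temporal_flag)
  # spatial side: rescaled maps give identical correlations
  lib <- build_template_library()
  mask <- lib$mask
  set.seed(4)
  maps <- rbind(lib$maps$auditory[mask] + rnorm(sum(mask), 0, 0.3),
                rnorm(sum(mask)))
  cs1 <- fake_component_set(tcs, maps, mask)
  cs2 <- fake_component_set(tcs, maps * -3 + 1, mask)
  sf1 <- spatial_filter(cs1, lib)
  sf2 <- spatial_filter(cs2, lib)
  expect_equal(abs(sf1$correlation_matrix), abs(sf2$correlation_matrix),
               tolerance = 1e-12)
})

test_that("spatial filter matches templates and reports presence", {
  lib <- build_template_library()
  mask <- lib$mask
  V <- sum(mask)
  set.seed(5)
  # inject a template itself as a fake component: exact match
  maps <- rbind(lib$maps$default_mode[mask],
                rnorm(V))
  tcs <- matrix(rnorm(100 * 2), 100, 2)
  cs <- fake_component_set(tcs, maps, mask)
  sf <- spatial_filter(cs, lib)
  self <- sf$matches[sf$matches$component == 1 &
                       sf$matches$template == "default_mode", ]
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_true(sf$presence[["default_mode"]])
  # pure-noise component matches nothing
  expect_false(any(sf$matches$component == 2))
  expect_equal(sf$best_match$template[1], "default_mode")
  # grid mismatch errors
  lib2 <- build_template_library(grid_shape = c(20L, 20L, 12L))
  expect_error(spatial_filter(cs, lib2), "grids differ")
})

test_that("calibrated planted maps match only their own template", {
  lib <- build_template_library()
  mask <- lib$mask
  hits <- 0L; clean <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    map <- stfica:::calibrated_network_map(lib$maps$default_mode, mask, 0.6)
    cs <- fake_component_set(matrix(rnorm(60), 60, 1),
                             rbind(map[mask]), mask)
    sf <- spatial_filter(cs, lib)
    got <- sf$matches$template[sf$matches$component == 1]
    if ("default_mode" %in% got) hits <- hits + 1L
    if (length(setdiff(got, "default_mode")) == 0L) clean <- clean + 1L
  }
  expect_gte(hits, 9L)
  expect_gte(clean, 9L)
})

test_that("thresholded-map spatial filtering is available as a variant", {
  lib <- build_template_library()
  mask <- lib$mask
  V <- sum(mask)
  set.seed(6)
  # clear activation structure: template plus background noise
  maps <- rbind(4 * (lib$maps$auditory[mask] / max(lib$maps$auditory)) +
                  rnorm(V, 0, 0.3))
  cs <- fake_component_set(matrix(rnorm(80), 80, 1), maps, mask)
  sf <- spatial_filter(cs, lib, use_thresholded_maps = TRUE)
  expect_true(sf$presence[["auditory"]])
})

test_that("cohort summaries count network presence with a full schema", {
  lib <- build_template_library()
  mask <- lib$mask
  V <- sum(mask)
  make_report <- function(with_dmn, seed) {
    set.seed(seed)
    maps <- rbind(if (with_dmn) lib$maps$default_mode[mask] else rnorm(V),
                  rnorm(V))
    e <- default_design()$expected_response
    tcs <- cbind(e, rnorm(length(e)))
    filter_report(fake_component_set(tcs, maps, mask), e, lib)
  }
  reports <- c(lapply(1:5, function(i) make_report(TRUE, i)),
               list(make_report(FALSE, 6)))
  cs <- cohort_summary(reports)
  expect_equal(nrow(cs$network_counts), 10L)
  expect_setequal(cs$network_counts$network, lib$names)
  expect_equal(cs$network_counts$n_subjects_present[
    cs$network_counts$network == "default_mode"], 5L)
  expect_true(all(cs$network_counts$n_total == 6L))
  # every subject carries one positive temporal flag by construction
  expect_true(all(cs$temporal_hits$n_positive >= 1L))
  # empty cohort: empty but well-formed tables
  cs0 <- cohort_summary(list(), template_names = lib$names)
  expect_equal(nrow(cs0$network_counts), 10L)
  expect_true(all(cs0$network_counts$n_subjects_present == 0L))
  expect_equal(nrow(cs0$temporal_hits), 0L)
})

test_that("filter reports serialize to TSV and JSON", {
  lib <- build_template_library()
  mask <- lib$mask
  set.seed(8)
  e <- default_design()$expected_response
  cs <- fake_component_set(cbind(e, rnorm(length(e))),
                           rbind(lib$maps$default_mode[mask],
                                 rnorm(sum(mask))), mask)
  fr <- filter_report(cs, e, lib)
  dir <- withr::local_tempdir()
  write_filter_report(fr, dir)
  tab <- read.delim(file.path(dir, "filter_components.tsv"))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$temporal_flag, c("positive", "none"))
  js <- jsonlite::read_json(file.path(dir, "filter_report.json"))
  expect_true(js$presence$default_mode)
  path <- file.path(dir, "cohort.tsv")
  write_cohort_summary(cohort_summary(list(fr)), path)
  expect_equal(nrow(read.delim(path)), 10L)
})
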