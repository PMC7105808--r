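toy_vol <- function(Y, grid = NULL) {
  # wrap a T x V matrix as a fully-masked volume4d
  V <- ncol(Y)
  if (is.null(grid)) grid <- c(V, 1L, 1L)
  mask <- array(TRUE, grid)
  arr <- array(t(Y), c(grid, nrow(Y)))
  volume4d(arr, mask = mask)
}

test_that("prewhitening at a zero AR coefficient reduces to plain OLS", {
  des <- default_design()
  set.seed(1)
  Y <- matrix(rnorm(304 * 40), 304, 40)
  vol <- toy_vol(Y, c(10L, 2L, 2L))
  fit <- fit_first_level(vol, des, ar_rho = 0)
  X <- cbind(des$X, 1)
  beta <- solve(t(X) %*% X) %*% t(X) %*% Y
  expect_lt(max(abs(fit$pe - beta)), 1e-8)
  expect_equal(fit$dof, 304 - 7)
})

test_that("noise-free regressor multiples are recovered exactly", {
  des <- default_design()
  Y <- cbind(2 * des$X[, "F"], matrix(0, 304, 3))
  vol <- toy_vol(Y, c(2L, 2L, 1L))
  fit <- fit_first_level(vol, des)
  expect_equal(unname(fit$pe["F", 1]), 2, tolerance = 1e-10)
  # all-zero voxels give all-zero parameter estimates
  expect_true(all(abs(fit$pe[, 2:4]) < 1e-12))
  # rank-deficient designs are rejected
  bad <- cbind(des$X, des$X[, 1])
  expect_error(fit_first_level(vol, bad), "rank-deficient")
})

test_that("contrasts produce correct copes, t and z statistics", {
  des <- default_design()
  set.seed(2)
  # equal loading on F and H: the difference contrast is null
  Y <- des$X[, "F"] %*% t(rep(1, 30)) + des$X[, "H"] %*% t(rep(1, 30)) +
    matrix(rnorm(304 * 30, 0, 0.1), 304, 30)
  vol <- toy_vol(Y, c(10L, 3L, 1L))
  fit <- fit_first_level(vol, des, ar_rho = 0)
  null_stat <- contrast_to_z(fit, c(1, -1, 0))
  expect_lt(mean(abs(null_stat$zstat)), 1)    # centred on zero
  active <- contrast_to_z(fit, c(1, 0, 0))
  expect_gt(min(active$zstat), 10)            # strong planted effect
  # cope linearity: cope(c1 + c2) = cope(c1) + cope(c2)
  c1 <- c(1, 0, 0); c2 <- c(0, 1, 0)
  expect_equal(contrast_to_z(fit, c1 + c2)$cope,
               contrast_to_z(fit, c1)$cope + contrast_to_z(fit, c2)$cope)
  # t -> z probability transform against a reference value
  expect_equal(stfica:::t_to_z(3, 100), 2.93, tolerance = 0.02)
  expect_equal(stfica:::t_to_z(-3, 100), -2.93, tolerance = 0.02)
  expect_equal(stfica:::t_to_z(0, 50), 0)
})

test_that("the contrast registry lists the nine condition contrasts", {
  reg <- contrast_registry()
  expect_length(reg, 9L)
  expect_named(reg, c("frontal > rest", "horizontal > rest",
                      "vertical > rest", "horizontal > frontal",
                      "vertical > frontal", "frontal > vertical",
                      "horizontal > vertical", "frontal > horizontal",
                      "vertical > horizontal"))
  expect_equal(reg[["frontal > rest"]], c(1, 0, 0))
  expect_equal(reg[["horizontal > frontal"]], c(-1, 1, 0))
})

test_that("first-level type-I error is calibrated by prewhitening", {
  des <- default_design()
  grid <- c(16L, 16L, 8L)
  V <- prod(grid)
  set.seed(5)
  wn <- matrix(rnorm(304 * V), 304, V)
  ar <- matrix(as.numeric(stats::filter(wn, 0.3, method = "recursive")),
               304, V)
  vol <- toy_vol(ar, grid)
  z_pw <- contrast_to_z(fit_first_level(vol, des), c(1, 0, 0))$zstat
  z_ols <- contrast_to_z(fit_first_level(vol, des, prewhiten = FALSE),
                         c(1, 0, 0))$zstat
  frac_pw <- mean(abs(z_pw) > 1.96)
  frac_ols <- mean(abs(z_ols) > 1.96)
  expect_gte(frac_pw, 0.03)
  expect_lte(frac_pw, 0.07)
  expect_gt(frac_ols, 0.07)   # why prewhitening exists
})

test_that("group maps combine subjects with mixed-effects weighting", {
  # identical copes with zero varcopes pass through unchanged
  n <- 5L
  C <- matrix(rep(c(2, -1, 0.5), n), 3, n)
  S <- matrix(0, 3, n)
  g <- group_level(C, S)
  expect_equal(g$cope, c(2, -1, 0.5))
  expect_equal(g$dof, 4L)
  # equal varcopes: z agrees with the one-sample t oracle
  set.seed(6)
  V <- 400L; n <- 10L
  C <- matrix(rnorm(V * n), V, n)
  S <- matrix(0.05, V, n)
  g2 <- group_level(C, S)
  t_oracle <- apply(C, 1, function(x) {
    mean(x) / sqrt(var(x) / length(x))
  })
  z_oracle <- stfica:::t_to_z(t_oracle, n - 1)
  expect_lt(stats::quantile(abs(g2$zstat - z_oracle), 0.95), 0.05)
  # null calibration: |z| > 1.96 near the nominal rate
  frac <- mean(abs(g2$zstat) > 1.96)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
  expect_error(group_level(C[, 1:2], S[, 1:2]), "at least 3")
})

test_that("cluster labelling matches an independent graph-components oracle", {
  suppressMessages(library(igraph))
  grid <- c(12L, 12L, 8L)
  offs <- stfica:::neighbour_offsets(26L)
  set.seed(9)
  for (trial in 1:50) {
    mask <- array(runif(prod(grid)) < 0.35, grid)
    lab <- stfica:::label_components(mask, 26L)
    # oracle: graph over active voxels, edges between 26-neighbours
    vox <- which(mask, arr.ind = TRUE)
    n <- nrow(vox)
    if (n == 0L) { expect_true(all(lab == 0L)); next }
    key <- vox[, 1] + (vox[, 2] - 1) * grid[1] + (vox[, 3] - 1) * grid[1] * grid[2]
    idx <- integer(prod(grid)); idx[key] <- seq_len(n)
    edges <- integer(0)
    for (k in seq_len(nrow(offs))) {
      nb <- sweep(vox, 2, offs[k, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= grid[1] & nb[, 2] >= 1 &
        nb[, 2] <= grid[2] & nb[, 3] >= 1 & nb[, 3] <= grid[3]
      nbkey <- nb[ok, 1] + (nb[ok, 2] - 1) * grid[1] +
        (nb[ok, 3] - 1) * grid[1] * grid[2]
      hit <- idx[nbkey] > 0
      edges <- c(edges, rbind(which(ok)[hit], idx[nbkey][hit]))
    }
    g <- make_graph(edges, n = n, directed = FALSE)
    comp <- components(g)$membership
    mine <- lab[mask]
    # identical partitions: one-to-one label correspondence
    expect_equal(length(unique(mine)), max(comp))
    tab <- table(mine, comp)
    expect_true(all(rowSums(tab > 0) == 1L))
    expect_true(all(colSums(tab > 0) == 1L))
  }
})

test_that("GRF cluster p-values decrease in extent and respect thresholds", {
  p <- sapply(c(5, 10, 20, 50, 100, 200),
              stfica:::cluster_p_grf, z_thresh = 3.1, resels = 40,
              n_mask_voxels = 4000)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p <= 1))
  # defaults carried by the interface
  expect_equal(formals(grf_cluster_threshold)$z_thresh, 3.1)
  expect_equal(formals(grf_cluster_threshold)$p_thresh, 0.01)
  expect_equal(formals(local_maxima)$min_dist_mm, 20)
  expect_equal(formals(local_maxima)$max_n, 100)
})

test_that("local maxima honour the peak and distance-suppression rules", {
  grid <- c(20L, 12L, 10L)
  mask <- array(TRUE, grid)
  mk_cluster_table <- function(zmap, thresh = 3.1) {
    supra <- zmap > thresh
    lab <- stfica:::label_components(supra, 26L)
    structure(list(clusters = data.frame(id = seq_len(max(lab))),
                   label_map = lab, z_thresh = thresh),
              class = "cluster_table")
  }
  bump <- function(centre, height = 6) {
    height * stfica:::gaussian_blob(grid, centre, 1.4)
  }
  # single bump: exactly one peak, at the apex voxel
  z1 <- bump(c(8, 6, 5))
  pk1 <- local_maxima(z1[mask], mk_cluster_table(z1), mask, c(3, 3, 3))
  expect_equal(nrow(pk1), 1L)
  expect_equal(unlist(pk1[1, c("x", "y", "z")]), c(x = 8, y = 6, z = 5))
  # two bumps 10 mm apart on 3 mm voxels: second peak suppressed (< 20 mm)
  z2 <- bump(c(8, 6, 5)) + bump(c(8 + 10 / 3, 6, 5), height = 5)
  pk2 <- local_maxima(z2[mask], mk_cluster_table(z2), mask, c(3, 3, 3))
  expect_equal(nrow(pk2), 1L)
  # 25 mm apart: both reported
  z3 <- bump(c(6, 6, 5)) + bump(c(6 + 25 / 3, 6, 5), height = 5)
  pk3 <- local_maxima(z3[mask], mk_cluster_table(z3), mask, c(3, 3, 3))
  expect_equal(nrow(pk3), 2L)
  # max_n caps the number of peaks
  pk4 <- local_maxima(z3[mask], mk_cluster_table(z3), mask, c(3, 3, 3),
                      max_n = 1)
  expect_equal(nrow(pk4), 1L)
})

test_that("the model-based branch localizes a planted activation", {
  sub <- simulate_subject(seed = 17)
  pp <- preprocess_subject(sub)
  vol <- highpass_volume(pp$vol, 45)
  des <- default_design()
  fit <- fit_first_level(vol, des)
  stat <- contrast_to_z(fit, contrast_registry()[["frontal > rest"]])
  ct <- grf_cluster_threshold(stat, vol$mask, fit$residuals,
                              z_thresh = 3.1, p_thresh = 0.01)
  expect_gte(nrow(ct$clusters), 1L)
  expect_true(all(diff(ct$clusters$size_voxels) <= 0))
  # surviving cluster centroids sit on the bilateral planted blobs
  task_map <- Filter(function(p) p$name == "sensorimotor_task",
                     sub$truth$planted)[[1]]$map
  d <- dim(task_map)
  blob_l <- colMeans(which(task_map > 0.5 * max(task_map) &
                             slice.index(task_map, 1) < d[1] / 2,
                           arr.ind = TRUE))
  blob_r <- colMeans(which(task_map > 0.5 * max(task_map) &
                             slice.index(task_map, 1) >= d[1] / 2,
                           arr.ind = TRUE))
  centroids <- lapply(ct$clusters$id, function(i) {
    colMeans(which(ct$label_map == i, arr.ind = TRUE))
  })
  dist_to <- function(b) {
    min(vapply(centroids, function(ce) sqrt(sum((ce - b)^2)), numeric(1)))
  }
  expect_lt(dist_to(blob_l), 2)
  expect_lt(dist_to(blob_r), 2)
})
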