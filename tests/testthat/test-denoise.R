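# Small helper: masks and a fake component set on a toy grid.
toy_masks <- function(grid = c(12L, 12L, 8L)) {
  mask <- stfica:::head_mask_for_grid(grid)
  edge <- edge_mask_from(mask)
  csf <- stfica:::csf_map(grid, mask, sigma_vox = 1) > 0.3
  list(mask = mask, edge = edge, csf = csf)
}

test_that("high-frequency content matches the periodogram oracle", {
  tr <- 1.8
  Tn <- 304L
  t <- (seq_len(Tn) - 1) * tr
  # 0.25 Hz sinusoid: hfc = 0.25 / Nyquist(0.2778) ~ 0.90
  s <- sin(2 * pi * 0.25 * t)
  expect_equal(stfica:::high_frequency_content(s, tr), 0.90, tolerance = 0.02)
  # slow sinusoid sits near zero
  expect_lt(stfica:::high_frequency_content(sin(2 * pi * 0.02 * t), tr), 0.12)
  # cumulative-power oracle on a mixed series
  set.seed(2)
  x <- sin(2 * pi * 0.05 * t) + 0.7 * sin(2 * pi * 0.2 * t) + rnorm(Tn, 0, .1)
  spec <- Mod(fft(x - mean(x)))^2
  m <- Tn %/% 2
  freq <- seq_len(m) / (Tn * tr)
  cum <- cumsum(spec[2:(m + 1)]) / sum(spec[2:(m + 1)])
  oracle <- freq[which(cum >= 0.5)[1]] / (1 / (2 * tr))
  expect_equal(stfica:::high_frequency_content(x, tr), oracle)
})

test_that("AROMA features capture motion correlation and spatial fractions", {
  tm <- toy_masks()
  V <- sum(tm$mask)
  Tn <- 80L
  set.seed(5)
  params <- cbind(matrix(0, Tn, 3),
                  matrix(cumsum(rnorm(Tn * 3, 0, 0.1)), Tn, 3))
  trace <- motion_trace(params, Tn %/% 2L + 1L)
  edge_in <- tm$edge[tm$mask]
  csf_in <- tm$csf[tm$mask]
  maps <- rbind(as.numeric(edge_in),          # fully on the edge
                as.numeric(!edge_in & !csf_in), # fully in the core
                as.numeric(csf_in))           # fully in CSF
  tcs <- cbind(params[, 4],                    # equals an RP series
               rnorm(Tn), rnorm(Tn))
  cs <- fake_component_set(tcs, maps, tm$mask)
  feats <- aroma_features(cs, trace, tm$mask, tm$edge, tm$csf, tr = 1.8)
  expect_gte(feats$max_rp_corr[1], 0.999)
  expect_equal(feats$edge_frac[1], 1)
  expect_equal(feats$edge_frac[2], 0)
  expect_equal(feats$csf_frac[3], 1)
  expect_true(all(feats$hfc >= 0 & feats$hfc <= 1))
  expect_error(aroma_features(cs, trace, tm$mask,
                              array(FALSE, dim(tm$mask)), tm$csf),
               "empty")
})

test_that("noise classification applies the CSF, HFC and hyperplane rules", {
  f <- function(hfc = 0, rp = 0, edge = 0, csf = 0) {
    data.frame(component = 1, hfc = hfc, max_rp_corr = rp,
               edge_frac = edge, csf_frac = csf)
  }
  expect_false(classify_noise(f()))                   # all-zero -> signal
  expect_true(classify_noise(f(csf = 0.2)))           # CSF rule (> 0.10)
  expect_true(classify_noise(f(hfc = 0.5)))           # HFC rule (> 0.35)
  expect_false(classify_noise(f(csf = 0.09)))
  expect_false(classify_noise(f(hfc = 0.34)))
  # hyperplane rule: high edge fraction with some motion correlation
  expect_true(classify_noise(f(rp = 0.5, edge = 0.7)))
  expect_false(classify_noise(f(rp = 0.1, edge = 0.2)))
  # thresholds are configurable
  strict <- aroma_thresholds(csf_threshold = 0.01)
  expect_true(classify_noise(f(csf = 0.05), strict))
})

test_that("non-aggressive regression removes only the flagged contribution", {
  tm <- toy_masks()
  V <- sum(tm$mask)
  Tn <- 60L
  set.seed(7)
  # orthogonal signal and noise time courses, disjoint maps
  tc_sig <- sin(2 * pi * seq_len(Tn) / 16)
  tc_noise <- cos(2 * pi * seq_len(Tn) / 8)
  tc_sig <- (tc_sig - mean(tc_sig)) / sd(tc_sig)
  tc_noise <- (tc_noise - mean(tc_noise)) / sd(tc_noise)
  map_sig <- rnorm(V); map_noise <- rnorm(V)
  S_sig <- outer(tc_sig, map_sig)
  S_noise <- outer(tc_noise, map_noise)
  arr <- array(0, c(dim(tm$mask), Tn))
  m <- matrix(arr, length(tm$mask), Tn)
  m[as.vector(tm$mask), ] <- t(S_sig + S_noise)
  vol <- volume4d(array(m, c(dim(tm$mask), Tn)), mask = tm$mask)
  cs <- fake_component_set(cbind(tc_sig, tc_noise),
                           rbind(map_sig, map_noise), tm$mask)
  # no flags: output equals input exactly
  out0 <- nonaggressive_regress(vol, cs, c(FALSE, FALSE))
  expect_identical(out0$data, vol$data)
  # flagging the noise component recovers the signal field
  out1 <- nonaggressive_regress(vol, cs, c(FALSE, TRUE))
  got <- stfica:::vol_matrix(out1)
  expect_lt(max(abs(got - S_sig)), 1e-8)
  # equals the brute-force normal-equations oracle
  Y <- stfica:::vol_matrix(vol)
  X <- cbind(1, cs$timecourses)
  beta <- solve(t(X) %*% X) %*% t(X) %*% Y
  oracle <- Y - X[, 3, drop = FALSE] %*% beta[3, , drop = FALSE]
  expect_lt(max(abs(got - oracle)), 1e-10)
})

test_that("partial regression removes less variance than aggressive", {
  tm <- toy_masks()
  V <- sum(tm$mask)
  Tn <- 80L
  set.seed(8)
  # correlated signal/noise time courses
  base <- rnorm(Tn)
  tc1 <- scale(base + rnorm(Tn, 0, 0.6))[, 1]
  tc2 <- scale(base + rnorm(Tn, 0, 0.6))[, 1]
  maps <- rbind(rnorm(V), rnorm(V))
  X <- cbind(tc1, tc2) %*% maps + matrix(rnorm(Tn * V, 0, 0.3), Tn, V)
  arr <- matrix(0, length(tm$mask), Tn)
  arr[as.vector(tm$mask), ] <- t(X)
  vol <- volume4d(array(arr, c(dim(tm$mask), Tn)), mask = tm$mask)
  cs <- fake_component_set(cbind(tc1, tc2), maps, tm$mask)
  non <- stfica:::vol_matrix(nonaggressive_regress(vol, cs, c(FALSE, TRUE)))
  agg <- stfica:::vol_matrix(aggressive_regress(vol, cs, c(FALSE, TRUE)))
  v_non <- apply(non, 2, var)
  v_agg <- apply(agg, 2, var)
  expect_true(all(v_non - v_agg >= -1e-10))
  expect_gt(mean(v_non - v_agg), 0)
  # flagging everything leaves the OLS residual plus intercept
  all_out <- stfica:::vol_matrix(nonaggressive_regress(vol, cs, c(TRUE, TRUE)))
  Xd <- cbind(1, tc1, tc2)
  resid <- X - Xd %*% solve(crossprod(Xd), crossprod(Xd, X))
  expect_lt(max(abs(sweep(all_out, 2, colMeans(X)) - resid)), 1e-8)
})

test_that("edge mask is a shell around the brain boundary", {
  tm <- toy_masks()
  expect_true(any(tm$edge & tm$mask))       # inner rim
  expect_true(any(tm$edge & !tm$mask))      # outer shell
  # interior voxels are not edge
  interior <- stfica:::erode3d(stfica:::erode3d(tm$mask))
  expect_false(any(tm$edge & interior))
})

test_that("planted motion components are flagged, task components are not", {
  # end-to-end over several seeds on the reduced protocol
  proto <- small_protocol(n_recorded = 124L)
  paradigm <- build_paradigm()
  ok_edge <- 0L; ok_task <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    sub <- simulate_subject(proto, paradigm, seed = 300L + s)
    pp <- preprocess_subject(sub, proto)
    cs <- probabilistic_ica(pp$vol, K = 12L, seed = s)
    edge <- edge_mask_from(pp$vol$mask)
    feats <- aroma_features(cs, pp$trace, pp$vol$mask, edge,
                            pp$truth$csf_mask)
    flags <- classify_noise(feats)
    mask <- pp$vol$mask
    edge_map <- Filter(function(p) p$name == "edge_motion",
                       pp$truth$planted)[[1]]$map[mask]
    task_map <- Filter(function(p) p$name == "sensorimotor_task",
                       pp$truth$planted)[[1]]$map[mask]
    k_edge <- which.max(abs(apply(cs$maps, 1, cor, y = edge_map)))
    k_task <- which.max(abs(apply(cs$maps, 1, cor, y = task_map)))
    if (flags[k_edge]) ok_edge <- ok_edge + 1L
    if (!flags[k_task]) ok_task <- ok_task + 1L
  }
  expect_gte(ok_edge, n_seeds - 1L)
  expect_gte(ok_task, n_seeds - 1L)
})
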