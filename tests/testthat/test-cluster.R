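test_that("GFP peak detection matches a triple-scan oracle and separation rule", {
  expect_identical(find_gfp_peaks(1:10), integer(0))
  expect_identical(find_gfp_peaks(c(0, 1, 0, 2, 0)), c(2L, 4L))
  set.seed(51)
  for (rep_ in 1:5) {
    v <- rnorm(200)
    oracle <- integer(0)
    for (t in 2:199) {
      if (v[t - 1] < v[t] && v[t] > v[t + 1]) oracle <- c(oracle, t)
    }
    expect_identical(find_gfp_peaks(v), oracle)
  }
  # among close peaks the larger survives
  v <- c(0, 3, 0, 5, 0, 0, 0, 0, 0, 2, 0)
  expect_identical(find_gfp_peaks(v, min_separation_frames = 4L), c(4L, 10L))
  expect_error(find_gfp_peaks(c(1, 2)), class = "megstates_invalid_argument")
})

test_that("spatial similarity follows the mode conventions", {
  a <- c(0.2, 0.5, 0.9, 0.1)
  expect_equal(spatial_similarity(a, a, "meg"), 1)
  expect_equal(spatial_similarity(a, a, "eeg"), 1)
  expect_equal(spatial_similarity(a, -a, "eeg"), 1)     # polarity blind
  expect_equal(spatial_similarity(c(1, 1, 0, 0), c(0, 0, 2, 3), "meg"), 0)
  expect_equal(spatial_similarity(a, 3 * a, "meg"), 1)  # scale blind
  expect_error(spatial_similarity(a, rep(0, 4), "meg"),
               class = "megstates_undefined_similarity")
  expect_error(spatial_similarity(a, a[1:3], "meg"),
               class = "megstates_invalid_argument")
})

test_that("k = 1 on copies of one map recovers it exactly", {
  map <- abs(rnorm(12)); map <- map / sqrt(sum(map^2))
  X <- matrix(rep(map, 10), 10, byrow = TRUE)
  km <- modified_kmeans(X, 1, "meg", n_restarts = 2, seed = 1)
  expect_equal(km$ev, 1, tolerance = 1e-12)
  expect_gt(spatial_similarity(km$microstates$maps[1, ], map, "meg"),
            1 - 1e-12)
})

test_that("two orthogonal populations are recovered with similarity >= 0.999", {
  m1 <- c(rep(1, 6), rep(0, 6)); m1 <- m1 / sqrt(sum(m1^2))
  m2 <- c(rep(0, 6), rep(1, 6)); m2 <- m2 / sqrt(sum(m2^2))
  X <- rbind(matrix(rep(m1, 20), 20, byrow = TRUE),
             matrix(rep(m2, 20), 20, byrow = TRUE))
  km <- modified_kmeans(X, 2, "meg", n_restarts = 5, seed = 2)
  mm <- match_maps(rbind(m1, m2), km$microstates$maps, "meg")
  expect_gte(mm$mean_sim, 0.999)
  expect_setequal(km$assignments[1:20], km$assignments[1])
})

test_that("k-means explained variance beats exhaustive 2-partition enumeration", {
  set.seed(53)
  X <- matrix(abs(rnorm(36)), 12, 3)
  X <- X / sqrt(rowSums(X^2))
  update_meg <- function(Xc) {
    m <- colMeans(Xc); m[m < 0] <- 0; m / sqrt(sum(m^2))
  }
  ev_of_partition <- function(in1) {
    t1 <- update_meg(X[in1, , drop = FALSE])
    t2 <- update_meg(X[!in1, , drop = FALSE])
    S <- X %*% cbind(t1, t2)
    best <- pmax(S[, 1], S[, 2])
    mean(best)
  }
  best_ev <- -Inf
  for (code in 1:(2^11 - 1)) {
    in1 <- c(TRUE, as.logical(bitwAnd(code, 2^(0:10))))
    if (all(in1) || !any(in1)) next
    best_ev <- max(best_ev, ev_of_partition(in1))
  }
  km <- modified_kmeans(X, 2, "meg", n_restarts = 50, seed = 3)
  expect_gte(km$ev, best_ev - 1e-9)
})

test_that("explained variance is non-decreasing within a restart and templates stay normalised", {
  for (sd_ in 1:5) {
    set.seed(60 + sd_)
    X <- matrix(abs(rnorm(40 * 8)), 40, 8)
    km <- modified_kmeans(X, 3, "meg", n_restarts = 1, seed = 60 + sd_)
    expect_true(all(diff(km$ev_trace) >= -1e-12))
    expect_equal(unname(rowSums(km$microstates$maps^2)), rep(1, 3),
                 tolerance = 1e-12)
    expect_true(all(km$microstates$maps >= 0))
  }
  set.seed(66)
  Xe <- matrix(rnorm(40 * 8), 40, 8)
  kme <- modified_kmeans(Xe, 3, "eeg", n_restarts = 1, seed = 66)
  expect_true(all(diff(kme$ev_trace) >= -1e-12))
  expect_lt(max(abs(rowMeans(kme$microstates$maps))), 1e-9)
  expect_error(modified_kmeans(Xe[1:2, ], 3, "eeg"),
               class = "megstates_invalid_argument")
})

test_that("same seed gives identical k-means results", {
  set.seed(70)
  X <- matrix(abs(rnorm(60 * 10)), 60, 10)
  a <- modified_kmeans(X, 4, "meg", n_restarts = 5, seed = 7)
  b <- modified_kmeans(X, 4, "meg", n_restarts = 5, seed = 7)
  expect_identical(a$microstates$maps, b$microstates$maps)
  expect_identical(a$assignments, b$assignments)
})

test_that("two-level clustering recovers shared maps across subjects", {
  s <- small_setup(K = 4, n = 24, seed = 301)
  recs <- lapply(1:3, function(i) {
    simulate_resting(s$layout, s$maps, duration_s = 40, fs = 250,
                     snr = 10, seed = 400 + i)$recording
  })
  res <- two_level_clustering(recs, k_grid = 2:7, n_restarts = 8,
                              seed = 5)
  expect_equal(res$group$k_opt, 4L)
  mm <- match_maps(s$maps, res$group$microstates, "meg")
  expect_gte(mm$mean_sim, 0.95)
})

test_that("single-subject two-level result matches the individual result", {
  s <- small_setup(K = 3, n = 16, seed = 311)
  rec <- simulate_resting(s$layout, s$maps, duration_s = 30, fs = 250,
                          snr = 10, seed = 91)$recording
  res <- two_level_clustering(list(rec), k_grid = 2:6, n_restarts = 8,
                              seed = 9)
  ind <- res$individual[[1]]
  expect_equal(res$group$k_opt, ind$k_opt)
  mm <- match_maps(ind$microstates, res$group$microstates, "meg")
  expect_gte(mm$mean_sim, 0.999)
})

test_that("subjects with disjoint map sets drive the group k toward their union", {
  lay <- small_layout(24, seed = 321)
  maps_a <- make_topographies(3, lay, "meg", seed = 322)
  maps_b <- make_topographies(3, lay, "meg", seed = 400)
  # regenerate b until the union is itself well separated
  tries <- 0
  while (max(abs(maps_a %*% t(maps_b))) > 0.7 && tries < 50) {
    tries <- tries + 1
    maps_b <- make_topographies(3, lay, "meg", seed = 400 + tries)
  }
  recs <- c(
    lapply(1:2, function(i) {
      simulate_resting(lay, maps_a, duration_s = 40, fs = 250, snr = 10,
                       seed = 500 + i)$recording
    }),
    lapply(1:2, function(i) {
      simulate_resting(lay, maps_b, duration_s = 40, fs = 250, snr = 10,
                       seed = 600 + i)$recording
    }))
  res <- two_level_clustering(recs, k_grid = 2:8, n_restarts = 8,
                              seed = 11)
  expect_equal(res$group$k_opt, 6L)
})
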