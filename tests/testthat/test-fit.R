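test_that("back-fitting matches a per-frame exhaustive argmax oracle", {
  s <- small_setup(K = 4, n = 12, seed = 201)
  # frame equal to a template
  rec1 <- recording(cbind(s$maps[2, ]), fs = 250, modality = "meg",
                    channel_names = s$layout$channel_names)
  seg1 <- backfit(rec1, s$ms)
  expect_equal(seg1$labels, 2L)
  expect_equal(seg1$sims, 1, tolerance = 1e-12)

  set.seed(202)
  X <- matrix(abs(rnorm(12 * 200)), 12, 200)
  rec <- recording(X, fs = 250, modality = "meg",
                   channel_names = s$layout$channel_names)
  seg <- backfit(rec, s$ms, threshold = 0.5)
  for (t in seq_len(200)) {
    sims <- vapply(1:4, function(m) {
      spatial_similarity(X[, t], s$ms$maps[m, ], "meg")
    }, numeric(1))
    m_star <- which.max(sims)
    if (sims[m_star] < 0.5) {
      expect_equal(seg$labels[t], 0L)
    } else {
      expect_equal(seg$labels[t], m_star)
      expect_equal(seg$sims[t], sims[m_star], tolerance = 1e-12)
    }
  }
})

test_that("frames orthogonal to all templates stay unlabeled", {
  maps <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)) # unit rows
  ms <- microstates(maps, "meg")
  rec <- recording(cbind(c(0, 0, 1, 1)), fs = 100, modality = "meg")
  seg <- backfit(rec, ms)
  expect_equal(seg$labels, 0L)
  expect_error(backfit(recording(matrix(1, 3, 2), 100, "meg"), ms),
               class = "megstates_invalid_argument")
})

test_that("smoothing with lambda 0 is the identity and fixed points stay fixed", {
  s <- small_setup(K = 3)
  sim <- simulate_resting(s$layout, s$maps, duration_s = 4, fs = 250,
                          snr = 5, seed = 203)
  seg <- backfit(sim$recording, s$ms)
  expect_identical(smooth_labels(seg, besag_lambda = 0)$labels, seg$labels)

  uni <- fake_segmentation(rep(2L, 50), k = 3,
                           all_sims = matrix(c(0.1, 0.9, 0.1), 50, 3,
                                             byrow = TRUE))
  expect_identical(smooth_labels(uni, besag_lambda = 10)$labels,
                   uni$labels)
})

test_that("a near-tied single-frame blip is absorbed, matching exhaustive cost evaluation", {
  n <- 21
  S <- matrix(0.2, n, 2)
  S[, 1] <- 0.80
  S[11, ] <- c(0.79, 0.80)   # blip frame: state 2 marginally better
  labels <- rep(1L, n)
  labels[11] <- 2L
  seg <- fake_segmentation(labels, k = 2, all_sims = S,
                           sims = S[cbind(1:n, labels)])
  b <- 3L; lambda <- 10
  sm <- smooth_labels(seg, half_window_b = b, besag_lambda = lambda,
                      max_iter = 1)
  # oracle: evaluate the Besag cost of both labels at the blip frame
  cost <- function(m) {
    Nm <- sum(labels[8:14][-4] == m)
    (1 - S[11, m]^2) - lambda / (2 * b) * Nm
  }
  expect_lt(cost(1), cost(2))
  expect_equal(sm$labels[11], 1L)
  expect_true(all(sm$labels == 1L))
})

test_that("smoothing never labels sub-threshold frames", {
  s <- small_setup(K = 3)
  sim <- simulate_resting(s$layout, s$maps, duration_s = 10, fs = 250,
                          snr = 2, seed = 204)
  seg <- backfit(sim$recording, s$ms, threshold = 0.9)
  expect_gt(sum(seg$labels == 0), 0)
  sm <- smooth_labels(seg)
  expect_true(all(sm$labels[seg$labels == 0] == 0))
})

test_that("smoothing does not reduce frame-wise accuracy on noisy data (median over seeds)", {
  s <- small_setup(K = 3)
  deltas <- vapply(1:20, function(sd_) {
    sim <- simulate_resting(s$layout, s$maps, duration_s = 10, fs = 250,
                            snr = 10, seed = 900 + sd_)
    seg <- backfit(sim$recording, s$ms)
    sm <- smooth_labels(seg)
    lab_t <- sim$truth$labels
    acc0 <- mean(seg$labels == lab_t)
    acc1 <- mean(sm$labels == lab_t)
    acc1 - acc0
  }, numeric(1))
  expect_gte(median(deltas), 0)
})

test_that("segment extraction round-trips any label sequence", {
  expect_equal(extract_segments(c(1, 1, 2, 2, 2)),
               data.frame(state = c(1L, 2L), start = c(1L, 3L),
                          length = c(2L, 3L)))
  expect_equal(nrow(extract_segments(integer(0))), 0L)
  set.seed(205)
  for (rep_ in 1:5) {
    lab <- sample(0:3, 300, replace = TRUE)
    runs <- extract_segments(lab)
    expect_identical(rep(runs$state, runs$length), lab)
    expect_identical(runs$start,
                     c(1L, head(cumsum(runs$length), -1) + 1L))
  }
})

test_that("temporal metrics match a direct-summation oracle", {
  lab <- c(rep(1L, 25), rep(0L, 100), rep(2L, 75), rep(1L, 50))
  sims <- runif(250, 0.5, 1) * (lab > 0)
  gfp_v <- runif(250, 0.5, 2)
  seg <- fake_segmentation(lab, k = 3, fs = 250, sims = sims, gfp = gfp_v)
  tm <- temporal_metrics(seg)
  expect_equal(tm$coverage[1], 75 / 250)
  expect_equal(tm$coverage[3], 0)
  expect_equal(tm$mean_duration_ms[1], mean(c(25, 50)) * 1000 / 250)
  expect_equal(tm$occurrence_per_s[1], 2 / 1)
  gev_oracle <- vapply(1:3, function(m) {
    sum((gfp_v[lab == m] * sims[lab == m])^2) / sum(gfp_v^2)
  }, numeric(1))
  expect_equal(tm$gev, gev_oracle, tolerance = 1e-12)
  expect_equal(tm$gev_total, sum(gev_oracle), tolerance = 1e-12)
  expect_equal(sum(tm$coverage) + tm$unlabeled, 1)
})

test_that("noiseless self-consistent data give total GEV of 1", {
  s <- small_setup(K = 3)
  sim <- simulate_resting(s$layout, s$maps, duration_s = 6, fs = 250,
                          snr = Inf, seed = 206)
  seg <- backfit(sim$recording, s$ms)
  tm <- temporal_metrics(seg)
  expect_equal(tm$gev_total, 1, tolerance = 1e-9)
  zero <- fake_segmentation(rep(1L, 10), gfp = rep(0, 10))
  expect_error(temporal_metrics(zero), class = "megstates_undefined_gev")
})
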