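test_that("layouts have six non-self neighbours verified against a distance oracle", {
  lay8 <- make_layout(8, seed = 1)
  expect_equal(dim(lay8$neighbors), c(8L, 6L))
  for (i in 1:8) expect_false(i %in% lay8$neighbors[i, ])
  expect_identical(make_layout(8, seed = 1), lay8)

  lay <- make_layout(64, seed = 7)
  d <- as.matrix(dist(lay$positions))
  for (i in seq_len(64)) {
    brute <- order(d[i, -i]) # indices into the reduced vector
    others <- seq_len(64)[-i]
    expect_setequal(lay$neighbors[i, ], others[brute[1:6]])
  }
  expect_error(make_layout(7), class = "megstates_invalid_argument")
})

test_that("topographies respect mode constraints and pairwise separation", {
  lay <- small_layout(32)
  meeg <- make_topographies(2, lay, "eeg", seed = 3)
  expect_lt(max(abs(rowMeans(meeg))), 1e-12)
  mmeg <- make_topographies(6, lay, "meg", seed = 4)
  expect_true(all(mmeg >= 0))
  expect_equal(unname(rowSums(mmeg^2)), rep(1, 6), tolerance = 1e-12)
  cs <- mmeg %*% t(mmeg)
  expect_lte(max(abs(cs[upper.tri(cs)])), 0.7)
})

test_that("noiseless resting simulation is perfectly identifiable by back-fitting", {
  s <- small_setup(K = 3, mode = "meg")
  sim <- simulate_resting(s$layout, s$maps, duration_s = 8, fs = 250,
                          snr = Inf, seed = 11)
  seg <- backfit(sim$recording, s$ms)
  lab <- seg$labels
  expect_gt(mean(lab > 0), 0.99)
  expect_true(all(lab[lab > 0] == sim$truth$labels[lab > 0]))
})

test_that("resting simulation is deterministic and respects dwell bounds and coverage", {
  s <- small_setup(K = 2)
  a <- simulate_resting(s$layout, s$maps, duration_s = 4, fs = 250, seed = 5)
  b <- simulate_resting(s$layout, s$maps, duration_s = 4, fs = 250, seed = 5)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$labels, b$truth$labels)

  sim <- simulate_resting(s$layout, s$maps, duration_s = 300, fs = 250,
                          coverage_weights = c(0.5, 0.5), snr = 5, seed = 6)
  runs <- sim$truth$runs
  interior <- runs$length[-nrow(runs)]
  expect_true(all(interior >= ceiling(50 * 250 / 1000)))
  expect_true(all(interior <= floor(150 * 250 / 1000)))
  cov <- tabulate(sim$truth$labels, 2) / length(sim$truth$labels)
  expect_true(all(abs(cov - 0.5) < 0.05))
})

test_that("empirical coverage converges to the requested weights at 600 s", {
  s <- small_setup(K = 3)
  sim <- simulate_resting(s$layout, s$maps, duration_s = 600, fs = 250,
                          coverage_weights = c(0.5, 0.3, 0.2), snr = 5,
                          seed = 8)
  cov <- tabulate(sim$truth$labels, 3) / length(sim$truth$labels)
  expect_true(all(abs(cov - c(0.5, 0.3, 0.2)) < 0.03))
})

test_that("modality conventions hold: meg nonnegative, eeg average-referenced", {
  s_meg <- small_setup(K = 3, mode = "meg")
  sim <- simulate_resting(s_meg$layout, s_meg$maps, duration_s = 4,
                          fs = 250, snr = 3, seed = 9)
  expect_true(all(sim$recording$data >= 0))
  s_eeg <- small_setup(K = 3, mode = "eeg")
  sime <- simulate_resting(s_eeg$layout, s_eeg$maps, duration_s = 4,
                           fs = 250, snr = 3, seed = 9)
  expect_lt(max(abs(colMeans(sime$recording$data))), 1e-9)
  expect_error(
    simulate_resting(s_meg$layout, s_meg$maps, duration_s = 1,
                     coverage_weights = c(0, 0, 0), seed = 1),
    class = "megstates_invalid_argument")
})

test_that("evoked simulation bookkeeping and boost construction are exact", {
  s <- small_setup(K = 3)
  sim <- simulate_evoked(s$layout, s$maps, n_std = 30, n_dev = 6,
                         fs = 250, deviant_state = 3, boost_prob = 1,
                         snr = Inf, seed = 12)
  expect_equal(nrow(sim$events), 36)
  expect_equal(sum(sim$events$type == "deviant"), 6)
  seg <- backfit(sim$recording, s$ms)
  curves <- detection_rate_curve(seg, sim$events)
  keep <- curves$deviant$rel_ms >= 150 & curves$deviant$rel_ms < 300
  expect_true(all(curves$deviant$counts["3", keep] ==
                    curves$deviant$n_events))
  expect_identical(
    sim$recording$data,
    simulate_evoked(s$layout, s$maps, n_std = 30, n_dev = 6, fs = 250,
                    deviant_state = 3, boost_prob = 1, snr = Inf,
                    seed = 12)$recording$data)
})

test_that("zero boost produces no deviant-standard detection difference", {
  s <- small_setup(K = 3)
  diffs <- vapply(1:30, function(sd_) {
    sim <- simulate_evoked(s$layout, s$maps, n_std = 30, n_dev = 10,
                           fs = 100, deviant_state = 3, boost_prob = 0,
                           snr = Inf, seed = 1000 + sd_)
    seg <- backfit(sim$recording, s$ms)
    curves <- detection_rate_curve(seg, sim$events)
    unname(mms_mmn(curves$standard, curves$deviant)["3"])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("parcel simulation embeds label-locked effects and validates inputs", {
  lab <- list(labels = rep(rep(1:2, 25), each = 20))
  ps <- simulate_parcels(lab, n_parcels = 6,
                         effect_table = data.frame(parcel = 3, state = 2,
                                                   delta = 1),
                         noise_sd = 0.2, fs = 250, seed = 3)
  on_ <- mean(ps$values[3, lab$labels == 2])
  off_ <- mean(ps$values[3, lab$labels == 1])
  expect_gt(on_ - off_, 0.5)
  expect_true(all(ps$values >= 0))
  expect_identical(ps$values,
                   simulate_parcels(lab, 6,
                                    data.frame(parcel = 3, state = 2,
                                               delta = 1),
                                    noise_sd = 0.2, fs = 250,
                                    seed = 3)$values)
  expect_error(simulate_parcels(lab, 6,
                                data.frame(parcel = 1, state = 9,
                                           delta = 1)),
               class = "megstates_invalid_argument")
  expect_equal(length(simulate_parcels(lab, 34, fs = 250)$parcel_names), 34)
})

test_that("paired-modality coupling controls label agreement", {
  lay <- small_layout(16)
  full <- simulate_paired_modalities(lay, K = 3, duration_s = 4, fs = 250,
                                     coupling = 1, snr = Inf, seed = 21)
  expect_identical(full$truth$labels_meg, full$truth$labels_eeg)
  expect_identical(
    full$meg$data,
    simulate_paired_modalities(lay, K = 3, duration_s = 4, fs = 250,
                               coupling = 1, snr = Inf, seed = 21)$meg$data)
  none <- simulate_paired_modalities(lay, K = 3, duration_s = 60, fs = 250,
                                     coupling = 0, snr = Inf, seed = 22)
  agree <- mean(none$truth$labels_meg == none$truth$labels_eeg)
  expect_lt(abs(agree - 1 / 3), 0.1)
  expect_error(simulate_paired_modalities(lay, coupling = 2),
               class = "megstates_invalid_argument")
})
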