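test_that("detection-rate curves match a per-event counting loop and conserve events", {
  set.seed(701)
  lab <- sample(0:3, 5000, replace = TRUE)
  seg <- fake_segmentation(lab, k = 3, fs = 250)
  events <- data.frame(onset = sort(sample(200:4800, 40)),
                       type = rep(c("standard", "deviant"), 20),
                       std_pre_dev = FALSE)
  curves <- detection_rate_curve(seg, events, epoch_ms = c(-200, 500))
  off <- (-50):125
  for (tp in c("standard", "deviant")) {
    cv <- curves[[tp]]
    ons <- events$onset[events$type == tp]
    oracle <- matrix(0L, 4, length(off))
    for (o in ons) for (fi in seq_along(off)) {
      l <- lab[o + off[fi]]
      oracle[l + 1L, fi] <- oracle[l + 1L, fi] + 1L
    }
    expect_equal(unname(cv$counts), oracle)
    expect_true(all(cv$counts <= cv$n_events))
    expect_true(all(colSums(cv$counts) == cv$n_events))
  }
})

test_that("constant labeling gives a constant curve and edge events are dropped", {
  seg <- fake_segmentation(rep(3L, 1000), k = 3, fs = 250)
  events <- data.frame(onset = c(5L, seq(100L, 800L, by = 100L)),
                       type = "standard", std_pre_dev = FALSE)
  expect_warning(curves <- detection_rate_curve(seg, events),
                 "dropped")
  cv <- curves$standard
  expect_equal(cv$n_events, 8L)          # onset 5 cannot host a -200 ms edge
  expect_true(all(cv$counts["3", ] == 8L))
  expect_true(all(cv$counts[c("0", "1", "2"), ] == 0L))
})

test_that("mMS-MMN differences match a window-averaging oracle and sum to zero", {
  set.seed(702)
  mk_curve <- function(n_ev) {
    counts <- matrix(sample(0:n_ev, 4 * 175, replace = TRUE), 4, 175,
                     dimnames = list(0:3, NULL))
    structure(list(counts = counts,
                   rel_ms = seq(-200, 496, by = 4), n_events = n_ev,
                   type = "x"), class = "ms_detcurve")
  }
  cs <- mk_curve(55); cd <- mk_curve(55)
  m <- mms_mmn(cs, cd, window = c(150, 300))
  keep <- cs$rel_ms >= 150 & cs$rel_ms < 300
  oracle <- rowMeans(cd$counts[, keep]) / 55 -
    rowMeans(cs$counts[, keep]) / 55
  expect_equal(m, oracle, tolerance = 1e-12)
  expect_equal(unname(mms_mmn(cs, cs)), rep(0, 4))

  # label conservation: counts columns sum to n_events in real curves
  seg <- fake_segmentation(sample(0:2, 3000, replace = TRUE), k = 2,
                           fs = 250)
  ev <- data.frame(onset = seq(300, 2500, by = 150),
                   type = rep(c("standard", "deviant"), length.out = 15),
                   std_pre_dev = FALSE)
  curves <- detection_rate_curve(seg, ev)
  m2 <- mms_mmn(curves$standard, curves$deviant)
  expect_equal(sum(m2), 0, tolerance = 1e-12)
  expect_error(mms_mmn(cs, cd, window = c(150, 150)),
               class = "megstates_invalid_argument")
})

test_that("MMN peak recovers a constructed in-window deviant excursion", {
  fs <- 250
  n_fr <- 175                             # -200..496 ms
  rel <- seq(-200, by = 1000 / fs, length.out = n_fr)
  set.seed(703)
  # 2 regions x 40 epochs: noise plus a +3 z bump for deviants in region 1
  arr <- array(rnorm(2 * 40 * n_fr), c(2, 40, n_fr))
  types <- rep(c("standard", "deviant"), each = 20)
  bump <- rel >= 180 & rel <= 260
  for (e in 21:40) arr[1, e, bump] <- arr[1, e, bump] + 3
  pk <- mmn_peak(arr, types, fs = fs)
  expect_lt(pk[1], -1.5)                  # standard - deviant dives below zero
  expect_true(attr(pk, "peak_ms")[1] >= 150 &&
                attr(pk, "peak_ms")[1] <= 300)
  # flipped direction recovers the classical orientation
  pk2 <- mmn_peak(arr, types, fs = fs, direction = "deviant-standard")
  expect_gte(pk2[1], pk[1])

  # identical averages: flat difference, flagged zero
  arr0 <- array(rep(rnorm(n_fr), each = 2 * 40), c(2, 40, n_fr))
  arr0 <- arr0 + array(rnorm(2 * 40 * n_fr, sd = 1e-12), c(2, 40, n_fr))
  types0 <- rep(c("standard", "deviant"), 20)
  pk0 <- mmn_peak(arr0, types0, fs = fs)
  expect_lt(abs(pk0[1]), 1e-6)
})

test_that("zero-variance baselines drop the epoch with a warning", {
  fs <- 250
  n_fr <- 175
  set.seed(704)
  arr <- array(rnorm(1 * 4 * n_fr), c(1, 4, n_fr))
  arr[1, 2, ] <- 7                        # flat epoch
  types <- c("standard", "standard", "deviant", "deviant")
  expect_warning(pk <- mmn_peak(arr, types, fs = fs), "dropped")
  expect_equal(attr(pk, "n_dropped"), 1L)
})

test_that("lateralization score follows the stated sign convention", {
  expect_equal(lateralization_score(-2, -2), 0)
  expect_equal(lateralization_score(-5, -2), -3)
  expect_equal(lateralization_score(-1, -4), 3)
  expect_error(lateralization_score(NA, -1),
               class = "megstates_invalid_argument")
})
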