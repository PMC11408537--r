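test_that("segment shuffle preserves per-state run multisets exactly", {
  set.seed(601)
  lab <- rep(sample(0:3, 60, replace = TRUE), times = sample(1:8, 60,
                                                             replace = TRUE))
  ro <- extract_segments(lab)
  for (draw in 1:20) {
    perm <- segment_shuffle(lab)
    expect_equal(length(perm), length(lab))
    expect_equal(tabulate(perm + 1L, 4), tabulate(lab + 1L, 4))
    rp <- attr(perm, "runs")
    for (st in 0:3) {
      expect_equal(sort(rp$length[rp$state == st]),
                   sort(ro$length[ro$state == st]))
    }
  }
  expect_equal(as.integer(segment_shuffle(rep(2L, 10))), rep(2L, 10))
})

test_that("segment shuffle is uniform over run orderings", {
  lab <- c(1L, 1L, 2L, 3L, 3L, 3L)
  set.seed(602)
  seen <- table(replicate(6000, paste(segment_shuffle(lab),
                                      collapse = "")))
  expect_equal(length(seen), 6L)
  expect_true(all(abs(seen / 6000 - 1 / 6) < 0.02))
})

test_that("parcel permutation test detects an injected effect and flags degenerate cells", {
  set.seed(603)
  lab <- megstates:::draw_label_sequence(24000, 4, 250)$labels
  seg <- fake_segmentation(lab, k = 4, fs = 250)
  ps <- simulate_parcels(list(labels = lab), n_parcels = 8,
                         effect_table = data.frame(parcel = 3, state = 2,
                                                   delta = 1),
                         noise_sd = 0.2, fs = 250, seed = 604)
  res <- parcel_permutation_test(ps, seg, n_perm = 400, z_crit = 3.6,
                                 seed = 605)
  expect_gt(res$z[3, 2], 3.6)
  expect_true(res$significant[3, 2])

  ps$values[5, ] <- 1  # constant parcel: null sd collapses
  res2 <- parcel_permutation_test(ps, seg, n_perm = 100, seed = 606)
  expect_false(any(res2$defined[5, ]))
  expect_true(all(is.na(res2$z[5, ])))
})

test_that("paired coverage contrast matches the closed-form paired t", {
  a <- cbind(c(0.10, 0.12, 0.08, 0.15, 0.11))
  b <- cbind(c(0.09, 0.10, 0.09, 0.11, 0.10))
  res <- coverage_contrast(a, b)
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(res$cohen_d, mean(d) / sd(d), tolerance = 1e-10)
  expect_equal(attr(res, "alpha_per_test"), 0.05 / 1)

  eq <- coverage_contrast(a, a)
  expect_equal(eq$t, 0)
  expect_equal(eq$cohen_d, 0)
  expect_false(eq$significant)
})

test_that("coverage contrast has high power for the design-sized shift", {
  set.seed(607)
  rejections <- vapply(1:100, function(i) {
    base <- matrix(rnorm(113 * 6, mean = 0.12, sd = 0.05), 113, 6)
    shifted <- base
    shifted[, 1] <- shifted[, 1] + 0.05 + rnorm(113, sd = 0.01)
    coverage_contrast(shifted, base)$significant[1]
  }, logical(1))
  expect_gte(mean(rejections), 0.99)
})

test_that("alpha change index locates an added occipital 10 Hz tone", {
  set.seed(608)
  x <- matrix(rnorm(6 * 5000, sd = 0.5), 6, 5000)
  roe <- recording(x, fs = 250, modality = "eeg",
                   channel_names = paste0("CH", 1:6))
  idx_eq <- alpha_change_index(roe, roe, c("CH5", "CH6"))
  expect_equal(as.numeric(idx_eq), 0)
  expect_equal(attr(idx_eq, "flag"), "no-negative-excursion")

  tone <- sin(2 * pi * 10 * (0:4999) / 250)
  x2 <- x
  x2[5, ] <- x2[5, ] + tone
  x2[6, ] <- x2[6, ] + tone
  rce <- recording(x2, fs = 250, modality = "eeg",
                   channel_names = paste0("CH", 1:6))
  idx <- alpha_change_index(roe, rce, c("CH5", "CH6"))
  expect_lt(as.numeric(idx), 0)
  expect_lt(abs(attr(idx, "freq_hz") - 10), 0.5)
  expect_error(alpha_change_index(roe, rce, character(0)),
               class = "megstates_invalid_argument")
})

test_that("kendall tau-b matches brute-force counting and the reference implementation", {
  expect_equal(kendall_tau_b(1:6, (1:6) * 2)$tau_b, 1)
  expect_equal(kendall_tau_b(1:6, rev(1:6))$tau_b, -1)

  x <- c(1, 2, 2, 3, 4, 4, 5, 6)
  y <- c(2, 1, 3, 3, 5, 4, 4, 6)
  res <- kendall_tau_b(x, y)
  C <- 0; D <- 0
  for (i in 1:7) for (j in (i + 1):8) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1
    if (s < 0) D <- D + 1
  }
  n0 <- 8 * 7 / 2
  n1 <- sum(table(x) * (table(x) - 1) / 2)
  n2 <- sum(table(y) * (table(y) - 1) / 2)
  expect_equal(res$concordant, C)
  expect_equal(res$discordant, D)
  expect_equal(res$tau_b, (C - D) / sqrt((n0 - n1) * (n0 - n2)),
               tolerance = 1e-12)
  ref <- suppressWarnings(cor.test(x, y, method = "kendall"))
  expect_equal(res$tau_b, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_error(kendall_tau_b(rep(1, 5), 1:5),
               class = "megstates_undefined_tau")
})

test_that("tau-b is antisymmetric under order reversal", {
  set.seed(609)
  for (rep_ in 1:5) {
    x <- rnorm(10)
    y <- rnorm(10)
    a <- kendall_tau_b(x, y)$tau_b
    b <- kendall_tau_b(x, -y)$tau_b
    expect_equal(a, -b, tolerance = 1e-12)
    expect_lte(abs(a), 1)
  }
})
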