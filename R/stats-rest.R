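#' Segment-preserving shuffle of a label sequence
#'
#' Run-length-encodes the label sequence (unlabeled stretches are kept as
#' pseudo-state 0), uniformly permutes the order of the runs, and
#' concatenates. The per-state multisets of run counts and run durations
#' are preserved exactly, so the shuffle randomises only *when* each
#' microstate occurs - the permutation null used by the parcel and
#' co-occurrence tests.
#'
#' Note that adjacent runs of the same state can end up abutting after
#' the permutation; the run *assignment* (returned in the `runs`
#' attribute) preserves the multisets exactly, while a run-length
#' re-extraction of the returned sequence may merge such neighbours.
#'
#' @param seg an `ms_segmentation` or an integer label vector.
#' @return integer label sequence of the same length, with the permuted
#'   run list (data frame `state`, `length`) in attribute `runs`.
#' @export
segment_shuffle <- function(seg) {
  labels <- if (inherits(seg, "ms_segmentation")) seg$labels else
    as.integer(seg)
  if (!length(labels)) stop_invalid("empty segmentation")
  runs <- extract_segments(labels)
  ord <- sample.int(nrow(runs))
  structure(rep(runs$state[ord], runs$length[ord]),
            runs = data.frame(state = runs$state[ord],
                              length = runs$length[ord]))
}

#' Parcel-by-state permutation test for microstate-locked source activity
#'
#' For every parcel `p` and state `m` the observed statistic is the mean
#' parcel magnitude over frames labeled `m`. A null distribution comes
#' from `n_perm` segment-preserving shuffles of the label sequence
#' ([segment_shuffle()]); each cell is summarised as
#' `z = (observed - null_mean) / null_sd` and flagged significant when
#' `|z| >= z_crit` (default 3.6, the Bonferroni-style threshold for a
#' 34-parcel x 6-state grid).
#'
#' @param ps an `ms_parcels` (or list with `values` parcel x frame and
#'   `parcel_names`).
#' @param seg an `ms_segmentation` aligned frame-for-frame with `ps`.
#' @param n_perm number of permutations (default 1000).
#' @param z_crit significance threshold on `|z|`.
#' @param seed integer seed.
#' @return class `ms_permgrid`: list with matrices `observed`,
#'   `null_mean`, `null_sd`, `z` (parcel x state), logical `significant`
#'   and `defined` masks, plus `n_perm`, `z_crit`, `seed`. Cells with an
#'   undefined z (state unlabeled, or `null_sd` 0) are flagged in
#'   `defined` rather than raising an error.
#' @export
parcel_permutation_test <- function(ps, seg, n_perm = 1000L, z_crit = 3.6,
                                    seed = 1L) {
  labels <- if (inherits(seg, "ms_segmentation")) seg$labels else
    as.integer(seg)
  V <- ps$values
  if (ncol(V) != length(labels)) {
    stop_invalid("parcel series and segmentation frame counts differ")
  }
  K <- if (inherits(seg, "ms_segmentation")) seg$k else max(labels)
  P <- nrow(V)
  counts <- tabulate(labels[labels > 0L], K)
  state_means <- function(lab) {
    ind <- matrix(0, length(lab), K)
    pos <- lab > 0L
    ind[cbind(which(pos), lab[pos])] <- 1
    sw <- V %*% ind
    sweep(sw, 2L, pmax(counts, 1L), "/")
  }
  obs <- state_means(labels)
  with_seed(seed, {
    s1 <- matrix(0, P, K); s2 <- matrix(0, P, K)
    for (i in seq_len(n_perm)) {
      pm <- state_means(segment_shuffle(labels))
      s1 <- s1 + pm
      s2 <- s2 + pm^2
    }
    null_mean <- s1 / n_perm
    null_sd <- sqrt(pmax(s2 / n_perm - null_mean^2, 0) * n_perm /
                      (n_perm - 1))
    defined <- outer(rep(TRUE, P), counts > 0L) & null_sd > 0
    z <- matrix(NA_real_, P, K)
    z[defined] <- (obs[defined] - null_mean[defined]) / null_sd[defined]
    dimnames(obs) <- dimnames(null_mean) <- dimnames(null_sd) <-
      dimnames(z) <- dimnames(defined) <-
      list(ps$parcel_names, paste0("state", seq_len(K)))
    sig <- !is.na(z) & abs(z) >= z_crit
    structure(list(observed = obs, null_mean = null_mean,
                   null_sd = null_sd, z = z, significant = sig,
                   defined = defined, n_perm = as.integer(n_perm),
                   z_crit = z_crit, seed = as.integer(seed)),
              class = "ms_permgrid")
  })
}

#' @export
print.ms_permgrid <- function(x, ...) {
  cat(sprintf("<ms_permgrid> %d parcels x %d states, %d permutations, |z|>=%.2f: %d cells\n",
              nrow(x$z), ncol(x$z), x$n_perm, x$z_crit,
              sum(x$significant)))
  invisible(x)
}

#' Paired contrast of per-subject microstate coverages between conditions
#'
#' Runs one paired t-test per state on the subject-wise coverage vectors
#' of two conditions, reports Cohen's d for paired data
#' (`mean(diff) / sd(diff)`), and applies a Bonferroni decision at
#' `alpha / K` (with K = 6 states this is the 0.05 / 6 = 0.008333 per-test
#' level; the exact fraction is used, not the printed rounding).
#'
#' @param covA,covB subject x state coverage matrices, matched rows
#'   (paired subjects) and columns.
#' @param alpha family-wise error level (default 0.05).
#' @return data frame with columns `state`, `mean_diff`, `t`, `df`, `p`,
#'   `cohen_d`, `significant`; attribute `alpha_per_test` holds the exact
#'   Bonferroni per-test level.
#' @export
coverage_contrast <- function(covA, covB, alpha = 0.05) {
  covA <- as.matrix(covA); covB <- as.matrix(covB)
  if (!identical(dim(covA), dim(covB))) {
    stop_invalid("coverage matrices must have identical dimensions")
  }
  if (nrow(covA) < 3L) stop_invalid("need at least 3 paired subjects")
  K <- ncol(covA)
  a_per <- alpha / K
  out <- lapply(seq_len(K), function(m) {
    d <- covA[, m] - covB[, m]
    if (sd(d) == 0) {
      # identical coverages: t = d = 0; any genuine constant shift with
      # zero variance leaves t undefined (flagged NA)
      zero <- mean(d) == 0
      return(data.frame(state = m, mean_diff = mean(d),
                        t = if (zero) 0 else NA_real_,
                        df = length(d) - 1L,
                        p = if (zero) 1 else NA_real_,
                        cohen_d = if (zero) 0 else NA_real_,
                        significant = FALSE))
    }
    tt <- t.test(covA[, m], covB[, m], paired = TRUE)
    data.frame(state = m, mean_diff = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, cohen_d = mean(d) / sd(d),
               significant = tt$p.value < a_per)
  })
  res <- do.call(rbind, out)
  attr(res, "alpha_per_test") <- a_per
  res
}

#' Occipital alpha-power change index between two resting conditions
#'
#' Estimates power spectra by averaged periodograms over non-overlapping
#' 2-s Hann windows (0.5 Hz resolution), averages them over the supplied
#' occipital channels, forms the difference `P_ROE - P_RCE`, and returns
#' the amplitude of the most prominent negative local minimum of the
#' difference within the 8-12 Hz alpha band (the largest-magnitude
#' sub-zero dip). Eyes-closed alpha enhancement therefore yields a
#' negative index; when the difference has no negative excursion in the
#' band, the index is 0 with attribute `flag = "no-negative-excursion"`.
#'
#' @param roe,rce [recording()]s of the two conditions, sharing channels
#'   and sampling rate.
#' @param occipital_channels character vector of channel names (or
#'   integer indices) to average over.
#' @param band frequency band searched, default `c(8, 12)` Hz.
#' @param window_s periodogram window length in seconds.
#' @return scalar index (<= 0), with attributes `freq_hz` (location of
#'   the dip, `NA` when flagged) and `flag`.
#' @export
alpha_change_index <- function(roe, rce, occipital_channels,
                               band = c(8, 12), window_s = 2) {
  stopifnot(inherits(roe, "ms_recording"), inherits(rce, "ms_recording"))
  if (roe$fs != rce$fs) stop_invalid("recordings must share fs")
  if (!length(occipital_channels)) {
    stop_invalid("occipital channel list is empty")
  }
  chan_idx <- function(rec) {
    if (is.character(occipital_channels)) {
      idx <- match(occipital_channels, rec$channel_names)
      if (anyNA(idx)) stop_invalid("unknown occipital channel name")
      idx
    } else as.integer(occipital_channels)
  }
  welch <- function(rec) {
    x <- rec$data[chan_idx(rec), , drop = FALSE]
    nw <- as.integer(round(window_s * rec$fs))
    n_seg <- ncol(x) %/% nw
    if (n_seg < 1L) stop_invalid("recording shorter than one spectral window")
    han <- 0.5 - 0.5 * cos(2 * pi * seq(0, nw - 1) / (nw - 1))
    scale <- sum(han^2)
    nf <- nw %/% 2 + 1L
    acc <- numeric(nf)
    for (s in seq_len(n_seg)) {
      seg <- x[, ((s - 1L) * nw + 1L):(s * nw), drop = FALSE]
      for (c in seq_len(nrow(seg))) {
        v <- (seg[c, ] - mean(seg[c, ])) * han
        pxx <- abs(fft(v))^2 / (scale * rec$fs)
        acc <- acc + pxx[seq_len(nf)]
      }
    }
    list(freq = seq(0, nf - 1L) * rec$fs / nw,
         power = acc / (n_seg * nrow(x)))
  }
  sp_roe <- welch(roe)
  sp_rce <- welch(rce)
  dif <- sp_roe$power - sp_rce$power
  f <- sp_roe$freq
  in_band <- which(f >= band[1L] & f <= band[2L])
  # local minima of the difference inside the band (band edges included)
  is_min <- vapply(in_band, function(i) {
    left <- if (i > 1L) dif[i] <= dif[i - 1L] else TRUE
    right <- if (i < length(dif)) dif[i] <= dif[i + 1L] else TRUE
    left && right && dif[i] < 0
  }, logical(1L))
  if (!any(is_min)) {
    return(structure(0, freq_hz = NA_real_, flag = "no-negative-excursion"))
  }
  cand <- in_band[is_min]
  best <- cand[which.min(dif[cand])]
  structure(dif[best], freq_hz = f[best], flag = "ok")
}

#' Kendall rank correlation tau-b with tie correction
#'
#' Counts concordant and discordant pairs directly and applies the
#' standard tie corrections:
#' `tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2))` with `n0 = n(n-1)/2` and
#' `n1`, `n2` the tied-pair counts of each variable. The p-value uses the
#' normal approximation with the tie-corrected variance of `C - D`
#' (two-sided).
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return list with `tau_b`, `p`, `concordant`, `discordant`, `n`.
#' @examples
#' kendall_tau_b(1:5, c(2, 1, 4, 3, 5))
#' @export
kendall_tau_b <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop_invalid("x and y must have equal length")
  if (n < 3L) stop_invalid("need n >= 3")
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  prod_ <- dx[up] * dy[up]
  C <- sum(prod_ > 0)
  D <- sum(prod_ < 0)
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) {
    stop(structure(class = c("megstates_undefined_tau", "error", "condition"),
                   list(message = "all values tied in x or y", call = NULL)))
  }
  tau <- (C - D) / den
  # tie-corrected variance of C - D (the cor.test normal approximation)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_cd <- (v0 - vt - vu) / 18 + v1 + v2
  z <- (C - D) / sqrt(var_cd)
  p <- 2 * pnorm(-abs(z))
  list(tau_b = tau, p = p, concordant = C, discordant = D, n = n)
}
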