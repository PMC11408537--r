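#' Generate smooth, well-separated synthetic microstate topographies
#'
#' Each map is a sum of 2-4 Gaussian bumps evaluated at the sensor
#' positions, then normalised to unit Euclidean norm. EEG-mode maps are
#' average-referenced (per-map channel mean zero) and signed; MEG-mode
#' maps (combined-gradiometer magnitudes) are elementwise nonnegative.
#' Candidate maps are drawn until all pairwise absolute cosine
#' similarities are at most `max_cosine`; generation fails after a
#' bounded number of retries.
#'
#' @param K number of maps, at least 2.
#' @param layout an [make_layout()] sensor layout.
#' @param mode `"meg"` or `"eeg"`.
#' @param seed integer seed.
#' @param max_cosine separation bound on pairwise |cosine| (default 0.7).
#' @param max_tries retries per map before giving up.
#' @return a `K x C` numeric matrix with unit-norm rows and attributes
#'   `mode` and `seed`.
#' @examples
#' lay <- make_layout(32, seed = 1)
#' maps <- make_topographies(4, lay, mode = "eeg", seed = 2)
#' rowSums(maps^2)
#' @export
make_topographies <- function(K, layout, mode = c("meg", "eeg"), seed = 1L,
                              max_cosine = 0.7, max_tries = 500L) {
  mode <- match.arg(mode)
  stopifnot(inherits(layout, "ms_layout"))
  if (!is.numeric(K) || length(K) != 1L || K < 2) {
    stop_invalid("K must be a single number >= 2")
  }
  K <- as.integer(K)
  pos <- layout$positions
  C <- nrow(pos)
  with_seed(seed, {
    draw_map <- function() {
      nb <- sample(2:4, 1L)
      # bump centres on the hemisphere, widths in sphere-chord units
      theta <- runif(nb, 0, 2 * pi)
      zc <- runif(nb, 0.05, 0.95)
      rc <- sqrt(1 - zc^2)
      ctr <- cbind(rc * cos(theta), rc * sin(theta), zc)
      sig <- runif(nb, 0.35, 0.7)
      amp <- runif(nb, 0.5, 1.5)
      if (mode == "eeg") amp <- amp * sample(c(-1, 1), nb, replace = TRUE)
      m <- numeric(C)
      for (j in seq_len(nb)) {
        d2 <- rowSums(sweep(pos, 2L, ctr[j, ], "-")^2)
        m <- m + amp[j] * exp(-d2 / (2 * sig[j]^2))
      }
      if (mode == "eeg") m <- m - mean(m)
      nrm <- sqrt(sum(m^2))
      if (nrm < 1e-12) return(NULL)
      m / nrm
    }
    maps <- matrix(0, K, C, dimnames = list(NULL, layout$channel_names))
    k <- 1L
    tries <- 0L
    while (k <= K) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop(structure(
          class = c("megstates_generation_failure", "error", "condition"),
          list(message = sprintf(
            "could not draw %d maps with pairwise |cos| <= %.2f", K, max_cosine),
            call = NULL)))
      }
      cand <- draw_map()
      if (is.null(cand)) next
      if (k > 1L) {
        cs <- abs(maps[seq_len(k - 1L), , drop = FALSE] %*% cand)
        if (any(cs > max_cosine)) next
      }
      maps[k, ] <- cand
      k <- k + 1L
      tries <- 0L
    }
    attr(maps, "mode") <- mode
    attr(maps, "seed") <- as.integer(seed)
    maps
  })
}

# Draw a semi-Markov state sequence: run durations uniform in
# dwell_ms_range (clamped to whole frames inside the range), states
# sampled with no immediate self-transition. Because forbidding
# self-transitions biases the run-state chain's stationary distribution
# to w * (1 - w), the sampling weights are pre-adjusted by fixed-point
# iteration so the *empirical frame coverage* converges to
# coverage_weights. Returns list(labels, runs = data.frame(state, start,
# length)); the final run may be truncated by the recording end.
draw_label_sequence <- function(n_frames, K, fs, dwell_ms_range = c(50, 150),
                                coverage_weights = NULL) {
  if (is.null(coverage_weights)) coverage_weights <- rep(1 / K, K)
  if (length(coverage_weights) != K) {
    stop_invalid("coverage_weights must have length K")
  }
  if (all(coverage_weights <= 0)) {
    stop_invalid("coverage_weights must have at least one positive entry")
  }
  lo <- dwell_ms_range[1L]; hi <- dwell_ms_range[2L]
  if (!(lo < hi) || lo <= 0) stop_invalid("dwell range must satisfy 0 < lo < hi")
  lo_f <- max(1L, as.integer(ceiling(lo * fs / 1000 - 1e-9)))
  hi_f <- max(lo_f, as.integer(floor(hi * fs / 1000 + 1e-9)))
  w <- coverage_weights / sum(coverage_weights)
  # stationary coverage under no-self-transition sampling with weights v
  # is proportional to v * (1 - v); invert by fixed point v <- c * w / (1 - v)
  v <- w
  if (K > 1L) {
    for (i in seq_len(200L)) {
      v_new <- w / pmax(1 - v, 1e-6)
      v_new <- v_new / sum(v_new)
      if (max(abs(v_new - v)) < 1e-12) {
        v <- v_new
        break
      }
      v <- v_new
    }
  }
  labels <- integer(n_frames)
  starts <- integer(0); lens <- integer(0); states <- integer(0)
  t <- 1L
  prev <- 0L
  while (t <= n_frames) {
    vw <- v
    if (prev > 0L && sum(vw[-prev]) > 0) vw[prev] <- 0
    s <- sample.int(K, 1L, prob = vw)
    len <- as.integer(round(runif(1L, lo, hi) * fs / 1000))
    len <- min(max(len, lo_f), hi_f)
    len <- min(len, n_frames - t + 1L)
    labels[t:(t + len - 1L)] <- s
    starts <- c(starts, t); lens <- c(lens, len); states <- c(states, s)
    t <- t + len
    prev <- s
  }
  list(labels = labels,
       runs = data.frame(state = states, start = starts, length = lens))
}

# Assemble a sensor signal from a label sequence: frame t is
# envelope(t) * map[L(t), ] plus modality-specific noise. EEG runs get a
# random +/-1 polarity and the result is re-referenced to a zero channel
# mean per frame; MEG noise is half-normal so the signal stays >= 0.
build_signal <- function(labels, runs, maps, mode, fs, envelope_hz, snr) {
  n <- length(labels)
  C <- ncol(maps)
  tt <- (seq_len(n) - 1L) / fs
  env <- abs(sin(2 * pi * envelope_hz * tt))
  env <- env / mean(env)
  pol <- rep(1, n)
  if (mode == "eeg") {
    flips <- sample(c(-1, 1), nrow(runs), replace = TRUE)
    for (r in seq_len(nrow(runs))) {
      idx <- runs$start[r]:(runs$start[r] + runs$length[r] - 1L)
      pol[idx] <- flips[r]
    }
  }
  x <- t(maps[labels, , drop = FALSE]) * rep(env * pol, each = C)
  if (is.finite(snr)) {
    noise_sd <- sqrt(mean(x^2)) / snr
    noise <- matrix(rnorm(C * n, sd = noise_sd), C, n)
    if (mode == "meg") noise <- abs(noise)
    x <- x + noise
  }
  if (mode == "eeg") x <- sweep(x, 2L, colMeans(x), "-")
  rownames(x) <- colnames(maps)
  x
}

#' Simulate a resting-state recording with known microstate ground truth
#'
#' Generates a piecewise quasi-stable topographic process: state run
#' durations are uniform on `dwell_ms_range` milliseconds (the canonical
#' microstate dwell range is 50-150 ms), states are drawn from
#' `coverage_weights` with no immediate self-transition, the amplitude
#' envelope is a rectified sinusoid (default 10 Hz, emulating an
#' alpha-band envelope), and modality-specific noise is added at the
#' requested signal-to-noise ratio. EEG runs receive a random polarity
#' (microstate analysis is polarity-blind) and the recording is
#' average-referenced; MEG recordings stay elementwise nonnegative.
#'
#' @param layout an [make_layout()] layout.
#' @param maps `K x C` unit-norm topography matrix from
#'   [make_topographies()] (its `mode` attribute selects the convention).
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz (default 250).
#' @param dwell_ms_range run-duration range in ms, default `c(50, 150)`.
#' @param snr signal-to-noise ratio (RMS signal / RMS noise); `Inf`
#'   disables noise.
#' @param envelope_hz envelope frequency in Hz (default 10).
#' @param coverage_weights K state prevalences (default uniform).
#' @param condition condition tag for the recording.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list with `recording` (an [recording()]) and `truth` (class
#'   `ms_truth`: `true_maps`, `labels`, `runs`, `envelope`,
#'   `coverage_targets`, `mode`, `seed`).
#' @examples
#' lay <- make_layout(16, seed = 1)
#' maps <- make_topographies(3, lay, mode = "meg", seed = 2)
#' sim <- simulate_resting(lay, maps, duration_s = 2, fs = 100, seed = 3)
#' table(sim$truth$labels)
#' @export
simulate_resting <- function(layout, maps, duration_s, fs = 250,
                             dwell_ms_range = c(50, 150), snr = 10,
                             envelope_hz = 10, coverage_weights = NULL,
                             condition = "ROE", seed = 1L) {
  stopifnot(inherits(layout, "ms_layout"))
  mode <- attr(maps, "mode") %||% "meg"
  if (fs <= 0) stop_invalid("fs must be positive")
  if (!is.finite(snr) && !identical(snr, Inf)) stop_invalid("snr must be > 0")
  if (is.finite(snr) && snr <= 0) stop_invalid("snr must be > 0")
  K <- nrow(maps)
  n <- as.integer(round(duration_s * fs))
  with_seed(seed, {
    seq_ <- draw_label_sequence(n, K, fs, dwell_ms_range, coverage_weights)
    x <- build_signal(seq_$labels, seq_$runs, maps, mode, fs, envelope_hz, snr)
    tt <- (seq_len(n) - 1L) / fs
    env <- abs(sin(2 * pi * envelope_hz * tt)); env <- env / mean(env)
    rec <- recording(x, fs = fs, modality = mode, condition = condition,
                     channel_names = layout$channel_names)
    truth <- structure(list(
      true_maps = maps, labels = seq_$labels, runs = seq_$runs,
      envelope = env,
      coverage_targets = (coverage_weights %||% rep(1 / K, K)) /
        sum(coverage_weights %||% rep(1 / K, K)),
      mode = mode, seed = as.integer(seed)), class = "ms_truth")
    list(recording = rec, truth = truth)
  })
}

#' Simulate an event-locked (oddball) recording
#'
#' Generates a continuous recording with baseline microstate dynamics and
#' a pseudorandomly intermixed sequence of standard and deviant auditory
#' events. After each deviant onset the generator raises, with
#' probability `boost_prob`, the prevalence of `deviant_state` inside the
#' deviance-detection window (default 150-300 ms post-onset), emulating a
#' stimulus-locked microstate perturbation.
#'
#' @inheritParams simulate_resting
#' @param n_std,n_dev numbers of standard and deviant events (defaults
#'   612 and 55, the classic oddball paradigm counts).
#' @param isi_ms onset-to-onset interval in ms.
#' @param deviant_state state index (1..K) boosted after deviants.
#' @param boost_window_ms window relative to onset, default `c(150, 300)`.
#' @param boost_prob probability that a given deviant's window is forced
#'   to `deviant_state` (1 = always, 0 = no effect).
#' @param pad_s padding before the first and after the last event, s.
#' @return list with `recording`, `events` (class `ms_events`: data frame
#'   `onset` [1-based frame], `type` (`standard`/`deviant`),
#'   `std_pre_dev` flag) and `truth`.
#' @examples
#' lay <- make_layout(16, seed = 1)
#' maps <- make_topographies(3, lay, mode = "meg", seed = 2)
#' sim <- simulate_evoked(lay, maps, n_std = 20, n_dev = 4, fs = 100,
#'                        deviant_state = 2, seed = 3)
#' table(sim$events$type)
#' @export
simulate_evoked <- function(layout, maps, n_std = 612, n_dev = 55,
                            isi_ms = 600, deviant_state = 1L,
                            boost_window_ms = c(150, 300), boost_prob = 1,
                            fs = 250, dwell_ms_range = c(50, 150), snr = 10,
                            envelope_hz = 10, pad_s = 1, seed = 1L) {
  stopifnot(inherits(layout, "ms_layout"))
  mode <- attr(maps, "mode") %||% "meg"
  K <- nrow(maps)
  if (deviant_state < 1 || deviant_state > K) {
    stop_invalid("deviant_state must be in 1..K")
  }
  n_ev <- n_std + n_dev
  with_seed(seed, {
    types <- rep("standard", n_ev)
    types[sample.int(n_ev, n_dev)] <- "deviant"
    isi_f <- as.integer(round(isi_ms * fs / 1000))
    pad_f <- as.integer(round(pad_s * fs))
    onsets <- pad_f + 1L + (seq_len(n_ev) - 1L) * isi_f
    n <- onsets[n_ev] + as.integer(round(0.5 * fs)) + pad_f
    win_f <- as.integer(round(boost_window_ms * fs / 1000))
    if (onsets[n_ev] + win_f[2L] > n) {
      stop_invalid("events overlap the recording end")
    }
    seq_ <- draw_label_sequence(n, K, fs, dwell_ms_range, NULL)
    labels <- seq_$labels
    for (e in which(types == "deviant")) {
      if (runif(1L) < boost_prob) {
        idx <- (onsets[e] + win_f[1L]):(onsets[e] + win_f[2L] - 1L)
        labels[idx] <- deviant_state
      }
    }
    runs <- extract_segments(labels)
    x <- build_signal(labels, runs, maps, mode, fs, envelope_hz, snr)
    rec <- recording(x, fs = fs, modality = mode, condition = "MMN",
                     channel_names = layout$channel_names)
    std_pre_dev <- types == "standard" &
      c(types[-1L], "none") == "deviant"
    events <- structure(
      data.frame(onset = onsets, type = types, std_pre_dev = std_pre_dev),
      class = c("ms_events", "data.frame"))
    truth <- structure(list(
      true_maps = maps, labels = labels, runs = runs,
      deviant_state = as.integer(deviant_state),
      boost_window_ms = boost_window_ms, mode = mode,
      seed = as.integer(seed)), class = "ms_truth")
    list(recording = rec, events = events, truth = truth)
  })
}

# Schaefer-style parcel names: 17 networks x 2 hemispheres when n = 34,
# otherwise generic labels.
parcel_names_for <- function(n_parcels) {
  nets <- c("VisCent", "VisPeri", "SomMotA", "SomMotB", "DorsAttnA",
            "DorsAttnB", "SalVentAttnA", "SalVentAttnB", "LimbicA",
            "LimbicB", "ContA", "ContB", "ContC", "DefaultA", "DefaultB",
            "DefaultC", "TempPar")
  if (n_parcels == 34L) {
    as.vector(outer(nets, c("LH", "RH"), function(a, b) paste(b, a, sep = "_")))
  } else {
    sprintf("P%03d", seq_len(n_parcels))
  }
}

#' Simulate parcel-level source-magnitude series locked to a state sequence
#'
#' Produces a nonnegative parcel-by-frame matrix emulating source
#' magnitudes averaged within cortical atlas parcels: parcel `p` at frame
#' `t` is `baseline + delta(p, L(t)) + noise`, clipped at zero, where the
#' state-specific offsets come from `effect_table`. With an empty effect
#' table the series is independent of the labels (a permutation null).
#'
#' @param truth an `ms_truth` (or any list with `labels`) giving the
#'   per-frame state sequence.
#' @param n_parcels number of parcels (34 gives Schaefer-style
#'   17-network x hemisphere names).
#' @param effect_table `NULL` or a data frame with columns `parcel`
#'   (index), `state` (index) and `delta` (offset added on frames labeled
#'   `state`).
#' @param noise_sd Gaussian noise SD.
#' @param baseline baseline magnitude.
#' @param fs sampling rate of the aligned segmentation, Hz.
#' @param seed integer seed.
#' @return class `ms_parcels`: list with `values` (parcel x frame, >= 0),
#'   `parcel_names`, `fs`, `seed`.
#' @examples
#' lab <- list(labels = rep(1:2, each = 50))
#' ps <- simulate_parcels(lab, n_parcels = 4, fs = 100, seed = 1)
#' dim(ps$values)
#' @export
simulate_parcels <- function(truth, n_parcels, effect_table = NULL,
                             noise_sd = 0.2, baseline = 1, fs = 250,
                             seed = 1L) {
  labels <- truth$labels
  if (n_parcels < 1) stop_invalid("n_parcels must be >= 1")
  K <- max(labels, 1L)
  n <- length(labels)
  if (!is.null(effect_table) && nrow(effect_table)) {
    if (any(effect_table$state < 1 | effect_table$state > K)) {
      stop_invalid("effect_table refers to a state not present in the labels")
    }
    if (any(!is.finite(effect_table$delta))) {
      stop_invalid("effect_table deltas must be finite")
    }
    if (any(effect_table$parcel < 1 | effect_table$parcel > n_parcels)) {
      stop_invalid("effect_table refers to a parcel out of range")
    }
  }
  with_seed(seed, {
    v <- matrix(baseline, n_parcels, n) +
      matrix(rnorm(n_parcels * n, sd = noise_sd), n_parcels, n)
    if (!is.null(effect_table) && nrow(effect_table)) {
      for (r in seq_len(nrow(effect_table))) {
        idx <- which(labels == effect_table$state[r])
        v[effect_table$parcel[r], idx] <-
          v[effect_table$parcel[r], idx] + effect_table$delta[r]
      }
    }
    v[v < 0] <- 0
    nm <- parcel_names_for(as.integer(n_parcels))
    rownames(v) <- nm
    structure(list(values = v, parcel_names = nm, fs = fs,
                   seed = as.integer(seed)), class = "ms_parcels")
  })
}

#' @export
print.ms_parcels <- function(x, ...) {
  cat(sprintf("<ms_parcels> %d parcels x %d frames @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$fs))
  invisible(x)
}

#' Simulate simultaneously recorded MEG and EEG with tunable coupling
#'
#' Generates one MEG-mode and one EEG-mode recording driven by state
#' sequences whose run-wise agreement is controlled by `coupling`: at 1
#' the same label sequence drives both modalities (through distinct map
#' sets, paired by index); at 0 the EEG state of each run is drawn
#' independently.
#'
#' @inheritParams simulate_resting
#' @param K number of states shared by the two map sets.
#' @param coupling probability in `[0, 1]` that an EEG run copies the
#'   concurrent MEG state (via the index pairing).
#' @return list with `meg`, `eeg` (recordings), and `truth` (`maps_meg`,
#'   `maps_eeg`, `labels_meg`, `labels_eeg`, `runs`, `coupling`, `seed`).
#' @examples
#' lay <- make_layout(16, seed = 1)
#' sim <- simulate_paired_modalities(lay, K = 3, duration_s = 2, fs = 100,
#'                                   coupling = 1, seed = 2)
#' identical(sim$truth$labels_meg, sim$truth$labels_eeg)
#' @export
simulate_paired_modalities <- function(layout, K = 6, duration_s = 60,
                                       fs = 250, dwell_ms_range = c(50, 150),
                                       snr = 10, envelope_hz = 10,
                                       coupling = 1, seed = 1L) {
  if (coupling < 0 || coupling > 1) stop_invalid("coupling must be in [0, 1]")
  with_seed(seed, {
    maps_meg <- make_topographies(K, layout, "meg",
                                  seed = child_seed(seed, 11L))
    maps_eeg <- make_topographies(K, layout, "eeg",
                                  seed = child_seed(seed, 22L))
    n <- as.integer(round(duration_s * fs))
    seq_meg <- draw_label_sequence(n, K, fs, dwell_ms_range, NULL)
    lab_eeg <- seq_meg$labels
    copy <- runif(nrow(seq_meg$runs)) < coupling
    for (r in which(!copy)) {
      idx <- seq_meg$runs$start[r]:(seq_meg$runs$start[r] +
                                      seq_meg$runs$length[r] - 1L)
      lab_eeg[idx] <- sample.int(K, 1L)
    }
    runs_eeg <- extract_segments(lab_eeg)
    x_meg <- build_signal(seq_meg$labels, seq_meg$runs, maps_meg, "meg",
                          fs, envelope_hz, snr)
    x_eeg <- build_signal(lab_eeg, runs_eeg, maps_eeg, "eeg",
                          fs, envelope_hz, snr)
    truth <- structure(list(
      maps_meg = maps_meg, maps_eeg = maps_eeg,
      labels_meg = seq_meg$labels, labels_eeg = lab_eeg,
      runs = seq_meg$runs, coupling = coupling, seed = as.integer(seed)),
      class = "ms_truth")
    list(meg = recording(x_meg, fs, "meg", "ROE", layout$channel_names),
         eeg = recording(x_eeg, fs, "eeg", "ROE", layout$channel_names),
         truth = truth)
  })
}
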