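#' Event-locked microstate detection-rate curves
#'
#' For each event type and each frame relative to stimulus onset, counts
#' how many events have that frame labeled by each microstate (row
#' `"0"` collects unlabeled frames). With all events retained, the
#' per-frame counts over states 0..K sum to the number of events
#' exactly; no count can exceed it. Events whose epoch would cross the
#' recording edge are dropped with a warning and reflected in
#' `n_events`.
#'
#' @param seg an `ms_segmentation`.
#' @param events an `ms_events` data frame (`onset` 1-based frames,
#'   `type`).
#' @param epoch_ms epoch limits relative to onset, default
#'   `c(-200, 500)` ms.
#' @return named list (one entry per event type) of class
#'   `ms_detcurve` objects: list with `counts` ((K+1) x n_frames integer
#'   matrix, rows `"0".."K"`), `rel_ms` (frame times relative to onset),
#'   `n_events`, `type`.
#' @export
detection_rate_curve <- function(seg, events, epoch_ms = c(-200, 500)) {
  stopifnot(inherits(seg, "ms_segmentation"))
  fs <- seg$fs
  off <- as.integer(round(epoch_ms[1L] * fs / 1000)):
    as.integer(round(epoch_ms[2L] * fs / 1000))
  n <- length(seg$labels)
  K <- seg$k
  out <- list()
  for (tp in unique(as.character(events$type))) {
    ons <- events$onset[events$type == tp]
    ok <- ons + off[1L] >= 1L & ons + off[length(off)] <= n
    if (any(!ok)) {
      warning(sum(!ok), " ", tp,
              " event(s) dropped: epoch outside the recording")
    }
    ons <- ons[ok]
    counts <- matrix(0L, K + 1L, length(off),
                     dimnames = list(0:K, round(off * 1000 / fs)))
    for (o in ons) {
      lab <- seg$labels[o + off]
      counts[cbind(lab + 1L, seq_along(off))] <-
        counts[cbind(lab + 1L, seq_along(off))] + 1L
    }
    out[[tp]] <- structure(list(counts = counts,
                                rel_ms = off * 1000 / fs,
                                n_events = length(ons), type = tp),
                           class = "ms_detcurve")
  }
  out
}

#' @export
print.ms_detcurve <- function(x, ...) {
  cat(sprintf("<ms_detcurve> %s: %d events, %d states, %d frames (%g..%g ms)\n",
              x$type, x$n_events, nrow(x$counts) - 1L, ncol(x$counts),
              min(x$rel_ms), max(x$rel_ms)))
  invisible(x)
}

#' Microstate mismatch-negativity statistic (mMS-MMN)
#'
#' The per-state difference in mean in-window detection rate between
#' deviant and standard stimuli: counts are normalised per event (so
#' unequal event numbers compare fairly), averaged over the analysis
#' window (default 150-300 ms post-onset, the deviance-detection
#' window), and differenced deviant minus standard. Including the
#' unlabeled row, the differences sum to zero (one label per frame).
#'
#' @param curve_std,curve_dev `ms_detcurve` objects on the same state
#'   set and epoch grid.
#' @param window window in ms relative to onset, default `c(150, 300)`;
#'   converted to frames half-open as `[ceil(lo*fs), floor(hi*fs))`.
#' @return named numeric vector over rows `"0".."K"` (rates in
#'   events^-1 units).
#' @export
mms_mmn <- function(curve_std, curve_dev, window = c(150, 300)) {
  stopifnot(inherits(curve_std, "ms_detcurve"),
            inherits(curve_dev, "ms_detcurve"))
  if (!identical(dim(curve_std$counts), dim(curve_dev$counts))) {
    stop_invalid("curves differ in state set or epoch grid")
  }
  rel <- curve_std$rel_ms
  keep <- rel >= window[1L] & rel < window[2L]
  if (!any(keep)) stop_invalid("empty window after frame rounding")
  rate_std <- rowMeans(curve_std$counts[, keep, drop = FALSE]) /
    curve_std$n_events
  rate_dev <- rowMeans(curve_dev$counts[, keep, drop = FALSE]) /
    curve_dev$n_events
  rate_dev - rate_std
}

#' MMN peak amplitude from epoched parcel (source-region) series
#'
#' Implements the region-wise mismatch-negativity amplitude measure on
#' epoched source magnitudes: each epoch is z-scored per region against
#' its pre-stimulus baseline, converted to absolute values, averaged
#' within stimulus type (standards restricted to those flagged as
#' immediately preceding a deviant, equalising epoch counts), and the
#' per-region peak is the most prominent negative local minimum of the
#' difference wave inside the search window. The default difference is
#' `standard - deviant`; set `direction = "deviant-standard"` for the
#' classical MMN orientation.
#'
#' @param parcel_epochs 3-d array `region x epoch x frame` of epoched
#'   source magnitudes spanning `epoch_ms`.
#' @param types character vector per epoch, `"standard"` / `"deviant"`.
#' @param std_pre_dev logical per epoch: standard immediately preceding
#'   a deviant (used to subset the standards). Ignored for deviants.
#' @param fs sampling rate in Hz.
#' @param epoch_ms epoch span in ms relative to onset, default
#'   `c(-200, 500)`.
#' @param baseline_ms baseline length before onset used for z-scoring,
#'   default 200.
#' @param search_ms peak search window, default `c(150, 300)`.
#' @param direction `"standard-deviant"` (default) or
#'   `"deviant-standard"`.
#' @return numeric vector of per-region peak amplitudes (<= 0; 0 with
#'   attribute flag when no negative excursion exists), with attributes
#'   `peak_ms` (latencies) and `n_dropped` (epochs dropped for a
#'   zero-variance baseline).
#' @export
mmn_peak <- function(parcel_epochs, types, std_pre_dev = NULL, fs,
                     epoch_ms = c(-200, 500), baseline_ms = 200,
                     search_ms = c(150, 300),
                     direction = c("standard-deviant", "deviant-standard")) {
  direction <- match.arg(direction)
  stopifnot(length(dim(parcel_epochs)) == 3L)
  R <- dim(parcel_epochs)[1L]
  E <- dim(parcel_epochs)[2L]
  Tn <- dim(parcel_epochs)[3L]
  if (length(types) != E) stop_invalid("types must have one entry per epoch")
  if (!all(c("standard", "deviant") %in% types)) {
    stop_invalid("both stimulus types must be present")
  }
  rel_ms <- seq(epoch_ms[1L], by = 1000 / fs, length.out = Tn)
  bl <- which(rel_ms >= -baseline_ms & rel_ms < 0)
  if (length(bl) < 2L) stop_invalid("baseline window too short")
  zabs <- array(NA_real_, dim(parcel_epochs))
  dropped <- 0L
  keep_ep <- rep(TRUE, E)
  for (e in seq_len(E)) {
    for (r in seq_len(R)) {
      v <- parcel_epochs[r, e, ]
      mu <- mean(v[bl]); s <- sd(v[bl])
      if (s == 0) {
        keep_ep[e] <- FALSE
        next
      }
      zabs[r, e, ] <- abs((v - mu) / s)
    }
  }
  if (any(!keep_ep)) {
    dropped <- sum(!keep_ep)
    warning(dropped, " epoch(s) dropped: zero-variance baseline")
  }
  sel_std <- keep_ep & types == "standard"
  if (!is.null(std_pre_dev)) sel_std <- sel_std & std_pre_dev
  sel_dev <- keep_ep & types == "deviant"
  if (!any(sel_std) || !any(sel_dev)) {
    stop_invalid("no usable epochs for one of the stimulus types")
  }
  avg <- function(sel) apply(zabs[, sel, , drop = FALSE], c(1L, 3L), mean)
  dif <- if (direction == "standard-deviant") {
    avg(sel_std) - avg(sel_dev)
  } else {
    avg(sel_dev) - avg(sel_std)
  }
  win <- which(rel_ms >= search_ms[1L] & rel_ms <= search_ms[2L])
  peaks <- numeric(R); lat <- rep(NA_real_, R)
  for (r in seq_len(R)) {
    d <- dif[r, ]
    is_min <- vapply(win, function(i) {
      left <- if (i > 1L) d[i] <= d[i - 1L] else TRUE
      right <- if (i < length(d)) d[i] <= d[i + 1L] else TRUE
      left && right && d[i] < 0
    }, logical(1L))
    if (any(is_min)) {
      cand <- win[is_min]
      best <- cand[which.min(d[cand])]
      peaks[r] <- d[best]
      lat[r] <- rel_ms[best]
    }
  }
  structure(peaks, peak_ms = lat, n_dropped = dropped,
            flag = ifelse(is.na(lat), "no-negative-excursion", "ok"))
}

#' MMN lateralization score
#'
#' The right-minus-left discrepancy in MMN peak amplitude over the
#' auditory regions. With negative-valued peaks, a more negative right
#' peak gives a negative score (right-lateralized response); a more
#' negative left peak gives a positive score (left-lateralized).
#'
#' @param peak_right,peak_left peak amplitudes from [mmn_peak()].
#' @return `peak_right - peak_left`.
#' @examples
#' lateralization_score(-5, -2)  # -3: right-lateralized
#' @export
lateralization_score <- function(peak_right, peak_left) {
  if (anyNA(c(peak_right, peak_left))) {
    stop_invalid("undefined peak amplitude")
  }
  peak_right - peak_left
}
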