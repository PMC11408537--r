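#' Competitively back-fit microstate templates to a recording
#'
#' Assigns to every frame the template with the highest
#' [spatial_similarity()] to the frame's topography; frames whose best
#' similarity falls below `threshold` (default 0.50, the conventional
#' spatial-correlation floor) stay unlabeled (label 0). The per-frame
#' winning similarity and GFP are carried along for smoothing and for the
#' explained-variance metrics.
#'
#' @param rec an [recording()].
#' @param ms an [microstates()] set with matching channels and mode.
#' @param threshold minimum similarity for labeling, default 0.50.
#' @return class `ms_segmentation`: list with `labels` (per-frame integer
#'   in `0..K`), `sims` (winning similarity; 0 where unlabeled),
#'   `all_sims` (frame x K similarity matrix), `gfp`, `fs`, `k`, `mode`,
#'   `threshold`.
#' @examples
#' lay <- make_layout(16, seed = 1)
#' maps <- make_topographies(3, lay, mode = "meg", seed = 2)
#' sim <- simulate_resting(lay, maps, duration_s = 2, fs = 100, snr = Inf,
#'                         seed = 3)
#' seg <- backfit(sim$recording, microstates(maps, "meg"))
#' table(seg$labels)
#' @export
backfit <- function(rec, ms, threshold = 0.50) {
  stopifnot(inherits(rec, "ms_recording"), inherits(ms, "ms_microstates"))
  if (ncol(ms$maps) != nrow(rec$data)) {
    stop_invalid("channel count of recording and templates differ")
  }
  if (rec$modality != ms$mode) {
    stop_invalid("recording modality and template mode differ")
  }
  S <- similarity_matrix(t(rec$data), ms$maps, ms$mode)
  labels <- max.col(S, ties.method = "first")
  sims <- S[cbind(seq_len(nrow(S)), labels)]
  unl <- sims < threshold
  labels[unl] <- 0L
  sims[unl] <- 0
  structure(list(labels = as.integer(labels), sims = sims, all_sims = S,
                 gfp = gfp(rec)$values, fs = rec$fs, k = ms$k,
                 mode = ms$mode, threshold = threshold),
            class = "ms_segmentation")
}

#' @export
print.ms_segmentation <- function(x, ...) {
  cat(sprintf(
    "<ms_segmentation> %d frames @ %g Hz, K=%d, labeled %.1f%%\n",
    length(x$labels), x$fs, x$k, 100 * mean(x$labels > 0)))
  invisible(x)
}

#' Besag temporal smoothing of a microstate label sequence
#'
#' Iteratively relabels frames to favour temporally contiguous segments:
#' a labeled frame `t` is moved to the state `m` minimising
#' `cost(t, m) = (1 - sim(t, m)^2) - lambda / (2 b) * N_m(t)`, where
#' `N_m(t)` counts frames labeled `m` in the window of half-size `b`
#' around `t` (excluding `t` itself). Frames left unlabeled by the
#' similarity floor are frozen: smoothing never labels a frame whose best
#' similarity is below the back-fitting threshold. Sweeps are synchronous
#' and repeat until no label changes or `max_iter` is reached.
#'
#' @param seg an `ms_segmentation` from [backfit()].
#' @param half_window_b window half-size in frames (default 3).
#' @param besag_lambda smoothing weight (default 10); 0 is the identity.
#' @param max_iter sweep cap.
#' @return the smoothed `ms_segmentation` (with `sims` updated to the
#'   similarity of the final label).
#' @export
smooth_labels <- function(seg, half_window_b = 3L, besag_lambda = 10,
                          max_iter = 50L) {
  stopifnot(inherits(seg, "ms_segmentation"))
  b <- as.integer(half_window_b)
  if (b < 0 || besag_lambda < 0) stop_invalid("b and lambda must be >= 0")
  if (besag_lambda == 0 || b == 0) return(seg)
  S <- seg$all_sims
  n <- nrow(S)
  K <- ncol(S)
  data_cost <- 1 - S^2
  labels <- seg$labels
  movable <- labels > 0L
  pen <- besag_lambda / (2 * b)
  for (it in seq_len(max_iter)) {
    # N_m(t): windowed counts per state via cumulative sums
    Nm <- matrix(0, n, K)
    for (m in seq_len(K)) {
      ind <- as.numeric(labels == m)
      cs <- cumsum(ind)
      lo <- pmax(seq_len(n) - b, 1L)
      hi <- pmin(seq_len(n) + b, n)
      Nm[, m] <- cs[hi] - c(0, cs)[lo] - ind
    }
    cost <- data_cost - pen * Nm
    new_labels <- labels
    new_labels[movable] <- max.col(-cost[movable, , drop = FALSE],
                                   ties.method = "first")
    if (all(new_labels == labels)) break
    labels <- new_labels
  }
  seg$labels <- as.integer(labels)
  sims <- numeric(n)
  sims[movable] <- S[cbind(which(movable), labels[movable])]
  seg$sims <- sims
  seg
}

#' Run-length view of a label sequence
#'
#' Decomposes a per-frame label sequence into maximal constant runs.
#' Starts are 1-based and runs are half-open in frames: concatenating
#' `rep(state, length)` over the rows reconstructs the input exactly.
#'
#' @param labels integer vector (an `ms_segmentation` is also accepted).
#' @return data frame with columns `state`, `start`, `length`.
#' @examples
#' extract_segments(c(1, 1, 2, 2, 2))
#' @export
extract_segments <- function(labels) {
  if (inherits(labels, "ms_segmentation")) labels <- labels$labels
  if (!length(labels)) {
    return(data.frame(state = integer(0), start = integer(0),
                      length = integer(0)))
  }
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths)
  data.frame(state = r$values,
             start = ends - r$lengths + 1L,
             length = r$lengths)
}

#' Temporal metrics of a microstate segmentation
#'
#' Computes, per state `m`: the time coverage (frames labeled `m` divided
#' by all frames), the mean segment duration in milliseconds, the
#' occurrence rate (segments of `m` per second), and the global explained
#' variance `GEV_m = sum_{t: L(t)=m} (gfp_t * sim_t)^2 / sum_t gfp_t^2`.
#' Coverages over the states plus the unlabeled fraction sum to 1
#' exactly; the total GEV is the sum of the per-state GEVs and lies in
#' `[0, 1]`.
#'
#' @param seg an `ms_segmentation`.
#' @return class `ms_metrics`: list with `coverage`, `mean_duration_ms`,
#'   `occurrence_per_s` (each length K), `gev` (length K), `gev_total`,
#'   `unlabeled` (fraction), `k`, `fs`.
#' @export
temporal_metrics <- function(seg) {
  stopifnot(inherits(seg, "ms_segmentation"))
  n <- length(seg$labels)
  if (!n) stop_invalid("empty segmentation")
  K <- seg$k
  denom <- sum(seg$gfp^2)
  if (denom <= 0) {
    stop(structure(class = c("megstates_undefined_gev", "error", "condition"),
                   list(message = "zero total GFP", call = NULL)))
  }
  runs <- extract_segments(seg$labels)
  cov <- tabulate(seg$labels[seg$labels > 0L], K) / n
  dur <- occ <- numeric(K)
  for (m in seq_len(K)) {
    rm_ <- runs$length[runs$state == m]
    dur[m] <- if (length(rm_)) mean(rm_) * 1000 / seg$fs else 0
    occ[m] <- length(rm_) / (n / seg$fs)
  }
  gev_num <- (seg$gfp * seg$sims)^2
  gev <- vapply(seq_len(K), function(m) {
    sum(gev_num[seg$labels == m]) / denom
  }, numeric(1L))
  structure(list(coverage = cov, mean_duration_ms = dur,
                 occurrence_per_s = occ, gev = gev, gev_total = sum(gev),
                 unlabeled = 1 - sum(cov), k = K, fs = seg$fs),
            class = "ms_metrics")
}

#' @export
print.ms_metrics <- function(x, ...) {
  df <- data.frame(state = seq_len(x$k),
                   coverage = round(x$coverage, 3),
                   mean_duration_ms = round(x$mean_duration_ms, 1),
                   occurrence_per_s = round(x$occurrence_per_s, 2),
                   gev = round(x$gev, 3))
  print(df, row.names = FALSE)
  cat(sprintf("unlabeled %.1f%%, total GEV %.3f\n",
              100 * x$unlabeled, x$gev_total))
  invisible(x)
}
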