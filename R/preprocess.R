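#' Combine planar gradiometer pairs into magnitude signals
#'
#' For every sensor site the two orthogonal planar gradients are merged
#' into a single nonnegative planar gradient magnitude,
#' `sqrt(gx^2 + gy^2)`, yielding reference-free topographies suitable for
#' MEG microstate analysis. Magnetometers are excluded by construction:
#' only the two gradiometer matrices enter.
#'
#' @param grad_x,grad_y channel-by-frame matrices of the two gradient
#'   directions, matched in shape (and channel order).
#' @return a nonnegative channel-by-frame matrix of the same shape.
#' @examples
#' combine_planar(matrix(3), matrix(4))  # 5
#' @export
combine_planar <- function(grad_x, grad_y) {
  grad_x <- as.matrix(grad_x); grad_y <- as.matrix(grad_y)
  if (!identical(dim(grad_x), dim(grad_y))) {
    stop_invalid("grad_x and grad_y must have identical dimensions")
  }
  out <- sqrt(grad_x^2 + grad_y^2)
  dimnames(out) <- dimnames(grad_x)
  out
}

#' Spatial trimmed-mean filter over the six nearest neighbours
#'
#' Smooths each topography and suppresses single-sensor outliers: for
#' every channel the filter pools the channel with its six nearest
#' neighbours (from the layout's neighbour table), drops one maximum and
#' one minimum of the seven values, and outputs the mean of the remaining
#' five. Constant topographies are left unchanged and the per-frame value
#' range never widens.
#'
#' @param rec an [recording()].
#' @param layout an [make_layout()] layout covering every channel of
#'   `rec` (matched by position: channel i uses neighbour row i).
#' @return a filtered [recording()] of the same shape.
#' @export
spatial_filter <- function(rec, layout) {
  stopifnot(inherits(rec, "ms_recording"), inherits(layout, "ms_layout"))
  C <- nrow(rec$data)
  if (nrow(layout$neighbors) != C || ncol(layout$neighbors) != 6L) {
    stop_invalid("layout neighbour table must be C x 6 for this recording")
  }
  x <- rec$data
  out <- matrix(0, C, ncol(x), dimnames = dimnames(x))
  for (c in seq_len(C)) {
    rows <- c(c, layout$neighbors[c, ])
    vals <- lapply(rows, function(r) x[r, ])
    mx <- Reduce(pmax, vals)
    mn <- Reduce(pmin, vals)
    out[c, ] <- (Reduce(`+`, vals) - mx - mn) / 5
  }
  rec$data <- out
  rec
}

#' Band-limit and decimate a recording
#'
#' Applies, in order, a zero-phase Butterworth band-stop at the power-line
#' frequency, a high-pass, and a low-pass (all forward-backward via
#' [signal::filtfilt()]), then decimates to `target_fs`. The low-pass
#' doubles as the anti-alias filter, so `target_fs` must be an integer
#' divisor of `fs` and at least twice the low-pass corner.
#'
#' @param rec an [recording()].
#' @param notch power-line frequency in Hz (`NULL` to skip); default 50.
#' @param hp high-pass corner in Hz (`NULL` to skip); default 1.
#' @param lp low-pass corner in Hz (`NULL` to skip); default 30.
#' @param target_fs output sampling rate in Hz; default 250.
#' @param notch_width half-width of the band-stop in Hz.
#' @return a filtered, resampled [recording()]. MEG recordings are
#'   clipped at zero after filtering (ringing can produce small negative
#'   excursions that the nonnegativity invariant forbids).
#' @export
standard_filter_resample <- function(rec, notch = 50, hp = 1, lp = 30,
                                     target_fs = 250, notch_width = 2) {
  stopifnot(inherits(rec, "ms_recording"))
  fs <- rec$fs
  if (target_fs > fs) stop_invalid("target_fs must not exceed fs")
  if (abs(fs / target_fs - round(fs / target_fs)) > 1e-9) {
    stop_invalid("target_fs must be an integer divisor of fs")
  }
  x <- rec$data
  nyq <- fs / 2
  apply_filt <- function(x, filt) {
    t(apply(x, 1L, function(ch) signal::filtfilt(filt, ch)))
  }
  if (!is.null(notch) && notch < nyq) {
    bs <- signal::butter(2, c(notch - notch_width, notch + notch_width) / nyq,
                         type = "stop")
    x <- apply_filt(x, bs)
  }
  if (!is.null(hp) && hp > 0) {
    bh <- signal::butter(2, hp / nyq, type = "high")
    x <- apply_filt(x, bh)
  }
  if (!is.null(lp) && lp < nyq) {
    bl <- signal::butter(4, lp / nyq, type = "low")
    x <- apply_filt(x, bl)
  }
  dec <- as.integer(round(fs / target_fs))
  if (dec > 1L) x <- x[, seq(1L, ncol(x), by = dec), drop = FALSE]
  if (rec$modality == "meg") x[x < 0] <- 0
  dimnames(x) <- list(rec$channel_names, NULL)
  recording(x, fs = target_fs, modality = rec$modality,
            condition = rec$condition, channel_names = rec$channel_names)
}

#' Epoch a recording and reject high-amplitude artifact epochs
#'
#' Splits the recording into consecutive fixed-length windows and flags
#' artifactual ones by a z-value criterion: each sample is z-scored per
#' channel over the whole recording, absolute z-values are summed across
#' channels per frame, and an epoch's score is the maximum of that sum
#' over its frames. Epochs whose score exceeds `z_thresh` are dropped and
#' the survivors are concatenated in temporal order.
#'
#' @param rec an [recording()].
#' @param epoch_s epoch length in seconds (default 2).
#' @param z_thresh rejection threshold on the channel-summed absolute
#'   z-score.
#' @return list with `recording` (clean concatenated epochs; duration is
#'   a multiple of `epoch_s`) and `report` (data frame: `epoch`, `score`,
#'   `kept`).
#' @export
epoch_and_reject <- function(rec, epoch_s = 2, z_thresh = 20) {
  stopifnot(inherits(rec, "ms_recording"))
  len <- as.integer(round(epoch_s * rec$fs))
  n_ep <- ncol(rec$data) %/% len
  if (n_ep < 1L) stop_invalid("recording is shorter than one epoch")
  x <- rec$data
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, sd)
  sdv[sdv == 0] <- 1
  z <- abs((x - mu) / sdv)
  zsum <- colSums(z)
  scores <- vapply(seq_len(n_ep), function(e) {
    max(zsum[((e - 1L) * len + 1L):(e * len)])
  }, numeric(1L))
  kept <- scores <= z_thresh
  if (!any(kept)) {
    stop(structure(class = c("megstates_empty_result", "error", "condition"),
                   list(message = "all epochs rejected", call = NULL)))
  }
  idx <- unlist(lapply(which(kept), function(e) {
    ((e - 1L) * len + 1L):(e * len)
  }))
  out <- rec
  out$data <- rec$data[, idx, drop = FALSE]
  list(recording = out,
       report = data.frame(epoch = seq_len(n_ep), score = scores, kept = kept))
}
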