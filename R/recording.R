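#' Construct a sensor recording
#'
#' A `Recording` is a channel-by-frame numeric matrix together with its
#' sampling rate, modality convention and an optional condition tag.
#' MEG recordings hold combined planar gradient magnitudes and must be
#' elementwise nonnegative; EEG recordings hold signed, average-referenced
#' potentials.
#'
#' @param data numeric matrix, channels in rows, frames in columns.
#'   Row names, when present, are used as channel names.
#' @param fs sampling rate in Hz (positive scalar).
#' @param modality `"meg"` (combined gradiometers, nonnegative) or
#'   `"eeg"` (signed, average-referenced).
#' @param condition free-form condition tag (e.g. `"ROE"`, `"RCE"`,
#'   `"MMN"`).
#' @param channel_names optional character vector overriding row names.
#' @return an object of class `ms_recording` with elements `data`, `fs`,
#'   `modality`, `condition`, `channel_names`.
#' @examples
#' rec <- recording(matrix(abs(rnorm(40)), 4, 10), fs = 250, modality = "meg")
#' dim(rec$data)
#' @export
recording <- function(data, fs, modality = c("meg", "eeg"),
                      condition = "unspecified", channel_names = NULL) {
  modality <- match.arg(modality)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop_invalid("recording data must be numeric")
  if (anyNA(data) || any(!is.finite(data))) {
    stop_invalid("recording data must be finite (no NaN/Inf)")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_invalid("fs must be a positive scalar")
  }
  if (modality == "meg" && any(data < 0)) {
    stop_invalid("meg (combined-gradiometer) data must be nonnegative")
  }
  if (is.null(channel_names)) {
    channel_names <- rownames(data) %||% paste0("CH", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    stop_invalid("channel_names length must equal the number of rows")
  }
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, modality = modality,
                 condition = condition, channel_names = channel_names),
            class = "ms_recording")
}

#' @export
print.ms_recording <- function(x, ...) {
  cat(sprintf("<ms_recording> %s/%s: %d channels x %d frames @ %g Hz (%.1f s)\n",
              x$modality, x$condition, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Global field power of a recording
#'
#' The per-frame spatial summary used to locate high signal-to-noise
#' topographies. For EEG the GFP is the spatial standard deviation across
#' channels after removing the per-frame channel mean (the average
#' reference); for nonnegative MEG data no mean is subtracted and the GFP
#' is the root-mean-square across channels.
#'
#' @param rec an [recording()] with at least two channels.
#' @return an object of class `ms_gfp`: list with `values` (per-frame
#'   nonnegative numeric) and `mode` (`"signed"` for eeg, `"positive"`
#'   for meg).
#' @examples
#' rec <- recording(rbind(c(1, 3), c(-1, 4)), fs = 250, modality = "eeg")
#' gfp(rec)$values
#' @export
gfp <- function(rec) {
  stopifnot(inherits(rec, "ms_recording"))
  x <- rec$data
  if (nrow(x) < 2L) stop_invalid("gfp needs at least 2 channels")
  if (rec$modality == "eeg") {
    mu <- colMeans(x)
    v <- sqrt(colMeans(sweep(x, 2L, mu, "-")^2))
    mode <- "signed"
  } else {
    v <- sqrt(colMeans(x^2))
    mode <- "positive"
  }
  structure(list(values = as.numeric(v), mode = mode), class = "ms_gfp")
}

#' @export
print.ms_gfp <- function(x, ...) {
  cat(sprintf("<ms_gfp> %d frames, mode=%s, mean=%.4g\n",
              length(x$values), x$mode, mean(x$values)))
  invisible(x)
}
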