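# Readers and writers: CSV recordings with a sampling-rate header,
# BrainVision vhdr/vmrk/eeg triplets (binary multiplexed IEEE float 32
# and vectorized ASCII dialects), event TSVs, template CSV + JSON
# sidecars, segmentation TSV + JSON headers. Frames are 1-based inside R
# and 0-based in files.

#' Write a recording to disk
#'
#' @param rec an [recording()].
#' @param path output path: `.csv` for the CSV dialect or `.vhdr` for a
#'   BrainVision triplet (the `.vmrk`/`.eeg` companions are written next
#'   to it).
#' @param format `"csv"`, `"brainvision"`, or `"auto"` (by extension).
#' @param binary for BrainVision: `TRUE` writes binary multiplexed
#'   IEEE_FLOAT_32, `FALSE` vectorized ASCII.
#' @param events optional `ms_events` written to the `.vmrk` file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv",
                                                  "brainvision"),
                            binary = TRUE, events = NULL) {
  stopifnot(inherits(rec, "ms_recording"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vhdr$", path)) "brainvision" else "csv"
  }
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# megstates-recording v1",
                 sprintf("# fs=%.17g", rec$fs),
                 sprintf("# modality=%s", rec$modality),
                 sprintf("# condition=%s", rec$condition)), con)
    df <- data.frame(channel = rec$channel_names, rec$data,
                     check.names = FALSE)
    colnames(df) <- c("channel", sprintf("f%d", seq_len(ncol(rec$data)) - 1L))
    write.csv(df, con, row.names = FALSE, quote = FALSE)
  } else {
    write_brainvision(rec, path, binary = binary, events = events)
  }
  invisible(path)
}

write_brainvision <- function(rec, vhdr_path, binary = TRUE, events = NULL) {
  base <- sub("\\.vhdr$", "", basename(vhdr_path))
  dir <- dirname(vhdr_path)
  data_file <- paste0(base, ".eeg")
  mrk_file <- paste0(base, ".vmrk")
  C <- nrow(rec$data)
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "",
           "[Common Infos]",
           "Codepage=UTF-8",
           paste0("DataFile=", data_file),
           paste0("MarkerFile=", mrk_file),
           paste0("DataFormat=", if (binary) "BINARY" else "ASCII"),
           paste0("DataOrientation=",
                  if (binary) "MULTIPLEXED" else "VECTORIZED"),
           paste0("NumberOfChannels=", C),
           sprintf("SamplingInterval=%.17g", 1e6 / rec$fs),
           "")
  if (binary) {
    hdr <- c(hdr, "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32", "")
  } else {
    hdr <- c(hdr, "[ASCII Infos]", "DecimalSymbol=.", "SkipLines=0",
             "SkipColumns=0", "")
  }
  hdr <- c(hdr, "[Channel Infos]",
           sprintf("Ch%d=%s,,1,unit", seq_len(C), rec$channel_names))
  writeLines(hdr, vhdr_path)
  mrk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
           "",
           "[Common Infos]",
           "Codepage=UTF-8",
           paste0("DataFile=", data_file),
           "",
           "[Marker Infos]",
           sprintf("Mk1=New Segment,,1,1,0,0"))
  if (!is.null(events) && nrow(events)) {
    mrk <- c(mrk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                          seq_len(nrow(events)) + 1L,
                          as.character(events$type), events$onset))
  }
  writeLines(mrk, file.path(dir, mrk_file))
  if (binary) {
    con <- file(file.path(dir, data_file), "wb")
    on.exit(close(con))
    # multiplexed: channel index varies fastest, i.e. column-major C x T
    writeBin(as.numeric(rec$data), con, size = 4L, endian = "little")
  } else {
    # vectorized: one text line per channel
    lines <- vapply(seq_len(C), function(c) {
      paste(sprintf("%.17g", rec$data[c, ]), collapse = " ")
    }, character(1L))
    writeLines(lines, file.path(dir, data_file))
  }
  invisible(vhdr_path)
}

bv_parse_error <- function(line_no, msg) {
  stop(structure(class = c("megstates_parse_error", "error", "condition"),
                 list(message = sprintf("line %d: %s", line_no, msg),
                      call = NULL)))
}

#' Read a recording from disk
#'
#' Reads the CSV dialect written by [write_recording()] or a BrainVision
#' `vhdr`/`vmrk`/data triplet (binary multiplexed IEEE_FLOAT_32 or
#' vectorized ASCII). Malformed headers raise a parse error carrying the
#' offending line number; a truncated binary data file is an error, not
#' a silent truncation.
#'
#' @param path `.csv` or `.vhdr` path.
#' @param format `"auto"` (default, by extension), `"csv"` or
#'   `"brainvision"`.
#' @param modality,condition recording tags used for BrainVision input
#'   (the format itself does not carry them); ignored for CSV, which
#'   stores them in its header.
#' @return an [recording()]; for BrainVision, attribute `events` holds
#'   the stimulus markers as an `ms_events` data frame when present.
#' @export
read_recording <- function(path, format = c("auto", "csv", "brainvision"),
                           modality = "meg", condition = "unspecified") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vhdr$", path)) "brainvision" else "csv"
  }
  if (format == "csv") {
    lines <- readLines(path, n = 10L)
    meta <- grep("^# ", lines, value = TRUE)
    get_meta <- function(key, default = NULL) {
      hit <- grep(paste0("^# ", key, "="), meta, value = TRUE)
      if (!length(hit)) return(default)
      sub(paste0("^# ", key, "="), "", hit[1L])
    }
    fs <- as.numeric(get_meta("fs"))
    if (is.na(fs)) bv_parse_error(2L, "missing or invalid '# fs=' header")
    df <- read.csv(path, comment.char = "#", check.names = FALSE)
    mat <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(mat) <- "double"
    recording(mat, fs = fs,
              modality = get_meta("modality", modality),
              condition = get_meta("condition", condition),
              channel_names = as.character(df[[1L]]))
  } else {
    read_brainvision(path, modality = modality, condition = condition)
  }
}

read_brainvision <- function(vhdr_path, modality = "meg",
                             condition = "unspecified") {
  lines <- readLines(vhdr_path)
  section <- ""
  kv <- list()
  channels <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, ";")) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- ln
      next
    }
    if (i == 1L) next   # format banner
    if (!grepl("=", ln, fixed = TRUE)) {
      bv_parse_error(i, paste0("expected key=value, got '", ln, "'"))
    }
    key <- sub("=.*$", "", ln)
    val <- sub("^[^=]*=", "", ln)
    if (section == "[Channel Infos]") {
      channels <- c(channels, strsplit(val, ",", fixed = TRUE)[[1L]][1L])
    } else {
      kv[[paste0(section, key)]] <- val
    }
  }
  need <- function(key, line_hint) {
    v <- kv[[paste0("[Common Infos]", key)]]
    if (is.null(v)) bv_parse_error(line_hint, paste0("missing ", key))
    v
  }
  n_chan <- as.integer(need("NumberOfChannels", 1L))
  samp_int <- as.numeric(need("SamplingInterval", 1L))
  if (is.na(n_chan) || n_chan < 1L) bv_parse_error(1L, "bad NumberOfChannels")
  if (is.na(samp_int) || samp_int <= 0) {
    bv_parse_error(1L, "bad SamplingInterval")
  }
  if (length(channels) != n_chan) {
    bv_parse_error(1L, sprintf("found %d channel entries, expected %d",
                               length(channels), n_chan))
  }
  fmt <- toupper(need("DataFormat", 1L))
  orient <- toupper(need("DataOrientation", 1L))
  data_path <- file.path(dirname(vhdr_path), need("DataFile", 1L))
  if (!file.exists(data_path)) bv_parse_error(1L, "data file missing")
  if (fmt == "BINARY") {
    bfmt <- kv[["[Binary Infos]BinaryFormat"]]
    if (is.null(bfmt) || toupper(bfmt) != "IEEE_FLOAT_32") {
      bv_parse_error(1L, "only IEEE_FLOAT_32 binary data is supported")
    }
    if (orient != "MULTIPLEXED") {
      bv_parse_error(1L, "binary data must be MULTIPLEXED")
    }
    n_bytes <- file.info(data_path)$size
    if (n_bytes %% (4L * n_chan) != 0) {
      bv_parse_error(1L, sprintf(
        "binary data truncated: %d bytes is not a whole number of %d-channel frames",
        n_bytes, n_chan))
    }
    n_frames <- as.integer(n_bytes / (4L * n_chan))
    con <- file(data_path, "rb")
    on.exit(close(con))
    vals <- readBin(con, what = "numeric", n = n_chan * n_frames,
                    size = 4L, endian = "little")
    mat <- matrix(vals, n_chan, n_frames)
  } else if (fmt == "ASCII") {
    if (orient != "VECTORIZED") {
      bv_parse_error(1L, "ASCII data must be VECTORIZED")
    }
    dl <- readLines(data_path)
    if (length(dl) != n_chan) {
      bv_parse_error(1L, sprintf("ASCII data has %d lines, expected %d",
                                 length(dl), n_chan))
    }
    rows <- lapply(dl, function(l) as.numeric(strsplit(trimws(l),
                                                       "\\s+")[[1L]]))
    if (length(unique(lengths(rows))) != 1L) {
      bv_parse_error(1L, "ASCII data lines differ in length")
    }
    mat <- do.call(rbind, rows)
  } else {
    bv_parse_error(1L, paste0("unsupported DataFormat ", fmt))
  }
  rec <- recording(mat, fs = 1e6 / samp_int, modality = modality,
                   condition = condition, channel_names = channels)
  mrk_file <- kv[["[Common Infos]MarkerFile"]]
  if (!is.null(mrk_file)) {
    mrk_path <- file.path(dirname(vhdr_path), mrk_file)
    if (file.exists(mrk_path)) {
      ml <- grep("^Mk[0-9]+=Stimulus,", readLines(mrk_path), value = TRUE)
      if (length(ml)) {
        parts <- strsplit(sub("^Mk[0-9]+=", "", ml), ",", fixed = TRUE)
        attr(rec, "events") <- structure(
          data.frame(onset = as.integer(vapply(parts, `[`, "", 3L)),
                     type = vapply(parts, `[`, "", 2L),
                     std_pre_dev = NA),
          class = c("ms_events", "data.frame"))
      }
    }
  }
  rec
}

#' Write / read an event list as a two-column TSV
#'
#' Columns `sample` (0-based frame index) and `type`; an optional third
#' column `std_pre_dev` is preserved when present.
#'
#' @param events an `ms_events` data frame.
#' @param path TSV path.
#' @return `path` / the `ms_events` data frame (onsets 1-based in R).
#' @export
write_events <- function(events, path) {
  df <- data.frame(sample = events$onset - 1L,
                   type = as.character(events$type))
  if (!is.null(events$std_pre_dev)) df$std_pre_dev <- events$std_pre_dev
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path)
  out <- data.frame(onset = as.integer(df$sample) + 1L, type = df$type,
                    std_pre_dev = df$std_pre_dev %||% NA)
  structure(out, class = c("ms_events", "data.frame"))
}

#' Write / read microstate templates as CSV plus a JSON sidecar
#'
#' The CSV holds the channels x K template matrix (one column per
#' microstate); the sidecar (`<path>.json`) records mode, k and
#' provenance so the set round-trips losslessly.
#'
#' @param ms an [microstates()] set.
#' @param path CSV path.
#' @return `path` / the [microstates()] set.
#' @export
write_microstates <- function(ms, path) {
  stopifnot(inherits(ms, "ms_microstates"))
  m <- t(ms$maps)
  df <- data.frame(channel = colnames(ms$maps) %||%
                     sprintf("CH%03d", seq_len(nrow(m))), m,
                   check.names = FALSE)
  colnames(df) <- c("channel", sprintf("MS%d", seq_len(ms$k)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(mode = ms$mode, k = ms$k,
                            provenance = ms$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_microstates
#' @export
read_microstates <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.csv(path, check.names = FALSE)
  maps <- t(as.matrix(df[, -1L, drop = FALSE]))
  colnames(maps) <- as.character(df[[1L]])
  microstates(maps, mode = meta$mode, provenance = meta$provenance)
}

#' Write / read a segmentation as TSV plus a JSON header
#'
#' TSV columns: `frame` (0-based), `label`, `sim`, `gfp`; the JSON
#' header (`<path>.json`) stores `fs`, `k`, `threshold` and `mode`.
#' The dense per-frame similarity matrix is not serialized, so a
#' round-tripped segmentation supports metrics and statistics but not
#' further smoothing.
#'
#' @param seg an `ms_segmentation`.
#' @param path TSV path.
#' @return `path` / the `ms_segmentation`.
#' @export
write_segmentation <- function(seg, path) {
  stopifnot(inherits(seg, "ms_segmentation"))
  df <- data.frame(frame = seq_along(seg$labels) - 1L, label = seg$labels,
                   sim = seg$sims, gfp = seg$gfp)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs = seg$fs, k = seg$k, mode = seg$mode,
                            threshold = seg$threshold),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_segmentation
#' @export
read_segmentation <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.delim(path)
  structure(list(labels = as.integer(df$label), sims = df$sim,
                 all_sims = NULL, gfp = df$gfp, fs = meta$fs,
                 k = as.integer(meta$k), mode = meta$mode,
                 threshold = meta$threshold),
            class = "ms_segmentation")
}
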