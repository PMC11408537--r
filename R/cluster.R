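#' Construct a microstate template set
#'
#' @param maps `K x C` matrix of template topographies; rows are
#'   normalised to unit Euclidean norm (EEG maps are average-referenced
#'   first).
#' @param mode `"meg"` or `"eeg"`.
#' @param provenance `"individual"` or `"group"`.
#' @return class `ms_microstates`: list with `maps`, `mode`, `k`,
#'   `provenance`.
#' @export
microstates <- function(maps, mode = c("meg", "eeg"),
                        provenance = c("individual", "group")) {
  mode <- match.arg(mode); provenance <- match.arg(provenance)
  maps <- as.matrix(maps)
  maps <- normalize_rows(maps, mode)
  if (mode == "meg") {
    if (any(maps < -1e-12)) {
      stop_invalid("meg-mode templates must be nonnegative")
    }
    maps[maps < 0] <- 0   # numeric dust from normalisation
  }
  structure(list(maps = maps, mode = mode, k = nrow(maps),
                 provenance = provenance), class = "ms_microstates")
}

#' @export
print.ms_microstates <- function(x, ...) {
  cat(sprintf("<ms_microstates> k=%d, mode=%s, %s-level, %d channels\n",
              x$k, x$mode, x$provenance, ncol(x$maps)))
  invisible(x)
}

#' Locate peaks in a global field power series
#'
#' Returns the frames of strict local maxima (`g[t-1] < g[t] > g[t+1]`).
#' When two maxima fall closer than `min_separation_frames`, the larger
#' one is kept (ties resolved toward the earlier frame). Topographies at
#' these frames have the highest signal-to-noise ratio and are the input
#' to microstate clustering.
#'
#' @param g an `ms_gfp` from [gfp()], or a numeric vector.
#' @param min_separation_frames minimum frame gap between reported
#'   peaks; 0 disables the constraint.
#' @return integer vector of 1-based frame indices (possibly empty).
#' @examples
#' find_gfp_peaks(c(0, 1, 0, 2, 0))  # 2 and 4
#' @export
find_gfp_peaks <- function(g, min_separation_frames = 0L) {
  v <- if (inherits(g, "ms_gfp")) g$values else as.numeric(g)
  if (length(v) < 3L) stop_invalid("series must have at least 3 frames")
  core <- v[2:(length(v) - 1L)]
  is_pk <- core > v[1:(length(v) - 2L)] & core > v[3:length(v)]
  peaks <- which(is_pk) + 1L
  if (min_separation_frames > 0L && length(peaks) > 1L) {
    ord <- peaks[order(-v[peaks], peaks)]
    kept <- integer(0)
    for (p in ord) {
      if (!length(kept) || all(abs(kept - p) >= min_separation_frames)) {
        kept <- c(kept, p)
      }
    }
    peaks <- sort(kept)
  }
  peaks
}

#' Modified k-means clustering of GFP-peak topographies
#'
#' Polarity- and scale-aware k-means on unit-normalised topographies.
#' Each observation is assigned to the template with the highest
#' [spatial_similarity()]; templates are then updated per mode: in EEG
#' mode as the first principal eigenvector of the assigned maps' scatter
#' (polarity-invariant), in MEG mode as the normalised mean of the
#' assigned maps with negative entries clamped to zero. Iteration stops
#' when the relative change in explained variance falls below `tol`; the
#' best of `n_restarts` seeded restarts is returned.
#'
#' Explained variance is `1 - mean(d)` over assigned observations with
#' the mode dissimilarity `d` of [spatial_similarity()] squared semantics
#' (`1 - sim^2` in EEG mode, `1 - sim` in MEG mode); it is non-decreasing
#' over iterations within a restart.
#'
#' @param peak_maps `N x C` matrix of topographies (rows).
#' @param k number of clusters, `2 <= k` recommended, `k <= N` required.
#' @param mode `"meg"` or `"eeg"`.
#' @param n_restarts random restarts (default 100).
#' @param tol relative explained-variance convergence tolerance.
#' @param max_iter iteration cap per restart.
#' @param seed integer seed.
#' @return list with `microstates` (an [microstates()] set),
#'   `assignments` (length-N integer), `sims` (similarity of each map to
#'   its template) and `ev` (explained variance of the best restart).
#' @export
modified_kmeans <- function(peak_maps, k, mode = c("meg", "eeg"),
                            n_restarts = 100L, tol = 1e-6, max_iter = 100L,
                            seed = 1L) {
  mode <- match.arg(mode)
  X <- normalize_rows(as.matrix(peak_maps), mode)
  N <- nrow(X)
  if (k > N) stop_invalid("k must not exceed the number of maps")
  if (k < 1) stop_invalid("k must be >= 1")
  update_template <- function(Xc) {
    if (mode == "eeg") {
      sc <- crossprod(Xc)
      ev <- eigen(sc, symmetric = TRUE)
      v <- ev$vectors[, 1L]
      v <- v - mean(v)            # stay in the average-reference subspace
      v / sqrt(sum(v^2))
    } else {
      m <- colMeans(Xc)
      m[m < 0] <- 0
      nrm <- sqrt(sum(m^2))
      if (nrm < 1e-300) m else m / nrm
    }
  }
  run_once <- function(init_idx) {
    Tm <- X[init_idx, , drop = FALSE]
    ev_prev <- -Inf
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      S <- similarity_matrix(X, Tm, mode)
      assign <- max.col(S, ties.method = "first")
      sims <- S[cbind(seq_len(N), assign)]
      # re-seed empty clusters from the worst-fit map
      for (c in seq_len(k)) {
        if (!any(assign == c)) {
          worst <- which.min(sims)
          assign[worst] <- c
          sims[worst] <- 1
        }
      }
      ev <- 1 - mean(sim_to_dist(S[cbind(seq_len(N), assign)], mode))
      trace <- c(trace, ev)
      for (c in seq_len(k)) {
        Tm[c, ] <- update_template(X[assign == c, , drop = FALSE])
      }
      if (is.finite(ev_prev) &&
          abs(ev - ev_prev) <= tol * max(abs(ev_prev), 1e-12)) {
        break
      }
      ev_prev <- ev
    }
    S <- similarity_matrix(X, Tm, mode)
    assign <- max.col(S, ties.method = "first")
    ev <- 1 - mean(sim_to_dist(S[cbind(seq_len(N), assign)], mode))
    list(Tm = Tm, assign = assign, ev = ev, trace = trace,
         sims = S[cbind(seq_len(N), assign)])
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      res <- run_once(sample.int(N, k))
      if (is.null(best) || res$ev > best$ev) best <- res
    }
    list(microstates = microstates(best$Tm, mode,
                                   provenance = "individual"),
         assignments = best$assign, sims = best$sims, ev = best$ev,
         ev_trace = best$trace)
  })
}
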