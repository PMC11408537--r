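#' Default pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with its
#' conventional default: 250 Hz target rate with a 1-30 Hz band and a
#' 50 Hz notch; 2-s artifact epochs; k-means over k = 2..12 selected by
#' the meta-criterion; back-fitting with the 0.50 similarity floor and
#' Besag smoothing (half-window 3 frames, factor 10); 1000 permutations
#' with |z| >= 3.6 for the parcel test and 10000 permutations with mean
#' z > 3 for the co-occurrence test; Bonferroni per-test levels stored
#' as exact fractions (0.05/6 for the six coverage contrasts, 0.05/204
#' for the 34-parcel x 6-state grid). Synthetic-data settings default to
#' the study-like conditions (six states, 50-150 ms dwell, 10 Hz
#' envelope, 612 standard + 55 deviant stimuli, deviance window
#' 150-300 ms).
#'
#' @param ... named overrides; nested lists are merged recursively, e.g.
#'   `ms_config(fit = list(threshold = 0.6))`.
#' @return a nested named list of class `ms_config`.
#' @examples
#' cfg <- ms_config()
#' cfg$stats$alpha_per_state      # 0.05 / 6
#' @export
ms_config <- function(...) {
  defaults <- list(
    preprocess = list(notch = 50, hp = 1, lp = 30, target_fs = 250,
                      epoch_s = 2, z_thresh = 20),
    cluster = list(k_grid = 2:12, k_select = "meta", n_restarts = 20L,
                   tol = 1e-6, min_peak_separation = 0L),
    fit = list(threshold = 0.50, half_window_b = 3L, besag_lambda = 10),
    stats = list(n_perm_parcel = 1000L, n_perm_cooc = 10000L,
                 z_crit_parcel = 3.6, z_crit_cooc = 3, alpha = 0.05,
                 n_states = 6L, n_parcels = 34L,
                 alpha_per_state = 0.05 / 6,
                 alpha_per_parcel = 0.05 / (34 * 6),
                 fdr_q = 0.05,
                 mmn_window_ms = c(150, 300), mmn_baseline_ms = 200,
                 epoch_ms = c(-200, 500), alpha_band = c(8, 12)),
    synth = list(n_subjects = 5L, K = 6L, n_channels = 64L,
                 duration_s = 240, fs = 250, dwell_ms_range = c(50, 150),
                 snr = 10, envelope_hz = 10, n_std = 612L, n_dev = 55L,
                 isi_ms = 600, boost_prob = 1, coupling = 1,
                 n_parcels = 34L),
    seed = 1L)
  overrides <- list(...)
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_rec(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  structure(merge_rec(defaults, overrides), class = "ms_config")
}

#' @export
print.ms_config <- function(x, ...) {
  cat("<ms_config>\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Optimally match two microstate map sets
#'
#' Finds the one-to-one assignment between the rows of two map matrices
#' that maximises the mean [spatial_similarity()] (exhaustive over
#' permutations up to K = 8, greedy beyond), e.g. to compare recovered
#' templates against ground truth.
#'
#' @param maps_a,maps_b `K x C` map matrices (equal K).
#' @param mode `"meg"` or `"eeg"`.
#' @return list with `perm` (index into rows of `maps_b` matched to each
#'   row of `maps_a`), `sims` (per-pair similarities) and `mean_sim`.
#' @export
match_maps <- function(maps_a, maps_b, mode = c("meg", "eeg")) {
  mode <- match.arg(mode)
  if (inherits(maps_a, "ms_microstates")) maps_a <- maps_a$maps
  if (inherits(maps_b, "ms_microstates")) maps_b <- maps_b$maps
  K <- nrow(maps_a)
  if (nrow(maps_b) != K) stop_invalid("map sets differ in K")
  S <- similarity_matrix(maps_a, maps_b, mode)
  if (K <= 8L) {
    perms <- permutations_of(K)
    scores <- vapply(perms, function(p) mean(S[cbind(seq_len(K), p)]),
                     numeric(1L))
    best <- perms[[which.max(scores)]]
  } else {
    best <- integer(K)
    avail <- seq_len(K)
    for (i in order(-apply(S, 1L, max))) {
      j <- avail[which.max(S[i, avail])]
      best[i] <- j
      avail <- setdiff(avail, j)
    }
  }
  sims <- S[cbind(seq_len(K), best)]
  list(perm = best, sims = sims, mean_sim = mean(sims))
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[idx]] <- append(p, n, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}
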