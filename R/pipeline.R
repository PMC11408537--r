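#' Run the resting-state + oddball experiment end to end on synthetic data
#'
#' Orchestrates the first experiment workflow: a shared ground-truth map
#' set drives per-subject eyes-open (ROE), eyes-closed (RCE) and oddball
#' (MMN) recordings; microstates are identified on the spatially
#' filtered ROE data with two-level clustering; the group templates are
#' back-fitted (with smoothing) to every condition; and the statistics
#' follow: per-state coverage contrasts ROE vs RCE (Bonferroni 0.05/6),
#' the occipital alpha-change index with Kendall tau-b correlations
#' against coverage changes, the parcel-by-state permutation test, and
#' the event-locked detection-rate / mMS-MMN statistics.
#'
#' Condition-dependent prevalence is built in: RCE doubles the weight of
#' states 1-2 (emulating posterior-state enhancement with eyes closed)
#' and the deviant perturbation boosts `deviant_state` in the 150-300 ms
#' window.
#'
#' @param config an [ms_config()]; `config$synth` sets the scale
#'   (subjects, duration, channels, snr), `config$seed` all randomness.
#' @param conditions subset of `c("ROE", "RCE", "MMN")` to simulate;
#'   contrasts and alpha statistics are skipped (with a flag) when RCE
#'   is absent, evoked statistics when MMN is absent.
#' @return a results bundle (list) with elements `group`
#'   (identification), `recovery` (match against ground truth),
#'   `metrics` (per subject x condition), `coverage` (subject x state
#'   per condition), `contrast_roe_rce`, `alpha` (indices + tau),
#'   `parcels` (permutation grid, subject 1), `evoked` (curves +
#'   mMS-MMN), `skipped` (character), `config`, `seed`.
#' @export
run_experiment1 <- function(config = ms_config(),
                            conditions = c("ROE", "RCE", "MMN")) {
  sy <- config$synth
  seed <- config$seed
  lay <- make_layout(sy$n_channels, seed = child_seed(seed, 1L))
  maps <- make_topographies(sy$K, lay, "meg", seed = child_seed(seed, 2L))
  skipped <- character(0)
  n_sub <- sy$n_subjects
  w_roe <- rep(1, sy$K)
  w_rce <- w_roe
  w_rce[seq_len(min(2L, sy$K))] <- 2            # posterior states up, eyes closed
  sims_roe <- vector("list", n_sub)
  recs <- list(ROE = list(), RCE = list(), MMN = list())
  events <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    base <- child_seed(seed, 100L + s)
    sims_roe[[s]] <- simulate_resting(
      lay, maps, duration_s = sy$duration_s, fs = sy$fs,
      dwell_ms_range = sy$dwell_ms_range, snr = sy$snr,
      envelope_hz = sy$envelope_hz, coverage_weights = w_roe,
      condition = "ROE", seed = base)
    recs$ROE[[s]] <- spatial_filter(sims_roe[[s]]$recording, lay)
    if ("RCE" %in% conditions) {
      rce <- simulate_resting(
        lay, maps, duration_s = sy$duration_s, fs = sy$fs,
        dwell_ms_range = sy$dwell_ms_range, snr = sy$snr,
        envelope_hz = sy$envelope_hz, coverage_weights = w_rce,
        condition = "RCE", seed = child_seed(base, 1L))
      recs$RCE[[s]] <- spatial_filter(rce$recording, lay)
    }
    if ("MMN" %in% conditions) {
      ev <- simulate_evoked(
        lay, maps, n_std = sy$n_std, n_dev = sy$n_dev, isi_ms = sy$isi_ms,
        deviant_state = sy$K, boost_window_ms = config$stats$mmn_window_ms,
        boost_prob = sy$boost_prob, fs = sy$fs,
        dwell_ms_range = sy$dwell_ms_range, snr = sy$snr,
        envelope_hz = sy$envelope_hz, seed = child_seed(base, 2L))
      recs$MMN[[s]] <- spatial_filter(ev$recording, lay)
      events[[s]] <- ev$events
    }
  }
  cl <- config$cluster
  ident <- two_level_clustering(recs$ROE, k_grid = cl$k_grid,
                                k_select = cl$k_select,
                                n_restarts = cl$n_restarts, tol = cl$tol,
                                min_peak_separation = cl$min_peak_separation,
                                seed = child_seed(seed, 3L))
  group_ms <- ident$group$microstates
  # identification sees spatially filtered data, so recovery is judged
  # against the equally filtered ground-truth maps
  maps_f <- t(spatial_filter(recording(t(maps), fs = sy$fs,
                                       modality = "meg",
                                       channel_names = lay$channel_names),
                             lay)$data)
  recovery <- if (group_ms$k == sy$K) {
    match_maps(maps_f, group_ms, mode = "meg")
  } else NULL
  ft <- config$fit
  seg_of <- function(rec) {
    smooth_labels(backfit(rec, group_ms, threshold = ft$threshold),
                  half_window_b = ft$half_window_b,
                  besag_lambda = ft$besag_lambda)
  }
  metrics <- list()
  coverage <- list()
  segs <- list()
  for (cond in intersect(conditions, names(recs))) {
    if (!length(recs[[cond]])) next
    segs[[cond]] <- lapply(recs[[cond]], seg_of)
    metrics[[cond]] <- lapply(segs[[cond]], temporal_metrics)
    coverage[[cond]] <- do.call(rbind, lapply(metrics[[cond]],
                                              `[[`, "coverage"))
  }
  contrast <- NULL
  alpha <- NULL
  if (!is.null(coverage$RCE)) {
    contrast <- coverage_contrast(coverage$ROE, coverage$RCE,
                                  alpha = config$stats$alpha)
    occ <- utils::tail(lay$channel_names, max(4L, sy$n_channels %/% 8L))
    idx <- vapply(seq_len(n_sub), function(s) {
      as.numeric(alpha_change_index(recs$ROE[[s]], recs$RCE[[s]], occ,
                                    band = config$stats$alpha_band))
    }, numeric(1L))
    taus <- if (n_sub >= 3L) {
      lapply(seq_len(group_ms$k), function(m) {
        d_cov <- coverage$ROE[, m] - coverage$RCE[, m]
        if (sd(d_cov) == 0 || sd(idx) == 0) return(NULL)
        kendall_tau_b(d_cov, idx)
      })
    } else NULL
    alpha <- list(index = idx, tau = taus, occipital = occ)
  } else {
    skipped <- c(skipped, "contrast_roe_rce", "alpha")
  }
  parcels <- NULL
  if (length(segs$ROE)) {
    ps <- simulate_parcels(list(labels = segs$ROE[[1L]]$labels),
                           n_parcels = config$stats$n_parcels,
                           fs = sy$fs, seed = child_seed(seed, 4L))
    parcels <- parcel_permutation_test(
      ps, segs$ROE[[1L]], n_perm = config$stats$n_perm_parcel,
      z_crit = config$stats$z_crit_parcel, seed = child_seed(seed, 5L))
  }
  evoked <- NULL
  if (!is.null(segs$MMN)) {
    evoked <- lapply(seq_len(n_sub), function(s) {
      curves <- detection_rate_curve(segs$MMN[[s]], events[[s]],
                                     epoch_ms = config$stats$epoch_ms)
      list(curves = curves,
           mms_mmn = mms_mmn(curves$standard, curves$deviant,
                             window = config$stats$mmn_window_ms))
    })
  } else {
    skipped <- c(skipped, "evoked")
  }
  list(group = ident, recovery = recovery, metrics = metrics,
       coverage = coverage, contrast_roe_rce = contrast, alpha = alpha,
       parcels = parcels, evoked = evoked, skipped = skipped,
       truth = list(maps = maps, layout = lay), config = config,
       seed = seed)
}

#' Run the simultaneous EEG-MEG experiment end to end on synthetic data
#'
#' Orchestrates the second experiment workflow: per subject, paired
#' MEG/EEG recordings with run-wise label coupling are simulated;
#' microstates are identified per modality with two-level clustering;
#' the group sets are back-fitted to every subject; and the cross-modal
#' statistics follow: the per-subject co-occurrence permutation test
#' with the group mean-z > 3 association rule, and the cross-subject
#' Pearson correlation of per-state GEV with Benjamini-Hochberg FDR.
#'
#' @param config an [ms_config()]; `config$synth$coupling` sets the
#'   label coupling (1 = shared sequences, 0 = independent).
#' @return a results bundle (list) with `ident_meg`, `ident_eeg`,
#'   `cooc` (per-subject `ms_cooc`), `group_assoc`
#'   ([cooccurrence_group()] result), `gev_meg`, `gev_eeg` (subject x
#'   state), `gev_cor` ([gev_correlation()] result, `NULL` for < 4
#'   subjects), `config`, `seed`.
#' @export
run_experiment2 <- function(config = ms_config()) {
  sy <- config$synth
  seed <- config$seed
  lay <- make_layout(sy$n_channels, seed = child_seed(seed, 1L))
  n_sub <- sy$n_subjects
  pairs <- lapply(seq_len(n_sub), function(s) {
    simulate_paired_modalities(lay, K = sy$K, duration_s = sy$duration_s,
                               fs = sy$fs,
                               dwell_ms_range = sy$dwell_ms_range,
                               snr = sy$snr, envelope_hz = sy$envelope_hz,
                               coupling = sy$coupling,
                               seed = child_seed(seed, 200L + s))
  })
  cl <- config$cluster
  ident_meg <- two_level_clustering(
    lapply(pairs, function(p) spatial_filter(p$meg, lay)),
    k_grid = cl$k_grid, k_select = cl$k_select,
    n_restarts = cl$n_restarts, tol = cl$tol,
    min_peak_separation = cl$min_peak_separation,
    seed = child_seed(seed, 3L))
  ident_eeg <- two_level_clustering(
    lapply(pairs, function(p) p$eeg),
    k_grid = cl$k_grid, k_select = cl$k_select,
    n_restarts = cl$n_restarts, tol = cl$tol,
    min_peak_separation = cl$min_peak_separation,
    seed = child_seed(seed, 4L))
  ft <- config$fit
  fitseg <- function(rec, ms) {
    smooth_labels(backfit(rec, ms, threshold = ft$threshold),
                  half_window_b = ft$half_window_b,
                  besag_lambda = ft$besag_lambda)
  }
  cooc <- vector("list", n_sub)
  gev_meg <- matrix(0, n_sub, ident_meg$group$microstates$k)
  gev_eeg <- matrix(0, n_sub, ident_eeg$group$microstates$k)
  for (s in seq_len(n_sub)) {
    seg_m <- fitseg(spatial_filter(pairs[[s]]$meg, lay),
                    ident_meg$group$microstates)
    seg_e <- fitseg(pairs[[s]]$eeg, ident_eeg$group$microstates)
    cooc[[s]] <- cooccurrence_permutation(
      seg_m, seg_e, n_perm = config$stats$n_perm_cooc,
      seed = child_seed(seed, 300L + s))
    gev_meg[s, ] <- temporal_metrics(seg_m)$gev
    gev_eeg[s, ] <- temporal_metrics(seg_e)$gev
  }
  group_assoc <- cooccurrence_group(cooc,
                                    z_crit = config$stats$z_crit_cooc)
  gev_cor <- if (n_sub >= 4L) {
    gev_correlation(gev_meg, gev_eeg, q_crit = config$stats$fdr_q)
  } else NULL
  list(ident_meg = ident_meg, ident_eeg = ident_eeg, cooc = cooc,
       group_assoc = group_assoc, gev_meg = gev_meg, gev_eeg = gev_eeg,
       gev_cor = gev_cor, config = config, seed = seed)
}
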