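#' Cluster topographies over a grid of k and select k by the meta-criterion
#'
#' Runs [modified_kmeans()] for every entry of `k_grid`, evaluates the
#' validity-criterion curves with [compute_criteria()], and selects the
#' number of microstates with [meta_criterion()] (or uses a fixed `k`
#' when `k_select` is an integer).
#'
#' @param peak_maps `N x C` matrix of GFP-peak topographies.
#' @param mode `"meg"` or `"eeg"`.
#' @param k_grid candidate cluster counts (default `2:12`).
#' @param k_select `"meta"` to use the meta-criterion, or a fixed integer.
#' @param n_restarts,tol,max_iter passed to [modified_kmeans()].
#' @param seed integer seed.
#' @param provenance `"individual"` or `"group"` tag for the result.
#' @return list with `microstates` (selected set), `k_opt`, `ev`,
#'   `criteria` (an `ms_criteria`, `NULL` when `k_select` is fixed),
#'   `candidates`, and `fits` (the per-k [modified_kmeans()] results).
#' @export
select_microstates <- function(peak_maps, mode = c("meg", "eeg"),
                               k_grid = 2:12, k_select = "meta",
                               n_restarts = 20L, tol = 1e-6,
                               max_iter = 100L, seed = 1L,
                               provenance = "individual") {
  mode <- match.arg(mode)
  N <- nrow(peak_maps)
  k_grid <- k_grid[k_grid <= max(2L, N - 1L)]
  if (!length(k_grid)) stop_invalid("k_grid empty after bounding by N-1")
  if (is.numeric(k_select)) {
    k <- as.integer(k_select)
    fit <- modified_kmeans(peak_maps, k, mode, n_restarts = n_restarts,
                           tol = tol, max_iter = max_iter, seed = seed)
    fit$microstates$provenance <- provenance
    return(list(microstates = fit$microstates, k_opt = k, ev = fit$ev,
                criteria = NULL, candidates = NULL, fits = setNames(
                  list(fit), k)))
  }
  fits <- lapply(seq_along(k_grid), function(i) {
    modified_kmeans(peak_maps, k_grid[i], mode, n_restarts = n_restarts,
                    tol = tol, max_iter = max_iter,
                    seed = child_seed(seed, i))
  })
  crit <- compute_criteria(peak_maps, lapply(fits, `[[`, "assignments"),
                           k_grid, mode, seed = child_seed(seed, 999L))
  sel <- meta_criterion(crit)
  best <- fits[[match(sel$k_opt, k_grid)]]
  best$microstates$provenance <- provenance
  list(microstates = best$microstates, k_opt = sel$k_opt, ev = best$ev,
       criteria = crit, candidates = sel$candidates,
       fits = setNames(fits, k_grid))
}

#' Two-level (individual then group) microstate identification
#'
#' The standard group-level identification scheme: each subject's
#' recording is reduced to topographies at its GFP peaks and clustered
#' individually (with a subject-level meta-criterion choice of k); the
#' resulting individual template maps from all subjects are pooled and
#' clustered again at the group level (with a group-level meta-criterion
#' choice of k). The group templates are the microstate set used for
#' back-fitting.
#'
#' @param recordings list of [recording()] objects sharing modality and
#'   channels.
#' @param k_grid candidate cluster counts.
#' @param k_select `"meta"` or a fixed integer, applied at both levels.
#' @param n_restarts,tol restarts and tolerance for [modified_kmeans()].
#' @param min_peak_separation frame gap for [find_gfp_peaks()].
#' @param seed integer seed.
#' @return list with `group` (the group-level [select_microstates()]
#'   result, `provenance = "group"`) and `individual` (per-subject
#'   results).
#' @export
two_level_clustering <- function(recordings, k_grid = 2:12,
                                 k_select = "meta", n_restarts = 20L,
                                 tol = 1e-6, min_peak_separation = 0L,
                                 seed = 1L) {
  if (!length(recordings)) stop_invalid("need at least one recording")
  mode <- recordings[[1L]]$modality
  individual <- vector("list", length(recordings))
  for (s in seq_along(recordings)) {
    rec <- recordings[[s]]
    if (rec$modality != mode) stop_invalid("recordings mix modalities")
    res <- tryCatch({
      pk <- find_gfp_peaks(gfp(rec), min_peak_separation)
      if (length(pk) < max(3L, min(k_grid) + 1L)) {
        stop_invalid("too few GFP peaks for clustering")
      }
      select_microstates(t(rec$data[, pk, drop = FALSE]), mode,
                         k_grid = k_grid, k_select = k_select,
                         n_restarts = n_restarts, tol = tol,
                         seed = child_seed(seed, s))
    }, error = function(e) {
      stop("subject ", s, ": ", conditionMessage(e), call. = FALSE)
    })
    individual[[s]] <- res
  }
  if (length(individual) == 1L) {
    # degenerate pipeline: the pooled set is one subject's templates, so
    # the group result is that subject's result
    group <- individual[[1L]]
    group$microstates$provenance <- "group"
    return(list(group = group, individual = individual))
  }
  pooled <- do.call(rbind, lapply(individual, function(r) r$microstates$maps))
  group <- select_microstates(pooled, mode, k_grid = k_grid,
                              k_select = k_select, n_restarts = n_restarts,
                              tol = tol, seed = child_seed(seed, 100000L),
                              provenance = "group")
  list(group = group, individual = individual)
}
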