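# Pairwise-distance based cluster-validity indices. All indices are
# stored so that larger is better (Davies-Bouldin is negated); NaN marks
# a degenerate configuration (e.g. singleton-only clusters, zero Dunn
# denominator).

# Goodman-Kruskal Gamma over (within, between) distance pairs, exact on
# the supplied sets via sorting.
gamma_index <- function(dw, db) {
  if (!length(dw) || !length(db)) return(NaN)
  sb <- sort(db)
  n_gt <- length(sb) - findInterval(dw, sb)        # b > w  (concordant)
  n_lt <- findInterval(dw, sb, left.open = TRUE)   # b < w  (discordant)
  splus <- sum(as.numeric(n_gt))
  sminus <- sum(as.numeric(n_lt))
  if (splus + sminus == 0) return(NaN)
  (splus - sminus) / (splus + sminus)
}

# All six indices for one assignment, from the full distance matrix D and
# a seeded pair subsample (idx_i, idx_j) for Gamma / point-biserial.
criteria_for_assignment <- function(D, assign, pair_i, pair_j) {
  k <- max(assign)
  n <- length(assign)
  counts <- tabulate(assign, k)
  if (all(counts <= 1L)) {
    return(list(gamma = NaN, silhouette = NaN, davies_bouldin = NaN,
                point_biserial = NaN, dunn = NaN, W = NaN))
  }
  ind <- matrix(0, n, k)
  ind[cbind(seq_len(n), assign)] <- 1
  sums <- D %*% ind                                # n x k: sum d to cluster
  # silhouette
  a <- sums[cbind(seq_len(n), assign)] / pmax(counts[assign] - 1L, 1L)
  means_other <- sweep(sums, 2L, pmax(counts, 1L), "/")
  means_other[cbind(seq_len(n), assign)] <- Inf
  b <- apply(means_other, 1L, min)
  sil_ok <- counts[assign] > 1L
  sil <- if (any(sil_ok)) {
    mean(((b - a) / pmax(a, b))[sil_ok])
  } else NaN
  # per-cluster scatter and between-cluster mean distances
  Wc <- numeric(k); Sc <- numeric(k)
  for (c in seq_len(k)) {
    wsum <- sum(sums[assign == c, c])
    Wc[c] <- wsum / 2                               # sum of within pairs
    Sc[c] <- if (counts[c] > 1L) wsum / (counts[c] * (counts[c] - 1L)) else NaN
  }
  M <- crossprod(ind, sums)                         # k x k: summed cross d
  nm <- outer(counts, counts)
  Mbar <- M / nm                                    # mean between distance
  db_terms <- vapply(seq_len(k), function(c) {
    r <- (Sc[c] + Sc[-c]) / Mbar[c, -c]
    if (all(is.na(r))) NaN else max(r, na.rm = TRUE)
  }, numeric(1L))
  dbi <- if (all(is.na(db_terms))) NaN else -mean(db_terms, na.rm = TRUE)
  # Dunn from the full matrix
  same <- assign[row(D)] == assign[col(D)]
  diag_mask <- row(D) == col(D)
  max_diam <- suppressWarnings(max(D[same & !diag_mask]))
  min_between <- suppressWarnings(min(D[!same]))
  dunn <- if (!is.finite(max_diam) || max_diam <= 0 ||
              !is.finite(min_between)) NaN else min_between / max_diam
  # Gamma + point-biserial on the pair subsample
  dsub <- D[cbind(pair_i, pair_j)]
  within <- assign[pair_i] == assign[pair_j]
  g <- gamma_index(dsub[within], dsub[!within])
  pb <- if (length(unique(within)) < 2L || sd(dsub) == 0) NaN else
    suppressWarnings(cor(dsub, as.numeric(!within)))
  # Ward-style within dispersion for Krzanowski-Lai
  W <- sum(Wc / pmax(counts, 1L))
  list(gamma = g, silhouette = sil, davies_bouldin = dbi,
       point_biserial = pb, dunn = dunn, W = W)
}

#' Cluster-validity criterion curves over a grid of cluster counts
#'
#' Evaluates six validity indices (Gamma, silhouette, Davies-Bouldin,
#' point-biserial, Dunn, Krzanowski-Lai) for a family of clusterings of
#' the same topographies, one assignment per entry of `k_grid`. The
#' dissimilarity is the mode-specific `1 - sim^2` (EEG) or `1 - sim`
#' (MEG). All curves are oriented so that larger is better
#' (Davies-Bouldin is stored negated); degenerate configurations yield
#' `NaN`. Krzanowski-Lai needs both neighbours on the grid, so its first
#' and last entries are `NaN` by construction.
#'
#' For tractability the index evaluation subsamples at most `max_points`
#' maps (the full distance matrix is quadratic) and at most `max_pairs`
#' distance pairs for Gamma and point-biserial, both seeded.
#'
#' @param peak_maps `N x C` topography matrix.
#' @param assignments list of integer assignment vectors, parallel to
#'   `k_grid`, each of length `N` with values in `1..k`.
#' @param k_grid integer vector of evaluated cluster counts.
#' @param mode `"meg"` or `"eeg"`.
#' @param max_points,max_pairs subsampling caps.
#' @param seed integer seed for the subsamples.
#' @return class `ms_criteria`: list with `k_grid`, `curves` (6 x
#'   length(k_grid) matrix, rows named by criterion), `W` (within
#'   dispersions) and `mode`.
#' @export
compute_criteria <- function(peak_maps, assignments, k_grid,
                             mode = c("meg", "eeg"), max_points = 2000L,
                             max_pairs = 50000L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(assignments) == length(k_grid))
  X <- normalize_rows(as.matrix(peak_maps), mode)
  N <- nrow(X)
  with_seed(seed, {
    keep <- if (N > max_points) sort(sample.int(N, max_points)) else seq_len(N)
    Xs <- X[keep, , drop = FALSE]
    n <- nrow(Xs)
    S <- similarity_matrix(Xs, Xs, mode)
    D <- sim_to_dist(S, mode)
    diag(D) <- 0
    n_pairs <- n * (n - 1) / 2
    if (n_pairs > max_pairs) {
      pi_ <- sample.int(n, max_pairs, replace = TRUE)
      pj_ <- sample.int(n - 1L, max_pairs, replace = TRUE)
      pj_ <- ifelse(pj_ >= pi_, pj_ + 1L, pj_)
    } else {
      cmb <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      pi_ <- cmb[, 1L]; pj_ <- cmb[, 2L]
    }
    crit_names <- c("gamma", "silhouette", "davies_bouldin",
                    "point_biserial", "dunn", "krzanowski_lai")
    curves <- matrix(NaN, 6L, length(k_grid),
                     dimnames = list(crit_names, k_grid))
    Wk <- rep(NaN, length(k_grid))
    for (i in seq_along(k_grid)) {
      res <- criteria_for_assignment(D, assignments[[i]][keep], pi_, pj_)
      curves["gamma", i] <- res$gamma
      curves["silhouette", i] <- res$silhouette
      curves["davies_bouldin", i] <- res$davies_bouldin
      curves["point_biserial", i] <- res$point_biserial
      curves["dunn", i] <- res$dunn
      Wk[i] <- res$W
    }
    # Krzanowski-Lai: DIFF(k) = (k-1)^(2/C) W(k-1) - k^(2/C) W(k)
    C <- ncol(X)
    diff_k <- rep(NaN, length(k_grid))
    for (i in seq_along(k_grid)[-1L]) {
      diff_k[i] <- (k_grid[i - 1L])^(2 / C) * Wk[i - 1L] -
        (k_grid[i])^(2 / C) * Wk[i]
    }
    for (i in seq_along(k_grid)) {
      if (i > 1L && i < length(k_grid) && is.finite(diff_k[i]) &&
          is.finite(diff_k[i + 1L]) && abs(diff_k[i + 1L]) > 0) {
        curves["krzanowski_lai", i] <- abs(diff_k[i]) / abs(diff_k[i + 1L])
      }
    }
    structure(list(k_grid = k_grid, curves = curves, W = Wk, mode = mode),
              class = "ms_criteria")
  })
}

#' @export
print.ms_criteria <- function(x, ...) {
  cat(sprintf("<ms_criteria> k in {%s}\n", paste(x$k_grid, collapse = ", ")))
  print(round(x$curves, 3))
  invisible(x)
}

# Min-max normalise one curve to [0, 1], ignoring NaN.
minmax01 <- function(v) {
  ok <- is.finite(v)
  if (!any(ok)) return(v)
  rng <- range(v[ok])
  if (diff(rng) == 0) {
    v[ok] <- 0.5
    return(v)
  }
  (v - rng[1L]) / diff(rng)
}

#' Meta-criterion: consensus choice of the number of microstates
#'
#' Each validity curve is min-max normalised to `[0, 1]`; the median
#' curve is the elementwise median of the normalised curves. The
#' candidate set collects the arg-max of every individual curve plus the
#' arg-max of the median curve; the selected `k` is the median of these
#' candidates (for an even candidate count the lower middle value is
#' taken, keeping the result on the grid). The selection is invariant to
#' affine rescaling of any single criterion curve.
#'
#' @param crit an `ms_criteria` from [compute_criteria()].
#' @return list with `k_opt` (selected integer), `candidates` (arg-max
#'   per criterion and of the median curve) and `median_curve`.
#' @export
meta_criterion <- function(crit) {
  stopifnot(inherits(crit, "ms_criteria"))
  curves <- crit$curves
  valid <- rowSums(is.finite(curves)) > 0
  if (sum(valid) < 2L) {
    stop(structure(class = c("megstates_selection_failure", "error",
                             "condition"),
                   list(message = "fewer than 2 valid criterion curves",
                        call = NULL)))
  }
  normed <- curves
  for (i in seq_len(nrow(curves))) normed[i, ] <- minmax01(curves[i, ])
  med_curve <- apply(normed, 2L, function(col) {
    if (all(!is.finite(col))) NaN else median(col[is.finite(col)])
  })
  argmax_k <- function(v) {
    if (all(!is.finite(v))) return(NA_integer_)
    crit$k_grid[which.max(replace(v, !is.finite(v), -Inf))]
  }
  cands <- c(vapply(seq_len(nrow(normed)), function(i) argmax_k(normed[i, ]),
                    integer(1L)),
             argmax_k(med_curve))
  names(cands) <- c(rownames(curves), "median")
  cc <- sort(cands[!is.na(cands)])
  if (!length(cc)) {
    stop(structure(class = c("megstates_selection_failure", "error",
                             "condition"),
                   list(message = "no criterion produced a candidate k",
                        call = NULL)))
  }
  # median with lower-middle tie-break: stays an element of the grid
  k_opt <- if (length(cc) %% 2L == 1L) {
    cc[(length(cc) + 1L) %/% 2L]
  } else {
    cc[length(cc) %/% 2L]
  }
  list(k_opt = as.integer(k_opt), candidates = cands,
       median_curve = med_curve)
}
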