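#' EEG-MEG microstate co-occurrence counts
#'
#' Counts, over the shared frames of two simultaneous segmentations, how
#' often each EEG state is labeled while each MEG state is labeled:
#' `grid[m, e]` is the number of frames with MEG label `m` and EEG label
#' `e`. Index 0 rows/columns hold unlabeled frames, so the grid total
#' equals the frame count exactly.
#'
#' @param seg_meg,seg_eeg `ms_segmentation`s with equal frame counts
#'   (and sampling rates).
#' @return integer matrix `(K_meg + 1) x (K_eeg + 1)` with dimnames
#'   `0:K`.
#' @export
cooccurrence_counts <- function(seg_meg, seg_eeg) {
  lm <- if (inherits(seg_meg, "ms_segmentation")) seg_meg$labels else
    as.integer(seg_meg)
  le <- if (inherits(seg_eeg, "ms_segmentation")) seg_eeg$labels else
    as.integer(seg_eeg)
  if (length(lm) != length(le)) {
    stop_invalid("segmentations differ in frame count")
  }
  km <- if (inherits(seg_meg, "ms_segmentation")) seg_meg$k else max(lm)
  ke <- if (inherits(seg_eeg, "ms_segmentation")) seg_eeg$k else max(le)
  idx <- lm * (ke + 1L) + le + 1L
  counts <- tabulate(idx, (km + 1L) * (ke + 1L))
  matrix(counts, km + 1L, ke + 1L, byrow = TRUE,
         dimnames = list(meg = 0:km, eeg = 0:ke))
}

#' Permutation test of EEG-MEG microstate co-occurrence
#'
#' Contrasts the observed co-occurrence grid against a null in which the
#' MEG segmentation is shuffled segment-preservingly
#' ([segment_shuffle()]; the EEG segmentation is held fixed), yielding a
#' z-score per cell. At the group level the per-subject z grids are
#' averaged and a mean z above 3 declares an association between an MEG
#' and an EEG microstate; unlabeled rows/columns participate in the
#' counting but not in the association decision.
#'
#' @inheritParams cooccurrence_counts
#' @param n_perm number of MEG-segmentation shuffles (default 10000).
#' @param seed integer seed.
#' @return class `ms_cooc`: list with `counts`, `z`, `null_mean`,
#'   `null_sd`, `defined` (FALSE where `null_sd` is 0), `n_perm`,
#'   `seed`.
#' @export
cooccurrence_permutation <- function(seg_meg, seg_eeg, n_perm = 10000L,
                                     seed = 1L) {
  lm <- if (inherits(seg_meg, "ms_segmentation")) seg_meg$labels else
    as.integer(seg_meg)
  le <- if (inherits(seg_eeg, "ms_segmentation")) seg_eeg$labels else
    as.integer(seg_eeg)
  obs <- cooccurrence_counts(seg_meg, seg_eeg)
  km <- nrow(obs) - 1L; ke <- ncol(obs) - 1L
  ncell <- (km + 1L) * (ke + 1L)
  with_seed(seed, {
    s1 <- matrix(0, km + 1L, ke + 1L)
    s2 <- matrix(0, km + 1L, ke + 1L)
    for (i in seq_len(n_perm)) {
      pl <- segment_shuffle(lm)
      idx <- pl * (ke + 1L) + le + 1L
      g <- matrix(tabulate(idx, ncell), km + 1L, ke + 1L, byrow = TRUE)
      s1 <- s1 + g
      s2 <- s2 + g^2
    }
    null_mean <- s1 / n_perm
    null_sd <- sqrt(pmax(s2 / n_perm - null_mean^2, 0) * n_perm /
                      (n_perm - 1))
    defined <- null_sd > 0
    z <- matrix(NA_real_, km + 1L, ke + 1L, dimnames = dimnames(obs))
    z[defined] <- (obs[defined] - null_mean[defined]) / null_sd[defined]
    dimnames(null_mean) <- dimnames(null_sd) <- dimnames(defined) <-
      dimnames(obs)
    structure(list(counts = obs, z = z, null_mean = null_mean,
                   null_sd = null_sd, defined = defined,
                   n_perm = as.integer(n_perm), seed = as.integer(seed)),
              class = "ms_cooc")
  })
}

#' @export
print.ms_cooc <- function(x, ...) {
  cat(sprintf("<ms_cooc> %d x %d grid (incl. unlabeled), %d permutations\n",
              nrow(x$counts), ncol(x$counts), x$n_perm))
  print(round(x$z, 2))
  invisible(x)
}

#' Group-level co-occurrence association decision
#'
#' Averages per-subject co-occurrence z grids and declares an MEG-EEG
#' microstate association wherever the mean z exceeds `z_crit`
#' (default 3). Unlabeled rows/columns are excluded from the decision.
#'
#' @param cooc_list list of `ms_cooc` objects with identical grids.
#' @param z_crit association threshold on the mean z.
#' @return list with `mean_z` (full grid) and `associated` (logical
#'   `K_meg x K_eeg` mask over labeled states only).
#' @export
cooccurrence_group <- function(cooc_list, z_crit = 3) {
  stopifnot(length(cooc_list) >= 1L)
  zs <- lapply(cooc_list, `[[`, "z")
  mean_z <- Reduce(`+`, lapply(zs, function(z) {
    z[is.na(z)] <- 0
    z
  })) / length(zs)
  dimnames(mean_z) <- dimnames(cooc_list[[1L]]$counts)
  lab <- mean_z[-1L, -1L, drop = FALSE]
  list(mean_z = mean_z, associated = lab > z_crit, z_crit = z_crit)
}

#' Cross-subject correlation of EEG and MEG microstate explained variance
#'
#' Correlates, across subjects, the global explained variance (GEV) of
#' every MEG microstate with that of every EEG microstate (Pearson),
#' adjusts the two-sided p-values over all `K_meg x K_eeg` cells with
#' Benjamini-Hochberg FDR, and masks the cells that are both positive
#' and significant after correction - the criterion for declaring a link
#' between an MEG and an EEG microstate.
#'
#' @param gev_meg,gev_eeg subject x state GEV matrices with matched rows
#'   (same subjects), at least 4 of them.
#' @param q_crit FDR level (default 0.05).
#' @return list with matrices `r`, `p`, `q` (`K_meg x K_eeg`) and the
#'   logical `positive_significant` mask. Zero-variance columns give
#'   `NA` cells that are excluded from the FDR adjustment.
#' @export
gev_correlation <- function(gev_meg, gev_eeg, q_crit = 0.05) {
  gev_meg <- as.matrix(gev_meg); gev_eeg <- as.matrix(gev_eeg)
  if (nrow(gev_meg) != nrow(gev_eeg)) {
    stop_invalid("GEV matrices must have the same subjects (rows)")
  }
  if (nrow(gev_meg) < 4L) stop_invalid("need at least 4 subjects")
  km <- ncol(gev_meg); ke <- ncol(gev_eeg)
  r <- p <- matrix(NA_real_, km, ke,
                   dimnames = list(paste0("meg", seq_len(km)),
                                   paste0("eeg", seq_len(ke))))
  for (i in seq_len(km)) {
    for (j in seq_len(ke)) {
      if (sd(gev_meg[, i]) == 0 || sd(gev_eeg[, j]) == 0) next
      ct <- stats::cor.test(gev_meg[, i], gev_eeg[, j], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  q <- p
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  list(r = r, p = p, q = q,
       positive_significant = !is.na(r) & r > 0 & !is.na(q) & q < q_crit)
}
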