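#' Spatial similarity between two topographies
#'
#' The mode-specific similarity underlying clustering, back-fitting and
#' explained variance. In EEG mode maps are average-referenced and
#' polarity is irrelevant, so the similarity is the absolute Pearson
#' correlation. In MEG mode the data are nonnegative combined-gradient
#' magnitudes with no reference, so the similarity is the uncentered
#' cosine (no mean subtraction, no absolute value).
#'
#' @param a,b numeric vectors of equal length with nonzero norm.
#' @param mode `"meg"` or `"eeg"`.
#' @return similarity in `[0, 1]` (MEG cosines of nonnegative vectors and
#'   absolute correlations are both bounded by 1).
#' @examples
#' spatial_similarity(c(1, -1), c(-1, 1), mode = "eeg")  # 1: polarity blind
#' spatial_similarity(c(1, 0), c(0, 1), mode = "meg")    # 0: disjoint support
#' @export
spatial_similarity <- function(a, b, mode = c("meg", "eeg")) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) stop_invalid("topographies differ in length")
  if (mode == "eeg") {
    a <- a - mean(a); b <- b - mean(b)
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-300 || nb < 1e-300) {
    stop(structure(class = c("megstates_undefined_similarity", "error",
                             "condition"),
                   list(message = "zero-norm topography", call = NULL)))
  }
  s <- sum(a * b) / (na * nb)
  if (mode == "eeg") abs(s) else s
}

# Row-normalise observations for the mode: EEG rows are centred first.
# Zero-norm rows come back as all-zero rows (similarity 0 to everything).
normalize_rows <- function(X, mode) {
  if (mode == "eeg") X <- X - rowMeans(X)
  nrm <- sqrt(rowSums(X^2))
  ok <- nrm > 1e-300
  X[ok, ] <- X[ok, , drop = FALSE] / nrm[ok]
  X[!ok, ] <- 0
  X
}

# N x K similarity matrix between observation rows and template rows.
# Both are normalised per `mode`; EEG similarities take |.|.
similarity_matrix <- function(X, templates, mode) {
  Xn <- normalize_rows(as.matrix(X), mode)
  Tn <- normalize_rows(as.matrix(templates), mode)
  S <- Xn %*% t(Tn)
  if (mode == "eeg") S <- abs(S)
  S[S > 1] <- 1
  S
}

# Mode-specific dissimilarity used by the cluster-validity criteria and
# the k-means objective: 1 - sim^2 (eeg, polarity-invariant) or 1 - sim (meg).
sim_to_dist <- function(S, mode) {
  if (mode == "eeg") 1 - S^2 else 1 - S
}
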