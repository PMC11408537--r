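#' Generate a quasi-uniform hemispherical sensor layout
#'
#' Places `n_channels` sensors quasi-uniformly on the upper unit
#' hemisphere (a Fibonacci lattice with a small seeded jitter) and
#' tabulates, for every channel, its six nearest neighbours by Euclidean
#' distance. The six-neighbour table drives the spatial (trimmed-mean)
#' filter applied before microstate identification.
#'
#' @param n_channels number of sensors, at least 8 (so that six
#'   neighbours exist besides the channel itself).
#' @param seed integer seed for the jitter; identical `(n_channels,
#'   seed)` pairs give identical layouts.
#' @return an object of class `ms_layout`: list with `channel_names`,
#'   `positions` (n x 3 matrix on the unit sphere, z >= 0) and
#'   `neighbors` (n x 6 integer matrix, row i = the 6 nearest channels
#'   to channel i, nearest first).
#' @examples
#' lay <- make_layout(32, seed = 1)
#' dim(lay$neighbors)
#' @export
make_layout <- function(n_channels, seed = 1L) {
  if (!is.numeric(n_channels) || length(n_channels) != 1L || n_channels < 8) {
    stop_invalid("n_channels must be a single number >= 8")
  }
  n <- as.integer(n_channels)
  with_seed(seed, {
    i <- seq_len(n) - 0.5
    # golden-angle spiral over the upper hemisphere: z in (0, 1)
    z <- i / n
    phi <- i * pi * (3 - sqrt(5))
    r <- sqrt(pmax(0, 1 - z^2))
    pos <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
    jitter <- matrix(rnorm(3L * n, sd = 0.02), n, 3L)
    pos <- pos + jitter
    pos <- pos / sqrt(rowSums(pos^2))          # back onto the sphere
    pos[, 3L] <- abs(pos[, 3L])                # stay on the hemisphere
    names <- sprintf("CH%03d", seq_len(n))
    rownames(pos) <- names
    d <- as.matrix(stats::dist(pos))
    nb <- t(vapply(seq_len(n), function(i) {
      order(d[i, ])[2:7]                       # skip self at rank 1
    }, integer(6L)))
    rownames(nb) <- names
    structure(list(channel_names = names, positions = pos, neighbors = nb),
              class = "ms_layout")
  })
}

#' @export
print.ms_layout <- function(x, ...) {
  cat(sprintf("<ms_layout> %d channels on the unit hemisphere, 6-NN table\n",
              length(x$channel_names)))
  invisible(x)
}
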