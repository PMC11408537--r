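# Shared small fixtures, all generated in code.

small_layout <- function(n = 16L, seed = 101L) make_layout(n, seed = seed)

small_setup <- function(K = 3L, mode = "meg", n = 16L, seed = 101L) {
  lay <- small_layout(n, seed)
  maps <- make_topographies(K, lay, mode, seed = seed + 1L)
  list(layout = lay, maps = maps, ms = microstates(maps, mode))
}

# Minimal hand-built segmentation for tests that do not need a recording.
fake_segmentation <- function(labels, k = max(labels), fs = 250,
                              sims = NULL, gfp = NULL, all_sims = NULL) {
  n <- length(labels)
  structure(list(labels = as.integer(labels),
                 sims = sims %||% as.numeric(labels > 0),
                 all_sims = all_sims,
                 gfp = gfp %||% rep(1, n),
                 fs = fs, k = as.integer(k), mode = "meg",
                 threshold = 0.5),
            class = "ms_segmentation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
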