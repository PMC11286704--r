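# Shared fixtures and independent oracles, built in code at test time.

# small synthetic series with a deterministic intensity pattern
make_series <- function(nz = 4, ny = 20, nx = 20, spacing = c(1, 1),
                        thick = 2, base = 0, label = "test") {
  v <- array(base + seq_len(nz * ny * nx) %% 7, dim = c(nz, ny, nx))
  image_series(v, pixel_spacing_mm = spacing, slice_thickness_mm = thick,
               series_label = label)
}

make_pair <- function(...) {
  a <- make_series(...)
  b <- make_series(...)
  b$voxels <- b$voxels + 1
  exam_pair(a, b)
}

# memoized noise-free default phantom shared across test files
.fixture_env <- new.env(parent = emptyenv())
clean_phantom <- function(seed = 42) {
  key <- paste0("ph", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_phantom(
      phantom_config(seed = seed, noise_sd = 0))
  .fixture_env[[key]]
}

# Independent maximum-entropy threshold oracle: plain exhaustive scan,
# computing each class entropy from scratch (no shared code with the
# implementation's cumulative-sum formulation).
kapur_oracle <- function(counts) {
  p <- counts / sum(counts)
  nb <- length(p)
  edges <- seq(0, 1, length.out = nb + 1)
  best_h <- -Inf
  best_s <- NA
  for (s in 1:(nb - 1)) {
    lo <- p[1:s]
    hi <- p[(s + 1):nb]
    if (sum(lo) == 0 || sum(hi) == 0) next
    q0 <- lo[lo > 0] / sum(lo)
    q1 <- hi[hi > 0] / sum(hi)
    h <- -sum(q0 * log(q0)) - sum(q1 * log(q1))
    if (h > best_h + 1e-12) {
      best_h <- h
      best_s <- s
    }
  }
  edges[best_s + 1]
}

# wrap a counts vector as the histogram class the thresholder consumes
as_hist <- function(counts) {
  structure(list(counts = counts,
                 bin_edges = seq(0, 1, length.out = length(counts) + 1)),
            class = "pooled_histogram")
}

# disk test slice for the active-contour tools
disk_slice <- function(n = 96, r = 15, fg = 0.9, bg = 0.1,
                       center = c(n / 2, n / 2)) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  img <- matrix(bg, n, n)
  img[(rr - center[1])^2 + (cc - center[2])^2 <= r^2] <- fg
  img
}
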