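# Intensity normalization and pooled maximum-entropy (Kapur) thresholding.
#
# Both series of an exam are normalized against a single clip value (the
# 99.999th percentile of the pooled intensities) and thresholded at a single
# pooled level, so pre/post volumes are measured on the same intensity scale.

#' Normalize a matched exam pair to [0, 1]
#'
#' The clip value is the 99.999th percentile (linear interpolation) of the
#' pooled pre+post intensities; every voxel is divided by it and clamped to
#' \[0, 1\], so the top 0.001% of voxels saturate at 1.
#'
#' @param pair an [exam_pair]
#' @param clip_percentile percentile defining the clip value; default 99.999
#' @return a `normalized_pair` with elements `pre`, `post` (arrays in
#'   \[0,1\]), `clip_value`, and the pair's `spacing`
#' @export
normalize_pair <- function(pair, clip_percentile = 99.999) {
  stopifnot(inherits(pair, "exam_pair"))
  pooled <- c(pair$pre$voxels, pair$post$voxels)
  clip <- unname(quantile(pooled, clip_percentile / 100, type = 7))
  if (!is.finite(clip) || clip <= 0)
    stop("degenerate intensities: pooled clip value is not positive")
  norm <- function(v) {
    out <- v / clip
    out[out > 1] <- 1
    out
  }
  structure(list(pre = norm(pair$pre$voxels), post = norm(pair$post$voxels),
                 clip_value = clip,
                 spacing = series_spacing(pair$pre)),
            class = "normalized_pair")
}

#' Pooled intensity histogram of a normalized pair
#'
#' Equal-width bins on \[0, 1\]; every bin is right-open except the last,
#' which includes 1. Counts pool all voxels of both series.
#'
#' @param norm a `normalized_pair`
#' @param bins number of bins (default 256)
#' @return a `pooled_histogram` with `counts` (length `bins`) and
#'   `bin_edges` (length `bins + 1`)
#' @export
pooled_histogram <- function(norm, bins = 256L) {
  stopifnot(inherits(norm, "normalized_pair"), bins >= 2L)
  v <- c(norm$pre, norm$post)
  idx <- pmin(floor(v * bins) + 1L, bins)
  counts <- tabulate(idx, nbins = bins)
  structure(list(counts = counts,
                 bin_edges = seq(0, 1, length.out = bins + 1L)),
            class = "pooled_histogram")
}

#' Maximum inter-class entropy (Kapur) threshold
#'
#' Scans every cut point between bins and returns the bin edge t* that
#' maximizes the sum of the Shannon entropies of the below- and
#' above-threshold classes, each computed from the class-normalized bin
#' probabilities over nonempty bins (natural log). Cuts that leave either
#' class empty are not candidates; ties resolve to the lowest threshold.
#'
#' @param hist a `pooled_histogram` (any bin count >= 2)
#' @return the threshold, a value in \[0, 1\]
#' @export
max_entropy_threshold <- function(hist) {
  stopifnot(inherits(hist, "pooled_histogram"))
  counts <- as.numeric(hist$counts)
  nb <- length(counts)
  if (sum(counts > 0) < 2L)
    stop("degenerate histogram: fewer than 2 nonempty bins")
  total <- sum(counts)
  p <- counts / total
  plogp <- ifelse(p > 0, p * log(p), 0)
  cp <- cumsum(p)            # class-0 mass up to cut s
  cpl <- cumsum(plogp)       # sum p log p up to cut s
  best_h <- -Inf
  best_s <- NA_integer_
  for (s in seq_len(nb - 1L)) {
    p0 <- cp[s]
    p1 <- 1 - p0
    if (p0 <= 0 || p1 <= 0) next
    # H(class) = log P - (1/P) * sum_{class} p log p
    h0 <- log(p0) - cpl[s] / p0
    h1 <- log(p1) - (cpl[nb] - cpl[s]) / p1
    h <- h0 + h1
    if (h > best_h + 1e-12) {
      best_h <- h
      best_s <- s
    }
  }
  hist$bin_edges[best_s + 1L]
}

#' Apply an intensity threshold to a normalized pair
#'
#' Strict comparison: a voxel enters the candidate-fluid mask iff its
#' normalized intensity exceeds `t`.
#'
#' @param norm a `normalized_pair`
#' @param t threshold in (0, 1)
#' @return list with logical masks `pre` and `post`
#' @export
apply_threshold <- function(norm, t) {
  stopifnot(inherits(norm, "normalized_pair"), t > 0, t < 1)
  list(pre = norm$pre > t, post = norm$post > t)
}
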