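test_that("normalization clips at the pooled 99.999th percentile", {
  # constant positive pair: percentile equals the constant, all values -> 1
  a <- image_series(array(5, dim = c(2, 16, 16)), c(1, 1), 1)
  pair <- exam_pair(a, a)
  norm <- normalize_pair(pair)
  expect_equal(norm$clip_value, 5)
  expect_true(all(norm$pre == 1) && all(norm$post == 1))

  # pooled uniform 0..10^6-1: clip ~ 999990, ~0.001% of voxels clamped
  n <- 500000L
  v1 <- array(seq(0, 1e6 - 2, length.out = n), dim = c(5, 100, 1000))
  v2 <- array(seq(1, 1e6 - 1, length.out = n), dim = c(5, 100, 1000))
  pair2 <- exam_pair(image_series(v1, c(1, 1), 1),
                     image_series(v2, c(1, 1), 1))
  norm2 <- normalize_pair(pair2)
  expect_equal(norm2$clip_value,
               unname(quantile(c(v1, v2), 0.99999)), tolerance = 1e-12)
  expect_equal(norm2$clip_value, 999990, tolerance = 1e-4)
  clamped <- sum(norm2$pre == 1) + sum(norm2$post == 1)
  expect_lt(abs(clamped / (2 * n) - 1e-5), 2e-5)

  zero <- image_series(array(0, dim = c(2, 16, 16)), c(1, 1), 1)
  expect_error(normalize_pair(exam_pair(zero, zero)),
               "degenerate intensities")
})

test_that("pooled histogram conserves counts and bins correctly", {
  pair <- make_pair(nz = 3, ny = 16, nx = 16)
  norm <- normalize_pair(pair)
  h <- pooled_histogram(norm)
  expect_equal(sum(h$counts), 2 * length(pair$pre$voxels))
  expect_length(h$bin_edges, 257)

  # all values exactly 1 -> all mass in the last bin
  ones <- image_series(array(3, dim = c(1, 16, 16)), c(1, 1), 1)
  h1 <- pooled_histogram(normalize_pair(exam_pair(ones, ones)))
  expect_equal(h1$counts[256], 512)
  expect_equal(sum(h1$counts[-256]), 0)

  # known values land in hand-computed bins: 0, 0.25, 0.5, 0.75 at 4 bins
  vals <- rep(c(0, 0.25, 0.5, 0.75), each = 64)
  s <- image_series(array(vals, dim = c(1, 16, 16)), c(1, 1), 1)
  nrm <- structure(list(pre = s$voxels, post = s$voxels, clip_value = 1,
                        spacing = series_spacing(s)),
                   class = "normalized_pair")
  h4 <- pooled_histogram(nrm, bins = 4L)
  expect_equal(h4$counts, c(128, 128, 128, 128))
})

test_that("maximum-entropy threshold matches the exhaustive oracle", {
  # two-spike 5-bin histogram: all separating cuts tie at H = 0; lowest wins
  expect_equal(max_entropy_threshold(as_hist(c(8, 0, 0, 0, 8))), 0.2)
  expect_equal(max_entropy_threshold(as_hist(c(8, 0, 0, 0, 8))),
               kapur_oracle(c(8, 0, 0, 0, 8)))

  # spikes in bins 10 and 200 of 256: threshold separates them
  counts <- numeric(256)
  counts[10] <- 500
  counts[200] <- 300
  t <- max_entropy_threshold(as_hist(counts))
  expect_gt(t * 256, 10 - 1e-9)
  expect_lte(t * 256, 200)
  expect_equal(t, kapur_oracle(counts))

  expect_error(max_entropy_threshold(as_hist(c(0, 7, 0))),
               "degenerate histogram")

  # oracle equivalence on random histograms of varied size
  set.seed(101)
  for (i in 1:200) {
    nb <- sample(c(8L, 32L, 256L), 1)
    counts <- rpois(nb, lambda = sample(c(0.5, 3, 50), 1))
    if (sum(counts > 0) < 2) next
    expect_equal(max_entropy_threshold(as_hist(counts)),
                 kapur_oracle(counts))
  }
})

test_that("threshold is scale-invariant and masks are anti-monotone in t", {
  pair <- make_pair(nz = 3, ny = 20, nx = 20)
  t1 <- max_entropy_threshold(pooled_histogram(normalize_pair(pair)))
  scaled <- exam_pair(
    image_series(pair$pre$voxels * 37.5, pair$pre$pixel_spacing_mm,
                 pair$pre$slice_thickness_mm),
    image_series(pair$post$voxels * 37.5, pair$post$pixel_spacing_mm,
                 pair$post$slice_thickness_mm))
  t2 <- max_entropy_threshold(pooled_histogram(normalize_pair(scaled)))
  expect_equal(t1, t2)

  norm <- normalize_pair(pair)
  lo <- apply_threshold(norm, 0.3)
  hi <- apply_threshold(norm, 0.6)
  expect_true(all(hi$pre[hi$pre] %in% lo$pre[hi$pre]))
  expect_true(all(!hi$pre | lo$pre))
  expect_true(all(!hi$post | lo$post))

  # threshold above the data maximum -> empty masks
  capped <- structure(list(pre = norm$pre * 0.9, post = norm$post * 0.9,
                           clip_value = norm$clip_value,
                           spacing = norm$spacing),
                      class = "normalized_pair")
  none <- apply_threshold(capped, 0.999999)
  expect_false(any(none$pre) || any(none$post))
})

test_that("the pooled threshold isolates fluid on a noise-free phantom", {
  ph <- clean_phantom()
  norm <- normalize_pair(ph$exam)
  t <- max_entropy_threshold(pooled_histogram(norm))
  m <- apply_threshold(norm, t)
  truth <- ph$truth$bowel_mask_pre
  recall <- sum(m$pre & truth) / sum(truth)
  expect_gte(recall, 0.95)
})
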