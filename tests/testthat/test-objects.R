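spacing_iso <- voxel_spacing(c(1, 1), 1)

test_that("26-connected labelling is correct and deterministic", {
  m <- array(FALSE, dim = c(4, 16, 16))
  expect_equal(label_clusters(m)$n_clusters, 0)

  # two diagonal-touching voxels form one 26-connected cluster
  m[2, 5, 5] <- TRUE
  m[3, 6, 6] <- TRUE
  expect_equal(label_clusters(m)$n_clusters, 1)

  # phantom: bowel tubes + disjoint confounder pieces are separate clusters
  ph <- clean_phantom()
  all_fluid <- Reduce(`|`, ph$truth$confounder_masks,
                      ph$truth$bowel_mask_pre)
  per_conf <- vapply(ph$truth$confounder_masks,
                     function(x) label_clusters(x)$n_clusters, integer(1))
  expect_equal(label_clusters(all_fluid)$n_clusters, 3L + sum(per_conf))
})

test_that("small-cluster removal is strict, idempotent and volume-ordered", {
  m <- array(FALSE, dim = c(12, 16, 16))
  m[1, 15, 1:5] <- TRUE                # 5 voxels = 0.005 mL at 1 mm iso
  m[3:12, 2:11, 5:14] <- TRUE          # 10x10x10 = 1.0 mL exactly
  out <- remove_small_clusters(m, spacing_iso, min_ml = 1)
  expect_equal(sum(out), 1000)          # 0.005 mL cluster removed
  expect_false(out[1, 15, 3])
  expect_identical(remove_small_clusters(out, spacing_iso, 1), out)
  expect_lte(sum(out), sum(m))
  expect_identical(remove_small_clusters(m, spacing_iso, min_ml = 0), m)
})

test_that("isotropic resampling preserves volume and is identity when iso", {
  m <- array(FALSE, dim = c(6, 20, 20))
  m[2:4, 5:10, 5:10] <- TRUE
  iso <- resample_isotropic(m, spacing_iso)
  expect_identical(iso$data, m)
  expect_equal(iso$iso_mm, 1)

  # 1 mL cube at 0.8 x 0.8 x 4 mm -> 0.8 mm isotropic, volume preserved
  sp <- voxel_spacing(c(0.8, 0.8), 4)
  m2 <- array(FALSE, dim = c(10, 30, 30))
  m2[2:9, 3:9, 3:9] <- TRUE            # 8*7*7 = 392 voxels = 1.0035 mL
  v_native <- compute_volume(m2, sp)
  iso2 <- resample_isotropic(m2, sp)
  v_iso <- sum(iso2$data) * iso2$iso_mm^3 / 1000
  expect_lt(abs(v_iso - v_native) / v_native, 0.05)

  empty <- resample_isotropic(array(FALSE, dim = c(3, 16, 16)), sp)
  expect_false(any(empty$data))
})

test_that("morphometry matches closed forms on canonical shapes", {
  # single voxel: cube closed form, A = 6 faces
  m <- array(0L, dim = c(8, 16, 16))
  m[4, 8, 8] <- 1L
  f <- compute_morphometry(m, iso_mm = 1)
  expect_equal(f$sphericity, pi^(1 / 3) * 6^(2 / 3) / 6, tolerance = 1e-12)
  expect_equal(f$volume_ml, 0.001)
  expect_true(f$unstable)

  # rod along the craniocaudal (row) axis: angle ~ 0, maximal span
  rod <- array(0L, dim = c(5, 60, 5))
  rod[3, 6:55, 3] <- 1L
  fr <- compute_morphometry(rod, iso_mm = 1)
  expect_lte(fr$principal_axis_angle_deg, 5)
  expect_equal(fr$craniocaudal_span_frac, 50 / 60)

  # digital ball r = 10: face counting gives ~2/3 (6 pi r^2 surface),
  # well above the rod but below the single-voxel cube bound
  n <- 25
  ctr <- 13
  co <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  ball <- array(as.integer((co$z - ctr)^2 + (co$y - ctr)^2 +
                             (co$x - ctr)^2 <= 100), dim = c(n, n, n))
  fb <- compute_morphometry(ball, iso_mm = 1)
  expect_gt(fb$sphericity, 0.6)
  expect_lt(abs(fb$sphericity - 2 / 3), 0.05)
  expect_gt(fb$sphericity, fr$sphericity)
  # the equal-volume cube is the face-count maximizer: no shape beats it
  expect_lte(fb$sphericity, pi^(1 / 3) * 6^(2 / 3) / 6 * 1.05)
  expect_lte(fr$sphericity, pi^(1 / 3) * 6^(2 / 3) / 6 * 1.05)
  # independent area check: face count within 5% of 6 pi r^2
  faces <- 6 * pi * 100
  expect_lt(abs(fb$sphericity -
                  pi^(1 / 3) * (6 * sum(ball))^(2 / 3) / faces), 0.05)
})

test_that("heuristic rules classify phantom objects by their morphometry", {
  rules <- load_rules()
  ph <- clean_phantom()
  sp <- series_spacing(ph$exam$pre)
  classify_mask <- function(mask) {
    cc <- label_clusters(mask)
    iso <- resample_isotropic(cc$labels, sp)
    f <- compute_morphometry(iso$data, iso$iso_mm)
    vapply(seq_len(nrow(f)), function(i) classify_nonbowel(f[i, ], rules),
           character(1))
  }
  expect_equal(classify_mask(ph$truth$confounder_masks$bladder), "bladder")
  expect_equal(classify_mask(ph$truth$confounder_masks$spinal_canal),
               "spinal_canal")
  expect_equal(classify_mask(ph$truth$confounder_masks$gallbladder),
               "gallbladder")
  # bowel tubes must match no rule
  expect_true(all(is.na(classify_mask(ph$truth$bowel_mask_pre))))

  # malformed rule tables are rejected at load time
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(object_class = "bladder",
                                 predicates = list(list(feature = "nope",
                                                        min = 1)))),
                       bad, auto_unbox = TRUE)
  expect_error(load_rules(bad), "unknown feature")
})

test_that("non-bowel removal deletes confounders and retains bowel", {
  ph <- clean_phantom()
  sp <- series_spacing(ph$exam$pre)
  norm <- normalize_pair(ph$exam)
  t <- max_entropy_threshold(pooled_histogram(norm))
  mask <- apply_threshold(norm, t)$pre
  mask <- remove_small_clusters(mask, sp)
  res <- remove_nonbowel(mask, sp)
  truth <- ph$truth$bowel_mask_pre
  retained <- sum(res$mask & truth) / sum(truth)
  expect_gte(retained, 0.95)
  removed_classes <- unique(res$log$object_class)
  expect_gte(length(removed_classes), 4)
  # bowel-only mask passes through untouched
  res2 <- remove_nonbowel(ph$truth$bowel_mask_pre, sp)
  expect_identical(res2$mask, ph$truth$bowel_mask_pre)
  expect_equal(nrow(res2$log), 0)
  # empty mask is a no-op
  e <- array(FALSE, dim = dim(truth))
  res3 <- remove_nonbowel(e, sp)
  expect_identical(res3$mask, e)
})
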