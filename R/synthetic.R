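# Synthetic abdominal phantoms with exact ground truth, plus simulated
# imperfect raters and rating tables, so the whole pipeline is testable
# without patient data.
#
# The phantom emulates the target acquisition: a coronal T2-weighted stack
# (slices anterior->posterior, rows craniocaudal) of a torso with bright
# fluid structures on a darker tissue background. Bowel fluid is rendered
# as smooth curved tubes in the mid-abdomen; the post-secretin stack is
# identical except the tubes are dilated until exactly the requested
# secreted volume has been added, preserving the voxelwise registration of
# protocol-matched acquisitions. Confounders are caricatures keyed to the
# heuristic rule table's feature ranges.

.all_confounders <- c("spinal_canal", "discs", "renal_pelvis", "bladder",
                      "gallbladder", "fat_rim")

#' Phantom configuration
#'
#' Defaults mirror the target acquisitions: 4 mm coronal slices, in-plane
#' spacing 1.5 mm (a coarsened 96x96 matrix over a 144 mm field of view so
#' phantoms stay small), fluid at 0.9 and tissue at 0.25 on the unit
#' intensity scale, additive Gaussian noise with sd 0.03, three bowel
#' tubes, and a 55 mL secretory response (the scale of semi-automated
#' clinical measurements).
#'
#' @param shape (slices, rows, cols)
#' @param pixel_spacing_mm in-plane (row, col) spacing, mm
#' @param slice_thickness_mm slice thickness, mm
#' @param n_bowel_tubes number of bowel fluid tubes (1-4)
#' @param secretion_delta_ml target secreted volume, mL (>= 0)
#' @param confounders subset of `c("spinal_canal", "discs", "renal_pelvis",
#'   "bladder", "gallbladder", "fat_rim")`
#' @param fluid_intensity,tissue_intensity intensities in \[0,1\],
#'   fluid > tissue
#' @param noise_sd additive Gaussian noise sd (intensity units)
#' @param seed integer seed; the generator is bit-reproducible per seed
#' @return a `phantom_config` list
#' @export
phantom_config <- function(shape = c(32L, 96L, 96L),
                           pixel_spacing_mm = c(1.5, 1.5),
                           slice_thickness_mm = 4,
                           n_bowel_tubes = 3L,
                           secretion_delta_ml = 55,
                           confounders = .all_confounders,
                           fluid_intensity = 0.9,
                           tissue_intensity = 0.25,
                           noise_sd = 0.03,
                           seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= c(8L, 64L, 64L)),
            fluid_intensity > tissue_intensity, tissue_intensity >= 0,
            fluid_intensity <= 1, noise_sd >= 0, secretion_delta_ml >= 0,
            n_bowel_tubes >= 1L, n_bowel_tubes <= 4L)
  confounders <- if (length(confounders) == 0L) character(0) else
    match.arg(confounders, .all_confounders, several.ok = TRUE)
  structure(list(shape = as.integer(shape),
                 pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 n_bowel_tubes = as.integer(n_bowel_tubes),
                 secretion_delta_ml = secretion_delta_ml,
                 confounders = confounders,
                 fluid_intensity = fluid_intensity,
                 tissue_intensity = tissue_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

# 6-neighbour binary dilation by one voxel
.dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

# 26-neighbour dilation (three 6-dilations along axes gives the chebyshev
# ball only approximately; compose axis dilations exactly instead)
.dilate26 <- function(m) {
  d <- dim(m)
  grow <- function(x, axis) {
    y <- x
    idx <- function(shift) {
      i <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      i[[axis]] <- pmin(pmax(i[[axis]] + shift, 1L), d[axis])
      i
    }
    lo <- idx(-1L); hi <- idx(1L)
    y | x[lo[[1]], lo[[2]], lo[[3]]] | x[hi[[1]], hi[[2]], hi[[3]]]
  }
  grow(grow(grow(m, 1L), 2L), 3L)
}

# Rasterize a tube: sweep a sphere of radius r (mm) along sampled path
# points given in mm coordinates (z, y, x).
.raster_tube <- function(shape, vox_mm, path_mm, r_mm) {
  out <- array(FALSE, dim = shape)
  half <- ceiling(r_mm / vox_mm)
  for (i in seq_len(nrow(path_mm))) {
    p <- path_mm[i, ]
    ctr <- p / vox_mm + 0.5
    lo <- pmax(floor(ctr - half), 1)
    hi <- pmin(ceiling(ctr + half), shape)
    iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
    zz <- (iz - 0.5) * vox_mm[1] - p[1]
    yy <- (iy - 0.5) * vox_mm[2] - p[2]
    xx <- (ix - 0.5) * vox_mm[3] - p[3]
    dist2 <- outer(outer(zz^2, yy^2, "+"), xx^2, "+")
    out[iz, iy, ix] <- out[iz, iy, ix] | (dist2 <= r_mm^2)
  }
  out
}

# Ellipsoid mask from center (mm) and semi-axes (mm), both (z, y, x).
.raster_ellipsoid <- function(coords, center, semi) {
  ((coords$z - center[1]) / semi[1])^2 +
    ((coords$y - center[2]) / semi[2])^2 +
    ((coords$x - center[3]) / semi[3])^2 <= 1
}

#' Generate a phantom exam pair with ground truth
#'
#' Renders the phantom described by `config` and returns both the
#' geometry-matched [exam_pair] and the exact truth: pre/post bowel masks,
#' per-confounder masks (pairwise disjoint and disjoint from bowel), and
#' true volumes computed as voxel counts times the voxel volume. The
#' post-secretin tubes are the pre tubes dilated shell-by-shell, taking a
#' raster-ordered partial shell at the end, so the added volume matches the
#' requested secretory response to within half a voxel.
#'
#' @param config a [phantom_config()]
#' @return list with `exam` (an [exam_pair]) and `truth` (list:
#'   `bowel_mask_pre`, `bowel_mask_post`, `confounder_masks`,
#'   `true_pre_ml`, `true_post_ml`)
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  d <- config$shape
  vox_mm <- c(config$slice_thickness_mm, config$pixel_spacing_mm)
  vox_ml <- prod(vox_mm) / 1000
  L <- d * vox_mm  # physical extents (z, y, x), mm
  ax <- list(z = (seq_len(d[1]) - 0.5) * vox_mm[1],
             y = (seq_len(d[2]) - 0.5) * vox_mm[2],
             x = (seq_len(d[3]) - 0.5) * vox_mm[3])
  coords <- list(
    z = array(rep(ax$z, times = d[2] * d[3]), dim = d),
    y = array(rep(rep(ax$y, each = d[1]), times = d[3]), dim = d),
    x = array(rep(ax$x, each = d[1] * d[2]), dim = d))

  body_semi <- c(0.45, 0.48, 0.42) * L
  body_ctr <- 0.5 * L
  rho2 <- ((coords$z - body_ctr[1]) / body_semi[1])^2 +
    ((coords$y - body_ctr[2]) / body_semi[2])^2 +
    ((coords$x - body_ctr[3]) / body_semi[3])^2
  body <- rho2 <= 1

  # --- bowel tubes: curved, mid-abdominal, anterior half of the stack.
  # Band positions, wobble amplitudes and depth planes are chosen so tube
  # envelopes keep a >= 1-voxel moat from each other and every confounder.
  tube_r <- 7  # mm
  if (config$n_bowel_tubes <= 3L) {
    y_bands <- c(0.30, 0.46, 0.62)[seq_len(config$n_bowel_tubes)]
    y_amp <- 3
  } else {
    y_bands <- c(0.24, 0.37, 0.50, 0.63)
    y_amp <- 1.5
  }
  z_planes <- c(0.42, 0.50, 0.46, 0.52)[seq_len(config$n_bowel_tubes)]
  phases <- stats::runif(config$n_bowel_tubes, 0, 2 * pi)
  bowel <- array(FALSE, dim = d)
  tubes <- vector("list", config$n_bowel_tubes)
  tt <- seq(0, 1, length.out = 160)
  for (k in seq_len(config$n_bowel_tubes)) {
    path <- cbind(rep(z_planes[k] * L[1], length(tt)),
                  y_bands[k] * L[2] +
                    y_amp * sin(2 * pi * 1.5 * tt + phases[k]),
                  (0.26 + 0.46 * tt) * L[3])
    tubes[[k]] <- .raster_tube(d, vox_mm, path, tube_r)
    bowel <- bowel | tubes[[k]]
  }

  # --- confounders (analytic geometry keyed to the default rule table)
  conf <- list()
  if ("spinal_canal" %in% config$confounders) {
    canal_path <- cbind(rep(0.78 * L[1], 120),
                        seq(0.10, 0.90, length.out = 120) * L[2],
                        rep(0.50 * L[3], 120))
    conf$spinal_canal <- .raster_tube(d, vox_mm, canal_path, 3)
  }
  if ("discs" %in% config$confounders) {
    discs <- array(FALSE, dim = d)
    for (yf in c(0.15, 0.275, 0.40, 0.525, 0.65))
      discs <- discs | .raster_ellipsoid(
        coords, c(0.64 * L[1], yf * L[2], 0.50 * L[3]), c(6, 2.5, 7))
    conf$discs <- discs
  }
  if ("renal_pelvis" %in% config$confounders) {
    pelvis <- .raster_ellipsoid(
      coords, c(0.68 * L[1], 0.42 * L[2], 0.30 * L[3]), c(6, 8, 6))
    ureter_path <- cbind(rep(0.68 * L[1], 40),
                         seq(0.42, 0.58, length.out = 40) * L[2],
                         (0.30 - seq(0, 0.02, length.out = 40)) * L[3])
    branch_path <- cbind(rep(0.68 * L[1], 20),
                         seq(0.42, 0.36, length.out = 20) * L[2],
                         seq(0.30, 0.24, length.out = 20) * L[3])
    conf$renal_pelvis <- pelvis |
      .raster_tube(d, vox_mm, ureter_path, 2) |
      .raster_tube(d, vox_mm, branch_path, 2)
  }
  if ("bladder" %in% config$confounders)
    conf$bladder <- .raster_ellipsoid(
      coords, c(0.50 * L[1], 0.82 * L[2], 0.50 * L[3]), c(21, 15, 21))
  if ("gallbladder" %in% config$confounders)
    conf$gallbladder <- .raster_ellipsoid(
      coords, c(0.266 * L[1], 0.36 * L[2], 0.34 * L[3]), c(5.9, 15, 11))
  if ("fat_rim" %in% config$confounders)
    conf$fat_rim <- body & rho2 > 0.94 &
      coords$z > 0.35 * L[1] & coords$z < 0.50 * L[1]

  # --- placement audit: all objects pairwise disjoint with a 1-voxel moat
  objs <- c(list(bowel = bowel), conf)
  for (i in seq_along(objs)) {
    grown <- .dilate26(objs[[i]])
    for (j in seq_along(objs)) {
      if (j == i) next
      if (any(grown & objs[[j]]))
        stop("placement failure: ", names(objs)[i], " touches ",
             names(objs)[j])
    }
  }

  # --- secretion: dilate bowel until exactly the target volume is added
  n_target <- round(config$secretion_delta_ml / vox_ml)
  blocked <- Reduce(`|`, lapply(conf, .dilate26),
                    array(FALSE, dim = d)) | !body
  bowel_post <- bowel
  n_added <- 0L
  guard <- 0L
  while (n_added < n_target) {
    guard <- guard + 1L
    if (guard > 60L)
      stop("placement failure: secretion target unreachable")
    shell <- which(.dilate26(bowel_post) & !bowel_post & !blocked)
    if (length(shell) == 0L)
      stop("placement failure: secretion target unreachable")
    take <- min(length(shell), n_target - n_added)
    bowel_post[shell[seq_len(take)]] <- TRUE  # raster order: deterministic
    n_added <- n_added + take
  }

  render <- function(bowel_mask) {
    v <- array(0, dim = d)
    v[body] <- config$tissue_intensity
    v[bowel_mask] <- config$fluid_intensity
    for (m in conf) v[m] <- config$fluid_intensity
    if (config$noise_sd > 0)
      v <- pmax(v + array(rnorm(prod(d), 0, config$noise_sd), dim = d), 0)
    pmin(v, 1)
  }
  pre_v <- render(bowel)
  post_v <- render(bowel_post)
  mk <- function(v, lab) image_series(v, config$pixel_spacing_mm,
                                      config$slice_thickness_mm,
                                      series_label = lab)
  truth <- list(bowel_mask_pre = bowel, bowel_mask_post = bowel_post,
                confounder_masks = conf,
                true_pre_ml = sum(bowel) * vox_ml,
                true_post_ml = sum(bowel_post) * vox_ml)
  list(exam = exam_pair(mk(pre_v, "phantom pre-secretin"),
                        mk(post_v, "phantom post-secretin")),
       truth = truth)
}

#' Simulate a pair of imperfect raters from a truth mask
#'
#' Each simulated rater perturbs the truth by toggling a random fraction of
#' its one-voxel boundary layer (inner surface voxels and outer shell).
#' The toggle probability is tuned by bounded bisection until the two
#' raters' mutual Dice coefficient is within 0.05 of `target_dsc`;
#' deterministic per seed.
#'
#' @param truth_mask nonempty logical 3D mask
#' @param target_dsc target mutual Dice, in (0.5, 1\]
#' @param seed integer seed
#' @return list of two logical masks (`rater1`, `rater2`)
#' @export
simulate_raters <- function(truth_mask, target_dsc, seed = 1L) {
  stopifnot(is.logical(truth_mask), length(dim(truth_mask)) == 3L)
  if (!any(truth_mask)) stop("truth_mask must be nonempty")
  if (target_dsc <= 0.5 || target_dsc > 1)
    stop("target_dsc must be in (0.5, 1]")
  if (target_dsc == 1) return(list(rater1 = truth_mask, rater2 = truth_mask))
  outer <- .dilate6(truth_mask) & !truth_mask
  inner <- truth_mask & .dilate6(!truth_mask)
  band <- which(inner | outer)
  perturb <- function(p, s) {
    set.seed(s)
    m <- truth_mask
    flip <- band[stats::runif(length(band)) < p]
    m[flip] <- !m[flip]
    m
  }
  eval_p <- function(p) {
    m1 <- perturb(p, seed * 1000L + 1L)
    m2 <- perturb(p, seed * 1000L + 2L)
    list(d = dice(m1, m2), m1 = m1, m2 = m2)
  }
  lo <- 0; hi <- 1
  for (it in seq_len(40L)) {
    p <- (lo + hi) / 2
    r <- eval_p(p)
    if (abs(r$d - target_dsc) <= 0.05)
      return(list(rater1 = r$m1, rater2 = r$m2))
    if (r$d > target_dsc) lo <- p else hi <- p
  }
  stop("target DSC infeasible for this mask")
}

#' Simulate a two-rater table of secretory-response measurements
#'
#' Exam true values are drawn Normal(`mu`, `sigma_between`^2); each rater
#' observes truth plus independent Normal(0, `sigma_rater`^2) error, so the
#' population ICC(2,1) is sigma_b^2 / (sigma_b^2 + sigma_r^2).
#'
#' @param n_exams number of exams (>= 3)
#' @param sigma_between between-exam sd, mL
#' @param sigma_rater within-rater error sd, mL
#' @param mu population mean secretory response, mL
#' @param seed integer seed
#' @return an `n_exams` x 2 matrix of measured delta volumes (mL)
#' @export
simulate_rating_table <- function(n_exams, sigma_between, sigma_rater,
                                  mu = 55, seed = 1L) {
  stopifnot(n_exams >= 3, sigma_between >= 0, sigma_rater >= 0)
  set.seed(seed)
  truth <- rnorm(n_exams, mu, sigma_between)
  vals <- truth + matrix(rnorm(2L * n_exams, 0, sigma_rater), n_exams, 2L)
  dimnames(vals) <- list(paste0("exam", seq_len(n_exams)), c("R1", "R2"))
  vals
}
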