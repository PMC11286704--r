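# Candidate-cluster extraction, morphometry and heuristic non-bowel removal.
#
# Clusters are 26-connected 3D components. Morphometric features are
# computed on an isotropically resampled copy of the labelled mask (target
# spacing = the smaller in-plane spacing, nearest-neighbour), but removal is
# applied to the native-spacing mask through the label correspondence, so
# measured volumes always come from acquisition geometry.

#' Label 26-connected clusters of a binary 3D mask
#'
#' Labels 1..K are assigned in raster order of each component's first voxel,
#' so labelling is deterministic.
#'
#' @param mask logical 3D array
#' @return list with `labels` (integer 3D array, 0 = background) and
#'   `n_clusters`
#' @export
label_clusters <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  lab <- .cc_label_3d(as.logical(mask), dim(mask))
  n <- attr(lab, "n_clusters")
  attr(lab, "n_clusters") <- NULL
  dim(lab) <- dim(mask)
  list(labels = lab, n_clusters = n)
}

#' Remove clusters below a minimum volume
#'
#' Clusters whose volume (in the native voxel geometry) is strictly less
#' than `min_ml` are deleted; clusters exactly at `min_ml` are retained.
#'
#' @param mask logical 3D array
#' @param spacing a [voxel_spacing]
#' @param min_ml minimum cluster volume in mL (default 1)
#' @return filtered logical mask
#' @export
remove_small_clusters <- function(mask, spacing, min_ml = 1.0) {
  cc <- label_clusters(mask)
  if (cc$n_clusters == 0L) return(mask)
  vox_ml <- .voxel_mm3(spacing) / 1000
  counts <- tabulate(cc$labels[cc$labels > 0L], nbins = cc$n_clusters)
  keep <- which(counts * vox_ml >= min_ml)
  out <- array(cc$labels %in% keep, dim = dim(mask))
  out
}

#' Resample a mask (or labelled array) to isotropic voxels
#'
#' Nearest-neighbour resampling onto cubic voxels whose edge is the smaller
#' in-plane spacing. Integer label arrays resample label-preservingly.
#'
#' @param mask logical or integer 3D array, (slice, row, col)
#' @param spacing a [voxel_spacing]
#' @return list with `data` (resampled array) and `iso_mm` (voxel edge, mm)
#' @export
resample_isotropic <- function(mask, spacing) {
  h <- min(spacing$pixel_spacing_mm)
  src_mm <- c(spacing$slice_thickness_mm, spacing$pixel_spacing_mm)
  d <- dim(mask)
  new_d <- pmax(1L, as.integer(round(d * src_mm / h)))
  maps <- lapply(1:3, function(a) {
    centers <- (seq_len(new_d[a]) - 0.5) * h
    pmin(pmax(floor(centers / src_mm[a]) + 1L, 1L), d[a])
  })
  list(data = mask[maps[[1]], maps[[2]], maps[[3]], drop = FALSE],
       iso_mm = h)
}

#' Morphometric features of labelled isotropic clusters
#'
#' For each label: volume (mL), normalized centroid (fractions of the array
#' extent, axes z = slice, y = row, x = col), axis-aligned bounding-box
#' extents (mm), sphericity, principal-axis angle from the craniocaudal
#' axis (degrees, 0-90) and craniocaudal span fraction.
#'
#' Sphericity is pi^(1/3) (6V)^(2/3) / A with the surface area A counted as
#' exposed voxel faces: exact and deterministic (a single voxel scores
#' A = 6 and sphericity pi^(1/3) 6^(2/3) / 6, about 0.806). Face counting
#' overestimates smooth areas by a factor approaching 3/2 (Cauchy
#' projection), so a digitized ball scores about 2/3 rather than 1; the
#' shipped heuristic ranges are calibrated to this scale.
#'
#' @param labeled integer 3D array of labels (0 = background), isotropic
#' @param iso_mm isotropic voxel edge, mm
#' @param cc_axis which array axis is craniocaudal: 1 (slice), 2 (row,
#'   default for coronal stacks) or 3 (col)
#' @return data.frame, one row per label
#' @export
compute_morphometry <- function(labeled, iso_mm, cc_axis = 2L) {
  stopifnot(length(dim(labeled)) == 3L, iso_mm > 0, cc_axis %in% 1:3)
  d <- dim(labeled)
  K <- max(labeled)
  if (K == 0L) return(.empty_morphometry())
  lin <- which(labeled > 0L)
  labs <- labeled[lin]
  ind <- arrayInd(lin, d)
  faces <- .cc_exposed_faces(as.integer(labeled), d, as.integer(K))
  rows <- lapply(seq_len(K), function(l) {
    sel <- labs == l
    co <- ind[sel, , drop = FALSE]
    n <- nrow(co)
    v_mm3 <- n * iso_mm^3
    area <- faces[l] * iso_mm^2
    cen <- (colMeans(co) - 0.5) / d
    bbox <- (apply(co, 2, max) - apply(co, 2, min) + 1) * iso_mm
    if (n >= 4L && any(apply(co, 2, var) > 0)) {
      ev <- eigen(stats::cov(co), symmetric = TRUE)$vectors[, 1]
      unstable <- FALSE
    } else {
      ev <- c(0, 0, 0); ev[cc_axis] <- 1   # degenerate: align with cc axis
      unstable <- TRUE
    }
    ang <- acos(min(1, abs(ev[cc_axis]) / sqrt(sum(ev^2)))) * 180 / pi
    data.frame(label = l, n_voxels = n, volume_ml = v_mm3 / 1000,
               centroid_z = cen[1], centroid_y = cen[2], centroid_x = cen[3],
               bbox_z_mm = bbox[1], bbox_y_mm = bbox[2], bbox_x_mm = bbox[3],
               sphericity = pi^(1 / 3) * (6 * v_mm3)^(2 / 3) / area,
               principal_axis_angle_deg = ang,
               craniocaudal_span_frac = bbox[cc_axis] / (d[cc_axis] * iso_mm),
               unstable = unstable)
  })
  do.call(rbind, rows)
}

.empty_morphometry <- function() {
  data.frame(label = integer(), n_voxels = integer(), volume_ml = numeric(),
             centroid_z = numeric(), centroid_y = numeric(),
             centroid_x = numeric(), bbox_z_mm = numeric(),
             bbox_y_mm = numeric(), bbox_x_mm = numeric(),
             sphericity = numeric(), principal_axis_angle_deg = numeric(),
             craniocaudal_span_frac = numeric(), unstable = logical())
}

.morph_features <- c("volume_ml", "centroid_z", "centroid_y", "centroid_x",
                     "bbox_z_mm", "bbox_y_mm", "bbox_x_mm", "sphericity",
                     "principal_axis_angle_deg", "craniocaudal_span_frac")

.nonbowel_classes <- c("spinal_canal", "intervertebral_disc",
                       "renal_pelvis_ureter", "bladder", "gallbladder",
                       "fat_rim")

#' Load a heuristic rule table
#'
#' A rule table is an ordered list of entries `{object_class, predicates}`
#' where each predicate is an interval `(feature, min, max)` over the
#' morphometric features. A cluster is assigned the class of the first rule
#' whose predicates all hold. The published feature set is fixed but the
#' numeric ranges are an implementation choice; the shipped defaults were
#' calibrated on the package's synthetic phantoms.
#'
#' @param path JSON rule file; default: the rule table shipped with the
#'   package
#' @return a validated `heuristic_rules` list
#' @export
load_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rules.json", package = "pftquant")
  rules <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (r in rules) {
    if (is.null(r$object_class) || !(r$object_class %in% .nonbowel_classes))
      stop("rule configuration error: unknown object_class ",
           r$object_class)
    for (p in r$predicates) {
      if (!(p$feature %in% .morph_features))
        stop("rule configuration error: unknown feature '", p$feature, "'")
      if (!is.null(p$min) && !is.null(p$max) && p$min > p$max)
        stop("rule configuration error: min > max for ", p$feature)
    }
  }
  structure(rules, class = "heuristic_rules")
}

#' Classify one cluster against a rule table
#'
#' @param features one row of [compute_morphometry()] output (or an
#'   equivalently named list)
#' @param rules a `heuristic_rules` table from [load_rules()]
#' @return the matched object class, or `NA_character_` when no rule
#'   matches (the cluster is retained as bowel fluid)
#' @export
classify_nonbowel <- function(features, rules) {
  stopifnot(inherits(rules, "heuristic_rules"))
  for (r in rules) {
    ok <- TRUE
    for (p in r$predicates) {
      v <- features[[p$feature]]
      lo <- if (is.null(p$min)) -Inf else p$min
      hi <- if (is.null(p$max)) Inf else p$max
      if (is.null(v) || is.na(v) || v < lo || v > hi) { ok <- FALSE; break }
    }
    if (ok) return(r$object_class)
  }
  NA_character_
}

#' Remove heuristically identified non-bowel clusters
#'
#' The native mask is labelled, the labelled array is resampled to
#' isotropic spacing, morphometry is computed there, each cluster is
#' classified against the rule table, and matched clusters are deleted from
#' the native-spacing mask through the label correspondence.
#'
#' @param mask logical 3D mask (after small-cluster filtering)
#' @param spacing a [voxel_spacing]
#' @param rules a `heuristic_rules` table; default: shipped table
#' @param cc_axis craniocaudal array axis (default 2, coronal rows)
#' @return list with `mask` (filtered native mask) and `log` (data.frame of
#'   removals: label, object_class, volume_ml, centroid_z/y/x)
#' @export
remove_nonbowel <- function(mask, spacing, rules = load_rules(),
                            cc_axis = 2L) {
  cc <- label_clusters(mask)
  empty_log <- data.frame(label = integer(), object_class = character(),
                          volume_ml = numeric(), centroid_z = numeric(),
                          centroid_y = numeric(), centroid_x = numeric())
  if (cc$n_clusters == 0L) return(list(mask = mask, log = empty_log))
  iso <- resample_isotropic(cc$labels, spacing)
  morph <- compute_morphometry(iso$data, iso$iso_mm, cc_axis = cc_axis)
  vox_ml <- .voxel_mm3(spacing) / 1000
  native_counts <- tabulate(cc$labels[cc$labels > 0L],
                            nbins = cc$n_clusters)
  cls <- vapply(seq_len(nrow(morph)),
                function(i) classify_nonbowel(morph[i, ], rules),
                character(1))
  drop <- morph$label[!is.na(cls)]
  log <- data.frame(label = drop,
                    object_class = cls[!is.na(cls)],
                    volume_ml = native_counts[drop] * vox_ml,
                    centroid_z = morph$centroid_z[match(drop, morph$label)],
                    centroid_y = morph$centroid_y[match(drop, morph$label)],
                    centroid_x = morph$centroid_x[match(drop, morph$label)])
  out <- mask
  if (length(drop)) out[cc$labels %in% drop] <- FALSE
  list(mask = out, log = if (length(drop)) log else empty_log)
}
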