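# Scripted equivalents of the four interactive refinement tools. All edits
# are 2D, acting on one displayed slice of one series, mirroring the
# interactive behaviour: seeded Chan-Vese add/remove, regional
# maximum-entropy add, unconditional regional remove.

#' Chan-Vese refinement parameters
#'
#' Defaults for the two-phase piecewise-constant active contour used by the
#' seeded add/remove tools: `mu` weights the contour length (per boundary
#' pixel edge, on the \[0,1\] intensity scale), `lambda1`/`lambda2` weight
#' the inside/outside data terms, the contour is initialized as a disk of
#' `init_radius` pixels at the seed, and evolution stops after `max_iter`
#' sweeps or when the relative energy decrease falls below `tol`.
#'
#' @param mu,lambda1,lambda2 energy weights
#' @param max_iter,tol stopping controls
#' @param init_radius seed-disk radius, pixels
#' @return a named list of parameters
#' @export
chan_vese_params <- function(mu = 0.25, lambda1 = 1, lambda2 = 1,
                             max_iter = 200L, tol = 1e-3, init_radius = 3) {
  stopifnot(mu >= 0, lambda1 > 0, lambda2 > 0, max_iter >= 1, tol >= 0,
            init_radius >= 1)
  list(mu = mu, lambda1 = lambda1, lambda2 = lambda2,
       max_iter = as.integer(max_iter), tol = tol,
       init_radius = init_radius)
}

# Run Chan-Vese from a seed disk and return the 8-connected foreground
# component containing the seed (NULL when the contour vanished there),
# plus the per-iteration energy trace.
.cv_component_at_seed <- function(norm_slice, seed_row, seed_col, params) {
  d <- dim(norm_slice)
  if (seed_row < 1 || seed_row > d[1] || seed_col < 1 || seed_col > d[2])
    stop("seed outside image bounds")
  # a (near-)uniform slice has no boundary for the data terms to find
  if (diff(range(norm_slice)) < 1e-9)
    return(list(component = NULL, energy = numeric(0)))
  rr <- matrix(seq_len(d[1]), d[1], d[2])
  cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  init <- (rr - seed_row)^2 + (cc - seed_col)^2 <= params$init_radius^2
  fit <- .cv_evolve(norm_slice, init, params$mu, params$lambda1,
                    params$lambda2, params$max_iter, params$tol)
  fg <- fit$mask
  comp <- NULL
  if (fg[seed_row, seed_col]) {
    lab3 <- label_clusters(array(fg, dim = c(1, d)))  # 26-conn == 8-conn here
    l <- lab3$labels[1, seed_row, seed_col]
    comp <- lab3$labels[1, , ] == l
  }
  list(component = comp, energy = fit$energy)
}

#' Add fluid at a seed point via Chan-Vese contouring
#'
#' Evolves the two-phase contour from a small disk at the seed and ORs the
#' converged foreground component containing the seed into the mask. The
#' edit is rejected (with a warning, mask unchanged) when no boundary is
#' found at the seed or the component exceeds half the slice area -- the
#' scripted equivalent of a leaked contour after a mis-click.
#'
#' @param norm_slice 2D numeric slice (normalized intensities)
#' @param mask_slice 2D logical mask of the same shape
#' @param seed_row,seed_col seed pixel (row, col)
#' @param params a [chan_vese_params()] list
#' @return the updated logical mask slice
#' @export
add_by_seed <- function(norm_slice, mask_slice, seed_row, seed_col,
                        params = chan_vese_params()) {
  stopifnot(identical(dim(norm_slice), dim(mask_slice)))
  res <- .cv_component_at_seed(norm_slice, seed_row, seed_col, params)
  if (is.null(res$component)) {
    warning("no boundary found at seed; mask unchanged")
    return(mask_slice)
  }
  if (sum(res$component) > 0.5 * length(mask_slice)) {
    warning("seeded region exceeds 50% of slice; edit rejected")
    return(mask_slice)
  }
  mask_slice | res$component
}

#' Remove fluid at a seed point via Chan-Vese contouring
#'
#' Same contour evolution as [add_by_seed()]; the identified component is
#' subtracted from the mask.
#'
#' @inheritParams add_by_seed
#' @return the updated logical mask slice
#' @export
remove_by_seed <- function(norm_slice, mask_slice, seed_row, seed_col,
                           params = chan_vese_params()) {
  stopifnot(identical(dim(norm_slice), dim(mask_slice)))
  res <- .cv_component_at_seed(norm_slice, seed_row, seed_col, params)
  if (is.null(res$component)) {
    warning("no boundary found at seed; mask unchanged")
    return(mask_slice)
  }
  if (sum(res$component) > 0.5 * length(mask_slice)) {
    warning("seeded region exceeds 50% of slice; edit rejected")
    return(mask_slice)
  }
  mask_slice & !res$component
}

# Even-odd polygon rasterization at pixel centres (pnpoly crossing test);
# vertices are (row, col) coordinates, half-open edge handling.
.polygon_mask <- function(nrow, ncol, vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) stop("polygon needs >= 3 vertices")
  if (!.polygon_simple(vertices)) stop("polygon is self-intersecting")
  py <- vertices[, 1]; px <- vertices[, 2]
  m <- length(py)
  r <- matrix(seq_len(nrow), nrow, ncol)
  ce <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  inside <- matrix(FALSE, nrow, ncol)
  j <- m
  for (i in seq_len(m)) {
    cross <- ((py[i] > r) != (py[j] > r)) &
      (ce < (px[j] - px[i]) * (r - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

.polygon_simple <- function(v) {
  m <- nrow(v)
  seg <- cbind(v, v[c(2:m, 1), , drop = FALSE])
  inter <- function(a, b) {
    d1 <- .cross2(b[3:4] - b[1:2], a[1:2] - b[1:2])
    d2 <- .cross2(b[3:4] - b[1:2], a[3:4] - b[1:2])
    d3 <- .cross2(a[3:4] - a[1:2], b[1:2] - a[1:2])
    d4 <- .cross2(a[3:4] - a[1:2], b[3:4] - a[1:2])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(m - 2)) {
    for (j in (i + 2):m) {
      if (i == 1 && j == m) next  # closing edge shares a vertex with edge 1
      if (inter(seg[i, ], seg[j, ])) return(FALSE)
    }
  }
  TRUE
}

.cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

#' Add fluid within a freeform region by local maximum-entropy threshold
#'
#' Computes the Kapur threshold from the histogram of in-polygon voxels
#' only (same criterion as the pooled pre-threshold) and ORs in-polygon
#' voxels above it into the mask. A degenerate in-polygon histogram makes
#' the edit a warning no-op.
#'
#' @param norm_slice 2D numeric slice (normalized intensities in \[0,1\])
#' @param mask_slice 2D logical mask of the same shape
#' @param vertices polygon as an n x 2 matrix of (row, col) vertices
#' @param bins histogram bins for the regional threshold (default 256)
#' @return the updated logical mask slice
#' @export
add_by_region <- function(norm_slice, mask_slice, vertices, bins = 256L) {
  stopifnot(identical(dim(norm_slice), dim(mask_slice)))
  poly <- .polygon_mask(nrow(norm_slice), ncol(norm_slice), vertices)
  vals <- norm_slice[poly]
  idx <- pmin(floor(vals * bins) + 1L, bins)
  counts <- tabulate(idx, nbins = bins)
  if (sum(counts > 0) < 2L) {
    warning("constant region inside polygon; mask unchanged")
    return(mask_slice)
  }
  hist <- structure(list(counts = counts,
                         bin_edges = seq(0, 1, length.out = bins + 1L)),
                    class = "pooled_histogram")
  t <- max_entropy_threshold(hist)
  mask_slice | (poly & norm_slice > t)
}

#' Remove all mask voxels within a freeform region
#'
#' Unconditional: every in-polygon voxel is cleared from the mask.
#'
#' @param mask_slice 2D logical mask
#' @param vertices polygon as an n x 2 matrix of (row, col) vertices
#' @return the updated logical mask slice
#' @export
remove_by_region <- function(mask_slice, vertices) {
  poly <- .polygon_mask(nrow(mask_slice), ncol(mask_slice), vertices)
  mask_slice & !poly
}

#' Apply a batch edit script to an exam's masks
#'
#' An edit script is an ordered list of edits, each a list with `tool`
#' (one of `"add_seed"`, `"remove_seed"`, `"add_region"`,
#' `"remove_region"`), `series` (`"pre"` or `"post"`), `slice`, and either
#' `row`/`col` (seed tools) or `vertices` (region tools, n x 2 (row, col)).
#' Edits touch only the named slice of the named series.
#'
#' @param norm a `normalized_pair`
#' @param masks list with logical masks `pre` and `post`
#' @param edits the edit script (list of edits)
#' @param params [chan_vese_params()] for the seed tools
#' @return the updated `masks` list
#' @export
apply_edits <- function(norm, masks, edits,
                        params = chan_vese_params()) {
  for (e in edits) {
    s <- match.arg(e$series, c("pre", "post"))
    k <- as.integer(e$slice)
    img <- norm[[s]][k, , ]
    msk <- masks[[s]][k, , ]
    msk <- switch(
      match.arg(e$tool, c("add_seed", "remove_seed", "add_region",
                          "remove_region")),
      add_seed = add_by_seed(img, msk, e$row, e$col, params),
      remove_seed = remove_by_seed(img, msk, e$row, e$col, params),
      add_region = add_by_region(img, msk, .edit_vertices(e)),
      remove_region = remove_by_region(msk, .edit_vertices(e))
    )
    masks[[s]][k, , ] <- msk
  }
  masks
}

.edit_vertices <- function(e) {
  v <- e$vertices
  if (is.list(v)) v <- do.call(rbind, lapply(v, unlist))
  matrix(as.numeric(v), ncol = 2)
}
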