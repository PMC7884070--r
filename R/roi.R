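#' Voxel grid with an affine voxel-to-mm mapping
#'
#' A grid is the geometry shared by all volumes of a dataset: integer voxel
#' coordinates (0-based i, j, k) plus a 4x4 affine mapping voxel indices to
#' millimeter (e.g. MNI) coordinates. The default constructor builds an
#' isotropic grid centered on the mm origin.
#'
#' @param dim length-3 integer grid dimensions.
#' @param voxel_mm isotropic voxel size in mm (default 2.5).
#' @param origin_mm mm coordinate of voxel (0,0,0); default centers the grid.
#' @param affine alternatively, a full 4x4 affine (overrides
#'   `voxel_mm`/`origin_mm`).
#' @return object of class `voxel_grid`: list with `dim` and `affine`.
#' @export
make_grid <- function(dim, voxel_mm = 2.5, origin_mm = NULL, affine = NULL) {
  stopifnot(length(dim) == 3, all(dim >= 1))
  dim <- as.integer(dim)
  if (is.null(affine)) {
    if (is.null(origin_mm)) origin_mm <- -(dim - 1) / 2 * voxel_mm
    affine <- diag(c(rep(voxel_mm, 3), 1))
    affine[1:3, 4] <- origin_mm
  }
  stopifnot(all(dim(affine) == c(4, 4)))
  structure(list(dim = dim, affine = affine), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid:", paste(x$dim, collapse = " x "), "voxels\n")
  invisible(x)
}

# round half away from zero (so e.g. 2.5 -> 3, -2.5 -> -3)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert mm coordinates to voxel indices
#'
#' Applies the inverse affine and rounds to the nearest voxel;
#' half-integers round away from zero. Coordinates outside the grid error.
#'
#' @param grid a `voxel_grid`.
#' @param mm length-3 numeric or n x 3 matrix of mm coordinates.
#' @return integer vector/matrix of 0-based (i, j, k) indices.
#' @export
mm_to_voxel <- function(grid, mm) {
  stopifnot(inherits(grid, "voxel_grid"))
  mm <- rbind(mm)
  v <- t(solve(grid$affine) %*% rbind(t(mm), 1))[, 1:3, drop = FALSE]
  ijk <- round_half_away(v)
  bad <- ijk < 0 | ijk >= matrix(grid$dim, nrow(ijk), 3, byrow = TRUE)
  if (any(bad)) {
    stop("mm coordinate outside the field of view: ",
         paste(mm[which(rowSums(bad) > 0)[1], ], collapse = ", "))
  }
  out <- matrix(as.integer(ijk), ncol = 3)
  if (nrow(out) == 1) drop(out) else out
}

#' Convert voxel indices to mm coordinates
#'
#' @param grid a `voxel_grid`.
#' @param ijk length-3 vector or n x 3 matrix of 0-based voxel indices.
#' @return mm coordinates (vector or n x 3 matrix).
#' @export
voxel_to_mm <- function(grid, ijk) {
  stopifnot(inherits(grid, "voxel_grid"))
  ijk <- rbind(ijk)
  out <- t(grid$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
  if (nrow(out) == 1) drop(out) else out
}

# 1-based linear (column-major) index of 0-based voxel coordinates
voxel_linear_index <- function(grid, ijk) {
  ijk <- rbind(ijk)
  as.integer(ijk[, 1] + ijk[, 2] * grid$dim[1] +
               ijk[, 3] * grid$dim[1] * grid$dim[2] + 1)
}

new_voxel_mask <- function(ijk, grid) {
  ijk <- matrix(as.integer(ijk), ncol = 3)
  # canonical order: ascending column-major linear index (i fastest), so a
  # full-grid mask extracts the beta matrix unchanged
  ord <- order(ijk[, 3], ijk[, 2], ijk[, 1])
  ijk <- ijk[ord, , drop = FALSE]
  structure(list(ijk = ijk, lin = voxel_linear_index(grid, ijk),
                 grid = grid, n_voxels = nrow(ijk)),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat("voxel_mask:", x$n_voxels, "voxels on a",
      paste(x$grid$dim, collapse = " x "), "grid\n")
  invisible(x)
}

#' Spherical region of interest as a voxel mask
#'
#' All voxels whose center lies within `radius_mm` (Euclidean, in mm) of
#' `center_mm`. Membership is by voxel center, without partial-volume
#' weighting. Voxels are stored in the canonical ascending column-major
#' order (linear grid index).
#'
#' @param center_mm length-3 mm coordinates of the sphere center.
#' @param radius_mm sphere radius in mm (> 0; default 10).
#' @param grid a `voxel_grid`.
#' @return a `voxel_mask`; errors if no voxel falls inside the sphere.
#' @export
sphere_voxels <- function(center_mm, radius_mm = 10, grid) {
  stopifnot(inherits(grid, "voxel_grid"), radius_mm > 0)
  inv <- solve(grid$affine)
  c_vox <- (inv %*% c(center_mm, 1))[1:3]
  spacing <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  half <- ceiling(radius_mm / spacing) + 1
  rng <- lapply(1:3, function(d) {
    max(0, floor(c_vox[d] - half[d])):min(grid$dim[d] - 1,
                                          ceiling(c_vox[d] + half[d]))
  })
  if (any(vapply(rng, length, 1L) == 0)) stop("empty sphere mask")
  cand <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  mm <- t(grid$affine %*% rbind(t(cand), 1))[, 1:3, drop = FALSE]
  d2 <- rowSums(sweep(mm, 2, center_mm)^2)
  inside <- d2 <= radius_mm^2 + 1e-9
  if (!any(inside)) stop("empty sphere mask: no voxel center within ",
                         radius_mm, " mm of the given center")
  new_voxel_mask(cand[inside, , drop = FALSE], grid)
}

#' Whole-grid mask
#'
#' @param grid a `voxel_grid`.
#' @return a `voxel_mask` covering every voxel of the grid.
#' @export
full_grid_mask <- function(grid) {
  cand <- as.matrix(expand.grid(i = 0:(grid$dim[1] - 1),
                                j = 0:(grid$dim[2] - 1),
                                k = 0:(grid$dim[3] - 1)))
  new_voxel_mask(cand, grid)
}

#' The six theory-of-mind network ROIs
#'
#' Peak MNI coordinates of the bilateral temporoparietal junction (TPJ),
#' bilateral superior temporal sulcus (STS), medial prefrontal cortex
#' (MPFC) and precuneus from a theory-of-mind meta-analysis, each used as
#' the center of a 10-mm-radius sphere.
#'
#' @return data.frame with columns `name`, `x`, `y`, `z` (MNI mm), `radius`.
#' @export
default_rois <- function() {
  data.frame(
    name = c("L_TPJ", "R_TPJ", "L_STS", "R_STS", "MPFC", "precuneus"),
    x = c(-52, 55, -59, 59, 1, -3),
    y = c(-56, -53, -26, -18, 58, -56),
    z = c(24, 24, -9, -17, 19, 37),
    radius = 10,
    stringsAsFactors = FALSE)
}

#' Read / write an ROI table
#'
#' Tab-separated table with columns `name`, `x`, `y`, `z`, `radius`
#' (mm). Arbitrary user-supplied ROI sets (e.g. alternative TPJ
#' definitions) are accepted this way.
#'
#' @param path file path.
#' @param rois data.frame in the [default_rois()] format.
#' @return `read_roi_table` returns the data.frame.
#' @export
read_roi_table <- function(path) {
  rois <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z", "radius")
  if (!all(need %in% names(rois))) {
    stop("ROI table must have columns: ", paste(need, collapse = ", "))
  }
  rois
}

#' @rdname read_roi_table
#' @export
write_roi_table <- function(rois, path) {
  utils::write.table(rois, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build sphere masks for a table of ROIs
#'
#' @param rois data.frame in the [default_rois()] format.
#' @param grid a `voxel_grid`.
#' @return named list of `voxel_mask` objects.
#' @export
roi_masks <- function(rois, grid) {
  out <- lapply(seq_len(nrow(rois)), function(i) {
    sphere_voxels(c(rois$x[i], rois$y[i], rois$z[i]), rois$radius[i], grid)
  })
  names(out) <- rois$name
  out
}

#' Pairwise overlap report for a set of masks
#'
#' Overlapping ROIs are allowed but reported: returns the number of shared
#' voxels for every mask pair.
#'
#' @param masks named list of `voxel_mask` objects.
#' @return data.frame with columns `roi_a`, `roi_b`, `n_shared`.
#' @export
roi_overlap_report <- function(masks) {
  nm <- names(masks)
  pairs <- utils::combn(length(masks), 2)
  data.frame(
    roi_a = nm[pairs[1, ]], roi_b = nm[pairs[2, ]],
    n_shared = apply(pairs, 2, function(p) {
      length(intersect(masks[[p[1]]]$lin, masks[[p[2]]]$lin))
    }),
    stringsAsFactors = FALSE)
}

#' Extract an ROI pattern matrix from a beta series
#'
#' Returns the trials x voxels matrix of the beta series restricted to the
#' mask, with condition/run labels carried over. Columns follow the mask's
#' canonical ascending linear-index voxel order, so the output is invariant
#' to mask construction order and a full-grid mask returns the series
#' unchanged. For searchlight use, a mask partially outside
#' the beta grid is intersected; a mask with no voxel in the beta grid
#' errors.
#'
#' @param beta_series a `beta_series`.
#' @param mask a `voxel_mask`.
#' @return object of class `pattern_set`: list with `x` (trials x voxels),
#'   `condition`, `run`, `trial_index`, `voxels`.
#' @export
extract_patterns <- function(beta_series, mask) {
  stopifnot(inherits(beta_series, "beta_series"), inherits(mask, "voxel_mask"))
  cols <- match(mask$lin, beta_series$voxels)
  cols <- cols[!is.na(cols)]
  if (length(cols) == 0) stop("mask does not intersect the beta-series grid")
  structure(list(x = beta_series$betas[, cols, drop = FALSE],
                 condition = beta_series$condition,
                 run = beta_series$run,
                 trial_index = beta_series$trial_index,
                 voxels = beta_series$voxels[cols]),
            class = "pattern_set")
}
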