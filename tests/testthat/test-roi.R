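test_that("mm-to-voxel conversion inverts the affine with documented rounding", {
  g1 <- make_grid(c(10, 10, 10), voxel_mm = 1, origin_mm = c(0, 0, 0))
  expect_equal(mm_to_voxel(g1, c(3, 4, 5)), c(3L, 4L, 5L))
  # half-integers round away from zero
  expect_equal(mm_to_voxel(g1, c(2.5, 0, 0))[1], 3L)

  g2 <- make_grid(c(80, 100, 60), voxel_mm = 2.5,
                  origin_mm = c(-90, -126, -72))
  mm <- c(-52, -56, 24)
  got <- mm_to_voxel(g2, mm)
  # independent check: solve the affine system directly
  expect_equal(got, as.integer(round(solve(g2$affine, c(mm, 1))[1:3])))
  expect_true(all(abs(voxel_to_mm(g2, got) - mm) <= 1.25))
  expect_error(mm_to_voxel(g2, c(500, 0, 0)), "outside")
})

test_that("sphere masks match a brute-force distance scan (257 voxels at r = 10)", {
  grid <- make_grid(c(17, 17, 17), voxel_mm = 2.5)
  center <- voxel_to_mm(grid, c(8, 8, 8))  # coincides with a voxel center
  mask <- sphere_voxels(center, 10, grid)
  expect_equal(mask$n_voxels, 257)
  expect_equal(mask$ijk, sphere_brute(center, 10, grid), ignore_attr = TRUE)
  # off-center case on an anisotropic-origin grid
  grid2 <- make_grid(c(12, 14, 10), voxel_mm = 2.5,
                     origin_mm = c(-11, -19, -7))
  mask2 <- sphere_voxels(c(1.3, -2.2, 0.4), 7.5, grid2)
  expect_equal(mask2$ijk, sphere_brute(c(1.3, -2.2, 0.4), 7.5, grid2),
               ignore_attr = TRUE)
})

test_that("sphere masks degenerate and grow sensibly with radius", {
  grid <- make_grid(c(9, 9, 9), voxel_mm = 2.5)
  center <- voxel_to_mm(grid, c(4, 4, 4))
  expect_equal(sphere_voxels(center, 1, grid)$n_voxels, 1)
  sizes <- vapply(c(1, 2.5, 5, 7.5, 10), function(r) {
    sphere_voxels(center, r, grid)$n_voxels
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  expect_error(sphere_voxels(c(1e6, 0, 0), 1, grid), "empty")
  expect_error(sphere_voxels(center, -1, grid))
})

test_that("the six default theory-of-mind ROIs are disjoint 10 mm spheres", {
  rois <- default_rois()
  expect_equal(rois$name,
               c("L_TPJ", "R_TPJ", "L_STS", "R_STS", "MPFC", "precuneus"))
  expect_true(all(rois$radius == 10))
  expect_equal(rois$x[rois$name == "L_TPJ"], -52)
  grid <- make_grid(c(61, 59, 34), voxel_mm = 2.5,
                    origin_mm = c(-75, -75, -35))
  masks <- roi_masks(rois, grid)
  overlap <- roi_overlap_report(masks)
  expect_equal(nrow(overlap), 15)  # all pairs checked
  expect_true(all(overlap$n_shared == 0))
})

test_that("pattern extraction uses the canonical voxel order", {
  grid <- make_grid(c(4, 4, 2), voxel_mm = 2.5)
  set.seed(1)
  bs <- make_beta_series(matrix(rnorm(6 * 32), 6, 32),
                         rep(c("endo_self", "exo_self"), 3),
                         rep(1:3, each = 2), grid)
  m1 <- sphere_voxels(voxel_to_mm(grid, c(1, 1, 0)), 3, grid)
  p1 <- extract_patterns(bs, m1)
  expect_equal(ncol(p1$x), m1$n_voxels)
  # single voxel: the matrix equals that voxel's beta column
  mono <- sphere_voxels(voxel_to_mm(grid, c(2, 2, 1)), 1, grid)
  expect_equal(drop(extract_patterns(bs, mono)$x),
               bs$betas[, mono$lin])
  # full-grid mask returns the whole series
  expect_equal(extract_patterns(bs, full_grid_mask(grid))$x, bs$betas)
  # insertion order does not matter: shuffled construction, same output
  shuf <- storymvpa:::new_voxel_mask(m1$ijk[rev(seq_len(m1$n_voxels)), ],
                                     grid)
  expect_identical(extract_patterns(bs, shuf)$x, p1$x)
  # mask disjoint from the series errors
  bs_small <- bs
  bs_small$voxels <- 1:2
  bs_small$betas <- bs$betas[, 1:2]
  far <- sphere_voxels(voxel_to_mm(grid, c(3, 3, 1)), 1, grid)
  expect_error(extract_patterns(bs_small, far), "does not intersect")
})

test_that("ROI tables round-trip through TSV", {
  f <- tempfile(fileext = ".tsv")
  write_roi_table(default_rois(), f)
  expect_equal(read_roi_table(f), default_rois())
  bad <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(a = 1), bad, sep = "\t", row.names = FALSE)
  expect_error(read_roi_table(bad), "columns")
})
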