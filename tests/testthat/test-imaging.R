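# Bead detection, subpixel refinement, displacement matching, segmentation
# and the action-area displacement field.

test_that("detection returns nothing on empty stacks and warns above the max", {
  empty <- image_stack(array(0, c(8, 8, 8)), 0.63)
  expect_warning(b <- detect_beads(empty, 1), "threshold")
  expect_equal(nrow(b$positions), 0)
})

test_that("a single noise-free Gaussian bead is detected at its voxel centre", {
  st <- gauss_bead_stack(centre = c(10, 12, 14))
  b <- detect_beads(st, 50)
  expect_equal(nrow(b$positions), 1)
  expect_equal(as.numeric(b$positions),
               (c(10, 12, 14) - 0.5) * 0.63, tolerance = 1e-12)
})

test_that("all beads of a synthetic pair are detected within one voxel", {
  pair <- make_bead_stack_pair(c(48, 48, 48), voxel_size = 0.63, n_beads = 50,
                               noise_sd = 5, seed = 4, min_separation = 8)
  b <- detect_beads(pair$deformed, 30)
  expect_equal(nrow(b$positions), 50)
  truth <- as.matrix(pair$truth[, c("x_um", "y_um", "z_um")])
  d <- vapply(seq_len(nrow(truth)), function(i)
    min(sqrt(colSums((t(b$positions) - truth[i, ])^2))), 0)
  expect_lt(max(d) / 0.63, 1)
})

test_that("subpixel refinement recovers off-centre positions and drops border beads", {
  # perfectly centred bead: position unchanged
  st <- gauss_bead_stack(centre = c(12, 12, 12))
  b0 <- detect_beads(st, 50)
  r0 <- refine_subpixel(st, b0)
  expect_equal(r0$positions, b0$positions, tolerance = 1e-6)
  # bead displaced 0.30 voxel in x: refined within 0.05 voxel of truth
  st2 <- gauss_bead_stack(centre = c(12.3, 12, 12))
  b2 <- detect_beads(st2, 50)
  r2 <- refine_subpixel(st2, b2)
  got_vox <- r2$positions[1, 1] / 0.63 + 0.5
  expect_lt(abs(got_vox - 12.3), 0.05)
  # bead 2 voxels from the border with a 7-subvolume is dropped
  far <- gauss_bead_stack(dims = c(24, 24, 24), centre = c(12, 12, 12))
  near <- gauss_bead_stack(dims = c(24, 24, 24), centre = c(2, 12, 12))
  both <- image_stack(far$intensities + near$intensities, 0.63)
  bb <- detect_beads(both, 50)
  expect_equal(nrow(bb$positions), 2)
  expect_warning(rr <- refine_subpixel(both, bb), "dropped 1")
  expect_equal(nrow(rr$positions), 1)
  expect_error(refine_subpixel(st, b0, subvolume = c(6, 7, 7)), "odd")
})

test_that("matching recovers zero, integer and subpixel shifts", {
  vs <- 0.63
  # identical stacks: zero vectors
  pair0 <- make_bead_stack_pair(c(40, 40, 40), vs, n_beads = 10, seed = 2)
  b <- refine_subpixel(pair0$deformed, detect_beads(pair0$deformed, 30))
  sp0 <- match_displacements(pair0$deformed, pair0$relaxed, b)
  expect_lt(max(abs(sp0$vectors)), 1e-3)
  # integer shift (2,1,0) voxels: exact translation inside the valid region
  pair2 <- make_bead_stack_pair(c(40, 40, 40), vs, n_beads = 10,
                                warp = c(2, 1, 0) * vs, seed = 2)
  b2 <- refine_subpixel(pair2$deformed, detect_beads(pair2$deformed, 30))
  sp2 <- match_displacements(pair2$deformed, pair2$relaxed, b2)
  err_vox <- sweep(sp2$vectors / vs, 2, c(2, 1, 0))
  expect_lt(max(abs(err_vox)), 0.05)
  # mismatched shapes rejected
  small <- image_stack(array(1, c(10, 10, 10)), vs)
  expect_error(match_displacements(pair2$deformed, small, b2), "shape")
})

test_that("subpixel shifts 0.1-0.9 voxels are recovered with mean error < 0.1 voxel", {
  vs <- 0.63
  errs <- vapply(seq(0.1, 0.9, by = 0.2), function(sv) {
    pair <- make_bead_stack_pair(c(36, 36, 36), vs, n_beads = 8,
                                 warp = c(sv * vs, 0, 0), seed = 6)
    b <- refine_subpixel(pair$deformed, detect_beads(pair$deformed, 30))
    sp <- match_displacements(pair$deformed, pair$relaxed, b)
    mean(abs(sp$vectors[, 1] / vs - sv))
  }, 0)
  expect_lt(mean(errs), 0.1)
})

test_that("segmentation keeps the largest component and fills interior holes", {
  vol <- array(0, c(20, 20, 20))
  cx <- seq_len(20) - 10.5
  sphere <- outer(outer(cx^2, cx^2, `+`), cx^2, `+`) <= 36
  vol[sphere] <- 100
  st <- image_stack(vol, 0.63, channel = "cell")
  mask <- segment_cell(st, threshold = 50)
  expect_equal(mask$occupancy, array(sphere, dim(sphere)))
  # interior hole is filled
  vol2 <- vol; vol2[10, 10, 10] <- 0
  m2 <- segment_cell(image_stack(vol2, 0.63, channel = "cell"), 50)
  expect_true(m2$occupancy[10, 10, 10])
  # a disconnected small blob is discarded
  vol3 <- vol; vol3[2, 2, 2] <- 100
  m3 <- segment_cell(image_stack(vol3, 0.63, channel = "cell"), 50)
  expect_false(m3$occupancy[2, 2, 2])
  expect_error(segment_cell(image_stack(vol * 0 + 1, 0.63, channel = "cell"),
                            threshold = 50), "no cell")
})

test_that("otsu threshold separates a bimodal volume", {
  set.seed(8)
  lo <- rnorm(4000, 10, 2)
  hi <- rnorm(4000, 100, 5)
  vol <- array(pmax(c(lo, hi), 0), c(20, 20, 20))
  thr <- tfm3d:::.otsu(as.numeric(vol))
  truth <- array(c(rep(FALSE, 4000), rep(TRUE, 4000)), c(20, 20, 20))
  expect_gt(mean((vol > thr) == truth), 0.999)
})

test_that("action-area masking applies the quadratic taper w(d) = 1 - (d/R)^2", {
  # cell: one voxel block; anchors placed around it with a uniform vector
  occ <- array(FALSE, c(15, 15, 15)); occ[7:9, 7:9, 7:9] <- TRUE
  mask <- voxel_mask(occ, 1)
  vm <- voxelize(mask, c(15, 15, 15))
  anchors <- rbind(c(4, 7.5, 7.5), c(11, 7.5, 7.5), c(7.5, 4, 7.5),
                   c(7.5, 11, 7.5), c(7.5, 7.5, 4), c(7.5, 7.5, 11))
  sparse <- structure(list(anchors = anchors,
                           vectors = matrix(rep(c(1, 0, 0), 6), ncol = 3,
                                            byrow = TRUE),
                           match_residual = rep(0, 6),
                           reliable = rep(TRUE, 6)),
                      class = "sparse_displacements")
  u <- build_displacement_field(sparse, mask, vm, action_radius = 10,
                                support_radius = 30)
  d <- attr(u, "surface_distance")
  nodes <- tfm3d:::.grid_nodes(vm)
  # beyond the frontier: identically zero
  expect_true(all(u[d > 10, ] == 0))
  # inside: x-component equals the taper of the uniform unit field
  inside <- which(d <= 10 & d >= 0)
  expect_equal(u[inside, 1], 1 - (d[inside] / 10)^2, tolerance = 1e-9)
  expect_equal(max(abs(u[, 2:3])), 0)
  # w(0) = 1 at the surface, continuous decay to w(10) = 0
  expect_equal(max(u[, 1]), max(1 - (d[d >= 0] / 10)^2), tolerance = 1e-9)
})

test_that("displacement field interpolation needs enough non-coplanar anchors", {
  occ <- array(FALSE, c(9, 9, 9)); occ[5, 5, 5] <- TRUE
  mask <- voxel_mask(occ, 1)
  vm <- voxelize(mask, c(9, 9, 9))
  flat <- structure(list(anchors = rbind(c(2, 2, 5), c(6, 2, 5), c(2, 6, 5),
                                         c(6, 6, 5)),
                         vectors = matrix(0, 4, 3),
                         match_residual = rep(0, 4),
                         reliable = rep(TRUE, 4)),
                    class = "sparse_displacements")
  expect_error(build_displacement_field(flat, mask, vm), "coplanar")
})
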