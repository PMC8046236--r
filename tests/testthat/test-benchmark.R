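# Synthetic benchmark generators: determinism, trivial cases, geometry, and
# the bead-pair construction contracts.

test_that("zero patches give zero tractions and zero displacements", {
  bp <- make_sphere_benchmark(radius = 15, box_dims = c(60, 60, 60),
                              n_patches = 0, element_size = 7.5, seed = 3)
  expect_equal(max(abs(bp$tractions$vectors)), 0)
  expect_equal(max(abs(bp$displacements)), 0)
  expect_equal(max(abs(bp$u_real)), 0)
})

test_that("identical seeds give identical problems, different seeds differ", {
  a <- make_sphere_benchmark(radius = 15, box_dims = c(60, 60, 60),
                             n_patches = 4, force_scale = 500,
                             element_size = 7.5, seed = 11, solve = FALSE)
  b <- make_sphere_benchmark(radius = 15, box_dims = c(60, 60, 60),
                             n_patches = 4, force_scale = 500,
                             element_size = 7.5, seed = 11, solve = FALSE)
  expect_identical(a$tractions$vectors, b$tractions$vectors)
  expect_identical(a$mesh$nodes, b$mesh$nodes)
  c3 <- make_sphere_benchmark(radius = 15, box_dims = c(60, 60, 60),
                              n_patches = 4, force_scale = 500,
                              element_size = 7.5, seed = 12, solve = FALSE)
  expect_false(isTRUE(all.equal(a$tractions$vectors, c3$tractions$vectors)))
})

test_that("the generator does not disturb the global RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(make_sphere_benchmark(radius = 15, box_dims = c(60, 60, 60),
                                  n_patches = 2, element_size = 7.5,
                                  seed = 5, solve = FALSE))
  expect_identical(runif(1), before)
})

test_that("benchmark geometry: spherical interface, constrained prism, patch areas", {
  bp <- make_sphere_benchmark(radius = 15, box_dims = c(60, 60, 60),
                              n_patches = 3, force_scale = 500,
                              element_size = 7.5, seed = 2, solve = FALSE)
  m <- bp$mesh
  rr <- sqrt(rowSums(sweep(m$nodes[m$gamma_nodes, ], 2, c(30, 30, 30))^2))
  expect_equal(rr, rep(15, length(rr)), tolerance = 1e-9)
  # tractions zero outside the designated patches
  on_patch <- unique(unlist(lapply(bp$patches, `[[`, "node_ids")))
  off <- setdiff(m$gamma_nodes, on_patch)
  idx <- match(off, bp$tractions$node_ids)
  expect_equal(max(abs(bp$tractions$vectors[idx, ])), 0)
  # nN force / patch area (um^2) = kPa traction
  p <- bp$patches[[1]]
  expect_equal(p$traction, p$force / p$area, tolerance = 1e-12)
  expect_error(make_sphere_benchmark(radius = 40, box_dims = c(60, 60, 60)),
               "radius")
})

test_that("direct solve with load stepping reaches displacements comparable to the radius", {
  bp <- make_sphere_benchmark(seed = 1)
  maxu <- max(sqrt(rowSums(bp$displacements^2)))
  expect_true(bp$direct_converged)
  expect_gt(maxu / bp$radius, 0.3)
  # u_real follows the deformed-to-relaxed convention
  expect_equal(bp$u_real, -bp$displacements)
  expect_equal(bp$deformed_mesh$nodes, bp$mesh$nodes + bp$displacements)
})

test_that("bead pair: zero warp gives identical stacks; integer warp translates", {
  p0 <- make_bead_stack_pair(c(32, 32, 32), 0.63, n_beads = 12, seed = 7)
  expect_identical(p0$deformed$intensities, p0$relaxed$intensities)
  expect_equal(max(abs(as.matrix(p0$truth[, c("ux_um", "uy_um", "uz_um")]))), 0)
  # uniform integer voxel shift: stack1 equals stack2 translated inside the
  # valid region
  s <- c(2, 1, 0)
  p <- make_bead_stack_pair(c(32, 32, 32), 1, n_beads = 12,
                            warp = s, seed = 7)
  d <- dim(p$deformed$intensities)
  v1 <- p$deformed$intensities[1:(d[1] - 2), 1:(d[2] - 1), ]
  v2 <- p$relaxed$intensities[3:d[1], 2:d[2], ]
  expect_equal(v1, v2, tolerance = 1e-10)
  # recorded truth equals the warp
  expect_equal(as.matrix(p$truth[, c("ux_um", "uy_um", "uz_um")]),
               matrix(rep(s, each = 12), ncol = 3), ignore_attr = TRUE)
})

test_that("benchmark export writes mesh, node table and metadata", {
  bp <- make_sphere_benchmark(radius = 15, box_dims = c(60, 60, 60),
                              n_patches = 2, element_size = 7.5, seed = 6,
                              solve = FALSE)
  d <- file.path(tempdir(), "bench_export")
  export_benchmark(bp, d)
  expect_true(all(file.exists(file.path(
    d, c("benchmark.vtu", "benchmark_nodes.csv", "benchmark.json")))))
  meta <- jsonlite::read_json(file.path(d, "benchmark.json"))
  expect_equal(meta$seed, 6)
  expect_equal(meta$material$C10, 20)
  df <- read.csv(file.path(d, "benchmark_nodes.csv"))
  expect_equal(nrow(df), nrow(bp$mesh$nodes))
  unlink(d, recursive = TRUE)
})

test_that("bead pair records subpixel truth and validates feasibility", {
  vs <- 0.63
  p <- make_bead_stack_pair(c(32, 32, 32), vs, n_beads = 5,
                            warp = c(0.4 * vs, 0, 0), seed = 3)
  expect_equal(p$truth$ux_um, rep(0.4 * vs, 5))
  expect_error(
    make_bead_stack_pair(c(16, 16, 16), vs, n_beads = 500, seed = 1),
    "infeasible")
  expect_error(
    make_bead_stack_pair(c(32, 32, 32), vs, n_beads = 3,
                         warp = c(50, 0, 0), seed = 1),
    "outside")
})

test_that("benchmark direct solve conserves energy against external work", {
  # quasi-static external work along the load path approximates the stored
  # strain energy (checked in the near-linear regime where work = W = U)
  bp <- make_sphere_benchmark(radius = 15, box_dims = c(60, 60, 60),
                              n_patches = 2, force_scale = 100,
                              element_size = 7.5, seed = 4)
  sol <- bp$direct_result
  # linear regime: external work = 1/2 f.u; energy must match within a few %
  W <- 0.5 * sum(sol$fext * sol$displacements)
  expect_lt(abs(W - sol$energy) / W, 0.05)
})
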