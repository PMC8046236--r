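# Voxelization, Kuhn tetrahedralization, interface extraction, quality
# maintenance and field transfer.

test_that("a single voxel splits into 6 tets conserving its volume exactly", {
  occ <- array(TRUE, c(1, 1, 1))
  vm <- structure(list(cell = occ, voxel_size = rep(2, 3), origin = c(0, 0, 0)),
                  class = "voxel_mesh")
  m <- tetrahedralize(vm)
  expect_equal(nrow(m$tets), 6)
  expect_equal(sum(mesh_quality(m)$volume), 8, tolerance = 1e-12)
})

test_that("voxelize centres the mask and labels the complement as ECM", {
  occ <- array(FALSE, c(3, 3, 3)); occ[2, 2, 2] <- TRUE
  vm <- voxelize(voxel_mask(occ, 10), c(30, 30, 30))
  expect_equal(sum(vm$cell), 1)
  expect_true(vm$cell[2, 2, 2])
  m <- tetrahedralize(vm)
  expect_equal(sum(m$domain == 1), 6)
  expect_equal(sum(m$domain == 2), 26 * 6)
  # the embedded voxel exposes 6 faces = 12 interface triangles
  expect_equal(nrow(m$gamma_s), 12)
  expect_error(voxelize(voxel_mask(array(FALSE, c(2, 2, 2)), 1), c(4, 4, 4)),
               "empty")
  expect_error(voxelize(voxel_mask(array(TRUE, c(4, 4, 4)), 1), c(4, 4, 4)),
               "margin")
})

test_that("paper-scale grid dimensions come out as round(box / voxel)", {
  occ <- array(FALSE, c(3, 3, 3)); occ[2, 2, 2] <- TRUE
  vm <- voxelize(voxel_mask(occ, 0.63), c(102, 102, 30))
  expect_equal(dim(vm$cell), as.integer(round(c(102, 102, 30) / 0.63)))
})

test_that("sphere mask volume is conserved through tetrahedralization", {
  n <- 13; r <- 5.2
  cx <- (seq_len(n) - (n + 1) / 2)
  occ <- array(outer(outer(cx^2, cx^2, `+`), cx^2, `+`) <= r^2, c(n, n, n))
  vm <- voxelize(voxel_mask(occ, 1), c(n + 4, n + 4, n + 4))
  m <- tetrahedralize(vm)
  vox_vol <- sum(occ) * 1
  tet_vol <- sum(mesh_quality(m)$volume[m$domain == 1])
  expect_lt(abs(tet_vol - vox_vol) / vox_vol, 0.005)
  # all signed volumes positive; Kuhn quality within the default bound
  q <- mesh_quality(m)
  expect_true(all(q$volume > 0))
  expect_lte(max(q$radius_edge), 1.5)
})

test_that("interface triangles are oriented from cell into ECM", {
  m <- box_mesh(c(3, 3, 3), h = 10, cell_at = c(2, 2, 2))
  g <- m$gamma_s; X <- m$nodes
  cell_ctr <- colMeans(X[unique(as.vector(m$tets[m$domain == 1, ])), ])
  for (r in seq_len(nrow(g))) {
    e1 <- X[g[r, 2], ] - X[g[r, 1], ]
    e2 <- X[g[r, 3], ] - X[g[r, 1], ]
    nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
             e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])
    expect_gt(sum(nrm * (colMeans(X[g[r, ], ]) - cell_ctr)), 0)
  }
})

test_that("remesh is the identity on clean configurations and preserves rigid motion", {
  m <- box_mesh(c(2, 2, 2), h = 5)
  m2 <- remesh(m, m$nodes)
  expect_equal(m2$nodes, m$nodes)
  expect_equal(m2$tets, m$tets)
  shift <- matrix(rep(c(3, -2, 7), each = nrow(m$nodes)), ncol = 3)
  m3 <- remesh(m, m$nodes + shift)
  expect_equal(m3$nodes, m$nodes + shift)
  expect_equal(m3$tets, m$tets)
  # inverted configuration is rejected
  bad <- m$nodes; bad[, 1] <- -bad[, 1]
  expect_error(remesh(m, bad), "inverted")
})

test_that("remesh smoothing restores the quality bound after distortion", {
  m <- box_mesh(c(4, 4, 4), h = 5)
  set.seed(2)
  X <- m$nodes
  fixed <- union(m$gamma_nodes, m$outer_nodes)
  free <- setdiff(seq_len(nrow(X)), fixed)
  X[free, ] <- X[free, ] + matrix(runif(3 * length(free), -1.0, 1.0),
                                  ncol = 3)
  expect_gt(max(mesh_quality(m, X)$radius_edge), 1.5)
  ms <- remesh(m, X, quality = 1.5, max_passes = 50)
  expect_lte(max(mesh_quality(ms)$radius_edge), 1.5)
  # interface geometry untouched
  expect_equal(ms$nodes[m$gamma_nodes, ], m$nodes[m$gamma_nodes, ])
})

test_that("transfer_field reproduces node fields exactly on identical meshes", {
  m <- box_mesh(c(3, 3, 3), h = 4)
  set.seed(5)
  f <- matrix(rnorm(3 * nrow(m$nodes)), ncol = 3)
  out <- transfer_field(m, m, f)
  expect_equal(unname(out[, 1:3]), f, tolerance = 1e-10)
})

test_that("transfer_field reproduces affine fields exactly across different meshes", {
  src <- box_mesh(c(3, 3, 3), h = 4)
  dst <- box_mesh(c(4, 4, 4), h = 2.2, box = c(14, 14, 14))
  # keep dst inside src's domain
  dst <- remesh(dst, sweep(dst$nodes * 0.8, 2, c(2, 2, 2), `+`))
  A <- matrix(c(0.2, -0.1, 0.05, 0.3, 0.4, -0.2, 0, 0.1, -0.3), 3)
  cvec <- c(1, -2, 0.5)
  f_src <- src$nodes %*% t(A) + rep(cvec, each = nrow(src$nodes))
  out <- transfer_field(src, dst, f_src)
  f_dst <- dst$nodes %*% t(A) + rep(cvec, each = nrow(dst$nodes))
  expect_equal(unname(out[, 1:3]), f_dst, tolerance = 1e-9)
  expect_equal(attr(out, "n_extrapolated"), 0)
})

test_that("element fields transfer through volume-weighted node projection", {
  m <- box_mesh(c(3, 3, 3), h = 4)
  # constant element field must transfer as the same constant
  ef <- matrix(2.5, nrow(m$tets), 1)
  out <- transfer_field(m, m, ef, what = "element")
  expect_equal(as.numeric(out), rep(2.5, nrow(m$nodes)), tolerance = 1e-12)
  # refinement: interpolation error of a smooth element field shrinks
  err_at <- function(h) {
    mh <- box_mesh(c(6, 6, 6), h = h, box = c(12, 12, 12))
    ctr <- t(vapply(seq_len(nrow(mh$tets)), function(e)
      colMeans(mh$nodes[mh$tets[e, ], ]), numeric(3)))
    ef <- matrix(sin(ctr[, 1] / 2) * cos(ctr[, 2] / 2), ncol = 1)
    probe <- matrix(c(5, 5, 5, 4, 6, 5, 6, 4, 4), ncol = 3, byrow = TRUE)
    got <- transfer_field(mh, probe, ef, what = "element")
    truth <- sin(probe[, 1] / 2) * cos(probe[, 2] / 2)
    max(abs(got - truth))
  }
  expect_lt(err_at(1), err_at(2))
})
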