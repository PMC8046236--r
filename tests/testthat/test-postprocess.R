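# Log-strain accumulation, stress reconstruction and surface traction
# evaluation, plus result export.

test_that("stress from log strain matches closed forms and the constitutive law", {
  mat <- neo_hookean()
  expect_equal(stress_from_log_strain(matrix(0, 3, 3), mat), matrix(0, 3, 3))
  # logV = ln(2) I: b = 4I, J = 8, bbar = I
  sig <- stress_from_log_strain(log(2) * diag(3), mat)
  expect_equal(sig, 2800 * diag(3), tolerance = 1e-9)
  # rotation-free states: must equal cauchy_stress at F = exp(logV)
  set.seed(13)
  for (i in 1:10) {
    S <- matrix(rnorm(9, 0, 0.2), 3); S <- (S + t(S)) / 2
    e <- eigen(S, symmetric = TRUE)
    F <- e$vectors %*% diag(exp(e$values)) %*% t(e$vectors)
    expect_equal(stress_from_log_strain(S, mat),
                 cauchy_stress(def_state(F), mat), tolerance = 1e-8)
  }
  expect_error(stress_from_log_strain(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3), mat),
               "symmetric")
})

test_that("coaxial stretches accumulate additively; non-coaxial ones are flagged by the gap", {
  lam <- 1.3
  F1 <- diag(c(lam, 1, 1))
  # two identical uniform stretches: total = 2 ln(lam) on the axis, exactly
  expect_equal(log_strain_additivity_gap(F1, F1), 0, tolerance = 1e-12)
  added <- def_state(F1)$logV + def_state(F1)$logV
  expect_equal(added, def_state(F1 %*% F1)$logV, tolerance = 1e-10)
  # non-coaxial: additive total differs from the exact composed strain
  th <- 0.5
  Q <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  F2 <- Q %*% diag(c(1, 1.4, 1)) %*% t(Q)
  gap <- log_strain_additivity_gap(F1, F2)
  expect_gt(gap, 1e-4)
  # exact oracle: polar decomposition of the composed motion
  exact <- def_state(F2 %*% F1)$logV
  expect_equal(norm(exact - (def_state(F1)$logV + def_state(F2)$logV), "F"),
               gap)
})

test_that("accumulate_log_strains sums element histories onto the final mesh", {
  m <- box_mesh(c(3, 3, 3), h = 4, cell_at = c(2, 2, 2))
  lv <- matrix(0, nrow(m$tets), 6)
  lv[, 1] <- log(1.2)  # uniform diag(ln 1.2, 0, 0)
  one <- accumulate_log_strains(list(list(mesh = m, logV = lv)), m)
  expect_equal(one, matrix(rep(c(log(1.2), 0, 0, 0, 0, 0),
                               each = nrow(m$nodes)), ncol = 6),
               tolerance = 1e-10, ignore_attr = TRUE)
  two <- accumulate_log_strains(list(list(mesh = m, logV = lv),
                                     list(mesh = m, logV = lv)), m)
  expect_equal(two[, 1], rep(2 * log(1.2), nrow(m$nodes)), tolerance = 1e-10)
  expect_error(accumulate_log_strains(list(), m), "empty")
})

test_that("hydrostatic nodal stress produces tractions along the normals", {
  # 2x2x2-voxel cell block: its surface has face-centre nodes with
  # axis-aligned normals
  occ <- array(FALSE, c(4, 4, 4)); occ[2:3, 2:3, 2:3] <- TRUE
  m <- tetrahedralize(voxelize(voxel_mask(occ, 5), c(30, 30, 30)))
  p <- 3.5
  sigma <- matrix(rep(c(-p, -p, -p, 0, 0, 0), each = nrow(m$nodes)), ncol = 6)
  tf <- surface_traction(sigma, m)
  nrm <- tfm3d:::.gamma_node_normals(m, m$nodes)
  expect_equal(tf$vectors, -p * nrm, tolerance = 1e-12, ignore_attr = TRUE)
  # t . n = sigma_nn for every node
  expect_equal(unname(rowSums(tf$vectors * nrm)),
               rep(-p, length(m$gamma_nodes)), tolerance = 1e-12)
  # pure 12-shear at a face-centre node with n = e3: traction is zero there
  # (the shear plane contains the normal), i.e. purely tangential stresses
  # produce no normal-face load
  sigma2 <- matrix(rep(c(0, 0, 0, 2, 0, 0), each = nrow(m$nodes)), ncol = 6)
  tf2 <- surface_traction(sigma2, m)
  i <- which(abs(abs(nrm[, 3]) - 1) < 1e-9)[1]
  expect_false(is.na(i))
  expect_equal(as.numeric(tf2$vectors[i, ]), c(0, 0, 0), tolerance = 1e-12)
  # and at a node with n = e1 the same shear gives a tangential traction
  j <- which(abs(abs(nrm[, 1]) - 1) < 1e-9)[1]
  tj <- as.numeric(tf2$vectors[j, ])
  expect_equal(tj[1], 0, tolerance = 1e-12)  # no normal component
  expect_gt(abs(tj[2]), 0)
})

test_that("gridded fields export as VTK ImageData", {
  occ <- array(FALSE, c(3, 3, 3)); occ[2, 2, 2] <- TRUE
  vm <- voxelize(voxel_mask(occ, 2), c(6, 6, 6))
  n <- prod(dim(vm$cell) + 1L)
  f <- file.path(tempdir(), "field.vti")
  write_vti(f, vm, point_data = list(u = matrix(1.5, n, 3)))
  doc <- readLines(f)
  expect_true(any(grepl("ImageData", doc)))
  expect_true(any(grepl('Name="u"', doc)))
  expect_true(any(grepl('Spacing="2 2 2"', doc)))
  unlink(f)
})

test_that("export writes loadable artifacts with stable names, deterministically", {
  m <- box_mesh(c(3, 3, 3), h = 5, cell_at = c(2, 2, 2))
  st <- run_inverse(m, matrix(0, nrow(m$nodes), 3), neo_hookean())
  dir1 <- file.path(tempdir(), "run1")
  dir2 <- file.path(tempdir(), "run2")
  export_results(st, st$traction_estimate, dir1)
  export_results(st, st$traction_estimate, dir2)
  for (f in c("volume.vtu", "surface.vtp", "summary.csv", "run.json"))
    expect_true(file.exists(file.path(dir1, f)))
  # VTU is well-formed XML with the documented field names
  doc <- readLines(file.path(dir1, "volume.vtu"))
  expect_true(any(grepl('Name="u_real"', doc)))
  expect_true(any(grepl('Name="u_computed"', doc)))
  expect_true(any(grepl('Name="err"', doc)))
  expect_true(any(grepl('Name="traction"',
                        readLines(file.path(dir1, "surface.vtp")))))
  # identical state exports byte-identical summaries
  expect_identical(readLines(file.path(dir1, "summary.csv")),
                   readLines(file.path(dir2, "summary.csv")))
  unlink(c(dir1, dir2), recursive = TRUE)
})
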