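# Finite-strain FE engine: trivial fixed points, patch test, objectivity,
# the uniaxial analytic oracle, force balance and the reaction-to-traction
# conversion.

test_that("zero prescribed displacement yields zero displacement and reactions", {
  m <- box_mesh(c(2, 2, 2), h = 5)
  mat <- neo_hookean()
  pres <- matrix(NA_real_, nrow(m$nodes), 3)
  pres[m$outer_nodes, ] <- 0
  sol <- solve_dirichlet(m, mat, pres)
  expect_true(sol$converged)
  expect_equal(max(abs(sol$displacements)), 0)
  expect_equal(max(abs(sol$reactions)), 0)
})

test_that("rigid translation of the whole boundary transports the body force-free", {
  m <- box_mesh(c(2, 2, 2), h = 5)
  mat <- neo_hookean()
  shift <- c(1.5, -0.7, 2.1)
  pres <- matrix(NA_real_, nrow(m$nodes), 3)
  pres[m$outer_nodes, ] <- rep(shift, each = length(m$outer_nodes))
  sol <- solve_dirichlet(m, mat, pres)
  expect_true(sol$converged)
  expect_equal(sol$displacements,
               matrix(rep(shift, each = nrow(m$nodes)), ncol = 3),
               tolerance = 1e-7)
  expect_lt(max(abs(sol$reactions)), 1e-4)
})

test_that("patch test: affine boundary data reproduce the homogeneous state exactly", {
  m <- box_mesh(c(2, 2, 2), h = 5)
  mat <- neo_hookean()
  A <- matrix(c(0.05, 0.02, 0, 0.01, -0.03, 0.005, 0, 0.02, 0.04), 3,
              byrow = TRUE)
  pres <- matrix(NA_real_, nrow(m$nodes), 3)
  pres[m$outer_nodes, ] <- m$nodes[m$outer_nodes, ] %*% t(A)
  sol <- solve_dirichlet(m, mat, pres)
  expect_true(sol$converged)
  expect_equal(sol$displacements, m$nodes %*% t(A), tolerance = 1e-9)
  # homogeneous deformation: every element carries the same F
  Fs <- sol$states$F
  expect_equal(Fs[, , 1], diag(3) + A, tolerance = 1e-9)
  expect_lt(max(abs(sweep(Fs, c(1, 2), Fs[, , 1]))), 1e-9)
})

test_that("global force balance holds in every converged solve", {
  m <- box_mesh(c(3, 3, 3), h = 5, cell_at = c(2, 2, 2))
  mat <- neo_hookean()
  # Dirichlet stretch
  pres <- matrix(NA_real_, nrow(m$nodes), 3)
  pres[m$outer_nodes, ] <- 0
  pres[m$outer_nodes, 1] <- 0.08 * m$nodes[m$outer_nodes, 1]
  sol <- solve_dirichlet(m, mat, pres)
  expect_true(sol$converged)
  expect_lt(max(abs(colSums(sol$reactions))), 1e-5)
  # Neumann traction patch on the interface
  gn <- m$gamma_nodes
  tv <- matrix(0, length(gn), 3); tv[, 1] <- 2
  sol2 <- solve_neumann(m, mat, traction_field(gn, tv))
  expect_true(sol2$converged)
  bal <- colSums(sol2$reactions) + colSums(sol2$fext)
  expect_lt(max(abs(bal)), 1e-5)
})

test_that("uniaxial bar matches the homogeneous Neo-Hookean solution within 1%", {
  mat <- neo_hookean()
  lam <- 1.5
  m <- solid_block_mesh(c(8, 4, 4), h = 0.5)  # 4 x 2 x 2 bar
  X <- m$nodes
  L <- max(X[, 1])
  left <- which(abs(X[, 1]) < 1e-9)
  right <- which(abs(X[, 1] - L) < 1e-9)
  pres <- matrix(NA_real_, nrow(X), 3)
  # sliding supports: only axial displacement prescribed on the end faces;
  # one corner pinned laterally to remove rigid modes
  pres[left, 1] <- 0
  pres[right, 1] <- (lam - 1) * L
  corner <- which(rowSums(abs(X)) < 1e-9)
  pres[corner, 2:3] <- 0
  drv <- which(abs(X[, 1]) < 1e-9 & abs(X[, 2]) < 1e-9)
  far <- drv[which.max(X[drv, 3])]
  pres[far, 2] <- 0
  sol <- solve_dirichlet(m, mat, pres)
  expect_true(sol$converged)
  oracle <- uniaxial_oracle(lam, mat)
  # deformation should be homogeneous: compare element Cauchy stress
  sig11 <- vapply(seq_len(nrow(m$tets)), function(e)
    cauchy_stress(def_state(sol$states$F[, , e]), mat)[1, 1], 0)
  expect_lt(max(abs(sig11 - oracle$sigma[1, 1])) /
            max(abs(oracle$sigma[1, 1]), 1), 0.01)
  # lateral contraction matches the oracle stretch
  width <- max(sol$displacements[, 2] + X[, 2])
  expect_equal(width / max(X[, 2]), oracle$lam_lat, tolerance = 0.01)
})

test_that("superposed rigid rotation rotates the stress objectively", {
  mat <- neo_hookean()
  set.seed(9)
  F <- random_F()
  th <- 0.7
  Q <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  s1 <- cauchy_stress(def_state(F), mat)
  s2 <- cauchy_stress(def_state(Q %*% F), mat)
  expect_equal(s2, Q %*% s1 %*% t(Q), tolerance = 1e-10)
})

test_that("traction-driven solves are linear in the load for small loads", {
  m <- box_mesh(c(3, 3, 3), h = 5, cell_at = c(2, 2, 2))
  mat <- neo_hookean()
  gn <- m$gamma_nodes
  tv <- matrix(0, length(gn), 3)
  tv[, 2] <- 0.05  # kPa, strains well below 0.5%
  u1 <- solve_neumann(m, mat, traction_field(gn, tv))$displacements
  u2 <- solve_neumann(m, mat, traction_field(gn, 2 * tv))$displacements
  expect_lt(rel_l2(u2, 2 * u1), 0.01)
  # zero tractions: zero displacement
  u0 <- solve_neumann(m, mat, traction_field(gn, 0 * tv))$displacements
  expect_equal(max(abs(u0)), 0)
})

test_that("reactions convert to tractions by tributary area with flipped sign", {
  m <- box_mesh(c(3, 3, 3), h = 5, cell_at = c(2, 2, 2))
  mat <- neo_hookean()
  gn <- m$gamma_nodes
  # zero reactions give zero tractions
  zero <- matrix(0, nrow(m$nodes), 3)
  res0 <- list(displacements = zero, reactions = zero, mesh = m)
  t0 <- reactions_to_tractions(res0, m)
  expect_equal(max(abs(t0$vectors)), 0)
  # reactions distributed as -t * tributary area reproduce the traction t
  A <- tfm3d:::.gamma_node_areas(m, m$nodes)
  t_target <- c(1.5, -0.5, 2)
  reac <- zero
  reac[gn, ] <- -outer(as.numeric(A[as.character(gn)]), t_target)
  res <- list(displacements = zero, reactions = reac, mesh = m)
  tf <- reactions_to_tractions(res, m)
  expect_equal(tf$vectors,
               matrix(rep(t_target, each = length(gn)), ncol = 3),
               tolerance = 1e-12)
  # interior nodes of a flat cube face carry |t| = R_total / A_face when the
  # total normal force is spread by area
  face_area <- 5 * 5  # one voxel face
  expect_equal(sum(A), 6 * face_area, tolerance = 1e-12)
})
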