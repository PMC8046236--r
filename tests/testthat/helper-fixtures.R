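# Shared fixtures: tiny meshes and oracle helpers, all built in code.

# solid box of nx x ny x nz voxels of pitch h, entire box = single domain
# (domain 2 everywhere unless cell_at is given as a voxel index triple)
box_mesh <- function(nv = c(2, 2, 2), h = 5, cell_at = NULL, box = NULL) {
  occ <- array(FALSE, nv)
  if (is.null(cell_at)) occ[1, 1, 1] <- TRUE else occ[matrix(cell_at, 1)] <- TRUE
  if (is.null(box)) box <- (nv + 2) * h
  tetrahedralize(voxelize(voxel_mask(occ, h), box))
}

# mesh of a solid block (no embedded cell): direct grid without voxelize
solid_block_mesh <- function(nv = c(4, 2, 2), h = 1) {
  vm <- structure(list(cell = array(FALSE, nv), voxel_size = rep(h, 3),
                       origin = c(0, 0, 0)), class = "voxel_mesh")
  vm$cell[1, 1, 1] <- TRUE  # one token cell voxel so gamma_s is nonempty
  tetrahedralize(vm)
}

# random deformation gradient with safely positive J
random_F <- function(spread = 0.25) {
  repeat {
    F <- diag(3) + matrix(stats::rnorm(9, 0, spread), 3)
    if (det(F) > 0.2) return(F)
  }
}

# independent finite-difference oracle: Cauchy stress as the push-forward of
# 2 dPsi/dC, differentiating the energy with unconstrained entry
# perturbations of C
fd_cauchy_stress <- function(F, mat, h = 1e-6) {
  psiC <- function(C) {
    J <- sqrt(det(C)); I1 <- sum(diag(C))
    mat$C10 * (J^(-2 / 3) * I1 - 3) + (1 / mat$D1) * (J - 1)^2
  }
  C <- t(F) %*% F
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Cp <- C; Cm <- C
    Cp[i, j] <- Cp[i, j] + h
    Cm[i, j] <- Cm[i, j] - h
    S[i, j] <- 2 * (psiC(Cp) - psiC(Cm)) / (2 * h)
  }
  S <- (S + t(S)) / 2
  F %*% S %*% t(F) / det(F)
}

# homogeneous uniaxial Neo-Hookean solution: given axial stretch lam_ax,
# find the lateral stretch making lateral Cauchy stress vanish, via 1-D
# root finding on the package's own constitutive law
uniaxial_oracle <- function(lam_ax, mat) {
  lat_stress <- function(lam_lat) {
    F <- diag(c(lam_ax, lam_lat, lam_lat))
    cauchy_stress(def_state(F), mat)[2, 2]
  }
  lam_lat <- stats::uniroot(lat_stress, c(0.3, 3), tol = 1e-12)$root
  F <- diag(c(lam_ax, lam_lat, lam_lat))
  list(F = F, sigma = cauchy_stress(def_state(F), mat), lam_lat = lam_lat)
}

# synthetic single-Gaussian-bead stack; centre in continuous 1-based voxel
# units, peak 100
gauss_bead_stack <- function(dims = c(24, 24, 24), centre = dims / 2,
                             sigma = 1.2, voxel_size = 0.63) {
  gx <- exp(-((seq_len(dims[1]) - centre[1])^2) / (2 * sigma^2))
  gy <- exp(-((seq_len(dims[2]) - centre[2])^2) / (2 * sigma^2))
  gz <- exp(-((seq_len(dims[3]) - centre[3])^2) / (2 * sigma^2))
  vol <- 100 * outer(outer(gx, gy), gz)
  image_stack(vol, voxel_size, channel = "beads")
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
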