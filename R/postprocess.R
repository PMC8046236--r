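# Merge the per-iteration deformation history into final-configuration
# logarithmic strains, recover stresses, and emit surface tractions.

.voigt_to_mat <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}
.mat_to_voigt <- function(m) c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])

#' Accumulate logarithmic strains across configurations
#'
#' Each iteration of the inverse solver deforms a different configuration; to
#' express the total deformation on the final mesh, the per-iteration Hencky
#' strain fields are transferred onto the final mesh (element values first
#' projected to nodes, then interpolated) and summed tensor-componentwise.
#' The additive treatment is exact for coaxial stretch sequences; for
#' non-coaxial histories it is a first-order approximation whose gap is the
#' commutator term quantified by [log_strain_additivity_gap()].
#'
#' @param history list of records `list(mesh=, logV=)` (per-element strain in
#'   Voigt order 11,22,33,12,13,23 on its source mesh), as accumulated in
#'   `inverse_state$logV_history`.
#' @param final_mesh the [tet_mesh()] to express the total strain on.
#' @param side elements used when projecting integration-point strains to
#'   nodes: both domains, or only the cell / ECM side of the interface
#'   (needed to evaluate the interface stress jump).
#' @return N x 6 matrix of nodal accumulated log strains.
#' @export
accumulate_log_strains <- function(history, final_mesh,
                                   side = c("all", "cell", "ecm")) {
  side <- match.arg(side)
  if (length(history) == 0) stop("accumulate_log_strains: empty history")
  total <- matrix(0, nrow(final_mesh$nodes), 6)
  for (rec in history) {
    keep <- switch(side, all = NULL, cell = rec$mesh$domain == 1L,
                   ecm = rec$mesh$domain == 2L)
    total <- total + transfer_field(rec$mesh, final_mesh, rec$logV,
                                    what = "element", elements = keep)
  }
  total
}

#' Additivity gap of sequential log strains
#'
#' For two sequential deformation gradients the exact total Hencky strain is
#' `lnV(F2 F1)`, while the iterative scheme adds `lnV(F1) + lnV(F2)`; the two
#' agree exactly only for coaxial (commuting) stretches. Returns the
#' Frobenius norm of the difference, a per-case diagnostic of the additive
#' approximation.
#'
#' @param F1,F2 3x3 deformation gradients applied in that order.
#' @return Frobenius norm of `lnV(F2 F1) - (lnV(F2) + lnV(F1))`.
#' @export
log_strain_additivity_gap <- function(F1, F2) {
  exact <- def_state(F2 %*% F1)$logV
  added <- def_state(F1)$logV + def_state(F2)$logV
  norm(exact - added, "F")
}

#' Cauchy stress from accumulated logarithmic strain
#'
#' Reconstructs the kinematics from the Hencky strain (`b = exp(2 lnV)`,
#' `J = sqrt(det b)`, `bbar = J^(-2/3) b`) and evaluates the Neo-Hookean
#' Cauchy stress.
#'
#' @param logV a 3x3 symmetric tensor or an N x 6 matrix in Voigt order
#'   (11,22,33,12,13,23).
#' @param mat a [neo_hookean()] material.
#' @return Stress in the same layout as the input (3x3 matrix or N x 6), kPa.
#' @export
stress_from_log_strain <- function(logV, mat) {
  one <- function(L) {
    if (max(abs(L - t(L))) > 1e-8 * max(1, max(abs(L))))
      stop("stress_from_log_strain: logV must be symmetric")
    L <- (L + t(L)) / 2
    e <- eigen(L, symmetric = TRUE)
    b <- e$vectors %*% diag(exp(2 * e$values)) %*% t(e$vectors)
    J <- sqrt(det(b))
    bbar <- J^(-2 / 3) * b
    I1b <- sum(diag(bbar))
    (2 * mat$C10 / J) * (bbar - (I1b / 3) * diag(3)) +
      (2 / mat$D1) * (J - 1) * diag(3)
  }
  if (is.matrix(logV) && ncol(logV) == 6) {
    t(apply(logV, 1, function(v) .mat_to_voigt(one(.voigt_to_mat(v)))))
  } else {
    one(as.matrix(logV))
  }
}

#' Surface tractions from a nodal stress field
#'
#' Evaluates `t = sigma . n` on the interface nodes using area-weighted unit
#' nodal normals of the given configuration (normals point from the cell into
#' the ECM).
#'
#' @param sigma N x 6 nodal stress (Voigt) over all mesh nodes, kPa.
#' @param mesh the [tet_mesh()] carrying the interface.
#' @param X node coordinates of the configuration to evaluate normals in
#'   (default: the mesh's own).
#' @return A [traction_field()] with `nodal_stress` attached.
#' @export
surface_traction <- function(sigma, mesh, X = mesh$nodes) {
  stopifnot(nrow(sigma) == nrow(mesh$nodes), ncol(sigma) == 6)
  gn <- mesh$gamma_nodes
  nrm <- .gamma_node_normals(mesh, X)  # rows follow sorted gamma_nodes
  tv <- t(vapply(seq_along(gn), function(i)
    as.numeric(.voigt_to_mat(sigma[gn[i], ]) %*% nrm[i, ]), numeric(3)))
  traction_field(gn, tv, nodal_stress = sigma[gn, , drop = FALSE])
}

#' Recover the final cell-surface tractions from an inverse run
#'
#' Accumulates the logarithmic strains of all iterations on the final
#' configuration, evaluates the Neo-Hookean stress, and projects it onto the
#' interface normals. Because the per-iteration tractions act as surface
#' loads on the interface, the stress field is discontinuous across it; the
#' surface load is the discrete stress jump between the cell and ECM sides,
#' `t = (sigma_cell - sigma_ecm) . n`. The accumulated strain describes the
#' recovered deformed-to-relaxed walk, i.e. the release of the cell-induced
#' deformation, so the cell-exerted traction is the negated jump.
#'
#' @param state a converged (or best-effort) [run_inverse()] state.
#' @param mat the [neo_hookean()] material used in the run.
#' @param side `"jump"` (default) evaluates the cell/ECM stress jump;
#'   `"cell"`, `"ecm"` or `"all"` project a single-sided or mixed nodal
#'   stress instead.
#' @return A [traction_field()] on the final-configuration interface nodes,
#'   kPa.
#' @export
recover_tractions <- function(state, mat, side = c("jump", "cell", "ecm", "all")) {
  side <- match.arg(side)
  if (length(state$logV_history) == 0)
    stop("recover_tractions: state has no iteration history")
  if (side == "jump") {
    sig_c <- stress_from_log_strain(
      accumulate_log_strains(state$logV_history, state$mesh, "cell"), mat)
    sig_e <- stress_from_log_strain(
      accumulate_log_strains(state$logV_history, state$mesh, "ecm"), mat)
    tf <- surface_traction(sig_c - sig_e, state$mesh)
  } else {
    logV <- accumulate_log_strains(state$logV_history, state$mesh, side)
    tf <- surface_traction(stress_from_log_strain(logV, mat), state$mesh)
  }
  traction_field(tf$node_ids, -tf$vectors, nodal_stress = tf$nodal_stress)
}

#' Discretely consistent traction recovery
#'
#' Alternative recovery that bypasses the stress postprocessing: the
#' recovered relaxed configuration (initial nodes plus the total computed
#' displacement) is taken as the reference, the walk is reversed to give the
#' recovered cell-induced deformation, and the internal nodal forces of that
#' deformation are evaluated. At interior nodes they vanish by equilibrium;
#' on the interface they equal the applied surface load exactly, so dividing
#' by the tributary areas of the imaged (deformed) configuration yields a
#' traction estimate whose only error is the convergence error of the walk
#' itself. Used as the round-trip benchmark estimator; the
#' [recover_tractions()] log-strain route matches it in the limit of fine
#' meshes and coaxial deformation histories.
#'
#' @param state a finished [run_inverse()] state.
#' @param mat the [neo_hookean()] material used in the run.
#' @return A [traction_field()] on the interface nodes, kPa.
#' @export
recover_tractions_consistent <- function(state, mat) {
  mesh0 <- state$mesh0
  Xfinal <- mesh0$nodes + state$u_total   # recovered relaxed configuration
  a <- cpp_assemble(Xfinal, mesh0$tets, -state$u_total, mat$C10, mat$D1, FALSE)
  if (!a$ok)
    stop("recover_tractions_consistent: recovered deformation inverts elements")
  f <- .u_as_mat(a$fint)
  A <- .gamma_node_areas(mesh0, mesh0$nodes)
  gn <- mesh0$gamma_nodes
  tv <- f[gn, , drop = FALSE] / A[as.character(gn)]
  traction_field(gn, tv)
}
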