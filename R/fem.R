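#' Traction field on the cell surface
#'
#' Per-node traction vectors (kPa) on the cell-ECM interface of a mesh.
#'
#' @param node_ids integer ids of interface nodes carrying the vectors.
#' @param vectors n x 3 matrix of traction vectors, kPa.
#' @param nodal_stress optional n-list or n x 6 matrix of symmetric stress
#'   tensors (Voigt order 11,22,33,12,13,23), kPa.
#' @return Object of class `traction_field`.
#' @export
traction_field <- function(node_ids, vectors, nodal_stress = NULL) {
  vectors <- as.matrix(vectors)
  stopifnot(length(node_ids) == nrow(vectors), ncol(vectors) == 3)
  structure(list(node_ids = as.integer(node_ids), vectors = vectors,
                 nodal_stress = nodal_stress),
            class = "traction_field")
}

#' @export
print.traction_field <- function(x, ...) {
  mag <- sqrt(rowSums(x$vectors^2))
  cat(sprintf("traction_field: %d surface nodes, |t| max %.3g kPa, mean %.3g kPa\n",
              length(x$node_ids), max(mag, 0), mean(mag)))
  invisible(x)
}

# dof helpers: dof = 3*(node-1)+comp, u stored row-per-node
.u_as_vec <- function(u) as.vector(t(u))
.u_as_mat <- function(v) matrix(v, ncol = 3, byrow = TRUE)
.node_dofs <- function(nodes) as.vector(t(outer(3 * (nodes - 1L), 1:3, `+`)))

# Assemble internal force (and tangent) with a cached sparsity pattern kept in
# an environment attached to the mesh call site.
.assemble <- function(mesh, u, mat, want_K = FALSE, cache = NULL) {
  a <- cpp_assemble(mesh$nodes, mesh$tets, u, mat$C10, mat$D1, want_K)
  if (want_K && a$ok) {
    if (!is.null(cache) && !is.null(cache$K)) {
      K <- cache$K
      K@x <- cpp_slot_accumulate(cache$slots, a$tx, length(K@x))
    } else {
      n <- 3L * nrow(mesh$nodes)
      K <- Matrix::sparseMatrix(i = a$ti, j = a$tj, x = a$tx, dims = c(n, n))
      if (!is.null(cache)) {
        cache$K <- K
        cache$slots <- cpp_csc_slots(a$ti, a$tj, K@p, K@i)
      }
    }
    a$K <- K
  }
  a
}

# One Newton solve at fixed load factor. `u` is the 3N start vector with the
# prescribed dofs already set; returns list(u, converged, iters, rnorm).
.newton <- function(mesh, mat, u, free, fext_fun, lam, cache,
                    tol_rel = 1e-8, max_iter = 25) {
  N3 <- length(u)
  rnorm0 <- NULL
  history <- numeric(0)
  for (it in seq_len(max_iter)) {
    um <- .u_as_mat(u)
    a <- .assemble(mesh, um, mat, want_K = TRUE, cache = cache)
    if (!a$ok) return(list(u = u, converged = FALSE, iters = it,
                           rnorm = Inf, history = history))
    fext <- fext_fun(um, lam)
    r <- fext - a$fint
    rn <- sqrt(sum(r[free]^2))
    if (is.null(rnorm0)) rnorm0 <- max(rn, sqrt(sum(fext[free]^2)))
    history <- c(history, rn)
    ref <- max(rnorm0, 1e-12)
    if (rn <= tol_rel * ref || rn < 1e-12)
      return(list(u = u, converged = TRUE, iters = it, rnorm = rn,
                  history = history))
    # fail fast on divergence: residual exploding or no net progress
    if (rn > 1e3 * ref ||
        (it >= 6 && rn > 0.95 * history[it - 3]))
      return(list(u = u, converged = FALSE, iters = it, rnorm = rn,
                  history = history))
    Kff <- a$K[free, free, drop = FALSE]
    du <- .sparse_solve(Kff, r[free], cache)
    if (is.null(du)) return(list(u = u, converged = FALSE, iters = it,
                                 rnorm = rn, history = history))
    # backtracking line search on the residual norm
    step <- 1
    accepted <- FALSE
    for (ls in 1:10) {
      u_try <- u
      u_try[free] <- u[free] + step * du
      a2 <- cpp_assemble(mesh$nodes, mesh$tets, .u_as_mat(u_try),
                         mat$C10, mat$D1, FALSE)
      if (a2$ok) {
        r2 <- fext_fun(.u_as_mat(u_try), lam) - a2$fint
        rn2 <- sqrt(sum(r2[free]^2))
        if (rn2 <= (1 - 1e-4 * step) * rn || rn2 <= tol_rel * ref) {
          u <- u_try; accepted <- TRUE; break
        }
      }
      step <- step / 2
    }
    if (!accepted) {
      # line search exhausted: treat as Newton failure (continuation bisects)
      return(list(u = u, converged = FALSE, iters = it, rnorm = rn,
                  history = history))
    }
  }
  list(u = u, converged = FALSE, iters = max_iter, rnorm = rn, history = history)
}

# Sparse symmetric solve with cached CHOLMOD symbolic factor; LU fallback for
# indefinite tangents encountered mid-continuation.
.sparse_solve <- function(K, r, cache = NULL) {
  Ks <- Matrix::forceSymmetric(K)
  du <- tryCatch({
    if (!is.null(cache) && !is.null(cache$chol) &&
        isTRUE(cache$chol_dim == nrow(Ks))) {
      f <- Matrix::update(cache$chol, Ks)
    } else {
      f <- Matrix::Cholesky(Ks, LDL = FALSE, perm = TRUE, super = TRUE)
      if (!is.null(cache)) { cache$chol <- f; cache$chol_dim <- nrow(Ks) }
    }
    if (!is.null(cache)) cache$chol <- f
    as.numeric(Matrix::solve(f, r))
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(du)) {
    du <- tryCatch(as.numeric(Matrix::solve(as(K, "generalMatrix"), r)),
                   error = function(e) NULL)
  }
  du
}

# Incremental continuation driver: ramps prescribed displacements and external
# loads by a common factor lambda with automatic bisection on Newton failure.
.fem_continuation <- function(mesh, mat, fixed_dofs, fixed_vals, fext_fun,
                              tol_rel = 1e-8, max_iter = 25,
                              min_step = 1 / 256, verbose = FALSE,
                              cache = NULL, step0 = 1) {
  N3 <- 3L * nrow(mesh$nodes)
  free <- setdiff(seq_len(N3), fixed_dofs)
  u <- numeric(N3)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  lam_done <- 0
  step <- step0
  trace <- list()
  while (lam_done < 1 - 1e-12) {
    lam <- min(1, lam_done + step)
    u_try <- u
    u_try[fixed_dofs] <- lam * fixed_vals
    res <- .newton(mesh, mat, u_try, free, fext_fun, lam, cache,
                   tol_rel = tol_rel, max_iter = max_iter)
    if (res$converged) {
      u <- res$u
      lam_done <- lam
      trace[[length(trace) + 1]] <-
        data.frame(lambda = lam, iters = res$iters, rnorm = res$rnorm)
      tfm_msg(sprintf("  load step lambda=%.4f: %d Newton its, |r|=%.3e",
                      lam, res$iters, res$rnorm), verbose = verbose)
      step <- min(step * 2, 1 - lam_done)
      if (step == 0) break
    } else {
      step <- step / 2
      tfm_msg(sprintf("  load step to lambda=%.4f failed; bisecting to %.5f",
                      lam, step), verbose = verbose)
      if (step < min_step)
        return(list(u = u, converged = FALSE, lambda = lam_done,
                    trace = do.call(rbind, trace)))
    }
  }
  list(u = u, converged = TRUE, lambda = 1,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(lambda = numeric(0), iters = integer(0), rnorm = numeric(0)))
}

.finish_solve <- function(mesh, mat, u_vec, fixed_dofs, fext_vec, converged,
                          trace, lambda = 1) {
  um <- .u_as_mat(u_vec)
  a <- cpp_assemble(mesh$nodes, mesh$tets, um, mat$C10, mat$D1, FALSE)
  reac <- numeric(length(u_vec))
  reac[fixed_dofs] <- (a$fint - fext_vec)[fixed_dofs]
  states <- cpp_def_states(mesh$nodes, mesh$tets, um)
  structure(list(displacements = um, reactions = .u_as_mat(reac),
                 states = states, converged = converged, lambda = lambda,
                 newton_history = trace, energy = a$energy,
                 fext = .u_as_mat(fext_vec), mesh = mesh, material = mat),
            class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf("solve_result: %s, max |u| = %.4g um, energy = %.4g nN um\n",
              if (x$converged) "converged" else "NOT converged",
              max(sqrt(rowSums(x$displacements^2))), x$energy))
  invisible(x)
}

#' Displacement-driven (Dirichlet) finite-strain solve
#'
#' Newton solution of the hyperelastic equilibrium with prescribed nodal
#' displacements; remaining boundary is traction-free. Prescribed
#' displacements are ramped with automatic bisection load stepping when a
#' full-step Newton solve diverges. Reaction forces (nN) are reported on the
#' constrained nodes.
#'
#' @param mesh a [tet_mesh()].
#' @param mat a [neo_hookean()] material.
#' @param prescribed N x 3 matrix of prescribed displacements (um) with `NA`
#'   for free dofs, or `list(nodes=, values=)`.
#' @param tol_rel relative Newton residual tolerance.
#' @param max_iter Newton iterations per load step.
#' @param verbose print per-step convergence lines.
#' @return A `solve_result` with fields `displacements`, `reactions`,
#'   `states`, `converged`, `newton_history`.
#' @export
solve_dirichlet <- function(mesh, mat, prescribed, tol_rel = 1e-8,
                            max_iter = 25, verbose = FALSE, cache = NULL) {
  pres <- .canonical_prescribed(mesh, prescribed)
  if (length(pres$dofs) == 0) stop("solve_dirichlet: no prescribed dofs")
  fext_fun <- function(um, lam) numeric(3L * nrow(mesh$nodes))
  if (length(pres$dofs) == 3L * nrow(mesh$nodes)) {
    # fully prescribed problem: pure evaluation, no free dofs to iterate
    u <- numeric(3L * nrow(mesh$nodes))
    u[pres$dofs] <- pres$vals
    a <- cpp_assemble(mesh$nodes, mesh$tets, .u_as_mat(u), mat$C10, mat$D1, FALSE)
    if (!a$ok)
      stop("solve_dirichlet: prescribed configuration inverts elements (min J = ",
           signif(a$minJ, 3), ")")
    return(.finish_solve(mesh, mat, u, pres$dofs, numeric(length(u)),
                         TRUE, data.frame(lambda = 1, iters = 0, rnorm = 0)))
  }
  sol <- .fem_continuation(mesh, mat, pres$dofs, pres$vals, fext_fun,
                           tol_rel = tol_rel, max_iter = max_iter,
                           verbose = verbose, cache = cache)
  if (!sol$converged)
    warning("solve_dirichlet: continuation stalled at lambda = ", sol$lambda)
  .finish_solve(mesh, mat, sol$u, pres$dofs, numeric(length(sol$u)),
                sol$converged, sol$trace, sol$lambda)
}

.canonical_prescribed <- function(mesh, prescribed) {
  N <- nrow(mesh$nodes)
  if (is.list(prescribed) && !is.data.frame(prescribed) &&
      !is.matrix(prescribed)) {
    nodes <- as.integer(prescribed$nodes)
    vals <- as.matrix(prescribed$values)
    stopifnot(length(nodes) == nrow(vals), ncol(vals) == 3)
    dofs <- .node_dofs(nodes)
    return(list(dofs = dofs, vals = as.vector(t(vals))))
  }
  pm <- as.matrix(prescribed)
  stopifnot(nrow(pm) == N, ncol(pm) == 3)
  v <- .u_as_vec(pm)
  dofs <- which(!is.na(v))
  list(dofs = dofs, vals = v[dofs])
}

#' Traction-driven (Neumann) finite-strain solve
#'
#' Solves equilibrium under surface tractions applied on the cell-ECM
#' interface, with the outer prism boundary encastred (fixed), which removes
#' the rigid modes. Tractions are true (Cauchy) tractions: consistent nodal
#' loads are re-assembled on the current deformed interface at every Newton
#' iteration using tributary (one-third rule) nodal areas.
#'
#' @param mesh a [tet_mesh()].
#' @param mat a [neo_hookean()] material.
#' @param tractions a [traction_field()] on interface nodes, kPa.
#' @param fixed_nodes nodes held at zero displacement (default: the outer
#'   prism boundary).
#' @param partial_ok if the continuation stalls before the full load, return
#'   the largest-load solution reached (its fraction in `$lambda`) instead of
#'   warning; used by the inverse solver, whose scaling step absorbs the
#'   shortfall.
#' @param cache optional environment reusing factorization symbolics across
#'   repeated solves on the same connectivity.
#' @inheritParams solve_dirichlet
#' @return A `solve_result`; `$lambda` is the load fraction actually applied
#'   (1 unless `partial_ok`).
#' @export
solve_neumann <- function(mesh, mat, tractions, fixed_nodes = mesh$outer_nodes,
                          tol_rel = 1e-8, max_iter = 25, verbose = FALSE,
                          partial_ok = FALSE, cache = NULL) {
  stopifnot(inherits(tractions, "traction_field"))
  if (length(fixed_nodes) == 0)
    stop("solve_neumann: outer boundary must be constrained")
  bad <- setdiff(tractions$node_ids, mesh$gamma_nodes)
  if (length(bad))
    stop("solve_neumann: traction nodes not on the interface: ",
         paste(head(bad), collapse = ", "))
  tdofs <- .node_dofs(tractions$node_ids)
  N3 <- 3L * nrow(mesh$nodes)
  fext_fun <- function(um, lam) {
    X <- mesh$nodes + um
    A <- .gamma_node_areas(mesh, X)
    Anode <- A[as.character(tractions$node_ids)]
    f <- numeric(N3)
    f[tdofs] <- lam * as.vector(t(tractions$vectors * Anode))
    f
  }
  fixed_dofs <- .node_dofs(sort(unique(as.integer(fixed_nodes))))
  # load-controlled problems with follower tractions can admit several
  # equilibria at full load; a quasi-static ramp (initial quarter step,
  # doubling on success) keeps the solution on the physical branch
  sol <- .fem_continuation(mesh, mat, fixed_dofs, numeric(length(fixed_dofs)),
                           fext_fun, tol_rel = tol_rel, max_iter = max_iter,
                           verbose = verbose, cache = cache, step0 = 0.25)
  if (!sol$converged && !partial_ok)
    warning("solve_neumann: continuation stalled at lambda = ", sol$lambda)
  fext <- fext_fun(.u_as_mat(sol$u), sol$lambda)
  .finish_solve(mesh, mat, sol$u, fixed_dofs, fext,
                sol$converged || partial_ok, sol$trace, sol$lambda)
}

#' Convert nodal reactions on the interface to surface tractions
#'
#' Nodal reaction forces (nN) on the cell surface are divided by the node's
#' tributary area (one third of the incident interface triangle areas,
#' evaluated in the current configuration) and flipped in sign, so the
#' returned tractions are those acting on the ECM.
#'
#' @param result a `solve_result` with reactions on all interface nodes.
#' @param mesh the mesh of the solve (defaults to `result$mesh`).
#' @return A [traction_field()] in kPa on the interface nodes.
#' @export
reactions_to_tractions <- function(result, mesh = result$mesh) {
  X <- mesh$nodes + result$displacements
  A <- .gamma_node_areas(mesh, X)
  gn <- mesh$gamma_nodes
  Anode <- A[as.character(gn)]
  if (any(!is.finite(Anode)) || any(Anode <= 0))
    stop("reactions_to_tractions: zero tributary area on the interface")
  tr <- -result$reactions[gn, , drop = FALSE] / Anode
  traction_field(gn, tr)
}
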