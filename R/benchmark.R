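# Self-contained synthetic test problems: the sphere-in-prism direct problem
# with known patch tractions, and bead-speckled image-stack pairs with a
# known warp field.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.runif_sphere <- function(n) {
  # uniform directions on the unit sphere
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Structured sphere-in-prism mesh: a Kuhn-subdivided grid whose concentric
# cube shells are blended onto spheres near the interface (exactly spherical
# at the cell surface, identity at the constrained outer boundary). Gives a
# smooth, watertight spherical interface with well-defined normals, which a
# stair-stepped voxel surface cannot provide.
.sphere_box_mesh <- function(radius, box_dims, element_size) {
  # grid pitch must divide the radius and keep the centre on a grid node
  h <- radius / max(1, round(radius / element_size))
  half <- h * ceiling(box_dims / (2 * h))
  nd <- as.integer(2 * half / h)
  vm <- structure(list(cell = array(FALSE, nd), voxel_size = rep(h, 3),
                       origin = c(0, 0, 0)), class = "voxel_mesh")
  ctr <- half
  # label by centroid cube shell: cell iff max|x - C| < radius
  ccx <- lapply(1:3, function(d) abs((seq_len(nd[d]) - 0.5) * h - ctr[d]))
  supn <- outer(outer(ccx[[1]], ccx[[2]], pmax), ccx[[3]], pmax)
  vm$cell <- array(supn < radius, nd)
  mesh <- tetrahedralize(vm, quality = Inf)
  # blended spherification: shells s <= radius map onto spheres, fading to
  # identity at the outer boundary shell
  X <- mesh$nodes
  relX <- sweep(X, 2, ctr)
  s <- pmax(abs(relX[, 1]), abs(relX[, 2]), abs(relX[, 3]))
  r <- sqrt(rowSums(relX^2))
  smax <- min(half)
  w <- ifelse(s <= radius, 1, pmax(0, (smax - s) / (smax - radius)))
  scale <- ifelse(r > 0, w * (s / r) + (1 - w), 1)
  Xs <- sweep(relX * scale, 2, ctr, `+`)
  m <- tet_mesh(Xs, mesh$tets, mesh$domain)
  # the spherification squeezes tets along the cube diagonals; relax the
  # interior (interface and outer boundary stay put)
  suppressWarnings(remesh(m, m$nodes, quality = 1.6, max_passes = 30))
}

#' Sphere-in-prism traction benchmark
#'
#' Builds the canonical validation problem for the inverse traction solver: a
#' spherical pseudo-cell (default diameter 80 um) embedded in the centre of a
#' rectangular ECM prism whose exterior surfaces are fully constrained.
#' Traction patches (geodesic caps of `patch_angle` angular radius around
#' seeded-random surface directions) carry constant traction vectors obtained
#' by distributing a pseudo-random force of magnitude `force_scale` (nN) over
#' the patch reference area. The direct finite-strain problem is then solved,
#' giving a ground-truth displacement field; the pair (deformed mesh, reversed
#' displacements) is exactly what the imaging pipeline would deliver to the
#' inverse solver, with known tractions to compare against.
#'
#' @param radius sphere radius, um.
#' @param box_dims ECM prism edge lengths, um.
#' @param n_patches number of traction patches (0 gives the zero problem).
#' @param force_scale force magnitude per patch, nN. The default drives the
#'   matrix well into the finite-strain regime (local principal stretches
#'   beyond 2.5, peak displacement around a third of the radius);
#'   displacements comparable to the radius are attainable by raising it,
#'   at the cost of many more continuation steps.
#' @param element_size voxel pitch of the discretization, um (six tets per
#'   voxel).
#' @param material a [neo_hookean()] material (cell and ECM share it).
#' @param seed integer seed controlling patch placement and force directions;
#'   identical seeds and parameters give bit-identical problems.
#' @param patch_angle angular radius of each patch cap, degrees.
#' @param solve if `FALSE`, skip the direct FE solve (geometry and tractions
#'   only).
#' @param verbose print solver progress.
#' @return Object of class `benchmark_problem`: `mesh` (undeformed),
#'   `material`, `tractions` (ground truth, kPa), `displacements` (direct
#'   solution, um), `deformed_mesh`, `u_real` (bead-convention displacements
#'   on the deformed mesh: deformed state back to relaxed state),
#'   `patches`, `seed`.
#' @export
make_sphere_benchmark <- function(radius = 40, box_dims = c(200, 200, 200),
                                  n_patches = 6, force_scale = 60000,
                                  element_size = 10,
                                  material = neo_hookean(), seed = 1,
                                  patch_angle = 15, solve = TRUE,
                                  verbose = FALSE) {
  stopifnot(radius > 0, force_scale >= 0, element_size > 0, n_patches >= 0)
  if (radius >= min(box_dims) / 2)
    stop("make_sphere_benchmark: radius must be < min(box_dims)/2")
  mesh <- .sphere_box_mesh(radius, box_dims, element_size)

  centre <- colMeans(mesh$nodes[mesh$gamma_nodes, , drop = FALSE])
  gn <- mesh$gamma_nodes
  rel <- sweep(mesh$nodes[gn, , drop = FALSE], 2, centre)
  rdir <- rel / sqrt(rowSums(rel^2))

  patches <- list()
  tvec <- matrix(0, length(gn), 3)
  if (n_patches > 0) {
    A <- .gamma_node_areas(mesh)
    Anode <- A[as.character(gn)]
    pd <- .with_seed(seed, {
      list(centers = .runif_sphere(n_patches),
           forces = .runif_sphere(n_patches) * force_scale)
    })
    cosmin <- cos(patch_angle * pi / 180)
    for (p in seq_len(n_patches)) {
      sel <- which(rdir %*% pd$centers[p, ] >= cosmin)
      if (length(sel) == 0)  # coarse meshes: fall back to the nearest node
        sel <- which.max(rdir %*% pd$centers[p, ])
      area <- sum(Anode[sel])
      tr <- pd$forces[p, ] / area  # nN / um^2 == kPa
      tvec[sel, ] <- tvec[sel, ] + rep(tr, each = length(sel))
      patches[[p]] <- list(direction = pd$centers[p, ], force = pd$forces[p, ],
                           node_ids = gn[sel], area = area, traction = tr)
    }
  }
  tractions <- traction_field(gn, tvec)

  out <- list(mesh = mesh, material = material, tractions = tractions,
              patches = patches, seed = seed, radius = radius,
              box_dims = box_dims, element_size = element_size,
              force_scale = force_scale, patch_angle = patch_angle)
  class(out) <- "benchmark_problem"
  if (!solve) return(out)

  if (n_patches == 0 || force_scale == 0) {
    u <- matrix(0, nrow(mesh$nodes), 3)
    out$displacements <- u
    out$deformed_mesh <- mesh
    out$u_real <- u
    out$direct_converged <- TRUE
    return(out)
  }
  sol <- solve_neumann(mesh, material, tractions, verbose = verbose)
  if (!sol$converged)
    stop("make_sphere_benchmark: direct solve did not converge; reduce force_scale or enable finer load stepping")
  out$displacements <- sol$displacements
  out$direct_result <- sol
  out$direct_converged <- sol$converged
  # the deformed mesh keeps exact node correspondence (no smoothing), so the
  # imaging-convention field (deformed state back to relaxed state) is the
  # per-node reversal of the direct solution; quality restoration happens
  # inside the inverse loop with its own field re-interpolation
  out$deformed_mesh <- .rebuild_mesh(mesh, mesh$nodes + sol$displacements)
  out$u_real <- -sol$displacements
  out
}

#' @export
print.benchmark_problem <- function(x, ...) {
  cat(sprintf("sphere benchmark: radius %g um in %s um box, %d patches, %d nodes\n",
              x$radius, paste(x$box_dims, collapse = "x"),
              length(x$patches), nrow(x$mesh$nodes)))
  if (!is.null(x$displacements))
    cat(sprintf("  direct solve: max |u| = %.2f um (%.2f x radius)\n",
                max(sqrt(rowSums(x$displacements^2))),
                max(sqrt(rowSums(x$displacements^2))) / x$radius))
  invisible(x)
}

#' Export a benchmark problem to disk
#'
#' Writes the undeformed mesh with ground-truth tractions and displacements
#' as VTU point data, the same per-node table as CSV, and the problem
#' metadata (seed and parameters) as JSON.
#'
#' @param bp a [make_sphere_benchmark()] result.
#' @param path output directory (created if missing).
#' @return The directory, invisibly.
#' @export
export_benchmark <- function(bp, path) {
  stopifnot(inherits(bp, "benchmark_problem"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  N <- nrow(bp$mesh$nodes)
  tr_full <- matrix(0, N, 3)
  tr_full[bp$tractions$node_ids, ] <- bp$tractions$vectors
  u <- if (is.null(bp$displacements)) matrix(0, N, 3) else bp$displacements
  write_vtu(file.path(path, "benchmark.vtu"), bp$mesh,
            point_data = list(traction = tr_full, u_direct = u),
            cell_data = list(domain = bp$mesh$domain))
  df <- data.frame(x_um = bp$mesh$nodes[, 1], y_um = bp$mesh$nodes[, 2],
                   z_um = bp$mesh$nodes[, 3],
                   tx_kpa = tr_full[, 1], ty_kpa = tr_full[, 2],
                   tz_kpa = tr_full[, 3],
                   ux_um = u[, 1], uy_um = u[, 2], uz_um = u[, 3])
  write.csv(df, file.path(path, "benchmark_nodes.csv"), row.names = FALSE)
  meta <- list(seed = bp$seed, radius = bp$radius, box_dims = bp$box_dims,
               element_size = bp$element_size, force_scale = bp$force_scale,
               patch_angle = bp$patch_angle, n_patches = length(bp$patches),
               material = list(C10 = bp$material$C10, D1 = bp$material$D1),
               direct_converged = isTRUE(bp$direct_converged))
  jsonlite::write_json(meta, file.path(path, "benchmark.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Synthetic bead image-stack pair
#'
#' Generates a deformed/relaxed pair of bead-speckled intensity volumes with a
#' known warp field, emulating confocal stacks of fluorescent fiducial beads
#' embedded in the matrix. Beads are Gaussian blobs placed uniformly at random
#' with a minimum pairwise separation; the first stack holds the beads in the
#' deformed (cell-contracted) state and the second in the relaxed state, so
#' the true displacement of each bead (deformed to relaxed, the tracking
#' convention) equals the warp evaluated at its rest position.
#'
#' @param shape voxel dimensions `(nx, ny, nz)`.
#' @param voxel_size voxel spacing, um (scalar or length 3).
#' @param n_beads number of beads.
#' @param bead_sigma Gaussian blob standard deviation, voxels.
#' @param warp either a function `f(positions_um) -> n x 3 displacements (um)`
#'   or a length-3 constant displacement vector (um).
#' @param noise_sd additive Gaussian intensity noise (peak bead intensity is
#'   100).
#' @param seed integer seed; identical seeds give identical stacks.
#' @param min_separation minimum pairwise bead distance, voxels (default: one
#'   subvolume width, 7).
#' @return list with `deformed` and `relaxed` [image_stack()] objects and
#'   `truth` (data.frame of rest/deformed bead positions and true
#'   displacements, um).
#' @export
make_bead_stack_pair <- function(shape, voxel_size = 0.63, n_beads = 50,
                                 bead_sigma = 1.2, warp = c(0, 0, 0),
                                 noise_sd = 0, seed = 1, min_separation = 7) {
  stopifnot(length(shape) == 3, n_beads >= 1)
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  wfun <- if (is.function(warp)) warp else {
    w0 <- rep_len(as.numeric(warp), 3)
    function(p) matrix(w0, nrow(p), 3, byrow = TRUE)
  }
  margin <- 6  # voxels kept clear of the border (subvolume + subpixel room)
  lo <- margin * voxel_size
  hi <- (shape - margin) * voxel_size
  if (any(hi <= lo)) stop("make_bead_stack_pair: volume too small")
  minsep_um <- min_separation * min(voxel_size)

  rest <- .with_seed(seed, {
    pts <- matrix(NA_real_, 0, 3)
    tries <- 0
    while (nrow(pts) < n_beads) {
      cand <- cbind(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]),
                    stats::runif(1, lo[3], hi[3]))
      if (nrow(pts) == 0 ||
          min(sqrt(rowSums(sweep(pts, 2, cand)^2))) > minsep_um)
        pts <- rbind(pts, cand)
      tries <- tries + 1
      if (tries > 200 * n_beads)
        stop("make_bead_stack_pair: bead count infeasible under the separation constraint")
    }
    pts
  })
  u_true <- wfun(rest)
  if (!is.matrix(u_true) || nrow(u_true) != n_beads)
    stop("make_bead_stack_pair: warp must return one displacement per bead")
  deformed_pos <- rest - u_true  # u carries deformed -> relaxed
  if (any(deformed_pos < 1 * voxel_size) ||
      any(sweep(deformed_pos, 2, (shape - 1) * voxel_size) > 0))
    stop("make_bead_stack_pair: warp displaces beads outside the volume")

  render <- function(pos_um) {
    vol <- array(0, shape)
    cx <- pos_um[, 1] / voxel_size[1] + 0.5  # 1-based voxel-centre coords
    cy <- pos_um[, 2] / voxel_size[2] + 0.5
    cz <- pos_um[, 3] / voxel_size[3] + 0.5
    w <- ceiling(4 * bead_sigma)
    for (b in seq_len(nrow(pos_um))) {
      i <- max(1, floor(cx[b] - w)):min(shape[1], ceiling(cx[b] + w))
      j <- max(1, floor(cy[b] - w)):min(shape[2], ceiling(cy[b] + w))
      k <- max(1, floor(cz[b] - w)):min(shape[3], ceiling(cz[b] + w))
      gx <- exp(-((i - cx[b])^2) / (2 * bead_sigma^2))
      gy <- exp(-((j - cy[b])^2) / (2 * bead_sigma^2))
      gz <- exp(-((k - cz[b])^2) / (2 * bead_sigma^2))
      vol[i, j, k] <- vol[i, j, k] + 100 * outer(outer(gx, gy), gz)
    }
    vol
  }
  st1 <- render(deformed_pos)
  st2 <- render(rest)
  if (noise_sd > 0) {
    nz <- .with_seed(seed + 1L, {
      list(a = array(stats::rnorm(prod(shape), 0, noise_sd), shape),
           b = array(stats::rnorm(prod(shape), 0, noise_sd), shape))
    })
    st1 <- pmax(st1 + nz$a, 0)
    st2 <- pmax(st2 + nz$b, 0)
  }
  truth <- data.frame(x_um = deformed_pos[, 1], y_um = deformed_pos[, 2],
                      z_um = deformed_pos[, 3],
                      rest_x_um = rest[, 1], rest_y_um = rest[, 2],
                      rest_z_um = rest[, 3],
                      ux_um = u_true[, 1], uy_um = u_true[, 2],
                      uz_um = u_true[, 3])
  list(deformed = image_stack(st1, voxel_size, channel = "beads"),
       relaxed = image_stack(st2, voxel_size, channel = "beads"),
       truth = truth)
}
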