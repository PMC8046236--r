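#' 3D intensity image stack
#'
#' @param intensities 3D numeric array, finite and non-negative.
#' @param voxel_size voxel spacing in um (scalar or length 3; default the
#'   confocal acquisition spacing 0.63 um isotropic).
#' @param channel `"beads"` or `"cell"`.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(intensities, voxel_size = 0.63,
                        channel = c("beads", "cell")) {
  channel <- match.arg(channel)
  stopifnot(is.array(intensities), length(dim(intensities)) == 3)
  if (!all(is.finite(intensities)) || any(intensities < 0))
    stop("image_stack: intensities must be finite and non-negative")
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  stopifnot(all(voxel_size > 0))
  structure(list(intensities = intensities, voxel_size = voxel_size,
                 channel = channel), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack (%s): %s voxels at %s um\n", x$channel,
              paste(dim(x$intensities), collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

# physical um <-> continuous 0-based voxel-index coordinate (voxel centre
# (i,j,k) 1-based lives at ((i-1/2) h); its 0-based index coord is i-1)
.um_to_idx <- function(p, h) sweep(p, 2, h, `/`) - 0.5
.idx_to_um <- function(q, h) sweep(q + 0.5, 2, h, `*`)

#' Detect beads as local intensity maxima
#'
#' Identifies bead candidates as strict local maxima of the intensity volume
#' over the 26-neighbourhood, above a threshold. Positions are reported at
#' voxel centres in um; refine with [refine_subpixel()].
#'
#' @param stack a beads-channel [image_stack()].
#' @param intensity_threshold detection threshold (same units as the
#'   intensities).
#' @return Object of class `bead_set`: `positions` (n x 3 um),
#'   `peak_intensity`.
#' @export
detect_beads <- function(stack, intensity_threshold) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$channel != "beads")
    warning("detect_beads: stack channel is not 'beads'")
  vol <- stack$intensities
  if (intensity_threshold >= max(vol)) {
    warning("detect_beads: threshold at or above the global maximum; no beads found")
    return(structure(list(positions = matrix(0, 0, 3),
                          peak_intensity = numeric(0)), class = "bead_set"))
  }
  ix <- cpp_local_maxima(as.numeric(vol), dim(vol), intensity_threshold)
  pos <- .idx_to_um(matrix(as.numeric(ix - 1L), ncol = 3), stack$voxel_size)
  structure(list(positions = pos,
                 peak_intensity = vol[ix]),
            class = "bead_set")
}

#' @export
print.bead_set <- function(x, ...) {
  cat(sprintf("bead_set: %d beads\n", nrow(x$positions)))
  invisible(x)
}

# sample a subvolume of `vol` around continuous 0-based centre `c0`
.subvol_offsets <- function(subvolume) {
  hw <- (subvolume - 1) / 2
  as.matrix(expand.grid(x = -hw[1]:hw[1], y = -hw[2]:hw[2], z = -hw[3]:hw[3]))
}

#' Subpixel bead localization
#'
#' Refines each bead position to the squared-intensity centre of mass of the
#' surrounding subvolume (default 7x7x7 voxels), re-centred and iterated until
#' the position update falls below `tol`. Beads whose subvolume would leave
#' the stack are dropped (their count is reported in a warning).
#'
#' @param stack the beads-channel [image_stack()] the beads were detected in.
#' @param beads a [detect_beads()] result.
#' @param subvolume odd voxel triple (default `c(7,7,7)`).
#' @param max_iter maximum centroid iterations per bead.
#' @param tol convergence tolerance on the position update, um.
#' @return A `bead_set` with subpixel positions; beads that failed to
#'   converge keep their last iterate and are flagged in `$flagged`.
#' @export
refine_subpixel <- function(stack, beads, subvolume = c(7, 7, 7),
                            max_iter = 50, tol = 0.01) {
  stopifnot(inherits(stack, "image_stack"), inherits(beads, "bead_set"))
  subvolume <- rep_len(as.integer(subvolume), 3)
  if (any(subvolume %% 2L == 0L))
    stop("refine_subpixel: subvolume must be odd in each dimension")
  h <- stack$voxel_size
  dims <- dim(stack$intensities)
  vol <- as.numeric(stack$intensities)
  off <- .subvol_offsets(subvolume)
  hw <- (subvolume - 1) / 2
  q <- .um_to_idx(beads$positions, h)
  keep <- q[, 1] >= hw[1] & q[, 1] <= dims[1] - 1 - hw[1] &
          q[, 2] >= hw[2] & q[, 2] <= dims[2] - 1 - hw[2] &
          q[, 3] >= hw[3] & q[, 3] <= dims[3] - 1 - hw[3]
  if (any(!keep))
    warning(sprintf("refine_subpixel: dropped %d bead(s) too close to the border",
                    sum(!keep)))
  q <- q[keep, , drop = FALSE]
  flagged <- logical(nrow(q))
  for (b in seq_len(nrow(q))) {
    c0 <- q[b, ]
    for (it in seq_len(max_iter)) {
      pts <- sweep(off, 2, c0, `+`)
      w <- cpp_trilinear(vol, dims, pts)^2
      sw <- sum(w)
      if (sw == 0) { flagged[b] <- TRUE; break }
      c1 <- colSums(pts * w) / sw
      moved <- sqrt(sum(((c1 - c0) * h)^2))
      c0 <- c1
      if (moved < tol) break
      if (it == max_iter) flagged[b] <- TRUE
    }
    q[b, ] <- c0
  }
  structure(list(positions = .idx_to_um(q, h),
                 peak_intensity = beads$peak_intensity[keep],
                 flagged = flagged), class = "bead_set")
}

#' Track bead displacements between two stacks
#'
#' For each bead, the subvolume around its position in the deformed stack is
#' shifted within the relaxed stack until the sum of squared intensity
#' differences is minimal: a coarse integer-shift search followed by
#' continuous subpixel minimization on the trilinearly interpolated relaxed
#' stack. The displacement convention carries the bead from its deformed to
#' its relaxed position.
#'
#' @param stack_deformed,stack_relaxed same-shape beads-channel stacks.
#' @param beads refined beads detected in `stack_deformed`.
#' @param search_radius integer-shift search radius, voxels.
#' @param subvolume odd voxel triple for the matching subvolume.
#' @return Object of class `sparse_displacements`: `anchors` (bead positions,
#'   um), `vectors` (displacements, um), `match_residual` (sum of squared
#'   intensity differences), `reliable` (FALSE where the integer minimum sat
#'   on the search boundary; such beads are excluded by
#'   [build_displacement_field()]).
#' @export
match_displacements <- function(stack_deformed, stack_relaxed, beads,
                                search_radius = 5, subvolume = c(7, 7, 7)) {
  stopifnot(inherits(stack_deformed, "image_stack"),
            inherits(stack_relaxed, "image_stack"),
            inherits(beads, "bead_set"))
  if (!identical(dim(stack_deformed$intensities), dim(stack_relaxed$intensities)))
    stop("match_displacements: stacks must have identical shapes")
  if (!isTRUE(all.equal(stack_deformed$voxel_size, stack_relaxed$voxel_size)))
    stop("match_displacements: stacks must share the voxel size")
  h <- stack_deformed$voxel_size
  dims <- dim(stack_deformed$intensities)
  v1 <- as.numeric(stack_deformed$intensities)
  v2 <- as.numeric(stack_relaxed$intensities)
  off <- .subvol_offsets(rep_len(as.integer(subvolume), 3))
  q <- .um_to_idx(beads$positions, h)
  n <- nrow(q)
  vec <- matrix(NA_real_, n, 3)
  resid <- numeric(n)
  reliable <- logical(n)
  r <- as.integer(search_radius)
  ishift <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  for (b in seq_len(n)) {
    pts1 <- sweep(off, 2, q[b, ], `+`)
    # symmetric sampling: both stacks are interpolated at half the shift, so
    # the interpolation blur affects them equally and the bias of the SSD
    # minimum cancels to first order
    ssd <- function(s) {
      s1 <- cpp_trilinear(v1, dims, sweep(pts1, 2, s / 2, `-`))
      s2 <- cpp_trilinear(v2, dims, sweep(pts1, 2, s / 2, `+`))
      sum((s1 - s2)^2)
    }
    vals <- apply(ishift, 1, ssd)
    best <- which.min(vals)
    s0 <- ishift[best, ]
    on_boundary <- any(abs(s0) == r) && r > 0
    opt <- stats::optim(s0, ssd, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 400))
    vec[b, ] <- opt$par * h
    resid[b] <- opt$value
    reliable[b] <- !on_boundary
  }
  structure(list(anchors = beads$positions, vectors = vec,
                 match_residual = resid, reliable = reliable),
            class = "sparse_displacements")
}

#' @export
print.sparse_displacements <- function(x, ...) {
  cat(sprintf("sparse_displacements: %d anchors (%d reliable), |u| max %.3g um\n",
              nrow(x$anchors), sum(x$reliable),
              max(sqrt(rowSums(x$vectors^2)), 0)))
  invisible(x)
}

# Otsu threshold on a 256-bin histogram
.otsu <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) stop("segment_cell: constant image")
  br <- seq(rng[1], rng[2], length.out = 257)
  hst <- tabulate(findInterval(x, br, all.inside = TRUE), 256)
  p <- hst / sum(hst)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-257]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Segment the cell from the cell-channel stack
#'
#' Automatic 3D threshold segmentation: voxels above the threshold (Otsu by
#' default) are labelled, the largest 6-connected component is kept, and
#' interior holes (background components not touching the stack border) are
#' filled in 3D.
#'
#' @param stack a cell-channel [image_stack()].
#' @param threshold numeric threshold or `"otsu"`.
#' @return A [voxel_mask()] of the cell.
#' @export
segment_cell <- function(stack, threshold = "otsu") {
  stopifnot(inherits(stack, "image_stack"))
  vol <- stack$intensities
  thr <- if (identical(threshold, "otsu")) .otsu(as.numeric(vol))
         else as.numeric(threshold)
  fg <- vol > thr
  if (!any(fg)) stop("segment_cell: no cell found above the threshold")
  lab <- cpp_label3d(as.logical(fg), dim(vol))
  main <- which.max(tabulate(lab[lab > 0]))
  mask <- array(lab == main, dim(vol))
  # fill holes: background components not touching the border are interior
  bg <- cpp_label3d(!mask, dim(vol))
  d <- dim(vol)
  border_labels <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                            bg[, , 1], bg[, , d[3]]))
  border_labels <- border_labels[border_labels > 0]
  hole <- bg > 0 & !(bg %in% border_labels)
  mask[hole] <- TRUE
  voxel_mask(mask, stack$voxel_size)
}

#' Build the nodal displacement field inside the cell action area
#'
#' Interpolates the sparse tracked bead displacements to the nodes of the FE
#' grid and applies the action-area masking: node displacements beyond
#' `action_radius` of the cell surface are zeroed, and nodes at surface
#' distance `0 <= d <= action_radius` are tapered by the decreasing quadratic
#' weight `w(d) = 1 - (d/action_radius)^2`, which decays continuously to zero
#' at the frontier. Interpolation is inverse-distance weighting over the
#' `k_neighbors` nearest reliable anchors; nodes farther than
#' `support_radius` from every anchor carry no information and are zeroed
#' (no extrapolation).
#'
#' @param sparse a [match_displacements()] result (unreliable anchors are
#'   dropped).
#' @param mask the segmented cell [voxel_mask()].
#' @param ecm_grid a `voxel_mesh` or [tet_mesh()] defining the target nodes.
#' @param action_radius trusted shell around the cell surface, um.
#' @param k_neighbors anchors used per node.
#' @param support_radius maximum nearest-anchor distance for a node to
#'   receive data, um.
#' @return N x 3 matrix of nodal displacements (um), class
#'   `displacement_field`, with the surface distance in `attr(,"surface_distance")`.
#' @export
build_displacement_field <- function(sparse, mask, ecm_grid,
                                     action_radius = 10, k_neighbors = 8,
                                     support_radius = action_radius) {
  stopifnot(inherits(sparse, "sparse_displacements"),
            inherits(mask, "voxel_mask"))
  ok <- sparse$reliable & !is.na(sparse$vectors[, 1])
  anchors <- sparse$anchors[ok, , drop = FALSE]
  vecs <- sparse$vectors[ok, , drop = FALSE]
  if (nrow(anchors) < 4) stop("build_displacement_field: fewer than 4 usable anchors")
  if (qr(sweep(anchors, 2, colMeans(anchors)))$rank < 3)
    stop("build_displacement_field: anchors are coplanar")
  nodes <- if (inherits(ecm_grid, "tet_mesh")) ecm_grid$nodes
           else .grid_nodes(ecm_grid)
  # Euclidean distance to the cell surface (0 inside the cell), um
  dvox <- cpp_edt3d(as.logical(mask$occupancy), dim(mask$occupancy),
                    mask$voxel_size)
  qi <- .um_to_idx(nodes, mask$voxel_size)
  d <- cpp_trilinear(as.numeric(dvox), dim(mask$occupancy), qi)
  w <- ifelse(d > action_radius, 0, 1 - (d / action_radius)^2)

  U <- matrix(0, nrow(nodes), 3)
  act <- which(w > 0)
  if (length(act)) {
    k <- min(k_neighbors, nrow(anchors))
    for (ii in act) {
      dd <- sqrt(colSums((t(anchors) - nodes[ii, ])^2))
      nn <- order(dd)[seq_len(k)]
      if (dd[nn[1]] > support_radius) next
      if (dd[nn[1]] < 1e-9) { U[ii, ] <- vecs[nn[1], ]; next }
      iw <- 1 / dd[nn]^2
      U[ii, ] <- colSums(vecs[nn, , drop = FALSE] * iw) / sum(iw)
    }
  } else {
    warning("build_displacement_field: no nodes inside the action area; zero field")
  }
  out <- U * w
  if (all(out == 0) && length(act))
    warning("build_displacement_field: anchors entirely outside the action area; zero field")
  class(out) <- c("displacement_field", class(out))
  attr(out, "surface_distance") <- d
  attr(out, "weight") <- w
  out
}

# nodes of the tet mesh a voxel_mesh would generate (grid corners)
.grid_nodes <- function(vmesh) {
  stopifnot(inherits(vmesh, "voxel_mesh"))
  np <- dim(vmesh$cell) + 1L
  h <- vmesh$voxel_size
  gx <- vmesh$origin[1] + (seq_len(np[1]) - 1) * h[1]
  gy <- vmesh$origin[2] + (seq_len(np[2]) - 1) * h[2]
  gz <- vmesh$origin[3] + (seq_len(np[3]) - 1) * h[3]
  cbind(rep(gx, times = np[2] * np[3]),
        rep(rep(gy, each = np[1]), times = np[3]),
        rep(gz, each = np[1] * np[2]))
}
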