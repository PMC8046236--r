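#' Voxel mask
#'
#' A 3D occupancy array with physical voxel spacing; the image-level
#' representation of the segmented cell. Voxel `(i,j,k)` (1-based) is the cube
#' centred at `((i-1/2)*dx, (j-1/2)*dy, (k-1/2)*dz)`.
#'
#' @param occupancy logical 3D array.
#' @param voxel_size voxel spacing in um (length 1 or 3).
#' @return Object of class `voxel_mask`.
#' @export
voxel_mask <- function(occupancy, voxel_size = 0.63) {
  stopifnot(is.array(occupancy), length(dim(occupancy)) == 3)
  occupancy <- array(as.logical(occupancy), dim(occupancy))
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  stopifnot(all(voxel_size > 0))
  structure(list(occupancy = occupancy, voxel_size = voxel_size),
            class = "voxel_mask")
}

#' Embed a cell mask in a rectangular prism voxel mesh
#'
#' The matrix volume is modelled as a rectangular prism with the cell located
#' at its centre; voxels inside the mask are labelled cell, the remainder ECM.
#'
#' @param mask a [voxel_mask()] of the cell.
#' @param box_dims prism edge lengths in um (length 3). Grid dimensions are
#'   `round(box_dims / voxel_size)`.
#' @return Object of class `voxel_mesh` with fields `cell` (logical 3D array),
#'   `voxel_size`, `origin` (um position of the corner of voxel (1,1,1)).
#' @export
voxelize <- function(mask, box_dims) {
  stopifnot(inherits(mask, "voxel_mask"), length(box_dims) == 3)
  if (!any(mask$occupancy)) stop("voxelize: empty cell mask")
  h <- mask$voxel_size
  nd <- as.integer(round(box_dims / h))
  md <- dim(mask$occupancy)
  # tight crop of the mask before centring
  ix <- which(mask$occupancy, arr.ind = TRUE)
  lo <- apply(ix, 2, min); hi <- apply(ix, 2, max)
  cd <- hi - lo + 1L
  if (any(cd + 2L > nd))
    stop("voxelize: mask does not fit in the box with a 1-voxel margin")
  cell <- array(FALSE, nd)
  off <- as.integer(floor((nd - cd) / 2))
  cell[off[1] + seq_len(cd[1]),
       off[2] + seq_len(cd[2]),
       off[3] + seq_len(cd[3])] <-
    mask$occupancy[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  structure(list(cell = cell, voxel_size = h, origin = c(0, 0, 0)),
            class = "voxel_mesh")
}

# 1-based grid-node linear index
.nid <- function(i, j, k, np) i + np[1] * ((j - 1L) + np[2] * (k - 1L))

# The six Kuhn (Freudenthal) path tetrahedra of the unit cube, as 0/1 vertex
# offsets. The same diagonal (0,0,0)-(1,1,1) in every voxel makes the
# space-filling triangulation face-conforming without parity flips.
.kuhn_offsets <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(p) {
    v <- matrix(0, 4, 3)
    v[2, p[1]] <- 1
    v[3, p[1]] <- 1; v[3, p[2]] <- 1
    v[4, ] <- 1
    v
  })
}

#' Convert a voxel mesh into a labelled tetrahedral mesh
#'
#' Each voxel is split into six Kuhn tetrahedra sharing the main diagonal, a
#' deterministic conforming subdivision that conserves the per-domain volume
#' exactly; one voxel of the image corresponds to six elements. The resulting
#' Kuhn tetrahedra have radius-edge ratio `sqrt(3)/2`, well inside the default
#' quality bound.
#'
#' @param vmesh a `voxel_mesh` from [voxelize()].
#' @param quality radius-edge quality bound checked on the result.
#' @return A [tet_mesh()] with cell/ECM element labels, interface surface and
#'   outer boundary.
#' @export
tetrahedralize <- function(vmesh, quality = 1.5) {
  stopifnot(inherits(vmesh, "voxel_mesh"))
  nd <- dim(vmesh$cell)
  np <- nd + 1L
  h <- vmesh$voxel_size
  # grid nodes
  gx <- vmesh$origin[1] + (seq_len(np[1]) - 1) * h[1]
  gy <- vmesh$origin[2] + (seq_len(np[2]) - 1) * h[2]
  gz <- vmesh$origin[3] + (seq_len(np[3]) - 1) * h[3]
  nodes <- cbind(rep(gx, times = np[2] * np[3]),
                 rep(rep(gy, each = np[1]), times = np[3]),
                 rep(gz, each = np[1] * np[2]))
  vox <- expand.grid(i = seq_len(nd[1]), j = seq_len(nd[2]), k = seq_len(nd[3]))
  lab <- ifelse(as.vector(vmesh$cell), 1L, 2L)
  tets <- vector("list", 6)
  for (t in seq_len(6)) {
    off <- .kuhn_offsets()[[t]]
    ids <- sapply(1:4, function(a)
      .nid(vox$i + off[a, 1], vox$j + off[a, 2], vox$k + off[a, 3], np))
    tets[[t]] <- matrix(as.integer(ids), ncol = 4)
  }
  tets <- do.call(rbind, tets)
  domain <- rep(lab, times = 6)
  # enforce positive orientation
  v <- cpp_tet_quality(nodes, tets)$volume
  neg <- v < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  m <- tet_mesh(nodes, tets, domain)
  q <- cpp_tet_quality(m$nodes, m$tets)
  if (max(q$radius_edge) > quality)
    warning(sprintf("tetrahedralize: max radius-edge ratio %.3f exceeds bound %.3f",
                    max(q$radius_edge), quality))
  m
}

#' Tetrahedral mesh with cell/ECM domains
#'
#' Container for the finite-element discretization: node coordinates (um),
#' element connectivity, per-element domain label, the oriented cell-ECM
#' interface surface (triangles whose normals point from the cell into the
#' ECM) and the outer boundary triangles of the prism.
#'
#' @param nodes N x 3 numeric matrix of coordinates (um).
#' @param tets M x 4 integer connectivity (1-based), positively oriented.
#' @param domain integer per element: 1 = cell, 2 = ECM.
#' @return Object of class `tet_mesh` with fields `nodes`, `tets`, `domain`,
#'   `gamma_s` (interface triangles), `outer` (boundary triangles),
#'   `gamma_nodes`, `outer_nodes`, `cell_nodes` (nodes of cell elements,
#'   including the interface).
#' @export
tet_mesh <- function(nodes, tets, domain) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  domain <- as.integer(domain)
  stopifnot(ncol(nodes) == 3, ncol(tets) == 4, length(domain) == nrow(tets),
            all(domain %in% 1:2), max(tets) <= nrow(nodes), min(tets) >= 1)
  vol <- cpp_tet_quality(nodes, tets)$volume
  if (any(vol <= 0)) stop("tet_mesh: non-positive signed element volumes")
  fc <- .mesh_faces(tets, domain)
  structure(list(nodes = nodes, tets = tets, domain = domain,
                 gamma_s = fc$gamma_s, outer = fc$outer,
                 gamma_nodes = sort(unique(as.vector(fc$gamma_s))),
                 outer_nodes = sort(unique(as.vector(fc$outer))),
                 cell_nodes = sort(unique(as.vector(tets[domain == 1L, , drop = FALSE])))),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tets (%d cell / %d ECM), %d interface tris\n",
              nrow(x$nodes), nrow(x$tets), sum(x$domain == 1), sum(x$domain == 2),
              nrow(x$gamma_s)))
  invisible(x)
}

# Outward-oriented faces of positively oriented tets: local index triples
# opposite each vertex.
.outward_faces <- rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))

# Classify all element faces; returns oriented interface (cell -> ECM) and
# outer boundary triangles.
.mesh_faces <- function(tets, domain) {
  M <- nrow(tets)
  faces <- matrix(0L, 4L * M, 3L)
  for (f in 1:4) faces[(f - 1L) * M + seq_len(M), ] <- tets[, .outward_faces[f, ]]
  fdom <- rep(domain, times = 4)
  a <- faces[, 1]; b <- faces[, 2]; c3 <- faces[, 3]
  lo <- pmin(a, b, c3); hi <- pmax(a, b, c3); mid <- a + b + c3 - lo - hi
  K <- max(tets) + 1
  key <- lo + mid * K + hi * K^2
  ord <- order(key)
  ks <- key[ord]
  first <- !duplicated(ks)
  grp <- cumsum(first)
  cnt <- tabulate(grp)
  # boundary faces appear once
  single <- ord[which(cnt[grp] == 1L)]
  outer <- faces[single, , drop = FALSE]
  # interface: shared faces with differing domains; orient from the cell side
  if (any(cnt == 2L)) {
    pos <- which(first & cnt[grp] == 2L)
    i1 <- ord[pos]; i2 <- ord[pos + 1L]
    mixed <- fdom[i1] != fdom[i2]
    cell_side <- ifelse(fdom[i1] == 1L, i1, i2)[mixed]
    gamma_s <- faces[cell_side, , drop = FALSE]
  } else gamma_s <- matrix(0L, 0, 3)
  list(gamma_s = gamma_s, outer = outer)
}

#' Element quality and volumes
#'
#' @param mesh a [tet_mesh()].
#' @param nodes optional alternative node coordinates (displaced configuration).
#' @return data.frame with `volume` (um^3) and `radius_edge` ratio per element.
#' @export
mesh_quality <- function(mesh, nodes = mesh$nodes) {
  q <- cpp_tet_quality(nodes, mesh$tets)
  data.frame(volume = as.numeric(q$volume),
             radius_edge = as.numeric(q$radius_edge))
}

# Triangle areas and (unnormalized) normals for node positions X.
.tri_geometry <- function(tris, X) {
  p1 <- X[tris[, 1], , drop = FALSE]
  e1 <- X[tris[, 2], , drop = FALSE] - p1
  e2 <- X[tris[, 3], , drop = FALSE] - p1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
  list(normal2A = n, area = sqrt(rowSums(n^2)))
}

# Tributary (one-third rule) areas of the interface nodes at configuration X.
# Returns a named vector over gamma_nodes.
.gamma_node_areas <- function(mesh, X = mesh$nodes) {
  g <- .tri_geometry(mesh$gamma_s, X)
  a <- rep(g$area / 3, times = 3)
  idx <- as.vector(mesh$gamma_s)
  ar <- vapply(split(a, idx), sum, 0)
  setNames(as.numeric(ar), names(ar))
}

# Area-weighted unit nodal normals of the interface at configuration X
# (pointing from cell into ECM). Rows indexed by gamma_nodes order.
.gamma_node_normals <- function(mesh, X = mesh$nodes) {
  g <- .tri_geometry(mesh$gamma_s, X)
  idx <- as.vector(mesh$gamma_s)
  acc <- rowsum(g$normal2A[rep(seq_len(nrow(mesh$gamma_s)), times = 3), , drop = FALSE],
                group = idx)
  nrm <- sqrt(rowSums(acc^2))
  if (any(nrm == 0)) stop("degenerate nodal normals on the interface")
  acc / nrm
}

#' Update and quality-repair a mesh in a displaced configuration
#'
#' Moves the mesh nodes to `displaced_nodes` and, if the radius-edge quality
#' bound is violated, applies constrained smart-Laplacian smoothing to the
#' interior nodes (interface and outer-boundary nodes are never moved, so the
#' cell surface geometry is preserved exactly). Connectivity is unchanged: the
#' mesher is a smoothing-based quality optimiser, not a re-triangulator.
#'
#' @param mesh a [tet_mesh()].
#' @param displaced_nodes N x 3 matrix of new node positions.
#' @param quality radius-edge bound (default 1.5).
#' @param max_passes smoothing sweeps to attempt.
#' @return A [tet_mesh()] on the displaced configuration. If the bound cannot
#'   be met a warning is issued and the best-effort mesh carries a
#'   `quality_report` attribute.
#' @export
remesh <- function(mesh, displaced_nodes, quality = 1.5, max_passes = 10) {
  stopifnot(inherits(mesh, "tet_mesh"),
            all(dim(displaced_nodes) == dim(mesh$nodes)))
  X <- as.matrix(displaced_nodes)
  q <- cpp_tet_quality(X, mesh$tets)
  if (min(q$volume) <= 0)
    stop("remesh: displaced configuration contains inverted elements; use a smaller configuration update step")
  if (max(q$radius_edge) <= quality)
    return(.rebuild_mesh(mesh, X))
  fixed <- union(mesh$gamma_nodes, mesh$outer_nodes)
  free_ok <- !(seq_len(nrow(X)) %in% fixed)
  adj <- .node_adjacency(mesh)
  # node -> incident elements
  inc <- split(rep(seq_len(nrow(mesh$tets)), 4), as.vector(mesh$tets))
  ratio <- as.numeric(q$radius_edge)
  for (pass in seq_len(max_passes)) {
    bad <- which(ratio > quality)
    if (length(bad) == 0) break
    cand <- intersect(unique(as.vector(mesh$tets[bad, , drop = FALSE])),
                      which(free_ok))
    improved <- FALSE
    for (nd in cand) {
      els <- inc[[as.character(nd)]]
      sub <- mesh$tets[els, , drop = FALSE]
      cur <- max(ratio[els])
      nb <- which(adj[nd, ] > 0)
      target <- colMeans(X[nb, , drop = FALSE])
      for (step in c(1, 0.5, 0.25)) {
        xn <- (1 - step) * X[nd, ] + step * target
        Xt <- X; Xt[nd, ] <- xn
        ql <- cpp_tet_quality(Xt, sub)
        if (min(ql$volume) > 0 && max(ql$radius_edge) < cur - 1e-12) {
          X[nd, ] <- xn
          ratio[els] <- as.numeric(ql$radius_edge)
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  q <- cpp_tet_quality(X, mesh$tets)
  if (max(q$radius_edge) > quality)
    warning(sprintf("remesh: quality bound %.2f not attained (worst %.3f); returning best effort",
                    quality, max(q$radius_edge)))
  out <- .rebuild_mesh(mesh, X)
  attr(out, "quality_report") <- summary(q$radius_edge)
  out
}

.rebuild_mesh <- function(mesh, X) {
  out <- mesh
  out$nodes <- X
  out
}

.node_adjacency <- function(mesh) {
  edges <- rbind(mesh$tets[, c(1, 2)], mesh$tets[, c(1, 3)], mesh$tets[, c(1, 4)],
                 mesh$tets[, c(2, 3)], mesh$tets[, c(2, 4)], mesh$tets[, c(3, 4)])
  N <- nrow(mesh$nodes)
  A <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                            j = c(edges[, 2], edges[, 1]),
                            x = 1, dims = c(N, N))
  A@x[] <- 1  # binarize duplicates
  A
}

#' Transfer a field between tetrahedral meshes
#'
#' Piecewise-linear transfer using barycentric coordinates of the destination
#' nodes in the source mesh. Per-element fields (one row per element, e.g.
#' integration-point tensors) are first projected to the source nodes by
#' volume-weighted averaging of incident elements and then interpolated.
#' Destination nodes falling outside the source domain use nearest-element
#' extrapolation; their count is reported via the `n_extrapolated` attribute.
#'
#' @param src,dst [tet_mesh()] objects (or `dst` an n x 3 matrix of query
#'   points).
#' @param field numeric vector/matrix with one row per `src` node
#'   (`what = "node"`) or per `src` element (`what = "element"`).
#' @param what field support on the source mesh.
#' @param elements optional logical mask of source elements used in the
#'   element-to-node projection (e.g. one side of the interface).
#' @return Matrix of values at the destination nodes.
#' @export
transfer_field <- function(src, dst, field, what = c("node", "element"),
                           elements = NULL) {
  what <- match.arg(what)
  stopifnot(inherits(src, "tet_mesh"))
  if (is.null(field) || length(field) == 0) stop("transfer_field: empty field")
  field <- as.matrix(field)
  if (what == "element") {
    if (nrow(field) != nrow(src$tets))
      stop("transfer_field: element field has wrong length")
    field <- .elements_to_nodes(src, field, keep = elements)
  } else if (nrow(field) != nrow(src$nodes)) {
    stop("transfer_field: node field has wrong length")
  }
  queries <- if (inherits(dst, "tet_mesh")) dst$nodes else as.matrix(dst)
  loc <- cpp_point_locate(src$nodes, src$tets, queries)
  out <- matrix(0, nrow(queries), ncol(field))
  for (a in 1:4) {
    nd <- src$tets[loc$element, a]
    out <- out + loc$bary[, a] * field[nd, , drop = FALSE]
  }
  attr(out, "n_extrapolated") <- sum(!loc$inside)
  out
}

# Volume-weighted projection of per-element values to nodes; `keep`
# restricts the averaging to a subset of elements (nodes touching none of
# them get zero).
.elements_to_nodes <- function(mesh, ef, keep = NULL) {
  vol <- as.numeric(cpp_tet_quality(mesh$nodes, mesh$tets)$volume)
  if (!is.null(keep)) vol[!keep] <- 0
  N <- nrow(mesh$nodes)
  num <- matrix(0, N, ncol(ef))
  wef <- ef * vol
  den <- rep(0, N)
  for (a in 1:4) {
    num <- num + .accum_rows(mesh$tets[, a], wef, N)
    den <- den + as.vector(.accum_rows(mesh$tets[, a], matrix(vol), N))
  }
  num / ifelse(den > 0, den, 1)
}

.accum_rows <- function(index, values, n) {
  out <- matrix(0, n, ncol(values))
  for (c in seq_len(ncol(values))) {
    s <- rowsum(values[, c], group = index)
    out[as.integer(rownames(s)), c] <- s
  }
  out
}
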