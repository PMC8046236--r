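# Writers for the standard interchange formats: VTK XML unstructured grids
# (VTU) and surfaces (VTP) for external viewers, CSV tables and multi-page
# TIFF stacks.

.vtk_data_arrays <- function(data, n) {
  if (length(data) == 0) return(character(0))
  unlist(lapply(names(data), function(nm) {
    v <- as.matrix(data[[nm]])
    stopifnot(nrow(v) == n)
    comp <- if (ncol(v) > 1) sprintf(' NumberOfComponents="%d"', ncol(v)) else ""
    c(sprintf('<DataArray type="Float64" Name="%s"%s format="ascii">', nm, comp),
      paste(apply(v, 1, paste, collapse = " "), collapse = "\n"),
      "</DataArray>")
  }))
}

.write_vtk_xml <- function(path, kind, nodes, cells, npc, cell_type,
                           point_data, cell_data) {
  n <- nrow(nodes); m <- nrow(cells)
  piece_attr <- if (kind == "UnstructuredGrid")
    sprintf('NumberOfPoints="%d" NumberOfCells="%d"', n, m)
  else sprintf('NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="0" NumberOfStrips="0" NumberOfPolys="%d"', n, m)
  cell_block_name <- if (kind == "UnstructuredGrid") "Cells" else "Polys"
  lines <- c(
    '<?xml version="1.0"?>',
    sprintf('<VTKFile type="%s" version="0.1" byte_order="LittleEndian">', kind),
    sprintf('<%s>', kind),
    sprintf('<Piece %s>', piece_attr),
    '<Points>',
    '<DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    paste(apply(nodes, 1, paste, collapse = " "), collapse = "\n"),
    '</DataArray>', '</Points>',
    sprintf('<%s>', cell_block_name),
    '<DataArray type="Int64" Name="connectivity" format="ascii">',
    paste(apply(cells - 1L, 1, paste, collapse = " "), collapse = "\n"),
    '</DataArray>',
    '<DataArray type="Int64" Name="offsets" format="ascii">',
    paste(seq_len(m) * npc, collapse = " "),
    '</DataArray>')
  if (kind == "UnstructuredGrid") {
    lines <- c(lines,
               '<DataArray type="UInt8" Name="types" format="ascii">',
               paste(rep(cell_type, m), collapse = " "),
               '</DataArray>')
  }
  lines <- c(lines, sprintf('</%s>', cell_block_name),
             '<PointData>', .vtk_data_arrays(point_data, n), '</PointData>',
             '<CellData>', .vtk_data_arrays(cell_data, m), '</CellData>',
             '</Piece>', sprintf('</%s>', kind), '</VTKFile>')
  writeLines(lines, path)
  invisible(path)
}

#' Write a tetrahedral mesh with fields as a VTU file
#'
#' @param path output file (.vtu).
#' @param mesh a [tet_mesh()].
#' @param point_data named list of per-node vectors/matrices.
#' @param cell_data named list of per-element vectors/matrices.
#' @return The path, invisibly.
#' @export
write_vtu <- function(path, mesh, point_data = list(), cell_data = list()) {
  .write_vtk_xml(path, "UnstructuredGrid", mesh$nodes, mesh$tets, 4L, 10L,
                 point_data, cell_data)
}

#' Write a triangulated surface with fields as a VTP file
#'
#' @param path output file (.vtp).
#' @param nodes N x 3 coordinates.
#' @param tris T x 3 triangle connectivity (1-based).
#' @param point_data named list of per-node values.
#' @return The path, invisibly.
#' @export
write_vtp <- function(path, nodes, tris, point_data = list()) {
  .write_vtk_xml(path, "PolyData", nodes, tris, 3L, 5L, point_data, list())
}

#' Write a gridded nodal field as VTK ImageData
#'
#' Writes point data living on the corner nodes of a voxel grid (e.g. the
#' output of [build_displacement_field()] on a `voxel_mesh`) as a VTI file.
#'
#' @param path output file (.vti).
#' @param vmesh the `voxel_mesh` defining grid spacing and origin.
#' @param point_data named list of vectors/matrices with one row per grid
#'   node (`prod(dim(vmesh$cell) + 1)` rows, x fastest).
#' @return The path, invisibly.
#' @export
write_vti <- function(path, vmesh, point_data = list()) {
  stopifnot(inherits(vmesh, "voxel_mesh"))
  nd <- dim(vmesh$cell)
  n <- prod(nd + 1L)
  lines <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="ImageData" version="0.1" byte_order="LittleEndian">',
    sprintf('<ImageData WholeExtent="0 %d 0 %d 0 %d" Origin="%s" Spacing="%s">',
            nd[1], nd[2], nd[3],
            paste(vmesh$origin, collapse = " "),
            paste(vmesh$voxel_size, collapse = " ")),
    sprintf('<Piece Extent="0 %d 0 %d 0 %d">', nd[1], nd[2], nd[3]),
    '<PointData>', .vtk_data_arrays(point_data, n), '</PointData>',
    '</Piece>', '</ImageData>', '</VTKFile>')
  writeLines(lines, path)
  invisible(path)
}

#' Write tracked displacements as CSV
#'
#' Columns: `x_um,y_um,z_um,ux_um,uy_um,uz_um,residual,reliable`.
#'
#' @param sparse a [match_displacements()] result.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_displacements_csv <- function(sparse, path) {
  stopifnot(inherits(sparse, "sparse_displacements"))
  df <- data.frame(x_um = sparse$anchors[, 1], y_um = sparse$anchors[, 2],
                   z_um = sparse$anchors[, 3],
                   ux_um = sparse$vectors[, 1], uy_um = sparse$vectors[, 2],
                   uz_um = sparse$vectors[, 3],
                   residual = sparse$match_residual,
                   reliable = sparse$reliable)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write an image stack as multi-page TIFF
#'
#' One page per z-slice; intensities are scaled to `[0, 1]` on write (TIFF
#' convention of the underlying reader) and rescaled by `scale` on read.
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path.
#' @param voxel_size voxel spacing to attach on read, um.
#' @param channel channel label to attach on read.
#' @param scale intensity scale factor applied on read.
#' @return `write_image_stack`: the path; `read_image_stack`: an
#'   [image_stack()].
#' @export
write_image_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("write_image_stack requires the 'tiff' package")
  stopifnot(inherits(stack, "image_stack"))
  vol <- stack$intensities
  mx <- max(vol, 1e-12)
  pages <- lapply(seq_len(dim(vol)[3]), function(k) vol[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, voxel_size = 0.63,
                             channel = c("beads", "cell"), scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("read_image_stack requires the 'tiff' package")
  if (!file.exists(path)) stop("read_image_stack: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vol <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (k in seq_along(pages)) vol[, , k] <- pages[[k]]
  image_stack(vol * scale, voxel_size, match.arg(channel))
}

#' Export an inverse run for external visualization
#'
#' Writes the final-configuration volume mesh (VTU) with the measured field,
#' total computed displacement and nodal error, the interface surface (VTP)
#' with the recovered tractions, a CSV summary of the run, and a JSON
#' metadata file. Field names are stable: `u_real`, `u_computed`, `err`,
#' `traction`.
#'
#' @param state a finished [run_inverse()] state.
#' @param tractions a [traction_field()], typically [recover_tractions()].
#' @param path output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
export_results <- function(state, tractions, path) {
  stopifnot(inherits(state, "inverse_state"), inherits(tractions, "traction_field"))
  mesh <- state$mesh
  if (nrow(mesh$gamma_s) == 0) stop("export_results: mesh has an empty interface")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  err_full <- rep(0, nrow(mesh$nodes))
  if (!is.null(state$nodal_errors)) err_full[state$eval_nodes] <- state$nodal_errors
  write_vtu(file.path(path, "volume.vtu"), mesh,
            point_data = list(u_real = state$u_real0,
                              u_computed = state$u_total,
                              err = err_full),
            cell_data = list(domain = state$mesh$domain))
  tr_full <- matrix(0, nrow(mesh$nodes), 3)
  tr_full[tractions$node_ids, ] <- tractions$vectors
  gids <- sort(unique(as.vector(mesh$gamma_s)))
  remap <- match(as.vector(mesh$gamma_s), gids)
  write_vtp(file.path(path, "surface.vtp"),
            mesh$nodes[gids, , drop = FALSE],
            matrix(remap, ncol = 3),
            point_data = list(traction = tr_full[gids, , drop = FALSE]))
  tr <- convergence_trace(state)
  mag <- sqrt(rowSums(tractions$vectors^2))
  summary_df <- data.frame(
    iterations = state$iteration,
    converged = state$converged,
    k_final = state$k,
    max_traction_x = max(abs(tractions$vectors[, 1])),
    max_traction_y = max(abs(tractions$vectors[, 2])),
    max_traction_z = max(abs(tractions$vectors[, 3])),
    max_traction_mag = max(mag),
    err_p50 = quantile(state$nodal_errors, 0.5, names = FALSE),
    err_p90 = quantile(state$nodal_errors, 0.9, names = FALSE),
    err_p95 = quantile(state$nodal_errors, 0.95, names = FALSE),
    err_max = max(state$nodal_errors))
  write.csv(summary_df, file.path(path, "summary.csv"), row.names = FALSE)
  if (!is.null(tr))
    write.csv(tr, file.path(path, "convergence_trace.csv"), row.names = FALSE)
  meta <- list(nodes = nrow(mesh$nodes), elements = nrow(mesh$tets),
               delta = state$delta, node_fraction = state$node_fraction,
               err_mode = state$err_mode, iterations = state$iteration,
               converged = state$converged)
  jsonlite::write_json(meta, file.path(path, "run.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
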