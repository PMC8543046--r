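# Plain-text interchange: ASCII PLY surfaces, legacy-ASCII VTK unstructured
# grids, TetGen-style .node/.ele, a JSON geometry sidecar for slice poses, and
# JSON contours.

#' Write a surface mesh as ASCII PLY
#' @param mesh a `surface_mesh`.
#' @param path output file.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment label %s", mesh$label),
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(format(mesh$vertices, digits = 9, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$triangles[, 1] - 1, mesh$triangles[, 2] - 1,
                   mesh$triangles[, 3] - 1), con)
  invisible(path)
}

#' Read an ASCII PLY surface mesh
#' @param path PLY file written by [write_ply()] (ASCII, xyz + faces).
#' @return a `surface_mesh`.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- which(lines == "end_header")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  lab <- sub("comment label ", "", grep("^comment label", lines, value = TRUE))
  V <- do.call(rbind, lapply(strsplit(lines[end + seq_len(nv)], " +"), as.numeric))
  Fm <- do.call(rbind, lapply(strsplit(lines[end + nv + seq_len(nf)], " +"),
                              function(x) as.integer(x[2:4]) + 1L))
  surface_mesh(V[, 1:3, drop = FALSE], Fm,
               label = if (length(lab)) lab else "BIVENTRICULAR", check = FALSE)
}

#' Write a tetrahedral mesh as a legacy-ASCII VTK unstructured grid
#' @param tmesh a [tetra_mesh()].
#' @param path output file.
#' @param point_data named list of per-vertex scalar vectors.
#' @export
write_vtk_tets <- function(tmesh, path, point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(tmesh$vertices); m <- nrow(tmesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", "tetra mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nv)), con)
  writeLines(apply(format(tmesh$vertices, digits = 9, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(paste(4, tmesh$tets[, 1] - 1, tmesh$tets[, 2] - 1,
                   tmesh$tets[, 3] - 1, tmesh$tets[, 4] - 1), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nv), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], digits = 9, trim = TRUE), con)
    }
  }
  invisible(path)
}

#' Write a tetrahedral mesh in TetGen-style .node/.ele format
#' @param tmesh a [tetra_mesh()].
#' @param basename output path without extension.
#' @export
write_tetgen <- function(tmesh, basename) {
  node <- paste0(basename, ".node")
  ele <- paste0(basename, ".ele")
  nv <- nrow(tmesh$vertices)
  writeLines(c(sprintf("%d 3 0 0", nv),
               paste(seq_len(nv),
                     apply(format(tmesh$vertices, digits = 9, trim = TRUE,
                                  scientific = FALSE), 1, paste, collapse = " "))),
             node)
  m <- nrow(tmesh$tets)
  writeLines(c(sprintf("%d 4 0", m),
               paste(seq_len(m), tmesh$tets[, 1], tmesh$tets[, 2],
                     tmesh$tets[, 3], tmesh$tets[, 4])), ele)
  invisible(basename)
}

#' Write the slice geometry sidecar (JSON)
#'
#' Per slice: `id`, `origin`, `u_axis`, `v_axis`, `spacing` (mm/col, mm/row),
#' `shape` (rows, cols), `view`, and optionally an `image` path.
#'
#' @param planes list of `slice_plane`s.
#' @param path output JSON file.
#' @param image_paths optional per-slice image file names.
#' @export
write_geometry_sidecar <- function(planes, path, image_paths = NULL) {
  entries <- lapply(seq_along(planes), function(k) {
    p <- planes[[k]]
    e <- list(id = if (is.null(p$id)) sprintf("slice%02d", k) else p$id,
              origin = p$origin, u_axis = p$u_axis, v_axis = p$v_axis,
              spacing = p$spacing, shape = p$shape, view = p$view)
    if (!is.null(image_paths)) e$image <- image_paths[[k]]
    e
  })
  jsonlite::write_json(list(slices = entries), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a slice geometry sidecar (JSON)
#' @param path sidecar file from [write_geometry_sidecar()].
#' @return list of `slice_plane`s (without pixels; `image` paths attached as
#'   an attribute when present).
#' @export
read_geometry_sidecar <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sl <- j$slices
  planes <- lapply(seq_len(nrow(sl)), function(k) {
    tryCatch(
      slice_plane(origin = unlist(sl$origin[k]), u_axis = unlist(sl$u_axis[k]),
                  v_axis = unlist(sl$v_axis[k]), spacing = unlist(sl$spacing[k]),
                  shape = unlist(sl$shape[k]),
                  view = sl$view[k], id = sl$id[k]),
      error = function(e)
        stop(sprintf("malformed sidecar entry for slice '%s': %s",
                     sl$id[k], conditionMessage(e)), call. = FALSE))
  })
  if (!is.null(sl$image)) attr(planes, "images") <- sl$image
  planes
}

#' Write per-slice contours (JSON)
#' @param contours per-slice lists of [labelled_contour()]s.
#' @param planes matching list of `slice_plane`s (for ids).
#' @param path output JSON file.
#' @export
write_contours_json <- function(contours, planes, path) {
  entries <- lapply(seq_along(contours), function(k) {
    list(slice = if (is.null(planes[[k]]$id)) sprintf("slice%02d", k) else planes[[k]]$id,
         contours = lapply(contours[[k]], function(cc)
           list(label = cc$label, closed = cc$closed, points = cc$points)))
  })
  jsonlite::write_json(list(slices = entries), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read per-slice contours (JSON)
#' @param path contours file from [write_contours_json()].
#' @return list (per slice) of lists of [labelled_contour()]s.
#' @export
read_contours_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(j$slices, function(e) {
    lapply(e$contours, function(cc) {
      P <- do.call(rbind, lapply(cc$points, unlist))
      labelled_contour(cc$label, P, isTRUE(cc$closed), slice_id = e$slice)
    })
  })
}

#' Write a shape model (JSON)
#' @param model a [shape_model()].
#' @param path output file.
#' @export
write_shape_model <- function(model, path) {
  jsonlite::write_json(list(mean_vertices = model$mean_vertices,
                            modes = model$modes,
                            variances = model$variances,
                            triangles = model$triangles,
                            vertex_labels = model$vertex_labels),
                       path, digits = NA)
  invisible(path)
}

#' Read a shape model (JSON)
#' @param path file from [write_shape_model()] (or any JSON with the same
#'   fields, e.g. an externally built model converted to this layout).
#' @return a [shape_model()].
#' @export
read_shape_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  shape_model(j$mean_vertices, j$modes, j$variances, j$triangles,
              if (is.null(j$vertex_labels)) NULL else as.character(j$vertex_labels))
}
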