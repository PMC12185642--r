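#' Tetrahedral volume mesh
#'
#' Container for the fluid domain: node coordinates in metres and tetrahedral
#' connectivity (1-based node indices). Tetrahedra are stored with positive
#' signed volume; cells supplied with negative orientation are reordered on
#' construction. Optional named cell regions (ROIs) are integer index vectors
#' into the cell list.
#'
#' @param nodes n x 3 numeric matrix of coordinates (m).
#' @param cells m x 4 integer matrix of node indices (1-based).
#' @param rois optional named list of integer cell-index vectors.
#' @return object of class `volume_mesh` with precomputed `cell_volumes` (m^3).
#' @export
volume_mesh <- function(nodes, cells, rois = NULL) {
  nodes <- as.matrix(nodes)
  cells <- as.matrix(cells)
  dimnames(nodes) <- NULL
  dimnames(cells) <- NULL
  storage.mode(cells) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must be n x 3")
  if (ncol(cells) != 4L) stop("cells must be m x 4 (tetrahedra)")
  if (min(cells) < 1L || max(cells) > nrow(nodes)) {
    stop("cell indices out of range")
  }
  v <- tet_signed_volumes(nodes, cells)
  neg <- v < 0
  if (any(neg)) {              # fix orientation: swap nodes 3 and 4
    cells[neg, c(3L, 4L)] <- cells[neg, c(4L, 3L)]
    v <- abs(v)
  }
  if (any(v <= 0)) stop("degenerate (zero-volume) tetrahedron present")
  if (!is.null(rois)) {
    if (is.null(names(rois)) || anyDuplicated(names(rois))) {
      stop("ROI names must be unique and non-empty")
    }
    for (r in rois) {
      if (length(r) && (min(r) < 1L || max(r) > nrow(cells))) {
        stop("ROI cell indices out of range")
      }
    }
  }
  structure(list(nodes = nodes, cells = cells, cell_volumes = v, rois = rois),
            class = "volume_mesh")
}

#' @keywords internal
tet_signed_volumes <- function(nodes, cells) {
  p1 <- nodes[cells[, 1], , drop = FALSE]
  a <- nodes[cells[, 2], , drop = FALSE] - p1
  b <- nodes[cells[, 3], , drop = FALSE] - p1
  c_ <- nodes[cells[, 4], , drop = FALSE] - p1
  rowSums(a * cross3(b, c_)) / 6
}

#' Triangulated lumen surface mesh
#'
#' Node coordinates (m), triangle connectivity, per-node outward unit normals
#' and per-node association areas. If normals are omitted they are computed as
#' area-weighted averages of incident triangle normals (triangle winding gives
#' the outward direction); association areas default to one third of the
#' summed incident triangle areas (lumped mass).
#'
#' @param nodes n x 3 numeric matrix (m).
#' @param triangles m x 3 integer matrix of node indices (1-based), wound so
#'   the right-hand normal points out of the fluid.
#' @param normals optional n x 3 matrix of outward unit normals.
#' @param node_areas optional per-node association areas (m^2).
#' @param rois optional named list of integer triangle-index vectors.
#' @return object of class `surface_mesh` with `tri_areas`, `tri_normals`,
#'   `tri_centroids` precomputed.
#' @export
surface_mesh <- function(nodes, triangles, normals = NULL, node_areas = NULL,
                         rois = NULL) {
  nodes <- as.matrix(nodes)
  triangles <- as.matrix(triangles)
  dimnames(nodes) <- NULL
  dimnames(triangles) <- NULL
  storage.mode(triangles) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must be n x 3")
  if (ncol(triangles) != 3L) stop("triangles must be m x 3")
  if (min(triangles) < 1L || max(triangles) > nrow(nodes)) {
    stop("triangle indices out of range")
  }
  p1 <- nodes[triangles[, 1], , drop = FALSE]
  e1 <- nodes[triangles[, 2], , drop = FALSE] - p1
  e2 <- nodes[triangles[, 3], , drop = FALSE] - p1
  cr <- cross3(e1, e2)
  a2 <- row_norms(cr)
  if (any(a2 <= 0)) stop("degenerate (zero-area) triangle present")
  tri_areas <- a2 / 2
  tri_normals <- cr / a2
  tri_centroids <- (p1 + nodes[triangles[, 2], , drop = FALSE] +
                      nodes[triangles[, 3], , drop = FALSE]) / 3
  if (is.null(node_areas)) {
    node_areas <- numeric(nrow(nodes))
    for (k in 1:3) {
      acc <- rowsum(tri_areas / 3, triangles[, k])
      idx <- as.integer(rownames(acc))
      node_areas[idx] <- node_areas[idx] + acc[, 1]
    }
  }
  if (any(node_areas < 0)) stop("association areas must be non-negative")
  if (abs(sum(node_areas) - sum(tri_areas)) > 1e-9 * sum(tri_areas)) {
    stop("association areas do not sum to the total surface area")
  }
  if (is.null(normals)) {
    normals <- matrix(0, nrow(nodes), 3)
    for (k in 1:3) {
      for (j in 1:3) {
        acc <- rowsum(tri_normals[, j] * tri_areas, triangles[, k])
        idx <- as.integer(rownames(acc))
        normals[idx, j] <- normals[idx, j] + acc[, 1]
      }
    }
    nn <- row_norms(normals)
    if (any(nn == 0)) stop("cannot compute a normal at an isolated node")
    normals <- normals / nn
  } else {
    normals <- as.matrix(normals)
    nn <- row_norms(normals)
    if (any(abs(nn - 1) > 1e-9)) stop("normals must have unit length (1e-9)")
  }
  if (!is.null(rois)) {
    if (is.null(names(rois)) || anyDuplicated(names(rois))) {
      stop("ROI names must be unique and non-empty")
    }
    for (r in rois) {
      if (length(r) && (min(r) < 1L || max(r) > nrow(triangles))) {
        stop("ROI triangle indices out of range")
      }
    }
  }
  structure(list(nodes = nodes, triangles = triangles, normals = normals,
                 node_areas = node_areas, tri_areas = tri_areas,
                 tri_normals = tri_normals, tri_centroids = tri_centroids,
                 rois = rois),
            class = "surface_mesh")
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat(sprintf("volume_mesh: %d nodes, %d tetrahedra, volume %.6g m^3\n",
              nrow(x$nodes), nrow(x$cells), sum(x$cell_volumes)))
  if (!is.null(x$rois)) cat("  ROIs:", paste(names(x$rois), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d nodes, %d triangles, area %.6g m^2\n",
              nrow(x$nodes), nrow(x$triangles), sum(x$tri_areas)))
  if (!is.null(x$rois)) cat("  ROIs:", paste(names(x$rois), collapse = ", "), "\n")
  invisible(x)
}
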