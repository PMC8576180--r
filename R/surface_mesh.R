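#' Triangulated open surface mesh
#'
#' Constructs the mesh container used throughout the package: an open
#' triangulated surface (the visible portion of a lung lobe) discretized with
#' 3-node membrane elements. Units are mm / kPa / mN (1 kPa = 1 mN/mm^2).
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z in mm.
#' @param triangles integer matrix, one row per element, 1-based node indices.
#'   Winding defines the outward element normal (right-hand rule).
#' @param thickness membrane thickness in mm (default 1.0).
#' @param ap_axis unit 3-vector giving the anterior-posterior direction of the
#'   global frame; used to orient per-element local frames and fibers. A bare
#'   STL does not encode anatomy, so this is an explicit input.
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(nodes, triangles, thickness = 1.0,
                         ap_axis = c(0, 1, 0)) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must have 3 columns")
  if (ncol(triangles) != 3L) stop("triangles must have 3 columns")
  if (any(triangles < 1L) || any(triangles > nrow(nodes)))
    stop("triangle indices out of range")
  if (thickness <= 0) stop("thickness must be positive")
  ap_axis <- as.numeric(ap_axis)
  ap_axis <- ap_axis / sqrt(sum(ap_axis^2))
  a <- triangle_areas(nodes, triangles)
  if (any(a <= 0)) {
    bad <- which(a <= 0)[1L]
    stop(sprintf("degenerate (zero-area) facet at element %d", bad))
  }
  ec <- edge_use_counts(triangles)
  if (any(ec$count > 2L))
    stop("mesh is not 2-manifold: an edge is shared by more than 2 triangles")
  structure(list(nodes = nodes, triangles = triangles,
                 thickness = thickness, ap_axis = ap_axis),
            class = "surface_mesh")
}

#' @method print surface_mesh
#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d nodes, %d elements, thickness %.3g mm\n",
              nrow(x$nodes), nrow(x$triangles), x$thickness))
  cat(sprintf("  perimeter nodes: %d; ap_axis: (%.3g, %.3g, %.3g)\n",
              length(perimeter_nodes(x)), x$ap_axis[1], x$ap_axis[2],
              x$ap_axis[3]))
  invisible(x)
}

triangle_areas <- function(nodes, triangles) {
  p0 <- nodes[triangles[, 1], , drop = FALSE]
  e1 <- nodes[triangles[, 2], , drop = FALSE] - p0
  e2 <- nodes[triangles[, 3], , drop = FALSE] - p0
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# undirected edge table with per-edge triangle-use counts
edge_use_counts <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  first <- !duplicated(key)
  list(edges = e[first, , drop = FALSE],
       count = as.integer(tab[paste(pmin(e[first, 1], e[first, 2]),
                                    pmax(e[first, 1], e[first, 2]))]))
}

#' Per-element local coordinate frames
#'
#' The local z-axis is the outward element normal (from triangle winding),
#' the local y-axis is the in-plane projection of the mesh `ap_axis`
#' (anterior-posterior), and the local x-axis completes a right-handed triad
#' (x = y x z). Fibers of the anisotropic law live along local x.
#'
#' @param mesh a [surface_mesh()].
#' @return list with `x_axis`, `y_axis`, `z_axis`: n_elem x 3 matrices.
#' @export
compute_local_frames <- function(mesh) {
  tri <- mesh$triangles
  p0 <- mesh$nodes[tri[, 1], , drop = FALSE]
  e1 <- mesh$nodes[tri[, 2], , drop = FALSE] - p0
  e2 <- mesh$nodes[tri[, 3], , drop = FALSE] - p0
  nz <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nz <- nz / sqrt(rowSums(nz^2))
  ap <- mesh$ap_axis
  proj <- ap[1] * nz[, 1] + ap[2] * nz[, 2] + ap[3] * nz[, 3]
  y <- cbind(ap[1] - proj * nz[, 1], ap[2] - proj * nz[, 2],
             ap[3] - proj * nz[, 3])
  ny <- sqrt(rowSums(y^2))
  if (any(ny < 1e-6)) {
    bad <- which(ny < 1e-6)[1L]
    stop(sprintf(
      "degenerate local frame: ap_axis parallel to the normal of element %d",
      bad))
  }
  y <- y / ny
  x <- cbind(y[, 2] * nz[, 3] - y[, 3] * nz[, 2],
             y[, 3] * nz[, 1] - y[, 1] * nz[, 3],
             y[, 1] * nz[, 2] - y[, 2] * nz[, 1])
  list(x_axis = x, y_axis = y, z_axis = nz)
}

#' Nodes on the open boundary of the surface
#'
#' A perimeter node is any node incident to an edge used by exactly one
#' triangle. These nodes receive the measured displacement boundary
#' conditions in the inverse analysis.
#'
#' @param mesh a [surface_mesh()].
#' @return sorted integer vector of node indices (empty for a closed surface).
#' @export
perimeter_nodes <- function(mesh) {
  ec <- edge_use_counts(mesh$triangles)
  b <- ec$edges[ec$count == 1L, , drop = FALSE]
  sort(unique(as.integer(b)))
}

#' Volume swept by a displacement field
#'
#' Signed volume enclosed between the reference surface and the surface
#' displaced by `u`, computed exactly per element as the prism bounded by the
#' reference triangle, the displaced triangle, and the three side quads
#' (tetrahedral decomposition). Positive when motion is along the outward
#' normal. This is the model-side analogue of the measured volumetric
#' deformation in a pressure-volume experiment.
#'
#' @param mesh a [surface_mesh()].
#' @param u displacement, either an n_nodes x 3 matrix or a length 3*n vector.
#' @return swept volume in mm^3.
#' @export
enclosed_volume_change <- function(mesh, u) {
  u <- as_disp_matrix(u, nrow(mesh$nodes))
  tri <- mesh$triangles
  X0 <- mesh$nodes[tri[, 1], , drop = FALSE]
  X1 <- mesh$nodes[tri[, 2], , drop = FALSE]
  X2 <- mesh$nodes[tri[, 3], , drop = FALSE]
  x0 <- X0 + u[tri[, 1], , drop = FALSE]
  x1 <- X1 + u[tri[, 2], , drop = FALSE]
  x2 <- X2 + u[tri[, 3], , drop = FALSE]
  det3 <- function(a, b, c) {
    a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  }
  # closed prism boundary: displaced top (original winding), reference bottom
  # (reversed), three side quads split into triangles
  v <- det3(x0, x1, x2) + det3(X0, X2, X1) +
    det3(X0, X1, x1) + det3(X0, x1, x0) +
    det3(X1, X2, x2) + det3(X1, x2, x1) +
    det3(X2, X0, x0) + det3(X2, x0, x2)
  sum(v) / 6
}

as_disp_matrix <- function(u, n_nodes) {
  if (is.matrix(u)) {
    stopifnot(nrow(u) == n_nodes, ncol(u) == 3L)
    return(u)
  }
  stopifnot(length(u) == 3L * n_nodes)
  matrix(u, ncol = 3L, byrow = TRUE)
}

as_disp_vector <- function(u, n_nodes) {
  if (is.matrix(u)) {
    stopifnot(nrow(u) == n_nodes, ncol(u) == 3L)
    return(as.numeric(t(u)))
  }
  stopifnot(length(u) == 3L * n_nodes)
  as.numeric(u)
}

# ---------------------------------------------------------------------------
# STL I/O
# ---------------------------------------------------------------------------

#' Read a triangulated surface from an STL file
#'
#' Handles both binary and ASCII STL. Duplicate vertices are merged within a
#' 1e-6 mm tolerance; facet orientation (winding) is preserved. Facets with
#' zero area are rejected with their index reported.
#'
#' @param path file path.
#' @param thickness,ap_axis passed to [surface_mesh()] (STL stores neither).
#' @return a [surface_mesh()].
#' @export
read_stl <- function(path, thickness = 1.0, ap_axis = c(0, 1, 0)) {
  if (!file.exists(path)) stop("cannot read STL file: ", path)
  con <- file(path, "rb")
  header <- readBin(con, "raw", 80L)
  sz <- file.size(path)
  is_binary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(ntri) == 1L && !is.na(ntri) && sz == 84 + 50 * as.numeric(ntri))
      is_binary <- TRUE
  }
  if (is_binary) {
    raw <- readBin(con, "raw", 50L * ntri)
    close(con)
    verts <- matrix(NA_real_, 3L * ntri, 3L)
    for (i in seq_len(ntri)) {
      off <- (i - 1L) * 50L
      v <- readBin(raw[(off + 13):(off + 48)], "numeric", 9L, size = 4L,
                   endian = "little")
      verts[(3 * i - 2):(3 * i), ] <- matrix(v, 3L, 3L, byrow = TRUE)
    }
  } else {
    close(con)
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L)
      stop("unreadable STL file (no complete facets): ", path)
    verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
    ntri <- nrow(verts) / 3L
  }
  if (any(!is.finite(verts))) stop("unreadable STL file (bad vertex data): ", path)
  # merge duplicates within tolerance by grid snapping
  tol <- 1e-6
  key <- apply(round(verts / tol), 1L, paste, collapse = "/")
  uid <- match(key, unique(key))
  nodes <- verts[!duplicated(key), , drop = FALSE]
  triangles <- matrix(uid, ncol = 3L, byrow = TRUE)
  a <- triangle_areas(nodes, triangles)
  if (any(a <= .Machine$double.eps)) {
    bad <- which(a <= .Machine$double.eps)[1L]
    stop(sprintf("degenerate (zero-area) facet %d in %s", bad, path))
  }
  surface_mesh(nodes, triangles, thickness = thickness, ap_axis = ap_axis)
}

#' Write a surface mesh to STL
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @param ascii write ASCII STL instead of binary (default `FALSE`).
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  tri <- mesh$triangles
  p0 <- mesh$nodes[tri[, 1], , drop = FALSE]
  p1 <- mesh$nodes[tri[, 2], , drop = FALSE]
  p2 <- mesh$nodes[tri[, 3], , drop = FALSE]
  e1 <- p1 - p0; e2 <- p2 - p0
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- n / sqrt(rowSums(n^2))
  m <- nrow(tri)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid pulmem", con)
    for (i in seq_len(m)) {
      writeLines(c(
        sprintf("  facet normal %.9e %.9e %.9e", n[i, 1], n[i, 2], n[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9e %.9e %.9e", p0[i, 1], p0[i, 2], p0[i, 3]),
        sprintf("      vertex %.9e %.9e %.9e", p1[i, 1], p1[i, 2], p1[i, 3]),
        sprintf("      vertex %.9e %.9e %.9e", p2[i, 1], p2[i, 2], p2[i, 3]),
        "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid pulmem", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(m), con, size = 4L, endian = "little")
    for (i in seq_len(m)) {
      writeBin(as.numeric(c(n[i, ], p0[i, ], p1[i, ], p2[i, ])), con,
               size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Legacy VTK output for visualization
# ---------------------------------------------------------------------------

#' Write mesh and fields to a legacy VTK file
#'
#' Emits an ASCII legacy VTK unstructured grid with optional nodal vector
#' fields (e.g. displacement) and per-element scalar or vector fields
#' (e.g. strain, shear modulus, principal directions).
#'
#' @param mesh a [surface_mesh()].
#' @param path output `.vtk` path.
#' @param point_vectors named list of n_nodes x 3 matrices.
#' @param cell_scalars named list of length n_elem numeric vectors.
#' @param cell_vectors named list of n_elem x 3 matrices.
#' @export
write_vtk <- function(mesh, path, point_vectors = list(),
                      cell_scalars = list(), cell_vectors = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$triangles)
  writeLines(c("# vtk DataFile Version 3.0", "pulmem surface", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)),
             con)
  writeLines(apply(mesh$nodes, 1L, function(r) paste(format(r, digits = 12),
                                                     collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(apply(mesh$triangles - 1L, 1L,
                   function(r) paste(c(3L, r), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  if (length(point_vectors)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_vectors)) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      writeLines(apply(point_vectors[[nm]], 1L,
                       function(r) paste(format(r, digits = 12),
                                         collapse = " ")), con)
    }
  }
  if (length(cell_scalars) || length(cell_vectors)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_scalars)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(cell_scalars[[nm]], digits = 12), con)
    }
    for (nm in names(cell_vectors)) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      writeLines(apply(cell_vectors[[nm]], 1L,
                       function(r) paste(format(r, digits = 12),
                                         collapse = " ")), con)
    }
  }
  invisible(path)
}
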