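# Unstructured triangular meshing of boundary shapes.
#
# The generator follows the distmesh recipe: boundary vertices at the target
# spacing (or supplied verbatim), interior seeds on a hexagonal lattice
# cleared away from the boundary, Delaunay triangulation (Bowyer-Watson, in
# C++), centroid-in-polygon filtering, then a few rounds of Laplacian
# smoothing of the interior with re-triangulation. The contract is the
# TriMesh invariant set, not any particular generator.

triangle_signed_areas <- function(points, triangles) {
  p1 <- points[triangles[, 1], , drop = FALSE]
  p2 <- points[triangles[, 2], , drop = FALSE]
  p3 <- points[triangles[, 3], , drop = FALSE]
  ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
     (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])) / 2
}

#' Per-triangle areas of a mesh
#' @param mesh a \code{mm_mesh}.
#' @return numeric vector of (positive) triangle areas.
#' @export
mesh_areas <- function(mesh) triangle_signed_areas(mesh$points, mesh$triangles)

mesh_edges <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

min_angles <- function(points, triangles) {
  ang <- function(a, b, c) {
    u <- b - a; v <- c - a
    acos(pmin(1, pmax(-1, rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2)))))
  }
  p1 <- points[triangles[, 1], , drop = FALSE]
  p2 <- points[triangles[, 2], , drop = FALSE]
  p3 <- points[triangles[, 3], , drop = FALSE]
  pmin(ang(p1, p2, p3), ang(p2, p3, p1), ang(p3, p1, p2))
}

new_tri_mesh <- function(points, triangles, boundary_polygon, stage,
                         flank_tol) {
  sa <- triangle_signed_areas(points, triangles)
  flip <- sa < 0
  if (any(flip)) {
    tmp <- triangles[flip, 2]
    triangles[flip, 2] <- triangles[flip, 3]
    triangles[flip, 3] <- tmp
  }
  edges <- mesh_edges(triangles)
  # boundary edges: incident to exactly one triangle
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  all_e <- c(key(triangles[, 1], triangles[, 2]),
             key(triangles[, 2], triangles[, 3]),
             key(triangles[, 3], triangles[, 1]))
  tab <- table(all_e)
  bkeys <- names(tab)[tab == 1]
  ek <- key(edges[, 1], edges[, 2])
  boundary_edges <- edges[ek %in% bkeys, , drop = FALSE]
  boundary_nodes <- sort(unique(as.vector(boundary_edges)))
  xmin <- min(points[, 1])
  flank_nodes <- boundary_nodes[points[boundary_nodes, 1] <= xmin + flank_tol]
  structure(list(points = points, triangles = triangles, edges = edges,
                 boundary_edges = boundary_edges,
                 boundary_nodes = boundary_nodes, flank_nodes = flank_nodes,
                 boundary_polygon = boundary_polygon, stage = stage),
            class = "mm_mesh")
}

#' @export
print.mm_mesh <- function(x, ...) {
  cat(sprintf("<TriMesh %s: %d points, %d triangles, %d boundary nodes (%d flank)>\n",
              if (!is.null(x$stage)) x$stage$label else "?", nrow(x$points),
              nrow(x$triangles), length(x$boundary_nodes),
              length(x$flank_nodes)))
  invisible(x)
}

# deterministic sub-nanometre jitter to break hex-lattice cocircularity
lattice_jitter <- function(n, h) {
  i <- seq_len(n)
  cbind(sin(i * 12.9898) * 1e-7 * h, sin(i * 78.233) * 1e-7 * h)
}

#' Triangulate a boundary shape
#'
#' @param shape a \code{mm_shape}, or a closed polygon matrix.
#' @param target_edge_length desired element edge length (model units).
#' @param boundary_points optional matrix of boundary vertices to use verbatim
#'   (in polygon order); when given the outline is not resampled. Used to make
#'   consecutive meshes share an identical boundary polygon.
#' @param smooth_iters rounds of interior Laplacian smoothing.
#' @param flank_tol tolerance for classifying flank (minimal-x) nodes;
#'   defaults to 1e-6 times the shape diameter.
#' @return a \code{mm_mesh} with points, counter-clockwise triangles, edge
#'   list, boundary/flank node sets and the generating boundary polygon.
#' @export
triangulate <- function(shape, target_edge_length, boundary_points = NULL,
                        smooth_iters = 2L, flank_tol = NULL) {
  xy <- if (inherits(shape, "mm_shape")) shape$outline else shape
  stage <- if (inherits(shape, "mm_shape")) shape$stage else NULL
  h <- target_edge_length
  diam <- max(diff(range(xy[, 1])), diff(range(xy[, 2])))
  if (h <= 0 || h >= diam) stop("target_edge_length must be positive and smaller than the shape diameter")
  if (abs(polygon_area(xy)) <= 0) stop("degenerate polygon")
  if (is.null(flank_tol)) flank_tol <- 1e-6 * diam

  if (is.null(boundary_points)) {
    per <- sum(sqrt(diff(rbind(xy, xy[1, ])[, 1])^2 +
                    diff(rbind(xy, xy[1, ])[, 2])^2))
    nb <- max(8L, round(per / h))
    bp <- resample_outline(xy, nb)
  } else bp <- boundary_points
  nb <- nrow(bp)

  # hexagonal interior lattice, cleared near the boundary
  xr <- range(xy[, 1]); yr <- range(xy[, 2])
  dy <- h * sqrt(3) / 2
  ys <- seq(yr[1] + dy / 2, yr[2], by = dy)
  pts_list <- vector("list", length(ys))
  for (r in seq_along(ys)) {
    off <- if (r %% 2 == 0) h / 2 else 0
    xs <- seq(xr[1] + off + h / 4, xr[2], by = h)
    if (length(xs)) pts_list[[r]] <- cbind(xs, ys[r])
  }
  interior <- do.call(rbind, pts_list)
  if (!is.null(interior) && nrow(interior)) {
    keep <- as.logical(point_in_polygon_cpp(interior[, 1], interior[, 2],
                                            bp[, 1], bp[, 2]))
    interior <- interior[keep, , drop = FALSE]
    if (nrow(interior)) {
      d <- dist_polyline_cpp(interior, bp)
      interior <- interior[d > 0.55 * h, , drop = FALSE]
    }
    if (nrow(interior))
      interior <- interior + lattice_jitter(nrow(interior), h)
  }
  pts <- rbind(as.matrix(bp), interior)
  colnames(pts) <- c("x", "y")

  build <- function(pts) {
    tri <- delaunay_cpp(pts)
    cen <- (pts[tri[, 1], , drop = FALSE] + pts[tri[, 2], , drop = FALSE] +
              pts[tri[, 3], , drop = FALSE]) / 3
    keep <- as.logical(point_in_polygon_cpp(cen[, 1], cen[, 2], bp[, 1], bp[, 2]))
    tri[keep, , drop = FALSE]
  }
  tri <- build(pts)
  if (smooth_iters > 0 && nrow(pts) > nb) {
    for (s in seq_len(smooth_iters)) {
      ed <- mesh_edges(tri)
      acc <- matrix(0, nrow(pts), 2); cnt <- numeric(nrow(pts))
      for (cc in 1:2) {
        acc[, cc] <- acc[, cc] +
          tabulate2(ed[, 1], pts[ed[, 2], cc], nrow(pts)) +
          tabulate2(ed[, 2], pts[ed[, 1], cc], nrow(pts))
      }
      cnt <- tabulate(ed[, 1], nrow(pts)) + tabulate(ed[, 2], nrow(pts))
      idx <- (nb + 1):nrow(pts)
      ok <- cnt[idx] > 0
      pts[idx[ok], ] <- acc[idx[ok], ] / cnt[idx[ok]]
      tri <- build(pts)
    }
  }
  mesh <- new_tri_mesh(pts, tri, bp, stage, flank_tol)
  a_mesh <- sum(mesh_areas(mesh))
  a_poly <- abs(polygon_area(bp))
  if (abs(a_mesh - a_poly) > 1e-6 * a_poly)
    stop(sprintf("mesh does not tile its boundary polygon (defect %.3g)",
                 abs(a_mesh - a_poly) / a_poly))
  mesh
}

# sum `val` into bins given by `bin` (weighted tabulate)
tabulate2 <- function(bin, val, nbins) {
  as.vector(unname(vapply(split(val, factor(bin, levels = seq_len(nbins))),
                          sum, numeric(1))))
}

#' Partition the mesh nodes into boundary, flank and interior sets
#'
#' @param mesh a \code{mm_mesh}.
#' @return list with \code{boundary_nodes}, \code{flank_nodes} and
#'   \code{interior_nodes}; flank nodes are the boundary nodes on the
#'   minimal-x (body) edge, whose displacement the deformation solver pins to
#'   zero.
#' @export
classify_boundary <- function(mesh) {
  list(boundary_nodes = mesh$boundary_nodes,
       flank_nodes = mesh$flank_nodes,
       interior_nodes = setdiff(seq_len(nrow(mesh$points)), mesh$boundary_nodes))
}

#' Triangle adjacency across shared edges
#'
#' @param mesh a \code{mm_mesh}.
#' @return data frame with one row per interior edge: the two incident
#'   triangles, the shared-edge length and the centroid distance (the
#'   geometric quantities used by the finite-volume diffusion stencil).
#' @export
edge_neighbors <- function(mesh) {
  tri <- mesh$triangles
  m <- nrow(tri)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- c(ekey(tri[, 1], tri[, 2]), ekey(tri[, 2], tri[, 3]),
            ekey(tri[, 3], tri[, 1]))
  owner <- rep(seq_len(m), 3)
  sp <- split(owner, keys)
  bad <- vapply(sp, length, integer(1)) > 2
  if (any(bad)) stop("non-manifold edge (shared by more than two triangles)")
  int <- sp[vapply(sp, length, integer(1)) == 2]
  t1 <- vapply(int, `[`, integer(1), 1)
  t2 <- vapply(int, `[`, integer(1), 2)
  ab <- do.call(rbind, strsplit(names(int), " "))
  a <- as.integer(ab[, 1]); b <- as.integer(ab[, 2])
  elen <- sqrt(rowSums((mesh$points[a, , drop = FALSE] -
                          mesh$points[b, , drop = FALSE])^2))
  cen <- (mesh$points[tri[, 1], ] + mesh$points[tri[, 2], ] +
            mesh$points[tri[, 3], ]) / 3
  cdist <- sqrt(rowSums((cen[t1, , drop = FALSE] - cen[t2, , drop = FALSE])^2))
  data.frame(tri1 = t1, tri2 = t2, node1 = a, node2 = b,
             edge_length = elen, centroid_distance = cdist,
             row.names = NULL)
}

#' Write a mesh in OFF format
#' @param mesh a \code{mm_mesh}.
#' @param file output path.
#' @export
write_mesh_off <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$points), nrow(mesh$triangles)), con)
  writeLines(sprintf("%.17g %.17g 0", mesh$points[, 1], mesh$points[, 2]), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(file)
}

#' Read a mesh written by \code{write_mesh_off}
#' @param file OFF file path.
#' @param stage optional stage to attach.
#' @return a \code{mm_mesh} (boundary polygon reconstructed from the boundary
#'   edges).
#' @export
read_mesh_off <- function(file, stage = NULL) {
  lines <- readLines(file)
  if (trimws(lines[1]) != "OFF") stop("not an OFF file")
  hd <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  np <- hd[1]; nt <- hd[2]
  pv <- do.call(rbind, lapply(lines[3:(2 + np)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:2])))
  tv <- do.call(rbind, lapply(lines[(3 + np):(2 + np + nt)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]][2:4]) + 1L))
  colnames(pv) <- c("x", "y")
  mesh <- new_tri_mesh(pv, tv, boundary_polygon = NULL, stage = stage,
                       flank_tol = 1e-6 * max(diff(range(pv[, 1])),
                                              diff(range(pv[, 2]))))
  mesh$boundary_polygon <- boundary_loop(mesh)
  mesh
}

# ordered boundary vertex loop from the boundary edges
boundary_loop <- function(mesh) {
  be <- mesh$boundary_edges
  nxt <- list()
  for (i in seq_len(nrow(be))) {
    a <- as.character(be[i, 1]); b <- as.character(be[i, 2])
    nxt[[a]] <- c(nxt[[a]], be[i, 2])
    nxt[[b]] <- c(nxt[[b]], be[i, 1])
  }
  start <- be[1, 1]
  loop <- c(start)
  prev <- -1L
  cur <- start
  repeat {
    cand <- nxt[[as.character(cur)]]
    nx <- cand[cand != prev][1]
    if (nx == start) break
    loop <- c(loop, nx)
    prev <- cur; cur <- nx
  }
  pts <- mesh$points[loop, , drop = FALSE]
  if (polygon_area(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  pts
}

#' Write a mesh (with optional per-triangle data) as legacy ASCII VTK
#' @param mesh a \code{mm_mesh}.
#' @param file output path.
#' @param cell_data optional named list of per-triangle numeric vectors.
#' @export
write_mesh_vtk <- function(mesh, file, cell_data = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "morphomovie mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", nrow(mesh$points)), con)
  writeLines(sprintf("%.17g %.17g 0", mesh$points[, 1], mesh$points[, 2]), con)
  nt <- nrow(mesh$triangles)
  writeLines(sprintf("CELLS %d %d", nt, 4 * nt), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(rep("5", nt), con)
  if (!is.null(cell_data) && length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", nt), con)
    for (nm in names(cell_data)) {
      writeLines(sprintf("SCALARS %s double 1", nm), con)
      writeLines("LOOKUP_TABLE default", con)
      writeLines(sprintf("%.17g", cell_data[[nm]]), con)
    }
  }
  invisible(file)
}

#' Read a legacy ASCII VTK unstructured grid written by \code{write_mesh_vtk}
#' @param file VTK file path.
#' @param stage optional stage to attach.
#' @return a \code{mm_mesh}; any cell data arrays are attached as the
#'   \code{cell_data} element.
#' @export
read_mesh_vtk <- function(file, stage = NULL) {
  lines <- readLines(file)
  pi_ <- grep("^POINTS", lines)[1]
  np <- as.integer(strsplit(lines[pi_], "\\s+")[[1]][2])
  pv <- do.call(rbind, lapply(lines[(pi_ + 1):(pi_ + np)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:2])))
  ci <- grep("^CELLS", lines)[1]
  nt <- as.integer(strsplit(lines[ci], "\\s+")[[1]][2])
  tv <- do.call(rbind, lapply(lines[(ci + 1):(ci + nt)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]][2:4]) + 1L))
  colnames(pv) <- c("x", "y")
  mesh <- new_tri_mesh(pv, tv, boundary_polygon = NULL, stage = stage,
                       flank_tol = 1e-6 * max(diff(range(pv[, 1])),
                                              diff(range(pv[, 2]))))
  mesh$boundary_polygon <- boundary_loop(mesh)
  cd <- grep("^SCALARS", lines)
  if (length(cd)) {
    mesh$cell_data <- lapply(cd, function(i)
      as.numeric(lines[(i + 2):(i + 1 + nt)]))
    names(mesh$cell_data) <- vapply(strsplit(lines[cd], "\\s+"), `[`,
                                    character(1), 2)
  }
  mesh
}
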