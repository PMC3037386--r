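# Conservative triangle-interpolation maps between the deformed mesh at t
# and the fresh mesh at t+1, and assembly of whole MorphoMovies.
#
# The deformed mesh at t and the fresh mesh at t+1 tile the identical
# polygon (the fresh mesh reuses the snapped deformed boundary as its
# boundary polygon), so the overlap-area weights satisfy both the partition
# (row) and coverage (column) identities to clipping accuracy.

#' Overlap area of two triangles
#'
#' Exact area of the convex intersection polygon (Sutherland-Hodgman
#' clipping).
#'
#' @param tri_a,tri_b 3x2 vertex matrices.
#' @return overlap area (>= 0).
#' @export
triangle_overlap_area <- function(tri_a, tri_b) {
  tri_a <- as.matrix(tri_a); tri_b <- as.matrix(tri_b)
  deg <- function(m) abs((m[2, 1] - m[1, 1]) * (m[3, 2] - m[1, 2]) -
                           (m[2, 2] - m[1, 2]) * (m[3, 1] - m[1, 1])) / 2 == 0
  if (deg(tri_a) || deg(tri_b)) stop("degenerate triangle")
  tri_overlap_cpp(tri_a, tri_b)
}

#' Build the triangle-interpolation map from a deformed mesh to the next mesh
#'
#' @param src_mesh mesh at frame t.
#' @param src_disp (n x 2) displacement matrix applied to \code{src_mesh}
#'   (use zero for an identity-geometry map).
#' @param tgt_mesh mesh at frame t+1, covering the same region as the
#'   deformed source mesh.
#' @param defect_tol maximum tolerated relative partition/coverage defect
#'   before the map is rejected as inconsistent.
#' @return object of class \code{mm_interp_map} holding the sparse weight
#'   matrix \code{W} (sources x targets, entries = overlap areas after
#'   proportional row repair), \code{src_areas} (deformed) and
#'   \code{tgt_areas}.
#' @export
build_interpolation_map <- function(src_mesh, src_disp, tgt_mesh,
                                    defect_tol = 1e-4) {
  newp <- src_mesh$points + src_disp
  src_areas <- triangle_signed_areas(newp, src_mesh$triangles)
  if (any(src_areas <= 0)) stop("deformed source mesh has inverted triangles")
  tgt_areas <- mesh_areas(tgt_mesh)
  mean_a <- mean(tgt_areas)
  tl <- overlap_map_cpp(newp, src_mesh$triangles, tgt_mesh$points,
                        tgt_mesh$triangles, 1e-12 * mean_a)
  W <- Matrix::sparseMatrix(i = tl$i, j = tl$j, x = tl$w,
                            dims = c(nrow(src_mesh$triangles),
                                     nrow(tgt_mesh$triangles)))
  rs <- Matrix::rowSums(W)
  part_def <- max(abs(rs - src_areas) / src_areas)
  if (part_def > defect_tol)
    stop(sprintf("partition defect %.3g exceeds %.3g: source and target do not tile the same region",
                 part_def, defect_tol))
  # proportional repair: dropped slivers are reassigned within each row so
  # the partition identity is exact
  W <- Matrix::Diagonal(x = src_areas / rs) %*% W
  cs <- Matrix::colSums(W)
  cov_def <- max(abs(cs - tgt_areas) / tgt_areas)
  if (cov_def > defect_tol)
    stop(sprintf("coverage defect %.3g exceeds %.3g", cov_def, defect_tol))
  structure(list(W = W, src_areas = src_areas, tgt_areas = tgt_areas,
                 partition_defect = part_def, coverage_defect = cov_def),
            class = "mm_interp_map")
}

#' @export
print.mm_interp_map <- function(x, ...) {
  cat(sprintf("<TriangleInterpolationMap %d -> %d triangles, %d overlaps, defects %.2g/%.2g>\n",
              nrow(x$W), ncol(x$W), Matrix::nnzero(x$W),
              x$partition_defect, x$coverage_defect))
  invisible(x)
}

#' Transfer a per-triangle field through an interpolation map
#'
#' \eqn{v_j = \sum_i v_i w_{ij} / A_j}: each target value is the area-weighted
#' convex combination of the source values it overlaps. Linear, positivity
#' and constant preserving, and obeys the maximum principle; the
#' area-integral \eqn{\sum_i v_i A_i} is conserved.
#'
#' @param field numeric vector, one value per source triangle.
#' @param map a \code{mm_interp_map}.
#' @return numeric vector, one value per target triangle.
#' @export
transfer <- function(field, map) {
  if (length(field) != nrow(map$W)) stop("field length does not match the source mesh")
  as.vector(Matrix::crossprod(map$W, field)) / map$tgt_areas
}

#' Reverse an interpolation map (target -> source direction)
#'
#' Transposition of the forward weights; reverse transfer is the exact
#' adjoint of forward transfer under the area-weighted inner product.
#'
#' @param map a \code{mm_interp_map}.
#' @return a \code{mm_interp_map} in the reverse direction.
#' @export
reverse_map <- function(map) {
  structure(list(W = Matrix::t(map$W), src_areas = map$tgt_areas,
                 tgt_areas = map$src_areas,
                 partition_defect = map$coverage_defect,
                 coverage_defect = map$partition_defect),
            class = "mm_interp_map")
}

#' Build a MorphoMovie from a shape sequence
#'
#' Runs the whole per-frame chain: control vectors from the splines, Gaussian
#' RBF boundary field with snapping to the next outline, spring-analogy
#' propagation with the chosen stiffness profile, re-meshing of the next
#' frame on the deformed boundary, and the conservative triangle
#' interpolation map.
#'
#' @param seq a \code{mm_sequence}.
#' @param splines list of \code{mm_spline} crossing all frames.
#' @param profile stiffness profile name (see \code{\link{stiffness_field}}).
#' @param target_edge_length mesh resolution.
#' @param rbf_width,rbf_ridge RBF parameters (see
#'   \code{\link{fit_gaussian_rbf}}).
#' @param stiffness_args extra arguments for \code{\link{stiffness_field}}.
#' @param verbose print per-frame progress.
#' @return object of class \code{mm_movie}: \code{meshes} (one per frame),
#'   \code{velocities} (per-frame displacement/hour matrices),
#'   \code{maps} (per frame pair), \code{log} (per-frame residuals and
#'   defects) and \code{config}.
#' @export
build_morphomovie <- function(seq, splines, profile = "constant",
                              target_edge_length = 0.2, rbf_width = NULL,
                              rbf_ridge = 1e-10, stiffness_args = list(),
                              verbose = FALSE) {
  T <- length(seq$frames)
  meshes <- vector("list", T)
  velocities <- vector("list", T - 1)
  maps <- vector("list", T - 1)
  logrec <- vector("list", T - 1)
  meshes[[1]] <- triangulate(seq$frames[[1]], target_edge_length)
  nb <- nrow(meshes[[1]]$boundary_polygon)
  for (t in seq_len(T - 1)) {
    mesh_t <- meshes[[t]]
    cv <- control_vectors(splines, seq$frames[[t]], seq$frames[[t + 1]])
    rbf <- fit_gaussian_rbf(cv, width = rbf_width, ridge = rbf_ridge)
    bdisp <- boundary_velocity_field(rbf, mesh_t, seq$frames[[t + 1]],
                                     snap = TRUE,
                                     fixed_below_x = seq$frames[[t]]$wall_x)
    stf <- do.call(stiffness_field, c(list(mesh_t, profile), stiffness_args))
    df <- propagate(mesh_t, bdisp, stf)
    newp <- mesh_t$points + df$disp
    bp_next <- newp[seq_len(nb), , drop = FALSE]
    if (!polygon_is_simple(bp_next))
      stop(sprintf("frame %d: deformed boundary self-intersects", t))
    meshes[[t + 1]] <- triangulate(seq$frames[[t + 1]], target_edge_length,
                                   boundary_points = bp_next)
    maps[[t]] <- build_interpolation_map(mesh_t, df$disp, meshes[[t + 1]])
    velocities[[t]] <- df$disp
    logrec[[t]] <- list(frame = t, iterations = df$iterations,
                        spring_residual = df$residual,
                        partition_defect = maps[[t]]$partition_defect,
                        coverage_defect = maps[[t]]$coverage_defect)
    if (verbose)
      message(sprintf("frame %d/%d: %d tris, %d spring iters, defect %.2g",
                      t, T - 1, nrow(meshes[[t + 1]]$triangles),
                      df$iterations, maps[[t]]$partition_defect))
  }
  structure(list(meshes = meshes, velocities = velocities, maps = maps,
                 log = logrec,
                 config = list(profile = profile,
                               target_edge_length = target_edge_length,
                               rbf_width = rbf_width, rbf_ridge = rbf_ridge,
                               stiffness_args = stiffness_args,
                               n_splines = length(splines),
                               shape_config = seq$config)),
            class = "mm_movie")
}

#' @export
print.mm_movie <- function(x, ...) {
  T <- length(x$meshes)
  cat(sprintf("<MorphoMovie: %d frames (%s .. %s), %d..%d triangles, profile '%s'>\n",
              T, x$meshes[[1]]$stage$label %||% "?",
              x$meshes[[T]]$stage$label %||% "?",
              nrow(x$meshes[[1]]$triangles), nrow(x$meshes[[T]]$triangles),
              x$config$profile))
  invisible(x)
}

#' Serialize a MorphoMovie to a directory of text files
#'
#' Per-frame OFF meshes, per-frame-pair displacement CSVs and sparse map
#' triplet files (i, j, w), plus a JSON manifest carrying the config and a
#' hash of it.
#'
#' @param movie a \code{mm_movie}.
#' @param dir output directory.
#' @export
write_morphomovie <- function(movie, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  T <- length(movie$meshes)
  for (t in seq_len(T))
    write_mesh_off(movie$meshes[[t]], file.path(dir, sprintf("mesh_%03d.off", t)))
  for (t in seq_len(T - 1)) {
    write.csv(format(as.data.frame(movie$velocities[[t]]) |>
                       setNames(c("dx", "dy")), digits = 17),
              file.path(dir, sprintf("velocity_%03d.csv", t)),
              row.names = FALSE, quote = FALSE)
    tr <- Matrix::summary(movie$maps[[t]]$W)
    write.csv(format(data.frame(i = tr$i, j = tr$j, w = tr$x), digits = 17),
              file.path(dir, sprintf("map_%03d.csv", t)), row.names = FALSE,
              quote = FALSE)
  }
  cfg <- movie$config
  manifest <- list(frames = T, config = cfg,
                   config_hash = config_hash(cfg),
                   version = as.character(utils::packageVersion("morphomovie")),
                   log = movie$log)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  # small deterministic polynomial hash; avoids an external digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read a MorphoMovie directory written by \code{write_morphomovie}
#' @param dir movie directory.
#' @return a \code{mm_movie} (stages restored from the shape config).
#' @export
read_morphomovie <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  T <- man$frames
  org <- man$config$shape_config$origin_day %||% 9L
  meshes <- lapply(seq_len(T), function(t)
    read_mesh_off(file.path(dir, sprintf("mesh_%03d.off", t)),
                  stage = stage_label(t - 1L, as.integer(org))))
  velocities <- lapply(seq_len(T - 1), function(t)
    as.matrix(read.csv(file.path(dir, sprintf("velocity_%03d.csv", t)))))
  maps <- lapply(seq_len(T - 1), function(t) {
    tr <- read.csv(file.path(dir, sprintf("map_%03d.csv", t)))
    newp <- meshes[[t]]$points + velocities[[t]]
    sa <- triangle_signed_areas(newp, meshes[[t]]$triangles)
    ta <- mesh_areas(meshes[[t + 1]])
    W <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$w,
                              dims = c(nrow(meshes[[t]]$triangles),
                                       nrow(meshes[[t + 1]]$triangles)))
    structure(list(W = W, src_areas = sa, tgt_areas = ta,
                   partition_defect = max(abs(Matrix::rowSums(W) - sa) / sa),
                   coverage_defect = max(abs(Matrix::colSums(W) - ta) / ta)),
              class = "mm_interp_map")
  })
  structure(list(meshes = meshes, velocities = velocities, maps = maps,
                 log = man$log, config = man$config), class = "mm_movie")
}
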