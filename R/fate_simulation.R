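# Virtual clonal fate simulation: advection of labeled-cell density through
# the triangle-interpolation maps, plus explicit finite-volume diffusion
# modeling isotropic cell mixing. Fields are per-triangle labeled-cell
# densities (dimensionless fractions in [0,1]); areas carry the units.

#' Diffusion (cell mixing) configuration
#'
#' @param D diffusion constant in model-area units per hour (>= 0).
#' @param substeps explicit Euler substeps per hour; increased automatically
#'   if the stability bound requires it.
#' @param safety stability safety factor in (0, 1].
#' @return a \code{mm_diffusion} config.
#' @export
diffusion_config <- function(D = 0.03, substeps = 10L, safety = 0.5) {
  if (D < 0) stop("D must be non-negative")
  if (substeps < 1) stop("substeps must be >= 1")
  structure(list(D = D, substeps = as.integer(substeps), safety = safety),
            class = "mm_diffusion")
}

#' Diffusion config from a mixing-calibration level
#'
#' The clone-overlap calibration compares virtual-clone overlap at the
#' reference mixing levels 0 / 0.03 / 0.08, whose original units are not
#' tied to this model's dimensionless geometry. They are re-expressed in
#' model-area units per hour by the factor \code{scale} (default 0.05),
#' chosen so the low level spreads a clone by about half the initial bud
#' radius over the full 72-hour window (\eqn{\sigma = \sqrt{2 D t}}) — the
#' magnitude of dispersal real mesenchymal clones display — rather than
#' homogenizing the whole bud.
#'
#' @param level mixing level on the reference scale (e.g. 0.03).
#' @param scale model-unit re-expression factor.
#' @param ... passed to \code{\link{diffusion_config}}.
#' @export
scaled_diffusion <- function(level, scale = 0.05, ...)
  diffusion_config(level * scale, ...)

#' Seed a virtual clone on one triangle
#'
#' Labeled-cell density 1 on the chosen triangle ("every cell labeled"),
#' 0 elsewhere.
#'
#' @param mesh a \code{mm_mesh}.
#' @param triangle_id triangle index.
#' @return numeric per-triangle field.
#' @export
seed_clone <- function(mesh, triangle_id) {
  nt <- nrow(mesh$triangles)
  if (triangle_id < 1 || triangle_id > nt) stop("triangle index out of range")
  f <- numeric(nt)
  f[triangle_id] <- 1
  f
}

# One-hour explicit-Euler diffusion operator as a sparse matrix.
# Two-point flux across each interior edge: F = D * L_e / d_c * (v_j - v_i);
# zero-flux boundaries. Returns the substep matrix and the substep count
# actually used (>= cfg$substeps when stability demands it).
diffusion_operator <- function(mesh, cfg, hours = 1) {
  nt <- nrow(mesh$triangles)
  if (cfg$D == 0) return(list(A = Matrix::Diagonal(nt), substeps = 1L))
  nb <- edge_neighbors(mesh)
  areas <- mesh_areas(mesh)
  cond <- cfg$D * nb$edge_length / nb$centroid_distance
  # stability: dt <= safety * min_i area_i / (sum of conductances at i)
  csum <- numeric(nt)
  for (r in seq_len(nrow(nb))) {
    csum[nb$tri1[r]] <- csum[nb$tri1[r]] + cond[r]
    csum[nb$tri2[r]] <- csum[nb$tri2[r]] + cond[r]
  }
  dt_max <- cfg$safety * min(areas / pmax(csum, .Machine$double.xmin))
  ns <- max(cfg$substeps, ceiling(hours / dt_max))
  dt <- hours / ns
  i <- c(nb$tri1, nb$tri2, nb$tri1, nb$tri2)
  j <- c(nb$tri2, nb$tri1, nb$tri1, nb$tri2)
  x <- c(dt * cond / areas[nb$tri1], dt * cond / areas[nb$tri2],
         -dt * cond / areas[nb$tri1], -dt * cond / areas[nb$tri2])
  A <- Matrix::Diagonal(nt) + Matrix::sparseMatrix(i = i, j = j, x = x,
                                                   dims = c(nt, nt))
  list(A = A, substeps = as.integer(ns))
}

#' Diffuse a field on a fixed mesh for a given number of hours
#'
#' Finite-volume two-point flux scheme on the triangle adjacency with
#' zero-flux boundaries, explicit Euler in time. Conserves the area integral
#' of the field.
#'
#' @param field per-triangle values.
#' @param mesh a \code{mm_mesh}.
#' @param cfg a \code{mm_diffusion}.
#' @param hours diffusion time.
#' @return diffused per-triangle field.
#' @export
diffuse <- function(field, mesh, cfg, hours = 1) {
  if (length(field) != nrow(mesh$triangles)) stop("field/mesh size mismatch")
  op <- diffusion_operator(mesh, cfg, hours)
  v <- field
  for (s in seq_len(op$substeps)) v <- as.vector(op$A %*% v)
  v
}

#' Simulate the fate of a labeled region through a MorphoMovie
#'
#' Per hour: diffuse on the current mesh (cell mixing), then transfer the
#' field to the next frame's mesh through the conservative interpolation
#' map.
#'
#' @param movie a \code{mm_movie}.
#' @param seed_field per-triangle field on \code{from_frame}'s mesh, or a
#'   single triangle index (then \code{\link{seed_clone}} is used).
#' @param cfg a \code{mm_diffusion}.
#' @param from_frame starting frame (default 1).
#' @param to_frame final frame (default last).
#' @return list of per-frame fields from \code{from_frame} to
#'   \code{to_frame}.
#' @export
simulate_fate <- function(movie, seed_field, cfg = diffusion_config(0),
                          from_frame = 1L, to_frame = length(movie$meshes)) {
  T <- length(movie$meshes)
  if (from_frame > to_frame) stop("from_frame must not exceed to_frame")
  if (to_frame > T) stop("to_frame beyond movie end")
  if (length(seed_field) == 1 && seed_field == round(seed_field))
    seed_field <- seed_clone(movie$meshes[[from_frame]], seed_field)
  fields <- vector("list", to_frame - from_frame + 1)
  fields[[1]] <- seed_field
  v <- seed_field
  for (t in seq_len(to_frame - from_frame)) {
    fr <- from_frame + t - 1L
    v <- diffuse(v, movie$meshes[[fr]], cfg, hours = 1)
    v <- transfer(v, movie$maps[[fr]])
    fields[[t + 1]] <- v
  }
  fields
}

#' One-hour forward transport operators of a movie
#'
#' Sparse matrices \eqn{M_t} with \eqn{field_{t+1} = M_t field_t}
#' (diffusion substeps followed by the interpolation transfer). Because
#' transport is linear these operators, composed, give the fate of every
#' seed triangle at once; \code{\link{best_match}} relies on this.
#'
#' @param movie a \code{mm_movie}.
#' @param cfg a \code{mm_diffusion}.
#' @return list of sparse matrices, one per frame pair.
#' @export
transport_operators <- function(movie, cfg = diffusion_config(0)) {
  T <- length(movie$meshes)
  lapply(seq_len(T - 1), function(t) {
    op <- diffusion_operator(movie$meshes[[t]], cfg, 1)
    A <- op$A
    M <- A
    if (op$substeps > 1) for (s in seq_len(op$substeps - 1)) M <- A %*% M
    map <- movie$maps[[t]]
    # transfer(v) = t(W) v / tgt_areas, so the operator is D(1/A_tgt) t(W)
    Matrix::Diagonal(x = 1 / map$tgt_areas) %*% Matrix::t(map$W) %*% M
  })
}

#' Trace progenitor regions backwards through a movie
#'
#' Reverse transport of final-frame region indicators: per hour the field is
#' pulled back through the transposed interpolation map and then diffused on
#' the earlier mesh (mixing acts in both time directions on membership
#' probabilities). If the regions partition the final frame, the per-triangle
#' probabilities across regions sum to one at every frame.
#'
#' @param movie a \code{mm_movie}.
#' @param final_regions list of disjoint triangle-index vectors on the last
#'   frame's mesh.
#' @param cfg a \code{mm_diffusion}.
#' @return list (one element per region) of lists of per-frame fields,
#'   indexed chronologically (element 1 = first frame).
#' @export
simulate_progenitors <- function(movie, final_regions,
                                 cfg = diffusion_config(0)) {
  T <- length(movie$meshes)
  all_idx <- unlist(final_regions)
  if (anyDuplicated(all_idx)) stop("final regions must be disjoint")
  ntT <- nrow(movie$meshes[[T]]$triangles)
  lapply(final_regions, function(reg) {
    v <- numeric(ntT); v[reg] <- 1
    fields <- vector("list", T)
    fields[[T]] <- v
    for (t in rev(seq_len(T - 1))) {
      rmap <- reverse_map(movie$maps[[t]])
      v <- transfer(v, rmap)
      v <- diffuse(v, movie$meshes[[t]], cfg, hours = 1)
      fields[[t]] <- v
    }
    fields
  })
}

#' Area integral of a per-triangle field
#' @param field per-triangle values.
#' @param mesh the mesh carrying the field.
#' @return \eqn{\sum_i v_i A_i}.
#' @export
field_integral <- function(field, mesh) sum(field * mesh_areas(mesh))
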