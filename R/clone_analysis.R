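# Experimental clones on the final mesh, virtual-clone scoring, exhaustive
# best-match search across seed triangles, map-level scores, mean-filter
# probability estimation, overlap quantification and clone extent
# measurements.

#' Construct an experimental clone from triangle indices
#' @param triangles triangle indices on the stated frame's mesh.
#' @param frame frame index the clone lives on (default: last frame).
#' @param meta optional metadata (e.g. the source mask file).
#' @export
experimental_clone <- function(triangles, frame = NULL, meta = NULL) {
  triangles <- sort(unique(as.integer(triangles)))
  if (length(triangles) < 1) stop("a clone needs at least one triangle")
  structure(list(triangles = triangles, n = length(triangles),
                 frame = frame, meta = meta), class = "mm_clone")
}

#' @export
print.mm_clone <- function(x, ...) {
  cat(sprintf("<ExperimentalClone: %d triangles%s>\n", x$n,
              if (!is.null(x$frame)) sprintf(" on frame %d", x$frame) else ""))
  invisible(x)
}

#' Rasterize a binary mask onto a mesh
#'
#' A triangle joins the clone when at least \code{coverage} of the labeled
#' mask pixels... more precisely: when the fraction of pixels under the
#' triangle that are labeled reaches \code{coverage}. The alignment maps
#' pixel coordinates (col, row with row 1 at the top) into mesh coordinates
#' by scale, rotation and translation.
#'
#' @param mask logical or 0/1 matrix (rows = image rows).
#' @param mesh a \code{mm_mesh}.
#' @param alignment list with \code{scale}, \code{rotation} (radians) and
#'   \code{translation} (length-2), pixel -> mesh; see
#'   \code{\link{mask_alignment}}.
#' @param coverage inclusion threshold (default 0.5).
#' @return a \code{mm_clone} (possibly empty, with a warning).
#' @export
rasterize_mask_to_mesh <- function(mask, mesh, alignment = mask_alignment(),
                                   coverage = 0.5) {
  mask <- as.matrix(mask) > 0
  nr <- nrow(mask); nc <- ncol(mask)
  # pixel centers in mesh coordinates
  px <- rep(seq_len(nc) - 0.5, each = nr)
  py <- rep(nr - seq_len(nr) + 0.5, times = nc)  # flip: row 1 = top
  th <- alignment$rotation
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pts <- cbind(px, py) %*% t(R) * alignment$scale
  pts[, 1] <- pts[, 1] + alignment$translation[1]
  pts[, 2] <- pts[, 2] + alignment$translation[2]
  lab <- as.vector(mask)
  tri <- mesh$triangles
  inc <- logical(nrow(tri))
  p <- mesh$points
  for (k in seq_len(nrow(tri))) {
    v <- p[tri[k, ], ]
    inb <- pts[, 1] >= min(v[, 1]) & pts[, 1] <= max(v[, 1]) &
      pts[, 2] >= min(v[, 2]) & pts[, 2] <= max(v[, 2])
    if (!any(inb)) next
    sub <- pts[inb, , drop = FALSE]
    inside <- as.logical(point_in_polygon_cpp(sub[, 1], sub[, 2],
                                              v[, 1], v[, 2]))
    if (!any(inside)) next
    inc[k] <- mean(lab[inb][inside]) >= coverage
  }
  idx <- which(inc)
  if (!length(idx)) {
    warning("mask rasterization produced an empty clone")
    return(structure(list(triangles = integer(0), n = 0L, frame = NULL,
                          meta = NULL), class = "mm_clone"))
  }
  experimental_clone(idx)
}

#' Pixel-to-mesh alignment transform
#' @param scale isotropic scale factor.
#' @param rotation rotation in radians.
#' @param translation length-2 translation in mesh units.
#' @export
mask_alignment <- function(scale = 1, rotation = 0, translation = c(0, 0)) {
  list(scale = scale, rotation = rotation, translation = translation)
}

#' Score a virtual clone against an experimental clone
#'
#' Two factors. The first is the probability affinity between the virtual
#' clone's labeled-cell distribution and the experimental clone, summed over
#' their common triangles and normalized so that a virtual clone matching
#' the experimental clone exactly scores 1:
#' \eqn{F_1 = \sum_{i \in E \cap supp(v)} v_i / (\|v\|_2 \sqrt{n_c})}.
#' The second is the proportion of experimental-clone triangles contained in
#' the virtual clone's support, a [0, 1] penalty for labeled cells found
#' outside the virtual clone. The product is bounded in [0, 1], equals 0
#' exactly when the supports are disjoint, and can only decrease when a
#' clone triangle moves from inside to outside the virtual support.
#'
#' @param virtual per-triangle virtual-clone probability field.
#' @param clone a \code{mm_clone} on the same mesh/frame.
#' @param support_threshold values above this count as inside the virtual
#'   clone (default 1e-6).
#' @return scalar score in [0, 1].
#' @export
clone_score <- function(virtual, clone, support_threshold = 1e-6) {
  if (clone$n < 1) stop("empty experimental clone")
  v <- virtual[clone$triangles]
  v[v <= support_threshold] <- 0
  m <- sum(v > 0)
  if (m == 0) return(0)
  nrm <- sqrt(sum(virtual^2))
  (sum(v) / (nrm * sqrt(clone$n))) * m / clone$n
}

#' Exhaustive best-match search over seed triangles
#'
#' Simulates (via composed linear transport operators) the virtual clone of
#' every seed triangle of \code{seed_frame}, scores each against the
#' experimental clone on the final frame, and returns the argmax. Ties break
#' to the lowest triangle index. The number of clone comparisons performed
#' equals the number of seed triangles.
#'
#' @param movie a \code{mm_movie}.
#' @param clone a \code{mm_clone} on the final frame.
#' @param cfg a \code{mm_diffusion}.
#' @param seed_frame frame whose triangles are candidate seeds (default 1).
#' @param operator optional precomputed full transport operator (matrix of
#'   final-frame fields, one column per seed) from
#'   \code{\link{full_transport_operator}}; avoids recomputation across
#'   clones.
#' @return list with \code{seed}, \code{score}, \code{n_comparisons} and the
#'   winning \code{field}.
#' @export
best_match <- function(movie, clone, cfg = diffusion_config(0),
                       seed_frame = 1L, operator = NULL) {
  if (is.null(operator))
    operator <- full_transport_operator(movie, cfg, seed_frame)
  nt <- ncol(operator)
  vals <- as.matrix(operator[clone$triangles, , drop = FALSE])
  vals[vals <= 1e-6] <- 0
  nrm <- sqrt(colSums(as.matrix(operator)^2))
  scores <- (colSums(vals) / (nrm * sqrt(clone$n))) *
    colSums(vals > 0) / clone$n
  seed <- which.max(scores)  # which.max takes the first (lowest index) tie
  list(seed = seed, score = scores[seed], n_comparisons = nt,
       field = as.vector(operator[, seed]), scores = as.vector(scores))
}

#' Full transport operator from a seed frame to the final frame
#'
#' Column s is the final-frame virtual-clone field of seed triangle s.
#'
#' @inheritParams best_match
#' @return sparse (or dense) matrix, final-frame triangles x seed triangles.
#' @export
full_transport_operator <- function(movie, cfg = diffusion_config(0),
                                    seed_frame = 1L) {
  T <- length(movie$meshes)
  n0 <- nrow(movie$meshes[[seed_frame]]$triangles)
  M <- diag(n0)
  for (t in seed_frame:(T - 1)) {
    op <- diffusion_operator(movie$meshes[[t]], cfg, 1)
    for (s in seq_len(op$substeps)) M <- as.matrix(op$A %*% M)
    map <- movie$maps[[t]]
    M <- as.matrix(Matrix::crossprod(map$W, M)) / map$tgt_areas
  }
  M
}

#' Score a whole movie against a clone collection
#'
#' Product over clones of their best-match scores; maps must match every
#' clone to score well.
#'
#' @param movie a \code{mm_movie}.
#' @param clones list of \code{mm_clone} on the final frame.
#' @param cfg a \code{mm_diffusion}.
#' @param seed_frame candidate-seed frame.
#' @return list with \code{total} (the product score), \code{per_clone}
#'   (best score and seed per clone) and \code{n_comparisons}.
#' @export
map_score <- function(movie, clones, cfg = diffusion_config(0),
                      seed_frame = 1L) {
  if (!length(clones)) stop("need at least one clone")
  op <- full_transport_operator(movie, cfg, seed_frame)
  per <- lapply(clones, function(cl) {
    bm <- best_match(movie, cl, cfg, seed_frame, operator = op)
    list(seed = bm$seed, score = bm$score)
  })
  scores <- vapply(per, function(p) p$score, numeric(1))
  list(total = prod(scores), per_clone = per,
       n_comparisons = length(clones) * ncol(op))
}

#' Number of clonal comparisons in a full map evaluation
#'
#' One comparison per (seed triangle, experimental clone) pair.
#'
#' @param n_seed_triangles triangles on the seed-frame mesh.
#' @param n_clones experimental clones.
#' @export
comparison_count <- function(n_seed_triangles, n_clones)
  as.numeric(n_seed_triangles) * as.numeric(n_clones)

#' Estimate a clone's probability distribution by mean filtering
#'
#' k rounds of averaging each triangle with itself and its edge-adjacent
#' neighbors, renormalizing the distribution to total 1 after every round.
#'
#' @param clone a \code{mm_clone}.
#' @param mesh the mesh carrying it.
#' @param iterations number of smoothing rounds (k = 0 gives the normalized
#'   indicator).
#' @return per-triangle probability field summing to 1.
#' @export
mean_filter <- function(clone, mesh, iterations = 3L) {
  nt <- nrow(mesh$triangles)
  v <- numeric(nt)
  v[clone$triangles] <- 1
  v <- v / sum(v)
  if (iterations > 0) {
    nb <- edge_neighbors(mesh)
    for (it in seq_len(iterations)) {
      acc <- v
      cnt <- rep(1, nt)
      for (r in seq_len(nrow(nb))) {
        acc[nb$tri1[r]] <- acc[nb$tri1[r]] + v[nb$tri2[r]]
        acc[nb$tri2[r]] <- acc[nb$tri2[r]] + v[nb$tri1[r]]
        cnt[nb$tri1[r]] <- cnt[nb$tri1[r]] + 1
        cnt[nb$tri2[r]] <- cnt[nb$tri2[r]] + 1
      }
      v <- acc / cnt
      v <- v / sum(v)
    }
  }
  v
}

#' Overlap score between two clone probability distributions
#'
#' Bhattacharyya coefficient \eqn{\sum_i \sqrt{p_i q_i}} over the common
#' support: symmetric, 0 for disjoint supports, 1 for identical normalized
#' distributions.
#'
#' @param a,b per-triangle probability fields on the same mesh (normalized to
#'   sum 1, as produced by \code{\link{mean_filter}}).
#' @return scalar overlap in [0, 1].
#' @export
overlap_score <- function(a, b) {
  if (length(a) != length(b)) stop("fields live on different meshes")
  sum(sqrt(pmax(a, 0) * pmax(b, 0)))
}

#' Clone extents along the PD and AP axes
#'
#' Axis-aligned extents of the clone's triangle union relative to the bud's
#' (non-flank, x > 0) extents, plus the PD/AP anisotropy ratio and an
#' isotropy class.
#'
#' @param clone a \code{mm_clone}.
#' @param mesh the mesh carrying it.
#' @param anisotropy_threshold ratio above which (or below whose inverse) a
#'   clone is classed anisotropic (default 1.5).
#' @return list with \code{pd_fraction}, \code{ap_fraction}, \code{ratio}
#'   and \code{class} ("isotropic" or "anisotropic").
#' @export
clone_extents <- function(clone, mesh, anisotropy_threshold = 1.5) {
  if (clone$n < 1) stop("empty clone")
  vids <- unique(as.vector(mesh$triangles[clone$triangles, , drop = FALSE]))
  cp <- mesh$points[vids, , drop = FALSE]
  bud <- mesh$points[mesh$points[, 1] >= -1e-9, , drop = FALSE]
  pd_limb <- diff(range(bud[, 1]))
  ap_limb <- diff(range(bud[, 2]))
  pd <- diff(range(cp[, 1])) / pd_limb
  ap <- diff(range(cp[, 2])) / ap_limb
  ratio <- pd / ap
  cls <- if (ratio > anisotropy_threshold) "anisotropic" else "isotropic"
  list(pd_fraction = pd, ap_fraction = ap, ratio = ratio, class = cls)
}
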