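# Edge spring analogy: propagate prescribed boundary displacements into the
# mesh interior by relaxing lineal edge springs to equilibrium. The spring
# analogy is a mesh-deformation device, not a mechanical model of the
# tissue; its one free knob — the spatial distribution of edge stiffness —
# is what generates alternative internal movement hypotheses for the same
# boundary history.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Per-edge stiffness field
#'
#' Stiffness of edge e is \eqn{k_e = f(x_e) / l_e} with \eqn{l_e} the edge
#' length (shorter edges are stiffer, the usual lineal spring-analogy
#' scaling) and \eqn{f} a profile over the PD (x) coordinate of the edge
#' midpoint:
#' \itemize{
#'   \item \code{"constant"}: f = 1 everywhere.
#'   \item \code{"sigmoid"}: f rises distally — stiffer distal edges restrict
#'     distal expansion.
#'   \item \code{"inverted_sigmoid"}: f falls distally — softer distal edges
#'     allow greater distal expansion.
#' }
#'
#' @param mesh a \code{mm_mesh}.
#' @param profile one of "constant", "sigmoid", "inverted_sigmoid".
#' @param midpoint profile midpoint as a fraction of the PD extent of the
#'   non-flank part of the mesh (default 2/3).
#' @param steepness dimensionless steepness; the logistic argument is
#'   \code{steepness * (x - x_mid) / PD_extent} scaled so the default gives a
#'   clear but smooth transition (default 10).
#' @param amplitude profile dynamic range: f spans [1, 1 + amplitude].
#' @return object of class \code{mm_stiffness}: per-edge coefficients plus
#'   the profile description.
#' @export
stiffness_field <- function(mesh, profile = c("constant", "sigmoid",
                                              "inverted_sigmoid"),
                            midpoint = 2 / 3, steepness = 10, amplitude = 4) {
  profile <- match.arg(profile)
  p <- mesh$points
  e <- mesh$edges
  mid_x <- (p[e[, 1], 1] + p[e[, 2], 1]) / 2
  len <- sqrt(rowSums((p[e[, 1], , drop = FALSE] - p[e[, 2], , drop = FALSE])^2))
  x0 <- 0                      # body wall
  x1 <- max(p[, 1])            # distal tip
  ext <- max(x1 - x0, .Machine$double.eps)
  z <- steepness * ((mid_x - x0) / ext - midpoint)
  f <- switch(profile,
              constant = rep(1, nrow(e)),
              sigmoid = 1 + amplitude * sigmoid(z),
              inverted_sigmoid = 1 + amplitude * (1 - sigmoid(z)))
  k <- f / len
  if (any(!is.finite(k)) || any(k <= 0))
    stop("non-positive or non-finite stiffness coefficient")
  structure(list(k = k, profile = profile, midpoint = midpoint,
                 steepness = steepness, amplitude = amplitude),
            class = "mm_stiffness")
}

#' Propagate boundary displacements into the mesh interior
#'
#' Jacobi relaxation of the spring equilibrium: each free node is repeatedly
#' moved to the stiffness-weighted average displacement of its edge
#' neighbors until the largest update falls below tolerance. Flank nodes are
#' pinned at zero, non-flank boundary nodes at the prescribed displacement.
#' The converged interior displacement is a convex combination of the
#' boundary values (discrete maximum principle). After applying the
#' displacements, element inversion is checked; on failure the step is
#' retried as two half-steps.
#'
#' @param mesh a \code{mm_mesh}.
#' @param boundary_disp (n_points x 2) matrix; rows of non-flank boundary
#'   nodes hold the prescribed displacement (interior rows ignored).
#' @param stiffness a \code{mm_stiffness} (default: constant profile).
#' @param max_iter iteration cap.
#' @param tol convergence tolerance; default 1e-8 times the mean edge length.
#' @param relaxation Jacobi relaxation factor omega in (0, 1].
#' @param fix_flank pin flank nodes to zero (disable only for rigid-motion
#'   checks).
#' @param .depth internal recursion depth of the half-step retry.
#' @return object of class \code{mm_displacement}: \code{disp} (n x 2),
#'   \code{iterations}, \code{residual}.
#' @export
propagate <- function(mesh, boundary_disp, stiffness = NULL,
                      max_iter = 10000L, tol = NULL, relaxation = 1,
                      fix_flank = TRUE, .depth = 0L) {
  n <- nrow(mesh$points)
  if (is.null(stiffness)) stiffness <- stiffness_field(mesh, "constant")
  elen <- sqrt(rowSums((mesh$points[mesh$edges[, 1], , drop = FALSE] -
                          mesh$points[mesh$edges[, 2], , drop = FALSE])^2))
  if (is.null(tol)) tol <- 1e-8 * mean(elen)
  fixed <- rep(FALSE, n)
  fixed[mesh$boundary_nodes] <- TRUE
  fd <- boundary_disp
  if (fix_flank) fd[mesh$flank_nodes, ] <- 0
  res <- spring_jacobi_cpp(n, mesh$edges, stiffness$k, fixed, fd,
                           as.integer(max_iter), tol, relaxation)
  if (res$residual >= tol && res$iterations >= max_iter)
    stop(sprintf("spring relaxation did not converge (residual %.3g after %d iterations)",
                 res$residual, res$iterations))
  newp <- mesh$points + res$disp
  if (any(triangle_signed_areas(newp, mesh$triangles) <= 0)) {
    if (.depth >= 4)
      stop("element inversion persists after half-step subdivision")
    half <- propagate(mesh, boundary_disp / 2, stiffness, max_iter, tol,
                      relaxation, fix_flank, .depth + 1L)
    mesh2 <- mesh
    mesh2$points <- mesh$points + half$disp
    rest <- boundary_disp - half$disp
    second <- propagate(mesh2, rest, stiffness, max_iter, tol, relaxation,
                        fix_flank, .depth + 1L)
    out <- half
    out$disp <- half$disp + second$disp
    out$iterations <- half$iterations + second$iterations
    out$residual <- max(half$residual, second$residual)
    return(out)
  }
  structure(list(disp = res$disp, iterations = res$iterations,
                 residual = res$residual), class = "mm_displacement")
}
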