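# Boundary control splines -> control vectors -> Gaussian RBF boundary
# velocity fields.
#
# A control spline is a user-supplied polyline crossing the whole outline
# sequence roughly along the PD axis. Its intersection with outline t and
# outline t+1 pairs up points on consecutive outlines; the resulting control
# vectors are interpolated onto every boundary mesh node with Gaussian radial
# basis functions (one scalar interpolant per displacement component).

#' Create a control spline from an ordered list of points
#' @param points two-column matrix of control points (>= 2 rows).
#' @param name optional identifier.
#' @export
control_spline <- function(points, name = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("a control spline needs at least 2 points")
  colnames(points) <- c("x", "y")
  structure(list(points = points, name = name), class = "mm_spline")
}

#' Write / read a named list of control splines as JSON
#' @param splines list of \code{mm_spline}.
#' @param file JSON path.
#' @export
write_splines <- function(splines, file) {
  obj <- lapply(splines, function(s)
    list(name = s$name, points = unname(apply(s$points, 1, as.numeric,
                                              simplify = FALSE))))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_splines
#' @export
read_splines <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = FALSE)
  lapply(obj, function(s)
    control_spline(do.call(rbind, lapply(s$points, unlist)), name = s$name))
}

# intersections of segment chains A (open) and B (closed polygon),
# ordered by arc-length position along A
segchain_intersections <- function(A, B, closedB = TRUE) {
  nA <- nrow(A); nB <- nrow(B)
  ia <- seq_len(nA - 1)
  ib <- if (closedB) seq_len(nB) else seq_len(nB - 1)
  jb <- if (closedB) c(2:nB, 1) else 2:nB
  res <- list()
  lenA <- c(0, cumsum(sqrt(diff(A[, 1])^2 + diff(A[, 2])^2)))
  for (i in ia) {
    p <- A[i, ]; r <- A[i + 1, ] - p
    q1 <- B[ib, , drop = FALSE]; q2 <- B[jb, , drop = FALSE]
    s <- q2 - q1
    denom <- r[1] * s[, 2] - r[2] * s[, 1]
    qp1 <- q1[, 1] - p[1]; qp2 <- q1[, 2] - p[2]
    t <- (qp1 * s[, 2] - qp2 * s[, 1]) / denom
    u <- (qp1 * r[2] - qp2 * r[1]) / (-denom)
    hit <- is.finite(t) & t >= -1e-12 & t <= 1 + 1e-12 &
      u >= -1e-12 & u <= 1 + 1e-12
    if (any(hit)) {
      tt <- t[hit]
      px <- p[1] + tt * r[1]; py <- p[2] + tt * r[2]
      res[[length(res) + 1]] <- cbind(x = px, y = py,
                                      s = lenA[i] + tt * sqrt(sum(r^2)),
                                      edge = which(hit))
    }
  }
  if (!length(res)) return(matrix(numeric(0), 0, 4,
                                  dimnames = list(NULL, c("x", "y", "s", "edge"))))
  out <- do.call(rbind, res)
  out <- out[order(out[, "s"]), , drop = FALSE]
  # merge numerically duplicated hits (spline passing through an outline vertex)
  if (nrow(out) > 1) {
    d <- c(Inf, sqrt(diff(out[, "x"])^2 + diff(out[, "y"])^2))
    out <- out[d > 1e-9, , drop = FALSE]
  }
  out
}

#' Intersect a control spline with a shape outline
#'
#' Returns the intersection points ordered along the spline. Intersections
#' with the flank (the artificial body: outline points at or left of the
#' body wall) are excluded, since flank boundary points are pinned.
#'
#' @param spline a \code{mm_spline}.
#' @param shape a \code{mm_shape}.
#' @return matrix with columns x, y, s (arc-length position along the spline).
#' @export
intersect_spline <- function(spline, shape) {
  out <- segchain_intersections(spline$points, shape$outline)
  if (!nrow(out)) return(out[, 1:3, drop = FALSE])
  # drop flank hits: points on the body-wall line or the artificial body
  wall_x <- max(shape$outline[shape$flank_span, 1])
  keep <- out[, "x"] > wall_x + 1e-9
  out[keep, 1:3, drop = FALSE]
}

#' Control vectors between two consecutive outlines
#'
#' The k-th intersection of each spline with outline t is paired with the
#' k-th intersection of the same spline with outline t+1 (rank pairing along
#' the spline).
#'
#' @param splines list of \code{mm_spline}.
#' @param shape_t,shape_t1 consecutive \code{mm_shape}s.
#' @return list with matrices \code{origins}, \code{tips} and
#'   \code{vectors = tips - origins}.
#' @export
control_vectors <- function(splines, shape_t, shape_t1) {
  org <- list(); tip <- list()
  for (si in seq_along(splines)) {
    a <- intersect_spline(splines[[si]], shape_t)
    b <- intersect_spline(splines[[si]], shape_t1)
    if (nrow(a) != nrow(b))
      stop(sprintf("spline '%s': %d intersections on frame t but %d on frame t+1",
                   splines[[si]]$name %||% as.character(si), nrow(a), nrow(b)))
    if (nrow(a) > 0) {
      org[[length(org) + 1]] <- a[, c("x", "y"), drop = FALSE]
      tip[[length(tip) + 1]] <- b[, c("x", "y"), drop = FALSE]
    }
  }
  if (!length(org)) stop("no control vectors: no spline intersects both outlines")
  origins <- do.call(rbind, org)
  tips <- do.call(rbind, tip)
  list(origins = origins, tips = tips, vectors = tips - origins)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit Gaussian radial basis interpolants to a control-vector set
#'
#' Two scalar interpolants (x and y displacement) as weighted sums of
#' Gaussian bumps \eqn{\phi(r) = exp(-r^2 / (2\sigma^2))} centred at the
#' control-vector origins. Coefficients solve the (optionally ridge
#' regularized) linear least squares system; with \code{ridge = 0} and a
#' nonsingular square system the fit interpolates the control vectors
#' exactly.
#'
#' @param cv a control-vector set from \code{control_vectors}.
#' @param width Gaussian scale sigma; default = mean spacing between
#'   consecutive origins.
#' @param ridge ridge parameter lambda (default 1e-10 for conditioning).
#' @return object of class \code{mm_rbf}.
#' @export
fit_gaussian_rbf <- function(cv, width = NULL, ridge = 1e-10) {
  centers <- cv$origins
  n <- nrow(centers)
  if (n < 1) stop("need at least one control vector")
  if (is.null(width)) {
    if (n > 1) {
      d <- sqrt(diff(centers[, 1])^2 + diff(centers[, 2])^2)
      width <- mean(d)
      if (width <= 0) width <- 1
    } else width <- 1
  }
  if (width <= 0) stop("width must be positive")
  if (ridge < 0) stop("ridge must be non-negative")
  G <- exp(-as.matrix(dist(centers))^2 / (2 * width^2))
  A <- G + diag(ridge, n)
  co <- tryCatch(solve(A, cv$vectors),
                 error = function(e)
                   stop("singular RBF system; increase ridge", call. = FALSE))
  structure(list(centers = centers, coefficients = co, width = width,
                 ridge = ridge), class = "mm_rbf")
}

#' Evaluate an RBF displacement interpolant at arbitrary points
#' @param rbf a \code{mm_rbf}.
#' @param pts two-column matrix of evaluation points.
#' @return matrix of interpolated (dx, dy).
#' @export
rbf_evaluate <- function(rbf, pts) {
  pts <- matrix(pts, ncol = 2)
  d2 <- outer(pts[, 1], rbf$centers[, 1], "-")^2 +
    outer(pts[, 2], rbf$centers[, 2], "-")^2
  Phi <- exp(-d2 / (2 * rbf$width^2))
  Phi %*% rbf$coefficients
}

#' Boundary velocity field on a mesh from an RBF interpolant
#'
#' Evaluates the interpolant at every non-flank boundary node; flank nodes
#' get zero. With \code{snap = TRUE} (the default) the displaced nodes are
#' then projected onto the next outline so that the deformed boundary lies
#' exactly on it.
#'
#' @param rbf a \code{mm_rbf}.
#' @param mesh mesh of frame t.
#' @param outline_t1 outline polygon of frame t+1 (matrix or
#'   \code{mm_shape}).
#' @param snap project displaced boundary nodes onto \code{outline_t1}.
#' @param fixed_below_x boundary nodes with x at or below this line are held
#'   at zero in addition to the flank nodes. Pass the bud attachment
#'   (body-wall) line when the artificial body is shared by all frames, so
#'   that only the bud boundary is displaced.
#' @return matrix (n_points x 2) of boundary displacements; zero on interior
#'   and flank rows.
#' @export
boundary_velocity_field <- function(rbf, mesh, outline_t1 = NULL, snap = TRUE,
                                    fixed_below_x = NULL) {
  n <- nrow(mesh$points)
  disp <- matrix(0, n, 2)
  bn <- setdiff(mesh$boundary_nodes, mesh$flank_nodes)
  if (!is.null(fixed_below_x))
    bn <- bn[mesh$points[bn, 1] > fixed_below_x + 1e-9]
  if (length(bn)) disp[bn, ] <- rbf_evaluate(rbf, mesh$points[bn, , drop = FALSE])
  if (snap) {
    if (is.null(outline_t1)) stop("snap requires the next outline")
    poly <- if (inherits(outline_t1, "mm_shape")) outline_t1$outline else outline_t1
    moved <- mesh$points[bn, , drop = FALSE] + disp[bn, , drop = FALSE]
    pr <- project_polyline_cpp(moved, as.matrix(poly))
    disp[bn, ] <- pr[, 1:2] - mesh$points[bn, , drop = FALSE]
  }
  disp
}
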