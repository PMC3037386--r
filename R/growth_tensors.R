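# Growth tensors: per-triangle velocity gradients and their decomposition
# into expansion rate (reported as cell-cycle time), anisotropy with
# principal direction, and rotation rate.

#' Velocity gradient of one triangle
#'
#' Assuming linear velocity variation within the triangle, L is the unique
#' 2x2 matrix mapping the two edge vectors to the corresponding velocity
#' differences.
#'
#' @param mesh a \code{mm_mesh}.
#' @param node_velocities (n_points x 2) matrix of node velocities (model
#'   units per hour).
#' @param tri triangle index.
#' @return 2x2 velocity-gradient matrix L (per hour).
#' @export
triangle_velocity_gradient <- function(mesh, node_velocities, tri) {
  v <- mesh$triangles[tri, ]
  p <- mesh$points
  E <- rbind(p[v[2], ] - p[v[1], ], p[v[3], ] - p[v[1], ])  # rows: edges
  dV <- rbind(node_velocities[v[2], ] - node_velocities[v[1], ],
              node_velocities[v[3], ] - node_velocities[v[1], ])
  det <- E[1, 1] * E[2, 2] - E[1, 2] * E[2, 1]
  if (abs(det) < .Machine$double.xmin) stop("degenerate triangle")
  # dv = L dx for both edges: t(dV) = L t(E)  =>  L = t(dV) %*% solve(t(E))
  unname(t(solve(E, dV)))
}

#' Decompose a velocity gradient
#'
#' Symmetric/antisymmetric split L = S + W. Expansion rate = tr(S) (relative
#' area growth per hour); anisotropy = (l1 - l2)/(l1 + l2) from the
#' eigenvalues l1 >= l2 of S with the principal direction of l1 (flagged NA
#' when l1 + l2 = 0); rotation rate = the angular velocity of W.
#'
#' @param L 2x2 velocity gradient.
#' @return list with \code{expansion_rate}, \code{anisotropy},
#'   \code{direction} (radians), \code{rotation_rate} and the parts \code{S},
#'   \code{W}.
#' @export
decompose <- function(L) {
  S <- (L + t(L)) / 2
  W <- (L - t(L)) / 2
  ev <- eigen(S, symmetric = TRUE)
  l1 <- ev$values[1]; l2 <- ev$values[2]
  expansion <- l1 + l2
  if (abs(expansion) < 1e-14) {
    aniso <- NA_real_
    dir <- NA_real_
  } else {
    aniso <- (l1 - l2) / (l1 + l2)
    dir <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  }
  list(expansion_rate = expansion, anisotropy = aniso, direction = dir,
       rotation_rate = W[2, 1], S = S, W = W)
}

#' Cell-cycle time from an expansion rate
#'
#' Time required to double the area of a tissue element growing at the given
#' relative rate: T = ln 2 / expansion_rate; Inf for non-positive rates.
#'
#' @param expansion_rate relative area growth per hour.
#' @return doubling time in hours (possibly Inf).
#' @export
cell_cycle_time <- function(expansion_rate)
  ifelse(expansion_rate > 0, log(2) / expansion_rate, Inf)

#' Per-triangle growth-tensor report for one frame of a movie
#'
#' Tabulates, for every triangle of the frame's mesh, the velocity-gradient
#' decomposition, the derived cell-cycle time and the anisotropy/rotation
#' ellipse (axes proportional to exp(eigenvalue * dt), rotated to the
#' principal direction). Also returns distal/proximal regional means of the
#' cell-cycle time, splitting the bud at one third of the PD extent from the
#' tip.
#'
#' @param movie a \code{mm_movie}.
#' @param frame frame index (must have a velocity field, so < last frame).
#' @param dt ellipse integration time in hours (default 1).
#' @param clamp_hours heat-map display clamp for cell-cycle times, low/high
#'   (default c(10, 42)).
#' @return list with \code{table} (data frame), \code{regional} (distal and
#'   proximal mean cell-cycle times) and the clamp used.
#' @export
tensor_report <- function(movie, frame = 1L, dt = 1,
                          clamp_hours = c(10, 42)) {
  if (frame >= length(movie$meshes)) stop("frame has no velocity field")
  mesh <- movie$meshes[[frame]]
  vel <- movie$velocities[[frame]]
  nt <- nrow(mesh$triangles)
  out <- data.frame(triangle = seq_len(nt), expansion_rate = NA_real_,
                    anisotropy = NA_real_, direction = NA_real_,
                    rotation_rate = NA_real_, cell_cycle = NA_real_,
                    ellipse_a = NA_real_, ellipse_b = NA_real_)
  for (k in seq_len(nt)) {
    d <- decompose(triangle_velocity_gradient(mesh, vel, k))
    ev <- eigen(d$S, symmetric = TRUE)$values
    out$expansion_rate[k] <- d$expansion_rate
    out$anisotropy[k] <- d$anisotropy
    out$direction[k] <- d$direction
    out$rotation_rate[k] <- d$rotation_rate
    out$cell_cycle[k] <- cell_cycle_time(d$expansion_rate)
    out$ellipse_a[k] <- exp(ev[1] * dt)
    out$ellipse_b[k] <- exp(ev[2] * dt)
  }
  cen <- (mesh$points[mesh$triangles[, 1], ] +
            mesh$points[mesh$triangles[, 2], ] +
            mesh$points[mesh$triangles[, 3], ]) / 3
  bud <- cen[, 1] > 0
  tip <- max(cen[, 1])
  split_x <- tip - (tip - 0) / 3
  distal <- bud & cen[, 1] >= split_x
  proximal <- bud & cen[, 1] < split_x
  cc <- out$cell_cycle
  cc_disp <- pmin(pmax(cc, clamp_hours[1]), clamp_hours[2])
  regional <- c(distal = mean(cc[distal & is.finite(cc)]),
                proximal = mean(cc[proximal & is.finite(cc)]))
  out$cell_cycle_display <- cc_disp
  list(table = out, regional = regional, clamp_hours = clamp_hours,
       split_x = split_x)
}
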