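semicircle_shape <- function(r = 1, depth = 0.5) {
  th <- seq(-pi / 2, pi / 2, length.out = 201)
  attach_flank(cbind(r * cos(th), r * sin(th)), depth)
}

test_that("spline-outline intersection matches closed forms and dense sampling", {
  shp <- semicircle_shape()
  ray <- control_spline(cbind(c(-0.2, 2), c(0, 0)))
  hit <- intersect_spline(ray, shp)
  expect_equal(nrow(hit), 1L)
  expect_equal(unname(hit[1, c("x", "y")]), c(1, 0), tolerance = 1e-3)
  far <- control_spline(cbind(c(5, 6), c(5, 5)))
  expect_equal(nrow(intersect_spline(far, shp)), 0L)
  # curved spline vs polygon against a fine-sampling oracle
  crv <- control_spline(cbind(seq(-0.3, 2, length.out = 30),
                              0.4 * sin(seq(0, 3, length.out = 30))))
  hits <- intersect_spline(crv, shp)
  orc <- oracle_spline_crossings(crv$points, shp$outline)
  orc <- orc[orc[, 1] > 1e-9, , drop = FALSE]
  expect_equal(nrow(hits), nrow(orc))
  for (i in seq_len(nrow(hits)))
    expect_lt(min(sqrt((orc[, 1] - hits[i, "x"])^2 +
                         (orc[, 2] - hits[i, "y"])^2)), 1e-3)
})

test_that("control vectors vanish for identical frames and follow similarity scalings", {
  shp <- semicircle_shape()
  spl <- make_control_splines(generate_synthetic_trajectory(frames = 2),
                              "straight", n = 5, max_angle = 0.9)
  cv <- control_vectors(spl, shp, shp)
  expect_lt(max(abs(cv$vectors)), 1e-9)
  # uniform scaling about the bud center: rays through the center pick up
  # radial vectors of length (s - 1) r at radius r
  s <- 1.2
  th <- seq(-pi / 2, pi / 2, length.out = 201)
  big <- attach_flank(cbind(s * cos(th), s * sin(th)), 0.5)
  rays <- lapply(seq(-0.9, 0.9, length.out = 5), function(a)
    control_spline(rbind(c(0, 0), 3 * c(cos(a), sin(a)))))
  cv2 <- control_vectors(rays, shp, big)
  r <- unname(sqrt(rowSums(cv2$origins^2)))
  expect_equal(unname(sqrt(rowSums(cv2$vectors^2))), (s - 1) * r,
               tolerance = 1e-9)
  dot <- rowSums(cv2$vectors * cv2$origins) /
    (sqrt(rowSums(cv2$vectors^2)) * r)
  expect_equal(unname(dot), rep(1, nrow(cv2$origins)), tolerance = 1e-9)
  # origins and tips sit on their outlines
  expect_lt(max(outline_distance(cv2$origins, shp$outline)), 1e-3)
  expect_lt(max(outline_distance(cv2$tips, big$outline)), 1e-3)
})

test_that("Gaussian RBF interpolation is exact at centers and uses the printed basis", {
  set.seed(11)
  centers <- cbind(runif(7), runif(7))
  vecs <- cbind(rnorm(7), rnorm(7))
  cv <- list(origins = centers, tips = centers + vecs, vectors = vecs)
  rbf <- fit_gaussian_rbf(cv, width = 0.5, ridge = 0)
  expect_lt(max(abs(rbf_evaluate(rbf, centers) - vecs)), 1e-8)
  # coefficients match an independent dense solve
  co <- oracle_rbf_solve(centers, vecs, 0.5)
  expect_equal(unname(rbf$coefficients), unname(co), tolerance = 1e-8)
  # single center: value decays as exp(-d^2 / (2 sigma^2))
  one <- list(origins = cbind(0, 0), tips = cbind(1, 0),
              vectors = cbind(1, 0))
  r1 <- fit_gaussian_rbf(one, width = 1, ridge = 0)
  expect_equal(as.vector(rbf_evaluate(r1, cbind(0, 0))), c(1, 0))
  d <- 0.7
  expect_equal(as.vector(rbf_evaluate(r1, cbind(d, 0))),
               c(exp(-d^2 / 2), 0), tolerance = 1e-12)
  # all-zero vectors give the zero interpolant
  z <- list(origins = centers, tips = centers,
            vectors = matrix(0, 7, 2))
  rz <- fit_gaussian_rbf(z, width = 0.5, ridge = 0)
  expect_equal(max(abs(rz$coefficients)), 0)
  # duplicate centers make the unridged system singular
  dup <- list(origins = centers[c(1, 1, 2), ], vectors = vecs[1:3, ])
  expect_error(fit_gaussian_rbf(dup, width = 0.5, ridge = 0), "ridge")
})

test_that("boundary velocity fields snap displaced nodes onto the next outline", {
  seq <- small_sequence()
  mesh <- triangulate(seq$frames[[1]], 0.2)
  spl <- make_control_splines(seq, "straight")
  cv <- control_vectors(spl, seq$frames[[1]], seq$frames[[2]])
  rbf <- fit_gaussian_rbf(cv)
  disp <- boundary_velocity_field(rbf, mesh, seq$frames[[2]], snap = TRUE,
                                  fixed_below_x = seq$frames[[1]]$wall_x)
  moved_nodes <- which(rowSums(abs(disp)) > 0)
  expect_true(all(moved_nodes %in% mesh$boundary_nodes))
  moved <- mesh$points[moved_nodes, ] + disp[moved_nodes, ]
  pr <- morphomovie:::project_polyline_cpp(moved, seq$frames[[2]]$outline)
  expect_lt(max(pr[, 3]), 1e-8)
  expect_equal(max(abs(disp[mesh$flank_nodes, ])), 0)
  # zero interpolant gives (after snapping a point already on the outline) a zero field
  z <- fit_gaussian_rbf(list(origins = cbind(1, 0), tips = cbind(1, 0),
                             vectors = cbind(0, 0)), width = 1)
  dz <- boundary_velocity_field(z, mesh, NULL, snap = FALSE)
  expect_equal(max(abs(dz)), 0)
})

test_that("interpolated boundary displacement stays smooth along the outline", {
  seq <- small_sequence()
  spl <- make_control_splines(seq, "straight")
  cv <- control_vectors(spl, seq$frames[[1]], seq$frames[[2]])
  rbf <- fit_gaussian_rbf(cv)   # sigma = mean center spacing
  shpd <- resample_outline(seq$frames[[1]], 200)
  u <- rbf_evaluate(rbf, shpd$outline)
  d2 <- diff(diff(u[, 1]))
  expect_lt(max(abs(d2)), 0.1 * (max(u[, 1]) - min(u[, 1]) + 1e-12))
})
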