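test_that("triangle overlap areas match closed forms and Monte-Carlo", {
  a <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(triangle_overlap_area(a, a), 0.5)
  far <- a + 10
  expect_equal(triangle_overlap_area(a, far), 0)
  b <- a; b[, 1] <- b[, 1] + 0.5
  mc <- oracle_mc_overlap(a, b)
  expect_lt(abs(triangle_overlap_area(a, b) - mc$area), 3 * mc$se)
  expect_error(triangle_overlap_area(a, rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate")
})

test_that("interpolation maps satisfy partition and coverage identities", {
  m <- triangulate(small_sequence()$frames[[1]], 0.25)
  zero <- matrix(0, nrow(m$points), 2)
  idm <- build_interpolation_map(m, zero, m)
  W <- as.matrix(idm$W)
  expect_equal(diag(W), mesh_areas(m), tolerance = 1e-9)
  expect_equal(sum(W) - sum(diag(W)), 0, tolerance = 1e-9)
  # a genuinely deformed frame pair from the movie
  mov <- small_movie()
  for (t in c(1, 3)) {
    map <- mov$maps[[t]]
    newp <- mov$meshes[[t]]$points + mov$velocities[[t]]
    src <- morphomovie:::triangle_signed_areas(newp, mov$meshes[[t]]$triangles)
    expect_equal(as.vector(Matrix::rowSums(map$W)), src, tolerance = 1e-6)
    expect_equal(as.vector(Matrix::colSums(map$W)),
                 mesh_areas(mov$meshes[[t + 1]]), tolerance = 1e-6)
  }
  # coarse-to-fine meshes of the same polygon
  coarse <- triangulate(small_sequence()$frames[[1]], 0.3)
  fine <- triangulate(small_sequence()$frames[[1]], 0.15,
                      boundary_points = coarse$boundary_polygon)
  cf <- build_interpolation_map(coarse, matrix(0, nrow(coarse$points), 2), fine)
  expect_equal(as.vector(Matrix::colSums(cf$W)), mesh_areas(fine),
               tolerance = 1e-6)
})

test_that("grid candidate search covers every truly overlapping pair", {
  mov <- small_movie()
  t <- 2
  newp <- mov$meshes[[t]]$points + mov$velocities[[t]]
  src <- mov$meshes[[t]]; tgt <- mov$meshes[[t + 1]]
  tl <- morphomovie:::overlap_map_cpp(newp, src$triangles, tgt$points,
                                      tgt$triangles, 1e-14)
  got <- paste(tl$i, tl$j)
  # brute force all-pairs clipping
  for (i in seq_len(min(nrow(src$triangles), 200))) {
    A <- newp[src$triangles[i, ], ]
    for (j in seq_len(nrow(tgt$triangles))) {
      B <- tgt$points[tgt$triangles[j, ], ]
      w <- morphomovie:::tri_overlap_cpp(A, B)
      if (w > 1e-10) expect_true(paste(i, j) %in% got)
    }
  }
})

test_that("transfer is conservative, linear and obeys the maximum principle", {
  mov <- small_movie()
  map <- mov$maps[[1]]
  n <- nrow(map$W)
  cst <- transfer(rep(3.5, n), map)
  expect_equal(cst, rep(3.5, ncol(map$W)), tolerance = 1e-9)
  ind <- numeric(n); ind[7] <- 1
  out <- transfer(ind, map)
  expect_true(all(out >= 0) && max(out) <= 1 + 1e-12)
  # integral bookkeeping: sum v_i * deformed_area_i is preserved
  set.seed(2)
  v <- runif(n)
  out2 <- transfer(v, map)
  expect_equal(sum(out2 * map$tgt_areas), sum(v * map$src_areas),
               tolerance = 1e-9)
  # linearity
  w <- runif(n)
  expect_equal(transfer(2 * v + 3 * w, map),
               2 * transfer(v, map) + 3 * transfer(w, map), tolerance = 1e-12)
  expect_true(max(out2) <= max(v) + 1e-12 && min(out2) >= min(v) - 1e-12)
  expect_error(transfer(v[-1], map), "length")
})

test_that("reverse maps are exact adjoints and smear without amplifying", {
  mov <- small_movie()
  map <- mov$maps[[2]]
  rev <- reverse_map(map)
  set.seed(3)
  u <- runif(nrow(map$W)); v <- runif(ncol(map$W))
  lhs <- sum(transfer(u, map) * v * map$tgt_areas)
  rhs <- sum(u * transfer(v, rev) * map$src_areas)
  expect_equal(lhs, rhs, tolerance = 1e-8)
  ones <- rep(1, ncol(map$W))
  expect_equal(transfer(ones, rev), rep(1, nrow(map$W)), tolerance = 1e-9)
  # forward then reverse: integral-preserving, maximum non-increasing
  f <- runif(nrow(map$W))
  fb <- transfer(transfer(f, map), rev)
  expect_lte(max(fb), max(f) + 1e-12)
  expect_equal(sum(fb * map$src_areas), sum(f * map$src_areas),
               tolerance = 1e-9)
})

test_that("whole movies preserve constants and stay consistent frame to frame", {
  mov <- small_movie()
  expect_length(mov$maps, length(mov$meshes) - 1)
  f <- rep(1, nrow(mov$meshes[[1]]$triangles))
  for (t in seq_along(mov$maps)) f <- transfer(f, mov$maps[[t]])
  expect_equal(f, rep(1, length(f)), tolerance = 1e-6)
  defects <- vapply(mov$log, function(l) l$partition_defect, numeric(1))
  expect_lt(max(defects), 1e-6)
  # identity geometry: identical frames and zero vectors give identity maps
  m <- disc_mesh()
  idm <- identity_movie(m, frames = 3)
  expect_equal(as.vector(Matrix::diag(idm$maps[[1]]$W)), mesh_areas(m),
               tolerance = 1e-9)
})

test_that("movies serialize to text and read back with identical transport", {
  mov <- small_movie()
  dir <- withr::local_tempdir()
  write_morphomovie(mov, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_morphomovie(dir)
  expect_length(back$meshes, length(mov$meshes))
  set.seed(8)
  v <- runif(nrow(mov$meshes[[1]]$triangles))
  f1 <- v; f2 <- v
  for (t in seq_along(mov$maps)) {
    f1 <- transfer(f1, mov$maps[[t]])
    f2 <- transfer(f2, back$maps[[t]])
  }
  expect_equal(f2, f1, tolerance = 1e-9)
})
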