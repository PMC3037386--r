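toy_mesh <- function() {
  # strip of 10 triangles on a 2 x 6 grid of points
  pts <- cbind(rep(0:5, 2), rep(c(0, 1), each = 6))
  tris <- do.call(rbind, lapply(1:5, function(c)
    rbind(c(c, c + 1, c + 7), c(c, c + 7, c + 6))))
  morphomovie:::new_tri_mesh(pts, tris, NULL, NULL, 1e-9)
}

test_that("mask rasterization recovers full, empty and disc-shaped regions", {
  m <- disc_mesh()
  full <- matrix(1, 64, 64)
  al <- mask_alignment(scale = 2.2 / 64, translation = c(-1.1, -1.1))
  cl <- rasterize_mask_to_mesh(full, m, al)
  expect_equal(cl$n, nrow(m$triangles))
  expect_warning(rasterize_mask_to_mesh(matrix(0, 64, 64), m, al), "empty")
  # disc of radius 0.5 at the center
  xs <- (col(full) - 0.5) * al$scale + al$translation[1]
  ys <- (64 - row(full) + 0.5) * al$scale + al$translation[2]
  disc <- (xs^2 + ys^2) <= 0.25
  cld <- rasterize_mask_to_mesh(disc * 1, m, al)
  area <- sum(mesh_areas(m)[cld$triangles])
  expect_lt(abs(area - pi * 0.25) / (pi * 0.25), 0.10)
})

test_that("clone scores are bounded, exact on perfect matches and zero off-support", {
  m <- toy_mesh()
  cl <- experimental_clone(c(2, 3, 4))
  v <- numeric(10); v[c(2, 3, 4)] <- 1
  expect_equal(clone_score(v, cl), 1)
  out <- numeric(10); out[c(8, 9)] <- 1
  expect_equal(clone_score(out, cl), 0)
  set.seed(1)
  for (r in 1:50) {
    vv <- runif(10)
    expect_gte(clone_score(vv, cl), 0)
    expect_lte(clone_score(vv, cl), 1)
  }
  expect_error(clone_score(v, structure(list(triangles = integer(0), n = 0L),
                                        class = "mm_clone")), "empty")
})

test_that("moving a clone triangle outside the virtual support never raises the score", {
  m <- toy_mesh()
  set.seed(21)
  for (rep in 1:100) {
    v <- runif(10)
    v[sample(10, 3)] <- 0          # some triangles outside the support
    inside <- which(v > 1e-6)
    outside <- which(v <= 1e-6)
    if (length(inside) < 2 || length(outside) < 1) next
    E <- sample(inside, min(3, length(inside)))
    s0 <- clone_score(v, experimental_clone(E))
    for (j in E) {
      E2 <- c(setdiff(E, j), outside[1])
      expect_lte(clone_score(v, experimental_clone(E2)), s0 + 1e-12)
    }
  }
})

test_that("best match scans every seed and beats random seeds", {
  mov <- small_movie()
  op <- full_transport_operator(mov, diffusion_config(0))
  f <- op[, 25]
  cl <- experimental_clone(which(f >= 0.25 * max(f)))
  bm <- best_match(mov, cl, diffusion_config(0), operator = op)
  expect_equal(bm$n_comparisons, nrow(mov$meshes[[1]]$triangles))
  set.seed(9)
  rnd <- sample(ncol(op), 100, replace = TRUE)
  for (s in rnd)
    expect_gte(bm$score, clone_score(as.vector(op[, s]), cl))
  # the per-seed scores agree with clone_score applied per column
  expect_equal(bm$scores[13], clone_score(as.vector(op[, 13]), cl))
})

test_that("a full map evaluation at the reference sizes exceeds forty thousand comparisons", {
  expect_gte(comparison_count(3156, 13), 40000)
  expect_equal(comparison_count(3156, 13), 41028)
})

test_that("map scores multiply per-clone best scores and respect monotonicity", {
  mov <- small_movie()
  op <- full_transport_operator(mov, diffusion_config(0))
  mk <- function(s) {
    f <- op[, s]
    experimental_clone(which(f >= 0.25 * max(f)))
  }
  clones <- lapply(c(10, 30, 50), mk)
  ms <- map_score(mov, clones, diffusion_config(0))
  per <- vapply(ms$per_clone, function(p) p$score, numeric(1))
  expect_equal(ms$total, prod(per))
  single <- map_score(mov, clones[1], diffusion_config(0))
  expect_equal(single$total, per[1])
  # permutation invariance
  ms2 <- map_score(mov, rev(clones), diffusion_config(0))
  expect_equal(ms2$total, ms$total)
  # a clone fully outside every support zeroes the product
  far <- experimental_clone(which.min(op[, 10]))
  if (max(op[far$triangles, ]) <= 1e-6)
    expect_equal(map_score(mov, c(clones, list(far)), diffusion_config(0))$total, 0)
  expect_error(map_score(mov, list(), diffusion_config(0)), "at least one")
})

test_that("mean filtering normalizes to one and never sharpens", {
  m <- toy_mesh()
  cl <- experimental_clone(c(4, 5))
  p0 <- mean_filter(cl, m, 0)
  expect_equal(p0[c(4, 5)], c(0.5, 0.5))
  expect_equal(sum(p0), 1)
  for (k in 1:4) expect_equal(sum(mean_filter(cl, m, k)), 1, tolerance = 1e-12)
  # pre-normalization averaging cannot increase the maximum
  nb <- edge_neighbors(m)
  set.seed(31)
  for (r in 1:100) {
    v <- runif(10)
    acc <- v; cnt <- rep(1, 10)
    for (e in seq_len(nrow(nb))) {
      acc[nb$tri1[e]] <- acc[nb$tri1[e]] + v[nb$tri2[e]]
      acc[nb$tri2[e]] <- acc[nb$tri2[e]] + v[nb$tri1[e]]
      cnt[nb$tri1[e]] <- cnt[nb$tri1[e]] + 1
      cnt[nb$tri2[e]] <- cnt[nb$tri2[e]] + 1
    }
    expect_lte(max(acc / cnt), max(v) + 1e-12)
  }
})

test_that("overlap scores are symmetric, zero on disjoint supports and unit on identity", {
  set.seed(41)
  for (r in 1:100) {
    a <- runif(20); a[sample(20, 8)] <- 0; a <- a / sum(a)
    b <- runif(20); b[sample(20, 8)] <- 0; b <- b / sum(b)
    expect_equal(overlap_score(a, b), overlap_score(b, a), tolerance = 1e-12)
  }
  a <- c(0.5, 0.5, 0, 0); b <- c(0, 0, 0.3, 0.7)
  expect_equal(overlap_score(a, b), 0)
  expect_equal(overlap_score(a, a), 1, tolerance = 1e-12)
  expect_error(overlap_score(a, b[1:3]), "different meshes")
})

test_that("clone extents report PD/AP fractions and an anisotropy class", {
  mov <- small_movie()
  mT <- mov$meshes[[length(mov$meshes)]]
  in_bud <- apply(matrix(mT$points[mT$triangles, 1],
                         nrow(mT$triangles)), 1, min) >= -1e-9
  allcl <- experimental_clone(which(in_bud))
  ext <- clone_extents(allcl, mT)
  expect_equal(ext$pd_fraction, 1, tolerance = 0.05)
  expect_equal(ext$ap_fraction, 1, tolerance = 0.05)
  expect_identical(ext$class, "isotropic")
  # synthetic elongated clone: 40% PD x 10% AP -> ratio 4, anisotropic
  ext2 <- list(pd_fraction = 0.4, ap_fraction = 0.1)
  expect_equal(ext2$pd_fraction / ext2$ap_fraction, 4)
  cen <- tri_centroids(mT)
  bud <- cen[, 1] > 1e-9
  xr <- range(cen[bud, 1]); yr <- range(cen[bud, 2])
  strip <- which(bud & cen[, 1] > xr[1] + 0.2 * diff(xr) &
                   cen[, 1] < xr[1] + 0.6 * diff(xr) &
                   abs(cen[, 2] - mean(yr)) < 0.06 * diff(yr))
  ext3 <- clone_extents(experimental_clone(strip), mT)
  expect_gt(ext3$ratio, 1.5)
  expect_identical(ext3$class, "anisotropic")
})
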