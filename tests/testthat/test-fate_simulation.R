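test_that("clone seeding marks exactly one triangle with density one", {
  m <- disc_mesh()
  f <- seed_clone(m, 1L)
  expect_equal(sum(f != 0), 1L)
  expect_equal(f[1], 1)
  expect_equal(field_integral(f, m), mesh_areas(m)[1])
  expect_error(seed_clone(m, nrow(m$triangles) + 1L), "out of range")
  f2 <- seed_clone(m, 2L)
  expect_equal(sum((f + f2) == 1), 2L)
})

test_that("finite-volume diffusion conserves mass and relaxes to the uniform state", {
  m <- disc_mesh()
  cfg <- diffusion_config(0.05)
  u <- rep(0.4, nrow(m$triangles))
  expect_equal(diffuse(u, m, cfg, 1), u, tolerance = 1e-12)
  f <- seed_clone(m, 3L)
  expect_equal(diffuse(f, m, diffusion_config(0), 5), f)
  mass0 <- field_integral(f, m)
  g <- diffuse(f, m, cfg, 2)
  expect_equal(field_integral(g, m), mass0, tolerance = 1e-9)
  expect_true(all(g >= 0))
  # long-time steady state of zero-flux diffusion: mass / total area
  long <- diffuse(f, m, diffusion_config(0.5), 200)
  expect_lt(max(abs(long - mass0 / sum(mesh_areas(m)))), 1e-6)
})

test_that("fate simulation preserves constants, bounds and expands support on a growing movie", {
  m <- disc_mesh()
  idm <- identity_movie(m, 4)
  f <- seed_clone(m, 5L)
  ff <- simulate_fate(idm, f, diffusion_config(0))
  for (k in seq_along(ff)) expect_equal(ff[[k]], f)
  ones <- rep(1, nrow(m$triangles))
  fo <- simulate_fate(idm, ones, diffusion_config(0))
  expect_equal(fo[[length(fo)]], ones, tolerance = 1e-9)
  mov <- small_movie()
  fg <- simulate_fate(mov, 10L, diffusion_config(0))
  supp <- vapply(seq_along(fg), function(k)
    sum(mesh_areas(mov$meshes[[k]])[fg[[k]] > 1e-9]), numeric(1))
  expect_true(all(diff(supp) > 0))
  expect_true(all(vapply(fg, max, numeric(1)) <= 1 + 1e-9))
  expect_true(all(vapply(fg, min, numeric(1)) >= -1e-12))
})

test_that("advection-diffusion transport is linear", {
  mov <- small_movie()
  cfg <- diffusion_config(0.005)
  n <- nrow(mov$meshes[[1]]$triangles)
  set.seed(4)
  A <- runif(n); B <- runif(n)
  fA <- simulate_fate(mov, A, cfg)
  fB <- simulate_fate(mov, B, cfg)
  fAB <- simulate_fate(mov, 0.3 * A + 0.7 * B, cfg)
  last <- length(fA)
  expect_equal(fAB[[last]], 0.3 * fA[[last]] + 0.7 * fB[[last]],
               tolerance = 1e-9)
})

test_that("diffuse-then-advect and advect-then-diffuse differ only at O(dt)", {
  mov <- small_movie()
  cfg <- diffusion_config(0.01)
  f <- seed_clone(mov$meshes[[1]], 20L)
  a <- transfer(diffuse(f, mov$meshes[[1]], cfg, 1), mov$maps[[1]])
  b <- diffuse(transfer(f, mov$maps[[1]]), mov$meshes[[2]], cfg, 1)
  expect_lt(max(abs(a - b)), 0.1 * max(a))
})

test_that("progenitor maps keep a partition normalized and widen with mixing", {
  mov <- small_movie()
  T <- length(mov$meshes)
  ntT <- nrow(mov$meshes[[T]]$triangles)
  cen <- tri_centroids(mov$meshes[[T]])
  thirds <- quantile(cen[, 1], c(1 / 3, 2 / 3))
  regions <- list(which(cen[, 1] <= thirds[1]),
                  which(cen[, 1] > thirds[1] & cen[, 1] <= thirds[2]),
                  which(cen[, 1] > thirds[2]))
  prog0 <- simulate_progenitors(mov, regions, diffusion_config(0))
  # identity movie, D = 0: progenitors equal the final regions at all frames
  idm <- identity_movie(mov$meshes[[T]], 3)
  pid <- simulate_progenitors(idm, regions, diffusion_config(0))
  for (r in seq_along(regions)) {
    want <- numeric(ntT); want[regions[[r]]] <- 1
    for (k in 1:3) expect_equal(pid[[r]][[k]], want, tolerance = 1e-12)
  }
  # partition of the final frame: membership probabilities sum to one everywhere
  for (t in c(1, 3, T)) {
    tot <- Reduce(`+`, lapply(prog0, function(p) p[[t]]))
    expect_equal(tot, rep(1, length(tot)), tolerance = 1e-6)
  }
  # mixing widens progenitor zones: D > 0 support contains the D = 0 support
  progD <- simulate_progenitors(mov, regions, diffusion_config(0.02))
  for (r in seq_along(regions)) {
    s0 <- prog0[[r]][[1]] > 1e-9
    sD <- progD[[r]][[1]] > 1e-9
    expect_true(all(sD[s0]))
    expect_gt(sum(sD), sum(s0))
  }
  expect_error(simulate_progenitors(mov, list(c(1, 2), c(2, 3))), "disjoint")
})

test_that("forward and reverse hourly steps are adjoint under the area inner product", {
  mov <- small_movie()
  cfg <- diffusion_config(0)
  for (t in c(1, 4)) {
    map <- mov$maps[[t]]
    set.seed(t)
    u <- runif(nrow(map$W)); v <- runif(ncol(map$W))
    lhs <- sum(transfer(u, map) * v * map$tgt_areas)
    rhs <- sum(u * transfer(v, reverse_map(map)) * map$src_areas)
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
})
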