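test_that("stiffness profiles scale edges along the PD axis as advertised", {
  m <- triangulate(small_sequence()$frames[[1]], 0.2)
  len <- sqrt(rowSums((m$points[m$edges[, 1], ] - m$points[m$edges[, 2], ])^2))
  midx <- (m$points[m$edges[, 1], 1] + m$points[m$edges[, 2], 1]) / 2
  cst <- stiffness_field(m, "constant")
  expect_equal(cst$k * len, rep(1, nrow(m$edges)))   # equal-length edges equal stiffness
  sig <- stiffness_field(m, "sigmoid")
  inv <- stiffness_field(m, "inverted_sigmoid")
  # compare the x-profile after removing the length dependence
  f_sig <- sig$k * len; f_inv <- inv$k * len
  o <- order(midx)
  expect_gt(mean(f_sig[o][midx[o] > quantile(midx, 0.8)]),
            mean(f_sig[o][midx[o] < quantile(midx, 0.2)]))  # distal stiffer
  expect_lt(mean(f_inv[o][midx[o] > quantile(midx, 0.8)]),
            mean(f_inv[o][midx[o] < quantile(midx, 0.2)]))  # distal softer
  expect_true(all(sig$k > 0) && all(inv$k > 0))
})

test_that("spring relaxation reproduces the analytic chain and rigid motions", {
  # 1D chain of n equal springs, ends held at 0 and 1
  n <- 11
  edges <- cbind(1:(n - 1), 2:n)
  fixed <- rep(FALSE, n); fixed[c(1, n)] <- TRUE
  fd <- cbind(c(0, rep(0, n - 2), 1), 0)
  res <- morphomovie:::spring_jacobi_cpp(n, edges, rep(1, n - 1), fixed, fd,
                                         100000L, 1e-12, 1)
  expect_equal(res$disp[, 1], oracle_chain(n - 1), tolerance = 1e-6)
  # zero boundary displacement -> zero field immediately
  m <- triangulate(small_sequence()$frames[[1]], 0.25)
  zero <- matrix(0, nrow(m$points), 2)
  df <- propagate(m, zero)
  expect_equal(max(abs(df$disp)), 0)
  expect_lte(df$iterations, 1L)
  # uniform translation of all boundary nodes (flank fix disabled)
  tr <- matrix(0, nrow(m$points), 2)
  tr[m$boundary_nodes, 1] <- 0.05
  tr[m$boundary_nodes, 2] <- -0.02
  dfr <- propagate(m, tr, fix_flank = FALSE)
  expect_equal(dfr$disp[, 1], rep(0.05, nrow(m$points)), tolerance = 1e-6)
  expect_equal(dfr$disp[, 2], rep(-0.02, nrow(m$points)), tolerance = 1e-6)
})

test_that("interior displacements obey the discrete maximum principle", {
  m <- triangulate(small_sequence()$frames[[1]], 0.25)
  set.seed(5)
  bd <- matrix(0, nrow(m$points), 2)
  bn <- setdiff(m$boundary_nodes, m$flank_nodes)
  bd[bn, ] <- cbind(runif(length(bn), -0.02, 0.05),
                    runif(length(bn), -0.03, 0.03))
  df <- propagate(m, bd, stiffness_field(m, "sigmoid"))
  int <- setdiff(seq_len(nrow(m$points)), m$boundary_nodes)
  for (cc in 1:2) {
    lo <- min(c(bd[bn, cc], 0)); hi <- max(c(bd[bn, cc], 0))
    expect_true(all(df$disp[int, cc] >= lo - 1e-9))
    expect_true(all(df$disp[int, cc] <= hi + 1e-9))
  }
})

test_that("relaxation residual decreases with more iterations and flags non-convergence", {
  m <- triangulate(small_sequence()$frames[[1]], 0.25)
  bd <- matrix(0, nrow(m$points), 2)
  bn <- setdiff(m$boundary_nodes, m$flank_nodes)
  bd[bn, 1] <- 0.05
  r1 <- morphomovie:::spring_jacobi_cpp(nrow(m$points), m$edges,
                                        stiffness_field(m, "constant")$k,
                                        {f <- rep(FALSE, nrow(m$points)); f[m$boundary_nodes] <- TRUE; f},
                                        bd, 20L, 0, 1)
  r2 <- morphomovie:::spring_jacobi_cpp(nrow(m$points), m$edges,
                                        stiffness_field(m, "constant")$k,
                                        {f <- rep(FALSE, nrow(m$points)); f[m$boundary_nodes] <- TRUE; f},
                                        bd, 200L, 0, 1)
  expect_lt(r2$residual, r1$residual)
  expect_error(propagate(m, bd, max_iter = 2L, tol = 1e-14),
               "did not converge")
})

test_that("no element inversion occurs across the shipped trajectory for all profiles", {
  for (profile in c("constant", "sigmoid", "inverted_sigmoid")) {
    mov <- small_movie(profile)
    for (t in seq_along(mov$velocities)) {
      newp <- mov$meshes[[t]]$points + mov$velocities[[t]]
      expect_true(all(morphomovie:::triangle_signed_areas(newp, mov$meshes[[t]]$triangles) > 0))
    }
  }
})
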