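# Independent oracles used by the tests. These deliberately re-derive
# quantities from first principles rather than reusing package internals.

# shoelace area, written independently of polygon_area()
oracle_shoelace <- function(xy) {
  xy <- unname(as.matrix(xy))
  n <- nrow(xy)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + xy[i, 1] * xy[j, 2] - xy[j, 1] * xy[i, 2]
  }
  abs(s) / 2
}

# brute-force all-pairs proper-intersection test for a closed polygon
oracle_polygon_simple <- function(xy) {
  n <- nrow(xy)
  seg <- cbind(xy, xy[c(2:n, 1), ])
  cross <- function(ax, ay, bx, by, cx, cy)
    (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (j == i + 1 || (i == 1 && j == n)) next
    d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
    d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
    d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
    d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
    if (d1 * d2 < 0 && d3 * d4 < 0) return(FALSE)
  }
  TRUE
}

# Monte-Carlo estimate of the overlap area of two triangles, with its SE
oracle_mc_overlap <- function(a, b, n = 1e6, seed = 99) {
  set.seed(seed)
  lo <- pmin(apply(a, 2, min), apply(b, 2, min))
  hi <- pmax(apply(a, 2, max), apply(b, 2, max))
  px <- runif(n, lo[1], hi[1]); py <- runif(n, lo[2], hi[2])
  inside_tri <- function(t, px, py) {
    s1 <- (t[2, 1] - t[1, 1]) * (py - t[1, 2]) - (t[2, 2] - t[1, 2]) * (px - t[1, 1])
    s2 <- (t[3, 1] - t[2, 1]) * (py - t[2, 2]) - (t[3, 2] - t[2, 2]) * (px - t[2, 1])
    s3 <- (t[1, 1] - t[3, 1]) * (py - t[3, 2]) - (t[1, 2] - t[3, 2]) * (px - t[3, 1])
    (s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0)
  }
  hit <- inside_tri(a, px, py) & inside_tri(b, px, py)
  box <- prod(hi - lo)
  p <- mean(hit)
  list(area = p * box, se = sqrt(p * (1 - p) / n) * box)
}

# dense-sampling intersection of a polyline with a polygon: returns the
# approximate crossing points by sign changes of the inside indicator
oracle_spline_crossings <- function(spline_pts, poly, n = 20000) {
  s <- seq(0, 1, length.out = nrow(spline_pts))
  t <- seq(0, 1, length.out = n)
  x <- approx(s, spline_pts[, 1], t)$y
  y <- approx(s, spline_pts[, 2], t)$y
  inside <- as.logical(morphomovie:::point_in_polygon_cpp(x, y, poly[, 1], poly[, 2]))
  flips <- which(diff(inside) != 0)
  cbind(x = (x[flips] + x[flips + 1]) / 2, y = (y[flips] + y[flips + 1]) / 2)
}

# direct dense solve of the Gaussian RBF system (oracle for fit_gaussian_rbf)
oracle_rbf_solve <- function(centers, values, sigma) {
  G <- exp(-as.matrix(dist(centers))^2 / (2 * sigma^2))
  solve(G, values)
}

# analytic spring chain: ends at 0 and 1, interior node j of n springs -> j/n
oracle_chain <- function(n) seq(0, n) / n

# distance from points to the closest vertex of a dense outline resampling
outline_distance <- function(pts, outline, n = 4000) {
  dense <- resample_outline(outline, n)
  if (inherits(dense, "mm_shape")) dense <- dense$outline
  sapply(seq_len(nrow(pts)), function(i)
    min(sqrt((dense[, 1] - pts[i, 1])^2 + (dense[, 2] - pts[i, 2])^2)))
}
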