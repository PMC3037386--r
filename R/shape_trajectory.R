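#' @useDynLib morphomovie, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx rnorm runif setNames
#' @importFrom utils read.csv write.csv
NULL

#' Signed polygon area (shoelace formula)
#'
#' @param xy two-column matrix of polygon vertices, not repeated at the end.
#' @return signed area; positive for counter-clockwise orientation.
#' @export
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Test whether a closed polygon is simple (no self-intersections)
#'
#' All-pairs segment intersection test; adjacent segments are allowed to
#' share their common endpoint only.
#'
#' @param xy polygon vertex matrix.
#' @param tol tolerance for degenerate contact.
#' @return TRUE if no two non-adjacent edges intersect.
#' @export
polygon_is_simple <- function(xy, tol = 1e-12) {
  n <- nrow(xy)
  a <- xy
  b <- xy[c(2:n, 1), , drop = FALSE]
  cross <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    # skip edges sharing a vertex with edge i
    js <- js[js != i + 1 & !(i == 1 & js == n)]
    if (!length(js)) next
    d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[js, 1], a[js, 2])
    d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[js, 1], b[js, 2])
    d3 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2], rep(a[i, 1], length(js)), rep(a[i, 2], length(js)))
    d4 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2], rep(b[i, 1], length(js)), rep(b[i, 2], length(js)))
    hit <- (d1 * d2 < -tol) & (d3 * d4 < -tol)
    if (any(hit)) return(FALSE)
  }
  TRUE
}

#' Morphometric stage label
#'
#' Stages are written mEdd:hh where dd is the morphometric embryonic day and
#' hh the hour within it. Hour index 0 of a trajectory starting at day 9 is
#' mE9:00; hour index 36 is mE10:12 (the stage corresponding to standard
#' E10.5).
#'
#' @param hour_index hour offset from the start of the trajectory (>= 0).
#' @param origin_day morphometric day of hour index 0 (default 9).
#' @return object of class \code{mm_stage} with fields \code{day},
#'   \code{hour} and a \code{label}.
#' @export
stage_label <- function(hour_index, origin_day = 9L) {
  if (any(hour_index < 0)) stop("hour_index must be non-negative")
  day <- origin_day + hour_index %/% 24L
  hour <- hour_index %% 24L
  structure(list(day = day, hour = hour,
                 label = sprintf("mE%d:%02d", day, hour)),
            class = "mm_stage")
}

#' @export
format.mm_stage <- function(x, ...) x$label

#' @export
print.mm_stage <- function(x, ...) { cat(x$label, "\n"); invisible(x) }

new_boundary_shape <- function(outline, flank_span, stage) {
  structure(list(outline = outline, flank_span = flank_span, stage = stage),
            class = "mm_shape")
}

#' @export
print.mm_shape <- function(x, ...) {
  cat(sprintf("<BoundaryShape %s: %d outline points, area %.4f>\n",
              x$stage$label, nrow(x$outline), abs(polygon_area(x$outline))))
  invisible(x)
}

#' Close an open bud curve with a rectangular flank
#'
#' The open curve must start and end on the body wall line (equal x at both
#' endpoints). A rectangular "artificial body" of the given depth is appended
#' on the negative-x side, standing in for the deep flank tissue in which the
#' bud is anchored.
#'
#' @param curve open curve as a two-column matrix, first and last point with
#'   equal x; traversed from negative-y endpoint to positive-y endpoint.
#' @param depth flank depth (>= 0) in model units.
#' @param stage optional stage to attach.
#' @return a \code{mm_shape}: closed counter-clockwise polygon with
#'   \code{flank_span} marking the flank vertex indices.
#' @export
attach_flank <- function(curve, depth, stage = stage_label(0L)) {
  if (depth < 0) stop("flank depth must be non-negative")
  x0 <- curve[1, 1]
  if (abs(curve[nrow(curve), 1] - x0) > 1e-9)
    stop("curve endpoints must share the same x (the body wall line)")
  ylo <- curve[1, 2]; yhi <- curve[nrow(curve), 2]
  if (ylo > yhi) { curve <- curve[rev(seq_len(nrow(curve))), ]; tmp <- ylo; ylo <- yhi; yhi <- tmp }
  if (depth == 0) {
    outline <- curve
    flank_span <- c(1L, nrow(outline))
  } else {
    flank <- rbind(c(x0 - depth, yhi), c(x0 - depth, ylo))
    outline <- rbind(curve, flank)
    flank_span <- c(nrow(outline) - 1L, nrow(outline))
  }
  colnames(outline) <- c("x", "y")
  if (polygon_area(outline) < 0)
    stop("curve orientation must run from the negative-y to the positive-y endpoint")
  shp <- new_boundary_shape(outline, flank_span, stage)
  shp$wall_x <- x0   # bud attachment line; the artificial body lies left of it
  if (!polygon_is_simple(outline)) stop("attach_flank produced a self-intersecting polygon")
  shp
}

#' Resample a closed outline to n approximately equally spaced points
#'
#' Arc-length resampling along the closed polygon. The first vertex of the
#' input is retained as the first vertex of the output.
#'
#' @param shape a \code{mm_shape} or a vertex matrix.
#' @param n number of output points (>= 8).
#' @return same type as the input with n outline points.
#' @export
resample_outline <- function(shape, n) {
  if (n < 8) stop("n must be at least 8")
  xy <- if (inherits(shape, "mm_shape")) shape$outline else shape
  closed <- rbind(xy, xy[1, ])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  s <- c(0, cumsum(seg))
  per <- s[length(s)]
  target <- seq(0, per, length.out = n + 1)[-(n + 1)]
  newx <- approx(s, closed[, 1], xout = target)$y
  newy <- approx(s, closed[, 2], xout = target)$y
  out <- cbind(newx, newy)
  colnames(out) <- c("x", "y")
  if (inherits(shape, "mm_shape")) {
    new_boundary_shape(out, flank_span = NULL, stage = shape$stage)
  } else out
}

# Open bud curve at a given frame of the synthetic trajectory.
# Parametric paddle: PD length L, base half-width w0, distal widening given
# by an extra factor peaking mid-distally (the nascent autopod).
bud_curve <- function(L, w0, widen, n = 256, wobble = NULL) {
  phi <- seq(-pi / 2, pi / 2, length.out = n)
  x <- L * cos(phi)
  y <- w0 * sin(phi) * (1 + widen * cos(phi))
  if (!is.null(wobble)) {
    r <- 1 + wobble(phi)
    x <- x * r; y <- y * ifelse(abs(phi) < pi / 2 - 1e-9, r, 1)
  }
  # endpoints exactly on the body wall
  x[1] <- 0; x[n] <- 0; y[1] <- -w0; y[n] <- w0
  cbind(x = x, y = y)
}

#' Generate a synthetic hourly limb-bud outline trajectory
#'
#' Emulates an hour-by-hour morphometric trajectory of a growing limb bud: a
#' semicircular bud protruding from a flat flank that elongates along the
#' proximo-distal (+x) axis and, from a configurable onset hour, widens
#' distally into a paddle. The flank ("artificial body") is a fixed rectangle
#' shared by every frame. Purely parametric; deterministic given the seed
#' (the seed only matters when \code{noise > 0}).
#'
#' @param frames number of hourly frames (default 72, spanning mE9:00 to
#'   mE11:23).
#' @param r0 initial bud radius = fixed base half-width (model units).
#' @param elongation_rate PD elongation per hour.
#' @param widen_onset hour at which distal widening starts.
#' @param widen_strength final relative distal widening (0 = none).
#' @param flank_depth depth of the rectangular flank.
#' @param n_outline outline points per frame.
#' @param origin_day morphometric day of frame 1.
#' @param noise amplitude of a smooth random boundary perturbation (default 0).
#' @param seed RNG seed for the perturbation.
#' @return object of class \code{mm_sequence}: list with \code{frames} (list
#'   of \code{mm_shape}) and the generating config.
#' @export
generate_synthetic_trajectory <- function(frames = 72L, r0 = 1,
                                          elongation_rate = 0.05,
                                          widen_onset = 36L,
                                          widen_strength = 0.5,
                                          flank_depth = 0.5,
                                          n_outline = 256L,
                                          origin_day = 9L,
                                          noise = 0, seed = 1L) {
  if (frames < 2) stop("frames must be >= 2")
  if (elongation_rate < 0 || widen_strength < 0 || r0 <= 0 || noise < 0)
    stop("rates and sizes must be non-negative (r0 positive)")
  wobble <- NULL
  if (noise > 0) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    a <- rnorm(3, 0, noise); ph <- runif(3, 0, 2 * pi)
    wobble <- function(phi) a[1] * cos(2 * phi + ph[1]) +
      a[2] * cos(3 * phi + ph[2]) + a[3] * cos(4 * phi + ph[3])
  }
  shp <- vector("list", frames)
  for (t in seq_len(frames)) {
    h <- t - 1L
    L <- r0 + elongation_rate * h
    widen <- if (h <= widen_onset) 0 else
      widen_strength * (h - widen_onset) / max(1, frames - 1 - widen_onset)
    crv <- bud_curve(L, r0, widen, n = n_outline, wobble = wobble)
    shp[[t]] <- attach_flank(crv, flank_depth, stage = stage_label(h, origin_day))
  }
  structure(list(frames = shp,
                 config = list(frames = frames, r0 = r0,
                               elongation_rate = elongation_rate,
                               widen_onset = widen_onset,
                               widen_strength = widen_strength,
                               flank_depth = flank_depth,
                               n_outline = n_outline,
                               origin_day = origin_day,
                               noise = noise, seed = seed)),
            class = "mm_sequence")
}

#' @export
print.mm_sequence <- function(x, ...) {
  n <- length(x$frames)
  cat(sprintf("<ShapeSequence: %d hourly frames, %s .. %s>\n", n,
              x$frames[[1]]$stage$label, x$frames[[n]]$stage$label))
  invisible(x)
}

#' Write / read a shape sequence as per-frame CSV plus a JSON manifest
#'
#' One CSV (columns x, y) per frame and a manifest listing frame number,
#' stage label and file name. Round-trips coordinates exactly at 1e-12.
#'
#' @param seq a \code{mm_sequence}.
#' @param dir output directory (created if absent).
#' @export
write_shape_sequence <- function(seq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- vector("list", length(seq$frames))
  for (t in seq_along(seq$frames)) {
    f <- sprintf("frame_%03d.csv", t)
    df <- as.data.frame(seq$frames[[t]]$outline)
    names(df) <- c("x", "y")
    write.csv(format(df, digits = 17), file.path(dir, f), row.names = FALSE,
              quote = FALSE)
    manifest[[t]] <- list(frame = t, stage = seq$frames[[t]]$stage$label,
                          file = f,
                          flank_span = seq$frames[[t]]$flank_span)
  }
  jsonlite::write_json(list(frames = manifest, config = seq$config),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_shape_sequence
#' @export
read_shape_sequence <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  frames <- vector("list", nrow(man$frames))
  for (t in seq_len(nrow(man$frames))) {
    df <- read.csv(file.path(dir, man$frames$file[t]))
    lab <- man$frames$stage[t]
    dd <- as.integer(sub("mE(\\d+):(\\d+)", "\\1", lab))
    hh <- as.integer(sub("mE(\\d+):(\\d+)", "\\2", lab))
    fs <- man$frames$flank_span[[t]]
    frames[[t]] <- new_boundary_shape(cbind(x = df$x, y = df$y),
                                      if (length(fs)) as.integer(fs) else NULL,
                                      stage_label((dd - man$config$origin_day) * 24L + hh,
                                                  man$config$origin_day))
  }
  structure(list(frames = frames, config = man$config), class = "mm_sequence")
}
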