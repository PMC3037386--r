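# Synthetic fixtures: control-spline sets over the synthetic trajectory,
# analytic oracle movies, binary mask IO and the self-contained fixture
# dataset generator.

#' Control-spline sets for a synthetic trajectory
#'
#' Three families, mirroring the main plausible AP asymmetries of bud
#' outgrowth: \code{"straight"} (radial rays from a hub in the body: fairly
#' straight distal growth), \code{"fan"} (splines whose angle opens with
#' distance: strong distal fanning-out), and \code{"posterior"} (splines
#' drifting toward negative y: posteriorly twisted growth).
#'
#' @param seq a \code{mm_sequence}.
#' @param set spline family.
#' @param n number of splines.
#' @param max_angle largest |angle| from the PD axis, radians.
#' @return list of \code{mm_spline}.
#' @export
make_control_splines <- function(seq, set = c("straight", "fan", "posterior"),
                                 n = 9L, max_angle = 1.05) {
  set <- match.arg(set)
  cfg <- seq$config
  hub <- c(-0.2 * cfg$r0, 0)
  reach <- cfg$r0 + cfg$elongation_rate * (cfg$frames - 1)
  S <- (reach + cfg$r0) * 1.6
  th0 <- seq(-max_angle, max_angle, length.out = n)
  lapply(seq_len(n), function(i) {
    s <- seq(0, S, length.out = 48)
    ang <- switch(set,
                  straight = rep(th0[i], length(s)),
                  fan = th0[i] * (0.55 + 0.9 * s / S),
                  posterior = th0[i] - 0.25 * s / S)
    pts <- cbind(hub[1] + s * cos(ang), hub[2] + s * sin(ang))
    control_spline(pts, name = sprintf("%s_%02d", set, i))
  })
}

#' Analytic uniform-growth oracle movie
#'
#' A disc mesh growing geometrically by a factor (1 + k) per hour about the
#' origin, with stored node velocities k * x. Every triangle then carries
#' velocity gradient kI, expansion rate 2k, zero anisotropy and rotation,
#' and discrete areas double in about ln2 / (2k) hours. Used as a closed-form
#' oracle for the tensor pipeline.
#'
#' @param k relative linear growth per hour.
#' @param hours number of frame pairs.
#' @param radius initial disc radius.
#' @param target_edge_length mesh resolution.
#' @return a \code{mm_movie}.
#' @export
uniform_growth_movie <- function(k = 0.05, hours = 12L, radius = 1,
                                 target_edge_length = 0.25) {
  th <- seq(0, 2 * pi, length.out = 49)[-49]
  circle <- cbind(radius * cos(th), radius * sin(th))
  mesh0 <- triangulate(circle, target_edge_length)
  T <- hours + 1L
  meshes <- vector("list", T)
  velocities <- vector("list", T - 1)
  maps <- vector("list", T - 1)
  for (t in seq_len(T)) {
    m <- mesh0
    g <- (1 + k)^(t - 1)
    m$points <- mesh0$points * g
    m$boundary_polygon <- mesh0$boundary_polygon * g
    m$stage <- stage_label(t - 1L)
    meshes[[t]] <- m
  }
  for (t in seq_len(T - 1)) {
    velocities[[t]] <- k * meshes[[t]]$points
    disp <- meshes[[t + 1]]$points - meshes[[t]]$points
    maps[[t]] <- build_interpolation_map(meshes[[t]], disp, meshes[[t + 1]])
  }
  structure(list(meshes = meshes, velocities = velocities, maps = maps,
                 log = list(),
                 config = list(profile = "analytic_uniform", k = k,
                               target_edge_length = target_edge_length)),
            class = "mm_movie")
}

#' Identity movie (repeated congruent frames)
#'
#' Zero velocities and identity interpolation maps over a fixed mesh; the
#' degenerate baseline for transport tests.
#'
#' @param mesh a \code{mm_mesh}.
#' @param frames number of frames.
#' @return a \code{mm_movie}.
#' @export
identity_movie <- function(mesh, frames = 3L) {
  meshes <- rep(list(mesh), frames)
  zero <- matrix(0, nrow(mesh$points), 2)
  map1 <- build_interpolation_map(mesh, zero, mesh)
  structure(list(meshes = meshes,
                 velocities = rep(list(zero), frames - 1),
                 maps = rep(list(map1), frames - 1),
                 log = list(), config = list(profile = "identity")),
            class = "mm_movie")
}

#' Write / read an ASCII PGM (P2) binary mask
#' @param mask 0/1 matrix (rows = image rows, row 1 at the top).
#' @param file path ending in .pgm.
#' @export
write_mask_pgm <- function(mask, file) {
  mask <- as.matrix(mask) > 0
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(mask), nrow(mask)), "1"), con)
  writeLines(apply(mask * 1L, 1, paste, collapse = " "), con)
  invisible(file)
}

#' @rdname write_mask_pgm
#' @export
read_mask <- function(file) {
  if (grepl("\\.png$", file, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG masks requires the png package")
    img <- png::readPNG(file)
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(img > 0.5)
  }
  lines <- readLines(file)
  lines <- lines[!grepl("^#", lines)]
  if (trimws(lines[1]) != "P2") stop("only ASCII PGM (P2) masks supported")
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  vals <- as.integer(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
  matrix(vals > 0, nrow = dims[2], ncol = dims[1], byrow = TRUE)
}

# render a set of mesh triangles to a pixel mask on a fixed grid
triangles_to_mask <- function(mesh, tri_ids, nx = 128, bbox = NULL) {
  if (is.null(bbox))
    bbox <- c(range(mesh$points[, 1]), range(mesh$points[, 2]))
  dx <- (bbox[2] - bbox[1]) / nx          # square pixels
  ny <- ceiling((bbox[4] - bbox[3]) / dx)
  cx <- bbox[1] + (seq_len(nx) - 0.5) * dx
  cy <- bbox[3] + (seq_len(ny) - 0.5) * dx
  px <- rep(cx, each = ny)
  py <- rep(rev(cy), times = nx)   # row 1 = top
  mask <- rep(FALSE, nx * ny)
  for (k in tri_ids) {
    v <- mesh$points[mesh$triangles[k, ], ]
    inb <- px >= min(v[, 1]) & px <= max(v[, 1]) &
      py >= min(v[, 2]) & py <= max(v[, 2])
    if (!any(inb)) next
    hit <- as.logical(point_in_polygon_cpp(px[inb], py[inb], v[, 1], v[, 2]))
    mask[which(inb)[hit]] <- TRUE
  }
  list(mask = matrix(mask, nrow = ny, ncol = nx),
       alignment = mask_alignment(scale = dx,
                                  translation = c(bbox[1], bbox[3])))
}

#' Generate the self-contained synthetic fixture dataset
#'
#' Builds the default 72-frame trajectory, three control-spline sets, two
#' movies (distinct stiffness profiles on the straight spline set), a set of
#' simulated clone masks with known generating seed triangles, and toy
#' expression masks — everything the downstream analyses need, with no
#' external data.
#'
#' @param seed RNG seed (drives clone seed-triangle sampling).
#' @param dir output directory; when NULL nothing is written and the objects
#'   are returned only.
#' @param frames trajectory length.
#' @param target_edge_length mesh resolution for the movies.
#' @param n_clones number of simulated clones.
#' @param clone_D diffusion constant used to grow the simulated clones
#'   (small, so the generating seed stays identifiable).
#' @return (invisibly) a list with the sequence, splines, movies, clones
#'   (masks + seed triangles + alignments) and expression masks.
#' @export
make_fixtures <- function(seed = 1L, dir = NULL, frames = 72L,
                          target_edge_length = 0.15, n_clones = 13L,
                          clone_D = 1e-4) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  seq <- generate_synthetic_trajectory(frames = frames)
  spl <- list(straight = make_control_splines(seq, "straight"),
              fan = make_control_splines(seq, "fan"),
              posterior = make_control_splines(seq, "posterior"))
  movieA <- build_morphomovie(seq, spl$straight, "sigmoid",
                              target_edge_length = target_edge_length)
  movieB <- build_morphomovie(seq, spl$straight, "inverted_sigmoid",
                              target_edge_length = target_edge_length)
  T <- length(movieA$meshes)
  mesh1 <- movieA$meshes[[1]]
  meshT <- movieA$meshes[[T]]
  cen1 <- (mesh1$points[mesh1$triangles[, 1], ] +
             mesh1$points[mesh1$triangles[, 2], ] +
             mesh1$points[mesh1$triangles[, 3], ]) / 3
  candidates <- which(cen1[, 1] > 0.15)   # seed inside the bud proper
  seeds <- sample(candidates, n_clones)
  op <- full_transport_operator(movieA, diffusion_config(clone_D))
  bbox <- c(range(meshT$points[, 1]), range(meshT$points[, 2]))
  clones <- lapply(seeds, function(s) {
    f <- as.vector(op[, s])
    tri_ids <- which(f >= 0.25 * max(f))
    r <- triangles_to_mask(meshT, tri_ids, bbox = bbox)
    list(seed_triangle = s, triangles = tri_ids, mask = r$mask,
         alignment = r$alignment)
  })
  # toy expression domains on two frames: a distal cap that later jumps
  # anteriorly (the regulated-expansion fixture)
  cenT <- (meshT$points[meshT$triangles[, 1], ] +
             meshT$points[meshT$triangles[, 2], ] +
             meshT$points[meshT$triangles[, 3], ]) / 3
  tipx <- max(cenT[, 1])
  expr_late <- as.numeric(cenT[, 1] > 0.6 * tipx)
  expr_late_anterior <- as.numeric(cenT[, 1] > 0.6 * tipx & cenT[, 2] > 0)
  fixtures <- list(sequence = seq, splines = spl,
                   movies = list(sigmoid = movieA,
                                 inverted_sigmoid = movieB),
                   clones = clones,
                   expression = list(late_cap = expr_late,
                                     late_cap_anterior = expr_late_anterior),
                   seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_shape_sequence(seq, file.path(dir, "shapes"))
    for (nm in names(spl))
      write_splines(spl[[nm]], file.path(dir, sprintf("splines_%s.json", nm)))
    write_morphomovie(movieA, file.path(dir, "movie_sigmoid"))
    write_morphomovie(movieB, file.path(dir, "movie_inverted_sigmoid"))
    dir.create(file.path(dir, "clones"), showWarnings = FALSE)
    for (i in seq_along(clones)) {
      write_mask_pgm(clones[[i]]$mask,
                     file.path(dir, "clones", sprintf("clone_%02d.pgm", i)))
      jsonlite::write_json(list(seed_triangle = clones[[i]]$seed_triangle,
                                alignment = clones[[i]]$alignment),
                           file.path(dir, "clones",
                                     sprintf("clone_%02d.json", i)),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(fixtures)
}
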