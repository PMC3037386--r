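# Shared, lazily built fixtures. The full-scale 72-frame movies are
# expensive, so they are cached across test files within one run.

.mm_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .mm_cache)) assign(key, builder(), envir = .mm_cache)
  get(key, envir = .mm_cache)
}

small_sequence <- function() cached("seq_small", function()
  generate_synthetic_trajectory(frames = 6))

small_movie <- function(profile = "constant") cached(paste0("mov_small_", profile), function() {
  seq <- small_sequence()
  spl <- make_control_splines(seq, "straight")
  build_morphomovie(seq, spl, profile, target_edge_length = 0.2)
})

full_sequence <- function() cached("seq72", function()
  generate_synthetic_trajectory())

full_movie <- function(profile = "sigmoid") cached(paste0("mov72_", profile), function() {
  seq <- full_sequence()
  spl <- make_control_splines(seq, "straight")
  build_morphomovie(seq, spl, profile, target_edge_length = 0.15)
})

full_operator <- function(D = 0, profile = "sigmoid") cached(sprintf("op72_%s_%g", profile, D),
  function() full_transport_operator(full_movie(profile), diffusion_config(D)))

disc_mesh <- function(h = 0.3) cached(paste0("disc_", h), function() {
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  triangulate(cbind(cos(th), sin(th)), h)
})

tri_centroids <- function(mesh)
  (mesh$points[mesh$triangles[, 1], , drop = FALSE] +
     mesh$points[mesh$triangles[, 2], , drop = FALSE] +
     mesh$points[mesh$triangles[, 3], , drop = FALSE]) / 3
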