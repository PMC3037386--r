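# Gene-expression domain transport: carry thresholded expression domains
# forward or backward through a MorphoMovie as if moved by tissue growth
# alone, then classify active up-/down-regulation by differencing the
# growth-only prediction against the observed domain.

#' Map a binary expression mask onto a mesh
#'
#' Shares the rasterization used for clones; returns an indicator field (1
#' inside the thresholded expression domain).
#'
#' @param mask binary image matrix.
#' @param mesh a \code{mm_mesh}.
#' @param alignment pixel-to-mesh transform (\code{\link{mask_alignment}}).
#' @param gene optional gene name.
#' @param frame frame the domain is observed on.
#' @param coverage triangle inclusion threshold.
#' @return object of class \code{mm_domain}: indicator \code{field}, gene
#'   and frame.
#' @export
map_domain <- function(mask, mesh, alignment = mask_alignment(),
                       gene = NULL, frame = NULL, coverage = 0.5) {
  cl <- suppressWarnings(rasterize_mask_to_mesh(mask, mesh, alignment, coverage))
  field <- numeric(nrow(mesh$triangles))
  if (cl$n > 0) field[cl$triangles] <- 1
  structure(list(field = field, gene = gene, frame = frame),
            class = "mm_domain")
}

#' Expression domain from a per-triangle indicator field
#' @param field 0/1 per-triangle values.
#' @param gene,frame metadata.
#' @export
expression_domain <- function(field, gene = NULL, frame = NULL) {
  if (!all(field %in% c(0, 1))) stop("domain field must be a 0/1 indicator")
  structure(list(field = field, gene = gene, frame = frame),
            class = "mm_domain")
}

#' Transport an expression domain through a movie
#'
#' Forward transport advects (and optionally diffuses) the domain to a later
#' frame; backward transport pulls it to an earlier frame through the
#' reverse maps. Diffusion defaults to zero: expression domains are tissue
#' marks, not mixing cell populations.
#'
#' @param movie a \code{mm_movie}.
#' @param domain a \code{mm_domain} (its \code{frame} must be set).
#' @param to_frame destination frame.
#' @param direction "forward" or "backward"; must agree with the frame
#'   ordering.
#' @param cfg a \code{mm_diffusion} (default D = 0).
#' @return per-triangle field on \code{to_frame}'s mesh, values in [0, 1].
#' @export
transport <- function(movie, domain, to_frame,
                      direction = c("forward", "backward"),
                      cfg = diffusion_config(0)) {
  direction <- match.arg(direction)
  from <- domain$frame
  if (is.null(from)) stop("domain has no frame")
  if (direction == "forward" && to_frame < from)
    stop("forward transport needs to_frame >= the domain frame")
  if (direction == "backward" && to_frame > from)
    stop("backward transport needs to_frame <= the domain frame")
  v <- domain$field
  if (direction == "forward") {
    for (t in seq_len(to_frame - from)) {
      fr <- from + t - 1L
      v <- diffuse(v, movie$meshes[[fr]], cfg, hours = 1)
      v <- transfer(v, movie$maps[[fr]])
    }
  } else {
    for (t in seq_len(from - to_frame)) {
      fr <- from - t
      v <- transfer(v, reverse_map(movie$maps[[fr]]))
      v <- diffuse(v, movie$meshes[[fr]], cfg, hours = 1)
    }
  }
  v
}

#' Classify active regulation from predicted vs observed domains
#'
#' Per triangle: "up" where the observed domain is on but the growth-only
#' prediction is below threshold (expression appeared beyond what movement
#' explains), "down" where the observed domain is off but the prediction is
#' above threshold, otherwise "consistent".
#'
#' @param predicted growth-only transported field.
#' @param observed a \code{mm_domain} (or 0/1 field) on the same mesh.
#' @param threshold classification threshold theta (default 0.5).
#' @return factor with levels up, down, consistent.
#' @export
regulation_difference <- function(predicted, observed, threshold = 0.5) {
  obs <- if (inherits(observed, "mm_domain")) observed$field else observed
  if (length(obs) != length(predicted)) stop("fields live on different meshes")
  cls <- rep("consistent", length(obs))
  cls[obs == 1 & predicted < threshold] <- "up"
  cls[obs == 0 & predicted > threshold] <- "down"
  factor(cls, levels = c("up", "down", "consistent"))
}
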