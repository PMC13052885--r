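#' Point cloud objects
#'
#' A `point_cloud` is an unordered set of N points sampled from an object's
#' surface, stored as an N x 3 coordinate matrix in a unit-sphere frame
#' (y is the vertical axis), with optional per-point part labels, a category
#' label and an instance identifier.
#'
#' @param coords numeric N x 3 matrix of point coordinates.
#' @param part_labels optional integer vector of length N assigning each point
#'   to a part (contiguous ids starting at 0).
#' @param category optional category name.
#' @param instance_id optional instance identifier.
#' @return An object of class `point_cloud`: a list with elements `coords`,
#'   `part_labels`, `category`, `instance_id`.
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), 10, 3))
#' n_points(pc)
#' @export
point_cloud <- function(coords, part_labels = NULL, category = NA_character_,
                        instance_id = NA_character_) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  stop_if_not_matrix3(coords)
  if (!is.null(part_labels)) {
    part_labels <- as.integer(part_labels)
    if (length(part_labels) != nrow(coords)) {
      stop("`part_labels` must have one entry per point (", nrow(coords),
           "), got ", length(part_labels), call. = FALSE)
    }
  }
  structure(
    list(coords = coords, part_labels = part_labels,
         category = as.character(category)[1],
         instance_id = as.character(instance_id)[1]),
    class = "point_cloud"
  )
}

#' @rdname point_cloud
#' @param pc a `point_cloud`.
#' @export
n_points <- function(pc) nrow(pc$coords)

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points", n_points(x)))
  if (!is.na(x$category)) cat(", category:", x$category)
  if (!is.null(x$part_labels)) {
    cat(sprintf(", %d parts", length(unique(x$part_labels))))
  }
  cat("\n")
  invisible(x)
}

#' Centre a cloud at the origin and scale it into the unit sphere
#'
#' Subtracts the centroid, then divides all coordinates by the maximum point
#' norm so the farthest point lies on the unit sphere. Degenerate clouds
#' (a single point, or all points coincident) are centred and left unscaled.
#' Labels and metadata are preserved. The operation is idempotent.
#'
#' @param pc a `point_cloud`.
#' @return The normalized `point_cloud`.
#' @export
normalize_unit_sphere <- function(pc) {
  stopifnot(inherits(pc, "point_cloud"))
  x <- pc$coords
  x <- sweep(x, 2, colMeans(x), "-")
  r <- max(row_norms(x))
  if (r > 1e-12) x <- x / r
  pc$coords <- x
  pc
}

#' Attach provenance to a stimulus
#'
#' A stimulus record is a `point_cloud` carrying the provenance needed to
#' regenerate it exactly: the base instance, the perturbation family, its
#' parameters and the seed.
#'
#' @param pc a `point_cloud`.
#' @param family perturbation family name (e.g. "density", "lego", "scramble").
#' @param params named list of condition parameters.
#' @param seed the RNG seed used.
#' @return `pc` with class `stimulus_record` prepended and a `provenance`
#'   element added.
#' @export
stimulus_record <- function(pc, family, params = list(), seed = NA_integer_) {
  stopifnot(inherits(pc, "point_cloud"))
  pc$provenance <- list(base_instance = pc$instance_id, family = family,
                        params = params, seed = seed)
  class(pc) <- c("stimulus_record", class(pc))
  pc
}
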