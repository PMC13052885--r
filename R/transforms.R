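# Stimulus perturbations: density downsampling, inversion, voxel "Lego"
# deformation, part subdivision + scrambling, and training-time augmentation.
# Every randomized transform is deterministic given its seed.

#' Randomly downsample a cloud to a proportion of its points
#'
#' Keeps a uniformly random subset without replacement of size
#' `floor(proportion * N)` (minimum 1). Part labels are subset consistently.
#' `proportion = 1` returns the input unchanged.
#'
#' @param pc a `point_cloud`.
#' @param proportion fraction in (0, 1].
#' @param seed RNG seed.
#' @return The downsampled `point_cloud`.
#' @export
downsample_density <- function(pc, proportion, seed) {
  stopifnot(inherits(pc, "point_cloud"))
  if (!is.numeric(proportion) || proportion <= 0 || proportion > 1) {
    stop("`proportion` must be in (0, 1]", call. = FALSE)
  }
  if (proportion == 1) return(pc)
  n <- n_points(pc)
  m <- max(1L, as.integer(floor(proportion * n)))
  keep <- with_seed(seed, sample.int(n, m))
  pc$coords <- pc$coords[keep, , drop = FALSE]
  if (!is.null(pc$part_labels)) pc$part_labels <- pc$part_labels[keep]
  pc
}

#' Turn an object upside down
#'
#' A proper rigid rotation of 180 degrees about the horizontal x axis
#' (y is vertical): (x, y, z) -> (x, -y, -z). Applying it twice is the
#' identity; all pairwise distances are preserved.
#'
#' @param pc a `point_cloud`.
#' @return The inverted `point_cloud`.
#' @export
invert <- function(pc) {
  stopifnot(inherits(pc, "point_cloud"))
  pc$coords[, 2] <- -pc$coords[, 2]
  pc$coords[, 3] <- -pc$coords[, 3]
  pc
}

# Occupancy grid of a cloud: integer cell coordinates (0-based), with the
# grid origin anchored at the axis-aligned bounding-box minimum corner.
#' Voxel occupancy grid of a point cloud
#'
#' @param pc a `point_cloud`.
#' @param voxel_size positive edge length in the cloud's (unit-sphere) units.
#' @return A `voxel_grid`: list with `voxel_size`, `origin`, and `occupied`
#'   (unique integer cell triples, one row per occupied voxel).
#' @export
voxel_grid <- function(pc, voxel_size) {
  stopifnot(inherits(pc, "point_cloud"))
  if (!is.numeric(voxel_size) || voxel_size <= 0) {
    stop("`voxel_size` must be > 0", call. = FALSE)
  }
  origin <- apply(pc$coords, 2, min)
  # points exactly on a shared grid plane belong to the upper cell (floor)
  idx <- floor(sweep(pc$coords, 2, origin, "-") / voxel_size)
  idx <- matrix(as.integer(idx), ncol = 3)
  occupied <- unique(idx)
  structure(list(voxel_size = voxel_size, origin = origin,
                 occupied = occupied), class = "voxel_grid")
}

# Enumerate exposed faces of an occupancy grid: faces of occupied voxels not
# shared with another occupied voxel. Returns a data.frame with the cell,
# axis (1..3) and side (-1/+1) of each exposed face.
#' @rdname voxel_grid
#' @param grid a `voxel_grid`.
#' @export
exposed_faces <- function(grid) {
  occ <- grid$occupied
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  occ_set <- key(occ)
  out <- list()
  for (axis in 1:3) {
    for (side in c(-1L, 1L)) {
      nb <- occ
      nb[, axis] <- nb[, axis] + side
      open <- !(key(nb) %in% occ_set)
      if (any(open)) {
        out[[length(out) + 1L]] <- data.frame(
          i = occ[open, 1], j = occ[open, 2], k = occ[open, 3],
          axis = axis, side = side)
      }
    }
  }
  do.call(rbind, out)
}

#' Lego-like voxel deformation of a point cloud
#'
#' Builds the occupancy grid at `voxel_size`, enumerates the exposed voxel
#' faces (faces not shared between two occupied voxels), samples `n_out`
#' points area-uniformly over those faces, and unit-sphere normalizes the
#' result. Local curvature is destroyed while global shape is preserved.
#' Every pre-normalization point lies exactly on an exposed face plane.
#'
#' @param pc a `point_cloud`.
#' @param voxel_size positive voxel edge length; `0` is accepted as the
#'   identity (no deformation).
#' @param n_out number of output points (default: input size).
#' @param seed RNG seed.
#' @param normalize unit-sphere normalize the result (disable to inspect the
#'   raw on-grid points).
#' @return A `point_cloud` (part labels dropped; category kept).
#' @export
voxelize_lego <- function(pc, voxel_size, n_out = n_points(pc), seed,
                          normalize = TRUE) {
  stopifnot(inherits(pc, "point_cloud"), n_out >= 1)
  if (voxel_size == 0) return(pc)
  grid <- voxel_grid(pc, voxel_size)
  faces <- exposed_faces(grid)
  pts <- with_seed(seed, {
    f <- sample.int(nrow(faces), n_out, replace = TRUE) # equal-area faces
    u <- runif(n_out); v <- runif(n_out)
    sel <- faces[f, ]
    base <- cbind(sel$i, sel$j, sel$k)
    p <- matrix(0, n_out, 3)
    for (axis in 1:3) {
      rows <- which(sel$axis == axis)
      if (!length(rows)) next
      off <- matrix(0, length(rows), 3)
      off[, axis] <- ifelse(sel$side[rows] > 0, 1, 0)
      others <- setdiff(1:3, axis)
      off[, others[1]] <- u[rows]
      off[, others[2]] <- v[rows]
      p[rows, ] <- (base[rows, , drop = FALSE] + off) * voxel_size
    }
    sweep(p, 2, grid$origin, "+")
  })
  out <- point_cloud(pts, category = pc$category, instance_id = pc$instance_id)
  if (normalize) normalize_unit_sphere(out) else out
}

#' Configuration for part scrambling
#'
#' Houses the scrambling parameters: the per-part offset half-range `r`
#' (offsets are uniform in the cube `[-r, r]^3`, default 0.6), the share
#' threshold above which a part is subdivided (default 0.30), and the number
#' of spectral sub-clusters used for subdivision (default 3).
#'
#' @param r positive offset half-range.
#' @param subdivide_threshold fraction in (0, 1).
#' @param n_subclusters integer >= 2.
#' @param knn_k neighbourhood size of the spectral-clustering affinity graph.
#' @param seed RNG seed.
#' @return A `scramble_config`.
#' @export
scramble_config <- function(r = 0.6, subdivide_threshold = 0.30,
                            n_subclusters = 3L, knn_k = 10L, seed = 1L) {
  stopifnot(r > 0, subdivide_threshold > 0, subdivide_threshold < 1,
            n_subclusters >= 2, knn_k >= 1)
  structure(list(r = r, subdivide_threshold = subdivide_threshold,
                 n_subclusters = as.integer(n_subclusters),
                 knn_k = as.integer(knn_k), seed = as.integer(seed)),
            class = "scramble_config")
}

# Normalized spectral clustering on a symmetric kNN connectivity graph:
# bottom eigenvectors of the symmetric normalized Laplacian, row-normalized,
# then k-means.
.spectral_cluster <- function(coords, n_clusters, knn_k, seed) {
  n <- nrow(coords)
  stopifnot(n >= n_clusters)
  k <- min(knn_k, n - 1L)
  idx <- knn_indices(coords, k = k, include_self = FALSE)
  A <- matrix(0, n, n)
  A[cbind(rep(seq_len(n), k), as.vector(idx))] <- 1
  A <- pmax(A, t(A)) # symmetrize (mutual OR)
  d <- pmax(rowSums(A), 1e-12)
  Dm <- 1 / sqrt(d)
  Lsym <- diag(n) - (Dm * A) %*% diag(Dm)
  ev <- eigen(Lsym, symmetric = TRUE)
  U <- ev$vectors[, n - seq_len(n_clusters) + 1L, drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  U <- U / pmax(rn, 1e-12)
  # individual random restarts may fail to converge or leave a cluster
  # empty; the best of the 10 restarts is used, so those warnings carry no
  # information
  km <- with_seed(seed, suppressWarnings(
    stats::kmeans(U, centers = n_clusters, nstart = 10, iter.max = 50)))
  km$cluster
}

#' Subdivide over-large parts by spectral clustering
#'
#' Any part whose share of the cloud exceeds `subdivide_threshold` is split
#' into `n_subclusters` new parts by spectral clustering on a symmetric
#' k-nearest-neighbour affinity graph of its points. Parts at or below the
#' threshold are untouched. The refined labels are re-indexed contiguously
#' from 0.
#'
#' @param pc a `point_cloud` with `part_labels`.
#' @param config a `scramble_config`.
#' @return The `point_cloud` with refined part labels.
#' @export
subdivide_large_parts <- function(pc, config = scramble_config()) {
  stopifnot(inherits(pc, "point_cloud"))
  if (is.null(pc$part_labels)) {
    stop("part labels are required for subdivision", call. = FALSE)
  }
  n <- n_points(pc)
  labs <- pc$part_labels
  shares <- table(labs) / n
  over <- as.integer(names(shares)[shares > config$subdivide_threshold])
  new_labs <- labs
  next_id <- max(labs) + 1L
  for (p in over) {
    sel <- which(labs == p)
    if (length(sel) < config$n_subclusters) {
      stop(sprintf("part %d exceeds the threshold but has only %d points (< %d clusters)",
                   p, length(sel), config$n_subclusters), call. = FALSE)
    }
    cl <- .spectral_cluster(pc$coords[sel, , drop = FALSE],
                            config$n_subclusters, config$knn_k,
                            derive_seed(config$seed, p))
    new_labs[sel] <- next_id + cl - 1L
    next_id <- next_id + config$n_subclusters
  }
  # re-index contiguously from 0
  pc$part_labels <- as.integer(factor(new_labs)) - 1L
  pc
}

#' Scramble the parts of a point cloud
#'
#' One part is chosen uniformly at random as the anchor; it is centred at
#' the origin (its centroid subtracted) and left fixed. Every other part is
#' centred on its own centroid and then displaced by a random offset with
#' each component uniform in `[-r, r]`. The scrambled cloud is globally
#' unit-sphere normalized, so each part's internal geometry is preserved up
#' to a single global scale. Deterministic given `config$seed`.
#'
#' @param pc a `point_cloud` with at least 2 parts.
#' @param config a `scramble_config`.
#' @param offsets optional matrix of explicit per-part offsets (one row per
#'   part id, in part-id order) overriding the random draw; used for
#'   reproducing a specific scramble.
#' @param anchor optional explicit anchor part id.
#' @param normalize unit-sphere normalize the result (disable to inspect the
#'   raw scrambled cloud, e.g. the anchor centred at the origin).
#' @return A `stimulus_record` with the scrambled cloud and full provenance
#'   (anchor, offsets, seed).
#' @export
scramble_parts <- function(pc, config = scramble_config(), offsets = NULL,
                           anchor = NULL, normalize = TRUE) {
  stopifnot(inherits(pc, "point_cloud"))
  if (is.null(pc$part_labels)) {
    stop("part labels are required for scrambling", call. = FALSE)
  }
  ids <- sort(unique(pc$part_labels))
  if (length(ids) < 2L) {
    stop("scrambling requires at least 2 parts", call. = FALSE)
  }
  drawn <- with_seed(config$seed, {
    a <- if (is.null(anchor)) ids[sample.int(length(ids), 1)] else anchor
    off <- if (is.null(offsets)) {
      matrix(stats::runif(3 * length(ids), -config$r, config$r),
             ncol = 3)
    } else {
      offsets
    }
    list(anchor = a, offsets = off)
  })
  coords <- pc$coords
  for (i in seq_along(ids)) {
    p <- ids[i]
    sel <- which(pc$part_labels == p)
    ctr <- colMeans(coords[sel, , drop = FALSE])
    coords[sel, ] <- sweep(coords[sel, , drop = FALSE], 2, ctr, "-")
    if (p != drawn$anchor) {
      coords[sel, ] <- sweep(coords[sel, , drop = FALSE], 2,
                             drawn$offsets[i, ], "+")
    }
  }
  out <- pc
  out$coords <- coords
  if (normalize) out <- normalize_unit_sphere(out)
  stimulus_record(out, family = "scramble",
                  params = list(r = config$r, anchor = drawn$anchor,
                                offsets = drawn$offsets),
                  seed = config$seed)
}

#' Training-time augmentation configuration
#'
#' Houses the augmentation ranges used during training: the random point
#' dropout ratio uniform in `[0, 0.875]` (dropped points are replaced by the
#' coordinates of the first point, never removed), a global scale factor
#' uniform in `[0.8, 1.25]`, and a per-axis shift uniform in `[-0.1, 0.1]`.
#'
#' @param dropout_range length-2 numeric, upper bound < 1.
#' @param scale_range length-2 numeric.
#' @param shift_range length-2 numeric.
#' @return An `augment_config`.
#' @export
augment_config <- function(dropout_range = c(0, 0.875),
                           scale_range = c(0.8, 1.25),
                           shift_range = c(-0.1, 0.1)) {
  stopifnot(length(dropout_range) == 2, dropout_range[2] < 1,
            dropout_range[1] >= 0, length(scale_range) == 2,
            length(shift_range) == 2)
  structure(list(dropout_range = dropout_range, scale_range = scale_range,
                 shift_range = shift_range), class = "augment_config")
}

# draw one set of augmentation parameters from the config (uses the current
# RNG stream)
sample_augment_params <- function(config) {
  list(dropout_ratio = stats::runif(1, config$dropout_range[1],
                                    config$dropout_range[2]),
       scale = stats::runif(1, config$scale_range[1], config$scale_range[2]),
       shift = stats::runif(3, config$shift_range[1], config$shift_range[2]))
}

#' Apply training augmentation to a cloud
#'
#' Order: dropout (replace `floor(ratio * N)` randomly chosen points by the
#' first point's coordinates) -> global scale -> per-axis shift. The point
#' count never changes. Deterministic given `seed`.
#'
#' @param pc a `point_cloud`.
#' @param config an `augment_config`.
#' @param seed RNG seed.
#' @param params optional explicit parameter list (as returned by the
#'   internal sampler) overriding the random draw.
#' @return The augmented `point_cloud`.
#' @export
augment_train <- function(pc, config = augment_config(), seed = 1L,
                          params = NULL) {
  stopifnot(inherits(pc, "point_cloud"))
  n <- n_points(pc)
  drawn <- with_seed(seed, {
    p <- if (is.null(params)) sample_augment_params(config) else params
    n_drop <- as.integer(floor(p$dropout_ratio * n))
    drop_idx <- if (n_drop > 0) sample.int(n, n_drop) else integer(0)
    list(p = p, drop_idx = drop_idx)
  })
  x <- pc$coords
  if (length(drawn$drop_idx)) {
    x[drawn$drop_idx, ] <- matrix(x[1, ], length(drawn$drop_idx), 3,
                                  byrow = TRUE)
  }
  x <- x * drawn$p$scale
  x <- sweep(x, 2, drawn$p$shift, "+")
  pc$coords <- x
  attr(pc, "augmentation") <- list(dropout_ratio = drawn$p$dropout_ratio,
                                   n_dropped = length(drawn$drop_idx),
                                   scale = drawn$p$scale,
                                   shift = drawn$p$shift)
  pc
}
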