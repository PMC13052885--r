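#' k-nearest-neighbour indices
#'
#' For each row of `x`, the indices of its `k` nearest rows under squared
#' Euclidean distance in the space of `x` (pass point coordinates for 3D
#' neighbourhoods, layer features for feature-space neighbourhoods). Ties are
#' broken by lowest index. When fewer than `k` candidates exist, the nearest
#' available ones are repeated so the result always has `k` columns.
#'
#' @param x numeric M x D matrix.
#' @param k number of neighbours (>= 1).
#' @param include_self whether a point may be its own neighbour.
#' @return Integer M x k matrix of row indices into `x`.
#' @export
knn_indices <- function(x, k, include_self = FALSE) {
  if (!is.numeric(k) || k < 1) stop("`k` must be >= 1", call. = FALSE)
  x <- as.matrix(x)
  d <- sqdist_rows(x, x)
  if (!include_self) diag(d) <- Inf
  .topk_rows(d, as.integer(k))
}

# k smallest per row of a distance matrix; ties by lowest index; recycle if
# fewer candidates than k (compiled kernel)
.topk_rows <- function(d, k) .topk_rows_cpp(d, as.integer(k))

# neighbours of query rows among reference rows (used by transition-down)
knn_query <- function(query, ref, k) {
  d <- sqdist_rows(as.matrix(query), as.matrix(ref))
  .topk_rows(d, as.integer(k))
}

#' Farthest point sampling
#'
#' Greedy max-min selection: starting from `start_index`, repeatedly add the
#' point whose minimum distance to the already-selected set is largest (ties
#' broken by lowest index). Deterministic given `start_index`; the default
#' start is the point farthest from the centroid, which makes the selected
#' set (and hence networks built on it) invariant to the input point order.
#'
#' @param coords numeric M x D matrix.
#' @param m number of points to select (1 <= m <= M).
#' @param start_index index of the first selected point, or `NULL` for the
#'   farthest-from-centroid default.
#' @return Integer vector of `m` selected row indices, in greedy order.
#' @export
farthest_point_sampling <- function(coords, m, start_index = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (m < 1 || m > n) {
    stop(sprintf("`m` must be in [1, %d], got %s", n, m), call. = FALSE)
  }
  if (is.null(start_index)) {
    ctr <- colMeans(coords)
    start_index <- which.max(rowSums(sweep(coords, 2, ctr, "-")^2))
  }
  stopifnot(start_index >= 1, start_index <= n)
  storage.mode(coords) <- "double"
  .fps_cpp(coords, as.integer(m), as.integer(start_index))
}
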