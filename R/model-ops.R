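# Exported computational primitives of the two architectures, in pure
# functional form (explicit weight arguments, forward only). The trainable
# network stages used by build_model/train wrap the same math with batch
# normalisation and backward passes (model-forward.R).

#' EdgeConv: dynamic graph edge convolution
#'
#' For each point i and neighbour j, builds the edge feature
#' `(f_j - f_i, f_i)`, applies the learned per-edge linear map `W` followed
#' by a leaky-ReLU nonlinearity, and aggregates over each point's k edges by
#' the channel-wise maximum. Neighbourhoods are supplied explicitly (for
#' DGCNN they are recomputed in feature space at every layer).
#'
#' @param features numeric M x D matrix of point features.
#' @param neighbors integer M x k matrix of neighbour indices
#'   (see [knn_indices()]).
#' @param W numeric (2D) x D' weight matrix of the per-edge map.
#' @param slope leaky-ReLU negative slope.
#' @return numeric M x D' matrix of aggregated edge features.
#' @export
edge_conv <- function(features, neighbors, W, slope = 0.2) {
  features <- as.matrix(features)
  M <- nrow(features)
  k <- ncol(neighbors)
  if (any(neighbors < 1L) || any(neighbors > M)) {
    stop("neighbour indices out of range", call. = FALSE)
  }
  if (nrow(W) != 2L * ncol(features)) {
    stop(sprintf("W must have %d rows for %d-dim features",
                 2L * ncol(features), ncol(features)), call. = FALSE)
  }
  ctr <- rep(seq_len(M), each = k)
  nbr <- as.vector(t(neighbors))
  E <- cbind(features[nbr, , drop = FALSE] - features[ctr, , drop = FALSE],
             features[ctr, , drop = FALSE])
  H <- lrelu_fwd(E %*% W, slope)$out
  max_k_fwd(H, k)$out
}

#' Learned position encoding of relative 3D displacement
#'
#' Applies a two-layer perceptron to the relative position
#' `coords_i - coords_j`, producing a D-vector per pair. Translation of both
#' points by the same vector leaves the encoding unchanged.
#'
#' @param coords_i,coords_j numeric matrices (n x 3) or 3-vectors.
#' @param weights list with `W1` (3 x D), `b1`, `W2` (D x D), `b2`.
#' @return numeric n x D matrix of encodings.
#' @export
position_encoding <- function(coords_i, coords_j, weights) {
  if (is.null(dim(coords_i))) coords_i <- matrix(coords_i, ncol = 3)
  if (is.null(dim(coords_j))) coords_j <- matrix(coords_j, ncol = 3)
  rel <- coords_i - coords_j
  h <- relu_fwd(sweep(rel %*% weights$W1, 2, weights$b1, "+"))$out
  sweep(h %*% weights$W2, 2, weights$b2, "+")
}

#' Vector self-attention over 3D neighbourhoods
#'
#' For each point i with neighbours j (defined in 3D space), computes query,
#' key and value projections of the input features, forms the attention
#' input `q_i - k_j + delta_ij` (with `delta` the learned position encoding
#' of the relative displacement when enabled, zero otherwise), maps it
#' through a two-layer perceptron to a per-neighbour attention *vector*
#' (one weight per channel), normalises channel-wise over the k neighbours
#' by a softmax, and returns `sum_j attn_ij * (v_j + delta_ij)`.
#'
#' @param features numeric M x D matrix (D = attention width).
#' @param coords numeric M x 3 point coordinates.
#' @param neighbors integer M x k neighbour indices (3D space, self
#'   included).
#' @param weights list with `Wq`, `Wk`, `Wv` (D x D, no bias), `g1_W`,
#'   `g1_b`, `g2_W`, `g2_b` (attention MLP) and, when position encoding is
#'   enabled, `pe1_W`, `pe1_b`, `pe2_W`, `pe2_b`.
#' @param use_position_encoding include the positional term.
#' @return list with `output` (M x D) and `attention` ((M*k) x D, rows in
#'   point-major order; each point's k weights sum to 1 per channel).
#' @export
vector_self_attention <- function(features, coords, neighbors, weights,
                                  use_position_encoding = TRUE) {
  features <- as.matrix(features)
  M <- nrow(features)
  D <- ncol(features)
  k <- ncol(neighbors)
  ctr <- rep(seq_len(M), each = k)
  nbr <- as.vector(t(neighbors))
  if (use_position_encoding) {
    if (is.null(coords)) {
      stop("coords are required when position encoding is enabled",
           call. = FALSE)
    }
    pe <- position_encoding(coords[ctr, , drop = FALSE],
                            coords[nbr, , drop = FALSE],
                            list(W1 = weights$pe1_W, b1 = weights$pe1_b,
                                 W2 = weights$pe2_W, b2 = weights$pe2_b))
  } else {
    pe <- 0
  }
  q <- features %*% weights$Wq
  kk <- features %*% weights$Wk
  v <- features %*% weights$Wv
  a_in <- q[ctr, , drop = FALSE] - kk[nbr, , drop = FALSE] + pe
  g <- relu_fwd(sweep(a_in %*% weights$g1_W, 2, weights$g1_b, "+"))$out
  g <- sweep(g %*% weights$g2_W, 2, weights$g2_b, "+")
  attn <- softmax_k_fwd(g / sqrt(D), k)$out
  vn <- v[nbr, , drop = FALSE] + pe
  out <- sum_k_fwd(attn * vn, k)$out
  list(output = out, attention = attn)
}

#' Transition Down: farthest-point downsampling with local aggregation
#'
#' Selects `target_count` representative points by farthest point sampling,
#' then computes each representative's feature as the channel-wise maximum
#' of a two-layer perceptron applied to its k nearest source points
#' (features concatenated with the relative displacement to the
#' representative).
#'
#' @param coords numeric M x 3 source coordinates.
#' @param features numeric M x D source features.
#' @param target_count number of representatives (1 <= target <= M).
#' @param k neighbourhood size.
#' @param weights list with `l1_W` ((D+3) x D'), `l1_b`, `l2_W` (D' x D'),
#'   `l2_b`.
#' @param start_index farthest-point-sampling start (`NULL`: farthest
#'   from the centroid).
#' @return list with `coords` (target x 3), `features` (target x D'), and
#'   `indices` (selected source rows).
#' @export
transition_down <- function(coords, features, target_count, k, weights,
                            start_index = NULL) {
  coords <- as.matrix(coords)
  features <- as.matrix(features)
  if (target_count < 1) stop("target_count must be >= 1", call. = FALSE)
  sel <- farthest_point_sampling(coords, target_count, start_index)
  new_xyz <- coords[sel, , drop = FALSE]
  idx <- knn_query(new_xyz, coords, k)
  ke <- ncol(idx)
  ctr <- rep(seq_len(target_count), each = ke)
  nbr <- as.vector(t(idx))
  G <- cbind(coords[nbr, , drop = FALSE] - new_xyz[ctr, , drop = FALSE],
             features[nbr, , drop = FALSE])
  h <- relu_fwd(sweep(G %*% weights$l1_W, 2, weights$l1_b, "+"))$out
  h <- relu_fwd(sweep(h %*% weights$l2_W, 2, weights$l2_b, "+"))$out
  list(coords = new_xyz, features = max_k_fwd(h, ke)$out, indices = sel)
}
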