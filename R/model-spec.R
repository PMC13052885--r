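#' The 40 ModelNet40 category names
#'
#' Standard alphabetical category roster of the ModelNet40 benchmark; the
#' ten experiment categories and the car category are all members.
#' @return character vector of 40 names.
#' @export
modelnet40_categories <- function() {
  c("airplane", "bathtub", "bed", "bench", "bookshelf", "bottle", "bowl",
    "car", "chair", "cone", "cup", "curtain", "desk", "door", "dresser",
    "flower_pot", "glass_box", "guitar", "keyboard", "lamp", "laptop",
    "mantel", "monitor", "night_stand", "person", "piano", "plant", "radio",
    "range_hood", "sink", "sofa", "stairs", "stool", "table", "tent",
    "toilet", "tv_stand", "vase", "wardrobe", "xbox")
}

#' Declarative DGCNN classifier specification
#'
#' Defaults reproduce the public reference classification architecture:
#' four EdgeConv stages of widths 64/64/128/256 with k = 20 feature-space
#' neighbours, a 1024-wide embedding, concatenated global max+mean pooling,
#' and a 512/256 classifier head with batch norm and dropout. The default
#' layout has 1,809,576 trainable parameters (1.81M).
#'
#' @param edge_widths EdgeConv output widths, one per stage.
#' @param emb_dim shared embedding width after multi-scale concatenation.
#' @param head_widths the two hidden widths of the classifier head.
#' @param k neighbourhood size of the dynamic feature-space graph.
#' @param n_classes number of output categories.
#' @param classes category names (defaults to ModelNet40 when
#'   `n_classes == 40`).
#' @param dropout head dropout probability.
#' @param use_downsampling insert a Transition Down stage (ratio
#'   `ds_ratio`, `td_k` 3D neighbours) after every EdgeConv layer.
#' @param ds_ratio downsampling ratio per stage.
#' @param td_k neighbourhood size of the Transition Down aggregation.
#' @param n_points nominal training cloud size; Transition Down target
#'   counts are fixed fractions of this nominal size (clamped to the points
#'   actually available), so the depth of abstraction does not shrink when
#'   sparser clouds are evaluated.
#' @return A `model_spec`.
#' @export
dgcnn_spec <- function(edge_widths = c(64, 64, 128, 256), emb_dim = 1024,
                       head_widths = c(512, 256), k = 20, n_classes = 40,
                       classes = NULL, dropout = 0.5,
                       use_downsampling = FALSE, ds_ratio = 4, td_k = 16,
                       n_points = 1024) {
  spec <- structure(list(
    family = "dgcnn", edge_widths = as.integer(edge_widths),
    emb_dim = as.integer(emb_dim), head_widths = as.integer(head_widths),
    k = as.integer(k), n_classes = as.integer(n_classes),
    classes = .default_classes(classes, n_classes), dropout = dropout,
    use_downsampling = isTRUE(use_downsampling),
    ds_ratio = as.integer(ds_ratio), td_k = as.integer(td_k),
    n_points = as.integer(n_points)),
    class = "model_spec")
  validate_spec(spec)
}

#' Declarative Point Transformer classifier specification
#'
#' Defaults reproduce the public reference classification architecture:
#' a 3 -> 32 -> 32 input MLP, a vector self-attention block at full
#' resolution, then `n_blocks` = 4 stages each of a Transition Down (ratio 4
#' point reduction via farthest point sampling + local max aggregation over
#' `k` = 16 3D neighbours, width doubling) followed by a vector
#' self-attention block with learned position encoding (inner width
#' `d_model` = 512), global mean pooling and a 256/64 head. The default
#' layout has 9,584,040 trainable parameters (9.58M). The point counts
#' follow the fixed ratio schedule `[N, N/4, N/16, N/64, N/256]`.
#'
#' @param base_dim width of the input embedding (doubles per stage).
#' @param d_model inner width of the attention blocks.
#' @param n_blocks number of Transition Down + attention stages.
#' @param k neighbourhood size (3D space) for attention and Transition Down.
#' @param head_widths the two hidden widths of the classifier head.
#' @param n_classes,classes,use_downsampling as in [dgcnn_spec()].
#' @param n_points nominal training cloud size anchoring the absolute
#'   Transition Down target counts (clamped to the available points at run
#'   time).
#' @param use_attention learned vector self-attention (`FALSE` replaces the
#'   attention weights by a uniform mean over neighbours).
#' @param use_position_encoding learned position encoding (`FALSE` sets the
#'   positional term to zero everywhere).
#' @param ds_ratio downsampling ratio per stage.
#' @return A `model_spec`.
#' @export
point_transformer_spec <- function(base_dim = 32, d_model = 512,
                                   n_blocks = 4, k = 16,
                                   head_widths = c(256, 64), n_classes = 40,
                                   classes = NULL, use_attention = TRUE,
                                   use_position_encoding = TRUE,
                                   use_downsampling = TRUE, ds_ratio = 4,
                                   n_points = 1024) {
  spec <- structure(list(
    family = "point_transformer", base_dim = as.integer(base_dim),
    d_model = as.integer(d_model), n_blocks = as.integer(n_blocks),
    k = as.integer(k), head_widths = as.integer(head_widths),
    n_classes = as.integer(n_classes),
    classes = .default_classes(classes, n_classes),
    use_attention = isTRUE(use_attention),
    use_position_encoding = isTRUE(use_position_encoding),
    use_downsampling = isTRUE(use_downsampling),
    ds_ratio = as.integer(ds_ratio), n_points = as.integer(n_points)),
    class = "model_spec")
  validate_spec(spec)
}

.default_classes <- function(classes, n_classes) {
  if (!is.null(classes)) {
    classes <- as.character(classes)
    if (length(classes) != n_classes) {
      stop("`classes` must have length n_classes", call. = FALSE)
    }
    return(classes)
  }
  if (n_classes == 40L) modelnet40_categories()
  else sprintf("class%02d", seq_len(n_classes))
}

validate_spec <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$k < 1) stop("k must be >= 1", call. = FALSE)
  if (spec$n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  if (anyDuplicated(spec$classes)) {
    stop("duplicate class names", call. = FALSE)
  }
  if (spec$family == "dgcnn") {
    if (length(spec$edge_widths) < 1) {
      stop("at least one EdgeConv stage is required", call. = FALSE)
    }
    if (spec$use_downsampling && spec$ds_ratio < 2) {
      stop("ds_ratio must be >= 2 when downsampling", call. = FALSE)
    }
  } else {
    if (spec$n_blocks < 1) stop("n_blocks must be >= 1", call. = FALSE)
    if (spec$ds_ratio < 2) stop("ds_ratio must be >= 2", call. = FALSE)
  }
  spec
}

#' Stage feature widths of a model specification
#' @param spec a `model_spec`.
#' @return integer vector of per-stage widths.
#' @export
stage_widths <- function(spec) {
  if (spec$family == "dgcnn") spec$edge_widths
  else spec$base_dim * 2^(0:spec$n_blocks)
}

#' Per-stage point counts under the downsampling schedule
#'
#' For a Point Transformer the counts follow the fixed ratio schedule
#' `[N, N/r, N/r^2, ...]` with `floor` and a minimum of 1 for N not
#' divisible by the ratios; with downsampling disabled all counts stay N.
#' For a DGCNN with the downsampling intervention these are the counts
#' entering each EdgeConv layer.
#'
#' @param spec a `model_spec`.
#' @param n_points input point count N.
#' @return integer vector of point counts, one per stage.
#' @export
stage_counts <- function(spec, n_points = spec$n_points) {
  n_points <- as.integer(n_points)
  if (spec$family == "point_transformer") {
    if (!spec$use_downsampling) {
      return(rep(n_points, spec$n_blocks + 1L))
    }
    pmax(1L, as.integer(floor(n_points / spec$ds_ratio^(0:spec$n_blocks))))
  } else {
    L <- length(spec$edge_widths)
    if (!spec$use_downsampling) return(rep(n_points, L))
    pmax(1L, as.integer(floor(n_points / spec$ds_ratio^(0:(L - 1L)))))
  }
}

#' Remove a mechanism from a Point Transformer specification
#'
#' `attention` replaces the learned attention weights by a uniform mean over
#' the k neighbours of the value term (NoAttn); `position_encoding` sets the
#' positional term to zero everywhere (NoPE); `downsampling` keeps every
#' Transition Down stage at full resolution, so local re-embedding happens
#' without point reduction (NoDS). Everything else is unchanged.
#'
#' @param spec a `model_spec` with `family = "point_transformer"`.
#' @param component one of "attention", "position_encoding", "downsampling".
#' @return The modified `model_spec`.
#' @export
ablate <- function(spec, component = c("attention", "position_encoding",
                                       "downsampling")) {
  component <- match.arg(component)
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "point_transformer") {
    stop("family '", spec$family, "' has no ", component,
         " mechanism to ablate", call. = FALSE)
  }
  switch(component,
    attention = spec$use_attention <- FALSE,
    position_encoding = spec$use_position_encoding <- FALSE,
    downsampling = spec$use_downsampling <- FALSE)
  spec
}

#' Add Transition Down stages to a DGCNN (downsampling intervention)
#'
#' Inserts a Transition Down stage (ratio-`ds_ratio` farthest-point-sampling
#' reduction with k-nearest-neighbour max aggregation in 3D space) after
#' every EdgeConv layer; subsequent feature-space graphs are computed on the
#' reduced point set. The classification head design is unchanged.
#'
#' @param spec a `model_spec` with `family = "dgcnn"`.
#' @param ds_ratio reduction ratio per stage.
#' @param td_k Transition Down neighbourhood size.
#' @return The modified `model_spec`.
#' @export
add_downsampling_to_dgcnn <- function(spec, ds_ratio = 4, td_k = 16) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "dgcnn") {
    stop("the downsampling intervention applies to dgcnn specs",
         call. = FALSE)
  }
  spec$use_downsampling <- TRUE
  spec$ds_ratio <- as.integer(ds_ratio)
  spec$td_k <- as.integer(td_k)
  spec
}

#' Reduced-width profile for CPU-scale experiments
#'
#' Desk-scale model and training settings for small synthetic datasets:
#' the same architectures with reduced widths and depths, smaller
#' neighbourhoods and 256-point clouds, trainable in minutes on one CPU.
#' The Point Transformer keeps three Transition Down stages so that the
#' deepest stage retains at least four points at the desk cloud size
#' (single-point stages give batch-norm statistics no support). The
#' full-scale defaults of [dgcnn_spec()] / [point_transformer_spec()]
#' remain available for users with GPU-scale resources and the external
#' datasets.
#'
#' @param categories category roster for the classifier output.
#' @param epochs training epochs.
#' @param n_points points per cloud.
#' @return list with elements `dgcnn`, `point_transformer`, `train`
#'   (a `train_config`) and `n_points`.
#' @export
desk_profile <- function(categories = scramble_categories(), epochs = 20,
                         n_points = 256) {
  n_cat <- length(categories)
  list(
    dgcnn = dgcnn_spec(edge_widths = c(16, 16, 32), emb_dim = 64,
                       head_widths = c(32, 16), k = 10,
                       n_classes = n_cat, classes = categories,
                       dropout = 0.2, td_k = 8, n_points = n_points),
    point_transformer = point_transformer_spec(
      base_dim = 8, d_model = 32, n_blocks = 3, k = 8,
      head_widths = c(32, 16), n_classes = n_cat, classes = categories,
      n_points = n_points),
    train = train_config(epochs = epochs, batch_size = 8),
    n_points = as.integer(n_points))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s, k=%d, %d classes, widths: %s\n", x$family,
              x$k, x$n_classes, paste(stage_widths(x), collapse = "/")))
  flags <- c(attention = x$use_attention %||% NA,
             position_encoding = x$use_position_encoding %||% NA,
             downsampling = x$use_downsampling)
  cat("  flags:", paste(names(flags), unlist(flags), sep = "=",
                        collapse = " "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
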