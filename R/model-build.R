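# Model construction and parameter counting. A built model is a list with
# the spec, a flat named list of trainable parameters, and an environment of
# non-trainable state (batch-norm running statistics).

#' Build a classifier from a specification
#'
#' Allocates and initialises all trainable parameters for the requested
#' architecture. Initialisation is deterministic given `seed`.
#'
#' @param spec a `model_spec`.
#' @param seed RNG seed for parameter initialisation.
#' @return A `point_classifier`: list with `spec`, `params`, `state`.
#' @export
build_model <- function(spec, seed = 1L) {
  validate_spec(spec)
  st <- new.env(parent = emptyenv())
  P <- with_seed(seed, {
    if (spec$family == "dgcnn") .build_dgcnn_params(spec, st)
    else .build_pt_params(spec, st)
  })
  structure(list(spec = spec, params = P, state = st, seed = as.integer(seed)),
            class = "point_classifier")
}

.build_dgcnn_params <- function(spec, st) {
  P <- list()
  widths <- spec$edge_widths
  d_prev <- 3L
  for (l in seq_along(widths)) {
    nm <- paste0("ec", l)
    P <- init_linear(P, nm, 2L * d_prev, widths[l], bias = FALSE)
    P <- init_bn(P, st, paste0(nm, "_bn"), widths[l])
    if (spec$use_downsampling) {
      P <- .init_td(P, st, paste0("td", l), widths[l] + 3L, widths[l])
    }
    d_prev <- widths[l]
  }
  P <- init_linear(P, "emb", sum(widths), spec$emb_dim, bias = FALSE)
  P <- init_bn(P, st, "emb_bn", spec$emb_dim)
  h <- spec$head_widths
  P <- init_linear(P, "fc1", 2L * spec$emb_dim, h[1], bias = FALSE)
  P <- init_bn(P, st, "fc1_bn", h[1])
  P <- init_linear(P, "fc2", h[1], h[2], bias = TRUE)
  P <- init_bn(P, st, "fc2_bn", h[2])
  P <- init_linear(P, "out", h[2], spec$n_classes, bias = TRUE)
  P
}

.init_td <- function(P, st, nm, d_in, d_out) {
  P <- init_linear(P, paste0(nm, "_l1"), d_in, d_out, bias = TRUE)
  P <- init_bn(P, st, paste0(nm, "_bn1"), d_out)
  P <- init_linear(P, paste0(nm, "_l2"), d_out, d_out, bias = TRUE)
  P <- init_bn(P, st, paste0(nm, "_bn2"), d_out)
  P
}

.build_pt_params <- function(spec, st) {
  P <- list()
  h <- spec$base_dim
  dm <- spec$d_model
  P <- init_linear(P, "in1", 3L, h, bias = TRUE)
  P <- init_linear(P, "in2", h, h, bias = TRUE)
  dims <- h * 2^(0:spec$n_blocks)
  for (b in 0:spec$n_blocks) {
    nm <- paste0("tb", b)
    d <- dims[b + 1L]
    P <- init_linear(P, paste0(nm, "_in"), d, dm, bias = TRUE)
    P <- init_linear(P, paste0(nm, "_out"), dm, d, bias = TRUE)
    P <- init_linear(P, paste0(nm, "_v"), dm, dm, bias = FALSE)
    if (spec$use_attention) {
      P <- init_linear(P, paste0(nm, "_q"), dm, dm, bias = FALSE)
      P <- init_linear(P, paste0(nm, "_k"), dm, dm, bias = FALSE)
      P <- init_linear(P, paste0(nm, "_g1"), dm, dm, bias = TRUE)
      P <- init_linear(P, paste0(nm, "_g2"), dm, dm, bias = TRUE)
    }
    if (spec$use_position_encoding) {
      P <- init_linear(P, paste0(nm, "_pe1"), 3L, dm, bias = TRUE)
      P <- init_linear(P, paste0(nm, "_pe2"), dm, dm, bias = TRUE)
    }
    if (b >= 1L) {
      P <- .init_td(P, st, paste0("td", b), dims[b] + 3L, d)
    }
  }
  hw <- spec$head_widths
  P <- init_linear(P, "head1", dims[length(dims)], hw[1], bias = TRUE)
  P <- init_linear(P, "head2", hw[1], hw[2], bias = TRUE)
  P <- init_linear(P, "head3", hw[2], spec$n_classes, bias = TRUE)
  P
}

#' Count trainable parameters of a built classifier
#' @param model a `point_classifier`.
#' @return integer: the exact number of trainable scalars.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "point_classifier"))
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.point_classifier <- function(x, ...) {
  cat(sprintf("<point_classifier> %s, %s trainable parameters\n",
              x$spec$family, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Save / load model weights
#'
#' Single-file JSON container with a version field, the spec, and all
#' parameters and running statistics at full precision. Intended for
#' desk-scale models.
#'
#' @param model a `point_classifier`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  st <- as.list(model$state)
  obj <- list(container_version = 1L,
              spec = unclass(model$spec),
              params = lapply(model$params, function(p) {
                if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
                else list(dim = NULL, data = as.vector(p))
              }),
              state = st)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$container_version)) {
    stop(path, ": not a model container (no version field)", call. = FALSE)
  }
  spec <- obj$spec
  class(spec) <- "model_spec"
  spec$classes <- as.character(spec$classes)
  for (f in c("edge_widths", "head_widths", "k", "n_classes", "emb_dim",
              "base_dim", "d_model", "n_blocks", "ds_ratio", "td_k")) {
    if (!is.null(spec[[f]])) spec[[f]] <- as.integer(spec[[f]])
  }
  P <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim)) {
      matrix(p$data, p$dim[1], p$dim[2])
    } else {
      as.numeric(p$data)
    }
  })
  st <- new.env(parent = emptyenv())
  for (nm in names(obj$state)) assign(nm, as.numeric(obj$state[[nm]]), st)
  structure(list(spec = validate_spec(spec), params = P, state = st,
                 seed = NA_integer_), class = "point_classifier")
}
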