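# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded operations do not perturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a base seed and integer offsets
#'
#' Mixes the inputs through a fixed linear-congruential step so that distinct
#' offsets give distinct, reproducible seeds, all below 2^31.
#' @noRd
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), vapply(list(...), as.numeric, numeric(1)))
  m <- 2147483629 # prime < 2^31
  s <- 0
  for (p in parts) s <- (s * 48271 + (p %% m) + 11) %% m
  as.integer(s + 1)
}

stop_if_not_matrix3 <- function(x, what = "coords") {
  if (!is.matrix(x) || !is.numeric(x) || ncol(x) != 3L || nrow(x) < 1L) {
    stop(sprintf("`%s` must be a numeric matrix with 3 columns and >= 1 row", what),
         call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", what), call. = FALSE)
  }
  invisible(x)
}

row_norms <- function(x) sqrt(rowSums(x * x))

#' Pairwise squared Euclidean distances between rows of a and rows of b
#' @noRd
sqdist_rows <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d[d < 0] <- 0
  d
}
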