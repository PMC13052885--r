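# Minimal neural-network primitives with hand-coded forward and backward
# passes (no autodiff is available in this stack, and the layer algebra is
# part of the contribution). Conventions: feature matrices are row-major
# (one row per point / edge); parameters live in a flat named list;
# gradients accumulate into an environment keyed by parameter name;
# batch-norm running statistics live in an environment on the model.

# --- parameter initialisation (uniform Kaiming-style, torch Linear default)
init_linear <- function(P, name, d_in, d_out, bias = TRUE) {
  bound <- 1 / sqrt(d_in)
  P[[paste0(name, "_W")]] <- matrix(stats::runif(d_in * d_out, -bound, bound),
                                    d_in, d_out)
  if (bias) {
    P[[paste0(name, "_b")]] <- stats::runif(d_out, -bound, bound)
  }
  P
}

init_bn <- function(P, st, name, d) {
  P[[paste0(name, "_g")]] <- rep(1, d)
  P[[paste0(name, "_be")]] <- rep(0, d)
  assign(paste0(name, "_rm"), rep(0, d), envir = st)
  assign(paste0(name, "_rv"), rep(1, d), envir = st)
  P
}

add_grad <- function(gacc, name, val) {
  if (is.null(gacc[[name]])) gacc[[name]] <- val else
    gacc[[name]] <- gacc[[name]] + val
  invisible(NULL)
}

# column-broadcast helpers (compiled single-pass kernels)
.addv <- function(X, v) .add_col_cpp(X, v)
.mulv <- function(X, v) .mul_col_cpp(X, v)

# --- linear
lin_fwd <- function(X, P, name) {
  W <- P[[paste0(name, "_W")]]
  if (ncol(X) != nrow(W)) {
    stop(sprintf("layer %s: input width %d does not match parameters (%d)",
                 name, ncol(X), nrow(W)), call. = FALSE)
  }
  out <- X %*% W
  b <- P[[paste0(name, "_b")]]
  if (!is.null(b)) out <- .addv(out, b)
  list(out = out, X = X, name = name)
}

lin_bwd <- function(cache, dY, P, gacc) {
  nm <- cache$name
  add_grad(gacc, paste0(nm, "_W"), crossprod(cache$X, dY))
  if (!is.null(P[[paste0(nm, "_b")]])) add_grad(gacc, paste0(nm, "_b"),
                                                colSums(dY))
  dY %*% t(P[[paste0(nm, "_W")]])
}

# --- batch norm over rows (per-column statistics): minibatch statistics
# during training (whole lockstep batch), running averages in evaluation
bn_fwd <- function(X, P, st, name, training, momentum = 0.1, eps = 1e-5) {
  g <- P[[paste0(name, "_g")]]
  be <- P[[paste0(name, "_be")]]
  batch_ok <- training && nrow(X) > 1L
  if (batch_ok) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    assign(paste0(name, "_rm"),
           (1 - momentum) * get(paste0(name, "_rm"), envir = st) +
             momentum * mu, envir = st)
    assign(paste0(name, "_rv"),
           (1 - momentum) * get(paste0(name, "_rv"), envir = st) +
             momentum * v, envir = st)
  } else {
    mu <- get(paste0(name, "_rm"), envir = st)
    v <- get(paste0(name, "_rv"), envir = st)
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- .scale_shift_cpp(X, mu, inv_sd)
  out <- .muladd_col_cpp(xhat, g, be)
  list(out = out, xhat = xhat, inv_sd = inv_sd, name = name,
       batch_stats = batch_ok)
}

bn_bwd <- function(cache, dY, P, gacc) {
  nm <- cache$name
  xhat <- cache$xhat
  add_grad(gacc, paste0(nm, "_g"), colSums(dY * xhat))
  add_grad(gacc, paste0(nm, "_be"), colSums(dY))
  dxhat <- .mulv(dY, P[[paste0(nm, "_g")]])
  if (!cache$batch_stats) {
    return(.mulv(dxhat, cache$inv_sd))
  }
  m <- nrow(xhat)
  s1 <- colSums(dxhat) / m
  s2 <- colSums(dxhat * xhat) / m
  dx <- .addv(dxhat, -s1) - .mulv(xhat, s2)
  .mulv(dx, cache$inv_sd)
}

# --- activations (slope masks kept for the backward pass)
lrelu_fwd <- function(X, slope = 0.2) {
  w <- slope + (1 - slope) * (X > 0)
  list(out = X * w, w = w)
}

lrelu_bwd <- function(cache, dY) {
  dY * cache$w
}

relu_fwd <- function(X) {
  pos <- X > 0
  list(out = X * pos, pos = pos)
}

relu_bwd <- function(cache, dY) {
  dY * cache$pos
}

# --- inverted dropout (train only)
dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, mask = NULL))
  mask <- matrix(stats::runif(length(X)) >= p, nrow(X), ncol(X)) / (1 - p)
  list(out = X * mask, mask = mask)
}

dropout_bwd <- function(cache, dY) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

# --- neighbour-axis helpers -------------------------------------------------
# Edge/neighbour tensors are stored as (M*k) x D matrices in point-major
# order (the k entries of point i occupy rows (i-1)*k + 1 .. i*k). The
# reshape to a k x (M*D) matrix used for per-neighbour reductions is a plain
# dim change (both layouts share the same column-major vector).
as_kmat <- function(X, k) matrix(as.vector(X), nrow = k)

# channel-wise softmax over the neighbour axis of a (M*k) x D tensor
softmax_k_fwd <- function(X, k) {
  D <- ncol(X); Mk <- nrow(X)
  Xm <- as_kmat(X, k)
  mx <- Xm[1, ]
  if (k > 1) for (j in 2:k) mx <- pmax(mx, Xm[j, ])
  Z <- exp(.addv(Xm, -mx))
  Pm <- .mulv(Z, 1 / colSums(Z))
  list(out = matrix(as.vector(Pm), Mk, D), Pm = Pm, k = k, D = D, Mk = Mk)
}

softmax_k_bwd <- function(cache, dY) {
  dYm <- as_kmat(dY, cache$k)
  ssum <- colSums(dYm * cache$Pm)
  dXm <- cache$Pm * .addv(dYm, -ssum)
  matrix(as.vector(dXm), cache$Mk, cache$D)
}

# max over the neighbour axis: (M*k) x D -> M x D, with argmax cache
max_k_fwd <- function(X, k) {
  D <- ncol(X); M <- nrow(X) / k
  Xm <- as_kmat(X, k) # k x (M*D)
  mx <- Xm[1, ]
  am <- rep(1L, ncol(Xm))
  if (k > 1) {
    for (j in 2:k) {
      better <- Xm[j, ] > mx # strict: first maximum wins ties
      if (any(better)) {
        am[better] <- j
        mx[better] <- Xm[j, better]
      }
    }
  }
  list(out = matrix(mx, M, D), am = am, k = k, M = M, D = D)
}

max_k_bwd <- function(cache, dY) {
  dXm <- matrix(0, cache$k, cache$M * cache$D)
  dXm[cbind(cache$am, seq_len(ncol(dXm)))] <- as.vector(dY)
  matrix(as.vector(dXm), cache$M * cache$k, cache$D)
}

# sum over the neighbour axis: (M*k) x D -> M x D
sum_k_fwd <- function(X, k) {
  D <- ncol(X); M <- nrow(X) / k
  Xm <- as_kmat(X, k)
  out <- matrix(colSums(Xm), M, D)
  list(out = out, k = k)
}

sum_k_bwd <- function(cache, dY) {
  dY[rep(seq_len(nrow(dY)), each = cache$k), , drop = FALSE]
}

# scatter-add rows of dX (grouped by idx) into an M x D matrix
scatter_rows <- function(dX, idx, M) {
  agg <- rowsum(dX, group = idx)
  out <- matrix(0, M, ncol(dX))
  out[as.integer(rownames(agg)), ] <- agg
  out
}

# cross-entropy over logits rows; returns loss and dlogits (mean over rows)
softmax_xent <- function(logits, targets) {
  logits <- as.matrix(logits)
  B <- nrow(logits)
  mx <- apply(logits, 1, max)
  Z <- exp(logits - mx)
  P <- Z / rowSums(Z)
  eps <- 1e-12
  loss <- -mean(log(P[cbind(seq_len(B), targets)] + eps))
  dY <- P
  dY[cbind(seq_len(B), targets)] <- dY[cbind(seq_len(B), targets)] - 1
  list(loss = loss, dlogits = dY / B, probs = P)
}
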