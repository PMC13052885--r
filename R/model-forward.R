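# Trainable network stages: the same layer math as model-ops.R, with batch
# normalisation where the reference architectures have it, full caches, and
# hand-coded backward passes.
#
# Minibatches are processed in lockstep: the B clouds of a batch are
# concatenated row-wise and share every linear/batch-norm/activation, while
# graph operations (kNN, farthest point sampling, gathers) stay
# block-diagonal per cloud. Batch norm therefore normalises over the whole
# minibatch during training (running statistics serve evaluation), as in
# the reference implementations. Feature matrices are row-per-point;
# edge/neighbour tensors are (rows*k) x D in point-major order.

# offsets of each cloud's row block from the per-cloud sizes
.offsets <- function(sizes) cumsum(c(0L, sizes[-length(sizes)]))

# per-cloud kNN graphs combined into global row indices; the effective k is
# capped at the smallest cloud's candidate count so neighbour tensors stay
# rectangular
.batch_knn <- function(X, sizes, k, include_self) {
  offs <- .offsets(sizes)
  ke <- if (include_self) min(k, min(sizes)) else min(k, min(sizes) - 1L)
  ke <- max(ke, 1L)
  idx <- matrix(0L, sum(sizes), ke)
  for (b in seq_along(sizes)) {
    rows <- offs[b] + seq_len(sizes[b])
    if (sizes[b] == 1L) {
      idx[rows, ] <- rows
    } else {
      ib <- knn_indices(X[rows, , drop = FALSE], ke, include_self)
      idx[rows, ] <- ib[, seq_len(ke), drop = FALSE] + offs[b]
    }
  }
  idx
}

# ---- EdgeConv stage (feature-space knn, linear-BN-LeakyReLU, max) ---------
.ec_fwd <- function(P, st, nm, feats, sizes, k, training) {
  M <- nrow(feats)
  idx <- .batch_knn(feats, sizes, k, include_self = FALSE)
  ke <- ncol(idx)
  ctr <- rep(seq_len(M), each = ke)
  nbr <- as.vector(t(idx))
  E <- cbind(feats[nbr, , drop = FALSE] - feats[ctr, , drop = FALSE],
             feats[ctr, , drop = FALSE])
  c1 <- lin_fwd(E, P, nm)
  b1 <- bn_fwd(c1$out, P, st, paste0(nm, "_bn"), training)
  a1 <- lrelu_fwd(b1$out, 0.2)
  mx <- max_k_fwd(a1$out, ke)
  list(out = mx$out,
       cache = list(k = ke, ctr = ctr, nbr = nbr, M = M, D = ncol(feats),
                    c1 = c1, b1 = b1, a1 = a1, mx = mx))
}

.ec_bwd <- function(cache, dOut, P, gacc) {
  d <- max_k_bwd(cache$mx, dOut)
  d <- lrelu_bwd(cache$a1, d)
  d <- bn_bwd(cache$b1, d, P, gacc)
  dE <- lin_bwd(cache$c1, d, P, gacc)
  Dp <- cache$D
  dDiff <- dE[, seq_len(Dp), drop = FALSE]
  dCtr <- dE[, Dp + seq_len(Dp), drop = FALSE]
  dF <- rowsum(dCtr - dDiff, cache$ctr) # every centre occurs: rows 1..M
  dF + scatter_rows(dDiff, cache$nbr, cache$M)
}

# ---- shared Transition Down stage (linear-BN-ReLU twice, max over k) ------
# Reduces cloud b from sizes[b] to targets[b] points (identity order when no
# reduction happens). `sel` returns global row indices for chain
# bookkeeping.
.td_fwd <- function(P, st, nm, xyz, feats, sizes, targets, k, training,
                    idx = NULL) {
  offs <- .offsets(sizes)
  ke <- max(1L, min(k, min(sizes)))
  if (!is.null(idx) && identical(targets, sizes) && ncol(idx) >= ke) {
    # no reduction: a precomputed self-kNN graph is exactly what is needed
    sel <- seq_len(sum(sizes))
    idx <- idx[, seq_len(ke), drop = FALSE]
  } else {
    sel <- integer(0)
    idx_rows <- vector("list", length(sizes))
    for (b in seq_along(sizes)) {
      rows <- offs[b] + seq_len(sizes[b])
      xb <- xyz[rows, , drop = FALSE]
      sb <- if (targets[b] == sizes[b]) seq_len(sizes[b]) else
        farthest_point_sampling(xb, targets[b])
      ib <- knn_query(xb[sb, , drop = FALSE], xb, ke)
      idx_rows[[b]] <- ib[, seq_len(ke), drop = FALSE] + offs[b]
      sel <- c(sel, sb + offs[b])
    }
    idx <- do.call(rbind, idx_rows)
  }
  Mt <- length(sel)
  new_xyz <- xyz[sel, , drop = FALSE]
  ctr <- rep(seq_len(Mt), each = ke)
  nbr <- as.vector(t(idx))
  G <- cbind(xyz[nbr, , drop = FALSE] - new_xyz[ctr, , drop = FALSE],
             feats[nbr, , drop = FALSE])
  c1 <- lin_fwd(G, P, paste0(nm, "_l1"))
  b1 <- bn_fwd(c1$out, P, st, paste0(nm, "_bn1"), training)
  r1 <- relu_fwd(b1$out)
  c2 <- lin_fwd(r1$out, P, paste0(nm, "_l2"))
  b2 <- bn_fwd(c2$out, P, st, paste0(nm, "_bn2"), training)
  r2 <- relu_fwd(b2$out)
  mx <- max_k_fwd(r2$out, ke)
  list(xyz = new_xyz, out = mx$out, sel = sel, sizes = targets,
       cache = list(k = ke, nbr = nbr, M_src = nrow(feats),
                    D_src = ncol(feats), c1 = c1, b1 = b1, r1 = r1,
                    c2 = c2, b2 = b2, r2 = r2, mx = mx))
}

.td_bwd <- function(cache, dOut, P, gacc) {
  d <- max_k_bwd(cache$mx, dOut)
  d <- relu_bwd(cache$r2, d)
  d <- bn_bwd(cache$b2, d, P, gacc)
  d <- lin_bwd(cache$c2, d, P, gacc)
  d <- relu_bwd(cache$r1, d)
  d <- bn_bwd(cache$b1, d, P, gacc)
  d <- lin_bwd(cache$c1, d, P, gacc)
  scatter_rows(d[, 4:(3 + cache$D_src), drop = FALSE], cache$nbr,
               cache$M_src)
}

# ---- DGCNN backbone (per minibatch) ---------------------------------------
.dgcnn_backbone_fwd <- function(model, coords_list, training) {
  spec <- model$spec; P <- model$params; st <- model$state
  L <- length(spec$edge_widths)
  sizes <- vapply(coords_list, nrow, integer(1))
  feats <- do.call(rbind, coords_list)
  xyz <- feats
  stage_feat <- ec_caches <- td_caches <- sels <- vector("list", L)
  for (l in seq_len(L)) {
    ec <- .ec_fwd(P, st, paste0("ec", l), feats, sizes, spec$k, training)
    ec_caches[[l]] <- ec$cache
    if (spec$use_downsampling) {
      # absolute target anchored at the nominal cloud size, clamped to the
      # points actually present (abstraction depth is density-invariant)
      nominal <- max(1L, spec$n_points %/% spec$ds_ratio^l)
      targets <- pmin(sizes, nominal)
      td <- .td_fwd(P, st, paste0("td", l), xyz, ec$out, sizes, targets,
                    spec$td_k, training)
      td_caches[[l]] <- td$cache
      sels[[l]] <- td$sel
      feats <- td$out
      xyz <- td$xyz
      sizes <- td$sizes
    } else {
      sels[[l]] <- seq_len(nrow(ec$out))
      feats <- ec$out
    }
    stage_feat[[l]] <- feats
  }
  # survivor chains: rows of each stage output still present in the final set
  Mf <- nrow(feats)
  tchain <- vector("list", L)
  tchain[[L]] <- seq_len(Mf)
  if (L > 1) {
    for (l in (L - 1):1) tchain[[l]] <- sels[[l + 1]][tchain[[l + 1]]]
  }
  C <- do.call(cbind, lapply(seq_len(L), function(l)
    stage_feat[[l]][tchain[[l]], , drop = FALSE]))
  e1 <- lin_fwd(C, P, "emb")
  eb <- bn_fwd(e1$out, P, st, "emb_bn", training)
  ea <- lrelu_fwd(eb$out, 0.2)
  H <- ea$out
  # per-cloud global max + mean pooling
  B <- length(coords_list)
  emb <- ncol(H)
  offs <- .offsets(sizes)
  Pool <- matrix(0, B, 2L * emb)
  ams <- vector("list", B)
  for (b in seq_len(B)) {
    Hb <- H[offs[b] + seq_len(sizes[b]), , drop = FALSE]
    am <- max.col(t(Hb), ties.method = "first")
    ams[[b]] <- am
    Pool[b, ] <- c(Hb[cbind(am, seq_len(emb))], colMeans(Hb))
  }
  list(pooled = Pool,
       cache = list(L = L, Mf = Mf, ams = ams, emb = emb, sizes = sizes,
                    offs = offs, widths = spec$edge_widths, tchain = tchain,
                    ec = ec_caches, td = td_caches, e1 = e1, eb = eb,
                    ea = ea, use_ds = spec$use_downsampling,
                    stage_rows = vapply(stage_feat, nrow, integer(1))))
}

.dgcnn_backbone_bwd <- function(cache, dPool, P, gacc) {
  emb <- cache$emb
  Mf <- cache$Mf
  dH <- matrix(0, Mf, emb)
  for (b in seq_along(cache$sizes)) {
    rows <- cache$offs[b] + seq_len(cache$sizes[b])
    dHb <- matrix(0, cache$sizes[b], emb)
    dHb[cbind(cache$ams[[b]], seq_len(emb))] <- dPool[b, seq_len(emb)]
    dHb <- dHb + matrix(dPool[b, emb + seq_len(emb)] / cache$sizes[b],
                        cache$sizes[b], emb, byrow = TRUE)
    dH[rows, ] <- dHb
  }
  d <- lrelu_bwd(cache$ea, dH)
  d <- bn_bwd(cache$eb, d, P, gacc)
  dC <- lin_bwd(cache$e1, d, P, gacc)
  offs <- c(0L, cumsum(cache$widths))
  d_next <- NULL # grad wrt stage_feat[[l]] arriving from stage l+1
  for (l in seq(cache$L, 1L)) {
    dS <- matrix(0, cache$stage_rows[l], cache$widths[l])
    dS[cache$tchain[[l]], ] <- dC[, (offs[l] + 1):offs[l + 1], drop = FALSE]
    if (!is.null(d_next)) dS <- dS + d_next
    dFl <- if (cache$use_ds) .td_bwd(cache$td[[l]], dS, P, gacc) else dS
    d_next <- .ec_bwd(cache$ec[[l]], dFl, P, gacc)
  }
  invisible(NULL) # gradient wrt input coordinates is not needed
}

# ---- DGCNN classifier head (per minibatch of pooled vectors) --------------
.dgcnn_head_fwd <- function(model, Pool, training) {
  P <- model$params; st <- model$state; spec <- model$spec
  f1 <- lin_fwd(Pool, P, "fc1")
  b1 <- bn_fwd(f1$out, P, st, "fc1_bn", training)
  a1 <- lrelu_fwd(b1$out, 0.2)
  d1 <- dropout_fwd(a1$out, spec$dropout, training)
  f2 <- lin_fwd(d1$out, P, "fc2")
  b2 <- bn_fwd(f2$out, P, st, "fc2_bn", training)
  a2 <- lrelu_fwd(b2$out, 0.2)
  d2 <- dropout_fwd(a2$out, spec$dropout, training)
  o <- lin_fwd(d2$out, P, "out")
  list(logits = o$out,
       cache = list(f1 = f1, b1 = b1, a1 = a1, d1 = d1, f2 = f2, b2 = b2,
                    a2 = a2, d2 = d2, o = o))
}

.dgcnn_head_bwd <- function(cache, dlogits, P, gacc) {
  d <- lin_bwd(cache$o, dlogits, P, gacc)
  d <- dropout_bwd(cache$d2, d)
  d <- lrelu_bwd(cache$a2, d)
  d <- bn_bwd(cache$b2, d, P, gacc)
  d <- lin_bwd(cache$f2, d, P, gacc)
  d <- dropout_bwd(cache$d1, d)
  d <- lrelu_bwd(cache$a1, d)
  d <- bn_bwd(cache$b1, d, P, gacc)
  lin_bwd(cache$f1, d, P, gacc) # gradient wrt pooled vectors
}

# ---- Point Transformer block ----------------------------------------------
.tb_fwd <- function(P, nm, xyz, Fin, sizes, spec, training, idx = NULL) {
  M <- nrow(Fin)
  dm <- spec$d_model
  if (is.null(idx)) {
    idx <- .batch_knn(xyz, sizes, spec$k, include_self = TRUE)
  }
  ke <- ncol(idx)
  ctr <- rep(seq_len(M), each = ke)
  nbr <- as.vector(t(idx))
  cin <- lin_fwd(Fin, P, paste0(nm, "_in"))
  X1 <- cin$out
  cv <- lin_fwd(X1, P, paste0(nm, "_v"))
  use_pe <- spec$use_position_encoding
  use_attn <- spec$use_attention
  pe_cache <- NULL
  if (use_pe) {
    rel <- xyz[ctr, , drop = FALSE] - xyz[nbr, , drop = FALSE]
    p1 <- lin_fwd(rel, P, paste0(nm, "_pe1"))
    pr <- relu_fwd(p1$out)
    p2 <- lin_fwd(pr$out, P, paste0(nm, "_pe2"))
    PE <- p2$out
    pe_cache <- list(p1 = p1, pr = pr, p2 = p2)
  } else {
    PE <- 0
  }
  vn <- cv$out[nbr, , drop = FALSE] + PE
  attn_cache <- NULL
  if (use_attn) {
    cq <- lin_fwd(X1, P, paste0(nm, "_q"))
    ck <- lin_fwd(X1, P, paste0(nm, "_k"))
    Ain <- cq$out[ctr, , drop = FALSE] - ck$out[nbr, , drop = FALSE] + PE
    g1 <- lin_fwd(Ain, P, paste0(nm, "_g1"))
    gr <- relu_fwd(g1$out)
    g2 <- lin_fwd(gr$out, P, paste0(nm, "_g2"))
    sm <- softmax_k_fwd(g2$out / sqrt(dm), ke)
    attn <- sm$out
    attn_cache <- list(cq = cq, ck = ck, g1 = g1, gr = gr, g2 = g2, sm = sm)
  } else {
    attn <- 1 / ke
  }
  res <- sum_k_fwd(attn * vn, ke)$out
  cout <- lin_fwd(res, P, paste0(nm, "_out"))
  out <- cout$out + Fin
  list(out = out,
       cache = list(nm = nm, M = M, k = ke, dm = dm, ctr = ctr, nbr = nbr,
                    cin = cin, cv = cv, vn = vn, attn = attn,
                    pe = pe_cache, at = attn_cache, cout = cout,
                    use_pe = use_pe, use_attn = use_attn))
}

.tb_bwd <- function(cache, dOut, P, gacc) {
  M <- cache$M; ke <- cache$k
  dFin <- dOut # residual branch
  dres <- lin_bwd(cache$cout, dOut, P, gacc)
  dres_e <- dres[cache$ctr, , drop = FALSE] # expand sum over k
  dPE <- NULL
  if (cache$use_attn) {
    dattn <- dres_e * cache$vn
    dvn <- dres_e * cache$attn
    at <- cache$at
    dg2 <- softmax_k_bwd(at$sm, dattn) / sqrt(cache$dm)
    d <- lin_bwd(at$g2, dg2, P, gacc)
    d <- relu_bwd(at$gr, d)
    dAin <- lin_bwd(at$g1, d, P, gacc)
    dq_full <- rowsum(dAin, cache$ctr)
    dk_full <- -scatter_rows(dAin, cache$nbr, M)
    dX1 <- lin_bwd(at$cq, dq_full, P, gacc) +
      lin_bwd(at$ck, dk_full, P, gacc)
    if (cache$use_pe) dPE <- dAin
  } else {
    dvn <- dres_e / ke
    dX1 <- 0
  }
  dv_full <- scatter_rows(dvn, cache$nbr, M)
  dX1 <- dX1 + lin_bwd(cache$cv, dv_full, P, gacc)
  if (cache$use_pe) {
    dPE <- if (is.null(dPE)) dvn else dPE + dvn
    d <- lin_bwd(cache$pe$p2, dPE, P, gacc)
    d <- relu_bwd(cache$pe$pr, d)
    lin_bwd(cache$pe$p1, d, P, gacc) # gradient wrt rel positions unused
  }
  dFin + lin_bwd(cache$cin, dX1, P, gacc)
}

# ---- Point Transformer full network ---------------------------------------
.pt_fwd <- function(model, coords_list, training) {
  spec <- model$spec; P <- model$params; st <- model$state
  sizes <- vapply(coords_list, nrow, integer(1))
  B <- length(coords_list)
  xyz <- do.call(rbind, coords_list)
  i1 <- lin_fwd(xyz, P, "in1")
  ir <- relu_fwd(i1$out)
  i2 <- lin_fwd(ir$out, P, "in2")
  idx <- .batch_knn(xyz, sizes, spec$k, include_self = TRUE)
  tb0 <- .tb_fwd(P, "tb0", xyz, i2$out, sizes, spec, training, idx = idx)
  Fc <- tb0$out
  td_caches <- tb_caches <- vector("list", spec$n_blocks)
  for (b in seq_len(spec$n_blocks)) {
    targets <- if (spec$use_downsampling) {
      # absolute target from the nominal cloud size, clamped to availability
      pmin(sizes, max(1L, spec$n_points %/% spec$ds_ratio^b))
    } else {
      sizes
    }
    td <- .td_fwd(P, st, paste0("td", b), xyz, Fc, sizes, targets, spec$k,
                  training, idx = idx)
    if (!identical(td$sizes, sizes)) {
      xyz <- td$xyz
      sizes <- td$sizes
      idx <- .batch_knn(xyz, sizes, spec$k, include_self = TRUE)
    }
    Fc <- td$out
    td_caches[[b]] <- td$cache
    tb <- .tb_fwd(P, paste0("tb", b), xyz, Fc, sizes, spec, training,
                  idx = idx)
    Fc <- tb$out
    tb_caches[[b]] <- tb$cache
  }
  # per-cloud mean pooling + shared head
  offs <- .offsets(sizes)
  Df <- ncol(Fc)
  pooled <- matrix(0, B, Df)
  for (b in seq_len(B)) {
    pooled[b, ] <- colMeans(Fc[offs[b] + seq_len(sizes[b]), , drop = FALSE])
  }
  h1 <- lin_fwd(pooled, P, "head1")
  r1 <- relu_fwd(h1$out)
  h2 <- lin_fwd(r1$out, P, "head2")
  r2 <- relu_fwd(h2$out)
  h3 <- lin_fwd(r2$out, P, "head3")
  list(logits = h3$out,
       cache = list(i1 = i1, ir = ir, i2 = i2, tb0 = tb0$cache,
                    td = td_caches, tb = tb_caches, sizes = sizes,
                    offs = offs, Df = Df, h1 = h1, r1 = r1, h2 = h2,
                    r2 = r2, h3 = h3, n_blocks = spec$n_blocks))
}

.pt_bwd <- function(cache, dlogits, P, gacc) {
  d <- lin_bwd(cache$h3, dlogits, P, gacc)
  d <- relu_bwd(cache$r2, d)
  d <- lin_bwd(cache$h2, d, P, gacc)
  d <- relu_bwd(cache$r1, d)
  dpooled <- lin_bwd(cache$h1, d, P, gacc)
  dF <- matrix(0, sum(cache$sizes), cache$Df)
  for (b in seq_along(cache$sizes)) {
    rows <- cache$offs[b] + seq_len(cache$sizes[b])
    dF[rows, ] <- matrix(dpooled[b, ] / cache$sizes[b], cache$sizes[b],
                         cache$Df, byrow = TRUE)
  }
  for (b in seq(cache$n_blocks, 1L)) {
    dF <- .tb_bwd(cache$tb[[b]], dF, P, gacc)
    dF <- .td_bwd(cache$td[[b]], dF, P, gacc)
  }
  dF <- .tb_bwd(cache$tb0, dF, P, gacc)
  d <- lin_bwd(cache$i2, dF, P, gacc)
  d <- relu_bwd(cache$ir, d)
  lin_bwd(cache$i1, d, P, gacc)
  invisible(NULL)
}

#' Class logits for a point cloud
#'
#' Runs the classifier forward in evaluation mode (batch-norm running
#' statistics, no dropout).
#'
#' @param model a `point_classifier`.
#' @param pc a `point_cloud` (or bare N x 3 coordinate matrix).
#' @return named numeric vector of logits, one per class.
#' @export
predict_logits <- function(model, pc) {
  stopifnot(inherits(model, "point_classifier"))
  coords <- if (inherits(pc, "point_cloud")) pc$coords else as.matrix(pc)
  stop_if_not_matrix3(coords)
  logits <- if (model$spec$family == "dgcnn") {
    bb <- .dgcnn_backbone_fwd(model, list(coords), training = FALSE)
    hd <- .dgcnn_head_fwd(model, bb$pooled, training = FALSE)
    as.vector(hd$logits)
  } else {
    as.vector(.pt_fwd(model, list(coords), training = FALSE)$logits)
  }
  names(logits) <- model$spec$classes
  logits
}
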