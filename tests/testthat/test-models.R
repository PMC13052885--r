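test_that("knn_indices matches a brute-force all-pairs oracle", {
  # printed example: collinear points at 0, 1, 3, k = 1, self excluded
  x <- cbind(c(0, 1, 3), 0, 0)
  expect_equal(knn_indices(x, 1, include_self = FALSE)[, 1], c(2L, 1L, 2L))
  # k = M with self included: every row's neighbour set is all rows
  idx <- knn_indices(x, 3, include_self = TRUE)
  for (i in 1:3) expect_setequal(idx[i, ], 1:3)
  # random instances
  set.seed(5)
  for (s in 1:60) {
    m <- sample(5:60, 1)
    k <- sample(seq_len(m - 1), 1)
    inc <- sample(c(TRUE, FALSE), 1)
    x <- matrix(rnorm(m * 3), m, 3)
    expect_identical(knn_indices(x, k, inc), oracle_knn(x, k, inc))
  }
  # fewer candidates than k: nearest available are recycled
  x2 <- matrix(rnorm(9), 3, 3)
  idx2 <- knn_indices(x2, 5, include_self = FALSE)
  expect_equal(ncol(idx2), 5L)
  expect_identical(idx2[, 1:2], idx2[, 3:4])
  expect_error(knn_indices(x2, 0), "k")
})

test_that("feature-space graphs differ from coordinate graphs when features reorder distances", {
  coords <- cbind(c(0, 1, 3), 0, 0)
  feats <- cbind(c(0, 5, 1), 0, 0) # feature distance ranks permuted
  g_coord <- knn_indices(coords, 1, include_self = FALSE)
  g_feat <- knn_indices(feats, 1, include_self = FALSE)
  expect_identical(g_feat, oracle_knn(feats, 1, FALSE))
  expect_false(identical(g_coord, g_feat))
})

test_that("farthest point sampling matches the greedy max-min oracle", {
  x <- cbind(c(0, 1, 2, 10), 0, 0)
  expect_equal(farthest_point_sampling(x, 2, start_index = 1), c(1L, 4L))
  expect_equal(farthest_point_sampling(x, 4, start_index = 1),
               oracle_fps(x, 4, 1))
  expect_equal(farthest_point_sampling(x, 1, start_index = 3), 3L)
  set.seed(11)
  for (s in 1:40) {
    m <- sample(4:100, 1)
    mm <- sample(seq_len(m), 1)
    st <- sample(seq_len(m), 1)
    x <- matrix(rnorm(m * 3), m, 3)
    expect_equal(farthest_point_sampling(x, mm, st), oracle_fps(x, mm, st))
  }
  expect_error(farthest_point_sampling(x, nrow(x) + 1), "m")
})

test_that("edge_conv obeys its symmetry and oracle contracts", {
  set.seed(2)
  W <- matrix(rnorm(6 * 4), 6, 4)
  # identical points: all edge differences zero, identical output rows
  f_same <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)
  nb <- knn_indices(f_same + matrix(rnorm(15, sd = 1e-9), 5, 3), 2,
                    include_self = FALSE)
  out_same <- edge_conv(f_same, nb, W)
  expect_lt(max(abs(sweep(out_same, 2, out_same[1, ], "-"))), 1e-9)
  # permutation equivariance with consistently recomputed neighbours
  f <- matrix(rnorm(8 * 3), 8, 3)
  nb1 <- knn_indices(f, 3, include_self = FALSE)
  o1 <- edge_conv(f, nb1, W)
  perm <- sample(8)
  fp <- f[perm, ]
  nb2 <- knn_indices(fp, 3, include_self = FALSE)
  o2 <- edge_conv(fp, nb2, W)
  expect_equal(o2, o1[perm, ], tolerance = 1e-12)
  # single point with self neighbour: leaky-relu of (0, x) %*% W
  x1 <- matrix(c(0.3, -0.7, 0.2), 1, 3)
  o3 <- edge_conv(x1, matrix(1L, 1, 1), W)
  manual <- cbind(matrix(0, 1, 3), x1) %*% W
  manual <- ifelse(manual > 0, manual, 0.2 * manual)
  expect_equal(o3, manual, tolerance = 1e-12)
  expect_error(edge_conv(f, nb1, matrix(0, 5, 4)), "rows")
})

test_that("invalid specifications and inputs fail at build/op time", {
  expect_error(dgcnn_spec(k = 0), "k must")
  expect_error(point_transformer_spec(n_blocks = 0), "n_blocks")
  expect_error(dgcnn_spec(n_classes = 1), "n_classes")
  expect_error(point_transformer_spec(classes = c("a", "a"),
                                      n_classes = 2), "duplicate")
  w <- .rand_attn_weights(3, seed = 2)
  feats <- matrix(rnorm(12), 4, 3)
  nb <- matrix(rep(1:4, 2), 4, 2)
  expect_error(vector_self_attention(feats, NULL, nb, w,
                                     use_position_encoding = TRUE),
               "coords")
})

test_that("vector self-attention weights normalise and match a direct-summation oracle", {
  D <- 2; M <- 4; k <- 2
  w <- .rand_attn_weights(D, seed = 7)
  set.seed(8)
  feats <- matrix(rnorm(M * D), M, D)
  coords <- matrix(rnorm(M * 3), M, 3)
  nb <- knn_indices(coords, k, include_self = TRUE)
  res <- vector_self_attention(feats, coords, nb, w)
  # attention weights sum to 1 over the neighbour axis per point and channel
  aw <- array(as.vector(t(res$attention)), c(D, k, M)) # channel fastest
  sums <- apply(aw, c(1, 3), sum)
  expect_equal(as.vector(sums), rep(1, D * M), tolerance = 1e-12)
  # independent direct-summation oracle, one point at a time
  relu0 <- function(z) pmax(z, 0)
  pe_fn <- function(ci, cj) {
    as.vector(relu0((ci - cj) %*% w$pe1_W + w$pe1_b) %*% w$pe2_W + w$pe2_b)
  }
  for (i in seq_len(M)) {
    q_i <- as.vector(feats[i, ] %*% w$Wq)
    raw <- matrix(0, k, D)
    vals <- matrix(0, k, D)
    for (jj in seq_len(k)) {
      j <- nb[i, jj]
      pe <- pe_fn(matrix(coords[i, ], 1), matrix(coords[j, ], 1))
      k_j <- as.vector(feats[j, ] %*% w$Wk)
      a_in <- q_i - k_j + pe
      g <- as.vector(relu0(a_in %*% w$g1_W + w$g1_b) %*% w$g2_W + w$g2_b)
      raw[jj, ] <- g / sqrt(D)
      vals[jj, ] <- as.vector(feats[j, ] %*% w$Wv) + pe
    }
    attn <- apply(raw, 2, function(col) exp(col - max(col)) /
                    sum(exp(col - max(col))))
    expect_equal(res$output[i, ], colSums(attn * vals), tolerance = 1e-6)
  }
})

test_that("attention degenerates correctly for k = 1 and is translation-invariant without PE", {
  D <- 3
  w <- .rand_attn_weights(D, seed = 9)
  set.seed(10)
  feats <- matrix(rnorm(5 * D), 5, D)
  coords <- matrix(rnorm(5 * 3), 5, 3)
  nb1 <- matrix(seq_len(5), 5, 1) # self only
  out <- vector_self_attention(feats, coords, nb1, w,
                               use_position_encoding = FALSE)
  expect_equal(out$output, feats %*% w$Wv, tolerance = 1e-12)
  # with PE disabled, translating the coordinates changes nothing
  nb <- knn_indices(coords, 3, include_self = TRUE)
  a <- vector_self_attention(feats, coords, nb, w,
                             use_position_encoding = FALSE)
  b <- vector_self_attention(feats, sweep(coords, 2, c(5, -2, 1), "+"), nb,
                             w, use_position_encoding = FALSE)
  expect_equal(a$output, b$output, tolerance = 1e-12)
})

test_that("position encoding depends only on the relative displacement", {
  D <- 4
  w <- .rand_attn_weights(D, seed = 12)
  pw <- list(W1 = w$pe1_W, b1 = w$pe1_b, W2 = w$pe2_W, b2 = w$pe2_b)
  p <- c(0.2, -0.4, 0.9)
  same <- position_encoding(rbind(p, p * 2), rbind(p, p * 2), pw)
  expect_equal(same[1, ], same[2, ], tolerance = 1e-12) # zero displacement
  shift <- c(3, -1, 2)
  a <- position_encoding(matrix(p, 1), matrix(-p, 1), pw)
  b <- position_encoding(matrix(p + shift, 1), matrix(-p + shift, 1), pw)
  expect_equal(a, b, tolerance = 1e-12)
  # antisymmetric arguments agree only if the learned map happens to be even
  cc <- position_encoding(matrix(-p, 1), matrix(p, 1), pw)
  manual <- function(rel) {
    as.vector(pmax(rel %*% pw$W1 + pw$b1, 0) %*% pw$W2 + pw$b2)
  }
  expect_equal(as.vector(a), manual(matrix(2 * p, 1)), tolerance = 1e-12)
  expect_equal(as.vector(cc), manual(matrix(-2 * p, 1)), tolerance = 1e-12)
})

test_that("transition_down reduces points per schedule with local re-embedding", {
  # the fixed ratio schedule at N = 1024 and at an indivisible N
  expect_equal(stage_counts(point_transformer_spec(), 1024),
               c(1024L, 256L, 64L, 16L, 4L))
  expect_equal(stage_counts(point_transformer_spec(), 205),
               c(205L, 51L, 12L, 3L, 1L))
  expect_equal(stage_counts(ablate(point_transformer_spec(), "downsampling"),
                            1024), rep(1024L, 5))
  # intervention schedule: counts entering successive EdgeConv layers
  expect_equal(stage_counts(add_downsampling_to_dgcnn(dgcnn_spec()), 1024),
               c(1024L, 256L, 64L, 16L))
  expect_equal(stage_counts(dgcnn_spec(), 1024), rep(1024L, 4))
  # functional op: target = M is pure re-embedding
  set.seed(3)
  coords <- matrix(rnorm(30), 10, 3)
  feats <- matrix(rnorm(40), 10, 4)
  wts <- list(l1_W = matrix(rnorm(7 * 6), 7), l1_b = rnorm(6),
              l2_W = matrix(rnorm(36), 6), l2_b = rnorm(6))
  td <- transition_down(coords, feats, 10, k = 3, weights = wts)
  expect_equal(nrow(td$features), 10L)
  expect_setequal(td$indices, 1:10)
  td2 <- transition_down(coords, feats, 4, k = 3, weights = wts)
  expect_equal(nrow(td2$coords), 4L)
  expect_identical(td2$indices, farthest_point_sampling(coords, 4))
  expect_error(transition_down(coords, feats, 0, 3, wts), "target_count")
})

test_that("default builds hit the published parameter counts", {
  md <- build_model(dgcnn_spec(), seed = 1)
  expect_identical(count_parameters(md), 1809576L)
  expect_equal(round(count_parameters(md) / 1e6, 2), 1.81)
  mp <- build_model(point_transformer_spec(), seed = 1)
  expect_identical(count_parameters(mp), 9584040L)
  expect_equal(round(count_parameters(mp) / 1e6, 2), 9.58)
  # a single 3 -> 8 affine map counts 3*8 + 8 = 32 scalars
  P <- shapecloud:::init_linear(list(), "x", 3, 8, bias = TRUE)
  expect_equal(sum(lengths(P)), 32L)
})

test_that("ablations alter only their target mechanism", {
  base <- tiny_pt_spec()
  m0 <- build_model(base, seed = 2)
  # NoPE: identical parameter layout except the positional maps
  m_nope <- build_model(ablate(base, "position_encoding"), seed = 2)
  dropped <- setdiff(names(m0$params), names(m_nope$params))
  expect_true(all(grepl("_pe[12]_", dropped)))
  expect_length(setdiff(names(m_nope$params), names(m0$params)), 0)
  # NoDS: parameter count preserved exactly (reduction is index selection)
  m_nods <- build_model(ablate(base, "downsampling"), seed = 2)
  expect_identical(count_parameters(m_nods), count_parameters(m0))
  expect_identical(names(m_nods$params), names(m0$params))
  # NoAttn: per-neighbour weights all equal 1/k
  spec_na <- ablate(base, "attention")
  m_na <- build_model(spec_na, seed = 2)
  set.seed(4)
  coords <- matrix(rnorm(20 * 3), 20, 3)
  fwd <- shapecloud:::.pt_fwd(m_na, list(coords), training = FALSE)
  expect_identical(fwd$cache$tb0$attn, 1 / base$k)
  # NoDS forward holds every stage at N points
  fwd2 <- shapecloud:::.pt_fwd(build_model(ablate(base, "downsampling"), 2),
                               list(coords), training = FALSE)
  expect_equal(sum(fwd2$cache$sizes), 20L)
  # ablating a mechanism dgcnn lacks is an error
  expect_error(ablate(tiny_dgcnn_spec(), "attention"), "no attention")
  # the intervention adds parameters
  d0 <- build_model(tiny_dgcnn_spec(), seed = 1)
  d1 <- build_model(add_downsampling_to_dgcnn(tiny_dgcnn_spec(), td_k = 3),
                    seed = 1)
  expect_gt(count_parameters(d1), count_parameters(d0))
})

test_that("logits are permutation-invariant for every family and variant", {
  set.seed(6)
  coords <- matrix(rnorm(48 * 3), 48, 3)
  perm <- sample(48)
  specs <- list(tiny_dgcnn_spec(),
                add_downsampling_to_dgcnn(tiny_dgcnn_spec(), td_k = 3),
                tiny_pt_spec(),
                ablate(tiny_pt_spec(), "downsampling"))
  for (spec in specs) {
    m <- build_model(spec, seed = 5)
    l1 <- predict_logits(m, coords)
    l2 <- predict_logits(m, coords[perm, ])
    expect_equal(l1, l2, tolerance = 1e-5)
  }
})

test_that("hand-coded backward passes agree with numerical gradients", {
  # relative errors are checked robustly: ReLU/max kinks make a few
  # coordinates legitimately non-smooth, so we require the bulk to match
  check_grads <- function(spec, M = 10, n_check = 40, seed = 3) {
    model <- build_model(spec, seed = seed)
    set.seed(seed)
    coords <- matrix(rnorm(M * 3), M, 3)
    snap <- as.list(model$state)
    restore <- function() for (nm in names(snap))
      assign(nm, snap[[nm]], model$state)
    batch <- list(coords, coords * 0.8 + 0.05)
    loss_fn <- function(m) {
      restore()
      if (spec$family == "dgcnn") {
        bb <- shapecloud:::.dgcnn_backbone_fwd(m, batch, TRUE)
        hd <- shapecloud:::.dgcnn_head_fwd(m, bb$pooled, TRUE)
        list(loss = shapecloud:::softmax_xent(hd$logits, c(2L, 1L))$loss,
             parts = list(bb = bb, hd = hd))
      } else {
        f <- shapecloud:::.pt_fwd(m, batch, TRUE)
        list(loss = shapecloud:::softmax_xent(f$logits, c(2L, 1L))$loss,
             parts = list(f = f))
      }
    }
    gacc <- new.env()
    fv <- loss_fn(model)
    if (spec$family == "dgcnn") {
      ce <- shapecloud:::softmax_xent(fv$parts$hd$logits, c(2L, 1L))
      dP <- shapecloud:::.dgcnn_head_bwd(fv$parts$hd$cache, ce$dlogits,
                                         model$params, gacc)
      shapecloud:::.dgcnn_backbone_bwd(fv$parts$bb$cache, dP,
                                       model$params, gacc)
    } else {
      ce <- shapecloud:::softmax_xent(fv$parts$f$logits, c(2L, 1L))
      shapecloud:::.pt_bwd(fv$parts$f$cache, ce$dlogits, model$params,
                           gacc)
    }
    eps <- 1e-6
    rels <- numeric(0)
    set.seed(seed + 1)
    for (t in seq_len(n_check)) {
      nm <- sample(names(model$params), 1)
      i <- sample(length(model$params[[nm]]), 1)
      g_an <- if (is.null(gacc[[nm]])) 0 else gacc[[nm]][i]
      m2 <- model
      m2$params[[nm]][i] <- model$params[[nm]][i] + eps
      lp <- loss_fn(m2)$loss
      m2$params[[nm]][i] <- model$params[[nm]][i] - eps
      lm <- loss_fn(m2)$loss
      g_num <- (lp - lm) / (2 * eps)
      rels <- c(rels, abs(g_an - g_num) /
                  max(1e-7, abs(g_an) + abs(g_num)))
    }
    rels
  }
  for (spec in list(tiny_dgcnn_spec(),
                    add_downsampling_to_dgcnn(tiny_dgcnn_spec(), td_k = 3),
                    tiny_pt_spec(),
                    ablate(tiny_pt_spec(), "attention"),
                    ablate(tiny_pt_spec(), "position_encoding"),
                    ablate(tiny_pt_spec(), "downsampling"))) {
    rels <- check_grads(spec)
    expect_lt(median(rels), 1e-5)
    expect_gte(mean(rels < 1e-2), 0.8)
  }
})

test_that("model containers round trip through save/load", {
  spec <- tiny_pt_spec()
  m <- build_model(spec, seed = 4)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(count_parameters(m2), count_parameters(m))
  set.seed(5)
  coords <- matrix(rnorm(30), 10, 3)
  expect_equal(predict_logits(m2, coords), predict_logits(m, coords),
               tolerance = 1e-12)
})
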