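# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own vectorised code paths.

rand_cloud <- function(n, seed, labels = FALSE) {
  set.seed(seed)
  point_cloud(matrix(rnorm(n * 3), n, 3),
              part_labels = if (labels) sample(0:2, n, replace = TRUE),
              category = "test", instance_id = paste0("rc", seed))
}

# all-pairs nearest neighbours by explicit per-row scan
oracle_knn <- function(x, k, include_self) {
  x <- as.matrix(x)
  m <- nrow(x)
  out <- matrix(0L, m, k)
  for (i in seq_len(m)) {
    d <- numeric(m)
    for (j in seq_len(m)) d[j] <- sum((x[i, ] - x[j, ])^2)
    if (!include_self) d[i] <- Inf
    ord <- order(d)[seq_len(min(k, sum(is.finite(d))))]
    out[i, ] <- rep_len(ord, k)
  }
  out
}

# greedy max-min farthest point sampling by explicit scan
oracle_fps <- function(coords, m, start) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  sel <- start
  while (length(sel) < m) {
    best <- -1; best_i <- 0L
    for (i in seq_len(n)) {
      di <- min(vapply(sel, function(s) sum((coords[i, ] - coords[s, ])^2),
                       numeric(1)))
      if (di > best) { best <- di; best_i <- i }
    }
    sel <- c(sel, best_i)
  }
  sel
}

# voxel occupancy by explicit per-point flooring against the bbox-min origin
oracle_occupancy <- function(coords, voxel_size) {
  origin <- apply(coords, 2, min)
  cells <- unique(t(apply(coords, 1, function(p)
    as.integer(floor((p - origin) / voxel_size)))))
  cells[order(cells[, 1], cells[, 2], cells[, 3]), , drop = FALSE]
}

# exposed faces by explicit neighbour lookup over the occupied set
oracle_exposed_faces <- function(occupied) {
  key <- apply(occupied, 1, paste, collapse = ",")
  faces <- list()
  for (r in seq_len(nrow(occupied))) {
    for (axis in 1:3) {
      for (side in c(-1L, 1L)) {
        nb <- occupied[r, ]
        nb[axis] <- nb[axis] + side
        if (!(paste(nb, collapse = ",") %in% key)) {
          faces[[length(faces) + 1L]] <- c(occupied[r, ], axis, side)
        }
      }
    }
  }
  do.call(rbind, faces)
}

# Pearson r and two-sided p from the definition (no cor/cor.test)
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), df = n - 2))
}

# second, independent coding of the dependent-correlation z (Steiger 1980,
# Z1* with the pooled-r covariance), written from the published formula
oracle_steiger_z <- function(r1, r2, r12, n) {
  fisher <- function(r) 0.5 * log((1 + r) / (1 - r))
  rb <- (r1 + r2) / 2
  cov_term <- (r12 * (1 - 2 * rb^2) - 0.5 * rb^2 * (1 - 2 * rb^2 - r12^2)) /
    (1 - rb^2)^2
  (fisher(r1) - fisher(r2)) * sqrt(n - 3) / sqrt(2 - 2 * cov_term)
}

# binomial 99% acceptance bounds for a proportion
binom_bounds <- function(n, p) {
  qbinom(c(0.005, 0.995), n, p) / n
}

# a minimal valid 3-part template of three boxes with prescribed half-sizes
three_box_template <- function(h1, h2, h3) {
  shape_template("threebox",
    c(s1 = 1, s2 = 1, s3 = 1),
    function(p) {
      list(primitives = list(
        primitive("box", center = c(-3, 0, 0), hx = h1[1] * p$s1,
                  hy = h1[2] * p$s1, hz = h1[3] * p$s1),
        primitive("box", center = c(0, 0, 0), hx = h2[1] * p$s2,
                  hy = h2[2] * p$s2, hz = h2[3] * p$s2),
        primitive("box", center = c(3, 0, 0), hx = h3[1] * p$s3,
                  hy = h3[2] * p$s3, hz = h3[3] * p$s3)),
        part_of = 0:2, part_names = c("a", "b", "c"))
    })
}

# a full sphere assembled from three equal-height bands, one part each
sphere_bands_template <- function(r = 1) {
  shape_template("sphere3",
    c(r = r),
    function(p) {
      h <- 2 * p$r / 3
      list(primitives = list(
        primitive("sphere_cap", r = p$r, h = h, h0 = 0),
        primitive("sphere_cap", r = p$r, h = h, h0 = h),
        primitive("sphere_cap", r = p$r, h = h, h0 = 2 * h)),
        part_of = 0:2, part_names = c("top", "middle", "bottom"))
    })
}

# a unit tetrahedron mesh
tetra_mesh <- function() {
  mesh(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
       faces = rbind(c(0L, 1L, 2L), c(0L, 1L, 3L), c(0L, 2L, 3L),
                     c(1L, 2L, 3L)))
}

# an axis-aligned cube mesh with side 1 centred at the origin
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = c(-0.5, 0.5), y = c(-0.5, 0.5),
                             z = c(-0.5, 0.5)))
  tri <- function(a, b, c) c(a, b, c) - 1L
  faces <- rbind(
    tri(1, 2, 4), tri(1, 4, 3),   # z = -0.5 (vertices 1:4)
    tri(5, 6, 8), tri(5, 8, 7),   # z = +0.5
    tri(1, 2, 6), tri(1, 6, 5),   # y = -0.5
    tri(3, 4, 8), tri(3, 8, 7),   # y = +0.5
    tri(1, 3, 7), tri(1, 7, 5),   # x = -0.5
    tri(2, 4, 8), tri(2, 8, 6))   # x = +0.5
  mesh(v, faces)
}

# tiny desk-scale specs used throughout the model tests
tiny_dgcnn_spec <- function(n_classes = 3, ...) {
  dgcnn_spec(edge_widths = c(6, 8), emb_dim = 12, head_widths = c(10, 6),
             k = 4, n_classes = n_classes,
             classes = letters[seq_len(n_classes)], dropout = 0,
             td_k = 3, ...)
}

tiny_pt_spec <- function(n_classes = 3, ...) {
  point_transformer_spec(base_dim = 4, d_model = 6, n_blocks = 2, k = 3,
                         head_widths = c(8, 6), n_classes = n_classes,
                         classes = letters[seq_len(n_classes)], ...)
}

# random weight set for the attention-operator tests
.rand_attn_weights <- function(D, seed) {
  set.seed(seed)
  list(Wq = matrix(rnorm(D * D), D), Wk = matrix(rnorm(D * D), D),
       Wv = matrix(rnorm(D * D), D),
       g1_W = matrix(rnorm(D * D), D), g1_b = rnorm(D),
       g2_W = matrix(rnorm(D * D), D), g2_b = rnorm(D),
       pe1_W = matrix(rnorm(3 * D), 3), pe1_b = rnorm(D),
       pe2_W = matrix(rnorm(D * D), D), pe2_b = rnorm(D))
}
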