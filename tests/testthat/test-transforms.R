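test_that("unit-sphere normalization meets its analytic contract", {
  pc <- point_cloud(rbind(c(0, 0, 0), c(2, 0, 0)))
  out <- normalize_unit_sphere(pc)
  expect_equal(out$coords, rbind(c(-1, 0, 0), c(1, 0, 0)))
  # idempotence
  out2 <- normalize_unit_sphere(out)
  expect_lt(max(abs(out2$coords - out$coords)), 1e-9)
  # direct recomputation oracle on a random cloud
  rc <- normalize_unit_sphere(rand_cloud(50, seed = 2))
  expect_lt(max(abs(colMeans(rc$coords))), 1e-9)
  expect_equal(max(sqrt(rowSums(rc$coords^2))), 1, tolerance = 1e-9)
  # degenerate cloud: centred, not scaled
  one <- normalize_unit_sphere(point_cloud(matrix(c(5, 5, 5), 1)))
  expect_equal(one$coords, matrix(0, 1, 3))
})

test_that("density downsampling keeps a floor-sized subset of the input", {
  pc <- rand_cloud(100, seed = 7, labels = TRUE)
  out <- downsample_density(pc, 0.2, seed = 1)
  expect_equal(n_points(out), 20L)
  # every output row present in the input, labels carried consistently
  key_in <- apply(pc$coords, 1, paste, collapse = "|")
  key_out <- apply(out$coords, 1, paste, collapse = "|")
  pos <- match(key_out, key_in)
  expect_false(anyNA(pos))
  expect_identical(out$part_labels, pc$part_labels[pos])
  # proportion = 1 is the identity
  expect_identical(downsample_density(pc, 1, seed = 9), pc)
  # floor rule at the printed grid: 20% of 1024 -> 204
  big <- rand_cloud(1024, seed = 8)
  expect_equal(n_points(downsample_density(big, 0.2, seed = 3)), 204L)
  # determinism and error cases
  expect_identical(downsample_density(pc, 0.4, seed = 5)$coords,
                   downsample_density(pc, 0.4, seed = 5)$coords)
  expect_error(downsample_density(pc, 0, seed = 1), "proportion")
  expect_error(downsample_density(pc, 1.2, seed = 1), "proportion")
})

test_that("inversion is the analytic 180-degree rotation, an involution and an isometry", {
  pc <- point_cloud(rbind(c(0, 1, 0)))
  expect_equal(invert(pc)$coords, rbind(c(0, -1, 0)))
  rc <- rand_cloud(40, seed = 4)
  expect_equal(invert(invert(rc))$coords, rc$coords)
  expect_equal(as.matrix(dist(invert(rc)$coords)), as.matrix(dist(rc$coords)),
               tolerance = 1e-12)
  # proper rotation: determinant +1
  R <- diag(c(1, -1, -1))
  expect_equal(det(R), 1)
  expect_equal(invert(rc)$coords, rc$coords %*% R)
})

test_that("voxel occupancy and exposed faces match brute-force oracles", {
  # single point: one voxel, all samples on its cube surface
  p1 <- point_cloud(matrix(c(0.3, 0.2, 0.9), 1))
  g1 <- voxel_grid(p1, 0.5)
  expect_equal(nrow(g1$occupied), 1L)
  out1 <- voxelize_lego(p1, 0.5, n_out = 200, seed = 3, normalize = FALSE)
  rel <- sweep(out1$coords, 2, g1$origin, "-") / 0.5
  on_plane <- abs(rel) < 1e-9 | abs(rel - 1) < 1e-9
  expect_true(all(apply(on_plane, 1, any)))

  # two adjacent voxels: 10 exposed faces, uniform sampling across them
  p2 <- point_cloud(rbind(c(0.5, 0.5, 0.5), c(1.5, 0.5, 0.5)))
  g2 <- voxel_grid(p2, 1)
  ef <- exposed_faces(g2)
  expect_equal(nrow(ef), 10L)
  oef <- oracle_exposed_faces(g2$occupied)
  expect_equal(nrow(oef), 10L)
  key_a <- sort(apply(ef[, 1:5], 1, paste, collapse = ","))
  key_b <- sort(apply(oef, 1, paste, collapse = ","))
  expect_identical(key_a, key_b)
  n <- 8000
  out2 <- voxelize_lego(p2, 1, n_out = n, seed = 5, normalize = FALSE)
  # classify each sample to a face and test uniformity within binomial bounds
  face_of <- function(p) {
    for (r in seq_len(nrow(ef))) {
      base <- c(ef$i[r], ef$j[r], ef$k[r])
      ax <- ef$axis[r]
      plane <- base[ax] + (ef$side[r] > 0)
      if (abs(p[ax] - plane) < 1e-9) {
        others <- setdiff(1:3, ax)
        if (all(p[others] >= base[others] - 1e-9 &
                p[others] <= base[others] + 1 + 1e-9)) {
          return(r)
        }
      }
    }
    NA_integer_
  }
  rel2 <- sweep(out2$coords, 2, g2$origin, "-") / 1
  faces <- apply(rel2, 1, face_of)
  expect_false(anyNA(faces))
  counts <- tabulate(faces, nbins = 10)
  bounds <- binom_bounds(n, 1 / 10)
  expect_true(all(counts / n >= bounds[1] & counts / n <= bounds[2]))

  # fine-grid limit: voxel smaller than half the nearest-neighbour spacing
  rc <- rand_cloud(120, seed = 11)
  d <- as.matrix(dist(rc$coords)); diag(d) <- Inf
  v <- min(d) / 2.5
  expect_equal(nrow(voxel_grid(rc, v)$occupied), 120L)

  # occupancy equals the brute-force oracle on random inputs
  for (s in 1:8) {
    rc <- rand_cloud(sample(20:200, 1), seed = 100 + s)
    v <- runif(1, 0.1, 0.8)
    occ <- voxel_grid(rc, v)$occupied
    occ <- occ[order(occ[, 1], occ[, 2], occ[, 3]), , drop = FALSE]
    expect_equal(unname(occ), unname(oracle_occupancy(rc$coords, v)))
  }

  expect_error(voxelize_lego(p1, -0.1, seed = 1), "voxel_size")
  # voxel size 0 is the identity condition
  expect_identical(voxelize_lego(p2, 0, seed = 1), p2)
})

test_that("over-large parts are subdivided by spectral clustering", {
  set.seed(42)
  # three well-separated blobs carrying a single part label
  blob <- function(center, n) sweep(matrix(rnorm(n * 3, sd = 0.05), n, 3),
                                    2, center, "+")
  coords <- rbind(blob(c(0, 0, 0), 40), blob(c(10, 0, 0), 40),
                  blob(c(0, 10, 0), 40))
  pc <- point_cloud(coords, part_labels = rep(0L, 120))
  out <- subdivide_large_parts(pc, scramble_config(seed = 3))
  expect_identical(sort(unique(out$part_labels)), 0:2)
  truth <- rep(1:3, each = 40)
  expect_equal(max(table(out$part_labels, truth) > 0) , 1)
  # each recovered cluster is exactly one blob
  tab <- table(out$part_labels, truth)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))

  # balanced parts at/below threshold are untouched (up to re-indexing)
  pc2 <- rand_cloud(100, seed = 9)
  pc2$part_labels <- rep(0:3, each = 25)
  out2 <- subdivide_large_parts(pc2, scramble_config(seed = 1))
  tab2 <- table(out2$part_labels, pc2$part_labels)
  expect_true(all(rowSums(tab2 > 0) == 1))

  # part-count arithmetic: original - n_over + 3 * n_over
  pc3 <- rand_cloud(120, seed = 10)
  pc3$part_labels <- rep(c(0L, 1L, 2L), times = c(80L, 20L, 20L))
  out3 <- subdivide_large_parts(pc3, scramble_config(seed = 2))
  expect_equal(length(unique(out3$part_labels)), 3L - 1L + 3L)

  # an over-threshold part smaller than the cluster count errors
  pc4 <- point_cloud(matrix(rnorm(12), 4, 3),
                     part_labels = c(0L, 0L, 1L, 1L))
  expect_error(subdivide_large_parts(pc4, scramble_config(seed = 1)),
               "clusters")
})

test_that("scrambling preserves part geometry up to one global scale", {
  pc <- generate_object(shape_templates("table")[[1]], 15, n_points = 300)
  cfg <- scramble_config(seed = 77)
  out <- scramble_parts(pc, cfg)
  expect_s3_class(out, "stimulus_record")
  scale_est <- NULL
  for (p in unique(pc$part_labels)) {
    sel <- which(pc$part_labels == p)
    if (length(sel) < 2) next
    d0 <- as.matrix(dist(pc$coords[sel, ]))
    d1 <- as.matrix(dist(out$coords[sel, ]))
    ratio <- d1[upper.tri(d1)] / d0[upper.tri(d0)]
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
    if (is.null(scale_est)) scale_est <- mean(ratio)
    expect_equal(mean(ratio), scale_est, tolerance = 1e-6) # one shared scale
  }
  # forced zero offsets: every part centred at the origin (pre-normalization)
  ids <- sort(unique(pc$part_labels))
  z <- scramble_parts(pc, cfg, offsets = matrix(0, length(ids), 3),
                      normalize = FALSE)
  for (p in ids) {
    ctr <- colMeans(z$coords[pc$part_labels == p, , drop = FALSE])
    expect_lt(max(abs(ctr)), 1e-9)
  }
  # anchor part centred at the origin pre-normalization
  raw <- scramble_parts(pc, cfg, normalize = FALSE)
  anchor <- raw$provenance$params$anchor
  actr <- colMeans(raw$coords[pc$part_labels == anchor, , drop = FALSE])
  expect_lt(max(abs(actr)), 1e-9)
  # determinism
  out2 <- scramble_parts(pc, cfg)
  expect_identical(out$coords, out2$coords)
  # single-part clouds cannot be scrambled
  solo <- rand_cloud(20, seed = 1)
  solo$part_labels <- rep(0L, 20)
  expect_error(scramble_parts(solo, cfg), "2 parts")
})

test_that("training augmentation follows dropout -> scale -> shift with exact counts", {
  pc <- rand_cloud(1024, seed = 20)
  # dropout forced to zero: exact affine map
  par0 <- list(dropout_ratio = 0, scale = 1.1, shift = c(0.05, -0.02, 0.08))
  a0 <- augment_train(pc, seed = 1, params = par0)
  expect_equal(a0$coords,
               sweep(pc$coords * 1.1, 2, c(0.05, -0.02, 0.08), "+"),
               tolerance = 1e-14)
  expect_equal(n_points(a0), 1024L)
  # dropout forced to the upper bound: floor(0.875 * 1024) = 896 replaced
  par1 <- list(dropout_ratio = 0.875, scale = 1, shift = c(0, 0, 0))
  a1 <- augment_train(pc, seed = 2, params = par1)
  expect_equal(attr(a1, "augmentation")$n_dropped, 896L)
  p0 <- a1$coords[1, ]
  eq0 <- rowSums(abs(sweep(a1$coords, 2, p0, "-"))) < 1e-14
  expect_gte(sum(eq0), 896L) # the replaced points (+ point 1 itself)
  expect_lte(sum(eq0), 897L)
  # parameter ranges over many draws
  cfg <- augment_config()
  set.seed(3)
  draws <- replicate(10000, unlist(
    shapecloud:::sample_augment_params(cfg)))
  expect_gte(min(draws["dropout_ratio", ]), 0)
  expect_lte(max(draws["dropout_ratio", ]), 0.875)
  expect_gte(min(draws["scale", ]), 0.8)
  expect_lte(max(draws["scale", ]), 1.25)
  expect_gte(min(draws[grep("shift", rownames(draws)), ]), -0.1)
  expect_lte(max(draws[grep("shift", rownames(draws)), ]), 0.1)
  # determinism
  expect_identical(augment_train(pc, seed = 5)$coords,
                   augment_train(pc, seed = 5)$coords)
})
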