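test_that("confusion matrices tally predictions exactly", {
  cats <- c("a", "b", "c")
  # perfect predictions: diagonal
  perfect <- data.frame(true = rep(cats, each = 4),
                        predicted = rep(cats, each = 4))
  cm <- confusion_from_predictions(perfect, cats)
  expect_equal(unname(diag(cm)), rep(4L, 3))
  expect_equal(sum(cm), 12L)
  # single off-diagonal row
  one <- confusion_from_predictions(data.frame(true = "a", predicted = "b"),
                                    cats)
  expect_equal(one["a", "b"], 1L)
  expect_equal(sum(one), 1L)
  # random table vs a brute-force tally oracle
  set.seed(7)
  for (rep in 1:20) {
    tab <- data.frame(true = sample(cats, 200, replace = TRUE),
                      predicted = sample(cats, 200, replace = TRUE))
    cm2 <- confusion_from_predictions(tab, cats)
    for (i in cats) for (j in cats) {
      expect_identical(cm2[i, j],
                       sum(tab$true == i & tab$predicted == j))
    }
  }
  expect_error(confusion_from_predictions(
    data.frame(true = "z", predicted = "a"), cats), "roster")
})

test_that("off-diagonal confusion correlation matches a from-definition oracle", {
  cats <- c("a", "b", "c")
  A <- matrix(c(8L, 1L, 3L,
                2L, 9L, 1L,
                4L, 0L, 6L), 3, 3, byrow = TRUE,
              dimnames = list(cats, cats))
  class(A) <- c("confusion_matrix", class(A))
  # identical matrices with non-uniform errors: r = 1
  self <- offdiag_correlation(A, A)
  expect_equal(self$r, 1, tolerance = 1e-12)
  # hand-enumerated pair vs the definition oracle
  B <- matrix(c(7L, 2L, 3L,
                1L, 8L, 3L,
                2L, 2L, 8L), 3, 3, byrow = TRUE,
              dimnames = list(cats, cats))
  class(B) <- c("confusion_matrix", class(B))
  got <- offdiag_correlation(A, B)
  va <- as.vector(t(A / rowSums(A)))[c(2, 3, 4, 6, 7, 8)]
  vb <- as.vector(t(B / rowSums(B)))[c(2, 3, 4, 6, 7, 8)]
  want <- oracle_pearson(va, vb)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_equal(got$df, 6 - 2)
  # consistent category reordering leaves r unchanged
  ord <- c(3, 1, 2)
  A2 <- A[ord, ord]; B2 <- B[ord, ord]
  class(A2) <- class(B2) <- c("confusion_matrix", "matrix")
  expect_equal(offdiag_correlation(A2, B2)$r, got$r, tolerance = 1e-12)
  # degenerate inputs error
  expect_error(offdiag_correlation(A, B[1:2, 1:2]), "share")
  U <- matrix(c(5L, 1L, 1L, 1L, 5L, 1L, 1L, 1L, 5L), 3, 3,
              dimnames = list(cats, cats))
  expect_error(offdiag_correlation(U, B), "zero variance")
})

test_that("accuracy-pattern correlations behave analytically and match the oracle", {
  pa <- accuracy_profile(paste0("c", 1:5), c(0.9, 0.8, 0.75, 0.5, 0.3))
  expect_equal(accuracy_pattern_correlation(pa, pa)$r, 1, tolerance = 1e-12)
  pb <- accuracy_profile(paste0("c", 1:5), 1 - pa$accuracy)
  expect_equal(accuracy_pattern_correlation(pa, pb)$r, -1,
               tolerance = 1e-12)
  pc_ <- accuracy_profile(paste0("c", 1:5), c(0.85, 0.8, 0.6, 0.55, 0.4))
  got <- accuracy_pattern_correlation(pa, pc_)
  want <- oracle_pearson(pa$accuracy, pc_$accuracy)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  # misaligned conditions are an error
  pd <- accuracy_profile(paste0("d", 1:5), pc_$accuracy)
  expect_error(accuracy_pattern_correlation(pa, pd), "condition")
  # property loop: r in [-1, 1], p in (0, 1], oracle agreement to 1e-12
  set.seed(13)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    x <- runif(n); y <- runif(n)
    p1 <- accuracy_profile(paste0("k", 1:n), x)
    p2 <- accuracy_profile(paste0("k", 1:n), y)
    got <- accuracy_pattern_correlation(p1, p2)
    want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_true(got$r >= -1 && got$r <= 1)
    expect_true(got$p > 0 && got$p <= 1)
  }
})

test_that("profiles derive correctly from prediction tables", {
  tab <- data.frame(density = c(1, 1, 0.2, 0.2, 0.2),
                    true = c("a", "a", "a", "b", "b"),
                    predicted = c("a", "a", "b", "b", "a"))
  prof <- accuracy_from_predictions(tab, "density")
  expect_equal(prof$accuracy, c(1, 1 / 3))
  expect_equal(prof$n, c(2L, 3L))
})

test_that("Steiger's dependent-correlation z matches an independent coding", {
  expect_equal(compare_dependent_correlations(0.5, 0.5, 0.3, 50)$z, 0)
  # worked case computed with the independently coded oracle
  z <- compare_dependent_correlations(0.63, 0.41, 0.52, 103)$z
  expect_equal(z, oracle_steiger_z(0.63, 0.41, 0.52, 103),
               tolerance = 1e-9)
  set.seed(17)
  for (i in 1:50) {
    r1 <- runif(1, -0.9, 0.9); r2 <- runif(1, -0.9, 0.9)
    r12 <- runif(1, -0.6, 0.6); n <- sample(10:500, 1)
    got <- compare_dependent_correlations(r1, r2, r12, n)
    expect_equal(got$z, oracle_steiger_z(r1, r2, r12, n), tolerance = 1e-9)
    expect_true(got$p > 0 && got$p <= 1)
    expect_equal(sign(got$z), sign(r1 - r2) * (abs(r1 - r2) > 1e-12))
  }
  # |z| grows strictly with n at fixed correlations
  zs <- vapply(c(20, 50, 200, 1000), function(n)
    abs(compare_dependent_correlations(0.7, 0.4, 0.5, n)$z), numeric(1))
  expect_true(all(diff(zs) > 0))
  expect_error(compare_dependent_correlations(1, 0.5, 0.2, 20), "inside")
  expect_error(compare_dependent_correlations(0.4, 0.5, 0.2, 3), "n must")
})

test_that("human tables round trip and reject schema violations", {
  prof <- accuracy_profile(c("d20", "d30", "d100"), c(0.864, 0.889, 0.953),
                           n = c(55L, 55L, 55L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_human_table(prof, f)
  back <- load_human_table(f)
  expect_s3_class(back, "accuracy_profile")
  expect_equal(back$accuracy, prof$accuracy)
  expect_equal(back$condition, prof$condition)
  # confusion-matrix schema
  cats <- c("a", "b", "c")
  cm <- matrix(c(5L, 1L, 0L, 2L, 6L, 1L, 0L, 0L, 9L), 3, 3,
               dimnames = list(cats, cats))
  class(cm) <- c("confusion_matrix", "matrix")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_human_table(cm, f2)
  back2 <- load_human_table(f2)
  expect_equal(unclass(back2)[cats, cats], unclass(cm)[cats, cats])
  # unrecognised schema errors name the columns
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("foo,bar", "1,2"), f3)
  expect_error(load_human_table(f3), "foo, bar")
  # out-of-range accuracies rejected
  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("condition,accuracy", "x,1.4"), f4)
  expect_error(load_human_table(f4), "\\[0, 1\\]")
})

test_that("the pooled condition list enumerates the full cross-experiment grid", {
  pool <- pooled_condition_list()
  expect_length(pool, 14L + 5L + 3L)
  expect_false(anyDuplicated(pool) > 0)
  expect_equal(sum(grepl("^density_", pool)), 14L)
  expect_equal(sum(grepl("^lego_", pool)), 5L)
  expect_equal(sum(grepl("^scramble", pool)), 3L)
})
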