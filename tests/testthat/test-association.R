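test_that("projection agrees with direct summation over genes", {
  x <- normalize_per_sample(random_matrix_study(n = 60, m = 5, seed = 23))
  set.seed(24)
  U <- qr.Q(qr(matrix(rnorm(60 * 4), 60, 4)))
  rownames(U) <- x$gene_ids
  proj <- project_samples(U, x)
  direct <- matrix(0, 4, 5)
  for (l in 1:4) for (j in 1:5)
    direct[l, j] <- sum(U[, l] * x$values[, j])
  expect_lt(max(abs(proj$coords - direct)), 1e-10)
})

test_that("a sample equal to a gene factor projects to a unit coordinate", {
  set.seed(25)
  U <- qr.Q(qr(matrix(rnorm(40 * 3), 40, 3)))
  rownames(U) <- sprintf("g%02d", 1:40)
  x <- expression_matrix(U[, 1, drop = FALSE], gene_ids = rownames(U),
                         sample_ids = "s1")
  proj <- project_samples(U, x)
  expect_equal(as.vector(proj$coords), c(1, 0, 0), tolerance = 1e-10)
})

test_that("tensor projection keeps one index per condition mode", {
  x <- normalize_per_sample(random_tensor_study(dims = c(50, 3, 2, 3), seed = 26))
  set.seed(27)
  U <- qr.Q(qr(matrix(rnorm(50 * 4), 50, 4)))
  rownames(U) <- x$gene_ids
  proj <- project_samples(U, x)
  expect_identical(dim(proj$coords), c(4L, 3L, 2L, 3L))
  expect_equal(unname(proj$coords[2, 3, 1, 2]),
               sum(U[, 2] * x$values[, 3, 1, 2]), tolerance = 1e-12)
})

test_that("projection rejects a study off the gene universe", {
  x <- random_matrix_study(n = 30, m = 4, seed = 28)
  U <- matrix(rnorm(30 * 2), 30, 2,
              dimnames = list(paste0("other", 1:30), NULL))
  expect_error(project_samples(U, x), "gene universe")
})

test_that("training-study projection matches the stacked-tensor contraction", {
  sim <- generate_unmatched_studies(n_genes = 300, sizes = c(8, 10, 6),
                                    planted = 30, seed = 29)
  fit <- integrate_unmatched(sim$studies)
  U <- fit$integration$gene_factors
  contracted <- ttm(fit$stacked$values, t(U), 1)
  for (k in seq_along(fit$profiles)) {
    proj <- project_samples(U, fit$profiles[[k]])
    expect_lt(max(abs(proj$coords[, seq_len(fit$L)] - contracted[, , k])), 1e-10)
  }
})

test_that("the ANOVA screen reproduces hand-computed sums of squares", {
  rep <- test_factor_label_association(matrix(c(1, 2, 3, 4), 1, 4),
                                       labels = c("A", "A", "B", "B"))
  tab <- as.data.frame(rep)
  expect_equal(tab$F, 8)
  expect_identical(c(tab$df1, tab$df2), c(2L - 1L, 2L))
  expect_equal(tab$P, 1 - pf(8, 1, 2), tolerance = 1e-12)
})

test_that("a class-indicator coordinate separates perfectly", {
  set.seed(64)
  coords <- matrix(c(rep(0, 10), rep(1, 10)) + rnorm(20, sd = 1e-4), 1, 20)
  rep <- test_factor_label_association(coords, rep(c("a", "b"), each = 10))
  expect_lt(as.data.frame(rep)$P, 1e-6)
})

test_that("association P-values are invariant to affine factor rescaling", {
  set.seed(30)
  coords <- matrix(rnorm(3 * 12), 3, 12)
  labels <- rep(c("x", "y", "z"), each = 4)
  a <- as.data.frame(test_factor_label_association(coords, labels))
  b <- as.data.frame(test_factor_label_association(coords * 7 + 2, labels))
  expect_equal(a$P, b$P, tolerance = 1e-10)
})

test_that("degenerate label designs are rejected", {
  coords <- matrix(rnorm(8), 1, 8)
  expect_error(test_factor_label_association(coords, rep("a", 8)),
               "two label classes")
  expect_error(test_factor_label_association(coords, c(1:8)),
               "more observations than classes")
  expect_error(test_factor_label_association(coords, rep("a", 3)),
               "does not match")
})

test_that("permuted labels on noise stay below the screen threshold", {
  set.seed(32)
  hits <- replicate(100, {
    coords <- matrix(rnorm(4 * 18), 4, 18)
    labels <- sample(rep(c("a", "b", "c"), each = 6))
    any(as.data.frame(test_factor_label_association(coords, labels))$significant)
  })
  expect_gte(mean(!hits), 0.95)
})
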