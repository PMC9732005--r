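test_that("svd_reduce reproduces the lambda-scaled gene factors", {
  x <- normalize_per_sample(random_matrix_study(n = 100, m = 7, seed = 21))
  out <- svd_reduce(x, L = 7)
  # x %*% v equals lambda_l * u_l for every component
  direct <- x$values %*% out$svd$sample_factors[, 1:7]
  scaled <- sweep(out$svd$gene_factors[, 1:7], 2,
                  out$svd$singular_values[1:7], "*")
  expect_lt(max(abs(out$profile$values - direct)), 1e-10)
  expect_lt(max(abs(out$profile$values - scaled)), 1e-10)
  expect_true(all(diff(out$svd$singular_values) <= 1e-12))
})

test_that("svd_reduce flags L beyond the sample count and kills rank-1 tails", {
  x <- normalize_per_sample(random_matrix_study(n = 50, m = 8, seed = 4))
  expect_error(svd_reduce(x, 9), "L cannot exceed")
  set.seed(5)
  r1 <- expression_matrix(outer(rnorm(40), rnorm(6)),
                          gene_ids = sprintf("g%02d", 1:40))
  out <- svd_reduce(r1, 6)
  expect_lt(max(abs(out$profile$values[, 2:6])), 1e-10)
})

test_that("full-rank HOSVD recomposes the tensor and yields orthonormal factors", {
  for (seed in 1:3) {
    set.seed(seed)
    a <- array(rnorm(20 * 6 * 5), dim = c(20, 6, 5))
    h <- hosvd(a)
    rec <- hosvd_reconstruct(h)
    expect_lt(sqrt(sum((rec - a)^2)) / sqrt(sum(a^2)), 1e-8)
    for (f in h$factors)
      expect_lt(max(abs(crossprod(f) - diag(ncol(f)))), 1e-8)
  }
})

test_that("HOSVD recovers an orthogonally decomposable superdiagonal tensor", {
  a <- array(0, dim = c(3, 3, 3))
  a[1, 1, 1] <- 3; a[2, 2, 2] <- 2; a[3, 3, 3] <- 1
  h <- hosvd(a)
  core <- h$core
  diag_vals <- abs(c(core[1, 1, 1], core[2, 2, 2], core[3, 3, 3]))
  expect_equal(diag_vals, c(3, 2, 1), tolerance = 1e-10)
  off <- core; off[1, 1, 1] <- 0; off[2, 2, 2] <- 0; off[3, 3, 3] <- 0
  expect_lt(max(abs(off)), 1e-10)
  for (f in h$factors)   # signed permutations of the identity
    expect_equal(abs(f)[order(apply(abs(f), 1, which.max)), ], diag(3),
                 tolerance = 1e-10)
})

test_that("all-zero tensors give a zero core with orthonormal factors", {
  h <- hosvd(array(0, dim = c(4, 3, 2)))
  expect_true(all(h$core == 0))
  for (f in h$factors)
    expect_lt(max(abs(crossprod(f) - diag(ncol(f)))), 1e-8)
})

test_that("core all-orthogonality holds at full ranks", {
  set.seed(8)
  a <- array(rnorm(10 * 6 * 4), dim = c(10, 6, 4))
  h <- hosvd(a)
  for (mode in 1:3) {
    unf <- unfold(h$core, mode)
    gram <- tcrossprod(unf)
    expect_lt(max(abs(gram - diag(diag(gram)))), 1e-6)
  }
})

test_that("hosvd_reduce honours mode ranks and row-major column order", {
  x <- normalize_per_sample(random_tensor_study(dims = c(60, 9, 4, 3), seed = 6))
  p <- hosvd_reduce(x, c(4, 2, 1))
  expect_identical(ncol(p$values), 8L)
  expect_identical(colnames(p$values)[1:3], c("1.1.1", "1.2.1", "2.1.1"))
  p5 <- hosvd_reduce(normalize_per_sample(random_tensor_study(c(60, 3, 2, 3), 7)),
                     c(2, 2, 2))
  expect_identical(ncol(p5$values), 8L)
  expect_error(hosvd_reduce(x, c(10, 2, 1)), "rank")
})

test_that("hosvd_reduce at unit ranks equals the direct leading contraction", {
  x <- normalize_per_sample(random_tensor_study(dims = c(40, 5, 4), seed = 9))
  p <- hosvd_reduce(x, c(1, 1))
  u1 <- svd(unfold(x$values, 2))$u[, 1]
  u2 <- svd(unfold(x$values, 3))$u[, 1]
  direct <- numeric(40)
  for (j1 in 1:5) for (j2 in 1:4)
    direct <- direct + x$values[, j1, j2] * u1[j1] * u2[j2]
  # sign conventions may differ; compare up to sign
  expect_lt(min(max(abs(p$values[, 1] - direct)),
                max(abs(p$values[, 1] + direct))), 1e-10)
})

test_that("align_signs flips negated studies back onto the reference", {
  x <- normalize_per_sample(random_matrix_study(n = 80, m = 6, seed = 10))
  p1 <- svd_reduce(x, 6)$profile
  p2 <- p1
  p2$values <- -p2$values
  p2$sample_factors <- -p2$sample_factors
  aligned <- align_signs(list(p1, p2))
  expect_equal(aligned[[1]]$values, aligned[[2]]$values)
  for (l in 1:6)
    expect_gt(cor(aligned[[1]]$values[, l], aligned[[2]]$values[, l]), 0.999)
  # identical profiles stay untouched
  same <- align_signs(list(p1, p1))
  expect_identical(same[[1]]$values, same[[2]]$values)
})

test_that("stack_profiles builds N x L x K with order-stable studies", {
  studies <- lapply(1:3, function(k)
    normalize_per_sample(random_matrix_study(n = 30, m = 5, seed = k)))
  profiles <- lapply(seq_along(studies), function(k)
    svd_reduce(studies[[k]], 5, study_id = paste0("st", k))$profile)
  profiles <- align_signs(profiles)
  st <- stack_profiles(profiles, L = 4)
  expect_identical(dim(st$values), c(30L, 4L, 3L))
  expect_error(stack_profiles(profiles, L = 6), "only 5 components")
  # permuting study order only permutes mode 3
  st_perm <- stack_profiles(profiles[c(2, 3, 1)], L = 4)
  expect_identical(unname(st_perm$values[, , c(3, 1, 2)]),
                   unname(st$values))
})

test_that("single-study integration spans the study's own leading subspace", {
  x <- normalize_per_sample(random_matrix_study(n = 40, m = 6, seed = 12))
  p <- svd_reduce(x, 4)$profile
  st <- stack_profiles(list(p), L = 4)
  fit <- integrate_studies(st)
  own <- svd(x$values)$u[, 1:4]
  proj <- crossprod(own, fit$gene_factors)    # 4 x 4 rotation if subspaces match
  expect_equal(crossprod(proj), diag(4), tolerance = 1e-8)
})

test_that("integration recovers a planted rank-one tensor direction", {
  set.seed(13)
  g <- rnorm(500); g <- g / sqrt(sum(g^2))
  a <- rnorm(6); b <- rnorm(3)
  arr <- outer(g, outer(a, b)) + array(rnorm(500 * 6 * 3, sd = 0.01),
                                       dim = c(500, 6, 3))
  st <- structure(list(values = arr, gene_ids = sprintf("g%03d", 1:500),
                       study_ids = paste0("k", 1:3), L = 6L),
                  class = "stacked_tensor")
  fit <- integrate_studies(st)
  expect_gt(abs(cor(fit$gene_factors[, 1], g)), 0.99)
})

test_that("nested drug HOSVD factor shapes and degenerate slices", {
  set.seed(14)
  proj <- array(rnorm(2 * 94 * 4 * 3), dim = c(2, 94, 4, 3))
  res <- nested_hosvd_drug(proj, T = 5)
  h <- res$hosvd[[1]]
  expect_identical(dim(h$factors[[1]]), c(94L, 94L))
  expect_identical(dim(h$factors[[2]]), c(4L, 4L))
  expect_identical(dim(h$factors[[3]]), c(3L, 3L))
  expect_true(all(res$drug_scores >= 0 & res$drug_scores <= 5))
  expect_error(nested_hosvd_drug(proj, T = 95), "T cannot exceed")
  zero <- array(0, dim = c(1, 6, 4, 3))
  expect_true(all(nested_hosvd_drug(zero, T = 2)$drug_scores == 0))
})

test_that("after compression no stacked object scales with the cell count", {
  sc_small <- generate_scrna_collection(n_measurements = 4, n_genes = 150,
                                        cells = 60, planted = 20, seed = 31)
  sc_big <- generate_scrna_collection(n_measurements = 4, n_genes = 150,
                                      cells = 120, planted = 20, seed = 31)
  r_small <- integrate_scrna(sc_small$bundles, L = 6)
  r_big <- integrate_scrna(sc_big$bundles, L = 6)
  expect_identical(dim(r_small$stacked$values), dim(r_big$stacked$values))
  expect_identical(dim(r_small$stacked$values), c(150L, 6L, 4L))
  expect_null(r_small$profiles[[1]]$sample_factors)
})
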