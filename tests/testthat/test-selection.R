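test_that("choose_factors matches brute-force core enumeration", {
  set.seed(17)
  core <- array(rnorm(6 * 4 * 3), dim = c(6, 4, 3))
  ranked <- choose_factors(core)
  brute <- order(apply(core^2, 1, sum), decreasing = TRUE)
  expect_identical(as.integer(ranked), brute)
  # single nonzero entry pins the top factor
  core0 <- array(0, dim = c(5, 3, 2)); core0[2, 1, 1] <- 4
  expect_identical(as.integer(choose_factors(core0, top_n = 1)), 2L)
})

test_that("choose_factors respects fixed-mode constraints", {
  set.seed(18)
  core <- array(rnorm(6 * 4 * 3, sd = 0.1), dim = c(6, 4, 3))
  core[4, , 3] <- core[4, , 3] + 5          # slice l3 = 3 dominated by l1 = 4
  top <- choose_factors(core, fixed_modes = list(`3` = 3), top_n = 1)
  expect_identical(as.integer(top), 4L)
  brute <- order(apply(core[, , 3, drop = FALSE]^2, 1, sum), decreasing = TRUE)
  expect_identical(as.integer(choose_factors(core, fixed_modes = list(`3` = 3))),
                   brute)
  expect_error(choose_factors(core, fixed_modes = list(`3` = 9)),
               "out of range")
})

test_that("gene_pvalues follows the chi-squared upper tail", {
  # statistic 3.841 on 1 df and 5.991 on 2 df both sit at P ~ 0.05
  u1 <- matrix(c(sqrt(3.841), rep(0, 999)), ncol = 1)
  sel1 <- gene_pvalues(u1, omega = 1, sigma = 1)
  expect_equal(sel1$table$P[1], 0.05, tolerance = 1e-3)
  expect_equal(sel1$table$P[2], 1)          # all-zero loading gives P = 1
  u2 <- matrix(c(sqrt(5.991 / 2), rep(0, 9), sqrt(5.991 / 2), rep(0, 9)),
               ncol = 2)
  sel2 <- gene_pvalues(u2, omega = 1:2, sigma = c(1, 1))
  expect_equal(sel2$table$P[1], exp(-5.991 / 2), tolerance = 1e-6)
  expect_equal(sel2$table$P[1], 0.05, tolerance = 1e-3)
})

test_that("gene_pvalues agrees with the numerical-integration oracle", {
  set.seed(19)
  for (df in c(1, 3, 7, 10)) {
    stat <- rchisq(50, df = df) + 0.01
    u <- sqrt(stat / df)
    U <- matrix(rep(u, df), ncol = df)
    sel <- gene_pvalues(U, omega = seq_len(df), sigma = rep(1, df))
    expect_lt(max(abs(sel$table$P - chisq_upper_oracle(stat, df))), 1e-8)
  }
})

test_that("gene_pvalues is invariant to global factor sign flips", {
  set.seed(20)
  U <- matrix(rnorm(300), 100, 3)
  a <- gene_pvalues(U, omega = 1:3)
  b <- gene_pvalues(U %*% diag(c(-1, 1, -1)), omega = 1:3)
  expect_identical(a$table$P, b$table$P)
})

test_that("gene_pvalues rejects degenerate inputs", {
  U <- matrix(rnorm(50), 25, 2)
  expect_error(gene_pvalues(U, omega = integer(0)), "non-empty")
  expect_error(gene_pvalues(U, omega = 3), "out of range")
  expect_error(gene_pvalues(cbind(rep(1, 25)), omega = 1), "sigma must be positive")
})

test_that("bh_adjust equals brute-force step-up on random vectors", {
  set.seed(22)
  worst <- 0
  for (rep in 1:50) {
    p <- runif(sample(1:200, 1))
    worst <- max(worst, max(abs(bh_adjust(p) - bh_bruteforce(p))))
  }
  expect_lt(worst, 1e-14)
  expect_identical(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("select_genes orders by adjusted P and applies a strict cutoff", {
  U <- matrix(c(10, 0.5, 8, 0.1), 4, 1,
              dimnames = list(c("w", "x", "y", "z"), NULL))
  sel <- bh_adjust_selection(gene_pvalues(U, 1, sigma = 1), threshold = 0.01)
  hits <- select_genes(sel)
  expect_identical(hits, c("w", "y"))
  none <- bh_adjust_selection(gene_pvalues(U, 1, sigma = 100), threshold = 0.01)
  expect_identical(select_genes(none), character(0))
  # strictly-below semantics
  sel$table$adjP <- c(0.01, 0.5, 0.009, 0.5)
  expect_identical(select_genes(sel, threshold = 0.01), "y")
})
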