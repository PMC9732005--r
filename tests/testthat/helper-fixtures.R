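# Shared fixture builders; everything is generated in code at test time.

random_matrix_study <- function(n = 50, m = 5, seed = 1, labels = NULL) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(n * m), n, m),
                    gene_ids = sprintf("g%03d", seq_len(n)),
                    sample_ids = sprintf("s%02d", seq_len(m)),
                    labels = labels)
}

random_tensor_study <- function(dims = c(30, 5, 4, 3), seed = 1) {
  set.seed(seed)
  arr <- array(rnorm(prod(dims)), dim = dims)
  dimnames(arr)[[1]] <- sprintf("g%03d", seq_len(dims[1]))
  expression_tensor(arr)
}

toy_bundle <- function() {
  # 4 genes x 3 cells with 5 stored non-zeros
  m <- Matrix::sparseMatrix(i = c(1, 2, 2, 3, 4), j = c(1, 1, 2, 3, 3),
                            x = c(5, 1, 2, 7, 3), dims = c(4, 3))
  scrna_bundle(m, gene_ids = paste0("g", 1:4), cell_ids = paste0("c", 1:3))
}

# independent upper-tail chi-squared oracle via numerical integration of the
# density (never calls pchisq)
chisq_upper_oracle <- function(x, df) {
  vapply(x, function(xi) {
    if (xi <= 0) return(1)
    stats::integrate(function(t) stats::dchisq(t, df = df),
                     lower = xi, upper = Inf,
                     rel.tol = 1e-12, abs.tol = 1e-14)$value
  }, numeric(1))
}

# brute-force Benjamini-Hochberg step-up
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}
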