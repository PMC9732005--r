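# Dense tensor algebra primitives: mode-n unfolding, folding, mode products,
# and the classical (truncated) higher-order SVD.

#' Mode-n unfolding of an array
#'
#' Returns the matricization of `a` along `mode`: rows index that mode,
#' columns enumerate the remaining modes in increasing order (column-major).
#'
#' @param a Numeric array.
#' @param mode Mode to place on the rows.
#' @return A matrix of size `dim(a)[mode]` x `prod(dim(a)[-mode])`.
#' @export
unfold <- function(a, mode) {
  d <- dim(a)
  stopifnot(mode >= 1, mode <= length(d))
  perm <- c(mode, seq_along(d)[-mode])
  m <- aperm(a, perm)
  dim(m) <- c(d[mode], prod(d[-mode]))
  m
}

#' Inverse of [unfold()]
#'
#' @param m Matrix produced by unfolding along `mode`.
#' @param mode Mode that sits on the rows of `m`.
#' @param dims Dimensions of the target array.
#' @return The folded array.
#' @export
fold <- function(m, mode, dims) {
  perm <- c(mode, seq_along(dims)[-mode])
  a <- array(m, dim = dims[perm])
  aperm(a, order(perm))
}

#' Mode-n product of a tensor with a matrix
#'
#' Contracts mode `mode` of `a` with the columns of `mat`:
#' the result's `mode` dimension becomes `nrow(mat)`.
#'
#' @param a Numeric array.
#' @param mat Matrix with `ncol(mat) == dim(a)[mode]`.
#' @param mode Mode to contract.
#' @return The transformed array.
#' @export
ttm <- function(a, mat, mode) {
  d <- dim(a)
  stopifnot(ncol(mat) == d[mode])
  m <- mat %*% unfold(a, mode)
  d[mode] <- nrow(mat)
  fold(m, mode, d)
}

# Deterministic sign convention: make each column's largest-magnitude element
# positive (first index on ties). All-zero columns are left untouched.
fix_column_signs <- function(u) {
  for (l in seq_len(ncol(u))) {
    i <- which.max(abs(u[, l]))
    if (length(i) && u[i, l] < 0) u[, l] <- -u[, l]
  }
  u
}

#' Higher-order singular value decomposition (Tucker/HOSVD)
#'
#' Classical (truncated) HOSVD: the factor matrix of each mode holds the
#' leading left singular vectors of that mode's unfolding, and the core is
#' the tensor contracted with the transposed factors. Factor columns follow a
#' deterministic sign convention (largest-magnitude element positive). At
#' full ranks the recomposition reproduces the input to numerical precision
#' and the core is all-orthogonal.
#'
#' @param a Numeric array (any number of modes >= 2).
#' @param ranks Integer vector of per-mode ranks; defaults to full ranks.
#' @return Object of class `hosvd_result`: `core` (array), `factors` (list of
#'   orthonormal matrices, one per mode), `ranks`, `dims`.
#' @export
hosvd <- function(a, ranks = dim(a)) {
  a <- as.array(a)
  d <- dim(a)
  stopifnot(length(d) >= 2)
  ranks <- as.integer(ranks)
  if (length(ranks) != length(d))
    stop("ranks must give one value per mode")
  if (any(ranks < 1) || any(ranks > d))
    stop("each rank must lie in [1, mode size]")
  factors <- vector("list", length(d))
  for (n in seq_along(d)) {
    unf <- unfold(a, n)
    sv <- svd(unf, nu = ranks[n], nv = 0)
    factors[[n]] <- fix_column_signs(sv$u[, seq_len(ranks[n]), drop = FALSE])
  }
  core <- a
  for (n in seq_along(d)) core <- ttm(core, t(factors[[n]]), n)
  structure(list(core = core, factors = factors, ranks = ranks, dims = d),
            class = "hosvd_result")
}

#' Recompose a tensor from its HOSVD
#'
#' @param h An `hosvd_result`.
#' @return The array `core x_1 U1 x_2 U2 ...` of the original dimensions.
#' @export
hosvd_reconstruct <- function(h) {
  a <- h$core
  for (n in seq_along(h$factors)) a <- ttm(a, h$factors[[n]], n)
  a
}

#' @export
print.hosvd_result <- function(x, ...) {
  cat(sprintf("<hosvd_result> dims (%s), ranks (%s)\n",
              paste(x$dims, collapse = " x "),
              paste(x$ranks, collapse = " x ")))
  invisible(x)
}
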