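test_that("generators are deterministic given a seed", {
  a <- generate_unmatched_studies(n_genes = 100, sizes = c(5, 6), planted = 10,
                                  seed = 50)
  b <- generate_unmatched_studies(n_genes = 100, sizes = c(5, 6), planted = 10,
                                  seed = 50)
  expect_identical(a$studies[[1]]$values, b$studies[[1]]$values)
  expect_identical(a$truth$planted_gene_ids, b$truth$planted_gene_ids)
  d1 <- generate_drug_tensor(n_genes = 80, drugs = 5, planted = 20, seed = 51)
  d2 <- generate_drug_tensor(n_genes = 80, drugs = 5, planted = 20, seed = 51)
  expect_identical(d1$tensor$values, d2$tensor$values)
  s1 <- generate_scrna_collection(n_measurements = 4, n_genes = 80, cells = 30,
                                  planted = 10, seed = 52)
  s2 <- generate_scrna_collection(n_measurements = 4, n_genes = 80, cells = 30,
                                  planted = 10, seed = 52)
  expect_identical(s1$bundles[[2]]$counts, s2$bundles[[2]]$counts)
})

test_that("planted structure matches the declared study design", {
  sim <- generate_unmatched_studies(n_genes = 500, sizes = c(9, 23, 8),
                                    planted = 50, effect = 3, seed = 53)
  expect_identical(length(sim$studies), 3L)
  expect_identical(vapply(sim$studies, function(s) ncol(s$values), integer(1)),
                   c(9L, 23L, 8L))
  expect_identical(length(sim$truth$planted_gene_ids), 50L)
  expect_true(all(sim$truth$planted_gene_ids %in% sim$studies[[1]]$gene_ids))
  # planted genes separate the classes, background genes do not
  x <- sim$studies[[1]]
  cls <- x$labels
  gap <- abs(rowMeans(x$values[, cls == "class1"]) -
             rowMeans(x$values[, cls == "class2"]))
  planted <- x$gene_ids %in% sim$truth$planted_gene_ids
  expect_gt(mean(gap[planted]), 3 * mean(gap[!planted]))
})

test_that("generated studies satisfy the normalization contract", {
  sim <- generate_unmatched_studies(n_genes = 200, sizes = c(6, 7), planted = 20,
                                    seed = 54)
  nx <- normalize_per_sample(sim$studies[[2]])
  expect_lt(max(abs(colSums(nx$values))), 1e-9 * 200)
  expect_lt(max(abs(colSums(nx$values^2) - 200)), 1e-6 * 200)
})

test_that("drug tensors respond monotonically in dose with shared replicates", {
  d <- generate_drug_tensor(n_genes = 300, drugs = 6, doses = 4, reps = 3,
                            effective = 2, effect = 4, seed = 55)
  eff <- match(d$truth$effective_drug_ids, dimnames(d$tensor$values)[[2]])
  prog <- match(names(d$truth$program), d$tensor$gene_ids)
  signs <- as.numeric(d$truth$program)
  # mean signed response of the planted program rises with dose
  resp <- sapply(1:4, function(dose)
    mean(signs * rowMeans(d$tensor$values[prog, eff, dose, ])))
  expect_true(all(diff(resp) > 0))
  # ineffective drugs carry no signed response
  noneff <- setdiff(1:6, eff)
  flat <- mean(signs * rowMeans(d$tensor$values[prog, noneff, 4, ]))
  expect_lt(abs(flat), resp[4] / 10)
})

test_that("zero drug effect produces flat scores", {
  d <- generate_drug_tensor(n_genes = 120, drugs = 6, effective = 2,
                            effect = 0, seed = 56)
  proj <- array(d$tensor$values[1:4, , , ], dim = c(4, 6, 4, 3))
  res <- nested_hosvd_drug(proj, T = 1)
  # no drug dominates: top score comparable to the uniform share
  expect_lt(max(res$drug_scores[, 1]), 0.9)
})

test_that("scrna collections have configured sparsity and group labels", {
  sc <- generate_scrna_collection(n_measurements = 6, n_genes = 200,
                                  cells = 80, planted = 40, seed = 57,
                                  keep_prob = 0.4)
  expect_identical(length(sc$bundles), 6L)
  expect_identical(nlevels(sc$truth$groups), 4L)
  zero_frac <- mean(as.matrix(sc$bundles[[1]]$counts) == 0)
  expect_gt(zero_frac, 0.4)
  expect_lt(zero_frac, 0.95)
  arms <- ifelse(grepl("case", sc$truth$groups), 1, -1)
  expect_identical(sum(arms), 0)            # arms balanced
})
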