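test_that("count filtering drops shallow samples then rare genes, strictly", {
  # boundary at the sample threshold: 5999 vs 6000 nonzero genes
  g <- 6500
  counts <- matrix(0L, g, 3,
                   dimnames = list(sprintf("g%04d", 1:g),
                                   c("deep", "edge", "shallow")))
  counts[, "deep"] <- 1L
  counts[1:6000, "edge"] <- 1L
  counts[1:5999, "shallow"] <- 1L
  res <- filter_counts(counts, min_nonzero_samples = 0)
  expect_setequal(colnames(res$counts), c("deep", "edge"))
  expect_identical(res$report$dropped_samples, "shallow")

  # boundary at the gene threshold: nonzero in 29 vs 30 samples
  counts2 <- matrix(1L, 3, 35,
                    dimnames = list(c("common", "edge", "rare"),
                                    sprintf("s%02d", 1:35)))
  counts2["edge", 31:35] <- 0L   # nonzero in 30
  counts2["rare", 30:35] <- 0L   # nonzero in 29
  res2 <- filter_counts(counts2, min_nonzero_genes = 1)
  expect_setequal(rownames(res2$counts), c("common", "edge"))
  expect_identical(res2$report$dropped_genes, "rare")

  # alternative total-count reading of the gene rule
  counts3 <- matrix(0L, 2, 5, dimnames = list(c("hi", "lo"),
                                              sprintf("s%d", 1:5)))
  counts3["hi", 1] <- 30L
  counts3["lo", 1] <- 29L
  res3 <- filter_counts(counts3, min_nonzero_genes = 0,
                        gene_mode = "total")
  expect_identical(rownames(res3$counts), "hi")
  expect_error(filter_counts(matrix(-1, 1, 1,
                                    dimnames = list("g", "s"))),
               "non-negative")
})

test_that("count filtering is idempotent on simulated shallow cohorts", {
  cfg <- sim_config(n_neurons = 142, n_genes = 400,
                    shallow_frac = 52 / 142, rare_gene_frac = 0.1,
                    seed = 19)
  counts <- simulate_counts(cfg)
  res <- filter_counts(counts, min_nonzero_genes = 200,
                       min_nonzero_samples = 30)
  again <- filter_counts(res$counts, min_nonzero_genes = 200,
                         min_nonzero_samples = 30)
  expect_identical(res$counts, again$counts)
  expect_setequal(res$report$dropped_samples,
                  attr(counts, "shallow_samples"))
})

test_that("PCA tails harvest the planted factor's driver genes", {
  set.seed(55)
  n <- 60; g <- 200
  drivers <- sprintf("g%03d", 1:10)
  loadvec <- rep(0, g); loadvec[1:10] <- c(rep(2, 5), rep(-2, 5))
  scores <- rnorm(n, sd = 3)
  x <- outer(loadvec, scores) + matrix(rnorm(g * n, sd = 0.3), g, n)
  dimnames(x) <- list(sprintf("g%03d", 1:g), sprintf("s%02d", 1:n))
  hv <- pca_variable_genes(x, n_pcs = 2, n_per_tail = 5)
  expect_true(all(drivers %in% hv))
  prov <- attr(hv, "provenance")
  expect_setequal(prov$gene_id[prov$pc == 1], drivers)
  expect_equal(nrow(prov), 2 * 2 * 5)
  # the union deduplicates across components
  expect_lte(length(hv), nrow(prov))
})

test_that("a 3-gene toy matches the hand-computed leading eigenvector", {
  # g1 and g2 carry the variance in opposite directions; g3 is inert
  x <- rbind(g1 = c(-3, -1, 1, 3), g2 = c(3, 1, -1, -3),
             g3 = c(0.01, -0.01, 0.01, -0.01))
  colnames(x) <- sprintf("s%d", 1:4)
  hv <- pca_variable_genes(x, n_pcs = 1, n_per_tail = 1)
  expect_setequal(hv, c("g1", "g2"))
})

test_that("PCA-tail selection is invariant to sample order and scale", {
  set.seed(56)
  x <- matrix(rnorm(120 * 40), 120, 40,
              dimnames = list(sprintf("g%03d", 1:120),
                              sprintf("s%02d", 1:40)))
  hv <- pca_variable_genes(x, n_pcs = 5, n_per_tail = 10)
  hv_perm <- pca_variable_genes(x[, sample(40)], n_pcs = 5,
                                n_per_tail = 10)
  expect_setequal(hv, hv_perm)
  hv_scaled <- pca_variable_genes(7 * x, n_pcs = 5, n_per_tail = 10)
  expect_setequal(hv, hv_scaled)
  expect_error(pca_variable_genes(x, n_pcs = 41), "n_pcs")
  expect_error(pca_variable_genes(x[1:10, ], n_pcs = 2, n_per_tail = 10),
               "n_per_tail")
})

test_that("template enrichment recovers the planted neuronal genes", {
  panel <- simulate_tissue_panel(n_tissues = 25, n_neuronal = 8,
                                 n_genes = 400, n_enriched = 40,
                                 seed = 61)
  hits <- template_enrichment(panel)
  sens <- mean(panel$enriched_genes %in% hits)
  expect_gte(sens, 0.95)
  stats <- attr(hits, "stats")
  expect_true(all(stats$r[stats$gene_id %in% hits] > 0))
  # a gene expressed only in neuronal tissues is selected
  expr <- panel$expr
  expr["g0001", ] <- c(rep(10, 8), rep(0, 17))
  hits2 <- template_enrichment(list(expr = expr,
                                    neuronal_tissues =
                                      panel$neuronal_tissues))
  expect_true("g0001" %in% hits2)
  # a uniform gene is untestable and excluded
  expr["g0002", ] <- 5
  hits3 <- template_enrichment(list(expr = expr,
                                    neuronal_tissues =
                                      panel$neuronal_tissues))
  expect_false("g0002" %in% attr(hits3, "stats")$gene_id)
})

test_that("a null panel yields about the one-sided nominal hit rate", {
  panel <- simulate_tissue_panel(n_tissues = 30, n_neuronal = 10,
                                 n_genes = 1000, n_enriched = 0,
                                 seed = 62)
  hits <- template_enrichment(panel, p_max = 0.01)
  # two-sided p < 0.01 restricted to r > 0: expect ~0.5% of genes
  expect_lte(length(hits), qbinom(0.999, 1000, 0.005) + 3)
})
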