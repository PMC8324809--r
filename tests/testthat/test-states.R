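# helpers: two well-separated planted blocks over 20 genes
planted_blocks <- function(n_per = 4, n_genes = 20, sd = 0.3, seed = 101) {
  set.seed(seed)
  a <- c(rep(2, n_genes / 2), rep(-2, n_genes / 2))
  b <- -a
  x <- cbind(
    matrix(rep(a, n_per), n_genes) + rnorm(n_genes * n_per, sd = sd),
    matrix(rep(b, n_per), n_genes) + rnorm(n_genes * n_per, sd = sd))
  dimnames(x) <- list(sprintf("g%02d", 1:n_genes),
                      sprintf("s%02d", 1:(2 * n_per)))
  with_stage(x)
}

test_that("profile clustering recovers planted blocks and handles edge cuts", {
  x <- planted_blocks()
  lab <- hcluster_profiles(x, k = 2)
  expect_identical(unname(lab[1:4] == lab[1]), rep(TRUE, 4))
  expect_identical(unname(lab[5:8] == lab[5]), rep(TRUE, 4))
  expect_false(lab[1] == lab[5])
  # duplicate profiles always co-cluster
  x2 <- x
  x2[, "s08"] <- x2[, "s01"]
  lab2 <- hcluster_profiles(x2, k = 3)
  expect_identical(lab2[["s08"]], lab2[["s01"]])
  # k = n gives singletons
  lab3 <- hcluster_profiles(x, k = 8)
  expect_identical(sort(unname(lab3)), 1:8)
  expect_error(hcluster_profiles(x, k = 9), "at least")
})

test_that("insufficient gene overlap between samples is an error naming the pair", {
  x <- with_stage(toy_matrix(rnorm(40), 10, 4))
  x[3:10, "s02"] <- NA  # shares only 2 genes with everyone
  expect_error(hcluster_profiles(x, k = 2), "s02")
})

test_that("silhouette widths match the brute-force a/b definition", {
  x <- planted_blocks(n_per = 2)  # 4 samples
  lab <- c(1, 1, 2, 2)
  D <- 1 - cor(unclass(x))
  sil <- cluster::silhouette(lab, as.dist(D))
  expect_equal(unname(sil[, "sil_width"]), brute_silhouette(D, lab),
               tolerance = 1e-9)
  res <- silhouette_with_null(x, lab, n_perm = 99, seed = 1)
  expect_equal(res$mean_width, mean(brute_silhouette(D, lab)),
               tolerance = 1e-9)
})

test_that("separated clusters beat the size-preserving permutation null", {
  x <- planted_blocks(n_per = 6)
  lab <- rep(1:2, each = 6)
  res <- silhouette_with_null(x, lab, n_perm = 1000, seed = 7)
  expect_gt(res$mean_width, 0.5)
  expect_lte(res$p_value, 0.01)
  expect_length(res$null, 1000)
  # permutations preserve cluster sizes -> p has the add-one form
  expect_gte(res$p_value, 1 / 1001)
  expect_error(silhouette_with_null(x, seq_len(ncol(x))), "two clusters")
})

test_that("templates are per-gene cluster medians", {
  x <- with_stage(toy_matrix(c(0, 0, 1, 2, 5, 4, 9, 9), 2, 4))
  lab <- c(1, 1, 1, 2)
  fit <- build_templates(x, lab)
  # cluster 1 rows: g01 over (0,1,5) -> 1; g02 over (0,2,4) -> 2
  expect_equal(unname(fit$templates[, "S1"]), c(1, 2))
  # single-member cluster template equals that profile
  expect_equal(unname(fit$templates[, "S2"]), c(9, 9))
  # oracle on richer data
  sim <- simulate_qpcr(sim_config(n_neurons = 40, n_genes = 15, seed = 3))
  dd <- neg_delta_delta_ct(neg_delta_ct(sim$ct, robust_gene_set(sim$ct)))
  lab2 <- rep(1:4, each = 10)
  fit2 <- build_templates(dd, lab2)
  for (s in 1:4) {
    oracle <- apply(dd[, lab2 == s], 1, median, na.rm = TRUE)
    expect_equal(fit2$templates[, paste0("S", s)], oracle,
                 tolerance = 1e-12)
  }
})

test_that("template-matching correlation follows the textbook t transform", {
  p <- c(1.2, -0.5, 3.1, 0.4, -2.2)
  t1 <- c(0.9, -0.1, 2.5, 0.0, -1.8)
  res <- ptm_correlate(p, t1)
  expect_equal(res$r, brute_pearson(p, t1), tolerance = 1e-12)
  tstat <- res$r * sqrt((5 - 2) / (1 - res$r^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), 3), tolerance = 1e-12)
  expect_equal(ptm_correlate(p, p)$r, 1)
  expect_equal(ptm_correlate(p, -p)$r, -1)
  expect_true(is.na(ptm_correlate(p, rep(1, 5))$r))   # zero variance
  expect_error(ptm_correlate(c(1, 2, NA, NA, NA), t1), "3 jointly")
})

test_that("assignment takes the best template above threshold, else sequesters", {
  x <- planted_blocks(n_per = 4)
  fit <- state_model(x, k = 2)
  asg <- predict(fit, x)
  expect_s3_class(asg, "state_assignment")
  # a profile equal to a template matches it exactly
  probe <- fit$templates[, "S1", drop = FALSE]
  colnames(probe) <- "probe"
  pa <- predict(fit, probe)
  expect_identical(pa$state, "S1")
  expect_equal(pa$best_r, 1)
  # assigned iff best_r >= r_min (strict boundary behavior)
  r_best <- asg$best_r[1]
  expect_identical(predict(fit, x, r_min = r_best)$state[1], asg$state[1])
  expect_identical(predict(fit, x, r_min = r_best + 1e-9)$state[1],
                   "sequestered")
  # all templates below threshold -> sequestered
  far <- matrix(rep(c(1, -1), 10) * 3, 20, 1,
                dimnames = list(rownames(x), "far"))
  far[, 1] <- far[, 1] + rnorm(20, sd = 0.1)
  all_r <- attr(predict(fit, far, r_min = -1), "all_r")
  if (max(all_r) < 0.45)
    expect_identical(predict(fit, far)$state, "sequestered")
})

test_that("raising the threshold only ever moves samples into sequestration", {
  sim <- simulate_qpcr(sim_config(n_neurons = 100, n_genes = 40,
                                  n_states = 3, state_softness = 0.3,
                                  seed = 23))
  dd <- neg_delta_delta_ct(neg_delta_ct(sim$ct, robust_gene_set(sim$ct)))
  fit <- state_model(dd, k = 3)
  thresholds <- c(0.2, 0.45, 0.7, 0.9)
  prev <- predict(fit, dd, r_min = thresholds[1])$state
  for (r in thresholds[-1]) {
    cur <- predict(fit, dd, r_min = r)$state
    moved <- prev != cur
    expect_true(all(cur[moved] == "sequestered"))
    prev <- cur
  }
})

test_that("training samples re-assign to their own clusters on discrete data", {
  sim <- simulate_qpcr(sim_config(n_neurons = 200, n_genes = 100,
                                  n_states = 4, state_softness = 0,
                                  seed = 31))
  dd <- neg_delta_delta_ct(neg_delta_ct(sim$ct, robust_gene_set(sim$ct)))
  fit <- state_model(dd, k = 4)
  asg <- predict(fit, dd)
  back <- mean(asg$state == fit$labels[asg$sample_id])
  expect_gte(back, 0.9)
})

test_that("state merging rebuilds templates and keeps the map total", {
  x <- planted_blocks(n_per = 4)
  fit <- state_model(x, k = 4)
  merged <- merge_states(fit, list(A = c("S1", "S3")))
  expect_length(merged$state_ids, 3)
  expect_true(all(fit$state_ids %in% names(merged$merge_map)))
  pooled <- names(fit$labels)[fit$labels %in% c("S1", "S3")]
  oracle <- apply(fit$data[, pooled], 1, median, na.rm = TRUE)
  expect_equal(merged$templates[, "A"], oracle, tolerance = 1e-12)
  # merging identical-template states leaves the template unchanged
  x2 <- x
  x2[, 3:4] <- x2[, 1:2]
  fit2 <- build_templates(with_stage(unclass(x2)), c(1, 1, 2, 2, 3, 3, 3, 3))
  m2 <- merge_states(fit2, list(AB = c("S1", "S2")))
  expect_equal(m2$templates[, "AB"], fit2$templates[, "S1"],
               tolerance = 1e-12)
  # an empty merge specification is the identity
  expect_identical(merge_states(fit2, list())$templates, fit2$templates)
  # an 8-state model merged 3-into-1 yields 6 states
  sim <- simulate_qpcr(sim_config(n_neurons = 120, n_genes = 50,
                                  n_states = 8, state_softness = 0,
                                  seed = 5))
  dd <- neg_delta_delta_ct(neg_delta_ct(sim$ct, robust_gene_set(sim$ct)))
  fit8 <- state_model(dd, k = 8)
  m6 <- merge_states(fit8, list(A = c("S1", "S2", "S3")))
  expect_length(m6$state_ids, 6)
  expect_error(merge_states(fit8, list(c("S1", "S2"), c("S2", "S4"))),
               "disjoint")
  expect_error(merge_states(fit8, list(c("S1", "S99"))), "S99")
})

test_that("merge suggestions link states with near-identical templates", {
  x <- planted_blocks(n_per = 4)
  x2 <- cbind(unclass(x), unclass(x)[, 1:4] +
                matrix(rnorm(80, sd = 0.05), 20))
  colnames(x2) <- sprintf("s%02d", 1:12)
  fit <- build_templates(with_stage(x2), c(rep(1, 4), rep(2, 4), rep(3, 4)))
  sug <- suggest_merges(fit, r_threshold = 0.95)
  expect_length(sug, 1)
  expect_setequal(sug[[1]], c("S1", "S3"))
})

test_that("state enrichment requires dominance over at least two other states", {
  set.seed(77)
  n_per <- 20
  states <- rep(paste0("S", 1:4), each = n_per)
  x <- matrix(rnorm(3 * 4 * n_per, sd = 1), 3, 4 * n_per,
              dimnames = list(c("up_in_s2", "flat", "two_high"),
                              sprintf("n%03d", seq_len(4 * n_per))))
  x["up_in_s2", states == "S2"] <- x["up_in_s2", states == "S2"] + 5
  # high in S1 and S3: beats only the two low states, each beaten by both
  x["two_high", states %in% c("S1", "S3")] <-
    x["two_high", states %in% c("S1", "S3")] + 5
  res <- state_enrichment(with_stage(x), setNames(states, colnames(x)))
  expect_true(res$enriched[res$gene_id == "up_in_s2" & res$state == "S2"])
  expect_false(any(res$enriched[res$gene_id == "flat"]))
  # S1 dominates S2 and S4 -> enriched; but a gene high in one state vs
  # exactly one other must not be flagged:
  y <- matrix(rnorm(2 * 3 * n_per, sd = 1), 2, 3 * n_per,
              dimnames = list(c("one_win", "ctl"),
                              sprintf("m%03d", seq_len(3 * n_per))))
  st3 <- rep(paste0("S", 1:3), each = n_per)
  # S1 and S3 high, S2 low: S1 beats only S2
  y["one_win", st3 != "S2"] <- y["one_win", st3 != "S2"] + 5
  res2 <- state_enrichment(with_stage(y), setNames(st3, colnames(y)))
  expect_false(res2$enriched[res2$gene_id == "one_win" &
                               res2$state == "S1"])
  # constant genes are untestable and excluded
  z <- rbind(y, const = 1)
  res3 <- state_enrichment(with_stage(z), setNames(st3, colnames(z)))
  expect_true("const" %in% attr(res3, "untestable"))
  expect_false("const" %in% res3$gene_id)
})

test_that("model printing and summaries expose the fitted structure", {
  x <- planted_blocks(n_per = 4)
  fit <- state_model(x, k = 2)
  expect_output(print(fit), "r_min = 0.45")
  s <- summary(fit)
  expect_s3_class(s, "summary.state_model")
  expect_output(print(s), "Template-template")
})
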