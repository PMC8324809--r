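# Shared fixtures and independent brute-force oracles.

# Small genes x samples matrix with dimnames.
toy_matrix <- function(values, n_genes, n_samples,
                       genes = sprintf("g%02d", seq_len(n_genes)),
                       samples = sprintf("s%02d", seq_len(n_samples))) {
  matrix(values, n_genes, n_samples, dimnames = list(genes, samples))
}

# Tag a handmade matrix with a normalization stage.
with_stage <- function(x, stage = "neg_ddct") {
  attr(x, "stage") <- stage
  x
}

# Brute-force silhouette widths from the a/b definition, given a full
# distance matrix and labels.
brute_silhouette <- function(D, labels) {
  n <- length(labels)
  vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(D[i, labels == cl])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# Brute-force BH step-up adjustment.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# Textbook Pearson correlation via covariance over sd products.
brute_pearson <- function(a, b) {
  n <- length(a)
  ca <- a - mean(a); cb <- b - mean(b)
  sum(ca * cb) / ((n - 1) * sd(a) * sd(b))
}

# Expected paracrine edges enumerated directly from a flags data.frame
# (producer: subtype -> peptide; receiver: peptide -> subtype).
brute_edges <- function(flags, sets, categories) {
  ids <- categorize(flags)
  out <- list()
  for (cid in categories) {
    i <- match(cid, ids)
    for (s in sets) {
      if (flags[[paste0(s$name, "_pep")]][i])
        out[[length(out) + 1]] <- c(cid, s$name, "producer")
      if (flags[[paste0(s$name, "_rec")]][i])
        out[[length(out) + 1]] <- c(s$name, cid, "receiver")
    }
  }
  ed <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(ed) <- c("from", "to", "role")
  ed[order(ed$from, ed$to, ed$role), ]
}

# Flags data.frame covering every (peptide, receptor) sign combination
# exactly once per planted replicate. Built as an expression matrix so
# the median-binarization path is exercised: value 1 = above the mixed
# 0/1 gene median of 0.5, value 0 = below.
exhaustive_cohort <- function(sets = default_peptide_sets(),
                              replicate_categories = character(0),
                              n_extra = 12) {
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), 2 * length(sets)))
  genes <- unlist(lapply(sets, function(s) c(s$peptide, s$receptors[1])))
  all_genes <- unlist(lapply(sets, function(s) c(s$peptide, s$receptors)))
  x <- matrix(0, length(all_genes), nrow(combos),
              dimnames = list(all_genes,
                              sprintf("n%03d", seq_len(nrow(combos)))))
  for (j in seq_len(nrow(combos)))
    x[genes, j] <- as.numeric(unlist(combos[j, ]))
  # fixed medians: replicated columns must not shift the cutoffs
  med <- setNames(rep(0.5, length(all_genes)), all_genes)
  flags0 <- binarize_flags(with_stage(x), sets, medians = med)
  ids <- categorize(flags0)
  for (cid in replicate_categories) {
    src <- which(ids == cid)[1]
    extra <- x[, rep(src, n_extra), drop = FALSE]
    colnames(extra) <- sprintf("%s_r%02d", cid, seq_len(n_extra))
    x <- cbind(x, extra)
  }
  binarize_flags(with_stage(x), sets, medians = med)
}
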