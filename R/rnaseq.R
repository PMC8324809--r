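#' Filter an RNA-seq count matrix
#'
#' Two-step quality filter applied to a UMI count matrix (genes x
#' samples): first, samples whose number of genes with nonzero counts is
#' strictly below `min_nonzero_genes` are dropped as shallow outliers;
#' then genes nonzero in strictly fewer than `min_nonzero_samples` of
#' the surviving samples are dropped as rare. The order (samples, then
#' genes) is fixed because the outcome depends on it. An alternative
#' reading of the rare-gene rule, dropping genes whose total count is
#' below the threshold, is available via `gene_mode = "total"`.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param min_nonzero_genes sample retention threshold (default 6000).
#' @param min_nonzero_samples gene retention threshold (default 30).
#' @param gene_mode `"samples"` (nonzero in >= threshold samples,
#'   default) or `"total"` (total counts >= threshold).
#' @return list with `counts` (filtered matrix) and `report`
#'   (`dropped_samples`, `dropped_genes`, thresholds and dimensions).
#' @export
filter_counts <- function(counts, min_nonzero_genes = 6000,
                          min_nonzero_samples = 30,
                          gene_mode = c("samples", "total")) {
  check_expr_matrix(counts, "counts")
  gene_mode <- match.arg(gene_mode)
  if (min_nonzero_genes < 0 || min_nonzero_samples < 0)
    stop("thresholds must be >= 0", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)

  nz_genes <- colSums(counts > 0)
  keep_s <- nz_genes >= min_nonzero_genes
  c1 <- counts[, keep_s, drop = FALSE]

  stat <- if (gene_mode == "samples") rowSums(c1 > 0) else rowSums(c1)
  keep_g <- stat >= min_nonzero_samples
  out <- c1[keep_g, , drop = FALSE]

  if (nrow(out) == 0 || ncol(out) == 0)
    warning("count filtering left an empty matrix", call. = FALSE)

  list(counts = out,
       report = list(
         dropped_samples = colnames(counts)[!keep_s],
         dropped_genes = rownames(c1)[!keep_g],
         min_nonzero_genes = min_nonzero_genes,
         min_nonzero_samples = min_nonzero_samples,
         gene_mode = gene_mode,
         n_samples = c(before = ncol(counts), after = ncol(out)),
         n_genes = c(before = nrow(counts), after = nrow(out))))
}

#' Highly variable genes from PCA loading tails
#'
#' Selects variable genes from the tails of principal-component
#' loadings: the expression matrix is centered per gene (not scaled, so
#' loadings reflect expression variability) and decomposed by PCA over
#' samples; from each of the first `n_pcs` components the `n_per_tail`
#' genes with the largest positive and largest negative loadings are
#' taken, and the deduplicated union is returned. With the default 50
#' PCs and 50 genes per tail, up to 5,000 slots collapse to the unique
#' variable-gene set.
#'
#' @param x normalized expression matrix, genes x samples.
#' @param n_pcs number of leading components to harvest (default 50).
#' @param n_per_tail genes per tail per component (default 50).
#' @return character vector of unique gene ids (ordered by the first
#'   component that selected them), with attribute `"provenance"`: a
#'   data.frame of `gene_id`, `pc`, `tail` for every selection.
#' @export
pca_variable_genes <- function(x, n_pcs = 50, n_per_tail = 50) {
  check_expr_matrix(x, "x")
  if (nrow(x) < 2 * n_per_tail)
    stop("need at least 2 * n_per_tail = ", 2 * n_per_tail,
         " genes, got ", nrow(x), call. = FALSE)
  if (ncol(x) < n_pcs)
    stop("need at least n_pcs = ", n_pcs, " samples, got ", ncol(x),
         call. = FALSE)
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE)
  avail <- ncol(pc$rotation)
  if (avail < n_pcs)
    stop("only ", avail, " components available for n_pcs = ", n_pcs,
         call. = FALSE)
  prov <- vector("list", n_pcs)
  for (j in seq_len(n_pcs)) {
    load <- pc$rotation[, j]
    ord <- order(load)
    neg <- names(load)[ord[seq_len(n_per_tail)]]
    pos <- names(load)[rev(ord)[seq_len(n_per_tail)]]
    prov[[j]] <- data.frame(
      gene_id = c(pos, neg), pc = j,
      tail = rep(c("positive", "negative"), each = n_per_tail),
      stringsAsFactors = FALSE)
  }
  prov <- do.call(rbind, prov)
  genes <- unique(prov$gene_id)
  attr(genes, "provenance") <- prov
  genes
}

#' Neuronal-tissue template enrichment
#'
#' Identifies genes specifically enriched in a designated subset of
#' tissues of a median-expression panel by correlating each gene's
#' tissue profile with the binary template (1 for neuronal tissues, 0
#' elsewhere) via [ptm_correlate()]. Genes with positive correlation
#' and `p < p_max` are returned; constant genes are untestable and
#' excluded.
#'
#' @param panel a `"tissue_panel"` (from [simulate_tissue_panel()] or a
#'   list with `expr` and `neuronal_tissues`), or a genes x tissues
#'   matrix if `neuronal_tissues` is supplied.
#' @param p_max p-value threshold (default 0.01).
#' @param neuronal_tissues tissue ids forming the template maximum;
#'   taken from the panel when omitted.
#' @return character vector of enriched gene ids with attribute
#'   `"stats"` (data.frame of `gene_id`, `r`, `p` for all testable
#'   genes).
#' @export
template_enrichment <- function(panel, p_max = 0.01,
                                neuronal_tissues = NULL) {
  if (inherits(panel, "tissue_panel") ||
      (is.list(panel) && !is.null(panel$expr))) {
    expr <- panel$expr
    neuronal_tissues <- neuronal_tissues %||% panel$neuronal_tissues
  } else {
    expr <- panel
  }
  check_expr_matrix(expr, "panel")
  if (is.null(neuronal_tissues) || length(neuronal_tissues) == 0)
    stop("neuronal_tissues must be supplied", call. = FALSE)
  if (!all(neuronal_tissues %in% colnames(expr)))
    stop("neuronal_tissues must be a subset of the panel tissues",
         call. = FALSE)
  if (length(neuronal_tissues) >= ncol(expr))
    stop("neuronal_tissues must be a proper subset of tissues",
         call. = FALSE)
  if (ncol(expr) < 3) stop("need at least 3 tissues", call. = FALSE)
  template <- as.numeric(colnames(expr) %in% neuronal_tissues)
  stats <- lapply(rownames(expr), function(g) {
    res <- ptm_correlate(expr[g, ], template)
    data.frame(gene_id = g, r = res$r, p = res$p,
               stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, stats)
  stats <- stats[is.finite(stats$r), , drop = FALSE]
  hits <- stats$gene_id[stats$r > 0 & stats$p < p_max]
  attr(hits, "stats") <- stats
  hits
}
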