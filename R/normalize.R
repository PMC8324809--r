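#' Median-reference normalization (-dCt)
#'
#' Normalizes raw Ct values against the per-sample median expression of a
#' reference gene set:
#' \deqn{-\Delta Ct(g, s) = \mathrm{median}_{r \in ref}\, Ct(r, s) - Ct(g, s)}
#' so that higher values mean higher expression (log2-like scale, one
#' unit ~ 2-fold). The reference is typically the robustly expressed gene
#' set ([robust_gene_set()]), whose median vector is more stable than any
#' single housekeeping gene (see [stability_rank()]).
#'
#' @param ct genes x samples Ct matrix, `NA` = failed reaction.
#' @param reference_genes non-empty character vector of reference gene
#'   ids present in `ct`.
#' @return matrix of -dCt values with attribute `stage = "neg_dct"`;
#'   missing Ct values stay missing.
#' @export
neg_delta_ct <- function(ct, reference_genes) {
  check_expr_matrix(ct, "ct")
  if (length(reference_genes) == 0)
    stop("reference_genes must be non-empty", call. = FALSE)
  missing_ref <- setdiff(reference_genes, rownames(ct))
  if (length(missing_ref))
    stop("reference gene(s) not in matrix: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  ref <- apply(ct[reference_genes, , drop = FALSE], 2, median, na.rm = TRUE)
  dead <- colnames(ct)[!is.finite(ref)]
  if (length(dead))
    stop("sample(s) with no present reference gene: ",
         paste(dead, collapse = ", "), call. = FALSE)
  out <- sweep(-ct, 2, ref, "+")    # ref[s] - ct[g, s]
  set_stage(out, "neg_dct")
}

#' Per-gene median centering (-ddCt)
#'
#' Rescales -dCt values by the across-sample median within each gene:
#' \deqn{-\Delta\Delta Ct(g, s) = -\Delta Ct(g, s) -
#'   \mathrm{median}_{s'}\, (-\Delta Ct(g, s'))}
#' so every gene's median over samples is zero and positive values mean
#' above-typical expression for that gene. The centering median is pooled
#' across all samples by default; pass `groups` (e.g. animal ids, one per
#' sample) to center within groups instead.
#'
#' @param ndct matrix at stage `"neg_dct"` from [neg_delta_ct()].
#' @param groups optional per-sample grouping for within-group centering.
#' @return matrix of -ddCt values with `stage = "neg_ddct"` and
#'   attribute `"centering_medians"` (the subtracted per-gene medians;
#'   a genes x group matrix when `groups` is given).
#' @export
neg_delta_delta_ct <- function(ndct, groups = NULL) {
  check_expr_matrix(ndct, "ndct")
  require_stage(ndct, "neg_dct", "ndct")
  all_missing <- rownames(ndct)[rowSums(!is.na(ndct)) == 0]
  if (length(all_missing))
    warning("gene(s) with all values missing left unchanged: ",
            paste(all_missing, collapse = ", "), call. = FALSE)
  if (is.null(groups)) {
    med <- apply(ndct, 1, median, na.rm = TRUE)
    out <- ndct - med
  } else {
    if (length(groups) != ncol(ndct))
      stop("groups must have one entry per sample", call. = FALSE)
    out <- ndct
    med <- sapply(split(seq_len(ncol(ndct)), groups), function(idx) {
      m <- apply(ndct[, idx, drop = FALSE], 1, median, na.rm = TRUE)
      out[, idx] <<- ndct[, idx, drop = FALSE] - m
      m
    })
  }
  out <- set_stage(out, "neg_ddct")
  attr(out, "centering_medians") <- med
  out
}

#' Reference-gene stability ranking
#'
#' Ranks candidate reference genes by a pairwise-variation stability
#' measure in the geNorm tradition: for each gene, the mean over all
#' other candidates of the standard deviation of the pairwise Ct
#' log-ratios (differences, since Ct is already log-scale). Lower scores
#' mean more stable expression. Used to justify normalizing against the
#' median of a robust gene set rather than individual housekeeping genes.
#'
#' @param ct genes x samples Ct matrix.
#' @param candidate_genes at least three candidate gene ids.
#' @return data.frame with columns `gene` and `stability`, sorted most
#'   stable first (ties keep input order).
#' @export
stability_rank <- function(ct, candidate_genes) {
  check_expr_matrix(ct, "ct")
  if (length(candidate_genes) < 3)
    stop("need at least 3 candidate genes", call. = FALSE)
  missing <- setdiff(candidate_genes, rownames(ct))
  if (length(missing))
    stop("candidate gene(s) not in matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  x <- ct[candidate_genes, , drop = FALSE]
  n <- length(candidate_genes)
  m <- vapply(seq_len(n), function(j) {
    v <- vapply(setdiff(seq_len(n), j), function(k) {
      sd(x[j, ] - x[k, ], na.rm = TRUE)
    }, numeric(1))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(gene = candidate_genes, stability = m,
                    stringsAsFactors = FALSE)
  out[order(out$stability), , drop = FALSE]
}

#' Back-transform -ddCt to Ct space for plotting
#'
#' Re-expresses median-centered values on the familiar Ct scale (lower =
#' more abundant) while preserving the normalized range:
#' \deqn{Ct_{plot}(g, s) = -(-\Delta\Delta Ct(g, s)) + \mathrm{median}\,Ct(g)}
#' The operation is the algebraic inverse of centering followed by sign
#' flip, so `-(to_ct_space(x, m) - m)` recovers `x`.
#'
#' @param nddct matrix at stage `"neg_ddct"`.
#' @param gene_ct_medians named per-gene median raw Ct values (one per
#'   gene in `nddct`).
#' @return matrix in Ct units, stage `"ct_space"`.
#' @export
to_ct_space <- function(nddct, gene_ct_medians) {
  check_expr_matrix(nddct, "nddct")
  require_stage(nddct, "neg_ddct", "nddct")
  missing <- setdiff(rownames(nddct), names(gene_ct_medians))
  if (length(missing))
    stop("missing gene median(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- -nddct + gene_ct_medians[rownames(nddct)]
  set_stage(out, "ct_space")
}
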