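#' Read a Ct matrix from a delimited file
#'
#' Parses a genes x samples table of qPCR cycle-threshold values. The
#' first column holds gene ids and the header holds sample ids. Cells
#' equal to `failed_marker` (and empty cells) are recorded as `NA`,
#' i.e. failed reactions.
#'
#' @param path path to a tab- or comma-delimited file (comma assumed for
#'   `.csv`, tab otherwise; override with `sep`).
#' @param failed_marker token marking a failed reaction (default `"999"`,
#'   a common instrument convention).
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return numeric matrix (genes x samples) with `NA` for failed
#'   reactions.
#' @export
read_ct_matrix <- function(path, failed_marker = "999", sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  if (anyDuplicated(genes))
    stop("duplicated gene id(s) in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(samples))
    stop("duplicated sample id(s) in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells[cells == failed_marker | cells == "" | cells == "NA"] <- NA
  ct <- suppressWarnings(matrix(as.numeric(cells), nrow = length(genes),
                                dimnames = list(genes, samples)))
  bad <- which(is.na(ct) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric cell(s) that are not the failed-reaction marker: ",
         paste(sprintf("(gene %s, sample %s)", genes[bad[, 1]],
                       samples[bad[, 2]]), collapse = ", "),
         call. = FALSE)
  ct
}

#' Write a Ct (or normalized) matrix to a delimited file
#'
#' Inverse of [read_ct_matrix()]: writes a genes x samples table with a
#' `gene_id` first column, encoding `NA` as `failed_marker`.
#'
#' @param x numeric matrix with gene row names and sample column names.
#' @param path output path (`.csv` writes comma-separated, else tab).
#' @param failed_marker token written for missing entries.
#' @export
write_ct_matrix <- function(x, path, failed_marker = "999") {
  check_expr_matrix(x, "x")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- cbind(gene_id = rownames(x),
               as.data.frame(ifelse(is.na(x), failed_marker,
                                    format(x, trim = TRUE))))
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-neuron metadata
#'
#' Reads the sample metadata table with columns `sample_id`, `animal_id`,
#' `projection` (one of `"SAN-projecting"`, `"non-SAN-projecting"`,
#' `"unknown"`), `x`, `y`, `z` coordinates in micrometres and `section`.
#'
#' @param path delimited file path.
#' @param sep separator; inferred from the extension when `NULL`.
#' @return data.frame with `projection` as a factor over the fixed
#'   vocabulary.
#' @export
read_neuron_meta <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  meta <- read.delim(path, sep = sep, header = TRUE,
                     stringsAsFactors = FALSE)
  need <- c("sample_id", "animal_id", "projection")
  if (!all(need %in% names(meta)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(meta$projection %in% PROJECTION_LEVELS))
    stop("projection labels must be one of: ",
         paste(PROJECTION_LEVELS, collapse = ", "), call. = FALSE)
  meta$projection <- factor(meta$projection, levels = PROJECTION_LEVELS)
  meta
}

#' Quality-control filtering of a Ct matrix
#'
#' Removes low-quality samples and genes by failed-reaction fraction:
#' first samples whose fraction of failed (missing) reactions is strictly
#' greater than `sample_fail_max`, then genes whose failed fraction
#' computed over the surviving samples is strictly greater than
#' `gene_fail_max`. An explicit `exclude_samples` list supports removal
#' of known outlier samples, which is not an automatic rule.
#'
#' @param ct genes x samples Ct matrix with `NA` = failed reaction.
#' @param sample_fail_max maximum tolerated failed fraction per sample.
#' @param gene_fail_max maximum tolerated failed fraction per gene.
#' @param exclude_samples optional sample ids dropped before filtering.
#' @return list with `ct` (filtered matrix) and `report`, a
#'   `"qc_report"` listing removed samples/genes with their failed
#'   fractions.
#' @export
qc_filter <- function(ct, sample_fail_max = 0.30, gene_fail_max = 0.20,
                      exclude_samples = NULL) {
  check_expr_matrix(ct, "ct")
  if (sample_fail_max < 0 || sample_fail_max > 1 ||
      gene_fail_max < 0 || gene_fail_max > 1)
    stop("failure-fraction thresholds must lie in [0, 1]", call. = FALSE)

  excluded <- intersect(exclude_samples %||% character(0), colnames(ct))
  ct1 <- ct[, setdiff(colnames(ct), excluded), drop = FALSE]

  sample_fail <- colMeans(is.na(ct1))
  drop_s <- sample_fail > sample_fail_max
  ct2 <- ct1[, !drop_s, drop = FALSE]

  if (ncol(ct2) > 0) {
    gene_fail <- rowMeans(is.na(ct2))
  } else {
    gene_fail <- setNames(rep(NA_real_, nrow(ct2)), rownames(ct2))
  }
  drop_g <- !is.na(gene_fail) & gene_fail > gene_fail_max
  out <- ct2[!drop_g, , drop = FALSE]

  if (nrow(out) == 0 || ncol(out) == 0)
    warning("QC filtering left an empty matrix", call. = FALSE)

  report <- structure(list(
    excluded_samples = excluded,
    removed_samples = sample_fail[drop_s],
    removed_genes = gene_fail[drop_g],
    sample_fail_max = sample_fail_max,
    gene_fail_max = gene_fail_max,
    n_samples = c(before = ncol(ct), after = ncol(out)),
    n_genes = c(before = nrow(ct), after = nrow(out))),
    class = "qc_report")
  list(ct = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Ct matrix QC report\n")
  cat("  samples:", x$n_samples["before"], "->", x$n_samples["after"],
      sprintf("(%d excluded a priori, %d with failed fraction > %.2f)\n",
              length(x$excluded_samples), length(x$removed_samples),
              x$sample_fail_max))
  cat("  genes:  ", x$n_genes["before"], "->", x$n_genes["after"],
      sprintf("(%d with failed fraction > %.2f)\n",
              length(x$removed_genes), x$gene_fail_max))
  invisible(x)
}

#' Detectable-expression calls
#'
#' A gene is detected in a sample whenever the reaction produced any
#' signal, i.e. the Ct value is present.
#'
#' @param ct genes x samples Ct matrix.
#' @return logical matrix of the same shape: `TRUE` where detected.
#' @export
call_detection <- function(ct) {
  check_expr_matrix(ct, "ct")
  !is.na(ct)
}

#' Abundant-expression calls
#'
#' A gene is abundantly expressed in a sample when its Ct is strictly
#' below the threshold (default 15 Ct). Per-(animal, gene) override
#' thresholds accommodate animal-specific abundance shifts, e.g. a
#' cholinergic marker running 7 Ct higher in one animal, called abundant
#' below 22 Ct there.
#'
#' @param ct genes x samples Ct matrix.
#' @param meta per-neuron metadata (required when `overrides` given).
#' @param threshold default abundance threshold in Ct units.
#' @param overrides optional `data.frame(animal, gene, threshold)`.
#' @return logical matrix: `TRUE` where abundant.
#' @export
call_abundance <- function(ct, meta = NULL, threshold = 15,
                           overrides = NULL) {
  check_expr_matrix(ct, "ct")
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  thr <- matrix(threshold, nrow(ct), ncol(ct), dimnames = dimnames(ct))
  if (!is.null(overrides)) {
    if (is.null(meta))
      stop("meta is required when overrides are given", call. = FALSE)
    if (!all(c("animal", "gene", "threshold") %in% names(overrides)))
      stop("overrides must be a data.frame(animal, gene, threshold)",
           call. = FALSE)
    for (i in seq_len(nrow(overrides))) {
      o <- overrides[i, ]
      if (!o$gene %in% rownames(ct))
        stop("override references unknown gene: ", o$gene, call. = FALSE)
      if (!o$animal %in% meta$animal_id)
        stop("override references unknown animal: ", o$animal,
             call. = FALSE)
      if (o$threshold <= 0) stop("threshold must be > 0", call. = FALSE)
      smp <- intersect(meta$sample_id[meta$animal_id == o$animal],
                       colnames(ct))
      thr[o$gene, smp] <- o$threshold
    }
  }
  !is.na(ct) & ct < thr
}

#' Robustly expressed gene set
#'
#' Returns the genes whose fraction of working (non-failed) reactions is
#' strictly greater than `min_working`, in input order. The default 0.60
#' gives the robust reference set used to build the median normalization
#' reference.
#'
#' @param ct genes x samples Ct matrix.
#' @param min_working minimum working-reaction fraction (exclusive).
#' @return character vector of gene ids.
#' @export
robust_gene_set <- function(ct, min_working = 0.60) {
  check_expr_matrix(ct, "ct")
  if (min_working < 0 || min_working > 1)
    stop("min_working must lie in [0, 1]", call. = FALSE)
  rownames(ct)[rowMeans(!is.na(ct)) > min_working]
}
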