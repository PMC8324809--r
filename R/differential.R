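#' Benjamini-Hochberg FDR adjustment
#'
#' Validating wrapper around the step-up false discovery rate
#' adjustment. Input p-values must lie in `[0, 1]`.
#'
#' @param p numeric vector of p-values.
#' @param method `"BH"` (default) or `"BY"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (!is.numeric(p) || any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  p.adjust(p, method = method)
}

#' Kolmogorov-Smirnov screen between projection groups
#'
#' Screens every gene for a difference in the distribution of expression
#' between SAN-projecting and non-SAN-projecting neurons using the
#' two-sample KS statistic, with FDR adjustment across tested genes and
#' a fold-change gate. On the -ddCt scale one unit is one Ct, i.e. about
#' 2-fold, so the log2 fold change is the difference of group medians
#' and a gene is significant when `q < alpha` and
#' `2^|log2fc| > fc_min`. Unknown-projection samples are excluded;
#' genes with fewer than `min_per_group` present values in either group
#' are skipped with a warning.
#'
#' @param x genes x samples matrix of -ddCt values (or raw Ct; see
#'   `fc_on`).
#' @param meta per-neuron metadata with `sample_id` and `projection`.
#' @param alpha FDR threshold (default 0.01).
#' @param fc_min fold-change gate (default 2).
#' @param min_per_group minimum present values per group per gene.
#' @param exact logical: exact KS p-values; by default exact when both
#'   groups have fewer than 30 values, asymptotic otherwise.
#' @param method FDR adjustment method passed to [bh_adjust()].
#' @return data.frame of class `"ks_screen"` with columns `gene_id`,
#'   `n_proj`, `n_nonproj`, `ks_D`, `p`, `q`, `log2fc` (median of
#'   SAN-projecting minus median of non-SAN-projecting) and
#'   `significant`; skipped genes are listed in attribute `"skipped"`.
#' @export
ks_screen <- function(x, meta, alpha = 0.01, fc_min = 2,
                      min_per_group = 5, exact = NULL,
                      method = c("BH", "BY")) {
  check_expr_matrix(x, "x")
  method <- match.arg(method)
  m <- meta[match(colnames(x), meta$sample_id), ]
  g1 <- which(m$projection == "SAN-projecting")
  g2 <- which(m$projection == "non-SAN-projecting")
  if (length(g1) == 0 || length(g2) == 0)
    stop("both projection groups must be present", call. = FALSE)

  skipped <- character(0)
  rows <- vector("list", nrow(x))
  for (gi in seq_len(nrow(x))) {
    a <- x[gi, g1]; a <- a[is.finite(a)]
    b <- x[gi, g2]; b <- b[is.finite(b)]
    if (length(a) < min_per_group || length(b) < min_per_group) {
      skipped <- c(skipped, rownames(x)[gi])
      next
    }
    use_exact <- if (is.null(exact)) max(length(a), length(b)) < 30 else exact
    kt <- suppressWarnings(ks.test(a, b, exact = use_exact))
    rows[[gi]] <- data.frame(
      gene_id = rownames(x)[gi],
      n_proj = length(a), n_nonproj = length(b),
      ks_D = unname(kt$statistic), p = kt$p.value,
      log2fc = median(a) - median(b),
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning(length(skipped), " gene(s) skipped for insufficient group ",
            "sizes", call. = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), n_proj = integer(0),
                      n_nonproj = integer(0), ks_D = numeric(0),
                      p = numeric(0), log2fc = numeric(0))
  }
  out$q <- if (nrow(out)) bh_adjust(out$p, method) else numeric(0)
  out$significant <- out$q < alpha & 2^abs(out$log2fc) > fc_min
  out <- out[, c("gene_id", "n_proj", "n_nonproj", "ks_D", "p", "q",
                 "log2fc", "significant")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "alpha") <- alpha
  attr(out, "fc_min") <- fc_min
  class(out) <- c("ks_screen", "data.frame")
  out
}

#' @export
print.ks_screen <- function(x, n = 10, ...) {
  cat(sprintf(
    "KS screen: %d genes tested, %d significant (q < %g, fold > %g)\n",
    nrow(x), sum(x$significant), attr(x, "alpha"), attr(x, "fc_min")))
  ord <- order(x$q, x$p)
  print.data.frame(head(as.data.frame(x)[ord, ], n), digits = 3)
  invisible(x)
}
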