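# Transcriptional-state model: hierarchical clustering of training
# profiles, per-cluster gene-median templates, and Pavlidis template
# matching assignment with sequestration of poorly matching neurons.

# Internal: sample-by-sample Pearson correlation matrix over pairwise
# complete genes, with a minimum-overlap check (error names the worst
# offending pair).
profile_cor <- function(x, min_overlap = 3) {
  present <- !is.na(x)
  overlap <- crossprod(present)
  off <- overlap
  diag(off) <- Inf
  if (any(off < min_overlap)) {
    idx <- which(off < min_overlap, arr.ind = TRUE)[1, ]
    stop("samples share fewer than ", min_overlap, " present genes: ",
         colnames(x)[idx[1]], " / ", colnames(x)[idx[2]], call. = FALSE)
  }
  suppressWarnings(cor(x, use = "pairwise.complete.obs"))
}

#' Hierarchical clustering of expression profiles
#'
#' Clusters sample profiles with complete linkage on the correlation
#' distance `1 - Pearson r` (computed over pairwise-present genes) and
#' cuts the tree into exactly `k` clusters. Cluster labels are renumbered
#' by decreasing size (ties by first appearance).
#'
#' @param x genes x samples matrix of -ddCt values.
#' @param k number of clusters (default 7, the number of initial
#'   training clusters before merging).
#' @return named integer vector of cluster labels (1 = largest), with the
#'   `hclust` tree in attribute `"tree"`.
#' @export
hcluster_profiles <- function(x, k = 7) {
  check_expr_matrix(x, "x")
  require_stage(x, "neg_ddct", "x")
  if (ncol(x) < k)
    stop("need at least k = ", k, " samples, got ", ncol(x), call. = FALSE)
  C <- profile_cor(x)
  d <- as.dist(1 - C)
  tree <- hclust(d, method = "complete")
  raw <- cutree(tree, k = k)
  sizes <- table(raw)
  new_order <- order(-as.vector(sizes), as.integer(names(sizes)))
  remap <- integer(k)
  remap[as.integer(names(sizes))[new_order]] <- seq_len(k)
  labels <- setNames(remap[raw], colnames(x))
  attr(labels, "tree") <- tree
  labels
}

# Internal: mean silhouette width on the 1 - Pearson profile distance.
mean_silhouette <- function(d, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)), d)
  mean(sil[, "sil_width"])
}

#' Silhouette width with a permutation null
#'
#' Computes the mean silhouette width of a clustering under the
#' `1 - Pearson` profile distance, and a permutation p-value against
#' `n_perm` relabelings that preserve the cluster sizes:
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param x genes x samples matrix of -ddCt values.
#' @param labels cluster labels, one per sample.
#' @param n_perm number of randomized trials (default 1000).
#' @param seed optional integer seed for the permutations.
#' @return list of class `"silhouette_null"`: `mean_width`, `p_value`,
#'   `null` (the permuted widths) and `n_perm`.
#' @export
silhouette_with_null <- function(x, labels, n_perm = 1000, seed = NULL) {
  check_expr_matrix(x, "x")
  if (length(labels) != ncol(x))
    stop("labels must have one entry per sample", call. = FALSE)
  sizes <- table(labels)
  if (sum(sizes >= 2) < 2)
    stop("need at least two clusters with at least two members",
         call. = FALSE)
  d <- as.dist(1 - profile_cor(x))
  obs <- mean_silhouette(d, labels)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    mean_silhouette(d, sample(labels))
  }, numeric(1))
  structure(list(mean_width = obs,
                 p_value = (1 + sum(null >= obs)) / (n_perm + 1),
                 null = null, n_perm = n_perm),
            class = "silhouette_null")
}

#' @export
print.silhouette_null <- function(x, ...) {
  cat(sprintf(
    "Mean silhouette width %.3f (null mean %.3f over %d permutations), p = %.4g\n",
    x$mean_width, mean(x$null), x$n_perm, x$p_value))
  invisible(x)
}

#' Build per-state templates from labeled profiles
#'
#' Computes the state templates as the per-gene medians of the member
#' profiles of each cluster (missing values excluded), and packages them
#' with the assignment threshold into a [state_model].
#'
#' @param x genes x samples matrix of -ddCt values (training data).
#' @param labels cluster labels, one per sample.
#' @param r_min template-matching correlation threshold (default 0.45).
#' @return an object of class `"state_model"`; see [state_model()].
#' @export
build_templates <- function(x, labels, r_min = 0.45) {
  check_expr_matrix(x, "x")
  if (length(labels) != ncol(x))
    stop("labels must have one entry per sample", call. = FALSE)
  if (r_min <= -1 || r_min > 1)
    stop("r_min must lie in (-1, 1]", call. = FALSE)
  lv <- sort(unique(labels))
  templates <- vapply(lv, function(s) {
    apply(x[, labels == s, drop = FALSE], 1, median, na.rm = TRUE)
  }, numeric(nrow(x)))
  state_ids <- paste0("S", lv)
  dimnames(templates) <- list(rownames(x), state_ids)
  empty <- colSums(is.finite(templates)) == 0
  if (any(empty))
    stop("state(s) with all-missing template: ",
         paste(state_ids[empty], collapse = ", "), call. = FALSE)
  structure(list(
    templates = templates,
    r_min = r_min,
    state_ids = state_ids,
    merge_map = setNames(state_ids, state_ids),
    labels = setNames(paste0("S", labels), colnames(x)),
    training_samples = colnames(x),
    data = x),
    class = "state_model")
}

#' Fit a transcriptional-state model
#'
#' The central estimator of the package: partitions training profiles
#' into `k` clusters by hierarchical clustering (Pearson correlation
#' distance, complete linkage; see [hcluster_profiles()]), takes
#' per-cluster gene medians as state templates, and fixes the Pavlidis
#' template matching threshold used by [predict.state_model()] to assign
#' any neuron to its best-correlated state or to the sequestered
#' catch-all. In the study design the training set is the SAN-projecting
#' neurons of a subset of animals; the fitted templates then classify all
#' remaining neurons.
#'
#' @param x genes x samples matrix of -ddCt values.
#' @param k number of initial clusters (default 7).
#' @param r_min assignment correlation threshold (default 0.45).
#' @param training optional sample ids (or logical/integer index) naming
#'   the training subset; defaults to all samples.
#' @param labels optional precomputed cluster labels for the training
#'   samples, bypassing clustering.
#' @return an object of class `"state_model"` with components
#'   `templates` (genes x states median matrix), `r_min`, `state_ids`,
#'   `merge_map`, `labels` (training cluster membership),
#'   `training_samples`, and `data` (the training matrix, retained so
#'   that [merge_states()] can rebuild templates).
#' @seealso [predict.state_model()], [merge_states()],
#'   [state_enrichment()], [silhouette_with_null()]
#' @export
#' @examples
#' sim <- simulate_qpcr(sim_config(n_neurons = 120, n_genes = 60,
#'                                 n_states = 3, state_softness = 0,
#'                                 failure_rate = 0, seed = 11))
#' nd <- neg_delta_ct(sim$ct, robust_gene_set(sim$ct))
#' dd <- neg_delta_delta_ct(nd)
#' fit <- state_model(dd, k = 3)
#' fit
#' head(predict(fit, dd))
state_model <- function(x, k = 7, r_min = 0.45, training = NULL,
                        labels = NULL) {
  check_expr_matrix(x, "x")
  xt <- if (is.null(training)) x else x[, training, drop = FALSE]
  xt <- set_stage(xt, get_stage(x))
  if (is.null(labels)) {
    labels <- hcluster_profiles(xt, k = k)
  } else if (length(labels) != ncol(xt)) {
    stop("labels must have one entry per training sample", call. = FALSE)
  }
  fit <- build_templates(xt, labels, r_min = r_min)
  fit$call <- match.call()
  fit
}

#' Pavlidis template matching correlation
#'
#' Pearson correlation between an expression profile and a state
#' template over jointly present genes, with the two-sided p-value from
#' the t transform of r on `n - 2` degrees of freedom.
#'
#' @param profile,template numeric vectors over the same genes.
#' @return list with `r`, `p` and `n` (genes used). A zero-variance
#'   profile or template yields `r = NA` (no match).
#' @export
ptm_correlate <- function(profile, template) {
  ok <- is.finite(profile) & is.finite(template)
  n <- sum(ok)
  if (n < 3)
    stop("need at least 3 jointly present genes, got ", n, call. = FALSE)
  a <- profile[ok]; b <- template[ok]
  if (sd(a) == 0 || sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- cor(a, b)
  r2 <- min(r^2, 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r2))
  list(r = r, p = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Assign neurons to states by template matching
#'
#' Correlates each sample profile with every state template (Pearson,
#' pairwise-present genes, minimum overlap 3) and assigns the sample to
#' the best-correlated state when `best_r >= r_min`; otherwise the
#' sample is sequestered. Ties are broken toward the lowest state index.
#' Samples for which no correlation is computable (insufficient overlap
#' or zero variance) are sequestered with a warning.
#'
#' @param object a fitted [state_model()].
#' @param newdata genes x samples matrix of -ddCt values.
#' @param r_min optional threshold overriding the fitted one.
#' @param ... unused.
#' @return data.frame of class `"state_assignment"` with columns
#'   `sample_id`, `state` (a state id or `"sequestered"`) and `best_r`;
#'   the full sample x state correlation matrix is in attribute
#'   `"all_r"`.
#' @export
predict.state_model <- function(object, newdata, r_min = NULL, ...) {
  check_expr_matrix(newdata, "newdata")
  r_min <- r_min %||% object$r_min
  tpl <- object$templates
  shared <- intersect(rownames(newdata), rownames(tpl))
  if (length(shared) < 3)
    stop("fewer than 3 genes shared between newdata and templates",
         call. = FALSE)
  xs <- newdata[shared, , drop = FALSE]
  ts <- tpl[shared, , drop = FALSE]
  suppressWarnings(R <- cor(xs, ts, use = "pairwise.complete.obs"))
  overlap <- crossprod(!is.na(xs), !is.na(ts))
  R[overlap < 3] <- NA
  no_match <- rowSums(is.finite(R)) == 0
  if (any(no_match))
    warning(sum(no_match), " sample(s) with no computable template ",
            "correlation were sequestered", call. = FALSE)
  best_idx <- apply(R, 1, function(r) {
    if (all(!is.finite(r))) NA_integer_ else which.max(replace(r, !is.finite(r), -Inf))
  })
  best_r <- R[cbind(seq_len(nrow(R)), ifelse(is.na(best_idx), 1L, best_idx))]
  best_r[is.na(best_idx)] <- NA_real_
  state <- ifelse(!is.na(best_idx) & best_r >= r_min,
                  colnames(tpl)[best_idx], SEQUESTERED)
  out <- data.frame(sample_id = colnames(newdata), state = state,
                    best_r = best_r, stringsAsFactors = FALSE)
  attr(out, "all_r") <- R
  attr(out, "r_min") <- r_min
  class(out) <- c("state_assignment", "data.frame")
  out
}

#' @rdname predict.state_model
#' @param x genes x samples matrix of -ddCt values.
#' @param model a fitted [state_model()].
#' @export
ptm_assign <- function(x, model, r_min = NULL) {
  predict(model, x, r_min = r_min)
}

#' Merge states of a fitted model
#'
#' Combines groups of states (e.g. states with visually similar
#' expression profiles) into single states. Templates of merged states
#' are rebuilt as per-gene medians over the pooled training samples of
#' the member clusters. Merging is always an explicit specification;
#' [suggest_merges()] proposes candidates from template-template
#' correlations but never merges silently.
#'
#' @param model a fitted [state_model()].
#' @param merge_spec list of character vectors of state ids to combine;
#'   list names become the merged state ids (unnamed groups are named by
#'   concatenation, e.g. `"S2+S5"`). An empty list returns the model
#'   unchanged.
#' @return a new `state_model` with updated `templates`, `merge_map` and
#'   `labels`.
#' @export
merge_states <- function(model, merge_spec) {
  stopifnot(inherits(model, "state_model"))
  if (length(merge_spec) == 0) return(model)
  members <- unlist(merge_spec)
  if (anyDuplicated(members))
    stop("merge groups must be disjoint", call. = FALSE)
  unknown <- setdiff(members, model$state_ids)
  if (length(unknown))
    stop("unknown state id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  nm <- names(merge_spec) %||% rep("", length(merge_spec))
  if (is.null(names(merge_spec))) nm <- rep("", length(merge_spec))
  nm[nm == ""] <- vapply(merge_spec[nm == ""], paste, "", collapse = "+")

  merge_map <- setNames(model$state_ids, model$state_ids)
  for (i in seq_along(merge_spec))
    merge_map[merge_spec[[i]]] <- nm[i]

  new_labels <- setNames(merge_map[model$labels], names(model$labels))
  # preserve original ordering: new states in order of first appearance
  # among the old state ids
  new_ids <- unique(unname(merge_map))
  templates <- vapply(new_ids, function(s) {
    apply(model$data[, new_labels == s, drop = FALSE], 1, median,
          na.rm = TRUE)
  }, numeric(nrow(model$data)))
  dimnames(templates) <- list(rownames(model$data), new_ids)

  out <- model
  out$templates <- templates
  out$state_ids <- new_ids
  out$merge_map <- merge_map
  out$labels <- new_labels
  out
}

#' Suggest state merges from template similarity
#'
#' Proposes groups of states whose templates correlate above
#' `r_threshold` (connected components of the template correlation
#' graph). Convenience for [merge_states()]; nothing is merged.
#'
#' @param model a fitted [state_model()].
#' @param r_threshold template-template Pearson correlation above which
#'   two states are linked.
#' @return list of character vectors (groups of >= 2 states), possibly
#'   empty.
#' @export
suggest_merges <- function(model, r_threshold = 0.9) {
  stopifnot(inherits(model, "state_model"))
  R <- suppressWarnings(cor(model$templates, use = "pairwise.complete.obs"))
  k <- ncol(R)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    if (is.finite(R[i, j]) && R[i, j] > r_threshold)
      parent[find(j)] <- find(i)
  comp <- vapply(seq_len(k), find, integer(1))
  groups <- split(model$state_ids, comp)
  unname(groups[lengths(groups) >= 2])
}

#' Per-gene state enrichment (ANOVA + Tukey HSD)
#'
#' Screens each gene for enrichment in specific states: a one-way ANOVA
#' across states followed by Tukey Honest Significant Difference
#' pairwise comparisons. A gene is flagged enriched in state `s` when
#' its mean in `s` exceeds that of at least `min_dominated` other states
#' with Tukey-adjusted `p < p_max`. Genes are screened one at a time
#' (no cross-gene correction). Constant genes are untestable and
#' excluded (recorded in attribute `"untestable"`).
#'
#' @param x genes x samples matrix of -ddCt values.
#' @param assignments a `"state_assignment"` data.frame from
#'   [predict.state_model()], or a vector of state labels (one per
#'   sample of `x`). Sequestered samples are ignored.
#' @param p_max Tukey-adjusted significance threshold (default 0.01).
#' @param min_dominated number of other states that must be exceeded
#'   (default 2).
#' @return data.frame (gene x state long form) with columns `gene_id`,
#'   `state`, `n_sig_higher`, `enriched` and `anova_p`.
#' @export
state_enrichment <- function(x, assignments, p_max = 0.01,
                             min_dominated = 2) {
  check_expr_matrix(x, "x")
  states <- if (inherits(assignments, "state_assignment")) {
    setNames(assignments$state, assignments$sample_id)[colnames(x)]
  } else if (!is.null(names(assignments))) {
    assignments[colnames(x)]
  } else {
    if (length(assignments) != ncol(x))
      stop("assignments must have one entry per sample", call. = FALSE)
    setNames(assignments, colnames(x))
  }
  keep <- !is.na(states) & states != SEQUESTERED
  x <- x[, keep, drop = FALSE]
  states <- factor(states[keep])
  sizes <- table(states)
  if (sum(sizes >= 2) < 2)
    stop("need at least two states with at least two members",
         call. = FALSE)
  lev <- levels(states)
  untestable <- character(0)
  rows <- vector("list", nrow(x))
  for (gi in seq_len(nrow(x))) {
    v <- x[gi, ]
    ok <- is.finite(v)
    vv <- v[ok]; ss <- droplevels(states[ok])
    if (length(vv) < 4 || nlevels(ss) < 2 || sd(vv) == 0 ||
        sum(table(ss) >= 2) < 2) {
      untestable <- c(untestable, rownames(x)[gi])
      next
    }
    fit <- aov(vv ~ ss)
    an_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$ss
    cmp <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    means <- tapply(vv, ss, mean)
    n_hi <- vapply(levels(ss), function(s) {
      inv <- cmp[, 1] == s | cmp[, 2] == s
      win <- tk[inv, "p adj"] < p_max &
        ifelse(cmp[inv, 1] == s,
               tk[inv, "diff"] > 0, tk[inv, "diff"] < 0)
      sum(win)
    }, integer(1))
    rows[[gi]] <- data.frame(
      gene_id = rownames(x)[gi], state = levels(ss),
      n_sig_higher = unname(n_hi),
      enriched = unname(n_hi) >= min_dominated,
      anova_p = an_p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), state = character(0),
                      n_sig_higher = integer(0), enriched = logical(0),
                      anova_p = numeric(0))
  rownames(out) <- NULL
  attr(out, "untestable") <- untestable
  out
}

#' @export
print.state_model <- function(x, ...) {
  cat("Transcriptional-state model\n")
  cat("  states:", length(x$state_ids),
      sprintf("(%s)", paste(x$state_ids, collapse = ", ")), "\n")
  cat("  genes:", nrow(x$templates),
      "  training samples:", length(x$training_samples), "\n")
  cat("  assignment threshold r_min =", x$r_min, "\n")
  invisible(x)
}

#' @export
summary.state_model <- function(object, ...) {
  sizes <- table(object$labels)
  tplcor <- suppressWarnings(
    cor(object$templates, use = "pairwise.complete.obs"))
  out <- list(state_sizes = sizes, template_cor = tplcor,
              r_min = object$r_min, n_genes = nrow(object$templates))
  class(out) <- "summary.state_model"
  out
}

#' @export
print.summary.state_model <- function(x, ...) {
  cat("Training cluster sizes:\n")
  print(x$state_sizes)
  cat("\nTemplate-template Pearson correlations:\n")
  print(round(x$template_cor, 2))
  cat("\nAssignment threshold r_min =", x$r_min, "over", x$n_genes,
      "genes\n")
  invisible(x)
}

#' Plot state templates as a heatmap
#'
#' @param x a fitted [state_model()].
#' @param ... passed to [graphics::image()].
#' @export
plot.state_model <- function(x, ...) {
  tpl <- x$templates
  ord <- order(apply(tpl, 1, which.max), -apply(tpl, 1, max, na.rm = TRUE))
  z <- t(tpl[ord, , drop = FALSE])
  image(x = seq_len(nrow(z)), y = seq_len(ncol(z)), z = z,
        xlab = "state", ylab = "gene (ordered by peak state)",
        xaxt = "n", main = "State templates (-ddCt medians)", ...)
  axis(1, at = seq_len(nrow(z)), labels = rownames(z))
  invisible(x)
}
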