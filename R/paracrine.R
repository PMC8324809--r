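# Combinatorial neuropeptide-receptor paracrine classification: each
# neuron is peptide+/- (above/below the gene's median) and receptor+/-
# (any cognate receptor above its own median) for every peptide set;
# the combined flags define the neuron's paracrine category.

#' Define a neuropeptide-receptor set
#'
#' @param name short set name used in category identifiers (e.g.
#'   `"Sst"`).
#' @param peptide gene id of the neuropeptide.
#' @param receptors character vector (>= 1) of cognate receptor gene
#'   ids.
#' @return list of class `"peptide_set"`.
#' @export
peptide_set <- function(name, peptide, receptors) {
  if (length(receptors) < 1)
    stop("a peptide set needs at least one receptor gene", call. = FALSE)
  structure(list(name = name, peptide = peptide,
                 receptors = as.character(receptors)),
            class = "peptide_set")
}

#' Default neuropeptide-receptor sets
#'
#' The three neuropeptide systems examined in detail in the cardiac
#' ganglion analysis: somatostatin, galanin and neuropeptide Y with
#' their cognate receptors.
#'
#' @return list of three [peptide_set()] objects.
#' @export
default_peptide_sets <- function() {
  list(peptide_set("Sst", "Sst", c("Sstr1", "Sstr2")),
       peptide_set("Gal", "Gal", c("Galr1", "Galr2")),
       peptide_set("Npy", "Npy", c("Npy1r", "Npy2r")))
}

#' Binarize peptide and receptor expression at the gene median
#'
#' For each peptide set, a neuron is peptide-positive when its
#' expression of the peptide gene is strictly above that gene's median
#' across all neurons, and receptor-positive when any one of the
#' cognate receptor genes is strictly above its own median. Values at
#' the median and missing values are negative.
#'
#' @param x genes x samples matrix of normalized expression (-ddCt).
#' @param sets list of [peptide_set()] objects (default
#'   [default_peptide_sets()]).
#' @param medians optional named vector of per-gene medians to binarize
#'   against (e.g. precomputed per animal); computed from `x` when
#'   `NULL`.
#' @return data.frame of class `"paracrine_flags"`: `sample_id` plus
#'   logical columns `<name>_pep` and `<name>_rec` per set; the sets are
#'   kept in attribute `"sets"`.
#' @export
binarize_flags <- function(x, sets = default_peptide_sets(),
                           medians = NULL) {
  check_expr_matrix(x, "x")
  genes <- unlist(lapply(sets, function(s) c(s$peptide, s$receptors)))
  absent <- setdiff(genes, rownames(x))
  if (length(absent))
    stop("gene(s) required by peptide sets absent from matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (is.null(medians))
    medians <- apply(x[unique(genes), , drop = FALSE], 1, median,
                     na.rm = TRUE)
  above <- function(g) {
    v <- x[g, ]
    !is.na(v) & v > medians[[g]]
  }
  out <- data.frame(sample_id = colnames(x), stringsAsFactors = FALSE)
  for (s in sets) {
    out[[paste0(s$name, "_pep")]] <- above(s$peptide)
    rec <- Reduce(`|`, lapply(s$receptors, above))
    out[[paste0(s$name, "_rec")]] <- rec
  }
  attr(out, "sets") <- sets
  class(out) <- c("paracrine_flags", "data.frame")
  out
}

#' Canonical category identifiers from paracrine flags
#'
#' Encodes each neuron's flags as an ordered string such as
#' `"Sst+R-|Gal-R+|Npy+R+"`. With `n` peptide sets the identifier space
#' has exactly `4^n` members (peptide +/- times receptor +/- per set).
#'
#' @param flags a `"paracrine_flags"` data.frame from
#'   [binarize_flags()].
#' @return character vector of category ids, one per neuron.
#' @export
categorize <- function(flags) {
  sets <- attr(flags, "sets")
  if (is.null(sets)) stop("flags must come from binarize_flags()",
                          call. = FALSE)
  parts <- lapply(sets, function(s) {
    pep <- flags[[paste0(s$name, "_pep")]]
    rec <- flags[[paste0(s$name, "_rec")]]
    if (is.null(pep) || is.null(rec) || anyNA(pep) || anyNA(rec))
      stop("incomplete flags for set ", s$name, call. = FALSE)
    sprintf("%s%sR%s", s$name, ifelse(pep, "+", "-"),
            ifelse(rec, "+", "-"))
  })
  do.call(paste, c(parts, sep = "|"))
}

#' Enumerate the full category identifier space
#'
#' @param sets list of [peptide_set()] objects.
#' @return character vector of all `4^length(sets)` category ids, in
#'   canonical order.
#' @export
category_space <- function(sets = default_peptide_sets()) {
  per_set <- lapply(sets, function(s) {
    c(sprintf("%s+R+", s$name), sprintf("%s+R-", s$name),
      sprintf("%s-R+", s$name), sprintf("%s-R-", s$name))
  })
  grid <- do.call(expand.grid,
                  c(rev(per_set), stringsAsFactors = FALSE))
  do.call(paste, c(rev(grid), sep = "|"))
}

#' Census of paracrine categories
#'
#' Counts neurons per category and retains categories with strictly
#' more than `min_n` members. When metadata is supplied the
#' SAN-projecting fraction of each category is reported.
#'
#' @param flags a `"paracrine_flags"` data.frame.
#' @param min_n retention threshold (categories kept when count
#'   `> min_n`; default 10).
#' @param meta optional metadata with `sample_id` and `projection`.
#' @return data.frame of class `"category_census"` with columns
#'   `category`, `n`, `san_frac` and `retained`, sorted by decreasing
#'   count then id; attributes `n_observed`, `n_retained`,
#'   `retained_neurons` and `n_total` summarize the census.
#' @export
category_census <- function(flags, min_n = 10, meta = NULL) {
  if (nrow(flags) < 1) stop("need at least one neuron", call. = FALSE)
  ids <- categorize(flags)
  tab <- table(ids)
  san_frac <- rep(NA_real_, length(tab))
  if (!is.null(meta)) {
    proj <- meta$projection[match(flags$sample_id, meta$sample_id)]
    san_frac <- vapply(names(tab), function(cid) {
      mean(proj[ids == cid] == "SAN-projecting", na.rm = FALSE)
    }, numeric(1))
  }
  out <- data.frame(category = names(tab), n = as.integer(tab),
                    san_frac = san_frac, stringsAsFactors = FALSE)
  out$retained <- out$n > min_n
  out <- out[order(-out$n, out$category), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_observed") <- nrow(out)
  attr(out, "n_retained") <- sum(out$retained)
  attr(out, "retained_neurons") <- sum(out$n[out$retained])
  attr(out, "n_total") <- nrow(flags)
  attr(out, "min_n") <- min_n
  attr(out, "sets") <- attr(flags, "sets")
  class(out) <- c("category_census", "data.frame")
  out
}

#' @export
print.category_census <- function(x, ...) {
  cat(sprintf(
    "Paracrine census: %d neurons in %d observed categories; %d retained (> %d neurons) covering %d neurons\n",
    attr(x, "n_total"), attr(x, "n_observed"), attr(x, "n_retained"),
    attr(x, "min_n"), attr(x, "retained_neurons")))
  print.data.frame(head(as.data.frame(x), 15), digits = 3)
  invisible(x)
}

# Internal: parse a category id back into per-set peptide/receptor
# signs; returns a named logical list.
parse_category <- function(id, sets) {
  parts <- strsplit(id, "|", fixed = TRUE)[[1]]
  res <- list()
  for (i in seq_along(sets)) {
    nm <- sets[[i]]$name
    body <- sub(paste0("^", nm), "", parts[i])
    res[[paste0(nm, "_pep")]] <- substr(body, 1, 1) == "+"
    res[[paste0(nm, "_rec")]] <- substr(body, 3, 3) == "+"
  }
  res
}

#' Build the bipartite producer/receiver paracrine network
#'
#' Constructs a directed graph with one circular node per retained
#' neuronal subtype (category) and one square node per neuropeptide.
#' A producer edge runs subtype -> peptide whenever the subtype is
#' peptide-positive for that set, and a receiver edge runs peptide ->
#' subtype whenever the subtype is receptor-positive. Node ordering is
#' deterministic (subtypes by decreasing size then id, then peptides in
#' set order).
#'
#' @param census a `"category_census"` from [category_census()].
#' @param sets list of [peptide_set()] objects; defaults to the sets
#'   recorded in the census.
#' @param retained_only build the network over retained categories only
#'   (default `TRUE`).
#' @return an [igraph::igraph] directed graph with vertex attributes
#'   `type` (`"subtype"`/`"peptide"`), `n_neurons` and `san_frac`, and
#'   edge attribute `role` (`"producer"`/`"receiver"`).
#' @export
build_network <- function(census, sets = NULL, retained_only = TRUE) {
  if (nrow(census) < 1) stop("census is empty", call. = FALSE)
  sets <- sets %||% attr(census, "sets")
  if (is.null(sets)) stop("peptide sets not available", call. = FALSE)
  sub <- if (retained_only) census[census$retained, , drop = FALSE]
         else census
  peptides <- vapply(sets, function(s) s$name, "")
  edges <- list()
  for (i in seq_len(nrow(sub))) {
    fl <- parse_category(sub$category[i], sets)
    for (s in sets) {
      if (fl[[paste0(s$name, "_pep")]])
        edges[[length(edges) + 1]] <- c(sub$category[i], s$name,
                                        "producer")
      if (fl[[paste0(s$name, "_rec")]])
        edges[[length(edges) + 1]] <- c(s$name, sub$category[i],
                                        "receiver")
    }
  }
  verts <- data.frame(
    name = c(sub$category, peptides),
    type = c(rep("subtype", nrow(sub)), rep("peptide", length(peptides))),
    n_neurons = c(sub$n, rep(NA_integer_, length(peptides))),
    san_frac = c(sub$san_frac, rep(NA_real_, length(peptides))),
    stringsAsFactors = FALSE)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    ed <- data.frame(from = em[, 1], to = em[, 2], role = em[, 3],
                     stringsAsFactors = FALSE)
  } else {
    ed <- data.frame(from = character(0), to = character(0),
                     role = character(0))
  }
  igraph::graph_from_data_frame(ed, directed = TRUE, vertices = verts)
}

#' Export a paracrine network
#'
#' Writes the network as GraphML (`format = "graphml"`) or as a plain
#' edge list with the edge role column (`format = "edgelist"`).
#'
#' @param graph an igraph network from [build_network()].
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @export
write_network <- function(graph, path,
                          format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    ed <- igraph::as_data_frame(graph, what = "edges")
    write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
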