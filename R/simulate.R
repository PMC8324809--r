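#' Simulation configuration for synthetic ganglion data
#'
#' Builds and validates the configuration object consumed by
#' [simulate_qpcr()] and [simulate_counts()]. The defaults emulate the
#' statistical structure of a spatially-tracked single-neuron HT-qPCR
#' study of a cardiac ganglionic plexus: a few hundred neurons assayed on
#' a couple of hundred genes across four animals, latent transcriptional
#' states organized as overlapping gradients rather than discrete
#' clusters, a strongly co-expressed cholinergic/catecholaminergic marker
#' pair (`Chat`/`Th`), a +7 Ct abundance shift of `Chat` in one animal,
#' missing-at-random reaction failures, state-dependent mixing of
#' SAN-projection labels, and uniform 3D coordinates carrying no
#' expression information.
#'
#' @param n_neurons number of single neurons to simulate.
#' @param n_genes number of gene assays.
#' @param n_states number of latent transcriptional states `K`.
#' @param state_softness non-negative mixing parameter: 0 gives discrete
#'   states, larger values give Dirichlet gradient mixing between state
#'   mean profiles (the Dirichlet concentration on non-self states equals
#'   `state_softness`).
#' @param state_means optional `n_states x n_genes` matrix of per-state
#'   mean Ct values; generated from `baseline_ct_range`, `marker_frac`
#'   and `marker_shift` when `NULL`.
#' @param noise_sd per-reaction Gaussian noise, in Ct units.
#' @param coexpression_pairs list of `list(gene_a=, gene_b=, r=)` entries;
#'   each pair shares a latent factor sized to induce the target Pearson
#'   correlation. Pair genes get state-flat means so the realized
#'   correlation is controlled by the shared factor alone.
#' @param animal_offsets `data.frame(animal, gene, shift)` of additive
#'   per-animal per-gene Ct shifts (a higher Ct means lower abundance).
#'   The default `"default"` plants a +7 Ct shift of `Chat` in the last
#'   animal; `NULL` disables all offsets.
#' @param failure_rate probability that any reaction fails (recorded as
#'   `NA`), missing completely at random.
#' @param projection_probs per-state probability that a neuron carries the
#'   SAN-projecting label; defaults to a decreasing gradient so states mix
#'   both labels.
#' @param unknown_frac fraction of neurons whose projection label is
#'   replaced by `"unknown"` (neurons from an animal without tracer).
#' @param n_animals number of animals; neurons are split evenly.
#' @param spatial_extent named `(x, y, z)` tissue extent in micrometres.
#' @param gene_names optional gene ids; defaults to a panel starting with
#'   `Chat`, `Th` and the three neuropeptide/receptor sets used by
#'   [default_peptide_sets()].
#' @param baseline_ct_range range of per-gene baseline median Ct.
#' @param marker_frac fraction of genes acting as markers for each state.
#' @param marker_shift Ct decrease (abundance increase) of a marker gene
#'   in its state.
#' @param shallow_frac for [simulate_counts()]: fraction of samples given
#'   a crippled library size (few nonzero genes).
#' @param rare_gene_frac for [simulate_counts()]: fraction of genes made
#'   rare across all samples.
#' @param count_dispersion negative-binomial `size` for counts.
#' @param mean_library_size expected library size of a normal sample.
#' @param seed integer seed; the same configuration and seed give
#'   bit-identical output.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_neurons = 400L,
                       n_genes = 200L,
                       n_states = 6L,
                       state_softness = 0.1,
                       state_means = NULL,
                       noise_sd = 1,
                       coexpression_pairs = list(
                         list(gene_a = "Chat", gene_b = "Th", r = 0.8)),
                       animal_offsets = "default",
                       failure_rate = 0.05,
                       projection_probs = NULL,
                       unknown_frac = 0.2,
                       n_animals = 4L,
                       spatial_extent = c(x = 18800, y = 19400, z = 16000),
                       gene_names = NULL,
                       baseline_ct_range = c(10, 26),
                       marker_frac = 0.15,
                       marker_shift = 4,
                       shallow_frac = 0,
                       rare_gene_frac = 0,
                       count_dispersion = 2,
                       mean_library_size = 4e5,
                       seed = 1L) {
  bad <- function(field, why)
    stop("invalid configuration field '", field, "': ", why, call. = FALSE)

  chk_count <- function(x, field, min = 1) {
    if (length(x) != 1 || !is.finite(x) || x < min || x != round(x))
      bad(field, paste0("must be a single integer >= ", min))
  }
  chk_prob <- function(x, field) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      bad(field, "probabilities must lie in [0, 1]")
  }

  chk_count(n_neurons, "n_neurons")
  chk_count(n_genes, "n_genes")
  chk_count(n_states, "n_states")
  chk_count(n_animals, "n_animals")
  chk_count(seed, "seed", min = -Inf)
  if (length(state_softness) != 1 || !is.finite(state_softness) ||
      state_softness < 0)
    bad("state_softness", "must be a single value >= 0")
  if (length(noise_sd) != 1 || !is.finite(noise_sd) || noise_sd <= 0)
    bad("noise_sd", "must be a single value > 0")
  chk_prob(failure_rate, "failure_rate")
  chk_prob(unknown_frac, "unknown_frac")
  chk_prob(shallow_frac, "shallow_frac")
  chk_prob(rare_gene_frac, "rare_gene_frac")

  if (is.null(gene_names)) {
    core <- c("Chat", "Th", "Sst", "Sstr1", "Sstr2", "Gal", "Galr1",
              "Galr2", "Npy", "Npy1r", "Npy2r")
    if (n_genes < length(core))
      gene_names <- core[seq_len(n_genes)]
    else
      gene_names <- c(core, sprintf("g%03d", seq_len(n_genes - length(core))))
  }
  if (length(gene_names) != n_genes || anyDuplicated(gene_names))
    bad("gene_names", "must be n_genes unique ids")

  if (!is.null(state_means)) {
    if (!is.matrix(state_means) || nrow(state_means) != n_states ||
        ncol(state_means) != n_genes)
      bad("state_means", "must be an n_states x n_genes matrix")
  }

  if (!is.null(coexpression_pairs)) {
    for (p in coexpression_pairs) {
      if (!all(c("gene_a", "gene_b", "r") %in% names(p)))
        bad("coexpression_pairs", "entries need gene_a, gene_b, r")
      if (!all(c(p$gene_a, p$gene_b) %in% gene_names))
        bad("coexpression_pairs",
            paste("unknown gene in pair:", p$gene_a, "/", p$gene_b))
      if (!is.finite(p$r) || p$r <= -1 || p$r >= 1)
        bad("coexpression_pairs", "target r must lie in (-1, 1)")
    }
  }

  animals <- sprintf("A%d", seq_len(n_animals))
  if (identical(animal_offsets, "default")) {
    # Emulates the one-animal abundance shift of a cholinergic marker;
    # pass animal_offsets = NULL for no per-animal shifts.
    animal_offsets <-
      if ("Chat" %in% gene_names && n_animals > 1)
        data.frame(animal = animals[n_animals], gene = "Chat", shift = 7,
                   stringsAsFactors = FALSE)
      else NULL
  }
  if (!is.null(animal_offsets) && nrow(animal_offsets) == 0)
    animal_offsets <- NULL
  if (!is.null(animal_offsets)) {
    if (!is.data.frame(animal_offsets) ||
        !all(c("animal", "gene", "shift") %in% names(animal_offsets)))
      bad("animal_offsets", "must be a data.frame(animal, gene, shift)")
    if (!all(animal_offsets$animal %in% animals))
      bad("animal_offsets", "unknown animal id")
    if (!all(animal_offsets$gene %in% gene_names))
      bad("animal_offsets", "unknown gene id")
  }

  if (is.null(projection_probs))
    projection_probs <- seq(0.75, 0.25, length.out = n_states)
  if (length(projection_probs) != n_states)
    bad("projection_probs", "must have one probability per state")
  chk_prob(projection_probs, "projection_probs")

  if (length(spatial_extent) != 3 || any(!is.finite(spatial_extent)) ||
      any(spatial_extent <= 0))
    bad("spatial_extent", "must be three positive lengths (x, y, z)")
  names(spatial_extent) <- c("x", "y", "z")

  if (length(baseline_ct_range) != 2 || diff(baseline_ct_range) <= 0)
    bad("baseline_ct_range", "must be an increasing range")
  chk_prob(marker_frac, "marker_frac")
  if (!is.finite(marker_shift)) bad("marker_shift", "must be finite")
  if (!is.finite(count_dispersion) || count_dispersion <= 0)
    bad("count_dispersion", "must be > 0")
  if (!is.finite(mean_library_size) || mean_library_size <= 0)
    bad("mean_library_size", "must be > 0")

  structure(list(
    n_neurons = as.integer(n_neurons), n_genes = as.integer(n_genes),
    n_states = as.integer(n_states), state_softness = state_softness,
    state_means = state_means, noise_sd = noise_sd,
    coexpression_pairs = coexpression_pairs,
    animal_offsets = animal_offsets, failure_rate = failure_rate,
    projection_probs = projection_probs, unknown_frac = unknown_frac,
    n_animals = as.integer(n_animals), animals = animals,
    spatial_extent = spatial_extent, gene_names = gene_names,
    baseline_ct_range = baseline_ct_range, marker_frac = marker_frac,
    marker_shift = marker_shift, shallow_frac = shallow_frac,
    rare_gene_frac = rare_gene_frac, count_dispersion = count_dispersion,
    mean_library_size = mean_library_size, seed = as.integer(seed)),
    class = "sim_config")
}

# Internal: Dirichlet draws via gamma variates, one row per observation.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# Internal: build the n_states x n_genes mean-Ct matrix. Marker genes are
# shifted to lower Ct (more abundant) in their state; genes belonging to a
# co-expression pair keep a state-flat profile so the pair's correlation
# is governed by the shared latent factor alone.
default_state_means <- function(config) {
  G <- config$n_genes; K <- config$n_states
  baseline <- runif(G, config$baseline_ct_range[1], config$baseline_ct_range[2])
  M <- matrix(rep(baseline, each = K), nrow = K,
              dimnames = list(NULL, config$gene_names))
  pair_genes <- unlist(lapply(config$coexpression_pairs,
                              function(p) c(p$gene_a, p$gene_b)))
  eligible <- setdiff(config$gene_names, pair_genes)
  n_mark <- max(1L, round(config$marker_frac * G))
  markers <- vector("list", K)
  for (k in seq_len(K)) {
    mk <- sample(eligible, min(n_mark, length(eligible)))
    M[k, mk] <- M[k, mk] - config$marker_shift
    markers[[k]] <- mk
  }
  list(means = M, markers = markers)
}

#' Simulate a single-neuron HT-qPCR experiment
#'
#' Draws a Ct matrix (genes x neurons), per-neuron metadata and the
#' generating ground truth from a [sim_config()]. Each neuron's expected
#' profile is a convex (Dirichlet-weighted) mixture of the state mean
#' profiles, so small `state_softness` gives discrete clusters and larger
#' values the "single cloud" gradient geometry; reaction failures are
#' inserted completely at random as `NA`; 3D coordinates are uniform in
#' the tissue extent and independent of state.
#'
#' @param config a [sim_config()].
#' @return list of class `"qpcr_sim"` with elements `ct` (genes x neurons
#'   Ct matrix, `NA` = failed reaction), `meta` (data.frame with
#'   `sample_id`, `animal_id`, `projection`, `x`, `y`, `z`, `section`),
#'   and `truth` (list with `state`, `weights`, `state_means`,
#'   `marker_genes`).
#' @export
#' @examples
#' sim <- simulate_qpcr(sim_config(n_neurons = 50, n_genes = 30, seed = 7))
#' dim(sim$ct)
#' table(sim$truth$state)
simulate_qpcr <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must be created by sim_config()", call. = FALSE)
  set.seed(config$seed)
  N <- config$n_neurons; G <- config$n_genes; K <- config$n_states

  if (is.null(config$state_means)) {
    sm <- default_state_means(config)
    M <- sm$means; markers <- sm$markers
  } else {
    M <- config$state_means
    colnames(M) <- config$gene_names
    markers <- NULL
  }

  state <- sample.int(K, N, replace = TRUE)
  if (config$state_softness == 0) {
    W <- matrix(0, N, K)
    W[cbind(seq_len(N), state)] <- 1
  } else {
    W <- matrix(NA_real_, N, K)
    for (k in seq_len(K)) {
      idx <- which(state == k)
      if (!length(idx)) next
      alpha <- rep(config$state_softness, K)
      alpha[k] <- alpha[k] + 1
      W[idx, ] <- rdirichlet(length(idx), alpha)
    }
  }

  expected <- t(W %*% M)                     # genes x neurons
  rownames(expected) <- config$gene_names
  ct <- expected + matrix(rnorm(G * N, sd = config$noise_sd), G, N)

  # Shared latent factors induce the target pairwise correlations.
  for (p in config$coexpression_pairs) {
    tau <- config$noise_sd * sqrt(abs(p$r) / (1 - abs(p$r)))
    z <- rnorm(N, sd = tau)
    ct[p$gene_a, ] <- ct[p$gene_a, ] + z
    ct[p$gene_b, ] <- ct[p$gene_b, ] + sign(p$r) * z
  }

  sample_ids <- sprintf("N%04d", seq_len(N))
  colnames(ct) <- sample_ids
  animal <- rep_len(config$animals, N)

  if (!is.null(config$animal_offsets)) {
    for (i in seq_len(nrow(config$animal_offsets))) {
      o <- config$animal_offsets[i, ]
      ct[o$gene, animal == o$animal] <- ct[o$gene, animal == o$animal] + o$shift
    }
  }

  ct <- pmin(pmax(ct, 0.1), 40)

  if (config$failure_rate > 0) {
    fail <- runif(G * N) < config$failure_rate
    ct[fail] <- NA_real_
  }

  projection <- ifelse(rbinom(N, 1, config$projection_probs[state]) == 1,
                       "SAN-projecting", "non-SAN-projecting")
  if (config$unknown_frac > 0) {
    unk <- runif(N) < config$unknown_frac
    projection[unk] <- "unknown"
  }

  ext <- config$spatial_extent
  coords <- cbind(x = runif(N, 0, ext["x"]),
                  y = runif(N, 0, ext["y"]),
                  z = runif(N, 0, ext["z"]))
  meta <- data.frame(
    sample_id = sample_ids,
    animal_id = animal,
    projection = factor(projection, levels = PROJECTION_LEVELS),
    x = coords[, "x"], y = coords[, "y"], z = coords[, "z"],
    section = as.integer(ceiling(coords[, "z"] / 40)),  # 40 um sections
    stringsAsFactors = FALSE)

  structure(list(
    ct = ct, meta = meta,
    truth = list(state = state, weights = W, state_means = M,
                 marker_genes = markers)),
    class = "qpcr_sim")
}

#' Simulate an RNA-seq UMI count matrix
#'
#' Draws non-negative integer counts from a negative-binomial model with
#' state-specific gene means. A fraction `shallow_frac` of samples is
#' given a crippled library size so that they fall below any reasonable
#' nonzero-gene threshold, and a fraction `rare_gene_frac` of genes is
#' made rare everywhere, providing fixtures for [filter_counts()].
#'
#' @param config a [sim_config()]; uses `n_genes` as genes and
#'   `n_neurons` as samples.
#' @return integer matrix (genes x samples) with a `"shallow_samples"`
#'   attribute naming the crippled samples and a `"rare_genes"` attribute
#'   naming the rare genes.
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must be created by sim_config()", call. = FALSE)
  set.seed(config$seed)
  G <- config$n_genes; N <- config$n_neurons; K <- config$n_states

  base <- rlnorm(G, meanlog = 1, sdlog = 1.5)
  state_fac <- matrix(rlnorm(K * G, 0, 0.5), K, G)
  state <- sample.int(K, N, replace = TRUE)
  lib <- rlnorm(N, log(config$mean_library_size), 0.3)

  shallow <- character(0)
  sample_ids <- sprintf("S%04d", seq_len(N))
  if (config$shallow_frac > 0) {
    n_sh <- round(config$shallow_frac * N)
    sh <- sample.int(N, n_sh)
    lib[sh] <- lib[sh] * 1e-3
    shallow <- sample_ids[sh]
  }
  rare <- character(0)
  if (config$rare_gene_frac > 0) {
    n_r <- round(config$rare_gene_frac * G)
    rg <- sample.int(G, n_r)
    base[rg] <- base[rg] * 1e-5
    rare <- config$gene_names[rg]
  }

  p <- base / sum(base)
  mu <- t(state_fac[state, ] * rep(p, each = N)) * rep(lib, each = G)
  counts <- matrix(rnbinom(G * N, mu = mu, size = config$count_dispersion),
                   G, N, dimnames = list(config$gene_names, sample_ids))
  storage.mode(counts) <- "integer"
  attr(counts, "shallow_samples") <- shallow
  attr(counts, "rare_genes") <- rare
  counts
}

#' Simulate a tissue-by-gene median expression panel
#'
#' Builds a median-expression matrix in the mould of a multi-tissue
#' expression atlas, with `n_enriched` planted genes high in the
#' `n_neuronal` neuronal tissues and low elsewhere, for testing
#' [template_enrichment()].
#'
#' @param n_tissues total number of tissues.
#' @param n_neuronal number of neuronal tissues (must be a proper,
#'   non-empty subset of the tissues).
#' @param n_genes number of genes.
#' @param n_enriched number of planted neuronally-enriched genes
#'   (`<= n_genes`).
#' @param seed integer seed.
#' @return list of class `"tissue_panel"` with `expr` (genes x tissues
#'   median expression), `neuronal_tissues`, and `enriched_genes` (the
#'   planted ids).
#' @export
simulate_tissue_panel <- function(n_tissues = 30, n_neuronal = 10,
                                  n_genes = 500, n_enriched = 50,
                                  seed = 1L) {
  if (n_neuronal >= n_tissues || n_neuronal < 1)
    stop("invalid configuration field 'n_neuronal': must satisfy ",
         "1 <= n_neuronal < n_tissues", call. = FALSE)
  if (n_enriched > n_genes || n_enriched < 0)
    stop("invalid configuration field 'n_enriched': must satisfy ",
         "0 <= n_enriched <= n_genes", call. = FALSE)
  set.seed(seed)
  tissues <- c(sprintf("neural_%02d", seq_len(n_neuronal)),
               sprintf("tissue_%02d", seq_len(n_tissues - n_neuronal)))
  genes <- sprintf("g%04d", seq_len(n_genes))
  expr <- matrix(rlnorm(n_genes * n_tissues, meanlog = 2, sdlog = 1),
                 n_genes, n_tissues, dimnames = list(genes, tissues))
  enriched <- character(0)
  if (n_enriched > 0) {
    enriched <- sample(genes, n_enriched)
    neur <- seq_len(n_neuronal)
    expr[enriched, neur] <- rlnorm(n_enriched * n_neuronal, 4, 0.3)
    expr[enriched, -neur] <- rlnorm(n_enriched * (n_tissues - n_neuronal),
                                    0, 0.3)
  }
  structure(list(expr = expr,
                 neuronal_tissues = tissues[seq_len(n_neuronal)],
                 enriched_genes = sort(enriched)),
            class = "tissue_panel")
}

#' @export
print.qpcr_sim <- function(x, ...) {
  cat("Synthetic single-neuron qPCR data:",
      nrow(x$ct), "genes x", ncol(x$ct), "neurons\n")
  cat("  states:", length(unique(x$truth$state)),
      " animals:", length(unique(x$meta$animal_id)),
      " failed reactions:", sum(is.na(x$ct)), "\n")
  invisible(x)
}
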