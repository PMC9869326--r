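#' Simulate a negative-binomial counts experiment with planted DE
#'
#' Baseline gene means are log-normal; a random subset of genes receives
#' a planted log2 fold-change drawn from Normal(0, lfc_scale); counts are
#' negative binomial at the given dispersion. An optional batch factor
#' shifts a random half of genes, either balanced across the two
#' conditions or confounded with them. Deterministic given the seed.
#'
#' @param n_genes number of genes.
#' @param n_per_group replicates per condition (conditions "a" and "b").
#' @param de_fraction fraction of genes with planted DE.
#' @param lfc_scale SD of planted log2 fold-changes.
#' @param dispersion NB dispersion alpha.
#' @param batch_effect NULL, or list(lfc = log2 shift magnitude,
#'   confounded = logical).
#' @param seed RNG seed.
#' @return list(experiment = \code{counts_experiment}, truth = list of
#'   de_genes, planted_log2fc, batch_labels).
#' @export
simulate_counts <- function(n_genes = 2000, n_per_group = 5,
                            de_fraction = 0.1, lfc_scale = 1,
                            dispersion = 0.1, batch_effect = NULL,
                            seed = 1L) {
  stopifnot(n_genes > 0, n_per_group >= 3, de_fraction >= 0, de_fraction <= 1)
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  n <- 2L * n_per_group
  cond <- rep(c("a", "b"), each = n_per_group)
  base_mu <- stats::rlnorm(n_genes, meanlog = log(100), sdlog = 1.2)
  n_de <- round(de_fraction * n_genes)
  de_idx <- sort(sample.int(n_genes, n_de))
  lfc <- stats::setNames(rep(0, n_genes), genes)
  lfc[de_idx] <- stats::rnorm(n_de, 0, lfc_scale)
  mu <- outer(base_mu, rep(1, n))
  mu[, cond == "b"] <- mu[, cond == "b"] * 2^lfc
  batch <- rep("batch1", n)
  if (!is.null(batch_effect)) {
    batch <- if (isTRUE(batch_effect$confounded)) {
      ifelse(cond == "a", "batch1", "batch2")
    } else {
      rep(rep(c("batch1", "batch2"), length.out = n_per_group), 2)
    }
    bgenes <- sample.int(n_genes, round(n_genes / 2))
    shift <- 2^batch_effect$lfc
    mu[bgenes, batch == "batch2"] <- mu[bgenes, batch == "batch2"] * shift
  }
  counts <- matrix(stats::rnbinom(n_genes * n, mu = mu, size = 1 / dispersion),
                   nrow = n_genes, dimnames = list(genes, sprintf("S%02d", seq_len(n))))
  meta <- data.frame(condition = cond, batch = batch,
                     age = round(stats::runif(n, 20, 70)),
                     stringsAsFactors = FALSE)
  list(experiment = counts_experiment(counts, meta, "condition"),
       truth = list(de_genes = genes[de_idx], planted_log2fc = lfc,
                    batch_labels = batch))
}

# synthetic FDR values: DE genes Beta(1, 50) truncated below 0.05,
# non-DE genes Uniform(0.05, 1]
sim_fdr <- function(is_de) {
  n <- length(is_de)
  fdr <- numeric(n)
  nd <- sum(is_de)
  if (nd) {
    u <- stats::runif(nd) * stats::pbeta(0.05, 1, 50)
    fdr[is_de] <- stats::qbeta(u, 1, 50)
  }
  fdr[!is_de] <- stats::runif(n - nd, 0.05, 1)
  fdr
}

#' Simulate a compendium with planted block structure
#'
#' Generates \code{n_comparisons} comparison records split into
#' \code{n_blocks}. Each block has a shared DEG core (a fraction of every
#' member's DEGs common to the block) plus member-private DEGs; FDR
#' values are low for DEGs (Beta(1, 50) truncated below 0.05) and
#' Uniform(0.05, 1] otherwise; log2 fold-changes of core genes follow a
#' shared block signature plus noise, so within-block profiles correlate.
#' The first comparison is the designated planted match: its core DEGs,
#' ranked by FDR, double as a ready-made query list.
#'
#' @param n_comparisons number of comparisons.
#' @param n_blocks number of planted blocks.
#' @param within_block_shared_fraction fraction of each member's DEGs
#'   drawn from the block core.
#' @param n_genes size of the gene universe.
#' @param n_de DEGs per comparison.
#' @param detect_fraction fraction of the universe detected per
#'   comparison (DEGs are always detected).
#' @param seed RNG seed.
#' @return list(compendium, truth = list(planted_clusters, planted_match,
#'   query_genes, block_cores)).
#' @export
simulate_compendium <- function(n_comparisons = 12, n_blocks = 2,
                                within_block_shared_fraction = 0.8,
                                n_genes = 1500, n_de = 100,
                                detect_fraction = 1, seed = 1L) {
  stopifnot(n_blocks <= n_comparisons, n_de < n_genes,
            within_block_shared_fraction >= 0, within_block_shared_fraction <= 1)
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  blocks <- rep(seq_len(n_blocks), length.out = n_comparisons)
  blocks <- sort(blocks)
  core_size <- round(within_block_shared_fraction * n_de)
  cores <- lapply(seq_len(n_blocks), function(b) sample(genes, core_size))
  sig <- lapply(seq_len(n_blocks), function(b)
    stats::setNames(stats::rnorm(core_size, 0, 2), cores[[b]]))
  records <- vector("list", n_comparisons)
  for (i in seq_len(n_comparisons)) {
    b <- blocks[i]
    core <- cores[[b]]
    private <- sample(setdiff(genes, core), n_de - core_size)
    de <- c(core, private)
    detected <- if (detect_fraction < 1) {
      unique(c(de, sample(genes, round(detect_fraction * n_genes))))
    } else genes
    is_de <- detected %in% de
    fdr <- sim_fdr(is_de)
    lfc <- stats::rnorm(length(detected), 0, 0.1)
    names(lfc) <- detected
    lfc[core] <- sig[[b]][core] + stats::rnorm(core_size, 0, 0.3)
    lfc[private] <- stats::rnorm(length(private), 0, 2)
    tab <- data.frame(gene = detected, log2fc = unname(lfc),
                      pvalue = fdr * 0.8, fdr = fdr, is_de = is_de,
                      stringsAsFactors = FALSE)
    id <- sprintf("SYN%03d", i)
    nm <- name_comparison(id, "tissue", "control", sprintf("treat%d", i))
    records[[i]] <- comparison_record(
      id = id, name = nm, source = "synthetic",
      category = sprintf("block%d", b), deg_table = tab,
      detected_genes = detected,
      n_samples_total = 10L, n_samples_up = 5L, n_samples_down = 5L)
  }
  comp <- compendium(records)
  # the ready-made query is the planted comparison's full ranked DEG list
  # (core + private), so its source strictly dominates its block-mates
  match_rec <- records[[1]]
  query <- rank_degs(match_rec$deg_table)$gene
  list(compendium = comp,
       truth = list(planted_clusters = stats::setNames(blocks,
                                                       names(comp$comparisons)),
                    planted_match = match_rec$id,
                    query_genes = query,
                    block_cores = cores))
}

#' Simulate a gene-set database
#'
#' Random sets drawn from the universe within a size range, optionally
#' with one set planted verbatim (for recovery tests).
#'
#' @param n_sets number of random sets.
#' @param size_range inclusive range of set sizes.
#' @param universe character vector of genes.
#' @param planted_in optional gene list included verbatim as set
#'   "PLANTED".
#' @param seed RNG seed.
#' @return A \code{gene_set_db}.
#' @export
simulate_genesets <- function(n_sets = 50, size_range = c(15L, 100L),
                              universe, planted_in = NULL, seed = 1L) {
  stopifnot(size_range[2] <= length(universe))
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i)
    sample(universe, sample(seq(size_range[1], size_range[2]), 1)))
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  if (!is.null(planted_in)) sets <- c(list(PLANTED = unique(planted_in)), sets)
  gene_set_db(sets, source_label = "simulated")
}
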