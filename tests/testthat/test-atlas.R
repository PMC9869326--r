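make_record <- function(id, fdr, lfc = NULL, detected = NULL) {
  genes <- names(fdr)
  if (is.null(lfc)) lfc <- rnorm(length(genes))
  tab <- data.frame(gene = genes, log2fc = lfc, pvalue = pmin(fdr, 1) * 0.9,
                    fdr = fdr, is_de = fdr < 0.05, stringsAsFactors = FALSE)
  if (is.null(detected)) detected <- genes
  comparison_record(id, paste0(id, ": t.a vs b"), "synthetic", tab, detected)
}

test_that("pairwise correlation uses co-detected union-DE genes", {
  set.seed(81)
  genes <- sprintf("g%03d", 1:100)
  fdr1 <- setNames(runif(100), genes); fdr1[1:20] <- runif(20, 0, 0.01)
  fdr2 <- fdr1 * 0.95 + 0.001  # near-duplicate profile
  fdr3 <- setNames(runif(100), genes); fdr3[90:100] <- 0.001
  comp <- compendium(list(make_record("a", fdr1), make_record("b", fdr2),
                          make_record("c", fdr3)))
  M <- pairwise_comparison_correlation(comp)
  expect_equal(diag(M$r2), c(a = 1, b = 1, c = 1))
  expect_equal(M$r2, t(M$r2))
  expect_gt(M$r2["a", "b"], 0.9)   # perturbation keeps r^2 high

  # a pair with < 3 co-usable genes is missing
  few1 <- make_record("d", setNames(c(0.01, 0.5, 0.6), c("x1", "x2", "x3")))
  few2 <- make_record("e", setNames(c(0.9, 0.8), c("x1", "x9")),
                      detected = c("x1", "x9"))
  comp2 <- compendium(list(few1, few2))
  M2 <- pairwise_comparison_correlation(comp2)
  expect_true(is.na(M2$r2["d", "e"]))
})

test_that("clustering recovers planted blocks and respects cut parameters", {
  skip_if_not_installed("mclust")
  sc <- tiny_compendium()
  M <- pairwise_comparison_correlation(sc$compendium)
  labels <- cluster_comparisons(M, n_clusters = 2)
  ari <- mclust::adjustedRandIndex(labels, sc$truth$planted_clusters)
  expect_equal(ari, 1)

  # two identical comparisons always co-cluster
  genes <- sprintf("g%03d", 1:50)
  fdr <- setNames(c(runif(10, 0, 0.01), runif(40, 0.1, 1)), genes)
  twin <- compendium(list(make_record("t1", fdr), make_record("t2", fdr),
                          make_record("t3", setNames(runif(50), genes))))
  Mt <- pairwise_comparison_correlation(twin)
  lt <- cluster_comparisons(Mt, n_clusters = 2)
  expect_equal(lt[["t1"]], lt[["t2"]])

  all_single <- cluster_comparisons(Mt, height = 0)
  expect_length(unique(all_single), 3L)
})

test_that("median within-cluster overlap matches constructed fractions", {
  g <- function(i) sprintf("g%03d", i)
  identical_pair <- list(
    make_record("i1", setNames(rep(0.01, 10), g(1:10))),
    make_record("i2", setNames(rep(0.01, 10), g(1:10))))
  half_pair <- list(
    make_record("h1", setNames(rep(0.01, 10), g(11:20))),
    make_record("h2", setNames(rep(0.01, 10), g(16:25))))
  disjoint_pair <- list(
    make_record("d1", setNames(rep(0.01, 10), g(31:40))),
    make_record("d2", setNames(rep(0.01, 10), g(41:50))))
  comp <- compendium(c(identical_pair, half_pair, disjoint_pair))
  labels <- setNames(c(1L, 1L, 2L, 2L, 3L, 3L), names(comp$comparisons))
  med <- median_cluster_overlap(comp, labels)
  expect_equal(unname(med), c(1.0, 0.5, 0.0))
  singleton <- median_cluster_overlap(comp, setNames(1:6, names(comp$comparisons)))
  expect_true(all(is.na(singleton)))
})

test_that("cluster annotation fuses member FDR profiles", {
  set.seed(82)
  universe <- sprintf("g%03d", 1:300)
  planted <- universe[1:30]
  db <- simulate_genesets(12, c(15L, 40L), universe, planted_in = planted,
                          seed = 82)
  recs <- lapply(1:3, function(i) {
    fdr <- setNames(runif(300, 0.05, 1), universe)
    fdr[planted] <- runif(30, 0, 0.01)
    make_record(paste0("m", i), fdr)
  })
  comp <- compendium(recs)
  labels <- setNames(rep(1L, 3), names(comp$comparisons))
  ann <- annotate_clusters(comp, labels, db)
  expect_equal(ann[["1"]]$term_id[1], "PLANTED")
  expect_lt(ann[["1"]]$fdr[1], 0.05)
})

test_that("the DE prior counts frequencies over detected comparisons", {
  g <- sprintf("g%02d", 1:10)
  r1 <- make_record("p1", setNames(c(rep(0.01, 3), rep(0.5, 7)), g))
  r2 <- make_record("p2", setNames(c(rep(0.01, 2), rep(0.5, 6)), g[1:8]),
                    detected = g[1:8])
  comp <- compendium(list(r1, r2))
  prior <- de_prior(comp)
  expect_equal(prior$de_frequency[prior$gene == "g01"], 1)      # 2/2
  expect_equal(prior$de_frequency[prior$gene == "g03"], 0.5)    # 1/2
  expect_equal(prior$de_frequency[prior$gene == "g09"], 0)      # detected once, never DE
  expect_equal(prior$rank, seq_len(nrow(prior)))
  expect_equal(prior$gene[1:2], c("g01", "g02"))  # ties broken lexicographically

  # brute-force check on random compendia
  set.seed(83)
  for (i in 1:20) {
    sc <- simulate_compendium(n_comparisons = 4, n_genes = 80, n_de = 10,
                              detect_fraction = 0.8, seed = 300 + i)
    prior <- de_prior(sc$compendium)
    g0 <- sample(prior$gene, 5)
    for (gene in g0) {
      nd <- sum(vapply(sc$compendium$comparisons, function(r)
        gene %in% r$detected_genes, logical(1)))
      ne <- sum(vapply(sc$compendium$comparisons, function(r)
        gene %in% r$deg_table$gene[r$deg_table$is_de], logical(1)))
      expect_equal(prior$de_frequency[prior$gene == gene],
                   if (nd) ne / nd else 0)
    }
  }
})

test_that("prior overlap curves behave at the identity and independence limits", {
  set.seed(84)
  sc <- tiny_compendium()
  prior <- de_prior(sc$compendium)
  self <- prior_overlap_curve(prior, prior, step = 0.1)
  expect_equal(self$n_overlap, self$n_top)  # identical priors overlap fully
  expect_true(is.na(self$odds_ratio[self$q == 1]))
  expect_lt(self$pvalue[1], 1e-6)

  # independent random priors give odds ratios near 1 at q = 0.1
  ors <- replicate(50, {
    genes <- sprintf("r%03d", 1:200)
    mk <- function() {
      d <- data.frame(gene = genes, de_frequency = runif(200))
      d <- d[order(-d$de_frequency, d$gene), ]
      d$rank <- seq_len(nrow(d)); class(d) <- c("de_prior", class(d)); d
    }
    curve <- prior_overlap_curve(mk(), mk(), step = 0.1)
    curve$odds_ratio[curve$q == 0.1]
  })
  expect_gt(median(ors), 0.8)
  expect_lt(median(ors), 1.25)
})
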