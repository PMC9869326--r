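test_that("user input normalization applies the 0.049 rules", {
  un <- prepare_user_input(paste0("g", 1:5))
  expect_equal(un$mode, "unordered")
  expect_equal(un$pvalues, rep(0.049, 5))

  or <- prepare_user_input(paste0("g", 1:5), ordered = TRUE)
  expect_equal(or$mode, "ordered")
  expect_equal(or$pvalues, 0.049 * (1:5) / 5)
  expect_equal(max(or$pvalues), 0.049)

  full <- prepare_user_input(c("a", "b"), pvalues = c(0.01, 0.2),
                             coefficients = c(1.5, -2))
  expect_equal(full$mode, "full")
  expect_equal(full$pvalues, c(0.01, 0.2))
  expect_error(prepare_user_input(c("a"), pvalues = 0.01), "coefficients")
  expect_error(prepare_user_input(c("a", "b"), pvalues = c(0, 0.5),
                                  coefficients = c(1, 2)), "\\(0, 1\\]")
})

test_that("duplicate query genes collapse by minimum p by default", {
  q <- prepare_user_input(c("a", "b", "a"), pvalues = c(0.5, 0.2, 0.01),
                          coefficients = c(1, 2, 3))
  expect_equal(q$genes, c("a", "b"))   # first-occurrence order kept
  expect_equal(q$pvalues, c(0.01, 0.2))
  expect_equal(q$coefficients, c(3, 2))
  qf <- prepare_user_input(c("a", "b", "a"), pvalues = c(0.5, 0.2, 0.01),
                           coefficients = c(1, 2, 3), collapse = "first")
  expect_equal(qf$pvalues, c(0.5, 0.2))
  up <- prepare_user_input(c("Tnf", "TNF"), uppercase = TRUE)
  expect_equal(up$genes, "TNF")
})

test_that("background resolution defaults to the compendium universe", {
  sc <- tiny_compendium()
  q <- prepare_user_input(sc$truth$query_genes)
  expect_setequal(resolve_background(q, sc$compendium), sc$compendium$universe)
  q2 <- prepare_user_input(c(sc$truth$query_genes, "NOVEL1"))
  expect_warning(bg <- resolve_background(q2, sc$compendium), "absent")
  expect_true("NOVEL1" %in% bg)
  q3 <- prepare_user_input("g1", background = c("g1", "g2", "g3"))
  expect_setequal(resolve_background(q3, sc$compendium), c("g1", "g2", "g3"))
})

test_that("a planted query ranks its source comparison first", {
  sc <- tiny_compendium()
  q <- prepare_user_input(sc$truth$query_genes, ordered = TRUE)
  rep <- query_compendium(q, sc$compendium)
  expect_equal(rep$deg_overlap$term_id[1], sc$truth$planted_match)
  expect_equal(rep$deg_overlap$rank[1], 1L)
  expect_lt(rep$deg_overlap$fdr[1], 0.05)
  # ranks are a dense permutation
  expect_setequal(rep$deg_overlap$rank, seq_len(nrow(rep$deg_overlap)))
})

test_that("self-query returns the comparison at rank 1 with perfect correlation", {
  sc <- tiny_compendium()
  rec <- sc$compendium$comparisons[[sc$truth$planted_match]]
  de <- rec$deg_table[rec$deg_table$is_de, ]
  q <- prepare_user_input(de$gene, pvalues = pmax(de$fdr, 1e-12),
                          coefficients = de$log2fc)
  rep <- query_compendium(q, sc$compendium)
  expect_equal(rep$deg_overlap$term_id[1], rec$id)
  corr_row <- rep$correlations[rep$correlations$term_id == rec$id, ]
  expect_equal(corr_row$pearson_r, 1, tolerance = 1e-12)
  expect_equal(corr_row$spearman_rho, 1, tolerance = 1e-12)
})

test_that("correlation channels honor the input mode", {
  sc <- tiny_compendium()
  genes <- sc$truth$query_genes
  un <- query_compendium(prepare_user_input(genes), sc$compendium)
  expect_equal(nrow(un$correlations), 0L)   # unordered: no correlations
  or <- query_compendium(prepare_user_input(genes, ordered = TRUE),
                         sc$compendium)
  expect_true(all(is.na(or$correlations$pearson_r)))  # ordered: Spearman only
  expect_true(any(!is.na(or$correlations$spearman_rho)))
  # disabling correlations does not perturb the overlap channel
  expect_equal(un$deg_overlap$pvalue, or$deg_overlap$pvalue)
})

test_that("per-comparison correlation needs three overlapping DEGs", {
  tab <- data.frame(gene = paste0("g", 1:10), log2fc = seq(-2, 2.5, 0.5),
                    pvalue = rep(0.001, 10), fdr = rep(0.01, 10),
                    is_de = TRUE)
  rec <- comparison_record("c1", "S: t.a vs b", "synthetic", tab,
                           paste0("g", 1:10))
  coefs <- setNames(tab$log2fc, tab$gene)
  full <- correlate_with_comparison(coefs, rec)
  expect_equal(full$pearson_r, 1)
  expect_equal(full$spearman_rho, 1)
  expect_equal(full$n, 10L)
  expect_true(is.na(correlate_with_comparison(coefs[1:2], rec)$pearson_r))

  set.seed(61)
  z <- MASS::mvrnorm(200, c(0, 0), matrix(c(1, 0.8, 0.8, 1), 2))
  tab2 <- data.frame(gene = paste0("h", 1:200), log2fc = z[, 2],
                     pvalue = 0.001, fdr = 0.01, is_de = TRUE)
  rec2 <- comparison_record("c2", "S2: t.a vs b", "synthetic", tab2,
                            paste0("h", 1:200))
  est <- correlate_with_comparison(setNames(z[, 1], tab2$gene), rec2)
  expect_gt(est$pearson_r, 0.7)
  expect_lt(est$pearson_r, 0.9)
})

test_that("input-as-reference recovers its own comparison and matches brute force", {
  sc <- tiny_compendium()
  rec <- sc$compendium$comparisons[[3]]
  own <- rec$deg_table$gene[rec$deg_table$is_de]
  res <- input_as_reference(own, sc$compendium)
  expect_equal(res$term_id[which.min(res$pvalue)], rec$id)

  disjoint <- input_as_reference(paste0("zz", 1:20), sc$compendium)
  expect_true(all(disjoint$pvalue == 1))

  set.seed(62)
  for (i in 1:10) {
    small <- simulate_compendium(n_comparisons = 4, n_blocks = 2,
                                 n_genes = 120, n_de = 15, seed = 100 + i)
    user <- sample(small$compendium$universe, 20)
    res <- input_as_reference(user, small$compendium)
    bg <- unique(c(small$compendium$universe, user))
    for (id in res$term_id) {
      r <- small$compendium$comparisons[[id]]
      ranked <- r$deg_table[r$deg_table$is_de, ]
      ranked <- ranked[order(ranked$fdr, -abs(ranked$log2fc), ranked$gene), ]
      oracle <- ranked_hyper_oracle(ranked$gene, unique(user), bg)
      expect_equal(res$pvalue[res$term_id == id], oracle$pvalue,
                   tolerance = 1e-9)
    }
  }
})

test_that("genes-only mode matches the full query's overlap channel", {
  sc <- tiny_compendium()
  q <- prepare_user_input(sc$truth$query_genes, ordered = TRUE)
  full <- query_compendium(q, sc$compendium)
  go <- enrich_genes_only(q, sc$compendium)
  expect_equal(go$deg_overlap$pvalue, full$deg_overlap$pvalue)
  expect_equal(nrow(go$user_pathways), 0L)
  mixed <- prepare_user_input(paste0("ENSG", 1:10))
  w <- capture_warnings(enrich_genes_only(mixed, sc$compendium))
  expect_match(w, "namespace", all = FALSE)  # also warns about absent genes
})

test_that("report tables cap rows and classify sign agreement", {
  sc <- tiny_compendium()
  rec <- sc$compendium$comparisons[[sc$truth$planted_match]]
  de <- rec$deg_table[rec$deg_table$is_de, ]
  q <- prepare_user_input(de$gene, pvalues = pmax(de$fdr, 1e-12),
                          coefficients = de$log2fc)
  rep <- query_compendium(q, sc$compendium)
  tabs <- report_tables(rep, q, sc$compendium, top_n = 5)
  expect_lte(nrow(tabs$channels$deg_overlap), 5L)
  expect_true(all(c("neg_log10_fdr") %in% names(tabs$channels$deg_overlap)))
  sc_tab <- tabs$scatter
  both <- sc_tab[!is.na(sc_tab$user_coefficient) &
                   !is.na(sc_tab$comparison_log2fc), ]
  expect_true(all(both$agreement == "same-sign"))  # self-query agrees everywhere
  empty_rep <- rep
  for (ch in c("deg_overlap", "pathway_overlap", "tf_overlap", "correlations"))
    empty_rep[[ch]] <- empty_rep[[ch]][0, ]
  tabs0 <- report_tables(empty_rep)
  expect_equal(nrow(tabs0$channels$deg_overlap), 0L)
})
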