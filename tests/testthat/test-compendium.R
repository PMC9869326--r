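test_that("comparison naming is alphabetical and idempotent", {
  expect_equal(name_comparison("SRP032743", "ESC", "siLIN41-1", "Control"),
               "SRP032743: ESC.Control vs siLIN41-1")
  expect_equal(name_comparison("SRP032743", "ESC", "Control", "siLIN41-1"),
               "SRP032743: ESC.Control vs siLIN41-1")
  expect_equal(name_comparison("S1", "unknown", "a", "b"),
               "S1: unknown.a vs b")
  expect_error(name_comparison("", "t", "a", "b"), "non-empty")
})

test_that("inclusion screening flags each exclusion rule with its reason", {
  base <- function(...) {
    args <- utils::modifyList(
      list(study_id = "S1", tissue = "liver", cond1 = "control",
           cond2 = "treated", n1 = 5, n2 = 5), list(...))
    do.call(design_spec, args)
  }
  expect_true(check_inclusion(base())$include)
  expect_equal(check_inclusion(base(n1 = 2, n2 = 8))$reasons, "replicates")
  expect_equal(check_inclusion(base(generic_ids = TRUE))$reasons,
               "generic-conditions")
  expect_equal(check_inclusion(base(tissue2 = "kidney"))$reasons,
               "cross-tissue")
  expect_equal(check_inclusion(base(cond2 = "unknown"))$reasons,
               "na-or-unknown-condition")

  strat <- base(group_meta = data.frame(
    group = rep(1:2, each = 4),
    sex = rep(c("F", "M"), each = 4)), controlled_vars = "sex")
  expect_equal(check_inclusion(strat)$reasons, "stratification")
  balanced <- base(group_meta = data.frame(
    group = rep(1:2, each = 4),
    sex = rep(c("F", "M"), 4)), controlled_vars = "sex")
  expect_true(check_inclusion(balanced)$include)
})

test_that("time-series and treatment-pair rules follow the adjacency convention", {
  tl <- c("T0", "T2", "T3", "T4")
  ts <- function(c1, c2) design_spec("S1", "cells", c1, c2, 5, 5,
                                     time_levels = tl)
  expect_true(check_inclusion(ts("T0", "T4"))$include)   # reference to any
  expect_true(check_inclusion(ts("T2", "T3"))$include)   # stepwise
  expect_equal(check_inclusion(ts("T2", "T4"))$reasons, "nonlinear-timepoint")

  tvt <- design_spec("S1", "cells", "drugA", "drugB", 5, 5,
                     n_study_comparisons = 5L, control_label = "untreated")
  expect_equal(check_inclusion(tvt)$reasons, "treatment-vs-treatment")
  few <- design_spec("S1", "cells", "drugA", "drugB", 5, 5,
                     n_study_comparisons = 3L, control_label = "untreated")
  expect_true(check_inclusion(few)$include)
})

make_de_result <- function(n_de, n_genes = 100, seed = 1) {
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  is_de <- seq_len(n_genes) <= n_de
  fdr <- ifelse(is_de, runif(n_genes, 0, 0.04), runif(n_genes, 0.06, 1))
  tab <- data.frame(gene = genes, log2fc = rnorm(n_genes, 0, 2),
                    pvalue = fdr * 0.8, fdr = fdr, is_de = is_de,
                    stringsAsFactors = FALSE)
  structure(list(deg_table = tab, detected_genes = genes),
            class = "de_result")
}

test_that("compendium assembly accounts for every exclusion", {
  ok_spec <- function(id, c2 = "treated")
    design_spec(id, "liver", "control", c2, 5, 5)
  results <- list(
    list(de = make_de_result(20, seed = 1), spec = ok_spec("S1")),
    list(de = make_de_result(20, seed = 2),
         spec = design_spec("S2", "liver", "control", "treated", 2, 8)),
    list(de = make_de_result(3, seed = 3), spec = ok_spec("S3")),
    list(de = make_de_result(30, seed = 4), spec = ok_spec("S4")))
  built <- build_compendium(results)
  expect_length(built$compendium, 2L)
  expect_equal(nrow(built$report), 4L)
  expect_equal(sum(built$report$included), 2L)
  expect_setequal(built$report$reason[!built$report$included],
                  c("replicates", "too-few-degs"))
  # empty input still yields a valid object
  empty <- build_compendium(list())
  expect_length(empty$compendium, 0L)
})

test_that("duplicate comparison names are suffixed, not dropped", {
  spec1 <- design_spec("S1", "liver", "control", "treated", 5, 5)
  results <- list(list(de = make_de_result(20, seed = 1), spec = spec1),
                  list(de = make_de_result(25, seed = 2), spec = spec1))
  expect_message(built <- build_compendium(results), "suffixing")
  expect_length(built$compendium, 2L)
})

test_that("summary cards cap their lists and count both directions", {
  de <- make_de_result(60, n_genes = 200, seed = 5)
  rec <- comparison_record("id1", "S1: t.a vs b", "synthetic",
                           de$deg_table, de$detected_genes)
  rec <- build_summary_card(rec)
  card <- rec$summary_card
  expect_lte(length(card$top_up), 15L)
  expect_lte(length(card$top_down), 15L)
  expect_equal(card$n_de_total, 60L)
  expect_equal(card$n_de_up + card$n_de_down, 60L)
  # ordered by significance
  tab <- rec$deg_table
  first_up <- tab[tab$gene == card$top_up[1], ]
  up_all <- tab[tab$is_de & tab$log2fc > 0, ]
  expect_equal(first_up$fdr, min(up_all$fdr))
})

test_that("annotation restricts term sizes to the detected background", {
  set.seed(51)
  universe <- sprintf("G%04d", 1:400)
  de <- make_de_result(40, n_genes = 400, seed = 51)
  planted <- de$deg_table$gene[order(de$deg_table$fdr)][1:25]
  db <- simulate_genesets(20, c(15L, 50L), universe, planted_in = planted,
                          seed = 51)
  # a set whose genes lie outside the background must vanish
  db$sets$OUTSIDE <- sprintf("X%03d", 1:30)
  db$descriptions["OUTSIDE"] <- "OUTSIDE"
  rec <- comparison_record("id1", "S1: t.a vs b", "synthetic",
                           de$deg_table, de$detected_genes)
  rec <- annotate_comparison(rec, pathway_db = db, tf_db = db)
  expect_false("OUTSIDE" %in% rec$enriched_pathways$term_id)
  expect_equal(rec$enriched_pathways$term_id[1], "PLANTED")
  expect_true(rec$enriched_pathways$significant[1])
})

test_that("compendium GMT export splits directions and skips empty sets", {
  tab <- data.frame(gene = paste0("g", 1:6),
                    log2fc = c(1, 2, 3, -1, -2, 0.5),
                    pvalue = rep(0.001, 6),
                    fdr = c(rep(0.01, 5), 0.9),
                    is_de = c(rep(TRUE, 5), FALSE))
  rec1 <- comparison_record("c1", "S1: t.a vs b", "synthetic", tab,
                            paste0("g", 1:10))
  tab2 <- tab; tab2$is_de <- FALSE
  rec2 <- comparison_record("c2", "S2: t.a vs b", "synthetic", tab2,
                            paste0("g", 1:10))
  comp <- compendium(list(rec1, rec2))
  expect_setequal(compendium_to_gmt(comp, "up")$sets$c1, paste0("g", 1:3))
  expect_setequal(compendium_to_gmt(comp, "down")$sets$c1, paste0("g", 4:5))
  all_db <- compendium_to_gmt(comp, "all")
  expect_length(all_db$sets$c1, 5L)
  expect_false("c2" %in% names(all_db$sets))  # zero-DEG comparison omitted
  expect_equal(comp$universe, paste0("g", 1:10))
})

test_that("reference-overlap arithmetic reproduces the published validation cells", {
  # printed counts: study total 40, intersecting 35, atlas total 782
  study <- sprintf("S%03d", 1:40)
  atlas <- c(study[1:35], sprintf("A%04d", 1:747))
  bg <- unique(c(study, atlas, sprintf("B%04d", 1:5000)))
  res <- overlap_with_reference(atlas, study, bg)
  expect_equal(res$n_intersect, 35L)
  expect_equal(res$n_study_specific, 5L)
  expect_equal(res$n_atlas_specific, 747L)
  expect_equal(round(res$genes_captured, 2), 87.50)
  expect_lt(res$pvalue, 1e-10)
  expect_gt(res$odds_ratio, 1)
})

test_that("compendium save/load round-trips records and annotation", {
  sc <- tiny_compendium()
  dir <- withr::local_tempdir()
  save_compendium(sc$compendium, dir)
  back <- load_compendium(dir)
  expect_equal(names(back$comparisons), names(sc$compendium$comparisons))
  expect_setequal(back$universe, sc$compendium$universe)
  r0 <- sc$compendium$comparisons[[1]]; r1 <- back$comparisons[[1]]
  expect_equal(r1$deg_table$gene, r0$deg_table$gene)
  expect_equal(r1$deg_table$fdr, r0$deg_table$fdr, tolerance = 1e-12)
  expect_equal(r1$name, r0$name)
})
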