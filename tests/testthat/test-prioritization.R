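test_that("build_groups partitions comparisons into the six groups", {
  cfg <- study_config(design = layout_design(3), n_genes = 20, seed = 2)
  bundle <- generate_study(cfg)
  groups <- build_groups(bundle$comparisons)
  expect_named(groups, meta_group_ids())
  expect_equal(unname(vapply(groups, function(g) length(g$comparisons), 0L)),
               c(5L, 7L, 1L, 1L, 1L, 1L))
  # partition: no loss, no duplication
  expect_equal(sum(lengths(lapply(groups, `[[`, "comparisons"))), 16)
  all_sources <- unlist(lapply(groups, function(g)
    vapply(g$comparisons, `[[`, "", "source_name")))
  expect_setequal(all_sources,
                  vapply(bundle$comparisons, `[[`, "", "source_name"))
  expect_length(build_groups(list()), 0)
})

test_that("consistency reproduces the printed quantization", {
  expect_equal(consistency(c(0.3, 1.2, -0.1, 0.8, 0.05), "up"), 80)
  expect_equal(consistency(c(1, 2, 0.5, 0.1, 0.9, 0.2, -1), "up"), 86)
  expect_equal(consistency(rep(-1, 5), "up"), 0)
  expect_equal(consistency(c(1, 1, 1, 1, 1, 1, -1), "down"), 14)
  expect_error(consistency(numeric(0)), class = "undefined_consistency")
})

test_that("up and down consistencies are complementary unless lfc hits zero", {
  set.seed(4)
  for (i in 1:25) {
    lfc <- round(rnorm(sample(3:9, 1)), 1)
    up <- consistency(lfc, "up", round = FALSE)
    down <- consistency(lfc, "down", round = FALSE)
    expect_lte(up + down, 100)
    if (all(lfc != 0)) expect_equal(up + down, 100)
  }
  expect_lt(consistency(c(0, 1, -1), "up", round = FALSE) +
              consistency(c(0, 1, -1), "down", round = FALSE), 100)
})

test_that("metascore aggregates rank-normalized families", {
  tab <- data.frame(gene = c("A", "B", "C", "D", "E"),
                    omics = c(5, 4, 3, 2, 1),
                    text = c(10, 30, 20, 50, 40))
  # single family: order equals that family's order
  expect_equal(metascore(tab, "omics")$gene, c("A", "B", "C", "D", "E"))
  # identical families: any weights give the same order
  tab2 <- transform(tab, text = omics)
  expect_equal(metascore(tab2, c("omics", "text"),
                         c(omics = 9, text = 1))$gene,
               metascore(tab2, "omics")$gene)
  # equal weights over two families: brute-force mean-rank oracle
  r_omics <- rank(tab$omics); r_text <- rank(tab$text)
  oracle <- tab$gene[order(-(r_omics + r_text) / 2, tab$gene)]
  expect_equal(metascore(tab, c("omics", "text"))$gene, oracle)
  expect_error(metascore(tab, c("omics", "text"),
                         c(omics = 0, text = 0)), class = "config_error")
})

test_that("filter cascade is order-preserving, idempotent, and truncates", {
  genes <- sprintf("g%02d", 1:60)
  ann <- data.frame(gene = genes, druggable_class = "Kinase",
                    has_small_molecule = TRUE, is_essential = FALSE,
                    novelty_level = 3L)
  cfg <- filter_config(top_k = 50)
  expect_equal(apply_filters(genes, ann, cfg), genes[1:50])
  # essential gene removed
  ann$is_essential[3] <- TRUE
  out <- apply_filters(genes, ann, cfg)
  expect_false("g03" %in% out)
  expect_equal(out, genes[-3][1:50])
  expect_equal(apply_filters(out, ann, cfg), out)  # idempotent
  # filters off: plain truncation
  off <- filter_config(require_druggable_class = FALSE,
                       require_small_molecule = FALSE,
                       exclude_essential = FALSE, top_k = 50)
  expect_equal(apply_filters(genes, ann, off), genes[1:50])
  # unannotated genes fail the druggable-class requirement
  expect_equal(apply_filters(c("zz", genes), ann, cfg), genes[-3][1:50])
  # novel mode forces omics-only scoring
  expect_equal(filter_config(novelty_mode = "novel")$enabled_families,
               "omics")
})

test_that("candidate selection applies the top-k and consistency gates", {
  cons <- list("CNS-fALS" = data.frame(gene = c("A", "B", "C"),
                                       up_pct = c(80, 50, 14),
                                       down_pct = c(20, 50, 86),
                                       n_comparisons = 5),
               "CNS-sALS" = data.frame(gene = c("A", "B", "C"),
                                       up_pct = c(71, 57, 14),
                                       down_pct = c(29, 43, 86),
                                       n_comparisons = 7))
  tops <- list("CNS-fALS" = c("A", "B"), "CNS-sALS" = c("C"))
  sel <- select_candidates(tops, cons, cfg = filter_config())
  # A selected through 80% fALS up-consistency
  expect_true("A" %in% sel$gene)
  # C selected through the down direction (86%)
  expect_true("C" %in% sel$gene)
  # B in a top list but never >= 80% consistent
  expect_false("B" %in% sel$gene)
  # consistency alone never selects a gene absent from every top list
  sel2 <- select_candidates(list("CNS-fALS" = character(0)), cons,
                            cfg = filter_config())
  expect_equal(nrow(sel2), 0)
  # diMN candidates carry their group effect
  eff <- data.frame(gene = "D", lfc = 0.3, p_value = 0.01)
  sel3 <- select_candidates(list("diMN-tx-fALS" = "D"),
                            dimn_effects = list("diMN-tx-fALS" = eff),
                            cfg = filter_config())
  expect_equal(sel3$dimn_lfc, 0.3)
  expect_equal(sel3$compartment, "diMN")
})
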