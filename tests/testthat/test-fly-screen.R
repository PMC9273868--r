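test_that("ortholog scores are offspring means with lethal exclusion", {
  expect_equal(ortholog_score(c(-4, -3)), -3.5)
  expect_equal(ortholog_score(0), 0)
  expect_equal(ortholog_score(c(0, 1)), 0.5)
  expect_equal(ortholog_score(c(-4, -3, NA)), -3.5)  # lethal never imputed
  lethal <- ortholog_score(c(NA, NA))
  expect_true(is.na(lethal))
  expect_equal(attr(lethal, "reason"), "lethal")
  expect_error(ortholog_score(2.5), class = "domain_error")
  # mean stays within the offspring range
  set.seed(3)
  for (i in 1:10) {
    s <- sample(-4:2, sample(1:6, 1), replace = TRUE)
    expect_gte(ortholog_score(s), min(s))
    expect_lte(ortholog_score(s), max(s))
  }
})

test_that("classification thresholds are inclusive and severity-ordered", {
  expect_equal(classify_modification(-3.5), "strong_rescue")
  expect_equal(classify_modification(-3), "strong_rescue")
  expect_equal(classify_modification(-2.5), "moderate_rescue")
  expect_equal(classify_modification(-2), "moderate_rescue")
  expect_equal(classify_modification(-1), "mild_rescue")
  expect_equal(classify_modification(-0.5), "no_effect")
  expect_equal(classify_modification(0), "no_effect")
  expect_equal(classify_modification(0.5), "no_effect")
  expect_equal(classify_modification(1), "mild_enhance")
  expect_equal(classify_modification(2), "moderate_enhance")
  # monotone step function: severity never decreases as |score| grows
  sev <- c(no_effect = 0, mild_rescue = 1, moderate_rescue = 2,
           strong_rescue = 3, mild_enhance = 1, moderate_enhance = 2)
  neg <- seq(0, -4, by = -0.5)
  expect_true(all(diff(sev[vapply(neg, classify_modification, "")]) >= 0))
  pos <- seq(0, 2, by = 0.5)
  expect_true(all(diff(sev[vapply(pos, classify_modification, "")]) >= 0))
})

test_that("a gene is represented by its strongest ortholog modification", {
  expect_equal(gene_best_score(c(-3, -2.5, -2, NA)), -3)   # RARA-like
  expect_equal(gene_best_score(c(-3, -2)), -3)             # P2RY14-like
  expect_equal(gene_best_score(-2), -2)
  expect_equal(gene_best_score(c(-2, 2)), -2)  # tie resolves toward rescue
  none <- gene_best_score(c(NA, NA))
  expect_true(is.na(none))
  expect_equal(attr(none, "reason"), "no_scored_ortholog")
})

test_that("the screen fixture summarizes to the published counts", {
  s <- summarize_screen(load_screen_table())
  expect_equal(s$n_genes, 28)
  expect_equal(s$n_with_model, 26)
  expect_equal(s$n_orthologs, 34)
  expect_equal(s$n_strong_or_moderate_rescue, 18)
  expect_equal(s$n_strong_rescue_unreported, 8)
  expect_equal(as.vector(s$category_counts[c("strong_rescue",
                                             "moderate_rescue")]),
               c(9L, 9L))
  # the eight unreported strong rescues are the published gene set
  strong <- s$per_gene$gene[!is.na(s$per_gene$category) &
                              s$per_gene$category == "strong_rescue" &
                              s$per_gene$unreported]
  expect_setequal(strong, c("KCNB2", "KCNS3", "ADRA2B", "NR3C1", "P2RY14",
                            "PPP3CB", "PTPRC", "RARA"))
})

test_that("classification round-trips every printed interpretation", {
  labels <- c(strong_rescue = "Strong rescue",
              moderate_rescue = "Moderate rescue",
              mild_rescue = "Mild rescue", no_effect = "No modification",
              mild_enhance = "Mild enhancement",
              moderate_enhance = "Moderate enhancement")
  t3 <- load_screen_table()
  scored <- t3[t3$score_status == "scored", ]
  expect_equal(unname(labels[vapply(scored$score, classify_modification, "")]),
               scored$interpretation)
})

test_that("empty and incomplete screen tables are handled", {
  empty <- load_screen_table()[0, ]
  s <- summarize_screen(empty)
  expect_equal(s$n_genes, 0)
  expect_equal(s$n_with_model, 0)
  expect_equal(s$n_strong_or_moderate_rescue, 0)
  expect_error(summarize_screen(empty, candidates = "KCNB2"),
               class = "data_error")
})
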