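test_that("default design mirrors the 16-comparison study layout", {
  design <- default_study_design()
  expect_equal(nrow(design), 16)
  expect_equal(sum(grepl("^CNS", design$group_id)), 12)
  expect_equal(as.vector(table(factor(design$group_id, meta_group_ids()))),
               c(5, 7, 1, 1, 1, 1))
  cfg <- study_config(design = design, n_genes = 50, seed = 3)
  bundle <- generate_study(cfg)
  expect_length(bundle$comparisons, 16)
  expect_s3_class(bundle$comparisons[[1]], "comparison_dataset")
})

test_that("generation is a pure function of the config", {
  cfg <- study_config(design = layout_design(5), n_genes = 80,
                      planted_targets = planted_target_frame("G00007"),
                      planted_pathways = data.frame(pathway = "PW0001",
                                                    direction = "up",
                                                    magnitude = 0.05),
                      seed = 11)
  expect_identical(generate_study(cfg), generate_study(cfg))
  cfg2 <- cfg; cfg2$seed <- 12L
  expect_false(identical(generate_study(cfg)$comparisons[[1]]$matrix,
                         generate_study(cfg2)$comparisons[[1]]$matrix))
})

test_that("planted effects appear where penetrant and nowhere at penetrance 0", {
  pt <- planted_target_frame(c("G00001", "G00002"),
                             direction = c("up", "down"), effect = 1.2,
                             penetrance = c(1, 0))
  cfg <- study_config(design = single_group_design(m = 8, n = 40),
                      n_genes = 60, planted_targets = pt, seed = 21)
  bundle <- generate_study(cfg)
  lfc <- vapply(bundle$comparisons, function(cmp) {
    e <- compute_effects(cmp); e$lfc[match(c("G00001", "G00002"), e$gene)]
  }, numeric(2))
  # penetrant up-target: mean lfc near +1.2 (tolerance ~ noise_sd / sqrt(n))
  tol <- 3 * 0.5 * sqrt(2 / 40) / sqrt(8)
  expect_equal(mean(lfc[1, ]), 1.2, tolerance = tol * 4 / 1.2)
  # penetrance 0: indistinguishable from null
  expect_lt(abs(mean(lfc[2, ])), 4 * 0.5 * sqrt(2 / 40) / sqrt(8))
  expect_identical(bundle$truth$penetrant_comparisons$G00002, integer(0))
})

test_that("planted genes must exist in the universe", {
  expect_error(
    generate_study(study_config(design = single_group_design(1, 5),
                                n_genes = 10,
                                planted_targets = planted_target_frame("NOPE"),
                                seed = 1)),
    class = "config_error")
  expect_error(study_config(design = single_group_design(1, 5),
                            planted_targets = planted_target_frame(
                              "G00001", penetrance = 1.2)),
               class = "config_error")
})

test_that("chronology density controls the post-cutoff mixture", {
  all_pre <- generate_chronology(50, cutoff_density = 0, seed = 5)
  expect_true(all(all_pre$year <= 2010))
  all_post <- generate_chronology(50, cutoff_density = 1, seed = 5)
  expect_true(all(all_post$year > 2010))
  chron <- generate_chronology(100, cutoff_density = 0.2, seed = 42)
  # reproducible, and the post-cutoff count is the binomial draw made by the
  # generator under this seed
  expect_identical(chron, generate_chronology(100, 0.2, seed = 42))
  set.seed(42)
  expect_equal(sum(chron$year > 2010), sum(rbinom(100, 1, 0.2)))
})

test_that("null gene p-values are uniform (KS at alpha = 0.01)", {
  cfg <- study_config(design = single_group_design(m = 1, n = 10),
                      n_genes = 1500, seed = 33)
  eff <- compute_effects(generate_study(cfg)$comparisons[[1]])
  ks <- suppressWarnings(stats::ks.test(eff$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("fixture tables load with the published shape", {
  t1 <- load_comparison_table()
  expect_equal(nrow(t1), 16)
  expect_equal(sum(t1$tissue_class == "CNS"), 12)
  expect_equal(nrow(load_candidate_table()), 28)
  t3 <- load_screen_table()
  expect_equal(nrow(t3), 35)
  expect_equal(sum(!t3$model_available), 2)
  expect_equal(sum(t3$score_status == "lethal"), 1)
})

test_that("malformed fixtures fail with the offending row", {
  bad <- tempfile(fileext = ".tsv")
  t3 <- read.delim(ext <- system.file("extdata", "table3_screen.tsv",
                                      package = "alstargets"))
  t3$score[4] <- "wat"
  write.table(t3, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_screen_table(bad), "row 4", class = "parse_error")
})
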