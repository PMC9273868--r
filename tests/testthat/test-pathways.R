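toy_effects <- function(lfc, p = rep(0.001, length(lfc))) {
  data.frame(gene = paste0("g", seq_along(lfc)), lfc = lfc, p_value = p)
}

test_that("activation score is a gated weighted mean of member lfc", {
  eff <- toy_effects(c(0.4, 0.2, 0.2, -0.2))
  expect_equal(activation_score(eff, paste0("g", 1:4), gate_weight = 1), 0.15)
  expect_equal(activation_score(toy_effects(c(0, 0, 0)), paste0("g", 1:3)), 0)
  expect_equal(activation_score(toy_effects(c(1, -1)), paste0("g", 1:2)), 0)
  # non-significant genes are down-weighted, not dropped
  eff2 <- toy_effects(c(1, 0), p = c(0.001, 0.5))
  expect_equal(activation_score(eff2, c("g1", "g2")), 1 / 1.5)
  # topology weights
  expect_equal(activation_score(eff, paste0("g", 1:4),
                                weights = c(g1 = 3, g2 = 1, g3 = 1, g4 = 1),
                                gate_weight = 1), (1.2 + 0.2) / 6)
  expect_error(activation_score(eff, c("x", "y")), class = "no_overlap")
})

test_that("dysregulation calls require 80% unidirectionality and 0.01 magnitude", {
  m <- function(x) matrix(x, nrow = 1, dimnames = list("pw", NULL))
  crit <- dysregulation_criteria()
  # 4 of 5 positive with max |score| 0.02: activated
  calls <- call_dysregulated(m(c(0.02, 0.011, 0.004, 0.002, -0.003)), crit, "g")
  expect_equal(calls$direction, "activated")
  # all positive but magnitude never reaches 0.01: no call
  expect_equal(nrow(call_dysregulated(m(rep(0.005, 5)), crit)), 0)
  # 3 of 5 positive (60% < 80%): no call
  expect_equal(nrow(call_dysregulated(m(c(0.02, 0.02, 0.02, -0.02, -0.02)),
                                      crit)), 0)
  # the fraction is compared exactly: 7 comparisons need 6
  expect_equal(nrow(call_dysregulated(m(c(rep(0.02, 5), -0.01, -0.01)),
                                      crit)), 0)
  expect_equal(nrow(call_dysregulated(m(c(rep(0.02, 6), -0.01)), crit)), 1)
  # score exactly 0 counts toward neither direction
  expect_equal(nrow(call_dysregulated(m(c(0.02, 0.02, 0.02, 0.02, 0)), crit)),
               1)
})

test_that("adding an agreeing comparison never removes a call", {
  set.seed(6)
  crit <- dysregulation_criteria()
  for (i in 1:20) {
    scores <- matrix(rnorm(5, 0, 0.03), nrow = 1,
                     dimnames = list("pw", NULL))
    before <- call_dysregulated(scores, crit)
    if (nrow(before) == 1) {
      extra <- if (before$direction == "activated") 0.02 else -0.02
      after <- call_dysregulated(cbind(scores, extra), crit)
      expect_equal(after$direction, before$direction)
    }
  }
})

test_that("process enrichment follows the printed formula", {
  expect_equal(process_enrichment(N = 6, K = 2, n = 3, r = 1), 0.8)
  expect_equal(process_enrichment(N = 6, K = 2, n = 3, r = 0), 1)
  # enumeration oracle: draw n of N pathways, K dysregulated; the formula's
  # value is P(process draws >= r)
  for (N in c(5, 8, 12)) {
    subsets <- utils::combn(N, 3)
    for (K in c(1, 2, 3)) {
      hits <- colSums(subsets <= K)
      for (r in 0:3) {
        expect_equal(process_enrichment(N, K, n = 3, r = r),
                     mean(hits >= r), tolerance = 1e-12)
      }
    }
  }
  # conventional orientation: population successes r, observed K
  expect_equal(process_enrichment(4, 1, 2, 2, conventional = TRUE),
               1 - choose(2, 2) / choose(4, 2))
})

test_that("Bonferroni adjustment multiplies by processes tested, capped at 1", {
  sets <- setNames(lapply(1:6, function(i) paste0("g", i, 1:5)),
                   paste0("pw", 1:6))
  hier <- data.frame(pathway = paste0("pw", 1:6),
                     process = rep(c("A", "B", "C"), each = 2))
  coll <- pathway_collection(sets, hier)
  calls <- data.frame(pathway = c("pw1", "pw2"), direction = "activated",
                      group_id = "g")
  tab <- process_enrichment_table(calls, coll)
  expect_equal(tab$adjusted_p, pmin(1, tab$raw_p * 3))
  expect_true(all(tab$adjusted_p >= tab$raw_p & tab$adjusted_p <= 1))
})

test_that("similarity coefficients and the network threshold behave as stated", {
  A <- c("a", "b", "c", "d"); B <- c("c", "d", "e", "f")
  expect_equal(set_similarity(A, A), 1)
  expect_equal(set_similarity(A, c("x", "y")), 0)
  expect_equal(set_similarity(A, B), 1 / 3)
  expect_equal(set_similarity(A, B, "combined"), (1 / 3 + 1 / 2) / 2)
  calls <- data.frame(pathway = c("p1", "p2"), direction = "activated",
                      group_id = "g")
  sets <- list(p1 = A, p2 = B)
  # Jaccard 1/3 < 0.35: no edge; combined 0.4167 > 0.35: edge
  net_j <- similarity_network(calls, sets)
  expect_equal(igraph::ecount(net_j$graph), 0)
  net_c <- similarity_network(calls, sets, method = "combined")
  expect_equal(igraph::ecount(net_c$graph), 1)
  expect_equal(igraph::E(net_c$graph)$weight, 0.41667, tolerance = 1e-4)
})

test_that("the network is undirected, self-loop-free, and clusters by size", {
  sets <- list(p1 = letters[1:6], p2 = letters[2:7], p3 = letters[3:8],
               p4 = letters[4:9], p5 = LETTERS[1:5])
  calls <- data.frame(pathway = names(sets),
                      direction = c(rep("activated", 4), "inhibited"),
                      group_id = "g")
  net <- similarity_network(calls, sets, threshold = 0.35, min_cluster = 4)
  expect_false(igraph::is_directed(net$graph))
  expect_equal(sum(igraph::which_loop(net$graph)), 0)
  expect_length(net$clusters, 1)
  expect_setequal(net$clusters[[1]], paste0("p", 1:4))
  # raising the floor hides the cluster
  expect_length(similarity_network(calls, sets, min_cluster = 5)$clusters, 0)
})

test_that("planted pathways are recalled with the right direction (one seed)", {
  cfg <- study_config(
    design = single_group_design(m = 5, n = 25), n_genes = 600,
    n_pathways = 40, pathway_size_range = c(40, 60),
    planted_pathways = data.frame(pathway = paste0("PW000", 1:5),
                                  direction = c("up", "up", "down", "up",
                                                "down"),
                                  magnitude = 0.05),
    seed = 19)
  bundle <- generate_study(cfg)
  effs <- lapply(bundle$comparisons, compute_effects)
  calls <- call_dysregulated(score_pathways(effs, bundle$pathway_db),
                             dysregulation_criteria(), "CNS-fALS")
  got <- calls$direction[match(paste0("PW000", 1:5), calls$pathway)]
  expect_equal(got, c("activated", "activated", "inhibited", "activated",
                      "inhibited"))
})
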