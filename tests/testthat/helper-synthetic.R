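# Small study designs reused across tests. Sizes are deliberately modest so
# the default suite stays fast; recovery-style checks state their own sizes.

# one comparison per group, except 5 CNS-fALS and 7 CNS-sALS (the source
# study's group layout) with equal arms of size n
layout_design <- function(n = 10) {
  do.call(rbind, lapply(meta_group_ids(), function(g) {
    k <- if (g == "CNS-fALS") 5 else if (g == "CNS-sALS") 7 else 1
    data.frame(group_id = g,
               subtype = ifelse(grepl("fALS", g), "fALS", "sALS"),
               modality = ifelse(grepl("prot", g), "SWATH-MS", "RNA-seq"),
               n_case = n, n_control = n,
               source_name = paste0(g, "-", seq_len(k)),
               stringsAsFactors = FALSE)
  }))
}

# a single-group design: m comparisons in CNS-fALS with n/n arms
single_group_design <- function(m = 5, n = 20) {
  data.frame(group_id = "CNS-fALS", subtype = "fALS", modality = "RNA-seq",
             n_case = n, n_control = n,
             source_name = paste0("cmp-", seq_len(m)),
             stringsAsFactors = FALSE)
}

planted_target_frame <- function(genes, direction = "up", effect = 1.5,
                                 penetrance = 1) {
  data.frame(gene = genes, direction = direction, effect_size = effect,
             penetrance = penetrance, stringsAsFactors = FALSE)
}

# brute-force hypergeometric tail by enumerating all k-subsets of 1..N with
# targets 1..targets_N; returns P(successes > q) (or >= q if inclusive)
enum_tail <- function(N, targets_N, k, q, inclusive = FALSE) {
  subsets <- utils::combn(N, k)
  hits <- colSums(subsets <= targets_N)
  if (inclusive) mean(hits >= q) else mean(hits > q)
}
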