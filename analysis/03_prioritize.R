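#!/usr/bin/env Rscript
# Stage 3 — meta-analysis groups, consistency, metascore, filter cascade.
#
# Pools the comparisons into the six meta-analysis groups, ranks genes per
# group (omics evidence aggregated with the external text/finance/KOL score
# tables in high-confidence mode; omics only in novel mode), applies the
# druggability filters with the top-50 cut, and gates CNS candidates at 80%
# directional consistency. Reports how many planted targets surface.

library(alstargets)

bundle <- readRDS("results/bundle.rds")
effects <- readRDS("results/effects.rds")
out <- "results/analysis"

groups <- build_groups(bundle$comparisons)
cmp_ids <- vapply(bundle$comparisons, function(x) x$group_id, "")
group_eff <- lapply(setNames(names(groups), names(groups)),
                    function(gid) effects[cmp_ids == gid])
cns_cons <- lapply(group_eff[grep("^CNS-", names(groups))], consistency_table)
dimn_eff <- lapply(group_eff[grep("^diMN-", names(groups))], `[[`, 1)

all_cand <- list()
for (mode in c("high_confidence", "novel")) {
  fc <- filter_config(novelty_mode = mode)
  tops <- lapply(group_eff, function(effs) {
    sc <- merge(group_omics_scores(effs), bundle$score_tables, by = "gene")
    apply_filters(metascore(sc, fc$enabled_families)$gene,
                  bundle$annotations, fc)
  })
  cand <- select_candidates(tops, cns_cons, dimn_eff, fc)
  all_cand[[mode]] <- cand
  cat(sprintf("%s mode: %d candidates, %d of them planted\n", mode,
              nrow(cand),
              sum(cand$gene %in% bundle$truth$planted_targets$gene)))
}
candidates <- do.call(rbind, c(all_cand, list(make.row.names = FALSE)))
write.table(candidates, file.path(out, "candidates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(group_eff, "results/group_effects.rds")
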