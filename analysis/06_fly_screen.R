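#!/usr/bin/env Rscript
# Stage 6 — modifier-screen scoring over the transcribed screen table.
#
# Applies the eye-degeneration scale to the c9ALS fly screen results: each
# human gene is represented by its strongest-modifying ortholog, classified
# on the -4..2 scale, and the headline counts are written as JSON.

library(alstargets)

out <- "results/analysis"
s <- summarize_screen(load_screen_table())

cat(sprintf("screened genes: %d (%d with a fly model, %d distinct orthologs)\n",
            s$n_genes, s$n_with_model, s$n_orthologs))
cat(sprintf("strong or moderate rescue: %d genes\n",
            s$n_strong_or_moderate_rescue))
cat(sprintf("unreported strong rescues: %d genes\n",
            s$n_strong_rescue_unreported))
print(s$category_counts)

write.table(s$per_gene, file.path(out, "screen_per_gene.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(n_genes = s$n_genes, n_with_model = s$n_with_model,
       n_orthologs = s$n_orthologs,
       n_strong_or_moderate_rescue = s$n_strong_or_moderate_rescue,
       n_strong_rescue_unreported = s$n_strong_rescue_unreported),
  file.path(out, "screen_summary.json"), auto_unbox = TRUE, digits = NA)
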