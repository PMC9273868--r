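#' Pool comparisons into the six meta-analysis groups
#'
#' Partitions a list of comparisons by their `group_id`. Every comparison
#' lands in exactly one group; groups preserve input order.
#'
#' @param comparisons list of [comparison_dataset()] objects.
#' @return a named list of `meta_group` objects (fields `group_id`,
#'   `comparisons`), one per group id present in the input.
#' @export
build_groups <- function(comparisons) {
  stopifnot(is.list(comparisons))
  ids <- vapply(comparisons, function(x) x$group_id, "")
  out <- lapply(split(seq_along(comparisons), factor(ids, levels = unique(ids))),
                function(i) structure(list(group_id = ids[i[1]],
                                           comparisons = comparisons[i]),
                                      class = "meta_group"))
  out[order(match(names(out), meta_group_ids()))]
}

#' @export
print.meta_group <- function(x, ...) {
  cat(sprintf("<meta_group> %s: %d comparison(s)\n", x$group_id,
              length(x$comparisons)))
  invisible(x)
}

#' Per-comparison effects for every member of a meta-analysis group
#' @param group a `meta_group` from [build_groups()].
#' @return list of effect data frames (see [compute_effects()]).
#' @export
group_effects <- function(group) {
  stopifnot(inherits(group, "meta_group"))
  lapply(group$comparisons, compute_effects)
}

#' Directional consistency of a gene's fold changes across comparisons
#'
#' The percentage of comparisons in which the gene moves in the stated
#' direction: strictly positive log2 fold change for `"up"`, strictly
#' negative for `"down"` (an lfc of exactly 0 counts toward neither). By
#' default the percentage is rounded half-up to a whole percent, matching how
#' consistencies are reported (6 of 7 positive comparisons prints as 86%).
#'
#' @param lfc numeric vector: one log2 fold change per comparison.
#' @param direction `"up"` or `"down"`.
#' @param round round half-up to integer percent (default `TRUE`).
#' @return a percentage in \[0, 100\].
#' @examples
#' consistency(c(0.3, 1.2, -0.1, 0.8, 0.05), "up")  # 4/5 -> 80
#' consistency(c(1, 1, 1, 1, 1, 1, -1), "up")       # 6/7 -> 86
#' @export
consistency <- function(lfc, direction = c("up", "down"), round = TRUE) {
  direction <- match.arg(direction)
  if (length(lfc) == 0)
    abort("consistency undefined for an empty comparison list",
          "undefined_consistency")
  hits <- if (direction == "up") sum(lfc > 0) else sum(lfc < 0)
  pct <- 100 * hits / length(lfc)
  if (round) round_half_up(pct) else pct
}

#' Per-gene directional consistency for a whole group
#'
#' @param effects_list list of effect data frames covering the same gene
#'   universe (as from [group_effects()]).
#' @param round as in [consistency()].
#' @return data frame (gene, up_pct, down_pct, n_comparisons).
#' @export
consistency_table <- function(effects_list, round = TRUE) {
  lfc <- effects_lfc_matrix(effects_list)
  up <- 100 * rowSums(lfc > 0) / ncol(lfc)
  down <- 100 * rowSums(lfc < 0) / ncol(lfc)
  if (round) { up <- round_half_up(up); down <- round_half_up(down) }
  data.frame(gene = rownames(lfc), up_pct = unname(up),
             down_pct = unname(down), n_comparisons = ncol(lfc),
             stringsAsFactors = FALSE)
}

effects_lfc_matrix <- function(effects_list) {
  stopifnot(length(effects_list) >= 1)
  genes <- effects_list[[1]]$gene
  m <- vapply(effects_list,
              function(e) e$lfc[match(genes, e$gene)],
              numeric(length(genes)))
  m <- matrix(m, nrow = length(genes), dimnames = list(genes, NULL))
  if (anyNA(m)) abort("comparisons do not share a gene universe", "data_error")
  m
}

#' Group-level omics evidence score
#'
#' Combines a group's per-comparison effects into one per-gene association
#' score: the magnitude of the mean over comparisons of
#' `sign(lfc) * -log10(p)`. Signing each comparison's evidence by its fold
#' change direction before averaging means comparisons that disagree on
#' direction cancel, so only genes moved consistently (in either direction)
#' with small p-values earn large scores; the net direction is reported
#' alongside. This is the package's documented stand-in for a platform omics
#' association score and is the only score family computed from data; it is
#' pluggable wherever a score table is accepted.
#'
#' @param effects_list list of effect data frames for one group.
#' @return data frame (gene, omics, direction), unsorted; `omics >= 0` and
#'   `direction` is the sign (-1, 0, 1) of the mean signed evidence.
#' @export
group_omics_scores <- function(effects_list) {
  genes <- effects_list[[1]]$gene
  contr <- vapply(effects_list, function(e) {
    e <- e[match(genes, e$gene), ]
    sign(e$lfc) * -log10(e$p_value)
  }, numeric(length(genes)))
  contr <- matrix(contr, nrow = length(genes))
  signed <- rowMeans(contr)
  data.frame(gene = genes, omics = abs(signed), direction = sign(signed),
             stringsAsFactors = FALSE)
}

score_families <- function() c("omics", "text", "finance", "kol")

#' Aggregate score families into a metascore ranking
#'
#' Each enabled family is rank-normalized (average-tie ranks divided by the
#' number of genes, so every family lives on (0, 1\] regardless of its native
#' scale) and the metascore is the weighted mean of the normalized family
#' scores. Genes are returned in descending metascore order with ties broken
#' lexicographically by gene ID, so rankings are deterministic.
#'
#' @param scores data frame with a `gene` column plus one numeric column per
#'   score family (subset of omics, text, finance, kol).
#' @param enabled_families which families enter the aggregate.
#' @param weights named non-negative weights over `enabled_families`
#'   (default: equal). All-zero weights are a configuration error.
#' @return data frame (gene, metascore), sorted best-first.
#' @export
metascore <- function(scores, enabled_families = intersect(score_families(),
                                                           names(scores)),
                      weights = NULL) {
  stopifnot(is.data.frame(scores), "gene" %in% names(scores))
  if (length(enabled_families) == 0)
    abort("at least one score family must be enabled", "config_error")
  if (!all(enabled_families %in% score_families()))
    abort("unknown score family", "config_error")
  if (!all(enabled_families %in% names(scores)))
    abort("score table lacks an enabled family", "config_error")
  if (is.null(weights))
    weights <- setNames(rep(1, length(enabled_families)), enabled_families)
  weights <- weights[enabled_families]
  if (any(weights < 0) || anyNA(weights))
    abort("weights must be nonnegative", "config_error")
  if (sum(weights) == 0)
    abort("all weights zero", "config_error")
  n <- nrow(scores)
  norm <- vapply(enabled_families,
                 function(f) rank(scores[[f]], ties.method = "average") / n,
                 numeric(n))
  norm <- matrix(norm, nrow = n)
  ms <- as.vector(norm %*% weights) / sum(weights)
  out <- data.frame(gene = scores$gene, metascore = ms,
                    stringsAsFactors = FALSE)
  out[order(-out$metascore, out$gene), , drop = FALSE]
}

#' Druggability / novelty filter configuration
#'
#' @param require_druggable_class keep only genes with a druggable-class
#'   annotation (genes absent from the annotation table fail this).
#' @param require_small_molecule keep only genes already associated with a
#'   small molecule.
#' @param exclude_essential drop essential genes.
#' @param novelty_mode `"high_confidence"` (all score families allowed) or
#'   `"novel"` (omics evidence only, and only high-novelty genes pass the
#'   cascade).
#' @param enabled_families score families feeding [metascore()]; forced to
#'   `"omics"` in novel mode.
#' @param min_novelty_level minimum `novelty_level` annotation required in
#'   novel mode.
#' @param top_k prefix length of the ranked list kept after filtering.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(require_druggable_class = TRUE,
                          require_small_molecule = TRUE,
                          exclude_essential = TRUE,
                          novelty_mode = c("high_confidence", "novel"),
                          enabled_families = score_families(),
                          min_novelty_level = 3L,
                          top_k = 50L) {
  novelty_mode <- match.arg(novelty_mode)
  if (novelty_mode == "novel") enabled_families <- "omics"
  if (!all(enabled_families %in% score_families()))
    abort("unknown score family", "config_error")
  stopifnot(top_k >= 1)
  structure(list(require_druggable_class = require_druggable_class,
                 require_small_molecule = require_small_molecule,
                 exclude_essential = exclude_essential,
                 novelty_mode = novelty_mode,
                 enabled_families = enabled_families,
                 min_novelty_level = as.integer(min_novelty_level),
                 top_k = as.integer(top_k)),
            class = "filter_config")
}

#' Apply the druggability/novelty filter cascade to a ranked gene list
#'
#' Order-preserving: genes failing any enabled predicate are dropped, then
#' the list is truncated to `cfg$top_k`. Idempotent by construction.
#'
#' @param ranked character vector of genes, best first.
#' @param annotations annotation data frame (gene, druggable_class,
#'   has_small_molecule, is_essential, novelty_level, ...).
#' @param cfg a [filter_config()].
#' @return filtered, truncated character vector.
#' @export
apply_filters <- function(ranked, annotations, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  i <- match(ranked, annotations$gene)
  keep <- rep(TRUE, length(ranked))
  if (cfg$require_druggable_class)
    keep <- keep & !is.na(i) & !is.na(annotations$druggable_class[i])
  if (cfg$require_small_molecule)
    keep <- keep & !is.na(i) & annotations$has_small_molecule[i] %in% TRUE
  if (cfg$exclude_essential)
    keep <- keep & !is.na(i) & annotations$is_essential[i] %in% FALSE
  if (cfg$novelty_mode == "novel")
    keep <- keep & !is.na(i) &
      annotations$novelty_level[i] >= cfg$min_novelty_level
  head(ranked[keep], cfg$top_k)
}

#' Select candidate targets across the six meta-analyses
#'
#' A gene is a candidate only if it appears in at least one group's filtered
#' top list. CNS candidates must additionally be directionally consistent
#' (up or down) in at least `min_consistency` percent of the comparisons of
#' the familial or sporadic CNS group, evaluated on rounded percentages.
#' diMN candidates carry their group's log2 fold change and p-value.
#'
#' @param top_lists named list: group id -> character vector of top-ranked
#'   genes after filtering.
#' @param cns_consistency named list: CNS group id -> [consistency_table()]
#'   output for that group.
#' @param dimn_effects named list: diMN group id -> effect data frame for the
#'   group's comparison (diMN groups hold a single comparison each).
#' @param cfg a [filter_config()]; `novelty_mode` labels the candidates.
#' @param min_consistency CNS consistency gate in percent (default 80).
#' @return data frame of class rows: gene, category, compartment,
#'   consistency/effect bookkeeping columns.
#' @export
select_candidates <- function(top_lists, cns_consistency = list(),
                              dimn_effects = list(), cfg = filter_config(),
                              min_consistency = 80) {
  empty <- data.frame(gene = character(), category = character(),
                      compartment = character(), up_fALS = numeric(),
                      up_sALS = numeric(), down_fALS = numeric(),
                      down_sALS = numeric(), dimn_group = character(),
                      dimn_lfc = numeric(), dimn_p = numeric(),
                      stringsAsFactors = FALSE)
  in_top <- sort(unique(unlist(top_lists, use.names = FALSE)))
  if (length(in_top) == 0) return(empty)
  cns_groups <- grep("^CNS-", names(top_lists), value = TRUE)
  dimn_groups <- grep("^diMN-", names(top_lists), value = TRUE)
  rows <- lapply(in_top, function(g) {
    via_cns <- any(vapply(cns_groups, function(gr) g %in% top_lists[[gr]],
                          logical(1)))
    via_dimn <- vapply(dimn_groups, function(gr) g %in% top_lists[[gr]],
                       logical(1))
    cons <- function(grp, col) {
      tab <- cns_consistency[[grp]]
      if (is.null(tab)) return(NA_real_)
      v <- tab[[col]][match(g, tab$gene)]
      if (length(v)) v else NA_real_
    }
    up_f <- cons("CNS-fALS", "up_pct"); down_f <- cons("CNS-fALS", "down_pct")
    up_s <- cons("CNS-sALS", "up_pct"); down_s <- cons("CNS-sALS", "down_pct")
    cns_ok <- via_cns && isTRUE(any(c(up_f, down_f, up_s, down_s) >=
                                      min_consistency))
    dimn_hit <- dimn_groups[via_dimn]
    if (!cns_ok && length(dimn_hit) == 0) return(NULL)
    compartment <- if (cns_ok) "CNS" else "diMN"
    lfc <- p <- NA_real_; dimn_group <- NA_character_
    if (length(dimn_hit)) {
      dimn_group <- dimn_hit[1]
      eff <- dimn_effects[[dimn_group]]
      if (!is.null(eff)) {
        j <- match(g, eff$gene)
        lfc <- eff$lfc[j]; p <- eff$p_value[j]
      }
    }
    data.frame(gene = g, category = cfg$novelty_mode,
               compartment = compartment,
               up_fALS = up_f, up_sALS = up_s,
               down_fALS = down_f, down_sALS = down_s,
               dimn_group = dimn_group, dimn_lfc = lfc, dimn_p = p,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
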