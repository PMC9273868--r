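#' Aggregate offspring eye-degeneration scores for one fly ortholog
#'
#' RNAi crosses in the c9ALS fly model are scored per offspring on an
#' integer scale from -4 (strongest rescue of eye degeneration) to 2
#' (strongest enhancement). An ortholog's modification score is the
#' arithmetic mean of its offspring scores, so half-integer values such as
#' -3.5 arise when offspring split between adjacent integers. Lethal
#' crosses carry no score and are excluded, never imputed.
#'
#' @param offspring_scores numeric vector of integer scores in \[-4, 2\];
#'   `NA` entries mark lethal offspring classes.
#' @return the mean score, or `NA` (with a `"reason"` attribute `"lethal"`)
#'   when every entry is lethal.
#' @examples
#' ortholog_score(c(-4, -3))  # -3.5
#' @export
ortholog_score <- function(offspring_scores) {
  s <- offspring_scores[!is.na(offspring_scores)]
  if (length(s) == 0)
    return(structure(NA_real_, reason = "lethal"))
  if (any(s < -4 | s > 2 | s != round(s)))
    abort("offspring scores must be integers in [-4, 2]", "domain_error")
  mean(s)
}

#' Classify a modification score on the eye-degeneration scale
#'
#' Thresholds are applied in decreasing order of severity and are inclusive:
#' a score of exactly -3 is a strong rescue, exactly -2 moderate, exactly -1
#' mild; symmetrically >= 2 is a moderate enhancement and >= 1 mild; scores
#' strictly between -1 and 1 are no effect.
#'
#' @param score numeric in \[-4, 2\] (half-integers allowed).
#' @return one of `"strong_rescue"`, `"moderate_rescue"`, `"mild_rescue"`,
#'   `"no_effect"`, `"mild_enhance"`, `"moderate_enhance"`.
#' @export
classify_modification <- function(score) {
  if (is.na(score)) abort("cannot classify a missing score", "domain_error")
  if (score < -4 || score > 2)
    abort("score outside [-4, 2]", "domain_error")
  if (score <= -3) "strong_rescue"
  else if (score <= -2) "moderate_rescue"
  else if (score <= -1) "mild_rescue"
  else if (score >= 2) "moderate_enhance"
  else if (score >= 1) "mild_enhance"
  else "no_effect"
}

modification_labels <- function() {
  c(strong_rescue = "Strong rescue", moderate_rescue = "Moderate rescue",
    mild_rescue = "Mild rescue", no_effect = "No modification",
    mild_enhance = "Mild enhancement", moderate_enhance = "Moderate enhancement")
}

#' Best (strongest) modification score for a human gene
#'
#' A human gene may map to several fly orthologs; the score of the strongest
#' modification — maximal absolute value — represents the gene. Ties between
#' a rescue and an enhancement of equal magnitude resolve toward the rescue
#' (negative) score. Lethal / unscored orthologs are ignored.
#'
#' @param scores numeric vector of per-ortholog modification scores (`NA` =
#'   lethal or no model).
#' @return the representative score, or `NA` with a `"reason"` attribute
#'   when no ortholog was scored.
#' @examples
#' gene_best_score(c(-3, -2.5, -2, NA))  # -3
#' @export
gene_best_score <- function(scores) {
  s <- scores[!is.na(scores)]
  if (length(s) == 0)
    return(structure(NA_real_, reason = "no_scored_ortholog"))
  best <- s[order(-abs(s), s)][1]
  best
}

#' Summarize a modifier screen over candidate genes
#'
#' Reduces a screen table (one row per human gene / fly ortholog pair) to
#' per-gene best scores and the screen's headline counts: genes with an
#' available fly model, distinct fly orthologs, genes per modification
#' category, genes with a strong-or-moderate rescue, and strong-rescue genes
#' with no prior report anywhere in their rows.
#'
#' @param screen a screen table as from [load_screen_table()] (columns
#'   `human_gene`, `fly_symbol`, `model_available`, `score`, `reference`).
#' @param candidates optional character vector restricting the genes
#'   summarized (default: all genes in the table).
#' @return list with `per_gene` (data frame: gene, best_score, category,
#'   unreported) and the count fields `n_genes`, `n_with_model`,
#'   `n_orthologs`, `category_counts`, `n_strong_or_moderate_rescue`,
#'   `n_strong_rescue_unreported`.
#' @export
summarize_screen <- function(screen, candidates = unique(screen$human_gene)) {
  stopifnot(all(c("human_gene", "fly_symbol", "model_available", "score",
                  "reference") %in% names(screen)))
  missing <- setdiff(candidates, screen$human_gene)
  if (length(missing))
    abort(paste0("screen table does not cover: ",
                 paste(missing, collapse = ", ")), "data_error")
  screen <- screen[screen$human_gene %in% candidates, ]
  genes <- unique(screen$human_gene)
  per_gene <- lapply(genes, function(g) {
    rows <- screen[screen$human_gene == g, ]
    best <- gene_best_score(rows$score)
    scored <- !is.na(best)
    data.frame(
      gene = g,
      has_model = any(rows$model_available),
      best_score = as.numeric(best),
      category = if (scored) classify_modification(best) else NA_character_,
      unreported = all(is.na(rows$reference)),
      stringsAsFactors = FALSE)
  })
  if (length(per_gene) == 0)
    per_gene <- list(data.frame(gene = character(), has_model = logical(),
                                best_score = numeric(),
                                category = character(),
                                unreported = logical(),
                                stringsAsFactors = FALSE))
  per_gene <- do.call(rbind, c(per_gene, list(make.row.names = FALSE)))
  scored <- per_gene[!is.na(per_gene$category), ]
  cat_counts <- table(factor(scored$category, levels = names(modification_labels())))
  list(per_gene = per_gene,
       n_genes = length(genes),
       n_with_model = sum(per_gene$has_model),
       n_orthologs = length(unique(screen$fly_symbol)),
       category_counts = cat_counts,
       n_strong_or_moderate_rescue =
         sum(scored$category %in% c("strong_rescue", "moderate_rescue")),
       n_strong_rescue_unreported =
         sum(scored$category == "strong_rescue" & scored$unreported))
}
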