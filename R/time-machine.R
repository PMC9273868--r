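#' Enrichment counts for retrospective ranking validation
#'
#' The four counts behind both time-machine metrics: of `N` scored genes,
#' `targets_N` are the disease's (post-cutoff) targets; the ranking's top-`k`
#' prefix contains `targets_k` of them.
#'
#' @param targets_k targets found in the top-k prefix.
#' @param k prefix length.
#' @param targets_N targets among all scored genes (must be >= 1; a ranking
#'   cannot be validated against an empty target background).
#' @param N total scored genes.
#' @return an object of class `enrichment_counts`.
#' @export
enrichment_counts <- function(targets_k, k, targets_N, N) {
  v <- c(targets_k = targets_k, k = k, targets_N = targets_N, N = N)
  if (any(v != round(v)) || any(v < 0))
    abort("enrichment counts must be nonnegative integers", "domain_error")
  if (targets_N == 0)
    abort("no targets in the scored universe: enrichment undefined",
          "undefined_background")
  if (k < 1 || N < 1 || k > N || targets_N > N ||
      targets_k > min(k, targets_N))
    abort("inconsistent enrichment counts", "domain_error")
  structure(as.list(v), class = "enrichment_counts")
}

#' Enrichment log fold change of a ranking's top-k (ELFC)
#'
#' `log2((targets_k / k) / (targets_N / N))`: the log2 ratio of the target
#' rate in the top-k prefix to the background target rate. A prefix with no
#' targets substitutes 0.1 for the zero count so the metric stays finite
#' (and strongly negative) rather than diverging.
#'
#' @param counts an [enrichment_counts()].
#' @return the ELFC value (positive = enriched top of the list).
#' @examples
#' elfc(enrichment_counts(5, 10, 50, 1000))   # log2(10)
#' @export
elfc <- function(counts) {
  stopifnot(inherits(counts, "enrichment_counts"))
  tk <- if (counts$targets_k > 0) counts$targets_k else 0.1
  log2((tk / counts$k) * (counts$N / counts$targets_N))
}

#' Hypergeometric tail significance of a ranking's top-k (HGPV)
#'
#' `-log10` of the probability that a uniformly random size-`k` subset of the
#' scored genes contains strictly more than `targets_k` targets, i.e.
#' `-log10(1 - hgcdf(targets_k; k, targets_N, N))`. Higher values mean the
#' observed top-k target count is harder to reach by chance. When the tail is
#' exactly zero (the observed count is the deterministic maximum) the value
#' is clamped to `max_value` instead of infinity.
#'
#' @param counts an [enrichment_counts()].
#' @param inclusive use the inclusive tail `P(X >= targets_k)` instead of the
#'   default strict tail `P(X > targets_k)` printed in the defining formula.
#'   Default `FALSE`.
#' @param max_value clamp for a zero tail (default 300).
#' @return the HGPV value (>= 0).
#' @export
hgpv <- function(counts, inclusive = FALSE, max_value = 300) {
  stopifnot(inherits(counts, "enrichment_counts"))
  q <- counts$targets_k - if (inclusive) 1 else 0
  tail <- phyper(q, counts$targets_N, counts$N - counts$targets_N, counts$k,
                 lower.tail = FALSE)
  if (tail <= 0) return(max_value)
  min(-log10(tail), max_value)
}

#' Split a target chronology at a cutoff year
#'
#' Genes whose first clinical-trial year is on or before the cutoff are
#' "known" (available to a model trained on pre-cutoff data); genes entering
#' trials strictly after the cutoff are the "novel" evaluation set.
#'
#' @param chronology data frame (gene, year), one row per gene.
#' @param cutoff_year integer split year.
#' @return list with character vectors `known` and `novel` (disjoint; their
#'   union is the chronology's gene set).
#' @export
split_chronology <- function(chronology, cutoff_year) {
  stopifnot(is.data.frame(chronology),
            all(c("gene", "year") %in% names(chronology)))
  if (nrow(chronology) == 0)
    abort("empty chronology", "data_error")
  if (anyDuplicated(chronology$gene))
    abort("chronology must have one record per gene", "data_error")
  post <- chronology$year > cutoff_year
  list(known = chronology$gene[!post], novel = chronology$gene[post])
}

#' Score a gene ranking against a held-out target set
#'
#' Assembles [enrichment_counts()] from a ranked gene list and an evaluation
#' target set (typically the post-cutoff side of [split_chronology()]), then
#' computes both time-machine metrics. Higher values of either metric mean
#' the ranking concentrates the held-out targets near its top.
#'
#' @param ranked character vector of genes, best first (the scored universe).
#' @param targets character vector; must be a subset of `ranked`.
#' @param k prefix length to evaluate.
#' @param ... passed to [hgpv()].
#' @return list with `counts`, `elfc`, `hgpv`.
#' @export
evaluate_ranking <- function(ranked, targets, k, ...) {
  if (anyDuplicated(ranked))
    abort("ranking contains duplicate genes", "data_error")
  if (!all(targets %in% ranked))
    abort("evaluation targets outside the ranked universe", "data_error")
  if (k < 1 || k > length(ranked))
    abort("k outside 1..N", "domain_error")
  counts <- enrichment_counts(targets_k = sum(head(ranked, k) %in% targets),
                              k = k, targets_N = length(unique(targets)),
                              N = length(ranked))
  list(counts = counts, elfc = elfc(counts), hgpv = hgpv(counts, ...))
}
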