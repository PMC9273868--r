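#' A pathway collection with a top-level process hierarchy
#'
#' Bundles named gene sets with a Reactome-style hierarchy mapping every
#' pathway to exactly one top-level biological process (27 processes by
#' default in the synthetic collection), plus optional per-pathway topology
#' weights used by the activation scorer.
#'
#' @param pathways named list: pathway id -> character vector of member
#'   genes (nonempty).
#' @param hierarchy data frame (pathway, process) covering every pathway
#'   exactly once.
#' @param topology optional named list: pathway id -> named numeric weights
#'   over (a subset of) its member genes.
#' @return an object of class `pathway_collection`.
#' @export
pathway_collection <- function(pathways, hierarchy, topology = NULL) {
  stopifnot(is.list(pathways), length(pathways) >= 1, is.data.frame(hierarchy),
            all(c("pathway", "process") %in% names(hierarchy)))
  if (is.null(names(pathways)) || anyDuplicated(names(pathways)))
    abort("pathways must be uniquely named", "data_error")
  if (any(lengths(pathways) == 0))
    abort("empty gene set in pathway collection", "data_error")
  if (anyDuplicated(hierarchy$pathway))
    abort("hierarchy maps a pathway to more than one process", "data_error")
  if (!all(names(pathways) %in% hierarchy$pathway))
    abort("hierarchy does not cover every pathway", "data_error")
  structure(list(pathways = pathways,
                 hierarchy = hierarchy[match(names(pathways),
                                             hierarchy$pathway), ],
                 topology = topology),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d pathways, %d processes, sizes %d-%d\n",
              length(x$pathways), length(unique(x$hierarchy$process)),
              min(lengths(x$pathways)), max(lengths(x$pathways))))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' Standard tab-delimited gene-set format: set name, description, then
#' member genes, one set per line.
#'
#' @param path file path.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    abort(sprintf("GMT line %d has fewer than 3 fields", bad[1]),
          "parse_error")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Signed pathway activation score for one comparison
#'
#' A simplified topology-aware activation score: the weighted mean of the
#' pathway's member-gene log2 fold changes, where each gene's weight is its
#' topology weight (uniform when none is supplied) softly down-weighted (by
#' `gate_weight`) when its differential-expression p-value fails the
#' significance gate. Positive scores read as pathway activation in cases,
#' negative as inhibition. This scorer is deliberately simple and pluggable;
#' it is not a reimplementation of any proprietary pathway algorithm.
#'
#' @param effects effect data frame for one comparison (gene, lfc, p_value).
#' @param members character vector of pathway member genes.
#' @param weights optional named numeric topology weights over members.
#' @param p_gate significance gate on the per-gene p-value (default 0.05).
#' @param gate_weight multiplier applied to the weight of genes failing the
#'   gate (default 0.5); `gate_weight = 1` disables gating.
#' @return a single signed score.
#' @export
activation_score <- function(effects, members, weights = NULL,
                             p_gate = 0.05, gate_weight = 0.5) {
  i <- match(members, effects$gene)
  i <- i[!is.na(i)]
  if (length(i) == 0)
    abort("pathway has no genes in the effect universe", "no_overlap")
  genes <- effects$gene[i]
  w <- if (is.null(weights)) setNames(rep(1, length(genes)), genes)
       else weights[genes]
  w[is.na(w)] <- 1
  w <- w * ifelse(effects$p_value[i] < p_gate, 1, gate_weight)
  sum(w * effects$lfc[i]) / sum(w)
}

#' Score every pathway of a collection across a group's comparisons
#'
#' @param effects_list list of per-comparison effect data frames.
#' @param collection a [pathway_collection()].
#' @param ... passed to [activation_score()].
#' @return numeric matrix, pathways x comparisons.
#' @export
score_pathways <- function(effects_list, collection, ...) {
  stopifnot(inherits(collection, "pathway_collection"))
  out <- vapply(effects_list, function(eff)
    vapply(names(collection$pathways), function(p)
      activation_score(eff, collection$pathways[[p]],
                       weights = collection$topology[[p]], ...),
      numeric(1)),
    numeric(length(collection$pathways)))
  matrix(out, nrow = length(collection$pathways),
         dimnames = list(names(collection$pathways), NULL))
}

#' Dysregulation calling criteria
#'
#' @param unidirectional_fraction minimum fraction of a group's comparisons
#'   whose activation score shares one sign (default 0.80; compared exactly,
#'   without rounding, so 7 comparisons need 6).
#' @param magnitude_threshold minimum absolute activation score that must be
#'   reached in at least one comparison of the group (default 0.01).
#' @return an object of class `dysregulation_criteria`.
#' @export
dysregulation_criteria <- function(unidirectional_fraction = 0.80,
                                   magnitude_threshold = 0.01) {
  stopifnot(unidirectional_fraction > 0, unidirectional_fraction <= 1,
            magnitude_threshold > 0)
  structure(list(unidirectional_fraction = unidirectional_fraction,
                 magnitude_threshold = magnitude_threshold),
            class = "dysregulation_criteria")
}

#' Call dysregulated pathways within one comparison group
#'
#' A pathway is called activated (inhibited) in a group when the fraction of
#' the group's comparisons with strictly positive (negative) activation
#' score reaches `unidirectional_fraction`, and the maximum absolute score
#' over the group's comparisons reaches `magnitude_threshold`. A score of
#' exactly 0 counts toward neither direction.
#'
#' @param score_matrix pathways x comparisons matrix as from
#'   [score_pathways()].
#' @param criteria a [dysregulation_criteria()].
#' @param group_id label attached to the calls.
#' @return data frame (pathway, direction, group_id), one row per call; at
#'   most one call per pathway.
#' @export
call_dysregulated <- function(score_matrix, criteria = dysregulation_criteria(),
                              group_id = NA_character_) {
  stopifnot(is.matrix(score_matrix), ncol(score_matrix) >= 1,
            inherits(criteria, "dysregulation_criteria"))
  n <- ncol(score_matrix)
  frac_pos <- rowSums(score_matrix > 0) / n
  frac_neg <- rowSums(score_matrix < 0) / n
  big <- apply(abs(score_matrix), 1, max) >= criteria$magnitude_threshold
  act <- frac_pos >= criteria$unidirectional_fraction & big
  inh <- frac_neg >= criteria$unidirectional_fraction & big
  n_calls <- sum(act) + sum(inh)
  data.frame(
    pathway = c(rownames(score_matrix)[act], rownames(score_matrix)[inh]),
    direction = rep(c("activated", "inhibited"), c(sum(act), sum(inh))),
    group_id = rep(group_id, n_calls), stringsAsFactors = FALSE)
}

#' Hypergeometric process-level enrichment of dysregulated pathways
#'
#' Tail probability that a top-level process holds at least its observed
#' share of a group's dysregulated pathways, computed exactly as the
#' defining formula is printed:
#' `p = 1 - sum_{i=0}^{r-1} C(K, i) C(N-K, n-i) / C(N, n)`,
#' where `N` is the total number of pathways in the collection, `K` the
#' dysregulated pathways in the process of interest, `n` the group's total
#' dysregulated pathways, and `r` the pathways belonging to the process.
#' With `conventional = TRUE` the test uses the textbook orientation instead
#' (population successes = `r` process pathways, observed = `K`,
#' tail `P(X >= K)`).
#'
#' @param N,K,n,r the four counts described above.
#' @param conventional use the conventional orientation (default `FALSE`).
#' @return a p-value in \[0, 1\].
#' @export
process_enrichment <- function(N, K, n, r, conventional = FALSE) {
  v <- c(N = N, K = K, n = n, r = r)
  if (any(v != round(v)) || any(v < 0) || n > N || r > N || K > n)
    abort("inconsistent process enrichment counts", "domain_error")
  if (conventional) {
    # P(X >= K) drawing n from N with r successes
    phyper(K - 1, r, N - r, n, lower.tail = FALSE)
  } else {
    # as printed: 1 - P(X <= r - 1) drawing n from N with K successes
    if (r == 0) return(1)  # empty sum
    phyper(r - 1, K, N - K, n, lower.tail = FALSE)
  }
}

#' @rdname process_enrichment
#' @param calls dysregulation calls for one group (data frame with a
#'   `pathway` column).
#' @param collection a [pathway_collection()].
#' @param ... passed to [process_enrichment()].
#' @return `process_enrichment_table()`: one row per top-level process with
#'   the four counts, the raw p-value, and the Bonferroni-adjusted p-value
#'   (raw times the number of processes tested, capped at 1).
#' @export
process_enrichment_table <- function(calls, collection, ...) {
  stopifnot(inherits(collection, "pathway_collection"))
  hier <- collection$hierarchy
  processes <- sort(unique(hier$process))
  N <- length(collection$pathways)
  n <- length(unique(calls$pathway))
  called_proc <- hier$process[match(unique(calls$pathway), hier$pathway)]
  rows <- lapply(processes, function(pr) {
    r <- sum(hier$process == pr)
    K <- sum(called_proc == pr, na.rm = TRUE)
    data.frame(process = pr, N = N, K = K, n = n, r = r,
               raw_p = process_enrichment(N, K, n, r, ...),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- pmin(1, out$raw_p * length(processes))
  out[order(out$adjusted_p, out$process), ]
}

#' Gene-set similarity coefficient
#'
#' @param a,b character vectors (gene sets).
#' @param method `"jaccard"` (default) or `"combined"`, the EnrichmentMap
#'   style average of the Jaccard and overlap coefficients.
#' @return similarity in \[0, 1\].
#' @export
set_similarity <- function(a, b, method = c("jaccard", "combined")) {
  method <- match.arg(method)
  a <- unique(a); b <- unique(b)
  inter <- length(intersect(a, b))
  jac <- inter / length(union(a, b))
  if (method == "jaccard") return(jac)
  (jac + inter / min(length(a), length(b))) / 2
}

#' Similarity network of dysregulated pathways
#'
#' Builds an undirected graph whose nodes are the called pathways (carrying
#' their direction and group) and whose edges connect pathways with gene-set
#' similarity strictly above `threshold` (edge weight = coefficient).
#' Reported clusters are the connected components with at least
#' `min_cluster` nodes.
#'
#' @param calls dysregulation calls (pathway, direction, group_id).
#' @param gene_sets named list of gene sets covering every called pathway.
#' @param threshold similarity cut (default 0.35, strict inequality).
#' @param min_cluster minimum component size reported (default 4, i.e.
#'   clusters of more than three pathways).
#' @param method similarity coefficient, see [set_similarity()].
#' @return list with `graph` (an igraph object) and `clusters` (list of
#'   character vectors of pathway ids).
#' @export
similarity_network <- function(calls, gene_sets, threshold = 0.35,
                               min_cluster = 4,
                               method = c("jaccard", "combined")) {
  method <- match.arg(method)
  ids <- unique(calls$pathway)
  if (!all(ids %in% names(gene_sets)))
    abort("called pathway without a gene set", "data_error")
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  g <- igraph::set_vertex_attr(
    g, "direction", value = calls$direction[match(ids, calls$pathway)])
  edges <- list(); weights <- numeric(0)
  if (length(ids) >= 2) {
    pairs <- utils::combn(ids, 2)
    for (j in seq_len(ncol(pairs))) {
      s <- set_similarity(gene_sets[[pairs[1, j]]], gene_sets[[pairs[2, j]]],
                          method)
      if (s > threshold) {
        edges[[length(edges) + 1]] <- pairs[, j]
        weights <- c(weights, s)
      }
    }
  }
  if (length(edges)) {
    g <- igraph::add_edges(g, unlist(edges))
    g <- igraph::set_edge_attr(g, "weight", value = weights)
  }
  comp <- igraph::components(g)
  keep <- which(comp$csize >= min_cluster)
  clusters <- lapply(keep, function(k)
    igraph::V(g)$name[comp$membership == k])
  list(graph = g, clusters = clusters)
}
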