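#' Configure a synthetic ALS-style study
#'
#' Describes a full synthetic study: how many case-control comparisons each
#' meta-analysis group contains (default: the source study's layout of 5
#' familial + 7 sporadic CNS transcriptomic comparisons plus one diMN
#' comparison per modality and subtype, 16 in all, with the real per-cohort
#' sample sizes), the gene universe, targets planted with a known direction,
#' effect size and penetrance, pathways planted with a coherent activation
#' shift, and the log2-scale Gaussian noise level.
#'
#' @param design data frame with one row per comparison and columns
#'   `group_id`, `subtype`, `modality`, `n_case`, `n_control`,
#'   `source_name`. Default: [default_study_design()].
#' @param n_genes number of genes in the universe.
#' @param planted_targets `NULL` or a data frame with columns `gene`,
#'   `direction` (`"up"`/`"down"`), `effect_size` (log2 units, finite,
#'   positive) and `penetrance` (fraction of comparisons carrying the effect,
#'   in \[0, 1\]).
#' @param planted_pathways `NULL` or a data frame with columns `pathway`,
#'   `direction`, `magnitude` (mean activation shift applied coherently to
#'   member genes in every comparison).
#' @param noise_sd named numeric: per-sample Gaussian noise standard
#'   deviation on the log2 scale for `transcriptomic` and `proteomic`
#'   modalities.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline log2
#'   expression, shared across comparisons.
#' @param n_pathways,pathway_size_range synthetic pathway-collection shape.
#' @param chronology_density,chronology_cutoff fraction of genes whose first
#'   clinical-trial year falls after the cutoff, and the cutoff year.
#' @param seed integer seed; the whole bundle is a pure function of the
#'   config including this seed.
#' @return an object of class `study_config`.
#' @export
study_config <- function(design = default_study_design(),
                         n_genes = 2000,
                         planted_targets = NULL,
                         planted_pathways = NULL,
                         noise_sd = c(transcriptomic = 0.5, proteomic = 0.7),
                         baseline_mean = 8, baseline_sd = 1.5,
                         n_pathways = 150, pathway_size_range = c(10, 60),
                         chronology_density = 0.2, chronology_cutoff = 2010,
                         seed = 1L) {
  stopifnot(is.data.frame(design), nrow(design) >= 1, n_genes >= 1)
  need <- c("group_id", "subtype", "modality", "n_case", "n_control")
  if (length(setdiff(need, names(design))))
    abort("study design missing required columns", "config_error")
  if (any(design$n_case < 1 | design$n_control < 1))
    abort("case/control sizes must be >= 1", "config_error")
  if (!all(design$group_id %in% meta_group_ids()))
    abort("design group_id outside the six meta-analysis groups", "config_error")
  if (!is.null(planted_targets)) {
    stopifnot(all(c("gene", "direction", "effect_size", "penetrance") %in%
                    names(planted_targets)))
    if (!all(planted_targets$direction %in% c("up", "down")))
      abort("planted target direction must be up/down", "config_error")
    if (!all(is.finite(planted_targets$effect_size)))
      abort("planted effect sizes must be finite", "config_error")
    if (any(planted_targets$penetrance < 0 | planted_targets$penetrance > 1))
      abort("penetrance must lie in [0, 1]", "config_error")
  }
  if (!is.null(planted_pathways)) {
    stopifnot(all(c("pathway", "direction", "magnitude") %in%
                    names(planted_pathways)))
    if (!all(planted_pathways$direction %in% c("up", "down")))
      abort("planted pathway direction must be up/down", "config_error")
  }
  if (!all(c("transcriptomic", "proteomic") %in% names(noise_sd)) ||
      any(noise_sd <= 0))
    abort("noise_sd needs positive transcriptomic and proteomic entries",
          "config_error")
  structure(list(design = design, n_genes = as.integer(n_genes),
                 planted_targets = planted_targets,
                 planted_pathways = planted_pathways,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, n_pathways = as.integer(n_pathways),
                 pathway_size_range = as.integer(pathway_size_range),
                 chronology_density = chronology_density,
                 chronology_cutoff = as.integer(chronology_cutoff),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' @rdname study_config
#' @export
default_study_design <- function() {
  t1 <- load_comparison_table()
  modality <- c("Microarray" = "microarray", "RNA-seq" = "RNA-seq",
                "SWATH-MS" = "SWATH-MS")[t1$technology]
  data.frame(group_id = t1$group_id, subtype = t1$subtype,
             modality = unname(modality), n_case = t1$n_case,
             n_control = t1$n_control,
             source_name = paste(t1$data_series, t1$source),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic study bundle with planted truth
#'
#' Draws per-gene baselines, then for each configured comparison an
#' independent log2-scale Gaussian noise matrix; planted targets add their
#' effect (direction x effect_size) to case samples of the comparisons they
#' penetrate, and planted pathways shift their member genes coherently in
#' every comparison. The bundle also carries a synthetic pathway collection,
#' gene annotations (planted targets are always druggable, small-molecule
#' associated and non-essential, so rank-level recovery is not confounded by
#' annotation luck), external score tables for the text / finance / KOL
#' families, a clinical-trial chronology, and the planted truth.
#'
#' @param config a [study_config()].
#' @return an object of class `study_bundle`: a list with elements
#'   `comparisons` (list of [comparison_dataset()]), `pathway_db`
#'   ([pathway_collection()]), `annotations`, `score_tables`, `chronology`,
#'   `truth`, and `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  genes <- sprintf("G%05d", seq_len(config$n_genes))

  pt <- config$planted_targets
  if (!is.null(pt) && !all(pt$gene %in% genes))
    abort("planted target gene not in universe", "config_error")

  set.seed(derive_seed(config$seed, "pathways"))
  pathway_db <- generate_pathway_collection(
    genes, n_pathways = config$n_pathways,
    size_range = config$pathway_size_range)
  pp <- config$planted_pathways
  if (!is.null(pp) && !all(pp$pathway %in% names(pathway_db$pathways)))
    abort("planted pathway not in pathway collection", "config_error")

  set.seed(derive_seed(config$seed, "baseline"))
  baseline <- rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
  names(baseline) <- genes

  # which comparisons each planted target penetrates
  n_cmp <- nrow(config$design)
  set.seed(derive_seed(config$seed, "penetrance"))
  penetrant <- NULL
  if (!is.null(pt)) {
    penetrant <- lapply(seq_len(nrow(pt)), function(i)
      which(rbinom(n_cmp, 1, pt$penetrance[i]) == 1))
    names(penetrant) <- pt$gene
  }

  # per-gene coherent pathway shift (applied to case samples everywhere)
  shift <- setNames(numeric(config$n_genes), genes)
  if (!is.null(pp)) {
    for (i in seq_len(nrow(pp))) {
      members <- pathway_db$pathways[[pp$pathway[i]]]
      sgn <- if (pp$direction[i] == "up") 1 else -1
      shift[members] <- shift[members] + sgn * pp$magnitude[i]
    }
  }

  set.seed(derive_seed(config$seed, "expression"))
  comparisons <- vector("list", n_cmp)
  for (ci in seq_len(n_cmp)) {
    row <- config$design[ci, ]
    sd_i <- if (row$modality == "SWATH-MS") config$noise_sd[["proteomic"]]
            else config$noise_sd[["transcriptomic"]]
    n_s <- row$n_case + row$n_control
    m <- baseline + matrix(rnorm(config$n_genes * n_s, 0, sd_i),
                           nrow = config$n_genes)
    dimnames(m) <- list(genes, sprintf("c%02d_s%03d", ci, seq_len(n_s)))
    labels <- rep(c("case", "control"), c(row$n_case, row$n_control))
    case_cols <- which(labels == "case")
    m[, case_cols] <- m[, case_cols] + shift
    if (!is.null(pt)) {
      for (ti in seq_len(nrow(pt))) {
        if (ci %in% penetrant[[ti]]) {
          sgn <- if (pt$direction[ti] == "up") 1 else -1
          m[pt$gene[ti], case_cols] <-
            m[pt$gene[ti], case_cols] + sgn * pt$effect_size[ti]
        }
      }
    }
    comparisons[[ci]] <- comparison_dataset(
      m, labels, row$subtype, row$modality, row$group_id,
      source_name = row$source_name %||% sprintf("synthetic-%02d", ci))
  }

  set.seed(derive_seed(config$seed, "annotations"))
  annotations <- generate_annotations(genes, guaranteed = pt$gene)
  set.seed(derive_seed(config$seed, "scores"))
  score_tables <- generate_score_tables(genes)
  chronology <- generate_chronology(
    genes, cutoff_density = config$chronology_density,
    seed = derive_seed(config$seed, "chronology"),
    cutoff_year = config$chronology_cutoff)

  structure(list(comparisons = comparisons, pathway_db = pathway_db,
                 annotations = annotations, score_tables = score_tables,
                 chronology = chronology,
                 truth = list(planted_targets = pt,
                              penetrant_comparisons = penetrant,
                              planted_pathways = pp),
                 config = config),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %d comparisons, %d genes, %d pathways\n",
              length(x$comparisons), x$config$n_genes,
              length(x$pathway_db$pathways)))
  cat("  groups:", paste(sort(unique(vapply(x$comparisons, `[[`, "",
                                            "group_id"))), collapse = ", "),
      "\n")
  invisible(x)
}

# Synthetic Reactome-style collection. Processes are assigned cyclically and
# each owns a disjoint pool of the gene universe; a pathway draws ~80% of its
# members from its process pool and the rest anywhere, so same-process
# pathways share gene content while unrelated ones barely overlap. In
# addition, a later pathway of a process may be a "sibling" of an earlier
# one (keeping ~70% of its genes), emulating the nested parent/child sets of
# a real hierarchy that give similarity networks their clusters.
generate_pathway_collection <- function(genes, n_pathways = 150,
                                        size_range = c(10, 60),
                                        pool_fraction = 0.8,
                                        sibling_prob = 0.5,
                                        sibling_keep = 0.7) {
  processes <- readLines(ext_file("toplevel_processes.txt"))
  ids <- sprintf("PW%04d", seq_len(n_pathways))
  proc <- processes[(seq_len(n_pathways) - 1) %% length(processes) + 1]
  idx <- rep_len(seq_along(processes), length(genes))
  pool_of <- lapply(seq_along(processes), function(j) genes[idx == j])
  names(pool_of) <- processes
  sizes <- pmin(sample(seq(size_range[1], size_range[2]), n_pathways,
                       replace = TRUE),
                length(genes))
  sets <- vector("list", n_pathways)
  last_in_proc <- list()
  for (i in seq_len(n_pathways)) {
    parent <- last_in_proc[[proc[i]]]
    if (!is.null(parent) && runif(1) < sibling_prob) {
      keep <- sample(parent, min(length(parent),
                                 ceiling(sibling_keep * sizes[i])))
      rest <- sample(setdiff(genes, keep), max(0, sizes[i] - length(keep)))
      sets[[i]] <- sort(c(keep, rest))
    } else {
      pool <- pool_of[[proc[i]]]
      n_pool <- min(length(pool), ceiling(pool_fraction * sizes[i]))
      core <- sample(pool, n_pool)
      rest <- sample(setdiff(genes, core), sizes[i] - n_pool)
      sets[[i]] <- sort(c(core, rest))
    }
    last_in_proc[[proc[i]]] <- sets[[i]]
  }
  names(sets) <- ids
  pathway_collection(sets, data.frame(pathway = ids, process = proc,
                                      stringsAsFactors = FALSE))
}

generate_annotations <- function(genes, guaranteed = NULL) {
  classes <- c("GPCR", "Ion channel", "Kinase", "Nuclear receptor", "Enzyme",
               "Transporter", "Phosphatase", "Other")
  n <- length(genes)
  ann <- data.frame(
    gene = genes,
    druggable_class = ifelse(runif(n) < 0.6,
                             sample(classes, n, replace = TRUE),
                             NA_character_),
    has_small_molecule = runif(n) < 0.5,
    is_essential = runif(n) < 0.1,
    aging_associated = runif(n) < 0.15,
    novelty_level = sample(1:3, n, replace = TRUE),
    stringsAsFactors = FALSE)
  if (!is.null(guaranteed)) {
    i <- match(guaranteed, genes)
    ann$druggable_class[i] <- "Kinase"
    ann$has_small_molecule[i] <- TRUE
    ann$is_essential[i] <- FALSE
    ann$novelty_level[i] <- 3L
  }
  ann
}

# External score families accepted by contract (the platform's text-mining,
# finance and KOL scores are inputs, never computed here); the omics family
# is derived from the data by group_omics_scores().
generate_score_tables <- function(genes) {
  data.frame(gene = genes,
             text = runif(length(genes)),
             finance = runif(length(genes)),
             kol = runif(length(genes)),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic clinical-trial chronology
#'
#' Each gene receives a first-clinical-trial year; a fraction
#' `cutoff_density` of genes (Bernoulli per gene) falls strictly after the
#' cutoff year ("novel" trial entrants for the time-machine split), the rest
#' on or before it.
#'
#' @param genes character vector of gene IDs (or a single integer, taken as a
#'   universe size with automatic IDs).
#' @param cutoff_density fraction in \[0, 1\] of post-cutoff genes.
#' @param seed integer seed.
#' @param cutoff_year the split year.
#' @param span how many years either side of the cutoff the years cover.
#' @return a data frame (gene, year), one row per gene.
#' @export
generate_chronology <- function(genes, cutoff_density, seed,
                                cutoff_year = 2010, span = 20) {
  if (is.numeric(genes) && length(genes) == 1)
    genes <- sprintf("G%05d", seq_len(genes))
  stopifnot(length(genes) >= 1, cutoff_density >= 0, cutoff_density <= 1)
  set.seed(seed)
  post <- rbinom(length(genes), 1, cutoff_density) == 1
  year <- integer(length(genes))
  year[post] <- sample(seq(cutoff_year + 1, cutoff_year + span),
                       sum(post), replace = TRUE)
  year[!post] <- sample(seq(cutoff_year - span, cutoff_year),
                        sum(!post), replace = TRUE)
  data.frame(gene = genes, year = year, stringsAsFactors = FALSE)
}
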