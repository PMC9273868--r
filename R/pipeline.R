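#' Configure an end-to-end workbench run
#'
#' Collects every stage's configuration in one place with the study's
#' thresholds as defaults: the 80% unidirectionality and 0.01 magnitude
#' rules for pathway calling, the 0.35 similarity cut, top-50 ranking cuts,
#' and the time-machine cutoff year. One global seed fans out to per-stage
#' seeds by stable hashing, so stages draw independent random streams.
#'
#' @param study a [study_config()] (its seed is overridden by `seed`).
#' @param criteria a [dysregulation_criteria()].
#' @param cutoff_year,k time-machine split year and prefix length.
#' @param similarity_threshold,similarity_method see [similarity_network()].
#' @param top_k ranking cut applied in both novelty modes.
#' @param seed global run seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(study = study_config(),
                       criteria = dysregulation_criteria(),
                       cutoff_year = 2010, k = 50,
                       similarity_threshold = 0.35,
                       similarity_method = "jaccard",
                       top_k = 50, seed = 1L) {
  stopifnot(inherits(study, "study_config"),
            inherits(criteria, "dysregulation_criteria"))
  study$seed <- derive_seed(seed, "study")
  structure(list(study = study, criteria = criteria,
                 cutoff_year = as.integer(cutoff_year), k = as.integer(k),
                 similarity_threshold = similarity_threshold,
                 similarity_method = similarity_method,
                 top_k = as.integer(top_k), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full target-discovery workbench on a synthetic study
#'
#' Executes the stage sequence generate -> effects -> prioritize ->
#' time-machine -> pathways -> screen summary, writing each stage's outputs
#' as plain-text files under `out_dir` and finally a manifest listing every
#' output with its MD5 checksum. The run is a pure function of the config
#' and seed: identical config + seed reproduce identical checksums. A stage
#' failure aborts with the stage name; outputs of earlier stages are left in
#' place.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return the manifest (also written to `manifest.json`), invisibly a list
#'   with per-stage file paths, checksums, seed and group inventory.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            "stage_error"))
  }

  # -- generate ---------------------------------------------------------
  bundle <- stage("generate", function() generate_study(cfg$study))
  meta <- data.frame(
    comparison = seq_along(bundle$comparisons),
    group_id = vapply(bundle$comparisons, `[[`, "", "group_id"),
    subtype = vapply(bundle$comparisons, `[[`, "", "subtype"),
    modality = vapply(bundle$comparisons, `[[`, "", "modality"),
    n_case = vapply(bundle$comparisons,
                    function(x) sum(x$labels == "case"), 0),
    n_control = vapply(bundle$comparisons,
                       function(x) sum(x$labels == "control"), 0))
  files["comparisons"] <- write_tsv(meta, file.path(out_dir, "comparisons.tsv"))
  files["chronology"] <- write_tsv(bundle$chronology,
                                   file.path(out_dir, "chronology.tsv"))

  # -- effects ----------------------------------------------------------
  effects <- stage("effects", function()
    lapply(bundle$comparisons, compute_effects))
  eff_long <- do.call(rbind, lapply(seq_along(effects), function(i)
    cbind(comparison = i, effects[[i]])))
  files["effects"] <- write_tsv(eff_long, file.path(out_dir, "effects.tsv"))

  # -- prioritize -------------------------------------------------------
  groups <- build_groups(bundle$comparisons)
  cmp_ids <- vapply(bundle$comparisons, `[[`, "", "group_id")
  group_eff <- lapply(setNames(names(groups), names(groups)),
                      function(gid) effects[cmp_ids == gid])
  prior <- stage("prioritize", function() {
    cns_cons <- lapply(group_eff[grep("^CNS-", names(groups))],
                       consistency_table)
    dimn_eff <- lapply(group_eff[grep("^diMN-", names(groups))], `[[`, 1)
    per_mode <- lapply(c("high_confidence", "novel"), function(mode) {
      fc <- filter_config(novelty_mode = mode, top_k = cfg$top_k)
      tops <- lapply(group_eff, function(effs) {
        sc <- merge(group_omics_scores(effs), bundle$score_tables,
                    by = "gene", sort = TRUE)
        ranked <- metascore(sc, enabled_families = fc$enabled_families)$gene
        apply_filters(ranked, bundle$annotations, fc)
      })
      list(tops = tops,
           candidates = select_candidates(tops, cns_cons, dimn_eff, fc))
    })
    names(per_mode) <- c("high_confidence", "novel")
    list(per_mode = per_mode, cns_cons = cns_cons)
  })
  candidates <- do.call(rbind, c(lapply(prior$per_mode, `[[`, "candidates"),
                                 list(make.row.names = FALSE)))
  files["candidates"] <- write_tsv(candidates,
                                   file.path(out_dir, "candidates.tsv"))
  top_long <- do.call(rbind, lapply(names(prior$per_mode), function(mode)
    do.call(rbind, lapply(names(prior$per_mode[[mode]]$tops), function(gid) {
      genes <- prior$per_mode[[mode]]$tops[[gid]]
      if (length(genes) == 0) return(NULL)
      data.frame(mode = mode, group_id = gid, rank = seq_along(genes),
                 gene = genes, stringsAsFactors = FALSE)
    }))))
  if (is.null(top_long))
    top_long <- data.frame(mode = character(), group_id = character(),
                           rank = integer(), gene = character())
  files["top_lists"] <- write_tsv(top_long, file.path(out_dir, "top_lists.tsv"))

  # -- time machine -----------------------------------------------------
  tm <- stage("timemachine", function() {
    split <- split_chronology(bundle$chronology, cfg$cutoff_year)
    lapply(names(groups), function(gid) {
      sc <- group_omics_scores(group_eff[[gid]])
      ranked <- metascore(sc, enabled_families = "omics")$gene
      ev <- evaluate_ranking(ranked, split$novel, k = cfg$k)
      list(group = gid, cutoff = cfg$cutoff_year, k = cfg$k,
           counts = unclass(ev$counts), elfc = ev$elfc, hgpv = ev$hgpv)
    })
  })
  files["timemachine"] <- file.path(out_dir, "timemachine.json")
  jsonlite::write_json(tm, files["timemachine"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  # -- pathways ---------------------------------------------------------
  pw <- stage("pathways", function() {
    calls <- do.call(rbind, lapply(names(groups), function(gid)
      call_dysregulated(score_pathways(group_eff[[gid]], bundle$pathway_db),
                        cfg$criteria, group_id = gid)))
    enrich <- do.call(rbind, lapply(split(calls, calls$group_id), function(cc)
      cbind(group_id = cc$group_id[1],
            process_enrichment_table(cc, bundle$pathway_db))))
    net <- similarity_network(calls, bundle$pathway_db$pathways,
                              threshold = cfg$similarity_threshold,
                              min_cluster = 4,
                              method = cfg$similarity_method)
    list(calls = calls, enrich = enrich, net = net)
  })
  files["pathway_calls"] <- write_tsv(pw$calls,
                                      file.path(out_dir, "pathway_calls.tsv"))
  files["process_enrichment"] <-
    write_tsv(pw$enrich, file.path(out_dir, "process_enrichment.tsv"))
  el <- igraph::as_data_frame(pw$net$graph, what = "edges")
  files["network_edges"] <- write_tsv(el, file.path(out_dir,
                                                    "network_edges.tsv"))
  files["network_graphml"] <- file.path(out_dir, "network.graphml")
  igraph::write_graph(pw$net$graph, files["network_graphml"],
                      format = "graphml")

  # -- screen summary (packaged fixture) --------------------------------
  screen <- stage("screen", function() summarize_screen(load_screen_table()))
  files["screen_summary"] <- file.path(out_dir, "screen_summary.json")
  jsonlite::write_json(
    list(n_genes = screen$n_genes, n_with_model = screen$n_with_model,
         n_orthologs = screen$n_orthologs,
         category_counts = as.list(screen$category_counts),
         n_strong_or_moderate_rescue = screen$n_strong_or_moderate_rescue,
         n_strong_rescue_unreported = screen$n_strong_rescue_unreported),
    files["screen_summary"], auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    seed = cfg$seed,
    n_groups = length(groups),
    groups = names(groups),
    n_candidates = nrow(candidates),
    files = as.list(files),
    checksums = as.list(tools::md5sum(unname(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Render the run's human-readable report tables
#'
#' Reads a completed run directory and returns the candidate table, the
#' process-enrichment table and the screen summary as R objects; empty
#' stages yield empty but well-formed tables.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return list with `candidates`, `enrichment`, `screen_summary`.
#' @export
report_tables <- function(out_dir) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(manifest_path))
    abort("no manifest.json: run_pipeline() has not completed here",
          "data_error")
  list(candidates = read_tsv_strict(file.path(out_dir, "candidates.tsv")),
       enrichment = read_tsv_strict(file.path(out_dir,
                                              "process_enrichment.tsv")),
       screen_summary = jsonlite::read_json(
         file.path(out_dir, "screen_summary.json"), simplifyVector = TRUE))
}
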