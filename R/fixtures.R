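#' Packaged study-table fixtures
#'
#' The package ships plain-text transcriptions of the source study's three
#' summary tables: the case-control comparison inventory (16 comparisons over
#' post-mortem CNS tissue and iPSC-derived motor neurons, diMN), the candidate
#' therapeutic target table (28 genes in high-confidence and novel categories),
#' and the Drosophila c9ALS modifier-screen results (human gene, fly ortholog,
#' eye-degeneration modification score). `load_study_fixtures()` returns all
#' three as typed data frames.
#'
#' @param path path to the TSV transcription (defaults to the packaged
#'   fixture; overridable for testing malformed inputs).
#' @return `load_comparison_table()`: a data frame with one row per
#'   case-control comparison (subtype, data series, platform, technology,
#'   source tissue, tissue class, mutant gene, case/control counts, year) plus
#'   a derived `group_id` column naming the meta-analysis group the comparison
#'   is pooled into.
#' @seealso [build_groups()], [summarize_screen()]
#' @export
load_comparison_table <- function(path = ext_file("table1_comparisons.tsv")) {
  df <- read_tsv_strict(path)
  need <- c("subtype", "data_series", "platform", "technology", "source",
            "tissue_class", "mutant_gene", "n_case", "n_control", "year")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(paste0("comparison table missing columns: ",
                 paste(miss, collapse = ", ")), "parse_error")
  for (i in seq_len(nrow(df))) {
    if (!df$subtype[i] %in% c("fALS", "sALS"))
      abort(sprintf("row %d: unknown subtype '%s'", i, df$subtype[i]),
            "parse_error")
    if (is.na(df$n_case[i]) || is.na(df$n_control[i]) ||
        df$n_case[i] < 1 || df$n_control[i] < 1)
      abort(sprintf("row %d: invalid case/control counts", i), "parse_error")
  }
  df$group_id <- comparison_group_id(df$tissue_class, df$technology, df$subtype)
  df
}

# The six meta-analysis groups: two CNS transcriptomic groups (fALS, sALS) and
# four diMN groups split by modality and subtype.
comparison_group_id <- function(tissue_class, technology, subtype) {
  ifelse(tissue_class == "CNS",
         paste0("CNS-", subtype),
         ifelse(technology == "SWATH-MS",
                paste0("diMN-prot-", subtype),
                paste0("diMN-tx-", subtype)))
}

#' @rdname load_comparison_table
#' @return `load_candidate_table()`: the 28-candidate table, with numeric
#'   directional-consistency percentages for CNS rows, log2 fold change and
#'   p-value for diMN rows, and logical `aging` / `proteomic` flags.
#' @export
load_candidate_table <- function(path = ext_file("table2_candidates.tsv")) {
  df <- read_tsv_strict(path)
  need <- c("gene", "category", "compartment", "fals_value", "sals_value",
            "fals_p", "sals_p", "protein_family", "tissue_enrichment",
            "aging", "proteomic", "mechanism")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(paste0("candidate table missing columns: ",
                 paste(miss, collapse = ", ")), "parse_error")
  for (i in seq_len(nrow(df))) {
    if (!df$category[i] %in% c("high_confidence", "novel"))
      abort(sprintf("row %d: unknown category '%s'", i, df$category[i]),
            "parse_error")
    if (!df$compartment[i] %in% c("CNS", "diMN"))
      abort(sprintf("row %d: unknown compartment '%s'", i, df$compartment[i]),
            "parse_error")
  }
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "-", NA, x)))
  df$fals_value <- num(df$fals_value)
  df$sals_value <- num(df$sals_value)
  df$fals_p <- num(df$fals_p)
  df$sals_p <- num(df$sals_p)
  df$aging <- df$aging == "yes"
  df$proteomic <- df$proteomic == "yes"
  df
}

#' @rdname load_comparison_table
#' @return `load_screen_table()`: one row per (human gene, fly ortholog) pair;
#'   `score` is numeric with `NA` for lethal crosses and absent fly models
#'   (`score_status` distinguishes `"scored"`, `"lethal"`, `"no_model"`), and
#'   `reference` is `NA` where the screen table cites no prior report.
#' @export
load_screen_table <- function(path = ext_file("table3_screen.tsv")) {
  df <- read_tsv_strict(path)
  need <- c("human_gene", "fly_symbol", "model_available", "score",
            "interpretation", "reference")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(paste0("screen table missing columns: ",
                 paste(miss, collapse = ", ")), "parse_error")
  df$model_available <- df$model_available == "Yes"
  status <- ifelse(!df$model_available, "no_model",
                   ifelse(df$score == "Lethal", "lethal", "scored"))
  score <- rep(NA_real_, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (status[i] == "scored") {
      v <- suppressWarnings(as.numeric(df$score[i]))
      if (is.na(v))
        abort(sprintf("row %d: unparseable score '%s'", i, df$score[i]),
              "parse_error")
      if (v < -4 || v > 2)
        abort(sprintf("row %d: score %g outside [-4, 2]", i, v), "parse_error")
      score[i] <- v
    }
    if (status[i] == "no_model" && df$score[i] != "-")
      abort(sprintf("row %d: score present without fly model", i),
            "parse_error")
  }
  df$score <- score
  df$score_status <- status
  df$interpretation <- ifelse(df$interpretation == "-", NA, df$interpretation)
  df$reference <- ifelse(df$reference == "-", NA, df$reference)
  df
}

#' @rdname load_comparison_table
#' @return `load_study_fixtures()`: a list with elements `comparisons`,
#'   `candidates` and `screen`.
#' @export
load_study_fixtures <- function() {
  list(comparisons = load_comparison_table(),
       candidates = load_candidate_table(),
       screen = load_screen_table())
}

#' Bookkeeping summaries of the fixture tables
#'
#' `comparison_summary()` totals the case/control sample counts by tissue
#' class. CNS comparisons use independent cohorts so their counts sum; the
#' four diMN comparisons re-use one Answer ALS cohort (25 fALS + 110 sALS
#' cases against 31 shared controls) across two modalities, so diMN subjects
#' are counted once per subtype from the transcriptomic rows.
#'
#' @param comparisons a comparison table as from [load_comparison_table()].
#' @return a list with `cns_cases`, `cns_controls`, `dimn_cases`,
#'   `dimn_controls`, and `n_groups`.
#' @export
comparison_summary <- function(comparisons = load_comparison_table()) {
  cns <- comparisons[comparisons$tissue_class == "CNS", ]
  dim_tx <- comparisons[comparisons$tissue_class == "diMN" &
                          comparisons$technology != "SWATH-MS", ]
  list(cns_cases = sum(cns$n_case),
       cns_controls = sum(cns$n_control),
       dimn_cases = sum(dim_tx$n_case),
       dimn_controls = max(dim_tx$n_control),
       n_groups = length(unique(comparisons$group_id)))
}

#' @rdname comparison_summary
#' @param candidates a candidate table as from [load_candidate_table()].
#' @return `candidate_summary()`: counts of candidates overall, by category,
#'   and carrying the aging-association flag (with its percentage).
#' @export
candidate_summary <- function(candidates = load_candidate_table()) {
  list(n_candidates = nrow(candidates),
       n_high_confidence = sum(candidates$category == "high_confidence"),
       n_novel = sum(candidates$category == "novel"),
       n_aging = sum(candidates$aging),
       pct_aging = round(100 * mean(candidates$aging), 1))
}
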