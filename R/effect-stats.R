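#' Construct a case-control comparison dataset
#'
#' A comparison bundles one cohort's log2-scale expression (or protein
#' abundance) matrix with its case/control labels and the metadata that
#' decides which meta-analysis group it is pooled into: ALS subtype (familial
#' or sporadic), assay modality and tissue class.
#'
#' @param matrix numeric matrix, genes as rows (rownames = gene IDs), samples
#'   as columns (colnames = sample IDs), values on log2 scale.
#' @param labels character vector over samples with values `"case"` /
#'   `"control"`; either named by sample ID or in column order.
#' @param subtype `"fALS"` or `"sALS"`.
#' @param modality `"microarray"`, `"RNA-seq"` or `"SWATH-MS"`.
#' @param group_id one of the six meta-analysis group labels
#'   (`"CNS-fALS"`, `"CNS-sALS"`, `"diMN-tx-fALS"`, `"diMN-tx-sALS"`,
#'   `"diMN-prot-fALS"`, `"diMN-prot-sALS"`).
#' @param source_name free-text provenance label.
#' @return an object of class `comparison_dataset`.
#' @export
comparison_dataset <- function(matrix, labels, subtype, modality, group_id,
                               source_name = "") {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix)))
    abort("expression matrix must have gene rownames", "data_error")
  if (anyDuplicated(rownames(matrix)))
    abort("duplicate gene IDs in expression matrix", "data_error")
  if (!is.null(names(labels))) labels <- labels[colnames(matrix)]
  if (length(labels) != ncol(matrix))
    abort("labels must cover every sample column", "data_error")
  if (!all(labels %in% c("case", "control")))
    abort("labels must be 'case' or 'control'", "data_error")
  if (!subtype %in% c("fALS", "sALS"))
    abort("subtype must be fALS or sALS", "data_error")
  if (!modality %in% c("microarray", "RNA-seq", "SWATH-MS"))
    abort("unknown modality", "data_error")
  if (!group_id %in% meta_group_ids())
    abort("unknown meta-analysis group id", "data_error")
  structure(list(matrix = matrix, labels = unname(labels), subtype = subtype,
                 modality = modality, group_id = group_id,
                 source_name = source_name),
            class = "comparison_dataset")
}

#' The six meta-analysis group labels
#' @return character vector of the six group IDs.
#' @export
meta_group_ids <- function() {
  c("CNS-fALS", "CNS-sALS", "diMN-tx-fALS", "diMN-tx-sALS",
    "diMN-prot-fALS", "diMN-prot-sALS")
}

#' @export
print.comparison_dataset <- function(x, ...) {
  cat(sprintf("<comparison_dataset> %s | %s | %s\n  %d genes, %d case / %d control%s\n",
              x$group_id, x$subtype, x$modality, nrow(x$matrix),
              sum(x$labels == "case"), sum(x$labels == "control"),
              if (nzchar(x$source_name)) paste0(" | ", x$source_name) else ""))
  invisible(x)
}

#' Per-gene differential effects for one comparison
#'
#' Computes, for every gene, the log2 fold change (case mean minus control
#' mean, both already on log2 scale) and a two-sided p-value from Welch's
#' unequal-variance t-test. Genes with zero variance in both arms get
#' `p = 1` with the fold change as computed, so constant genes never surface
#' as significant and never produce NaN statistics.
#'
#' @param comparison a [comparison_dataset()].
#' @return a data frame with columns `gene`, `lfc`, `p_value` (one row per
#'   gene, in matrix row order). `p_value` lies in (0, 1].
#' @details Requires at least 2 case and 2 control samples; fewer raises an
#'   `insufficient_replication` error. The location test is deliberately
#'   assumption-light (no count model, no moderation): downstream consumers
#'   only use the sign of `lfc` and the raw p-value.
#' @examples
#' m <- matrix(rnorm(40, 8), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' cmp <- comparison_dataset(m, rep(c("case", "control"), each = 5),
#'                           "fALS", "RNA-seq", "CNS-fALS")
#' head(compute_effects(cmp))
#' @export
compute_effects <- function(comparison) {
  stopifnot(inherits(comparison, "comparison_dataset"))
  m <- comparison$matrix
  case <- m[, comparison$labels == "case", drop = FALSE]
  ctrl <- m[, comparison$labels == "control", drop = FALSE]
  welch_rows(case, ctrl, rownames(m))
}

# Vectorized Welch test over matrix rows (case columns vs control columns).
welch_rows <- function(case, ctrl, genes) {
  nx <- ncol(case); ny <- ncol(ctrl)
  if (nx < 2 || ny < 2)
    abort("need >= 2 case and >= 2 control samples", "insufficient_replication")
  mx <- rowMeans(case); my <- rowMeans(ctrl)
  vx <- rowSums((case - mx)^2) / (nx - 1)
  vy <- rowSums((ctrl - my)^2) / (ny - 1)
  lfc <- mx - my
  se2 <- vx / nx + vy / ny
  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  p[degenerate] <- 1
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  data.frame(gene = genes, lfc = unname(lfc), p_value = unname(p),
             stringsAsFactors = FALSE)
}
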