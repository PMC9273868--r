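#' @keywords internal
"_PACKAGE"

#' @importFrom stats pt phyper rnorm runif rbinom setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up at integer precision; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

abort <- function(msg, class) {
  stop(structure(
    class = c(class, "alstargets_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

read_tsv_strict <- function(path, ...) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), "data_error")
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, na.strings = NULL, ...)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Stable per-stage seed fan-out from one run seed: a small polynomial hash of
# the stage name folded into the 31-bit range, so stages draw independent
# streams and adding a stage never shifts another stage's stream.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 10007L
  as.integer((as.numeric(seed) * 127L + h) %% 2147483647)
}

ext_file <- function(name) {
  system.file("extdata", name, package = "alstargets", mustWork = TRUE)
}
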