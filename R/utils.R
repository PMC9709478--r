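#' @keywords internal
"_PACKAGE"

## Shared internal helpers: argument checks and TSV I/O conventions.
## All tables are plain TSV; headers are ordinary column names, comment
## lines (provenance) start with '#'.

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    .stopf("'%s' must be a single non-missing number", name)
  if (x < lower || x > upper)
    .stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

#' Write a data frame as TSV
#'
#' Plain tab-separated output with a header row; optional provenance
#' comment lines (prefixed with `#`) above the header.
#'
#' @param x data frame.
#' @param path output path.
#' @param comments character vector of provenance lines, written as
#'   `#`-prefixed comments before the header.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by this package
#'
#' @param path input path.
#' @return data frame (comment lines starting with `#` are skipped).
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
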