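`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write a data frame as tab-separated text
#'
#' Plain `write.table()` wrapper with the conventions used throughout the
#' package: tab separator, no quoting, no row names, `NA` written as "NA".
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read tab-separated text as a data frame
#'
#' @param path input file path.
#' @return data frame with character columns left unconverted.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
}

# stop() with a consistent error class so callers/tests can match on it
triage_error <- function(msg, class) {
  stop(structure(class = c(class, "crctriage_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
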