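`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
assert_that <- function(ok, ...) if (!ok) stop2(...)

# deterministic numeric formatting for TSV output (stable across platforms)
num_chr <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

#' Write a data.frame as a TSV with header
#'
#' Thin wrapper over [data.table::fwrite()] with the conventions used by every
#' pipeline output table: tab separator, no quoting, `NA` as literal `NA`,
#' header always written (a header-only file for zero rows).
#'
#' @param x data.frame / data.table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(as.data.table(x), path, sep = "\t", quote = FALSE,
                     na = "NA", col.names = TRUE)
  invisible(path)
}

#' Read a TSV with header
#' @param path file path.
#' @return data.table.
#' @export
read_tsv <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  fread(path, sep = "\t", header = TRUE, data.table = TRUE)
}
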