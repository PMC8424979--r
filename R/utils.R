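#' @keywords internal
"_PACKAGE"

#' @importFrom stats density median optimize pf pchisq sd setNames rgeom runif
#'   dnorm uniroot
#' @importFrom utils read.delim write.table head modifyList
#' @importFrom mclust Mclust mclustBIC
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percentage of a count over a total, at printed precision
#'
#' Small reporting helper used throughout the summary layer, e.g. the share
#' of pathway genes attributable to a duplication event.
#'
#' @param numer,denom Numerator and denominator counts.
#' @param digits Decimal places to report (default 1).
#' @return A single number, `100 * numer / denom` rounded to `digits`.
#' @examples
#' pct_of(25, 39)  # 64.1
#' @export
pct_of <- function(numer, denom, digits = 1) {
  stopifnot(denom != 0)
  round(100 * numer / denom, digits)
}

#' Percent increase of one quantity over another
#'
#' @param x Larger (or later) value.
#' @param ref Reference value the increase is measured against.
#' @param digits Decimal places to report (default 1).
#' @return `100 * (x - ref) / ref`, rounded.
#' @examples
#' pct_increase(773, 449)  # genome-size contrast, 72.2
#' @export
pct_increase <- function(x, ref, digits = 1) {
  stopifnot(ref > 0)
  round(100 * (x - ref) / ref, digits)
}

## TSV conventions: every writer emits a single '#'-prefixed header line so
## outputs are self-describing yet trivially machine-readable.
write_tsv_commented <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

read_tsv_commented <- function(path, col_names = NULL) {
  header <- readLines(path, n = 1L)
  nm <- strsplit(sub("^#\\s*", "", header), "\t")[[1]]
  df <- tryCatch(
    read.delim(path, header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE),
    error = function(e) {
      as.data.frame(setNames(rep(list(character(0)), length(nm)), nm))
    })
  if (nrow(df)) names(df) <- nm else names(df) <- nm
  df
}

wgd_log <- function(...) {
  message("[wgdkit] ", ...)
}
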