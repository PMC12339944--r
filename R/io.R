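# Delimited-text readers/writers for series tables.  RFC-4180-style CSV
# (or tab-separated) with a mandatory header row; numeric parsing is
# locale-independent (dot decimal separator).

guess_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "tab", "txt")) "tsv" else "csv"
}

#' Read a series table from delimited text
#'
#' @param path File path (CSV or TSV, header row required).
#' @param format `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @param columns Optional character vector restricting and ordering the
#'   returned columns; unknown names raise a column error listing the
#'   available ones.
#' @return data.frame with attribute `source_path`; numeric columns are
#'   read as doubles, everything else as character.
#' @export
read_series <- function(path, format = c("auto", "csv", "tsv"),
                        columns = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    abort_it(paste0("file not found: ", path), "it_io_error")
  fmt <- guess_format(path, format)
  sep <- if (fmt == "tsv") "\t" else ","
  nf <- count.fields(path, sep = sep, quote = "\"")
  nf <- nf[!is.na(nf)]
  if (length(nf) == 0)
    abort_it(paste0("file is empty: ", path), "it_io_error")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    abort_it(sprintf("ragged rows in %s: line %d has %d fields, expected %d",
                     path, bad, nf[bad], nf[1]), "it_format_error")
  }
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  if (!is.null(columns)) {
    missing <- setdiff(columns, names(df))
    if (length(missing) > 0)
      abort_it(paste0("unknown column(s) ", paste(missing, collapse = ", "),
                      "; available: ", paste(names(df), collapse = ", ")),
               "it_column_error")
    df <- df[, columns, drop = FALSE]
  }
  attr(df, "source_path") <- path
  df
}

#' Write a series table as delimited text
#'
#' @param table data.frame of equal-length columns.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_series <- function(table, path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  fmt <- guess_format(path, format)
  if (fmt == "tsv") {
    write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    write.csv(table, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
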