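#' Write a table of keyed rows as CSV
#'
#' Rows must share an identical key set; columns are written in the key
#' order of the first row so output is deterministic. UTF-8, '.' decimal
#' separator, header always present.
#'
#' @param records A data.frame, or a list of named lists/vectors with
#'   homogeneous keys.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else if (length(records) == 0L) {
    stop("cannot infer a header from an empty record list; ",
         "pass a 0-row data.frame instead", call. = FALSE)
  } else {
    keys <- names(records[[1]])
    if (is.null(keys)) stop("rows must be named", call. = FALSE)
    for (r in records)
      if (!identical(sort(names(r)), sort(keys)))
        stop("heterogeneous row keys", call. = FALSE)
    df <- do.call(rbind, lapply(records, function(r)
      as.data.frame(as.list(r)[keys], stringsAsFactors = FALSE)))
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a CSV table written by [write_table()]
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
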