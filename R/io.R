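#' Read an activity matrix from delimited text
#'
#' Neurons as rows, time points as columns, no header by default. Uses
#' `data.table::fread()` when available (large recordings), falling back to
#' [utils::read.delim()].
#'
#' @param path file path (CSV or TSV; the separator is sniffed from the
#'   first line unless given).
#' @param sep field separator, or `NULL` to sniff.
#' @param header whether the first row is a header (default `FALSE`).
#' @return Numeric matrix, neurons x time.
#' @export
read_activity <- function(path, sep = NULL, header = FALSE) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  if (requireNamespace("data.table", quietly = TRUE)) {
    df <- data.table::fread(path, sep = sep, header = header)
    as.matrix(df)
  } else {
    as.matrix(read.delim(path, sep = sep, header = header))
  }
}

#' Read behavior channels from delimited text
#'
#' One column per behavior channel, with a header row of channel names.
#'
#' @param path file path.
#' @param dt sampling interval in seconds (default 1/3).
#' @param sep field separator, or `NULL` to sniff.
#' @return Named list of [time_series].
#' @export
read_behaviors <- function(path, dt = 1 / 3, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- read.delim(path, sep = sep, header = TRUE)
  out <- lapply(names(df), function(nm) time_series(df[[nm]], dt = dt,
                                                    label = nm))
  names(out) <- names(df)
  out
}
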