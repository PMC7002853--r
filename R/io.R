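# File input: plain numeric vectors and grouped tables.

#' Read a numeric vector from a plain-text file
#'
#' One value per line.  Any non-numeric line is an error; values are never
#' skipped silently.
#'
#' @param path File path.
#' @return A numeric vector.
#' @export
read_values <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no values in ", path)
  values <- suppressWarnings(as.numeric(lines))
  bad <- which(is.na(values))
  if (length(bad) > 0L)
    stop("non-numeric value at line ", bad[1], " of ", path, ": '",
         lines[bad[1]], "'")
  values
}

#' Split a grouped table into two sample vectors
#'
#' Reads a CSV or TSV file with a header and extracts the value column for
#' exactly two groups.  If the file contains more than two distinct group
#' labels, `groups` must pick two; the vectors are returned in the order
#' the labels are given.
#'
#' @param path CSV (`.csv`) or TSV (anything else) file with a header row.
#' @param value_column Name of the numeric measurement column.
#' @param group_column Name of the group-label column.
#' @param groups Optional character vector of two labels selecting (and
#'   ordering) the groups.
#' @return A named list of two numeric vectors.
#' @export
load_grouped_table <- function(path, value_column, group_column,
                               groups = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE)
  for (col in c(value_column, group_column)) {
    if (!col %in% names(tab))
      stop("column '", col, "' not found in ", path)
  }
  raw <- trimws(tab[[value_column]])
  values <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(values) | !nzchar(raw))
  if (length(bad) > 0L)
    stop("non-numeric or missing value in row ", bad[1], " of ", path)
  labels <- trimws(tab[[group_column]])
  present <- unique(labels)
  if (is.null(groups)) {
    if (length(present) != 2L)
      stop("expected exactly 2 group labels, found ", length(present),
           "; use `groups` to select two")
    groups <- present
  } else {
    if (length(groups) != 2L) stop("`groups` must name exactly two labels")
    missing <- setdiff(groups, present)
    if (length(missing) > 0L)
      stop("group label(s) not in file: ", paste(missing, collapse = ", "))
  }
  out <- lapply(groups, function(gr) values[labels == gr])
  names(out) <- groups
  if (any(lengths(out) == 0L)) stop("empty group")
  out
}
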