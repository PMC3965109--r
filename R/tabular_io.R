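#' Read a tab-delimited matrix file
#'
#' Reads a matrix stored in the tab-delimited layout used for genotype and
#' expression-trait uploads: row 1 holds column identifiers (cell (1,1) is
#' empty or a label), column 1 holds row identifiers, remaining cells are
#' numeric values or symbols from a declared alphabet.
#'
#' @param path Path to a tab-delimited file. Both `\n` and `\r\n` line
#'   endings are accepted; files are assumed UTF-8.
#' @param missing_token String that marks a missing cell (default `"NA"`).
#' @param alphabet Optional character vector. When given, cells must be
#'   either `missing_token` or one of these symbols (genotype files); when
#'   `NULL` (default) cells parse as real numbers.
#' @return A `matrix_file` object: a list with `row_ids`, `col_ids` and
#'   `values` (a dense matrix, numeric or character, with `NA` for missing
#'   cells).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_matrix(matrix_file(c("p1", "p2"), c("s1", "s2"),
#'                          matrix(1:4, 2, 2)), tf)
#' read_matrix(tf)
#' @export
read_matrix <- function(path, missing_token = "NA", alphabet = NULL) {
  lines <- read_text_lines(path)
  if (length(lines) < 1L) {
    stop("format error in '", path, "': file is empty", call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  col_ids <- header[-1L]
  ncol_expected <- length(header)
  body <- fields[-1L]
  n_fields <- lengths(body)
  bad <- which(n_fields != ncol_expected)
  if (length(bad)) {
    stop("format error in '", path, "', line ", bad[1L] + 1L,
         ": expected ", ncol_expected, " fields, found ",
         n_fields[bad[1L]], call. = FALSE)
  }
  row_ids <- vapply(body, `[[`, character(1L), 1L)
  check_unique_ids(row_ids, "row id", path)
  check_unique_ids(col_ids, "column id", path)
  if (any(!nzchar(row_ids)) || any(!nzchar(col_ids))) {
    stop("validation error in '", path, "': empty identifier", call. = FALSE)
  }
  cells <- matrix(unlist(lapply(body, `[`, -1L), use.names = FALSE),
                  nrow = length(body), ncol = length(col_ids), byrow = TRUE)
  miss <- cells == missing_token
  if (is.null(alphabet)) {
    values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
    bad_cell <- which(is.na(values) & !miss, arr.ind = TRUE)
    if (nrow(bad_cell)) {
      i <- bad_cell[1L, 1L]; j <- bad_cell[1L, 2L]
      stop("format error in '", path, "', line ", i + 1L,
           ": cell (row '", row_ids[i], "', column '", col_ids[j],
           "') token '", cells[i, j], "' is not a number", call. = FALSE)
    }
    values[miss] <- NA_real_
  } else {
    bad_cell <- which(!(cells %in% alphabet) & !miss, arr.ind = TRUE)
    if (length(bad_cell) && nrow(bad_cell)) {
      i <- bad_cell[1L, 1L]; j <- bad_cell[1L, 2L]
      stop("format error in '", path, "', line ", i + 1L,
           ": cell (row '", row_ids[i], "', column '", col_ids[j],
           "') token '", cells[i, j], "' not in alphabet {",
           paste(alphabet, collapse = ","), "}", call. = FALSE)
    }
    values <- cells
    values[miss] <- NA_character_
  }
  dimnames(values) <- list(row_ids, col_ids)
  matrix_file(row_ids, col_ids, values)
}

#' Construct a matrix_file object
#'
#' @param row_ids,col_ids Character vectors of unique identifiers.
#' @param values Matrix with dimensions `length(row_ids)` x
#'   `length(col_ids)`; `NA` marks missing cells.
#' @return A `matrix_file` object.
#' @export
matrix_file <- function(row_ids, col_ids, values) {
  row_ids <- as.character(row_ids); col_ids <- as.character(col_ids)
  values <- as.matrix(values)
  if (nrow(values) != length(row_ids) || ncol(values) != length(col_ids)) {
    stop("validation error: matrix dimensions do not match id lists",
         call. = FALSE)
  }
  check_unique_ids(row_ids, "row id", "<in-memory>")
  check_unique_ids(col_ids, "column id", "<in-memory>")
  dimnames(values) <- list(row_ids, col_ids)
  structure(list(row_ids = row_ids, col_ids = col_ids, values = values),
            class = "matrix_file")
}

#' @export
print.matrix_file <- function(x, ...) {
  cat("matrix_file: ", length(x$row_ids), " rows x ", length(x$col_ids),
      " columns, ", sum(is.na(x$values)), " missing cell(s)\n", sep = "")
  invisible(x)
}

#' Write a matrix_file to disk
#'
#' Inverse of [read_matrix()]: tab-delimited, `\n` line endings, numeric
#' cells rendered with 15 significant digits so that read-write round trips
#' preserve values to at least 12 significant digits.
#'
#' @param x A `matrix_file` object.
#' @param path Output path.
#' @param missing_token Token written for `NA` cells (default `"NA"`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, missing_token = "NA") {
  stopifnot(inherits(x, "matrix_file"))
  vals <- x$values
  if (is.numeric(vals)) {
    cells <- array(formatC(vals, digits = 15, format = "g"), dim = dim(vals))
  } else {
    cells <- vals
  }
  cells[is.na(vals)] <- missing_token
  lines <- c(paste(c("id", x$col_ids), collapse = "\t"),
             paste(x$row_ids, apply(cells, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a TSV table with a mandatory header
#'
#' @param path Path to a tab-delimited file whose first row names the
#'   columns.
#' @param required Character vector of column names that must be present.
#' @return A data.frame of character columns.
#' @export
read_table_file <- function(path, required = character()) {
  lines <- read_text_lines(path)
  if (!length(lines)) {
    stop("format error in '", path, "': file is empty", call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  missing_cols <- setdiff(required, header)
  if (length(missing_cols)) {
    stop("format error in '", path, "': missing mandatory column(s) ",
         paste0("'", missing_cols, "'", collapse = ", "), call. = FALSE)
  }
  body <- fields[-1L]
  n_fields <- lengths(body)
  bad <- which(n_fields != length(header))
  if (length(bad)) {
    stop("format error in '", path, "', line ", bad[1L] + 1L,
         ": expected ", length(header), " fields, found ",
         n_fields[bad[1L]], call. = FALSE)
  }
  if (!length(body)) {
    out <- as.data.frame(matrix(character(), 0L, length(header)),
                         stringsAsFactors = FALSE)
    names(out) <- header
    return(out)
  }
  m <- matrix(unlist(body, use.names = FALSE), nrow = length(body),
              byrow = TRUE)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- header
  out
}

#' Write phenolog results to a TSV file
#'
#' Writes a table of phenolog overlap-test results. The input must already
#' be sorted by ascending p-value (the ordering every sweep in this package
#' produces); an unsorted input is a contract violation and raises an error
#' rather than being silently re-sorted.
#'
#' @param results A `phenolog_result` data.frame (from [phenolog_test()],
#'   [broad_sweep()] or a workflow), sorted by ascending `p`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  results <- as.data.frame(results)
  if (nrow(results) > 1L && is.unsorted(results$p)) {
    stop("precondition error: results must be sorted by ascending p",
         call. = FALSE)
  }
  cols <- c("term1_label", "term1_source", "term2_label", "term2_source",
            "n1", "n2", "k", "N", "p", "p_adjusted")
  for (col in setdiff(cols, names(results))) {
    results[[col]] <- if (col == "p_adjusted") NA_real_ else NA
  }
  fmt <- results[cols]
  fmt$p <- formatC(results$p, digits = 3, format = "e")
  fmt$p_adjusted <- ifelse(is.na(results$p_adjusted), "NA",
                           formatC(results$p_adjusted, digits = 3,
                                   format = "e"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("I/O error: cannot open '", path, "' for writing: ",
         conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(fmt)) {
    writeLines(do.call(paste, c(lapply(fmt, as.character), sep = "\t")), con)
  }
  invisible(path)
}

# -- internal helpers --------------------------------------------------------

# readLines with \r\n tolerance; always returns trimmed-of-\r lines
read_text_lines <- function(path) {
  if (!file.exists(path)) {
    stop("I/O error: file '", path, "' does not exist", call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sub("\r$", "", lines)
}

check_unique_ids <- function(ids, what, path) {
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("validation error in '", path, "': duplicated ", what, " '",
         dup[1L], "'", call. = FALSE)
  }
  invisible(TRUE)
}
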