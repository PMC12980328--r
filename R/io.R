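# Readers and writers. Expression matrices are TSV/CSV with features in rows
# (first column = feature id, header = sample ids); results are long-format
# pair-per-row TSV with "#"-prefixed provenance header lines. ".gz" suffixes
# are honoured transparently on both read and write.

open_read <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

open_write <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

sep_for <- function(path) {
  if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
}

#' Read an expression matrix
#'
#' Expects UTF-8 TSV or CSV (by extension; `.gz` supported): first row is a
#' header of sample ids, first column holds feature ids. Empty cells or `NA`
#' are treated as missing. Row and column order are preserved.
#'
#' @param path Input file.
#' @return Numeric matrix, features in rows (`NA` marks missing values).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("read_expression: no such file: ", path)
  con <- open_read(path)
  on.exit(close(con))
  df <- utils::read.table(con, sep = sep_for(path), header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "#", quote = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("read_expression: need a feature id column plus samples")
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("read_expression: duplicate feature id: ", dup[1L])
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("read_expression: duplicate sample id: ",
         samples[duplicated(samples)][1L])
  cells <- as.matrix(df[, -1L, drop = FALSE])
  blank <- is.na(cells) | cells == "" | cells == "NA"
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !blank, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("read_expression: non-numeric value '", cells[bad[1L, , drop = FALSE]],
         "' at feature '", ids[bad[1L, 1L]], "', sample '",
         samples[bad[1L, 2L]], "'")
  num[blank] <- NA
  dimnames(num) <- list(ids, samples)
  num
}

#' Read a sample metadata table
#'
#' TSV/CSV whose first column holds sample ids; every other column becomes a
#' metadata variable, typed numerical iff all its non-missing values parse as
#' numbers, else categorical. `type_overrides` (a named vector like
#' `c(cohort = "categorical")`) wins over the inferred type.
#'
#' @param path Input file.
#' @param type_overrides Optional named character vector of
#'   `"numerical"`/`"categorical"` per column.
#' @return A `ccc_metadata`: `sample_id` (character) and `variables` (named
#'   list with `kind` and `values` per variable).
#' @export
read_metadata <- function(path, type_overrides = NULL) {
  if (!file.exists(path)) stop("read_metadata: no such file: ", path)
  con <- open_read(path)
  on.exit(close(con))
  df <- utils::read.table(con, sep = sep_for(path), header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "#", quote = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("read_metadata: need a sample id column plus variables")
  sample_id <- df[[1L]]
  if (anyDuplicated(sample_id))
    stop("read_metadata: duplicate sample id: ",
         sample_id[duplicated(sample_id)][1L])
  vars <- list()
  for (v in colnames(df)[-1L]) {
    raw <- df[[v]]
    raw[raw == "" | raw == "NA"] <- NA
    num <- suppressWarnings(as.numeric(raw))
    inferred <- if (all(is.na(num) == is.na(raw))) "numerical" else "categorical"
    kind <- if (!is.null(type_overrides) && v %in% names(type_overrides)) {
      match.arg(type_overrides[[v]], c("numerical", "categorical"))
    } else inferred
    vars[[v]] <- list(kind = kind,
                      values = if (kind == "numerical") num else raw)
  }
  structure(list(sample_id = sample_id, variables = vars),
            class = "ccc_metadata")
}

as_metadata_table <- function(metadata) {
  if (inherits(metadata, "ccc_metadata")) return(metadata)
  if (is.data.frame(metadata)) {
    sample_id <- as.character(metadata[[1L]])
    vars <- list()
    for (v in colnames(metadata)[-1L]) {
      col <- metadata[[v]]
      kind <- if (is.numeric(col)) "numerical" else "categorical"
      vars[[v]] <- list(kind = kind,
                        values = if (kind == "numerical") as.numeric(col)
                                 else as.character(col))
    }
    return(structure(list(sample_id = sample_id, variables = vars),
                     class = "ccc_metadata"))
  }
  stop("metadata must be a ccc_metadata or a data frame")
}

fmt_cell <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    out <- sprintf("%.9g", x)          # 9 significant digits
    out[is.na(x)] <- "NA"
    out
  } else {
    out <- as.character(x)
    out[is.na(x)] <- "NA"
    out
  }
}

#' Write a results table with a provenance header
#'
#' Writes any pair/tier/category/metadata table as TSV: "#"-prefixed header
#' lines carrying the effective configuration, then a column header and the
#' rows. Floats are written at 9 significant digits; missing values as `NA`;
#' `.gz` compresses. [read_results()] reproduces the values exactly at the
#' written precision.
#'
#' @param table A data frame.
#' @param path Output file.
#' @param config Optional named list echoed into `#key=value` header lines.
#' @param timestamp Include a `#written=` line? Disable for byte-reproducible
#'   output.
#' @export
write_results <- function(table, path, config = NULL, timestamp = FALSE) {
  con <- tryCatch(open_write(path),
                  error = function(e) stop("write_results: cannot open ", path))
  on.exit(close(con))
  hdr <- c(sprintf("#cccr_version=%s",
                   as.character(utils::packageVersion("cccr"))))
  if (timestamp)
    hdr <- c(hdr, sprintf("#written=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  for (k in names(config)) {
    hdr <- c(hdr, sprintf("#%s=%s", k, paste(fmt_cell(config[[k]]),
                                             collapse = ",")))
  }
  writeLines(hdr, con)
  cells <- vapply(table, fmt_cell, character(nrow(table)))
  if (nrow(table) == 1L) cells <- matrix(cells, nrow = 1L)
  writeLines(paste(colnames(table), collapse = "\t"), con)
  if (nrow(table) > 0L)
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Input file.
#' @return A data frame; columns are numeric where every value parses,
#'   logical for TRUE/FALSE columns, character otherwise. The `#` header is
#'   returned in attribute `"header"`.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("read_results: no such file: ", path)
  lines <- readLines(con <- open_read(path)); close(con)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 1L) stop("read_results: no column header in ", path)
  cols <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  if (length(body) == 1L) {
    df <- as.data.frame(matrix(character(0), ncol = length(cols),
                               dimnames = list(NULL, cols)),
                        stringsAsFactors = FALSE)
  } else {
    mat <- do.call(rbind, strsplit(body[-1L], "\t", fixed = TRUE))
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    colnames(df) <- cols
  }
  for (v in colnames(df)) {
    col <- df[[v]]
    col[col == "NA"] <- NA
    if (all(is.na(col) | col %in% c("TRUE", "FALSE"))) {
      df[[v]] <- as.logical(col)
    } else {
      num <- suppressWarnings(as.numeric(col))
      if (all(is.na(num) == is.na(col))) df[[v]] <- num else df[[v]] <- col
    }
  }
  attr(df, "header") <- hdr
  df
}

#' Write an expression matrix or metadata table as TSV
#'
#' Companion writers for the `simulate` pipeline outputs, in the formats
#' [read_expression()] and [read_metadata()] read back.
#'
#' @param mat Numeric matrix, features in rows.
#' @param path Output file (`.gz` supported).
#' @param id_column Name of the first (feature id) column.
#' @export
write_expression <- function(mat, path, id_column = "feature_id") {
  con <- open_write(path)
  on.exit(close(con))
  writeLines(paste(c(id_column, colnames(mat)), collapse = "\t"), con)
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], fmt_cell(mat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}

#' @rdname write_expression
#' @param df Data frame (first column sample ids) to write.
#' @export
write_table_tsv <- function(df, path) {
  con <- open_write(path)
  on.exit(close(con))
  cells <- vapply(df, fmt_cell, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df) > 0L)
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
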