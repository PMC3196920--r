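# Readers and writers for the plain-text formats the pipeline consumes:
# tab-delimited expression/flag matrices (plain or GEO Series-Matrix-like
# dialect), two-column group maps, and gene lists.

split_tsv_line <- function(line) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  # Series-Matrix tables quote identifiers; strip surrounding double quotes.
  sub('^"(.*)"$', "\\1", fields)
}

read_table_lines <- function(path, dialect) {
  lines <- readLines(path, warn = FALSE)
  if (dialect == "series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1L || length(end) != 1L || end <= begin) {
      stop("series_matrix dialect: table fences not found in ", path,
           call. = FALSE)
    }
    lines <- lines[(begin + 1L):(end - 1L)]
  }
  lines[nzchar(lines)]
}

#' Read an expression matrix from a delimited text file
#'
#' Supports two dialects: `plain_tsv` (header row of sample ids, first column
#' row ids) and `series_matrix` (identical content between
#' `!series_matrix_table_begin` / `!series_matrix_table_end` fences, all other
#' lines ignored, fields possibly double-quoted). Group labels are attached
#' from a sidecar two-column mapping (see [read_group_map()]) or given
#' directly.
#'
#' @param path Path to the matrix file.
#' @param dialect `"plain_tsv"` (default) or `"series_matrix"`.
#' @param groups Named character vector mapping sample ids to group labels,
#'   or the path of a sidecar group-map file.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path,
                                  dialect = c("plain_tsv", "series_matrix"),
                                  groups) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- read_table_lines(path, dialect)
  if (length(lines) < 2L) stop("no data rows in ", path, call. = FALSE)
  header <- split_tsv_line(lines[1L])
  sample_ids <- header[-1L]
  rows <- lapply(lines[-1L], split_tsv_line)
  row_ids <- vapply(rows, `[[`, character(1L), 1L)
  if (anyDuplicated(row_ids)) {
    stop("duplicate row id: ", row_ids[duplicated(row_ids)][1L],
         call. = FALSE)
  }
  values <- matrix(NA_real_, nrow = length(rows), ncol = length(sample_ids),
                   dimnames = list(row_ids, sample_ids))
  for (i in seq_along(rows)) {
    cells <- rows[[i]][-1L]
    if (length(cells) != length(sample_ids)) {
      stop(sprintf("row '%s' has %d values, expected %d", row_ids[i],
                   length(cells), length(sample_ids)), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(cells))
    if (anyNA(num)) {
      j <- which(is.na(num))[1L]
      stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                   cells[j], row_ids[i], sample_ids[j]), call. = FALSE)
    }
    values[i, ] <- num
  }
  if (is.character(groups) && length(groups) == 1L && is.null(names(groups)) &&
      file.exists(groups)) {
    groups <- read_group_map(groups)
  }
  expression_matrix(values, groups)
}

#' Write an expression matrix as plain TSV
#'
#' Values are written with full (17 significant digit) precision so that a
#' write/read round trip reproduces them bit-identically.
#'
#' @param expr An [expression_matrix()].
#' @param path Output file path.
#' @param group_path Optional path for the sidecar group map.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path, group_path = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(expr$values)), collapse = "\t"), con)
  body <- apply(expr$values, 1L, function(v) {
    paste(sprintf("%.17g", v), collapse = "\t")
  })
  writeLines(paste(rownames(expr$values), body, sep = "\t"), con)
  if (!is.null(group_path)) write_group_map(expr$groups, group_path)
  invisible(path)
}

#' Read a sample -> group mapping
#'
#' Two tab- or comma-separated columns: sample id, group label. A header line
#' `sample<sep>group` is allowed and skipped.
#'
#' @param path Path to the mapping file.
#' @return Named character vector (names are sample ids).
#' @export
read_group_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty group map: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed group-map line: ", lines[bad][1L], call. = FALSE)
  }
  ids <- vapply(parts, `[[`, character(1L), 1L)
  grp <- vapply(parts, `[[`, character(1L), 2L)
  if (identical(tolower(ids[1L]), "sample")) {
    ids <- ids[-1L]
    grp <- grp[-1L]
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sample id in group map: ", ids[duplicated(ids)][1L],
         call. = FALSE)
  }
  stats::setNames(grp, ids)
}

write_group_map <- function(groups, path) {
  writeLines(c("sample\tgroup", paste(names(groups), groups, sep = "\t")),
             path)
  invisible(path)
}

#' Read a detection-call (flag) matrix
#'
#' Same layout as the plain TSV expression matrix, but cells are detection
#' calls (`present`/`marginal`/`absent`, or `P`/`M`/`A`).
#'
#' @inheritParams read_expression_table
#' @return A [flag_matrix()].
#' @export
read_flag_table <- function(path, groups) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- read_table_lines(path, "plain_tsv")
  header <- split_tsv_line(lines[1L])
  sample_ids <- header[-1L]
  rows <- lapply(lines[-1L], split_tsv_line)
  row_ids <- vapply(rows, `[[`, character(1L), 1L)
  calls <- do.call(rbind, lapply(rows, `[`, -1L))
  dimnames(calls) <- list(row_ids, sample_ids)
  if (is.character(groups) && length(groups) == 1L && is.null(names(groups)) &&
      file.exists(groups)) {
    groups <- read_group_map(groups)
  }
  flag_matrix(calls, groups)
}

#' Write a flag matrix as plain TSV
#'
#' @param flags A [flag_matrix()].
#' @param path Output file path.
#' @param group_path Optional path for the sidecar group map.
#' @return `path`, invisibly.
#' @export
write_flag_table <- function(flags, path, group_path = NULL) {
  stopifnot(inherits(flags, "flag_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(flags$calls)), collapse = "\t"), con)
  body <- apply(flags$calls, 1L, paste, collapse = "\t")
  writeLines(paste(rownames(flags$calls), body, sep = "\t"), con)
  if (!is.null(group_path)) write_group_map(flags$groups, group_path)
  invisible(path)
}

#' Read a gene list
#'
#' One gene symbol per line; blank lines and `#` comments are ignored.
#' Duplicate symbols are removed (first occurrence kept) with a warning, so
#' order is preserved.
#'
#' @param path Path to the list file.
#' @param name List name; defaults to the file name without extension.
#' @return A `gene_list`: list with `name` and character vector `symbols`.
#' @export
read_gene_list <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty gene list: ", path, call. = FALSE)
  if (anyDuplicated(lines)) {
    dups <- unique(lines[duplicated(lines)])
    warning("duplicate symbols removed from gene list: ",
            paste(dups, collapse = ", "), call. = FALSE)
    lines <- lines[!duplicated(lines)]
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_list(name, lines)
}

#' Construct a gene list
#'
#' @param name List name.
#' @param symbols Character vector of unique gene symbols.
#' @return A `gene_list` object.
#' @export
gene_list <- function(name, symbols) {
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols)) {
    stop("gene list symbols must be unique", call. = FALSE)
  }
  structure(list(name = name, symbols = symbols), class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("gene_list '%s': %d symbols\n", x$name, length(x$symbols)))
  invisible(x)
}

#' Write a gene list, one symbol per line
#'
#' @param x A `gene_list` or character vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(x, path) {
  writeLines(as_gene_symbols(x), path)
  invisible(path)
}

# Accept either a gene_list or a bare character vector of symbols.
as_gene_symbols <- function(x) {
  if (inherits(x, "gene_list")) x$symbols else as.character(x)
}
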