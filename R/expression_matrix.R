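# Core containers: log2 expression matrices and MAS5-style detection-call
# (flag) matrices, each carrying a sample -> group mapping.

#' Construct an expression matrix
#'
#' An `expression_matrix` holds log2-scale signal values (rows are probe sets
#' or gene symbols, columns are samples) together with a group label for every
#' sample (e.g. `"patient"`, `"cell_line"`, `"muscle"`). Values are assumed to
#' be already normalised (e.g. RMA) and on the log2 scale.
#'
#' @param values Numeric matrix with unique, non-empty rownames and colnames;
#'   all values must be finite.
#' @param groups Named character vector mapping every sample id (column of
#'   `values`) to a group label.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `groups`.
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  rid <- rownames(values)
  sid <- colnames(values)
  if (is.null(rid) || anyNA(rid) || any(rid == "")) {
    stop("`values` must have non-empty rownames (row ids)", call. = FALSE)
  }
  if (is.null(sid) || anyNA(sid) || any(sid == "")) {
    stop("`values` must have non-empty colnames (sample ids)", call. = FALSE)
  }
  if (anyDuplicated(rid)) {
    stop("duplicate row id: ", rid[duplicated(rid)][1L], call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample id: ", sid[duplicated(sid)][1L], call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at row '%s', sample '%s'",
                 rid[bad[1L]], sid[bad[2L]]), call. = FALSE)
  }
  groups <- vapply(groups, as.character, character(1L))
  missing <- setdiff(sid, names(groups))
  if (length(missing)) {
    stop("samples without a group label: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(values = values, groups = groups[sid]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d rows x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Sample ids belonging to a group
#'
#' @param x An `expression_matrix` or `flag_matrix`.
#' @param group Group label.
#' @return Character vector of sample ids; error if the group is empty.
#' @export
samples_in_group <- function(x, group) {
  ids <- names(x$groups)[x$groups == group]
  if (!length(ids)) stop("no samples in group '", group, "'", call. = FALSE)
  ids
}

#' Construct a detection-call (flag) matrix
#'
#' Holds MAS5-style detection calls, one of `"present"`, `"marginal"` or
#' `"absent"` per probe and sample, plus a sample -> group mapping. The
#' single-letter codes `P`/`M`/`A` are accepted and normalised.
#'
#' @param calls Character matrix with rownames (probe ids) and colnames
#'   (sample ids).
#' @param groups Named character vector mapping sample ids to group labels.
#' @return An object of class `flag_matrix`.
#' @export
flag_matrix <- function(calls, groups) {
  if (!is.matrix(calls) || !is.character(calls)) {
    stop("`calls` must be a character matrix", call. = FALSE)
  }
  norm <- normalize_calls(calls)
  groups <- vapply(groups, as.character, character(1L))
  sid <- colnames(calls)
  if (is.null(sid) || is.null(rownames(calls))) {
    stop("`calls` must have rownames and colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(calls))) {
    stop("duplicate probe id in flag matrix", call. = FALSE)
  }
  missing <- setdiff(sid, names(groups))
  if (length(missing)) {
    stop("samples without a group label: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(calls = norm, groups = groups[sid]), class = "flag_matrix")
}

flag_levels <- c("present", "marginal", "absent")

normalize_calls <- function(calls) {
  map <- c(P = "present", M = "marginal", A = "absent",
           present = "present", marginal = "marginal", absent = "absent")
  out <- map[calls]
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop("invalid detection call '", calls[bad],
         "' (expected present/marginal/absent or P/M/A)", call. = FALSE)
  }
  dim(out) <- dim(calls)
  dimnames(out) <- dimnames(calls)
  out
}

#' @export
print.flag_matrix <- function(x, ...) {
  cat(sprintf("flag_matrix: %d probes x %d samples\n",
              nrow(x$calls), ncol(x$calls)))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}
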