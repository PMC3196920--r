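# Probe-set -> gene collapse with unique-probe priority.

#' Construct a probe -> gene annotation map
#'
#' Each row annotates one probe set with one gene symbol; probe sets matching
#' several genes appear on several rows. A probe set is *unique* when it is
#' annotated with exactly one gene; unique probe sets take priority when a
#' representative probe is chosen for a gene.
#'
#' @param probe Character vector of probe set ids.
#' @param gene Character vector of gene symbols, same length.
#' @return A `probe_gene_map`: data frame with columns `probe`, `gene`,
#'   `unique` (logical, per probe).
#' @export
probe_gene_map <- function(probe, gene) {
  probe <- as.character(probe)
  gene <- as.character(gene)
  stopifnot(length(probe) == length(gene))
  if (!length(probe)) stop("empty probe-gene map", call. = FALSE)
  df <- unique(data.frame(probe = probe, gene = gene,
                          stringsAsFactors = FALSE))
  if (anyNA(df$probe) || anyNA(df$gene) || any(df$gene == "")) {
    stop("probe-gene map contains missing probe or gene ids", call. = FALSE)
  }
  n_genes <- table(df$probe)
  df$unique <- as.vector(n_genes[df$probe]) == 1L
  class(df) <- c("probe_gene_map", "data.frame")
  df
}

#' Read a probe -> gene map from a two-column delimited file
#'
#' Columns: probe id, gene symbol (tab- or comma-separated; header allowed).
#'
#' @param path Path to the mapping file.
#' @return A [probe_gene_map()].
#' @export
read_probe_gene_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  probe <- vapply(parts, `[[`, character(1L), 1L)
  gene <- vapply(parts, `[[`, character(1L), 2L)
  if (identical(tolower(probe[1L]), "probe")) {
    probe <- probe[-1L]
    gene <- gene[-1L]
  }
  probe_gene_map(probe, gene)
}

#' Collapse probe sets to genes
#'
#' Chooses a single representative probe set per gene symbol. Uniquely
#' annotated probe sets take strict priority: whenever a gene matches at
#' least one unique probe set, only unique probe sets are eligible for it.
#' Within the eligible pool the probe set with the highest mean expression
#' across all samples is chosen; ties break lexicographically by probe id.
#' Probe sets absent from the map (and map entries absent from the matrix)
#' are dropped, with a message giving the count.
#'
#' @param expr An [expression_matrix()] whose rows are probe set ids.
#' @param map A [probe_gene_map()].
#' @return An [expression_matrix()] with one row per gene symbol. The chosen
#'   representative probe ids are attached as attribute
#'   `representative_probe` (named by gene).
#' @export
collapse_probes_to_genes <- function(expr, map) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(map, "probe_gene_map"))
  present <- map$probe %in% rownames(expr$values)
  n_unmapped <- length(setdiff(rownames(expr$values), map$probe))
  if (!any(present)) {
    stop("no probe ids shared between expression matrix and probe-gene map",
         call. = FALSE)
  }
  if (n_unmapped > 0L) {
    message(n_unmapped, " probe set(s) without annotation dropped")
  }
  map <- map[present, , drop = FALSE]
  probe_mean <- rowMeans(expr$values)[map$probe]
  chosen <- vapply(split(seq_len(nrow(map)), map$gene), function(idx) {
    pool <- idx
    if (any(map$unique[idx])) pool <- idx[map$unique[idx]]
    probes <- map$probe[pool]
    means <- probe_mean[pool]
    best <- probes[means == max(means)]
    sort(best)[1L]
  }, character(1L))
  values <- expr$values[chosen, , drop = FALSE]
  rownames(values) <- names(chosen)
  out <- expression_matrix(values, expr$groups)
  attr(out, "representative_probe") <- chosen
  out
}
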