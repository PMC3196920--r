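# Cell-type signature extraction from detection calls, gene-list enrichment
# among differential calls, and the two-comparison partition of inflammatory
# genes into stromal-derived and tumour-cell-derived lists.

#' Signature extraction rule
#'
#' A probe belongs to the signature of `target_group` when it is called
#' present in at least `target_present_fraction` of the target samples
#' (default 1: present in all of them) and, for every background group
#' separately, called absent in at least `background_absent_fraction` of that
#' group's samples (default 0.5). Marginal calls count as neither present nor
#' absent, the conservative reading in both directions.
#'
#' @param target_group Group label whose signature is extracted.
#' @param background_groups Character vector of background group labels.
#' @param target_present_fraction Fraction in \[0, 1\] (default 1).
#' @param background_absent_fraction Fraction in \[0, 1\] (default 0.5).
#' @return A list of class `signature_rule`.
#' @export
signature_rule <- function(target_group, background_groups,
                           target_present_fraction = 1,
                           background_absent_fraction = 0.5) {
  stopifnot(length(background_groups) >= 1L,
            target_present_fraction >= 0, target_present_fraction <= 1,
            background_absent_fraction >= 0,
            background_absent_fraction <= 1)
  structure(list(target_group = target_group,
                 background_groups = as.character(background_groups),
                 target_present_fraction = target_present_fraction,
                 background_absent_fraction = background_absent_fraction),
            class = "signature_rule")
}

#' Extract a cell-type-specific probe signature from detection calls
#'
#' @param flags A [flag_matrix()].
#' @param rule A [signature_rule()]; all its groups must be present in
#'   `flags` and non-empty.
#' @return Character vector of probe ids satisfying the rule.
#' @export
extract_signature <- function(flags, rule) {
  stopifnot(inherits(flags, "flag_matrix"),
            inherits(rule, "signature_rule"))
  target_ids <- samples_in_group(flags, rule$target_group)
  present_frac <- rowMeans(
    flags$calls[, target_ids, drop = FALSE] == "present")
  keep <- present_frac >= rule$target_present_fraction
  for (bg in rule$background_groups) {
    bg_ids <- samples_in_group(flags, bg)
    absent_frac <- rowMeans(
      flags$calls[, bg_ids, drop = FALSE] == "absent")
    keep <- keep & absent_frac >= rule$background_absent_fraction
  }
  rownames(flags$calls)[keep]
}

#' Map a probe-level signature to gene symbols
#'
#' Every gene that any selected probe matches (per the annotation map) is
#' included, so multi-gene probes contribute all their genes.
#'
#' @param probes Character vector of probe ids.
#' @param map A [probe_gene_map()].
#' @return Character vector of unique gene symbols, in first-seen order.
#' @export
signature_to_genes <- function(probes, map) {
  stopifnot(inherits(map, "probe_gene_map"))
  unique(map$gene[map$probe %in% probes])
}

#' Gene-list enrichment among differential calls
#'
#' Tests whether a gene list is over-represented among the up calls (and,
#' separately, the down calls) of a differential-expression result. The
#' universe is the full set of tested genes; list genes outside the universe
#' are dropped. Expected counts are `|list in universe| * (calls in
#' universe / |universe|)`. P-values come from Fisher's exact test on the
#' 2x2 table (in list vs not) x (called vs not), one-sided toward
#' over-representation; the complementary deficit p-values (one-sided toward
#' under-representation) are also reported, since a list can show both an
#' excess of up calls and a deficit of down calls.
#'
#' @param calls A `diffexp_result` (or data frame with `gene` and `call`).
#' @param list A `gene_list` or character vector of symbols.
#' @param list_name Name used in the output (defaults to the list's name).
#' @return One-row data frame of class `enrichment_result`: `list_name`,
#'   `n_list_in_universe`, `n_universe`, `observed_up`, `expected_up`,
#'   `observed_down`, `expected_down`, `p_up`, `p_down`, `p_up_deficit`,
#'   `p_down_deficit`.
#' @export
enrichment_test <- function(calls, list, list_name = NULL) {
  symbols <- as_gene_symbols(list)
  if (is.null(list_name)) {
    list_name <- if (inherits(list, "gene_list")) list$name else "gene_list"
  }
  universe <- calls$gene
  in_list <- universe %in% symbols
  k <- sum(in_list)
  if (k == 0L) {
    stop("no gene of list '", list_name, "' is in the tested universe",
         call. = FALSE)
  }
  dropped <- length(setdiff(symbols, universe))
  if (dropped > 0L) {
    warning(dropped, " gene(s) of list '", list_name,
            "' absent from the universe, dropped", call. = FALSE)
  }
  n <- length(universe)
  one_dir <- function(direction) {
    called <- calls$call == direction
    observed <- sum(in_list & called)
    expected <- k * sum(called) / n
    tab <- matrix(c(observed, sum(called) - observed,
                    k - observed, n - sum(called) - (k - observed)),
                  nrow = 2L)
    list(observed = observed, expected = expected,
         p_excess = stats::fisher.test(tab, alternative = "greater")$p.value,
         p_deficit = stats::fisher.test(tab, alternative = "less")$p.value)
  }
  up <- one_dir("up")
  down <- one_dir("down")
  out <- data.frame(
    list_name = list_name, n_list_in_universe = k, n_universe = n,
    observed_up = up$observed, expected_up = up$expected,
    observed_down = down$observed, expected_down = down$expected,
    p_up = up$p_excess, p_down = down$p_excess,
    p_up_deficit = up$p_deficit, p_down_deficit = down$p_deficit,
    stringsAsFactors = FALSE
  )
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Partition a gene list into stromal-derived and tumour-cell-derived genes
#'
#' Given differential calls from two comparisons sharing the tumour group
#' (tumours vs cell lines and tumours vs normal tissue), list genes called
#' up in *both* comparisons are attributed to nonmalignant stromal or
#' infiltrating immune cells (present in tumours in vivo but not intrinsic
#' to the malignant cells), while genes up versus normal tissue but *not*
#' up versus cell lines are attributed to the malignant cells themselves.
#' List genes missing from either universe are excluded with a warning.
#'
#' @param calls_vs_cell_lines,calls_vs_muscle `diffexp_result` objects for
#'   the two comparisons.
#' @param list A `gene_list` or character vector.
#' @return A list of class `partition_result` with `gene_list` elements
#'   `stromal_derived` and `tumour_derived` (disjoint by construction).
#' @export
partition_gene_lists <- function(calls_vs_cell_lines, calls_vs_muscle,
                                 list) {
  symbols <- as_gene_symbols(list)
  missing <- setdiff(symbols,
                     intersect(calls_vs_cell_lines$gene,
                               calls_vs_muscle$gene))
  if (length(missing)) {
    warning(length(missing),
            " list gene(s) absent from a comparison universe, excluded: ",
            paste(utils::head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ..." else "", call. = FALSE)
    symbols <- setdiff(symbols, missing)
  }
  up_cl <- calls_vs_cell_lines$gene[calls_vs_cell_lines$call == "up"]
  up_mu <- calls_vs_muscle$gene[calls_vs_muscle$call == "up"]
  stromal <- symbols[symbols %in% up_mu & symbols %in% up_cl]
  tumour <- symbols[symbols %in% up_mu & !(symbols %in% up_cl)]
  structure(list(stromal_derived = gene_list("stromal_derived", stromal),
                 tumour_derived = gene_list("tumour_derived", tumour)),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("partition: %d stromal-derived, %d tumour-derived genes\n",
              length(x$stromal_derived$symbols),
              length(x$tumour_derived$symbols)))
  invisible(x)
}

#' Write a partition result as two gene-list files
#'
#' @param x A `partition_result`.
#' @param prefix Output path prefix; writes `<prefix>.stromal.txt` and
#'   `<prefix>.tumour.txt`.
#' @return The two paths, invisibly.
#' @export
write_partition <- function(x, prefix) {
  paths <- c(paste0(prefix, ".stromal.txt"), paste0(prefix, ".tumour.txt"))
  write_gene_list(x$stromal_derived, paths[1L])
  write_gene_list(x$tumour_derived, paths[2L])
  invisible(paths)
}
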