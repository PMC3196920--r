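# Two-group differential expression: t statistics, fold changes,
# housekeeping-calibrated thresholds and up/down/unchanged calls.

#' Housekeeping genes used for fold-change calibration
#'
#' Fourteen ribosomal-protein and other constitutively expressed genes whose
#' observed fold changes between the compared groups set the minimum fold
#' change a differential call must strictly exceed.
#'
#' @return Character vector of 14 gene symbols.
#' @export
default_housekeeping_genes <- function() {
  c("RPS13", "RPS20", "RPL30", "RPL13A", "RPL9", "SRP14", "RPL24",
    "RPL22", "RPS29", "RPS16", "RPL4", "RPL6", "OAZ1", "RPS12")
}

#' Differential-expression configuration
#'
#' @param q_threshold Q-value cutoff for a differential call (default 0.01,
#'   i.e. 1% FDR).
#' @param housekeeping_genes Gene list (or character vector) used to derive
#'   the fold-change threshold; defaults to [default_housekeeping_genes()].
#' @param t_variant `"pooled"` (Student, equal variances; default) or
#'   `"welch"`.
#' @param fc_threshold_override Optional positive number; when given, the
#'   housekeeping calibration is skipped and this fold-change threshold is
#'   used directly.
#' @return A list of class `diffexp_config`.
#' @export
diffexp_config <- function(q_threshold = 0.01,
                           housekeeping_genes = default_housekeeping_genes(),
                           t_variant = c("pooled", "welch"),
                           fc_threshold_override = NULL) {
  t_variant <- match.arg(t_variant)
  stopifnot(is.numeric(q_threshold), q_threshold > 0, q_threshold < 1)
  hk <- as_gene_symbols(housekeeping_genes)
  if (!length(hk) && is.null(fc_threshold_override)) {
    stop("housekeeping list empty and no fc_threshold_override given",
         call. = FALSE)
  }
  if (!is.null(fc_threshold_override)) {
    stopifnot(is.numeric(fc_threshold_override), fc_threshold_override > 0)
  }
  structure(list(q_threshold = q_threshold, housekeeping_genes = hk,
                 t_variant = t_variant,
                 fc_threshold_override = fc_threshold_override),
            class = "diffexp_config")
}

#' Two-sample two-sided t test
#'
#' Pooled-variance (Student) or Welch t statistic with a two-sided p-value.
#' When both groups have zero variance and equal means the statistic is 0 and
#' p = 1 by convention; zero variance with unequal means gives p = 0.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param variant `"pooled"` or `"welch"`.
#' @return List with `t_stat`, `p_value`, `df`.
#' @export
two_group_t <- function(values_a, values_b,
                        variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  r <- row_two_group_t(rbind(a = values_a), rbind(b = values_b), variant)
  list(t_stat = unname(r$t_stat), p_value = unname(r$p_value),
       df = unname(r$df))
}

# Vectorised per-row two-group t over aligned matrices (rows = genes).
row_two_group_t <- function(va, vb, variant) {
  n1 <- ncol(va)
  n2 <- ncol(vb)
  m1 <- rowMeans(va)
  m2 <- rowMeans(vb)
  v1 <- rowSums((va - m1)^2) / (n1 - 1L)
  v2 <- rowSums((vb - m2)^2) / (n2 - 1L)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2L, length(m1))
  } else {
    se2 <- v1 / n1 + v2 / n2
    se <- sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  diff <- m1 - m2
  t_stat <- ifelse(se == 0, ifelse(diff == 0, 0, sign(diff) * Inf),
                   diff / se)
  p <- ifelse(is.finite(t_stat),
              2 * stats::pt(-abs(t_stat), df), 0)
  p[t_stat == 0] <- 1
  list(t_stat = t_stat, p_value = p, df = df,
       mean_a = m1, mean_b = m2)
}

#' Convert a log2 ratio to fold change and direction
#'
#' @param log_ratio Finite numeric vector of log2 expression ratios.
#' @return Data frame with `fold_change` (= 2^|log_ratio|, linear scale,
#'   always >= 1) and `direction` (`"up"`, `"down"`, or `"none"` at exactly
#'   zero).
#' @export
log_ratio_to_fc <- function(log_ratio) {
  if (!all(is.finite(log_ratio))) {
    stop("log_ratio must be finite", call. = FALSE)
  }
  data.frame(
    fold_change = 2^abs(log_ratio),
    direction = ifelse(log_ratio > 0, "up",
                       ifelse(log_ratio < 0, "down", "none")),
    stringsAsFactors = FALSE
  )
}

#' Housekeeping-calibrated fold-change threshold
#'
#' Computes, for each housekeeping gene found in the matrix, the linear fold
#' change between the two group means, and returns the maximum: the lowest
#' threshold not exceeded by any housekeeping gene. Differential calls must
#' strictly exceed this threshold.
#'
#' @param expr A gene-level [expression_matrix()].
#' @param group_a,group_b Group labels to compare.
#' @param housekeeping Gene list or character vector of housekeeping symbols.
#' @return The fold-change threshold (single number >= 1), with attribute
#'   `genes_used`.
#' @export
housekeeping_threshold <- function(expr, group_a, group_b, housekeeping) {
  hk <- as_gene_symbols(housekeeping)
  found <- intersect(hk, rownames(expr$values))
  if (!length(found)) {
    stop("no housekeeping gene found in matrix; sought: ",
         paste(hk, collapse = ", "), call. = FALSE)
  }
  if (length(found) < length(hk)) {
    warning("housekeeping gene(s) not in matrix, skipped: ",
            paste(setdiff(hk, found), collapse = ", "), call. = FALSE)
  }
  a <- expr$values[found, samples_in_group(expr, group_a), drop = FALSE]
  b <- expr$values[found, samples_in_group(expr, group_b), drop = FALSE]
  thr <- max(2^abs(rowMeans(a) - rowMeans(b)))
  attr(thr, "genes_used") <- found
  thr
}

#' Per-gene two-group differential expression
#'
#' For every row of the matrix: group means, log2 ratio (mean of group A
#' minus mean of group B), linear fold change, t statistic and two-sided
#' p-value, Storey q-value, and an `up`/`down`/`unchanged` call against the
#' q-value threshold and the (housekeeping-calibrated) fold-change threshold.
#'
#' @param expr A gene-level [expression_matrix()].
#' @param group_a,group_b Group labels to compare (log ratios are A minus B).
#' @param config A [diffexp_config()].
#' @param fc_threshold Optional precomputed fold-change threshold; when NULL
#'   it is derived with [housekeeping_threshold()] (or taken from the
#'   config's override).
#' @return A `diffexp_result`: data frame with columns `gene`, `mean_a`,
#'   `mean_b`, `log_ratio`, `fold_change`, `direction`, `t_stat`, `p_value`,
#'   `q_value`, `call`; the threshold used is attached as attribute
#'   `fc_threshold`.
#' @export
diff_expression <- function(expr, group_a, group_b,
                            config = diffexp_config(),
                            fc_threshold = NULL) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(config, "diffexp_config"))
  ids_a <- samples_in_group(expr, group_a)
  ids_b <- samples_in_group(expr, group_b)
  if (length(ids_a) < 2L || length(ids_b) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  if (is.null(fc_threshold)) {
    fc_threshold <- if (!is.null(config$fc_threshold_override)) {
      config$fc_threshold_override
    } else {
      housekeeping_threshold(expr, group_a, group_b,
                             config$housekeeping_genes)
    }
  }
  va <- expr$values[, ids_a, drop = FALSE]
  vb <- expr$values[, ids_b, drop = FALSE]
  tt <- row_two_group_t(va, vb, config$t_variant)
  log_ratio <- tt$mean_a - tt$mean_b
  fc <- log_ratio_to_fc(log_ratio)
  res <- data.frame(
    gene = rownames(expr$values),
    mean_a = unname(tt$mean_a),
    mean_b = unname(tt$mean_b),
    log_ratio = unname(log_ratio),
    fold_change = fc$fold_change,
    direction = fc$direction,
    t_stat = unname(tt$t_stat),
    p_value = unname(tt$p_value),
    q_value = qvalues(unname(tt$p_value)),
    stringsAsFactors = FALSE
  )
  res <- call_differential(res, config, fc_threshold)
  attr(res, "fc_threshold") <- as.numeric(fc_threshold)
  attr(res, "comparison") <- c(group_a, group_b)
  class(res) <- c("diffexp_result", "data.frame")
  res
}

#' Apply thresholds to make up/down/unchanged calls
#'
#' A gene is called `up` when its q-value is below the configured threshold,
#' its fold change strictly exceeds the fold-change threshold, and its log
#' ratio is positive; `down` symmetrically; otherwise `unchanged`.
#'
#' @param results Data frame with at least `q_value`, `fold_change`,
#'   `direction` columns.
#' @param config A [diffexp_config()] (its `q_threshold` is used).
#' @param fc_threshold Fold-change threshold (linear scale).
#' @return `results` with the `call` column set.
#' @export
call_differential <- function(results, config = diffexp_config(),
                              fc_threshold) {
  stopifnot(is.numeric(fc_threshold), length(fc_threshold) == 1L)
  signif <- results$q_value < config$q_threshold &
    results$fold_change > fc_threshold
  results$call <- ifelse(signif & results$direction == "up", "up",
                         ifelse(signif & results$direction == "down",
                                "down", "unchanged"))
  results
}

#' Write a differential-expression table as TSV
#'
#' Columns: gene, log_ratio, fold_change, t_stat, p_value, q_value, call.
#'
#' @param results A `diffexp_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_diffexp <- function(results, path) {
  cols <- c("gene", "log_ratio", "fold_change", "t_stat", "p_value",
            "q_value", "call")
  utils::write.table(results[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
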