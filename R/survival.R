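# Median-split prognostics: Kaplan-Meier estimation, log-rank testing and
# the per-gene survival screen.

#' Median-split group labels
#'
#' Labels each patient `high` when the gene's expression strictly exceeds
#' the cohort median and `low` otherwise (ties at the median go low). For
#' even n the median is the midpoint of the two central order statistics, so
#' distinct values split evenly.
#'
#' @param expr_values Named numeric vector (one gene's log2 expression per
#'   patient), length >= 4.
#' @return Character vector (`"high"`/`"low"`), same names and order, with
#'   attributes `median`, `n_high`, `n_low`.
#' @export
median_split <- function(expr_values) {
  if (length(expr_values) < 4L) {
    stop("median split needs at least 4 patients", call. = FALSE)
  }
  if (length(unique(expr_values)) == 1L) {
    stop("all expression values identical: no median split possible",
         call. = FALSE)
  }
  med <- stats::median(expr_values)
  labels <- ifelse(expr_values > med, "high", "low")
  attr(labels, "median") <- med
  attr(labels, "n_high") <- sum(labels == "high")
  attr(labels, "n_low") <- sum(labels == "low")
  labels
}

check_surv_input <- function(time, event) {
  if (any(time < 0)) stop("negative survival time", call. = FALSE)
  stopifnot(length(time) == length(event), is.logical(event) ||
              all(event %in% c(0, 1)))
  invisible(NULL)
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)` where `d_i`
#' events occur among `n_i` subjects at risk. Censored subjects leave the
#' risk set after their censoring time. Only event times are tabulated.
#'
#' @param time Numeric vector of follow-up times (months), >= 0.
#' @param event Logical (or 0/1) event indicators.
#' @return A `km_curve`: data frame with columns `time` (ascending distinct
#'   event times), `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(time, event) {
  check_surv_input(time, event)
  if (!length(time)) stop("at least one subject required", call. = FALSE)
  event <- as.logical(event)
  event_times <- sort(unique(time[event]))
  n_risk <- vapply(event_times, function(t) sum(time >= t), numeric(1L))
  n_event <- vapply(event_times, function(t) sum(time == t & event),
                    numeric(1L))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = event_times, n_risk = n_risk,
                    n_event = n_event, survival = surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank statistic with the hypergeometric variance
#' (tie-corrected): at each distinct event time the observed events in group
#' 1 are compared with their expectation under the null of equal hazards;
#' the squared standardised sum is referred to a chi-squared distribution
#' with 1 degree of freedom.
#'
#' @param time Numeric follow-up times for all subjects.
#' @param event Logical (or 0/1) event indicators.
#' @param group Two-level grouping vector (e.g. `"high"`/`"low"`).
#' @return List with `chi2`, `p_value`, `observed` and `expected` (per
#'   group, in level order).
#' @export
logrank_test <- function(time, event, group) {
  check_surv_input(time, event)
  event <- as.logical(event)
  group <- as.character(group)
  levels <- sort(unique(group))
  if (length(levels) != 2L) {
    stop("log-rank test requires exactly 2 non-empty groups", call. = FALSE)
  }
  if (!any(event)) stop("no events observed", call. = FALSE)
  g1 <- group == levels[1L]
  o1 <- 0
  e1 <- 0
  v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1L) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  chi2 <- if (v > 0) (o1 - e1)^2 / v else 0
  p <- if (v > 0) stats::pchisq(chi2, df = 1L, lower.tail = FALSE) else 1
  total_events <- sum(event)
  list(chi2 = chi2, p_value = p,
       observed = stats::setNames(c(o1, total_events - o1), levels),
       expected = stats::setNames(c(e1, total_events - e1), levels))
}

#' Median-split survival screen over a gene list
#'
#' For each gene: split the patients at the gene's median expression, derive
#' the endpoint's time and event indicator from the clinical table (see
#' [survival_endpoints()]), and run the log-rank test between the high and
#' low groups. Results are sorted by p-value. P-values are unadjusted, as is
#' conventional for small candidate panels; `bonferroni = TRUE` adds an
#' adjusted column.
#'
#' @param expr An [expression_matrix()] restricted to (or containing) the
#'   patient samples; sample ids must match the clinical table's `sample`
#'   column exactly.
#' @param genes A `gene_list` or character vector; genes absent from the
#'   matrix are skipped with a warning.
#' @param clinical A `clinical_table`.
#' @param endpoint `"EFS"` or `"OVS"`.
#' @param bonferroni Add a Bonferroni-adjusted p-value column (default
#'   FALSE).
#' @return Data frame with columns `gene`, `endpoint`, `n_high`, `n_low`,
#'   `chi2`, `p`, sorted by `p`.
#' @export
survival_screen <- function(expr, genes, clinical,
                            endpoint = c("EFS", "OVS"),
                            bonferroni = FALSE) {
  endpoint <- match.arg(endpoint)
  stopifnot(inherits(expr, "expression_matrix"))
  symbols <- as_gene_symbols(genes)
  ids <- clinical$sample
  orphans <- setdiff(ids, colnames(expr$values))
  if (length(orphans)) {
    stop("clinical sample(s) missing from expression matrix: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  found <- intersect(symbols, rownames(expr$values))
  if (!length(found)) {
    stop("none of the screened genes is in the expression matrix",
         call. = FALSE)
  }
  if (length(found) < length(symbols)) {
    warning("gene(s) absent from matrix skipped: ",
            paste(setdiff(symbols, found), collapse = ", "), call. = FALSE)
  }
  se <- survival_endpoints(clinical, endpoint)
  rows <- lapply(found, function(g) {
    split <- median_split(expr$values[g, ids])
    lr <- logrank_test(se$time, se$event, split)
    data.frame(gene = g, endpoint = endpoint,
               n_high = attr(split, "n_high"),
               n_low = attr(split, "n_low"),
               chi2 = lr$chi2, p = lr$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni) out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out[order(out$p), , drop = FALSE]
}
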