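# Shared builders for in-code fixtures.

extdata <- function(name) {
  system.file("extdata", name, package = "inflamsig", mustWork = TRUE)
}

# Small expression matrix with two groups; values filled deterministically
# unless a matrix is given.
make_expr <- function(n_genes = 6, n_a = 3, n_b = 3, values = NULL,
                      group_names = c("a", "b"), gene_ids = NULL) {
  n <- n_a + n_b
  if (is.null(values)) {
    values <- matrix(seq_len(n_genes * n) / 7, nrow = n_genes)
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("g%02d", seq_len(n_genes))
  dimnames(values) <- list(gene_ids, sprintf("s%02d", seq_len(n)))
  groups <- stats::setNames(rep(group_names, c(n_a, n_b)),
                            colnames(values))
  expression_matrix(values, groups)
}

# Flag matrix from a character matrix of P/M/A codes.
make_flags <- function(codes, groups) {
  flag_matrix(codes, groups)
}

# One-sided hypergeometric upper-tail sum, written independently of
# fisher.test/phyper: P(X >= x) for X ~ Hypergeom(N, K, k).
hyper_tail_ge <- function(x, N, K, k) {
  hi <- min(K, k)
  if (x > hi) return(0)
  sum(exp(lchoose(K, x:hi) + lchoose(N - K, k - (x:hi)) - lchoose(N, k)))
}

# Lower-tail analogue: P(X <= x).
hyper_tail_le <- function(x, N, K, k) {
  if (x < max(0, k - (N - K))) return(0)
  lo <- max(0, k - (N - K))
  sum(exp(lchoose(K, lo:x) + lchoose(N - K, k - (lo:x)) - lchoose(N, k)))
}

# Reference implementation of the probe-collapse rule: per gene, scan the
# annotated probes, restrict to uniquely mapping probes when any exist,
# then take the highest-mean probe (lexicographically first on ties).
brute_force_collapse <- function(expr, map) {
  map <- map[map$probe %in% rownames(expr$values), , drop = FALSE]
  out <- character(0)
  for (g in sort(unique(map$gene))) {
    cand <- map[map$gene == g, , drop = FALSE]
    if (any(cand$unique)) cand <- cand[cand$unique, , drop = FALSE]
    best_mean <- -Inf
    best_probe <- NULL
    for (p in sort(cand$probe)) {
      m <- mean(expr$values[p, ])
      if (m > best_mean) {
        best_mean <- m
        best_probe <- p
      }
    }
    out[g] <- best_probe
  }
  out
}

# Brute-force per-probe evaluation of a signature rule.
brute_force_signature <- function(flags, rule) {
  keep <- character(0)
  for (p in rownames(flags$calls)) {
    tgt <- flags$calls[p, flags$groups == rule$target_group]
    ok <- mean(tgt == "present") >= rule$target_present_fraction
    for (bg in rule$background_groups) {
      bgc <- flags$calls[p, flags$groups == bg]
      ok <- ok && mean(bgc == "absent") >= rule$background_absent_fraction
    }
    if (ok) keep <- c(keep, p)
  }
  keep
}

# Environment for subprocess Rscript calls so the CLI sees the same
# library paths as the test session.
rscript_env <- function() {
  paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
}
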