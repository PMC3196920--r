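make_rule <- function(...) {
  signature_rule("mac", c("imm", "nor"), ...)
}

test_that("signature rule keeps boundary probes and drops ubiquitous ones", {
  groups <- setNames(c("mac", "mac", rep("imm", 4), rep("nor", 4)),
                     sprintf("s%02d", 1:10))
  calls <- rbind(
    everywhere = rep("P", 10),
    boundary = c("P", "P", "A", "A", "P", "P", "A", "A", "P", "P"),
    good = c("P", "P", rep("A", 8)),
    onemiss = c("P", "M", rep("A", 8))
  )
  colnames(calls) <- names(groups)
  fl <- flag_matrix(calls, groups)
  sig <- extract_signature(fl, make_rule())
  # present everywhere fails the background rule; exactly 50% absent passes
  expect_setequal(sig, c("boundary", "good"))
  # marginal counts as not-present for the target rule
  expect_false("onemiss" %in% sig)
  expect_error(extract_signature(fl, signature_rule("mac", "missing")),
               "no samples in group")
})

test_that("signature extraction matches brute force on random flag matrices", {
  set.seed(21)
  groups <- setNames(c(rep("mac", 2), rep("imm", 5), rep("nor", 6)),
                     sprintf("s%02d", 1:13))
  calls <- matrix(sample(c("P", "M", "A"), 1000 * 13, replace = TRUE,
                         prob = c(0.45, 0.1, 0.45)),
                  nrow = 1000,
                  dimnames = list(sprintf("p%04d", 1:1000), names(groups)))
  fl <- flag_matrix(calls, groups)
  for (baf in c(0.4, 0.5, 0.8)) {
    rule <- make_rule(background_absent_fraction = baf)
    expect_identical(extract_signature(fl, rule),
                     brute_force_signature(fl, rule))
  }
})

test_that("signature extraction is column-order invariant and monotone", {
  set.seed(22)
  groups <- setNames(c(rep("mac", 2), rep("imm", 6), rep("nor", 6)),
                     sprintf("s%02d", 1:14))
  calls <- matrix(sample(c("P", "A"), 500 * 14, replace = TRUE),
                  nrow = 500,
                  dimnames = list(sprintf("p%03d", 1:500), names(groups)))
  fl <- flag_matrix(calls, groups)
  perm <- sample(ncol(calls))
  fl_perm <- flag_matrix(calls[, perm], groups[perm])
  rule <- make_rule()
  expect_setequal(extract_signature(fl, rule),
                  extract_signature(fl_perm, rule))
  # tightening the background requirement never adds probes
  loose <- extract_signature(fl, make_rule(background_absent_fraction = 0.5))
  tight <- extract_signature(fl, make_rule(background_absent_fraction = 0.7))
  expect_true(all(tight %in% loose))
})

test_that("probe signatures translate to genes through every annotated match", {
  map <- probe_gene_map(c("p1", "p2", "p2", "p3"),
                        c("A", "B", "C", "D"))
  expect_setequal(signature_to_genes(c("p1", "p2"), map), c("A", "B", "C"))
})

test_that("enrichment observed/expected counts and Fisher p-values are exact", {
  # universe of 20 genes, 5 up; list of 4 containing all-and-only up genes
  calls <- data.frame(
    gene = sprintf("g%02d", 1:20),
    call = rep(c("up", "unchanged"), c(5, 15))
  )
  res <- enrichment_test(calls, gene_list("demo", sprintf("g%02d", 1:4)))
  expect_equal(res$observed_up, 4)
  expect_equal(res$expected_up, 4 * 5 / 20)
  expect_equal(res$p_up, 5 / 4845, tolerance = 1e-12)
  # conservation: in-list plus out-of-list up calls equal the universe total
  expect_equal(res$observed_up + (5 - res$observed_up), 5)
  # a list with zero up calls in a universe with no up calls has p_up = 1
  calls0 <- transform(calls, call = "unchanged")
  res0 <- enrichment_test(calls0, gene_list("demo", sprintf("g%02d", 1:4)))
  expect_equal(res0$p_up, 1)
  expect_error(enrichment_test(calls, gene_list("x", "absent")),
               "universe")
})

test_that("enrichment p-values equal hypergeometric tail sums on small universes", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(20:100, 1)
    n_up <- sample(1:(n %/% 3), 1)
    k <- sample(2:(n %/% 2), 1)
    calls <- data.frame(
      gene = sprintf("g%03d", 1:n),
      call = sample(rep(c("up", "unchanged"), c(n_up, n - n_up)))
    )
    lst <- gene_list("rnd", sample(calls$gene, k))
    res <- enrichment_test(calls, lst)
    x <- res$observed_up
    expect_equal(res$p_up, hyper_tail_ge(x, n, n_up, k),
                 tolerance = 1e-10)
    expect_equal(res$p_up_deficit, hyper_tail_le(x, n, n_up, k),
                 tolerance = 1e-10)
  }
})

test_that("two-comparison partition assigns genes by call pattern", {
  mk <- function(genes, calls) data.frame(gene = genes, call = calls)
  universe <- c("S1", "T1", "D1", "U1", "X1")
  vs_cl <- mk(universe, c("up", "unchanged", "down", "unchanged", "up"))
  vs_mu <- mk(universe, c("up", "up", "down", "unchanged", "down"))
  lst <- gene_list("infl", c("S1", "T1", "D1", "U1", "MISSING"))
  expect_warning(part <- partition_gene_lists(vs_cl, vs_mu, lst),
                 "MISSING")
  # up in both -> stromal; up vs muscle only -> tumour; down -> neither
  expect_identical(part$stromal_derived$symbols, "S1")
  expect_identical(part$tumour_derived$symbols, "T1")
  expect_length(intersect(part$stromal_derived$symbols,
                          part$tumour_derived$symbols), 0)
  up_mu <- vs_mu$gene[vs_mu$call == "up"]
  expect_true(all(c(part$stromal_derived$symbols,
                    part$tumour_derived$symbols) %in% up_mu))
})
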