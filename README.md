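# inflamsig

Dissecting the inflammatory microenvironment of solid tumours from bulk
expression profiles.

Bulk tumour expression mixes the malignant cells' transcriptome with that
of infiltrating immune and stromal cells. `inflamsig` implements a
two-comparison design that separates the two, built around the Ewing
sarcoma family of tumours (ESFT) use case: patient tumours are compared
both with pure tumour **cell lines** (anything up in tumours but not in
cell lines must come from nonmalignant stromal/immune cells) and with the
surrounding **normal tissue** (anything up versus muscle distinguishes the
tumour site in vivo). Intersecting the calls with a curated inflammation
gene list yields disjoint *stromal-derived* and *tumour-cell-derived*
inflammatory gene lists, which are screened for prognostic value with
median-split Kaplan–Meier / log-rank analysis.

## What it computes

For each gene *g* in a log2 (RMA-style) expression matrix and two groups
A, B:

* log ratio `m_A − m_B`, fold change `FC = 2^|log ratio|` with direction;
* two-sided two-sample *t* (pooled by default, Welch by config) and a
  Storey *q*-value (spline-smoothed π₀ on the λ grid 0, 0.05, …, 0.90);
* call = up iff `q < 0.01` and `FC > τ` strictly, where the threshold τ is
  **calibrated on 14 housekeeping genes**: the largest fold change any of
  them shows between the same two groups (the lowest threshold none of
  them exceeds);
* gene-list enrichment via one-sided Fisher's exact test on
  (in list) × (called up), with expected counts
  `|list| × up-fraction of universe`;
* probe-set → gene collapse with strict unique-probe priority, then
  highest mean expression;
* cell-type signature extraction from MAS5-style present/absent call
  matrices (present in all target samples, absent in ≥ 50% of every
  background panel);
* median-split survival labelling (ties low), product-limit curves,
  unweighted log-rank with tie-corrected hypergeometric variance.

A fully seeded synthetic-study generator (`sim_config()`,
`simulate_expression()`, `simulate_flags()`, `simulate_clinical()`,
`write_study()`) plants ground truth for every stage, and
`run_full()` orchestrates the whole analysis from a flat key=value
config (a thin CLI lives in `inst/cli/inflamsig`).

## Worked example

```r
library(inflamsig)

cfg <- sim_config(seed = 42, prognostic_genes = c(G0001 = -log(2.5)))
sim <- simulate_expression(cfg)
sim$expr
#> expression_matrix: 2000 rows x 73 samples
#> groups: cell_line (11), muscle (18), patient (44)

de_cl <- diff_expression(sim$expr, "patient", "cell_line")
de_mu <- diff_expression(sim$expr, "patient", "muscle")
attr(de_cl, "fc_threshold")   # housekeeping-calibrated, this draw
#> [1] 1.299531

enrichment_test(de_cl, sim$truth$inflammation_list)[
  , c("observed_up", "expected_up", "p_up")]
#>   observed_up expected_up         p_up
#> 1          42      16.184 6.007639e-10

part <- partition_gene_lists(de_cl, de_mu, sim$truth$inflammation_list)
part
#> partition: 4 stromal-derived, 23 tumour-derived genes

clin <- simulate_clinical(cfg, sim$expr)
head(survival_screen(sim$expr,
                     c(part$stromal_derived$symbols,
                       part$tumour_derived$symbols, "G0001"),
                     clin, "OVS"), 2)
#>   gene endpoint n_high n_low      chi2           p
#>  G0076      OVS     22    22 10.796121 0.001017130
#>  G0001      OVS     22    22 10.031215 0.001539095
```

The planted inflammation list shows 42 up-regulated genes against 16.2
expected (Fisher `p ≈ 6e-10`), and the planted protective gene `G0001`
(hazard ratio 2.5 per SD of expression) sits near the top of the 28-gene
screen with a 22/22 median split.

The bundled 44-patient clinical table reproduces its printed footer
exactly:

```r
clinical_summary(read_clinical_table(
  system.file("extdata", "clinical_table1.tsv", package = "inflamsig")))
#> clinical summary (n = 44)
#>   mean age        17.9 years
#>   mean EFS        40.1 months
#>   mean OVS        57.0 months
#>   median follow-up 44.8 months
#>   male:female     1.75
#>   primary/recurrence/metastasis  32/5/7
```

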