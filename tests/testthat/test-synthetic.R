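test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 200, n_patients = 8, n_cell_lines = 4,
                    n_muscle = 4, n_inflammation_list = 30, seed = 5,
                    prognostic_genes = c(G0001 = -1))
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_flags(cfg)$flags$calls,
                   simulate_flags(cfg)$flags$calls)
  expect_identical(simulate_clinical(cfg, a$expr),
                   simulate_clinical(cfg, a$expr))
})

test_that("planted truth respects the config's structural constraints", {
  cfg <- sim_config(n_genes = 500, n_patients = 10, n_cell_lines = 5,
                    n_muscle = 5, n_inflammation_list = 60, seed = 6)
  sim <- simulate_expression(cfg)
  tr <- sim$truth
  planted <- c(tr$planted_up_vs_cell_lines, tr$planted_down_vs_cell_lines,
               tr$planted_up_vs_muscle, tr$planted_down_vs_muscle)
  # housekeeping genes are never planted
  expect_length(intersect(tr$housekeeping, planted), 0)
  expect_length(tr$housekeeping, 14)
  expect_length(tr$inflammation_list$symbols, 60)
  # up and down sets are disjoint within a contrast
  expect_length(intersect(tr$planted_up_vs_cell_lines,
                          tr$planted_down_vs_cell_lines), 0)
  # planted shifts point the right way: up genes higher in patients
  up <- tr$planted_up_vs_cell_lines[1]
  pat <- sim$expr$values[up, sim$expr$groups == "patient"]
  cl <- sim$expr$values[up, sim$expr$groups == "cell_line"]
  expect_gt(mean(pat) - mean(cl), 1)
  expect_error(sim_config(n_genes = 100, n_inflammation_list = 100,
                          n_housekeeping = 14),
               "exceed n_genes")
})

test_that("a zero-effect simulation is null-calibrated downstream", {
  cfg <- sim_config(effect_log2 = 0, seed = 11)
  sim <- simulate_expression(cfg)
  de <- diff_expression(sim$expr, "patient", "cell_line")
  # with no true effects, discoveries at q < 0.01 stay within the binomial
  # 99% envelope implied by the nominal threshold
  n_called <- sum(de$call != "unchanged")
  expect_lte(n_called, qbinom(0.995, nrow(de), 0.01))
  expect_gt(ks.test(de$p_value, "punif")$p.value, 0.01)
})

test_that("noiseless flags recover exactly the planted signature probes", {
  cfg <- sim_config(n_genes = 800, seed = 12)
  fl <- simulate_flags(cfg)
  rule <- signature_rule("macrophage", c("immune", "normal", "cell_line"))
  expect_setequal(extract_signature(fl$flags, rule),
                  fl$truth$signature_probes)
  # a background-absence requirement above the planted absence empties it
  cfg50 <- sim_config(n_genes = 800, seed = 12,
                      sig_background_absent = 0.5)
  fl50 <- simulate_flags(cfg50)
  strict <- signature_rule("macrophage",
                           c("immune", "normal", "cell_line"),
                           background_absent_fraction = 1.0)
  expect_length(extract_signature(fl50$flags, strict), 0)
})

test_that("simulated clinical tables satisfy the record invariants", {
  cfg <- sim_config(n_genes = 100, n_patients = 30, n_cell_lines = 4,
                    n_muscle = 4, n_inflammation_list = 20, seed = 13)
  sim <- simulate_expression(cfg)
  clin <- simulate_clinical(cfg, sim$expr)
  expect_equal(nrow(clin), 30)
  expect_true(all(clin$efs <= clin$ovs))
  expect_true(all(clin$ovs >= 0))
  expect_true(all(clin$status %in% c("Dead", "NED", "AWD")))
  # status agrees with the endpoint reconstruction rules
  expect_true(all(clin$status[clin$efs < clin$ovs & clin$status != "Dead"]
                  == "AWD"))
  # full censoring
  cfg1 <- sim_config(n_genes = 100, n_patients = 30, n_cell_lines = 4,
                     n_muscle = 4, n_inflammation_list = 20,
                     censor_rate = 1, seed = 13)
  clin1 <- simulate_clinical(cfg1, sim$expr)
  expect_true(all(clin1$status != "Dead"))
  expect_error(simulate_clinical(sim_config(prognostic_genes = c(NOPE = 1)),
                                 sim$expr),
               "NOPE")
})

test_that("a protective planted gene lengthens survival of its high group", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_genes = 150, n_patients = 44, n_cell_lines = 4,
                      n_muscle = 4, n_inflammation_list = 20, seed = s,
                      prognostic_genes = c(G0001 = -1))
    sim <- simulate_expression(cfg)
    clin <- simulate_clinical(cfg, sim$expr)
    sp <- median_split(sim$expr$values["G0001", clin$sample])
    med_surv <- function(keep) {
      km <- km_estimate(clin$ovs[keep], clin$status[keep] == "Dead")
      drop <- which(km$survival <= 0.5)
      if (length(drop)) km$time[drop[1]] else Inf
    }
    med_surv(sp == "high") > med_surv(sp == "low")
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("write_study materialises a readable, consistent study directory", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 150, n_patients = 10, n_cell_lines = 4,
                    n_muscle = 4, n_inflammation_list = 20, seed = 17)
  paths <- write_study(cfg, dir)
  expr <- read_expression_table(paths[["expression"]],
                                groups = paths[["groups"]])
  sim <- simulate_expression(cfg)
  expect_identical(expr$values, sim$expr$values)
  fl <- read_flag_table(paths[["flags"]], paths[["flag_groups"]])
  expect_identical(fl$calls, simulate_flags(cfg)$flags$calls)
  clin <- read_clinical_table(paths[["clinical"]])
  expect_equal(nrow(clin), 10)
  truth_up <- readLines(file.path(paths[["truth"]],
                                  "planted_up_vs_cell_lines.txt"))
  expect_setequal(truth_up, sim$truth$planted_up_vs_cell_lines)
})
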