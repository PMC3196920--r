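test_that("median split labels relative to the midpoint median, ties low", {
  sp <- median_split(c(a = 1, b = 2, c = 3, d = 4))
  expect_identical(as.vector(sp), c("low", "low", "high", "high"))
  expect_equal(attr(sp, "median"), 2.5)
  # 44 distinct values split 22/22
  set.seed(14)
  sp44 <- median_split(setNames(sample(44), paste0("P", 1:44)))
  expect_equal(attr(sp44, "n_high"), 22)
  expect_equal(attr(sp44, "n_low"), 22)
  # ties at the median go to the low group
  spt <- median_split(c(1, 2, 2, 2, 3, 9))
  expect_identical(as.vector(spt), c("low", "low", "low", "low", "high",
                                     "high"))
  expect_error(median_split(rep(2, 6)), "identical")
  expect_error(median_split(c(1, 2, 3)), "at least 4")
})

test_that("Kaplan-Meier estimate handles edge cases", {
  one <- km_estimate(5, TRUE)
  expect_equal(one$survival, 0)
  expect_equal(one$time, 5)
  none <- km_estimate(c(3, 7, 9), c(FALSE, FALSE, FALSE))
  expect_equal(nrow(none), 0)  # S stays at 1: no event times tabulated
  expect_error(km_estimate(-1, TRUE), "negative")
})

test_that("Kaplan-Meier matches the reference survival implementation to 1e-12", {
  skip_if_not_installed("survival")
  set.seed(8)
  for (i in 1:10) {
    n <- 30
    time <- round(rexp(n, 0.02), 1)
    event <- runif(n) < 0.6
    if (!any(event)) event[1] <- TRUE
    km <- km_estimate(time, event)
    ref <- survival::survfit(survival::Surv(time, event) ~ 1)
    ref_at_events <- summary(ref, times = km$time)
    expect_equal(km$survival, ref_at_events$surv, tolerance = 1e-12)
    expect_equal(km$n_risk, ref_at_events$n.risk, tolerance = 0)
    # invariant to subject order, monotone non-increasing
    perm <- sample(n)
    expect_identical(km_estimate(time[perm], event[perm]), km)
    expect_true(all(diff(km$survival) <= 1e-15))
  }
})

test_that("log-rank statistic matches the hand computation and is symmetric", {
  # 6-subject table: A = events at 1, 3, censored 5; B = events at 2, 4, 6
  time <- c(1, 3, 5, 2, 4, 6)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  group <- rep(c("A", "B"), each = 3)
  lr <- logrank_test(time, event, group)
  # O1 = 2, E1 = 1/2 + 2/5 + 1/2 + 1/3 = 26/15,
  # V = 1/4 + 6/25 + 1/4 + 2/9; chi2 = (4/15)^2 / V
  expect_equal(lr$chi2, (4 / 15)^2 / (1 / 4 + 6 / 25 + 1 / 4 + 2 / 9),
               tolerance = 1e-12)
  swap <- logrank_test(time, event, rev(group))
  expect_equal(swap$chi2, lr$chi2, tolerance = 1e-12)
  expect_equal(swap$p_value, lr$p_value, tolerance = 1e-12)
  # identical groups give chi2 = 0, p = 1
  same <- logrank_test(rep(time, 2), rep(event, 2),
                       rep(c("A", "B"), each = 6))
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)
  expect_error(logrank_test(time, rep(FALSE, 6), group), "no events")
})

test_that("log-rank chi-squared agrees with the reference implementation", {
  skip_if_not_installed("survival")
  set.seed(19)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    time <- round(rexp(n, 0.05), 1)
    event <- runif(n) < 0.7
    group <- sample(c("high", "low"), n, replace = TRUE)
    if (length(unique(group)) < 2 || !any(event)) next
    lr <- logrank_test(time, event, group)
    ref <- survival::survdiff(survival::Surv(time, event) ~ group)
    expect_equal(lr$chi2, ref$chisq, tolerance = 1e-10)
  }
})

test_that("log-rank detects a hazard ratio of 3 at the cohort's size", {
  hits <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    t1 <- rexp(22, 1)
    t2 <- rexp(22, 3)
    cens <- runif(44, 0, 1.4)  # ~60% event rate
    time <- pmin(c(t1, t2), cens)
    event <- c(t1, t2) <= cens
    logrank_test(time, event, rep(c("a", "b"), each = 22))$p_value < 0.05
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("endpoint reconstruction and cohort summaries match the printed table", {
  clin <- read_clinical_table(extdata("clinical_table1.tsv"))
  s <- clinical_summary(clin)
  expect_equal(s$mean_age, 17.9, tolerance = 0.05 / 17.9)
  expect_equal(s$median_followup, 44.8, tolerance = 1e-12)
  expect_equal(s$male_to_female, 1.75, tolerance = 1e-12)
  ovs <- survival_endpoints(clin, "OVS")
  expect_equal(sum(ovs$event), sum(clin$status == "Dead"))
  efs <- survival_endpoints(clin, "EFS")
  # every death is an EFS event, as is any earlier event before follow-up end
  expect_true(all(efs$event[clin$status == "Dead"]))
  expect_true(all(efs$event[clin$efs < clin$ovs]))
  expect_false(any(efs$event[clin$status != "Dead" &
                               clin$efs == clin$ovs]))
  # single record: means collapse to the record itself
  one <- clinical_summary(clin[1, ])
  expect_equal(one$mean_age, clin$age[1])
  expect_equal(one$mean_ovs, clin$ovs[1])
})

test_that("survival screen ranks an engineered separation gene first", {
  set.seed(4)
  clin <- read_clinical_table(extdata("clinical_table1.tsv"))
  n <- nrow(clin)
  values <- matrix(rnorm(5 * n, 8, 1), nrow = 5,
                   dimnames = list(sprintf("g%d", 1:5), clin$sample))
  # engineered gene: high expression exactly in the event-free patients
  ovs_event <- survival_endpoints(clin, "OVS")$event
  values["g1", ] <- ifelse(ovs_event, 6, 10) + rnorm(n, 0, 0.1)
  expr <- expression_matrix(values,
                            setNames(rep("patient", n), clin$sample))
  scr <- survival_screen(expr, sprintf("g%d", 1:5), clin, "OVS")
  expect_identical(scr$gene[1], "g1")
  expect_lt(scr$p[1], 0.001)
  expect_equal(scr$n_high + scr$n_low, rep(n, 5))
  # orphan clinical ids are a hard error naming the orphan
  expr2 <- expression_matrix(values[, -1], expr$groups[-1])
  expect_error(survival_screen(expr2, "g1", clin, "OVS"), clin$sample[1])
  # all-censored cohorts cannot be screened
  clin_cens <- transform(clin, status = "NED", efs = ovs)
  class(clin_cens) <- class(clin)
  expect_error(survival_screen(expr, "g1", clin_cens, "OVS"), "no events")
})

test_that("screen p-values are approximately uniform under label permutation", {
  set.seed(23)
  clin <- read_clinical_table(extdata("clinical_table1.tsv"))
  n <- nrow(clin)
  ps <- unlist(lapply(1:10, function(i) {
    values <- matrix(rnorm(32 * n, 8, 1), nrow = 32,
                     dimnames = list(sprintf("g%02d", 1:32),
                                     sample(clin$sample)))
    expr <- expression_matrix(values,
                              setNames(rep("patient", n),
                                       colnames(values)))
    survival_screen(expr, sprintf("g%02d", 1:32), clin, "OVS")$p
  }))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
})
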