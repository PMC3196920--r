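# Synthetic study generator with planted ground truth: Gaussian log2
# expression with group-specific shifts, detection-call matrices with
# planted cell-type-specific probes, and clinical tables whose hazards
# depend on designated prognostic genes.

#' Simulation configuration
#'
#' Defaults mirror the operating point of the targeted study design: 44
#' patient tumours, 11 cell lines and 18 normal muscle samples; log2
#' effects of 2 for planted differentially expressed genes; residual SD
#' 0.7 in log2 units; a 238-gene inflammation list whose members have a
#' 3-fold raised probability of being planted up-regulated; 14 zero-shift
#' housekeeping genes.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_patients,n_cell_lines,n_muscle Group sizes (defaults 44/11/18).
#' @param frac_up_vs_cell_lines,frac_down_vs_cell_lines Base probabilities
#'   that a gene is planted up/down in the patients-vs-cell-lines contrast
#'   (defaults 0.05/0.05).
#' @param frac_up_vs_muscle,frac_down_vs_muscle Same for patients vs muscle.
#' @param effect_log2 Absolute log2 shift for planted genes (default 2).
#' @param sigma Residual SD, log2 units (default 0.7).
#' @param n_inflammation_list Size of the planted inflammation list
#'   (default 238).
#' @param list_enrichment Multiplier on the up-planting probability for
#'   list members (default 3).
#' @param n_housekeeping Number of zero-shift housekeeping genes (default
#'   14; named with the standard housekeeping symbols so threshold
#'   calibration works out of the box).
#' @param prognostic_genes Named numeric vector: per-gene log hazard ratio
#'   per SD of expression (negative = protective). Default none.
#' @param censor_rate Probability a patient is censored before the event
#'   (default 0.4).
#' @param n_signature_probes Planted cell-type-specific probes (default 50).
#' @param flag_target_size Target-group samples in the flag matrix
#'   (default 2, as for a two-sample macrophage panel).
#' @param flag_background_sizes Named integer vector of background panel
#'   sizes (default immune 16, normal 20, cell_line 20).
#' @param flag_present_rate Present-call rate for non-signature probes
#'   (default 0.9).
#' @param sig_background_absent Fraction of each background panel in which
#'   a planted signature probe is absent (default 0.8).
#' @param marginal_rate Rate at which non-signature calls are degraded to
#'   marginal (default 0.02).
#' @param flag_noise Probability that any present/absent call is flipped
#'   (default 0).
#' @param seed Integer seed; all outputs are byte-identical for a fixed
#'   seed and config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_patients = 44, n_cell_lines = 11, n_muscle = 18,
                       frac_up_vs_cell_lines = 0.05,
                       frac_down_vs_cell_lines = 0.05,
                       frac_up_vs_muscle = 0.05,
                       frac_down_vs_muscle = 0.05,
                       effect_log2 = 2, sigma = 0.7,
                       n_inflammation_list = 238, list_enrichment = 3,
                       n_housekeeping = 14,
                       prognostic_genes = NULL,
                       censor_rate = 0.4,
                       n_signature_probes = 50,
                       flag_target_size = 2,
                       flag_background_sizes = c(immune = 16, normal = 20,
                                                 cell_line = 20),
                       flag_present_rate = 0.9,
                       sig_background_absent = 0.8,
                       marginal_rate = 0.02,
                       flag_noise = 0,
                       seed = 1) {
  fracs <- c(frac_up_vs_cell_lines, frac_down_vs_cell_lines,
             frac_up_vs_muscle, frac_down_vs_muscle, censor_rate,
             flag_present_rate, sig_background_absent, marginal_rate,
             flag_noise)
  stopifnot(all(fracs >= 0), all(fracs <= 1), sigma > 0,
            n_genes >= 1, n_patients >= 2, n_cell_lines >= 2, n_muscle >= 2,
            effect_log2 >= 0, list_enrichment >= 0,
            n_housekeeping >= 0, n_inflammation_list >= 0)
  if (n_inflammation_list + n_housekeeping > n_genes) {
    stop("inflammation list plus housekeeping genes exceed n_genes",
         call. = FALSE)
  }
  fields <- names(formals(sim_config))
  structure(mget(fields, envir = environment()), class = "sim_config")
}

sim_gene_names <- function(config) {
  n_hk <- config$n_housekeeping
  hk_pool <- default_housekeeping_genes()
  hk <- c(utils::head(hk_pool, n_hk),
          if (n_hk > length(hk_pool)) {
            sprintf("HK%02d", seq_len(n_hk - length(hk_pool)) +
                      length(hk_pool))
          })
  others <- sprintf("G%04d", seq_len(config$n_genes - length(hk)))
  list(housekeeping = hk, others = others, all = c(hk, others))
}

#' Simulate a log2 expression matrix with planted differential expression
#'
#' Per gene and sample: `value = baseline + group shift + N(0, sigma)`,
#' baselines Uniform(4, 12). Planted genes receive a +/- `effect_log2`
#' shift in the contrasted background group (so patients appear up or down
#' relative to it); housekeeping genes are never planted; membership in
#' the planted inflammation list multiplies a gene's up-planting
#' probability by `list_enrichment`.
#'
#' @param config A [sim_config()].
#' @return List with `expr` (an [expression_matrix()]) and `truth`: planted
#'   gene sets per contrast and direction, the housekeeping symbols and the
#'   inflammation `gene_list`.
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nm <- sim_gene_names(config)
  genes <- nm$all
  n_genes <- length(genes)
  inflammation <- sample(nm$others, config$n_inflammation_list)
  plantable <- !(genes %in% nm$housekeeping)
  in_list <- genes %in% inflammation

  plant <- function(frac_up, frac_down) {
    p_up <- pmin(frac_up * ifelse(in_list, config$list_enrichment, 1), 1)
    p_down <- pmin(frac_down, 1 - p_up)
    u <- stats::runif(n_genes)
    up <- plantable & u < p_up
    down <- plantable & !up & u < p_up + p_down
    list(up = genes[up], down = genes[down])
  }
  cl <- plant(config$frac_up_vs_cell_lines, config$frac_down_vs_cell_lines)
  mu <- plant(config$frac_up_vs_muscle, config$frac_down_vs_muscle)

  groups <- c(rep("patient", config$n_patients),
              rep("cell_line", config$n_cell_lines),
              rep("muscle", config$n_muscle))
  sample_ids <- c(sprintf("P%02d", seq_len(config$n_patients)),
                  sprintf("CL%02d", seq_len(config$n_cell_lines)),
                  sprintf("MU%02d", seq_len(config$n_muscle)))
  names(groups) <- sample_ids

  baseline <- stats::runif(n_genes, 4, 12)
  # Shifts applied to the background group so that "up" means higher in
  # patients for that contrast.
  shift_cl <- (-config$effect_log2) * (genes %in% cl$up) +
    config$effect_log2 * (genes %in% cl$down)
  shift_mu <- (-config$effect_log2) * (genes %in% mu$up) +
    config$effect_log2 * (genes %in% mu$down)
  shift <- cbind(patient = 0, cell_line = shift_cl, muscle = shift_mu)

  values <- baseline + shift[, groups] +
    matrix(stats::rnorm(n_genes * length(groups), 0, config$sigma),
           nrow = n_genes)
  dimnames(values) <- list(genes, sample_ids)

  truth <- list(
    planted_up_vs_cell_lines = cl$up,
    planted_down_vs_cell_lines = cl$down,
    planted_up_vs_muscle = mu$up,
    planted_down_vs_muscle = mu$down,
    housekeeping = nm$housekeeping,
    inflammation_list = gene_list("inflammation_synthetic", inflammation)
  )
  list(expr = expression_matrix(values, groups), truth = truth)
}

#' Simulate a detection-call matrix with planted signature probes
#'
#' Planted probes are present in every target-group sample and absent in a
#' configured fraction of each background panel; all other probes are
#' present at a group-independent rate (with occasional marginal calls).
#' Optional symmetric flip noise corrupts present/absent calls.
#'
#' @param config A [sim_config()].
#' @return List with `flags` (a [flag_matrix()]) and `truth` (the planted
#'   `signature_probes`).
#' @export
simulate_flags <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_sig <- config$n_signature_probes
  n_probes <- config$n_genes
  stopifnot(n_sig <= n_probes)
  probes <- c(sprintf("SIG%04d", seq_len(n_sig)),
              sprintf("NP%05d", seq_len(n_probes - n_sig)))
  bg_sizes <- config$flag_background_sizes
  groups <- c(rep("macrophage", config$flag_target_size),
              rep(names(bg_sizes), bg_sizes))
  sample_ids <- paste0(toupper(substr(groups, 1, 3)),
                       unlist(lapply(c(config$flag_target_size, bg_sizes),
                                     seq_len)))
  names(groups) <- sample_ids
  n_samples <- length(sample_ids)

  calls <- matrix(ifelse(stats::runif(n_probes * n_samples) <
                           config$flag_present_rate, "present", "absent"),
                  nrow = n_probes, dimnames = list(probes, sample_ids))
  marg <- matrix(stats::runif(n_probes * n_samples) < config$marginal_rate,
                 nrow = n_probes)
  calls[marg] <- "marginal"

  sig_rows <- seq_len(n_sig)
  calls[sig_rows, groups == "macrophage"] <- "present"
  for (bg in names(bg_sizes)) {
    ids <- sample_ids[groups == bg]
    n_absent <- round(config$sig_background_absent * length(ids))
    for (i in sig_rows) {
      absent_ids <- sample(ids, n_absent)
      calls[i, ids] <- "present"
      calls[i, absent_ids] <- "absent"
    }
  }

  if (config$flag_noise > 0) {
    flip <- matrix(stats::runif(n_probes * n_samples) < config$flag_noise,
                   nrow = n_probes) & calls != "marginal"
    calls[flip] <- ifelse(calls[flip] == "present", "absent", "present")
  }

  list(flags = flag_matrix(calls, groups),
       truth = list(signature_probes = probes[sig_rows]))
}

#' Simulate a clinical table linked to expression via planted hazards
#'
#' Event times are Exponential with per-patient log hazard
#' `log(base rate) + sum over prognostic genes of beta * standardised
#' expression` (negative beta = protective). Censoring times are drawn
#' independently of the event times, Exponential with rate chosen so that
#' a fraction `censor_rate` of patients is censored under the baseline
#' hazard; events beyond the follow-up horizon (180 months) are
#' administratively censored.
#' Event-free survival is generated at or before overall survival via an
#' earlier-relapse mechanism, so `efs <= ovs` by construction.
#'
#' @param config A [sim_config()] (its `prognostic_genes` and `censor_rate`
#'   are used).
#' @param expr An [expression_matrix()] containing the patient samples and
#'   every configured prognostic gene.
#' @return A `clinical_table` with one row per patient sample.
#' @export
simulate_clinical <- function(config, expr) {
  stopifnot(inherits(config, "sim_config"),
            inherits(expr, "expression_matrix"))
  set.seed(config$seed + 2L)
  ids <- names(expr$groups)[expr$groups == "patient"]
  if (!length(ids)) stop("no patient samples in matrix", call. = FALSE)
  n <- length(ids)
  betas <- config$prognostic_genes
  log_hr <- rep(0, n)
  if (length(betas)) {
    missing <- setdiff(names(betas), rownames(expr$values))
    if (length(missing)) {
      stop("prognostic gene(s) not in matrix: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    for (g in names(betas)) {
      x <- expr$values[g, ids]
      log_hr <- log_hr + betas[[g]] * as.vector(scale(x))
    }
  }
  base_rate <- log(2) / 57  # median survival ~ 57 months at baseline
  event_time <- stats::rexp(n, rate = base_rate * exp(log_hr))
  horizon <- 180
  censor_time <- if (config$censor_rate <= 0) {
    rep(horizon, n)
  } else if (config$censor_rate < 1) {
    # independent censoring; rate gives P(censored) = censor_rate at the
    # baseline hazard
    pmin(stats::rexp(n, rate = base_rate * config$censor_rate /
                       (1 - config$censor_rate)), horizon)
  } else {
    # degenerate all-censored case: censor strictly before the event
    stats::runif(n) * pmin(event_time, horizon)
  }
  ovs <- pmin(event_time, censor_time)
  dead <- config$censor_rate < 1 & event_time <= censor_time
  # Earlier-relapse mechanism: some patients relapse before death or
  # last follow-up.
  relapse <- stats::runif(n) < 0.3
  efs <- ifelse(relapse, ovs * stats::runif(n, 0.3, 0.9), ovs)
  status <- ifelse(dead, "Dead", ifelse(relapse, "AWD", "NED"))
  out <- data.frame(
    sample = ids,
    diagnosis = sample(c("Ewing", "PNET", "Askin"), n, replace = TRUE,
                       prob = c(32, 10, 2)),
    state = sample(c("Primary", "Recurrence", "Metastasis"), n,
                   replace = TRUE, prob = c(32, 5, 7)),
    age = sample(4:34, n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(1.75, 1)),
    efs = round(efs, 1),
    ovs = round(ovs, 1),
    status = status,
    pretreated = stats::runif(n) < 15 / 44,
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$efs <= out$ovs), all(out$ovs >= 0))
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Materialise a complete synthetic study directory
#'
#' Writes every input the pipeline reads: expression matrix + group map,
#' flag matrix + group map, inflammation and housekeeping gene lists, a
#' clinical table, and plain-text truth sidecar lists for each planted set.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(config = sim_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_expression(config)
  fl <- simulate_flags(config)
  clin <- simulate_clinical(config, sim$expr)
  p <- function(...) file.path(dir, ...)
  write_expression_table(sim$expr, p("expression.tsv"), p("groups.tsv"))
  write_flag_table(fl$flags, p("flags.tsv"), p("flag_groups.tsv"))
  write_gene_list(sim$truth$inflammation_list, p("inflammation_list.txt"))
  write_gene_list(sim$truth$housekeeping, p("housekeeping.txt"))
  utils::write.table(clin, p("clinical.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_dir <- p("truth")
  dir.create(truth_dir, showWarnings = FALSE)
  for (nm in c("planted_up_vs_cell_lines", "planted_down_vs_cell_lines",
               "planted_up_vs_muscle", "planted_down_vs_muscle")) {
    writeLines(sim$truth[[nm]], file.path(truth_dir, paste0(nm, ".txt")))
  }
  writeLines(fl$truth$signature_probes,
             file.path(truth_dir, "signature_probes.txt"))
  invisible(c(expression = p("expression.tsv"), groups = p("groups.tsv"),
              flags = p("flags.tsv"), flag_groups = p("flag_groups.tsv"),
              inflammation = p("inflammation_list.txt"),
              housekeeping = p("housekeeping.txt"),
              clinical = p("clinical.tsv"), truth = truth_dir))
}
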