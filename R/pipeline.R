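# End-to-end orchestration: collapse -> thresholds -> differential
# expression (two comparisons) -> enrichment -> partition -> signature ->
# survival screen, from a flat key=value run configuration.

#' Read a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Recognised keys: `expression`, `groups`, `probe_map`, `flags`,
#' `flag_groups`, `gene_list`, `housekeeping`, `clinical`, `outdir`,
#' `group_a` (default `patient`), `group_cell_lines` (default `cell_line`),
#' `group_muscle` (default `muscle`), `q_threshold`, `t_variant`,
#' `fc_threshold_vs_cell_lines`, `fc_threshold_vs_muscle`,
#' `signature_target`, `signature_background` (comma-separated),
#' `signature_target_present_fraction`, `signature_background_absent_fraction`,
#' `endpoints` (comma-separated subset of EFS,OVS), `seed`.
#'
#' @param path Path to the configuration file.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L],
                     call. = FALSE)
  cfg <- stats::setNames(lapply(kv, function(m) trimws(m[[3L]])),
                         vapply(kv, function(m) trimws(m[[2L]]),
                                character(1L)))
  run_config(cfg)
}

#' Normalise a run configuration list
#'
#' @param cfg Named list of configuration values (see [read_run_config()]).
#' @return Named list of class `run_config` with defaults filled in.
#' @export
run_config <- function(cfg) {
  defaults <- list(group_a = "patient", group_cell_lines = "cell_line",
                   group_muscle = "muscle", q_threshold = "0.01",
                   t_variant = "pooled", endpoints = "EFS,OVS",
                   signature_target_present_fraction = "1",
                   signature_background_absent_fraction = "0.5",
                   seed = "1")
  for (k in names(defaults)) {
    if (is.null(cfg[[k]]) || !nzchar(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  }
  if (is.null(cfg$expression)) stop("config key 'expression' is required",
                                    call. = FALSE)
  if (is.null(cfg$outdir)) stop("config key 'outdir' is required",
                                call. = FALSE)
  structure(cfg, class = "run_config")
}

split_csv <- function(x) trimws(strsplit(x, ",", fixed = TRUE)[[1L]])

pipeline_log <- function(log, fmt, ...) {
  line <- sprintf(fmt, ...)
  message(line)
  c(log, line)
}

#' Run the full analysis pipeline
#'
#' Executes every configured stage in order: read inputs, collapse probe
#' sets to genes (when a probe map is given), derive housekeeping
#' fold-change thresholds per comparison, run both differential-expression
#' comparisons (patients vs cell lines and patients vs muscle), test the
#' configured gene list for enrichment in each comparison, partition it
#' into stromal-derived and tumour-derived genes, extract the detection-
#' call signature (when a flag matrix is given), and screen the
#' partitioned genes for prognostic value on each configured endpoint
#' (when a clinical table is given). All stage outputs are written to
#' `outdir` as TSV/plain text, along with a `summary.txt` report and a
#' `MANIFEST` listing stage status. A stage failure aborts with a
#' stage-named error after writing the MANIFEST, so partial outputs are
#' retained.
#'
#' @param config A `run_config`, a named list, or the path of a key=value
#'   configuration file.
#' @return The run report (named list of stage summaries), invisibly.
#' @export
run_full <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  } else if (!inherits(config, "run_config")) {
    config <- run_config(config)
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  log <- character(0)
  report <- list()
  finish_manifest <- function(status) {
    writeLines(c(manifest, status), file.path(outdir, "MANIFEST"))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest <<- c(manifest, paste0(name, "\tFAILED"))
      finish_manifest("INCOMPLETE")
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  done <- function(name, files = character(0)) {
    manifest <<- c(manifest,
                   paste0(name, "\tOK",
                          if (length(files)) paste0("\t", paste(basename(files),
                                                                collapse = ","))))
  }

  # --- input stage -------------------------------------------------------
  expr <- stage("read_expression", {
    read_expression_table(config$expression,
                          dialect = config$dialect %||% "plain_tsv",
                          groups = config$groups)
  })
  done("read_expression")

  if (!is.null(config$probe_map)) {
    expr <- stage("collapse", {
      collapse_probes_to_genes(expr, read_probe_gene_map(config$probe_map))
    })
    log <- pipeline_log(log, "collapse: %d genes after probe collapse",
                        nrow(expr$values))
    done("collapse")
  }

  hk <- if (!is.null(config$housekeeping)) {
    read_gene_list(config$housekeeping)
  } else {
    default_housekeeping_genes()
  }
  de_config <- diffexp_config(
    q_threshold = as.numeric(config$q_threshold),
    housekeeping_genes = hk,
    t_variant = config$t_variant
  )

  # --- differential expression ------------------------------------------
  comparisons <- list(
    vs_cell_lines = list(group_b = config$group_cell_lines,
                         override = config$fc_threshold_vs_cell_lines),
    vs_muscle = list(group_b = config$group_muscle,
                     override = config$fc_threshold_vs_muscle)
  )
  de <- list()
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    de[[nm]] <- stage(paste0("diffexp_", nm), {
      thr <- if (!is.null(cmp$override)) as.numeric(cmp$override) else {
        housekeeping_threshold(expr, config$group_a, cmp$group_b, hk)
      }
      diff_expression(expr, config$group_a, cmp$group_b, de_config,
                      fc_threshold = thr)
    })
    path <- file.path(outdir, paste0("diffexp_", nm, ".tsv"))
    write_diffexp(de[[nm]], path)
    log <- pipeline_log(log,
                        "diffexp_%s: fold-change threshold %.4f; %d up, %d down of %d genes",
                        nm, attr(de[[nm]], "fc_threshold"),
                        sum(de[[nm]]$call == "up"),
                        sum(de[[nm]]$call == "down"), nrow(de[[nm]]))
    report[[paste0("diffexp_", nm)]] <- list(
      fc_threshold = attr(de[[nm]], "fc_threshold"),
      n_up = sum(de[[nm]]$call == "up"),
      n_down = sum(de[[nm]]$call == "down"),
      n_genes = nrow(de[[nm]]))
    done(paste0("diffexp_", nm), path)
  }

  # --- enrichment and partition -----------------------------------------
  if (!is.null(config$gene_list)) {
    glist <- stage("read_gene_list", read_gene_list(config$gene_list))
    enr <- stage("enrichment", {
      rbind(
        cbind(comparison = "vs_cell_lines",
              enrichment_test(de$vs_cell_lines, glist)),
        cbind(comparison = "vs_muscle",
              enrichment_test(de$vs_muscle, glist))
      )
    })
    enr_path <- file.path(outdir, "enrichment.tsv")
    utils::write.table(enr, enr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    report$enrichment <- enr
    log <- pipeline_log(log,
                        "enrichment (%s vs cell lines): %d up observed, %.1f expected",
                        glist$name, enr$observed_up[1L], enr$expected_up[1L])
    done("enrichment", enr_path)

    part <- stage("partition", {
      partition_gene_lists(de$vs_cell_lines, de$vs_muscle, glist)
    })
    part_paths <- write_partition(part, file.path(outdir, glist$name))
    report$partition <- list(
      n_stromal = length(part$stromal_derived$symbols),
      n_tumour = length(part$tumour_derived$symbols))
    log <- pipeline_log(log, "partition: %d stromal-derived, %d tumour-derived",
                        report$partition$n_stromal,
                        report$partition$n_tumour)
    done("partition", part_paths)
  } else {
    part <- NULL
  }

  # --- signature ---------------------------------------------------------
  if (!is.null(config$flags)) {
    sig <- stage("signature", {
      flags <- read_flag_table(config$flags, config$flag_groups)
      rule <- signature_rule(
        config$signature_target,
        split_csv(config$signature_background),
        as.numeric(config$signature_target_present_fraction),
        as.numeric(config$signature_background_absent_fraction))
      extract_signature(flags, rule)
    })
    sig_path <- file.path(outdir, "signature_probes.txt")
    writeLines(sig, sig_path)
    report$signature <- list(n_probes = length(sig))
    log <- pipeline_log(log, "signature: %d probes selected", length(sig))
    done("signature", sig_path)
  }

  # --- survival screen ---------------------------------------------------
  if (!is.null(config$clinical) && !is.null(part)) {
    screen_genes <- c(part$stromal_derived$symbols,
                      part$tumour_derived$symbols)
    if (length(screen_genes)) {
      clin <- stage("read_clinical", read_clinical_table(config$clinical))
      for (ep in split_csv(config$endpoints)) {
        scr <- stage(paste0("survival_screen_", ep), {
          patient_ids <- names(expr$groups)[expr$groups == config$group_a]
          sub <- expression_matrix(
            expr$values[, patient_ids, drop = FALSE],
            expr$groups[patient_ids])
          survival_screen(sub, screen_genes, clin, ep)
        })
        scr_path <- file.path(outdir,
                              paste0("survival_screen_", ep, ".tsv"))
        utils::write.table(scr, scr_path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        report[[paste0("survival_screen_", ep)]] <- utils::head(scr, 5L)
        log <- pipeline_log(log, "survival screen (%s): top gene %s, p = %.3g",
                            ep, scr$gene[1L], scr$p[1L])
        done(paste0("survival_screen_", ep), scr_path)
      }
    }
  }

  writeLines(log, file.path(outdir, "summary.txt"))
  finish_manifest("COMPLETE")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
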