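# Clinical-table ingestion and descriptive summaries.

#' Read a clinical table
#'
#' Expects a delimited text file (tab- or comma-separated, sniffed from the
#' header) with columns `sample, diagnosis, state, age, sex, efs, ovs,
#' status, pretreated`. `efs`/`ovs` are survival times in months; both the
#' decimal point and the decimal comma are accepted (clinical tables are
#' often typed with comma decimals; decimal commas require a tab-separated
#' file). `status` must be one of `Dead`, `NED` (no evidence of disease) or
#' `AWD` (alive with disease); `pretreated` accepts `+`/`-`, `yes`/`no`,
#' `TRUE`/`FALSE` or `1`/`0`.
#'
#' @param path Path to the table.
#' @return A `clinical_table`: data frame with one row per patient and typed
#'   columns (`age`, `efs`, `ovs` numeric; `pretreated` logical).
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  header <- tolower(trimws(parts[[1L]]))
  wanted <- c("sample", "diagnosis", "state", "age", "sex", "efs", "ovs",
              "status", "pretreated")
  idx <- match(wanted, header)
  if (anyNA(idx)) {
    stop("clinical table missing column(s): ",
         paste(wanted[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  rows <- parts[-1L]
  get <- function(row, col) trimws(row[[idx[match(col, wanted)]]])
  records <- lapply(rows, function(row) {
    sample <- get(row, "sample")
    rec <- data.frame(
      sample = sample,
      diagnosis = match_level(get(row, "diagnosis"),
                              c("Ewing", "PNET", "Askin"), sample),
      state = match_level(get(row, "state"),
                          c("Primary", "Recurrence", "Metastasis"), sample),
      age = parse_decimal(get(row, "age"), sample, "age"),
      sex = match_level(toupper(get(row, "sex")), c("M", "F"), sample),
      efs = parse_decimal(get(row, "efs"), sample, "efs"),
      ovs = parse_decimal(get(row, "ovs"), sample, "ovs"),
      status = match_level(get(row, "status"), c("Dead", "NED", "AWD"),
                           sample),
      pretreated = parse_flag(get(row, "pretreated"), sample),
      stringsAsFactors = FALSE
    )
    if (rec$age <= 0) {
      stop("non-positive age for sample ", sample, call. = FALSE)
    }
    if (rec$efs < 0 || rec$ovs < 0) {
      stop("negative survival time for sample ", sample, call. = FALSE)
    }
    if (rec$efs > rec$ovs) {
      stop("EFS exceeds OVS for sample ", sample, call. = FALSE)
    }
    rec
  })
  out <- do.call(rbind, records)
  if (anyDuplicated(out$sample)) {
    stop("duplicate sample code: ", out$sample[duplicated(out$sample)][1L],
         call. = FALSE)
  }
  class(out) <- c("clinical_table", "data.frame")
  out
}

match_level <- function(x, levels, sample) {
  hit <- levels[match(tolower(x), tolower(levels))]
  if (is.na(hit)) {
    stop(sprintf("unknown value '%s' for sample %s (expected one of %s)",
                 x, sample, paste(levels, collapse = "/")), call. = FALSE)
  }
  hit
}

parse_decimal <- function(x, sample, field) {
  v <- suppressWarnings(as.numeric(chartr(",", ".", x)))
  if (is.na(v)) {
    stop(sprintf("non-numeric %s '%s' for sample %s", field, x, sample),
         call. = FALSE)
  }
  v
}

parse_flag <- function(x, sample) {
  # "−" is the typographic minus occasionally found in typed tables.
  yes <- c("+", "yes", "true", "1")
  no <- c("-", "−", "no", "false", "0")
  lx <- tolower(x)
  if (lx %in% yes) return(TRUE)
  if (lx %in% no) return(FALSE)
  stop(sprintf("unknown pretreatment flag '%s' for sample %s", x, sample),
       call. = FALSE)
}

#' Descriptive summary of a clinical table
#'
#' Column means for age, event-free survival (EFS) and overall survival
#' (OVS); median follow-up (median of the OVS column, midpoint of the two
#' central values for even n); the male:female ratio; and per-state counts.
#'
#' @param records A `clinical_table` (see [read_clinical_table()]).
#' @return A list of class `clinical_summary` with elements `n`, `mean_age`,
#'   `mean_efs`, `mean_ovs`, `median_followup`, `male_to_female` (NA with a
#'   message when there are no females), `n_primary`, `n_recurrence`,
#'   `n_metastasis`.
#' @export
clinical_summary <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  n_f <- sum(records$sex == "F")
  mf <- if (n_f == 0L) {
    message("no female patients: male:female ratio undefined")
    NA_real_
  } else {
    sum(records$sex == "M") / n_f
  }
  structure(list(
    n = nrow(records),
    mean_age = mean(records$age),
    mean_efs = mean(records$efs),
    mean_ovs = mean(records$ovs),
    median_followup = stats::median(records$ovs),
    male_to_female = mf,
    n_primary = sum(records$state == "Primary"),
    n_recurrence = sum(records$state == "Recurrence"),
    n_metastasis = sum(records$state == "Metastasis")
  ), class = "clinical_summary")
}

#' @export
print.clinical_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "clinical summary (n = %d)\n",
    "  mean age        %.1f years\n",
    "  mean EFS        %.1f months\n",
    "  mean OVS        %.1f months\n",
    "  median follow-up %.1f months\n",
    "  male:female     %.2f\n",
    "  primary/recurrence/metastasis  %d/%d/%d\n"),
    x$n, x$mean_age, x$mean_efs, x$mean_ovs, x$median_followup,
    x$male_to_female, x$n_primary, x$n_recurrence, x$n_metastasis))
  invisible(x)
}

#' Derive survival time and event indicator for an endpoint
#'
#' Event reconstruction from the clinical columns: for overall survival (OVS)
#' the event is death (`status == "Dead"`); for event-free survival (EFS) the
#' event is death or any earlier event witnessed by `efs < ovs`. Patients
#' alive (NED/AWD) with `efs == ovs` are censored for both endpoints.
#'
#' @param records A `clinical_table`.
#' @param endpoint `"EFS"` or `"OVS"`.
#' @return Data frame with columns `sample`, `time` (months), `event`
#'   (logical).
#' @export
survival_endpoints <- function(records, endpoint = c("EFS", "OVS")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "OVS") {
    data.frame(sample = records$sample, time = records$ovs,
               event = records$status == "Dead", stringsAsFactors = FALSE)
  } else {
    data.frame(sample = records$sample, time = records$efs,
               event = records$status == "Dead" | records$efs < records$ovs,
               stringsAsFactors = FALSE)
  }
}
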