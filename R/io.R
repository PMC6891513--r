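# read a CSV or TSV, auto-detecting the delimiter from the header line
read_table_auto <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop(sprintf("%s: empty file", path))
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a peptide activity table
#'
#' Reads a CSV/TSV with `sequence` and `activity` columns (an optional row
#' number column, e.g. `no`, is kept if present so subsets can be selected).
#' Sequences are validated and canonicalized; row order is preserved.
#'
#' @param path File path. The bundled ORAC peptide database ships as
#'   `system.file("extdata", "orac_peptides.tsv", package = "pepqsar")`.
#' @return Data frame with columns `sequence` (canonical) and `activity`
#'   (plus `no` when present).
#' @export
read_activity_table <- function(path) {
  tab <- read_table_auto(path)
  names(tab) <- tolower(names(tab))
  if (!all(c("sequence", "activity") %in% names(tab))) {
    stop(sprintf("%s: need 'sequence' and 'activity' columns", path))
  }
  if (nrow(tab) == 0L) stop(sprintf("%s: no data rows", path))
  for (i in seq_len(nrow(tab))) {
    tab$sequence[i] <- tryCatch(
      validate_sequence(tab$sequence[i]),
      error = function(e) stop(sprintf("%s row %d: %s", path, i,
                                       conditionMessage(e)), call. = FALSE)
    )
    if (!is.finite(as.numeric(tab$activity[i]))) {
      stop(sprintf("%s row %d: non-numeric activity", path, i))
    }
  }
  tab$activity <- as.numeric(tab$activity)
  keep <- intersect(c("no", "sequence", "activity"), names(tab))
  tab[, keep, drop = FALSE]
}

#' The bundled ORAC peptide database
#'
#' Convenience accessor for the packaged peptide-activity table (26 short
#' hydrolysate peptides with ORAC-scale antioxidant activities, two of them
#' negative).
#'
#' @return Data frame with columns `no`, `sequence`, `activity`.
#' @export
orac_peptides <- function() {
  read_activity_table(system.file("extdata", "orac_peptides.tsv",
                                  package = "pepqsar"))
}

#' Read a candidate peptide list
#'
#' Accepts FASTA (detected by a leading `>`) or plain text with one sequence
#' per line. Order is preserved and duplicates are kept.
#'
#' @param path File path.
#' @return Character vector of canonical sequences.
#' @export
read_peptide_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("%s: empty peptide list", path))
  if (startsWith(trimws(lines[1]), ">")) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading FASTA requires the Biostrings package")
    }
    seqs <- as.character(Biostrings::readAAStringSet(path))
    ids <- names(seqs)
    out <- character(length(seqs))
    for (i in seq_along(seqs)) {
      out[i] <- tryCatch(
        validate_sequence(seqs[[i]]),
        error = function(e) stop(sprintf("%s record '%s': %s", path, ids[i],
                                         conditionMessage(e)), call. = FALSE)
      )
    }
    out
  } else {
    vapply(seq_along(lines), function(i) {
      tryCatch(validate_sequence(lines[i]),
               error = function(e) stop(sprintf("%s line %d: %s", path, i,
                                                conditionMessage(e)),
                                        call. = FALSE))
    }, character(1))
  }
}

#' Read per-residue composition from a table
#'
#' @param path CSV/TSV with a residue column followed by one or more numeric
#'   amount columns (e.g. total and free nmol/mg).
#' @param column Which amount column to use (name or index; default 2, the
#'   first amount column).
#' @return Named numeric vector suitable for [composition_profile()].
#' @export
read_composition_table <- function(path, column = 2L) {
  tab <- read_table_auto(path)
  amounts <- as.numeric(tab[[column]])
  if (anyNA(amounts)) stop(sprintf("%s: non-numeric amounts", path))
  names(amounts) <- as.character(tab[[1]])
  amounts
}

#' Read a fluorescence experiment from CSV/TSV
#'
#' Expected columns: `time`, `control`, and one column per dose with the dose
#' (mg/mL) as its header.
#'
#' @param path File path.
#' @return List with `times`, `control_curve`, `sample_curves`, `doses`.
#' @export
read_fluorescence_curves <- function(path) {
  tab <- read_table_auto(path)
  names(tab)[1:2] <- tolower(names(tab)[1:2])
  if (!all(c("time", "control") %in% names(tab)[1:2])) {
    stop(sprintf("%s: first two columns must be time, control", path))
  }
  dose_cols <- setdiff(names(tab), c("time", "control"))
  doses <- suppressWarnings(as.numeric(dose_cols))
  if (length(doses) == 0L || anyNA(doses)) {
    stop(sprintf("%s: dose columns must have numeric headers", path))
  }
  curves <- as.matrix(tab[, dose_cols, drop = FALSE])
  colnames(curves) <- dose_cols
  list(times = as.numeric(tab$time), control_curve = as.numeric(tab$control),
       sample_curves = curves, doses = doses)
}

#' Write a fluorescence experiment to TSV
#'
#' Inverse of [read_fluorescence_curves()].
#'
#' @param experiment List with `times`, `control_curve`, `sample_curves`.
#' @param path Output path.
#' @export
write_fluorescence_curves <- function(experiment, path) {
  tab <- data.frame(time = experiment$times, control = experiment$control_curve,
                    check.names = FALSE)
  tab <- cbind(tab, as.data.frame(experiment$sample_curves,
                                  check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a validation report, ranking, or dose-response fit to TSV
#'
#' Scalar summaries go into `# key: value` header comments followed by the
#' per-record table; output is deterministic (fixed column order, fixed
#' precision) so repeated runs are byte-identical.
#'
#' @param x A `validation_report`, a ranking data frame from
#'   [rank_peptides()], or a `dose_response`.
#' @param path Output path.
#' @param digits Number of significant digits for floats.
#' @export
write_report <- function(x, path, digits = 6) {
  fmt <- function(v) trimws(formatC(v, digits = digits, format = "g"))
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "validation_report")) {
    writeLines(c(
      sprintf("# seed: %d", x$seed),
      sprintf("# n_components: %d", x$n_components),
      sprintf("# r2_calibration: %s", fmt(x$r2_calibration)),
      sprintf("# q2_loo: %s", fmt(x$q2_loo)),
      sprintf("# rmse_calibration: %s", fmt(x$rmse_calibration)),
      sprintf("# rmse_prediction: %s", fmt(x$rmse_prediction)),
      sprintf("# pass_flag: %s", x$pass_flag)
    ), con)
    tab <- x$predictions
    tab$observed <- fmt(tab$observed)
    tab$predicted <- fmt(tab$predicted)
  } else if (inherits(x, "dose_response")) {
    writeLines(c(
      sprintf("# slope: %s", fmt(x$slope)),
      sprintf("# intercept: %s", fmt(x$intercept)),
      sprintf("# ec50: %s", fmt(x$ec50)),
      sprintf("# excluded: %s",
              if (length(x$excluded)) paste(x$excluded, collapse = ",") else "none")
    ), con)
    tab <- data.frame(dose = fmt(x$doses), caa = fmt(x$caa))
  } else if (is.data.frame(x) && "predicted_activity" %in% names(x)) {
    tab <- x
    tab$predicted_activity <- fmt(tab$predicted_activity)
  } else {
    stop("unsupported report object")
  }
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a ranking written by [write_report()]
#' @param path File path.
#' @return Data frame (sequence, predicted_activity, rank).
#' @export
read_ranking <- function(path) {
  tab <- read_table_auto(path)
  tab$predicted_activity <- as.numeric(tab$predicted_activity)
  tab$rank <- as.integer(tab$rank)
  tab
}
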