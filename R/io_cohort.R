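#' Construct a single-scan ROI time-series object
#'
#' A `ts_run` holds one resting-state scan's parcellated signal: a numeric
#' matrix with one row per time point (TR) and one column per parcel, plus
#' identifiers. This is the unit of analysis throughout the package; subjects
#' with multiple scans contribute multiple independent runs.
#'
#' @param data numeric T x C matrix, T >= 2 time points, C >= 1 channels.
#' @param subject_id,run_id character scalars identifying the scan.
#' @param site optional acquisition site label.
#' @param tr_seconds optional repetition time in seconds.
#' @param channel_labels optional length-C unique channel names; defaults to
#'   `roi_1..roi_C`.
#' @return an object of class `ts_run`.
#' @export
ts_run <- function(data, subject_id, run_id, site = NULL, tr_seconds = NULL,
                   channel_labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L) stop("degenerate input: a run needs at least 2 time points, got ", nrow(data))
  if (ncol(data) < 1L) stop("a run needs at least 1 channel")
  if (any(!is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value in run data at row %d, column %d", bad[1L], bad[2L]))
  }
  if (is.null(channel_labels))
    channel_labels <- colnames(data) %||% paste0("roi_", seq_len(ncol(data)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != ncol(data)) stop("channel_labels length must equal number of columns")
  if (anyDuplicated(channel_labels)) stop("channel_labels must be unique")
  if (!is.null(tr_seconds) && (!is_scalar_number(tr_seconds) || tr_seconds <= 0))
    stop("tr_seconds must be a positive number")
  colnames(data) <- channel_labels
  structure(
    list(subject_id = as.character(subject_id), run_id = as.character(run_id),
         site = if (is.null(site)) NA_character_ else as.character(site),
         tr_seconds = tr_seconds, data = data, channel_labels = channel_labels),
    class = "ts_run")
}

#' @export
print.ts_run <- function(x, ...) {
  cat(sprintf("<ts_run> subject=%s run=%s  T=%d x C=%d\n",
              x$subject_id, x$run_id, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' @export
dim.ts_run <- function(x) dim(x$data)

split_dialect <- function(lines, dialect) {
  switch(dialect,
         whitespace = strsplit(trimws(lines), "[ \t]+"),
         tsv = strsplit(lines, "\t", fixed = TRUE),
         csv = strsplit(lines, ",", fixed = TRUE),
         stop("unknown dialect: ", dialect))
}

detect_dialect <- function(line) {
  if (grepl(",", line, fixed = TRUE)) "csv"
  else if (grepl("\t", line, fixed = TRUE)) "tsv"
  else "whitespace"
}

#' Read an ROI time-course file
#'
#' Reads a plain-text matrix with rows = time points and columns = parcels,
#' the format produced by standard parcellation extraction tools. Lines
#' beginning with `#` are comments; a leading non-numeric row is taken as the
#' channel header, otherwise labels `roi_1..roi_C` are generated.
#'
#' @param path file path.
#' @param dialect `"auto"` (default; detected from the first data line),
#'   `"whitespace"`, `"tsv"` or `"csv"`.
#' @param subject_id,run_id identifiers for the resulting run; default to the
#'   file name without extension.
#' @inheritParams ts_run
#' @return a [ts_run].
#' @export
read_roi_timeseries <- function(path, dialect = c("auto", "whitespace", "tsv", "csv"),
                                subject_id = NULL, run_id = NULL,
                                site = NULL, tr_seconds = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  line_no <- which(keep) # original 1-based line numbers for error messages
  if (length(lines) < 2L) stop("degenerate input: fewer than 2 data rows in ", path)
  if (dialect == "auto") dialect <- detect_dialect(lines[[1L]])
  toks <- split_dialect(lines, dialect)
  widths <- lengths(toks)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[[1L]])[1L]
    stop(sprintf("ragged rows in %s: line %d has %d fields, expected %d",
                 path, line_no[bad], widths[bad], widths[1L]))
  }
  first <- suppressWarnings(as.numeric(toks[[1L]]))
  labels <- NULL
  if (anyNA(first)) { # header row
    labels <- trimws(toks[[1L]])
    toks <- toks[-1L]
    line_no <- line_no[-1L]
    if (length(toks) < 2L) stop("degenerate input: fewer than 2 data rows after header in ", path)
  }
  vals <- suppressWarnings(lapply(toks, as.numeric))
  for (i in seq_along(vals)) {
    if (anyNA(vals[[i]])) {
      j <- which(is.na(vals[[i]]))[1L]
      stop(sprintf("non-numeric cell in %s at line %d, field %d: '%s'",
                   path, line_no[i], j, toks[[i]][j]))
    }
  }
  mat <- do.call(rbind, vals)
  base <- sub("\\.[^.]*$", "", basename(path))
  ts_run(mat,
         subject_id = subject_id %||% base, run_id = run_id %||% base,
         site = site, tr_seconds = tr_seconds, channel_labels = labels)
}

#' Write an ROI time-course file
#'
#' Inverse of [read_roi_timeseries()]: writes the channel header and the data
#' matrix at full double precision, so that a read/write round trip reproduces
#' the matrix exactly.
#'
#' @param run a [ts_run].
#' @param path output path.
#' @param dialect one of `"whitespace"`, `"tsv"`, `"csv"`.
#' @param header write the channel-label header row (default TRUE).
#' @return `path`, invisibly.
#' @export
write_roi_timeseries <- function(run, path, dialect = c("whitespace", "tsv", "csv"),
                                 header = TRUE) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(run, "ts_run"))
  sep <- switch(dialect, whitespace = " ", tsv = "\t", csv = ",")
  rows <- apply(run$data, 1L, function(r) paste(sprintf("%.17g", r), collapse = sep))
  out <- c(if (header) paste(run$channel_labels, collapse = sep), rows)
  writeLines(out, path)
  invisible(path)
}

#' Z-score each channel of a run
#'
#' Standardizes every channel to mean 0 and unit sample standard deviation
#' (denominator T - 1). Runs are z-scored individually before any group-level
#' concatenation, so each scan contributes on a common scale regardless of
#' site or scanner gain.
#'
#' @param run a [ts_run].
#' @return a [ts_run] with standardized channels.
#' @export
zscore_run <- function(run) {
  stopifnot(inherits(run, "ts_run"))
  mu <- colMeans(run$data)
  s <- apply(run$data, 2L, sd)
  if (any(s == 0)) {
    bad <- run$channel_labels[s == 0]
    stop("constant channel(s) cannot be z-scored: ", paste(bad, collapse = ", "))
  }
  run$data <- sweep(sweep(run$data, 2L, mu, "-"), 2L, s, "/")
  colnames(run$data) <- run$channel_labels
  run
}

#' Read and validate a phenotype table
#'
#' Expects a CSV with columns `subject_id`, `run_id`, `sex` (`girl`/`boy`),
#' `dx` (`ADHD`/`control`) and optionally `age`, `subtype`, `site`.
#'
#' @param path CSV path.
#' @return validated phenotype `data.frame`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  validate_phenotypes(read.csv(path, stringsAsFactors = FALSE))
}

#' Validate a phenotype data frame
#'
#' @param df data frame with at least `subject_id`, `run_id`, `sex`, `dx`.
#' @return the validated data frame (character id columns, checked factors).
#' @export
validate_phenotypes <- function(df) {
  need <- c("subject_id", "run_id", "sex", "dx")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table missing column(s): ", paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  df$run_id <- as.character(df$run_id)
  if (anyDuplicated(df[c("subject_id", "run_id")]))
    stop("duplicate (subject_id, run_id) pairs in phenotype table")
  if (anyNA(df$sex) || !all(df$sex %in% SEX_LEVELS))
    stop("sex must be one of: ", paste(SEX_LEVELS, collapse = ", "))
  if (anyNA(df$dx) || !all(df$dx %in% DX_LEVELS))
    stop("dx must be one of: ", paste(DX_LEVELS, collapse = ", "))
  df
}

#' @rdname assemble_groups
#' @export
group_key <- function(sex, dx) paste(sex, dx, sep = "_")

#' Assemble per-group datasets from runs and phenotypes
#'
#' Partitions runs into the four sex-by-diagnosis groups and records, for each
#' group, the start/length boundaries of every run inside the group's
#' (conceptual) concatenation, so run identity is never lost downstream and
#' the Markov chain can be broken at scan boundaries during model fitting.
#'
#' @param runs list of [ts_run] objects (all sharing the same channels).
#' @param phenotypes validated phenotype data frame (see
#'   [validate_phenotypes()]).
#' @return named list of four `group_dataset` objects, keyed
#'   `girl_ADHD`, `boy_ADHD`, `girl_control`, `boy_control`. Each has fields
#'   `group_key`, `sex`, `dx`, `runs`, and a `boundaries` data frame
#'   (`run_id`, `start`, `length`) indexing the concatenated view.
#' @param sex,dx for `group_key()`: vectors of sex and diagnosis labels.
#' @export
assemble_groups <- function(runs, phenotypes) {
  phenotypes <- validate_phenotypes(phenotypes)
  stopifnot(length(runs) >= 1L, all(vapply(runs, inherits, logical(1), "ts_run")))
  C <- ncol(runs[[1L]]$data)
  for (r in runs) {
    if (ncol(r$data) != C)
      stop(sprintf("channel-count mismatch: run '%s' has %d channels, expected %d",
                   r$run_id, ncol(r$data), C))
  }
  key_pheno <- paste(phenotypes$subject_id, phenotypes$run_id, sep = "\r")
  key_runs <- vapply(runs, function(r) paste(r$subject_id, r$run_id, sep = "\r"), character(1))
  orphan <- !(key_runs %in% key_pheno)
  if (any(orphan)) {
    ids <- vapply(runs[orphan], function(r) sprintf("%s/%s", r$subject_id, r$run_id), character(1))
    stop("run(s) without phenotype row: ", paste(ids, collapse = ", "))
  }
  idx <- match(key_runs, key_pheno)
  gk <- group_key(phenotypes$sex[idx], phenotypes$dx[idx])
  out <- lapply(GROUP_LEVELS, function(g) {
    members <- runs[gk == g]
    lens <- vapply(members, function(r) nrow(r$data), integer(1))
    boundaries <- data.frame(
      run_id = vapply(members, `[[`, character(1), "run_id"),
      start = if (length(lens)) cumsum(c(1L, lens[-length(lens)])) else integer(0),
      length = lens, stringsAsFactors = FALSE)
    structure(list(group_key = g,
                   sex = strsplit(g, "_")[[1L]][1L],
                   dx = strsplit(g, "_")[[1L]][2L],
                   runs = members, boundaries = boundaries),
              class = "group_dataset")
  })
  names(out) <- GROUP_LEVELS
  out
}

#' Concatenated data matrix of a group dataset
#'
#' @param gd a `group_dataset` from [assemble_groups()].
#' @return the row-concatenated T_total x C matrix of all runs in the group.
#' @export
group_data <- function(gd) {
  stopifnot(inherits(gd, "group_dataset"))
  if (!length(gd$runs)) stop("group ", gd$group_key, " has no runs")
  do.call(rbind, lapply(gd$runs, `[[`, "data"))
}

#' @export
print.group_dataset <- function(x, ...) {
  cat(sprintf("<group_dataset> %s: %d runs, %d time points\n",
              x$group_key, nrow(x$boundaries), sum(x$boundaries$length)))
  invisible(x)
}
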