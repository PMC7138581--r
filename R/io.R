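#' Regional time-series panel
#'
#' One subject's regions x time matrix of BOLD-like signal. Region order is
#' the canonical node order for every downstream matrix and graph.
#'
#' @param values numeric matrix, regions in rows, time points in columns.
#' @param region_labels character vector of region names; synthesized as
#'   `R001..RNNN` when `NULL`.
#' @param subject_id subject identifier.
#' @param tr_seconds repetition time of the series.
#' @return An object of class `timeseries_panel`.
#' @export
timeseries_panel <- function(values, region_labels = NULL,
                             subject_id = "unknown", tr_seconds = 2.0) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("panel needs at least 2 regions and 2 time points", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("panel values must all be finite", call. = FALSE)
  }
  if (is.null(region_labels)) {
    region_labels <- default_labels(nrow(values))
  }
  if (length(region_labels) != nrow(values)) {
    stop("region_labels length must equal the number of rows", call. = FALSE)
  }
  rownames(values) <- region_labels
  structure(list(subject_id = subject_id,
                 region_labels = as.character(region_labels),
                 values = values,
                 tr_seconds = tr_seconds),
            class = "timeseries_panel")
}

default_labels <- function(n) sprintf("R%03d", seq_len(n))

#' @export
print.timeseries_panel <- function(x, ...) {
  cat(sprintf("<timeseries_panel> subject %s: %d regions x %d volumes, TR %g s\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a regional time-series file
#'
#' Delimited text (TSV default, CSV by extension): rows are regions, columns
#' are time points, all cells numeric. An optional leading comment line
#' `#regions<sep>lab1<sep>lab2...` carries region labels; otherwise labels
#' `R001..RNNN` are synthesized.
#'
#' @param path file to read.
#' @param subject_id subject id to attach (defaults to the file stem).
#' @param tr_seconds repetition time to attach.
#' @return A [timeseries_panel()].
#' @export
read_timeseries <- function(path, subject_id = NULL, tr_seconds = 2.0) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  sep <- delim_for(path)
  lines <- readLines(path)
  labels <- NULL
  if (length(lines) && startsWith(lines[[1]], "#regions")) {
    labels <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]][-1]
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty time-series file: ", path, call. = FALSE)
  fields <- strsplit(lines, sep, fixed = TRUE)
  width <- length(fields[[1]])
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) != width) {
      stop(sprintf("ragged time-series file %s: row %d has %d fields, expected %d",
                   path, i, length(fields[[i]]), width), call. = FALSE)
    }
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), nrow = length(fields), byrow = TRUE))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d, column %d of %s",
                 bad[1], bad[2], path), call. = FALSE)
  }
  if (nrow(vals) < 2L || ncol(vals) < 2L) {
    stop(sprintf("%s: need at least 2 regions and 2 time points (got %d x %d)",
                 path, nrow(vals), ncol(vals)), call. = FALSE)
  }
  timeseries_panel(vals, region_labels = labels, subject_id = subject_id,
                   tr_seconds = tr_seconds)
}

#' Write a regional time-series file
#'
#' Inverse of [read_timeseries()]; values are written with 17 significant
#' digits so a round-trip reproduces them exactly.
#'
#' @param panel a [timeseries_panel()].
#' @param path destination path (`.csv` switches to comma delimiter).
#' @export
write_timeseries <- function(panel, path) {
  stopifnot(inherits(panel, "timeseries_panel"))
  sep <- delim_for(path)
  header <- paste(c("#regions", panel$region_labels), collapse = sep)
  body <- apply(panel$values, 1L,
                function(row) paste(sprintf("%.17g", row), collapse = sep))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a subject manifest
#'
#' Delimited text with a header; required columns `subject_id` and `group`
#' (values normalized case-insensitively to `patient`/`control`), optional
#' clinical columns (`age`, `sex`, `education`, `duration`, `acth`, `ufc`,
#' `cortisol_0am`, `cortisol_4pm`, `cortisol_8am`). Blank optional cells
#' become `NA` and are dropped pairwise in correlation analyses.
#'
#' @param path manifest file.
#' @return A `data.frame` with class `subject_manifest`, one row per subject.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = delim_for(path),
                   stringsAsFactors = FALSE, na.strings = c("", "NA"))
  req <- c("subject_id", "group")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("manifest missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  as_manifest(df)
}

#' Coerce a data frame to a subject manifest
#'
#' @param df data frame with at least `subject_id` and `group` columns.
#' @return The validated manifest (class `subject_manifest`).
#' @export
as_manifest <- function(df) {
  df$subject_id <- as.character(df$subject_id)
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup)) {
    stop("duplicate subject_id in manifest: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  grp <- tolower(trimws(as.character(df$group)))
  ok <- grp %in% c("patient", "control")
  if (any(!ok)) {
    stop("unknown group label(s): ",
         paste(unique(df$group[!ok]), collapse = ", "),
         " (admissible: patient, control)", call. = FALSE)
  }
  df$group <- grp
  class(df) <- c("subject_manifest", "data.frame")
  df
}

#' Write a subject manifest
#' @param manifest a manifest data frame.
#' @param path destination path.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = delim_for(path), quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Write a labelled square matrix (connectivity or adjacency)
#'
#' Header row and first column carry region labels; numeric cells use 17
#' significant digits for exact round-trips.
#'
#' @param m numeric matrix with identical row/column labels.
#' @param path destination path.
#' @export
write_matrix <- function(m, path) {
  sep <- delim_for(path)
  labels <- rownames(m)
  if (is.null(labels)) labels <- default_labels(nrow(m))
  header <- paste(c("region", labels), collapse = sep)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(labels[i], sprintf("%.17g", m[i, ])), collapse = sep)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a labelled square matrix written by [write_matrix()]
#' @param path file to read.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  sep <- delim_for(path)
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  colnames(m) <- rownames(m)
  m
}

write_tidy <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- sprintf("%.17g", df[[j]])
  write.table(out, path, sep = delim_for(path), quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}
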