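#' Labelled time-series dataset
#'
#' Container for a fixed-length collection of univariate time series with
#' integer class labels, the unit every other function in the package
#' consumes. Rows are instances, columns time stamps.
#'
#' @param series numeric matrix, N instances by T time stamps. No missing
#'   values are allowed.
#' @param labels integer-valued vector of length N. Arbitrary integer codes
#'   (e.g. -1/1) are accepted; they are kept verbatim and a stable sorted
#'   level set is stored for internal 1..C coding.
#' @param name free-text dataset identifier. Normalization statistics carry
#'   this name as their `source` so that test-set normalization can be checked
#'   against the paired training set.
#' @param role `"train"` or `"test"`.
#'
#' @return An object of class `shapaal_dataset`: a list with elements
#'   `series`, `labels`, `label_levels`, `name`, `role`, and convenience
#'   counts `n`, `len`, `n_classes`.
#' @export
ts_dataset <- function(series, labels, name = "dataset", role = c("train", "test")) {
  role <- match.arg(role)
  if (!is.matrix(series)) series <- as.matrix(series)
  storage.mode(series) <- "double"
  if (nrow(series) < 1L) stop("empty dataset: N must be >= 1", call. = FALSE)
  if (ncol(series) < 2L) stop("series length T must be >= 2", call. = FALSE)
  if (anyNA(series) || any(!is.finite(series)))
    stop("series contain missing or non-finite values", call. = FALSE)
  if (length(labels) != nrow(series))
    stop("labels length (", length(labels), ") does not match N (", nrow(series), ")",
         call. = FALSE)
  if (any(labels != round(labels)))
    stop("labels must be integer-valued", call. = FALSE)
  labels <- as.integer(labels)
  levels <- sort(unique(labels))
  structure(
    list(series = series, labels = labels, label_levels = levels,
         name = name, role = role,
         n = nrow(series), len = ncol(series), n_classes = length(levels)),
    class = "shapaal_dataset")
}

#' @export
print.shapaal_dataset <- function(x, ...) {
  cat(sprintf("<shapaal_dataset '%s' (%s): N=%d, T=%d, C=%d, labels={%s}>\n",
              x$name, x$role, x$n, x$len, x$n_classes,
              paste(x$label_levels, collapse = ",")))
  invisible(x)
}

# internal 1..C coding of the stored labels
internal_labels <- function(dataset) {
  match(dataset$labels, dataset$label_levels)
}

# row subset preserving the full label level set (a subset of a C-class
# problem is still a C-class problem for the classifier head)
subset_dataset <- function(dataset, idx, name = dataset$name) {
  out <- ts_dataset(dataset$series[idx, , drop = FALSE], dataset$labels[idx],
                    name = name, role = dataset$role)
  out$label_levels <- dataset$label_levels
  out$n_classes <- length(dataset$label_levels)
  out
}

#' Read a UCR-archive-dialect time-series file
#'
#' One instance per line: an integer class label followed by T real values.
#' Both tab- and comma-separated files occur in the archive; the separator is
#' auto-detected per file unless given.
#'
#' @param path path to the text file.
#' @param dialect `"auto"` (default), `"tab"` or `"comma"`.
#' @param name dataset identifier; defaults to the file name stripped of a
#'   trailing `_TRAIN`/`_TEST` marker and extension, so that a train/test pair
#'   shares one name.
#' @param role `"train"` or `"test"`; defaults from a `_TEST` file-name marker.
#'
#' @return A [ts_dataset()].
#' @export
read_ucr <- function(path, dialect = c("auto", "tab", "comma"), name = NULL, role = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty input file: ", path, call. = FALSE)
  sep <- switch(dialect,
                tab = "\t", comma = ",",
                auto = if (grepl(",", lines[[1]], fixed = TRUE)) "," else "\t")
  parts <- strsplit(lines, sep, fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens < 3L))
    stop("line ", which(lens < 3L)[1],
         ": expected a label followed by at least 2 values", call. = FALSE)
  if (length(unique(lens)) != 1L)
    stop("ragged rows: line ", which(lens != lens[1])[1],
         " has ", lens[which(lens != lens[1])[1]],
         " fields, expected ", lens[1], call. = FALSE)
  vals <- suppressWarnings(vapply(parts, function(p) as.numeric(p),
                                  numeric(lens[1])))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 2, any))[1]
    stop("line ", bad, ": non-numeric field", call. = FALSE)
  }
  vals <- t(vals)                       # rows = instances
  base <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  if (is.null(role))
    role <- if (grepl("_TEST$", base, ignore.case = TRUE)) "test" else "train"
  if (is.null(name)) name <- sub("_(TRAIN|TEST)$", "", base, ignore.case = TRUE)
  ts_dataset(vals[, -1, drop = FALSE], vals[, 1], name = name, role = role)
}

#' Write a dataset as a UCR-archive-dialect text file
#'
#' Values are printed with `%.17g` so a write/read cycle preserves doubles
#' exactly and a read/write cycle reproduces the file byte for byte.
#'
#' @param dataset a [ts_dataset()].
#' @param path output file path.
#' @param dialect `"tab"` (default) or `"comma"`.
#' @return `path`, invisibly.
#' @export
write_ucr <- function(dataset, path, dialect = c("tab", "comma")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(dataset, "shapaal_dataset"))
  if (dataset$n < 1L) stop("empty dataset: nothing to write", call. = FALSE)
  sep <- if (dialect == "tab") "\t" else ","
  rows <- vapply(seq_len(dataset$n), function(i) {
    paste(c(sprintf("%d", dataset$labels[i]),
            sprintf("%.17g", dataset$series[i, ])), collapse = sep)
  }, character(1))
  ok <- tryCatch({ writeLines(rows, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Pooled z-normalization statistics of a training set
#'
#' A single mean and a single standard deviation pooled over all N x T
#' entries of the training matrix (population convention, divide by N*T).
#' The same pair is later applied to the paired test set: test statistics are
#' never consulted.
#'
#' @param train a [ts_dataset()] with role `"train"`.
#' @param floor smallest admissible standard deviation; effectively constant
#'   data (std below the floor) is refused rather than silently divided.
#' @return An object of class `shapaal_norm_stats` with fields `mean`, `std`,
#'   `source` (the training-set name).
#' @export
compute_norm_stats <- function(train, floor = 1e-12) {
  stopifnot(inherits(train, "shapaal_dataset"))
  if (train$role != "train")
    stop("normalization statistics must come from a training set", call. = FALSE)
  x <- as.vector(train$series)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))            # population convention
  if (!is.finite(s) || s < floor)
    stop("degenerate scale: training matrix is (near-)constant, std = ", s,
         call. = FALSE)
  structure(list(mean = m, std = s, source = train$name),
            class = "shapaal_norm_stats")
}

#' @export
print.shapaal_norm_stats <- function(x, ...) {
  cat(sprintf("<norm stats from '%s': mean=%.6g, std=%.6g>\n",
              x$source, x$mean, x$std))
  invisible(x)
}

#' Apply z-normalization with carried-over training statistics
#'
#' Every entry is mapped to `(value - stats$mean) / stats$std`; labels are
#' untouched. Normalizing a test set requires statistics whose `source`
#' matches the dataset name, enforcing the train-to-test carry-over.
#'
#' @param dataset a [ts_dataset()].
#' @param stats a [compute_norm_stats()] result.
#' @param check_source set `FALSE` to bypass the paired-source check (e.g.
#'   when deliberately reusing statistics across synthetic replicates).
#' @return The normalized dataset.
#' @export
z_normalize <- function(dataset, stats, check_source = TRUE) {
  stopifnot(inherits(dataset, "shapaal_dataset"),
            inherits(stats, "shapaal_norm_stats"))
  if (check_source && dataset$role == "test" && !identical(stats$source, dataset$name))
    stop("test set '", dataset$name,
         "' must be normalized with its paired training statistics (got '",
         stats$source, "')", call. = FALSE)
  out <- dataset
  out$series <- (dataset$series - stats$mean) / stats$std
  out
}
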