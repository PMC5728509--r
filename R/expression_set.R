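#' Labeled expression set
#'
#' The package's central container: a numeric feature-by-sample expression
#' matrix together with one class label per sample. Columns are samples and
#' rows are features throughout the package, matching the column-sample
#' dictionary layout used by the classifier; file orientation is purely an
#' I/O concern handled by [read_expression_table()].
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#' @param labels Character vector (or coercible) with one class label per
#'   sample (column). Labels are treated as opaque strings; class order is
#'   order of first appearance.
#' @param feature_ids,sample_ids Row / column identifiers; default to the
#'   dimnames of `values`, or `F1..Fn` / `S1..Sn` when absent.
#' @return An object of class `expression_set` with fields `values`
#'   (dimnames set from the ids), `labels` and `class_names`.
#' @examples
#' m <- matrix(rnorm(12), nrow = 3)
#' es <- expression_set(m, labels = c("A", "A", "B", "B"))
#' es$class_names
#' @export
expression_set <- function(values, labels,
                           feature_ids = rownames(values),
                           sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (features x samples)")
  }
  labels <- as.character(labels)
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(values)))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(labels) != ncol(values)) {
    stop(sprintf("expected one label per sample: %d labels for %d samples",
                 length(labels), ncol(values)))
  }
  if (length(feature_ids) != nrow(values)) {
    stop("length(feature_ids) must equal nrow(values)")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length(sample_ids) must equal ncol(values)")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyNA(labels) || any(labels == "")) {
    bad <- sample_ids[is.na(labels) | labels == ""]
    stop("missing label for sample(s): ", paste(bad, collapse = ", "))
  }
  if (anyNA(values)) {
    stop("expression matrix contains missing values; ",
         "use na_action = \"impute_mean\" in read_expression_table() or clean the input")
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(
    list(values = values, labels = labels,
         class_names = unique(labels)),
    class = "expression_set"
  )
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d features x %d samples, %d classes (%s)\n",
              nrow(x$values), ncol(x$values), length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

n_samples <- function(x) ncol(x$values)
n_features <- function(x) nrow(x$values)

#' Subset an expression set by feature and/or sample index
#'
#' @param x An `expression_set`.
#' @param features,samples Integer or logical index vectors; `NULL` keeps all.
#' @return A new `expression_set`.
#' @export
subset_expression_set <- function(x, features = NULL, samples = NULL) {
  v <- x$values
  lab <- x$labels
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    lab <- lab[samples]
  }
  expression_set(v, labels = lab)
}

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a labeled expression matrix
#'
#' Reads delimited text (TSV/CSV, delimiter chosen by extension) or a
#' GCT v1.2-style matrix, returning the data in the internal
#' features-by-samples orientation regardless of how the file is laid out.
#'
#' For delimited files, the first column holds row identifiers and a header
#' row is required. With `orientation = "samples_as_rows"` the label for each
#' sample is taken from the column named by `label_source` (default
#' `"Label"`); with `features_as_rows`, `label_source` must be a path to a
#' side file (CLS or one plain label per line). GCT files carry no labels, so
#' `label_source` is a CLS path, defaulting to the `.gct` path with a `.cls`
#' extension.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"delimited"` or `"gct"`.
#' @param orientation Layout of a delimited file. Ignored for GCT, which is
#'   always features-by-samples.
#' @param label_source Label column name, or path to a label side file.
#' @param na_action `"error"` (default) rejects missing values;
#'   `"impute_mean"` replaces them by the per-feature mean.
#' @return An [expression_set()].
#' @export
read_expression_table <- function(path,
                                  format = c("auto", "delimited", "gct"),
                                  orientation = c("samples_as_rows", "features_as_rows"),
                                  label_source = "Label",
                                  na_action = c("error", "impute_mean")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "delimited"
  }
  if (format == "gct") {
    return(.read_gct(path, label_source, na_action))
  }

  tab <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  row_ids <- tab[[1L]]
  tab <- tab[, -1L, drop = FALSE]

  if (orientation == "samples_as_rows") {
    if (!(label_source %in% names(tab))) {
      stop("label column not found: ", label_source)
    }
    labels <- tab[[label_source]]
    missing_lab <- is.na(labels) | labels == ""
    if (any(missing_lab)) {
      stop("missing label for sample(s): ",
           paste(row_ids[missing_lab], collapse = ", "))
    }
    tab <- tab[, setdiff(names(tab), label_source), drop = FALSE]
    vals <- .parse_numeric_cells(tab, row_ids)
    es_vals <- .handle_na(t(vals), na_action)  # to features x samples
    expression_set(es_vals, labels = labels)
  } else {
    if (!file.exists(label_source)) {
      stop("with features_as_rows, label_source must be a label side file; not found: ",
           label_source)
    }
    vals <- .parse_numeric_cells(tab, row_ids)
    labels <- .read_labels_file(label_source, n = ncol(vals))
    dimnames(vals) <- list(row_ids, colnames(tab))
    vals <- .handle_na(vals, na_action)
    expression_set(vals, labels = labels)
  }
}

# parse a character data.frame cell-wise, reporting coordinates of bad cells
.parse_numeric_cells <- function(tab, row_ids) {
  m <- matrix(NA_real_, nrow = nrow(tab), ncol = ncol(tab))
  for (j in seq_len(ncol(tab))) {
    cell <- tab[[j]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell) & cell != "" & toupper(cell) != "NA")
    if (length(bad)) {
      stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                   cell[bad[1L]], row_ids[bad[1L]], names(tab)[j]))
    }
    num[!is.na(cell) & cell == ""] <- NA_real_
    m[, j] <- num
  }
  colnames(m) <- names(tab)
  rownames(m) <- row_ids
  m
}

.handle_na <- function(values, na_action) {
  if (!anyNA(values)) return(values)
  if (na_action == "error") {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at feature '%s', sample '%s'",
                 rownames(values)[idx[1L]], colnames(values)[idx[2L]]))
  }
  for (i in seq_len(nrow(values))) {
    row <- values[i, ]
    if (anyNA(row)) {
      if (all(is.na(row))) stop("feature '", rownames(values)[i],
                                "' has no observed values; cannot impute")
      row[is.na(row)] <- mean(row, na.rm = TRUE)
      values[i, ] <- row
    }
  }
  values
}

.read_labels_file <- function(path, n) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) >= 3 && grepl("^\\s*\\d+\\s+\\d+\\s+1\\s*$", lines[1L])) {
    return(.parse_cls(lines, n))
  }
  labels <- trimws(lines)
  if (length(labels) == 1L) labels <- strsplit(labels, "\\s+")[[1L]]
  if (length(labels) != n) {
    stop(sprintf("label file has %d labels for %d samples", length(labels), n))
  }
  labels
}

# CLS: "<n> <K> 1" / "# name1 name2 ..." / space-separated labels or indices
.parse_cls <- function(lines, n) {
  header <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  names_line <- strsplit(trimws(sub("^#\\s*", "", lines[2L])), "\\s+")[[1L]]
  toks <- strsplit(trimws(lines[3L]), "\\s+")[[1L]]
  if (length(toks) != header[1L] || length(toks) != n) {
    stop(sprintf("CLS file declares %d samples, has %d tokens, expected %d",
                 header[1L], length(toks), n))
  }
  idx <- suppressWarnings(as.integer(toks))
  if (!anyNA(idx)) {
    # numeric codes index the declared class names, 0-based per convention
    if (min(idx) >= 1L && max(idx) <= length(names_line)) {
      offset <- 0L
    } else {
      offset <- 1L
    }
    names_line[idx + offset]
  } else {
    toks
  }
}

.read_gct <- function(path, label_source, na_action) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || !grepl("^#1\\.2", lines[1L])) {
    stop("not a GCT v1.2 file (missing #1.2 version line): ", path)
  }
  dims <- as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  tab <- utils::read.table(text = lines[-(1:2)], header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "")
  feature_ids <- tab[["Name"]]
  tab <- tab[, setdiff(names(tab), c("Name", "Description")), drop = FALSE]
  if (nrow(tab) != dims[1L] || ncol(tab) != dims[2L]) {
    stop(sprintf("GCT header declares %d x %d but body is %d x %d",
                 dims[1L], dims[2L], nrow(tab), ncol(tab)))
  }
  vals <- .parse_numeric_cells(tab, feature_ids)
  dimnames(vals) <- list(feature_ids, names(tab))
  vals <- .handle_na(vals, na_action)
  if (identical(label_source, "Label")) {
    label_source <- sub("\\.gct$", ".cls", path, ignore.case = TRUE)
  }
  if (!file.exists(label_source)) {
    stop("GCT carries no labels; CLS side file not found: ", label_source)
  }
  labels <- .read_labels_file(label_source, n = ncol(vals))
  expression_set(vals, labels = labels)
}

#' Write a labeled expression matrix
#'
#' The delimited format writes samples as rows (id column first, one column
#' per feature, final `Label` column). The GCT format writes a v1.2 matrix
#' plus a CLS label side file at the same path with a `.cls` extension.
#' Values are printed with 17 significant digits so a write/read round trip
#' reproduces every cell exactly.
#'
#' @param data An [expression_set()].
#' @param path Output file.
#' @param format `"delimited"` or `"gct"`.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(data, path, format = c("delimited", "gct")) {
  format <- match.arg(format)
  stopifnot(inherits(data, "expression_set"))
  if (ncol(data$values) == 0L) stop("refusing to write an expression set with no samples")
  if (!dir.exists(dirname(path))) stop("unwritable path (no such directory): ", path)
  fmt_num <- function(x) sprintf("%.17g", x)
  if (format == "delimited") {
    sep <- .delim_for(path)
    chr <- apply(data$values, c(1, 2), fmt_num)  # features x samples
    out <- cbind(sample_id = colnames(data$values), t(chr),
                 Label = data$labels)
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    chr <- apply(data$values, c(1, 2), fmt_num)
    body <- cbind(Name = rownames(data$values),
                  Description = rownames(data$values), chr)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2",
                 paste(nrow(data$values), ncol(data$values), sep = "\t")), con)
    utils::write.table(body, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    cls_path <- sub("\\.gct$", ".cls", path, ignore.case = TRUE)
    if (identical(cls_path, path)) cls_path <- paste0(path, ".cls")
    .write_cls(data$labels, cls_path)
  }
  invisible(path)
}

.write_cls <- function(labels, path) {
  classes <- unique(labels)
  writeLines(c(paste(length(labels), length(classes), 1),
               paste("#", paste(classes, collapse = " ")),
               paste(match(labels, classes) - 1L, collapse = " ")),
             path)
  invisible(path)
}
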