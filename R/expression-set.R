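#' Labeled expression study
#'
#' The universal input container of the package: a gene-by-sample matrix of
#' log2 expression values together with a binary group label per sample
#' (control = 0, case = 1). Case (here: lesional / diseased skin) is always
#' the ROC-positive class.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique rownames (gene ids) and colnames (sample ids). Values are assumed
#'   to be on the log2 scale already; see `log2_transform`.
#' @param labels Integer (0 = control, 1 = case) or character
#'   (`"control"`/`"case"`) vector. If named, names must cover the sample ids
#'   and are used to align labels to matrix columns; if unnamed, the vector
#'   must be in column order.
#' @param dedup Policy for duplicated gene ids: `"max_var"` keeps the row
#'   with the highest variance across samples (the common microarray
#'   probe-collapse rule) and warns; `"error"` refuses.
#' @param impute_median Replace missing values in a gene row by that row's
#'   median. Default `FALSE`: missing values are rejected.
#' @param log2_transform Apply `log2(x + 1)` for raw-scale input matrices.
#' @return An object of class `expr_study`: a list with elements `values`
#'   (validated matrix) and `labels` (named integer 0/1 vector in column
#'   order).
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' es <- expression_study(m, c(0, 0, 1, 1))
#' es
#' @export
expression_study <- function(values, labels,
                             dedup = c("max_var", "error"),
                             impute_median = FALSE,
                             log2_transform = FALSE) {
  dedup <- match.arg(dedup)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L)
    stop("degenerate input: expression matrix has no genes", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)

  labels <- normalize_labels(labels, colnames(values))

  if (anyDuplicated(rownames(values))) {
    if (dedup == "error")
      stop("duplicated gene ids: ",
           paste(unique(rownames(values)[duplicated(rownames(values))]),
                 collapse = ", "), call. = FALSE)
    values <- collapse_duplicate_genes(values)
  }

  if (log2_transform) {
    if (any(values < 0, na.rm = TRUE))
      stop("negative values are incompatible with log2(x + 1) transform",
           call. = FALSE)
    values <- log2(values + 1)
  }

  if (anyNA(values)) {
    if (!impute_median) {
      bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "missing value at gene '%s', sample '%s' (set impute_median = TRUE to impute row medians)",
        rownames(values)[bad[1L]], colnames(values)[bad[2L]]), call. = FALSE)
    }
    for (i in which(rowSums(is.na(values)) > 0L)) {
      med <- stats::median(values[i, ], na.rm = TRUE)
      if (!is.finite(med))
        stop(sprintf("gene '%s' has no observed values to impute from",
                     rownames(values)[i]), call. = FALSE)
      values[i, is.na(values[i, ])] <- med
    }
  }

  if (sum(labels == 0L) < 2L || sum(labels == 1L) < 2L)
    stop("degenerate design: need at least 2 samples in each of the ",
         "case and control groups", call. = FALSE)

  structure(list(values = values, labels = labels), class = "expr_study")
}

# Map label input to a named integer 0/1 vector aligned to sample_ids.
normalize_labels <- function(labels, sample_ids) {
  if (is.factor(labels)) labels <- as.character(labels)
  nm <- names(labels)
  if (is.character(labels)) {
    ok <- labels %in% c("case", "control")
    if (!all(ok))
      stop("labels must be 'case' or 'control'; got: ",
           paste(unique(labels[!ok]), collapse = ", "), call. = FALSE)
    labels <- ifelse(labels == "case", 1L, 0L)
  }
  if (!all(labels %in% c(0, 1)))
    stop("numeric labels must be 0 (control) or 1 (case)", call. = FALSE)
  labels <- as.integer(labels)
  names(labels) <- nm
  if (!is.null(nm)) {
    missing <- setdiff(sample_ids, nm)
    if (length(missing) > 0L)
      stop("labeled-sample mismatch: no label for sample(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stop("labeled-sample mismatch: ", length(labels), " labels for ",
         length(sample_ids), " samples", call. = FALSE)
  }
  names(labels) <- sample_ids
  labels
}

# Keep, per duplicated gene id, the row with the highest variance across
# samples (ties: first occurrence). Each collapse is reported in a warning.
collapse_duplicate_genes <- function(values) {
  ids <- rownames(values)
  dup_ids <- unique(ids[duplicated(ids)])
  keep <- rep(TRUE, nrow(values))
  for (g in dup_ids) {
    rows <- which(ids == g)
    v <- apply(values[rows, , drop = FALSE], 1L, stats::var)
    keep[rows[-which.max(v)]] <- FALSE
  }
  warning("collapsed duplicated gene id(s) to the highest-variance row: ",
          paste(dup_ids, collapse = ", "), call. = FALSE)
  values[keep, , drop = FALSE]
}

#' @export
print.expr_study <- function(x, ...) {
  cat(sprintf("expr_study: %d genes x %d samples (%d case / %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' @rdname expression_study
#' @param es An `expr_study` object.
#' @export
n_genes <- function(es) nrow(es$values)

#' @rdname expression_study
#' @export
gene_ids <- function(es) rownames(es$values)

#' @rdname expression_study
#' @export
sample_ids <- function(es) colnames(es$values)

# labels as a factor with control first — the level order used for the
# random forest and per-class error curves
label_factor <- function(es) {
  factor(ifelse(es$labels == 1L, "case", "control"),
         levels = c("control", "case"))
}

#' Read a labeled expression study from TSV files
#'
#' The matrix file is tab-separated with a header row of sample ids and a
#' first column of gene ids (GEO series-matrix style); the labels file has
#' two columns, `sample_id` and `group` (`case` or `control`). Every sample
#' in the matrix must be labeled.
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param labels_path Path to the two-column labels TSV.
#' @inheritParams expression_study
#' @return An [expression_study()] object.
#' @export
read_expression_set <- function(matrix_path, labels_path,
                                dedup = c("max_var", "error"),
                                impute_median = FALSE,
                                log2_transform = FALSE) {
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("expression matrix needs a gene id column plus at least one sample",
         call. = FALSE)
  ids <- raw[[1L]]
  num <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(ids, colnames(raw)[-1L]))
  was_na <- matrix(
    vapply(raw[-1L], function(col) is.na(col) | col %in% c("", "NA"),
           logical(nrow(raw))), nrow = nrow(raw))
  bad <- which(is.na(num) & !was_na, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell at gene '%s' (row %d), sample '%s': '%s'",
                 ids[bad[1L, 1L]], bad[1L, 1L],
                 colnames(num)[bad[1L, 2L]],
                 raw[bad[1L, 1L], bad[1L, 2L] + 1L]), call. = FALSE)

  lab <- utils::read.delim(labels_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(lab)))
    stop("labels file must have columns 'sample_id' and 'group'",
         call. = FALSE)
  labels <- stats::setNames(lab$group, lab$sample_id)

  expression_study(num, labels, dedup = dedup,
                   impute_median = impute_median,
                   log2_transform = log2_transform)
}

#' Write a labeled expression study to TSV files
#'
#' Values are serialized with `%.17g`, enough digits that
#' [read_expression_set()] reproduces the doubles bit-for-bit.
#'
#' @param es An `expr_study` object.
#' @param matrix_path,labels_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression_set <- function(es, matrix_path, labels_path) {
  stopifnot(inherits(es, "expr_study"))
  out <- matrix(sprintf("%.17g", es$values), nrow = nrow(es$values))
  lines <- c(paste(c("gene_id", sample_ids(es)), collapse = "\t"),
             paste(gene_ids(es), apply(out, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, matrix_path)
  lab <- data.frame(sample_id = sample_ids(es),
                    group = ifelse(es$labels == 1L, "case", "control"))
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, labels_path))
}
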