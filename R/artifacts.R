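# Writers for the pipeline's tab-separated artifacts. All writers are
# deterministic (fixed column order, fixed number formatting) so that
# reruns from the same configuration produce byte-identical files.

write_tsv <- function(df, path, digits = 15L) {
  num <- vapply(df, is.numeric, logical(1L)) & !vapply(df, is.integer, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.*g", digits, x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write / read a DEG table
#'
#' Columns: `gene_id  logFC  t  p_raw  p_adj  [direction]`.
#'
#' @param tab A `deg_table`.
#' @param path Output TSV path.
#' @export
write_deg_table <- function(tab, path) {
  cols <- intersect(c("gene_id", "logFC", "t", "p_raw", "p_adj", "direction"),
                    colnames(tab))
  write_tsv(tab[cols], path)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  class(tab) <- c("deg_table", "data.frame")
  tab
}

#' Write / read a signature gene set
#'
#' Columns: `rank  gene_id  importance  lfc_sign`.
#'
#' @param sig A `signature_set`.
#' @param path Output TSV path.
#' @export
write_signature <- function(sig, path) {
  write_tsv(sig[c("rank", "gene_id", "importance", "lfc_sign")], path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  sig <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  sig$lfc_sign <- as.integer(sig$lfc_sign)
  class(sig) <- c("signature_set", "data.frame")
  sig
}

#' Write a gene score matrix and its audit sidecar
#'
#' The score matrix TSV has samples as rows and signature genes as columns;
#' the sidecar records each gene's median and fold-change sign plus the
#' median source.
#'
#' @param gsm A `gene_score_matrix`.
#' @param path Score matrix TSV path.
#' @param sidecar_path Optional sidecar TSV path.
#' @export
write_score_matrix <- function(gsm, path, sidecar_path = NULL) {
  df <- data.frame(sample_id = rownames(gsm$scores),
                   gsm$scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  if (!is.null(sidecar_path)) {
    write_tsv(data.frame(gene_id = names(gsm$medians),
                         median = as.numeric(gsm$medians),
                         lfc_sign = as.integer(gsm$lfc_sign),
                         median_source = gsm$median_source,
                         stringsAsFactors = FALSE),
              sidecar_path)
  }
  invisible(path)
}

#' Serialize / restore an ANN model as JSON
#'
#' Weights are stored at full precision together with the training
#' metadata.
#'
#' @param model An `ann_model`.
#' @param path JSON path.
#' @export
write_ann_model <- function(model, path) {
  jsonlite::write_json(list(
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    feature_names = model$feature_names, meta = model$meta),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ann_model
#' @export
read_ann_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    W1 = matrix(obj$W1, nrow = length(obj$b1)),
    b1 = as.numeric(obj$b1),
    W2 = matrix(obj$W2, nrow = 1L),
    b2 = as.numeric(obj$b2),
    feature_names = obj$feature_names,
    meta = as.list(obj$meta)), class = "ann_model")
}
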