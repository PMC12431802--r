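#' Fit a random forest on DEG expression
#'
#' Grows a 500-tree classification forest (case vs control) on the
#' continuous expression values of the supplied genes, with the standard
#' classification defaults (`mtry = floor(sqrt(p))`, unlimited depth,
#' minimum node size 1), via the randomForest package. Inbag records and
#' per-tree training-set predictions are kept so the out-of-bag error curve
#' can be recomputed exactly.
#'
#' @param es An [expression_study()], typically restricted to DEGs with
#'   [restrict_genes()].
#' @param n_trees Number of trees (default 500).
#' @param seed RNG seed; the fit is deterministic given the seed.
#' @return A `sig_forest` object wrapping the fitted forest, the inbag count
#'   matrix (samples x trees), the per-tree training predictions, and the
#'   true labels.
#' @export
fit_forest <- function(es, n_trees = 500L, seed = 1L) {
  stopifnot(inherits(es, "expr_study"))
  if (n_genes(es) < 1L)
    stop("need at least one gene to fit a forest", call. = FALSE)
  x <- t(es$values)
  y <- label_factor(es)
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = as.integer(n_trees),
    importance = TRUE, keep.inbag = TRUE, keep.forest = TRUE)
  per_tree <- stats::predict(rf, newdata = x, predict.all = TRUE)$individual
  structure(list(rf = rf, inbag = rf$inbag, per_tree = per_tree,
                 labels = y, n_trees = as.integer(n_trees),
                 seed = as.integer(seed)),
            class = "sig_forest")
}

#' Restrict a study to a gene subset
#'
#' @param es An [expression_study()].
#' @param genes Character vector of gene ids (order preserved).
#' @return The restricted study.
#' @export
restrict_genes <- function(es, genes) {
  stopifnot(inherits(es, "expr_study"))
  missing <- setdiff(genes, gene_ids(es))
  if (length(missing) > 0L)
    stop("gene(s) absent from the study: ",
         paste(missing, collapse = ", "), call. = FALSE)
  expression_study(es$values[genes, , drop = FALSE], es$labels)
}

#' Out-of-bag error curve
#'
#' For each tree count t = 1..B, classifies every sample by the majority
#' vote of those of the first t trees in which the sample was out of bag,
#' and reports the misclassification rate overall and per class. Samples
#' never out of bag within the first t trees are excluded from that t's
#' denominator. Vote ties are resolved toward "control" (the first factor
#' level), a fixed, documented policy.
#'
#' @param forest A `sig_forest` from [fit_forest()].
#' @return A `forest_error_curve` data frame with columns `trees`,
#'   `error_overall`, `error_control`, `error_case`.
#' @export
oob_error_curve <- function(forest) {
  stopifnot(inherits(forest, "sig_forest"))
  oob <- forest$inbag == 0L                     # samples x trees
  is_case_vote <- forest$per_tree == "case"     # samples x trees
  case_votes <- t(apply(oob & is_case_vote, 1L, cumsum))
  total_votes <- t(apply(oob, 1L, cumsum))
  if (forest$n_trees == 1L) {                   # apply drops to a vector
    case_votes <- matrix(case_votes, ncol = 1L)
    total_votes <- matrix(total_votes, ncol = 1L)
  }
  # majority vote; ties (case == control votes) go to "control"
  pred_case <- case_votes > total_votes / 2
  voted <- total_votes > 0L
  truth_case <- forest$labels == "case"
  err <- (pred_case != truth_case) & voted

  rate <- function(rows) {
    n <- colSums(voted[rows, , drop = FALSE])
    e <- colSums(err[rows, , drop = FALSE])
    ifelse(n > 0L, e / n, NA_real_)
  }
  out <- data.frame(trees = seq_len(forest$n_trees),
                    error_overall = rate(rep(TRUE, length(truth_case))),
                    error_control = rate(!truth_case),
                    error_case = rate(truth_case))
  class(out) <- c("forest_error_curve", "data.frame")
  out
}

#' Error-minimizing tree count
#'
#' The smallest tree count achieving the minimum overall out-of-bag error
#' (ties broken toward fewer trees). Reported as a diagnostic; the full
#' forest is used for importance ranking.
#'
#' @param curve A `forest_error_curve`.
#' @return Integer tree count.
#' @export
optimal_tree_count <- function(curve) {
  stopifnot(inherits(curve, "forest_error_curve"), nrow(curve) > 0L)
  curve$trees[which.min(curve$error_overall)]
}

#' Rank genes by forest importance
#'
#' Mean decrease in Gini impurity (default — what the randomForest error
#' plot shows without arguments) or mean decrease in out-of-bag permutation
#' accuracy. Stable descending sort; importance ties are broken
#' lexicographically by gene id.
#'
#' @param forest A `sig_forest`.
#' @param measure `"gini"` or `"permutation"`.
#' @return Data frame `gene_id`, `importance`, most important first.
#' @export
rank_importance <- function(forest, measure = c("gini", "permutation")) {
  stopifnot(inherits(forest, "sig_forest"))
  measure <- match.arg(measure)
  imp <- randomForest::importance(
    forest$rf,
    type = if (measure == "gini") 2L else 1L,
    scale = FALSE)
  tab <- data.frame(gene_id = rownames(imp), importance = imp[, 1L],
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$importance, tab$gene_id), ]
  rownames(tab) <- NULL
  tab
}

#' Extract the top-k signature gene set
#'
#' The first k genes of an importance ranking, with the sign of each gene's
#' training logFC attached from the DEG table (needed downstream by the
#' gene-score rule).
#'
#' @param ranking Output of [rank_importance()].
#' @param deg_table A `deg_table` covering every ranked gene.
#' @param k Signature size (default 30).
#' @return A `signature_set` data frame: `rank`, `gene_id`, `importance`,
#'   `lfc_sign` (+1 / -1).
#' @export
top_k_signature <- function(ranking, deg_table, k = 30L) {
  k <- as.integer(k)
  if (k < 1L)
    stop("k must be >= 1", call. = FALSE)
  if (k > nrow(ranking))
    stop("requested k = ", k, " signature genes but only ", nrow(ranking),
         " ranked genes are available", call. = FALSE)
  top <- ranking[seq_len(k), , drop = FALSE]
  idx <- match(top$gene_id, deg_table$gene_id)
  if (anyNA(idx))
    stop("ranked gene(s) absent from the DEG table: ",
         paste(top$gene_id[is.na(idx)], collapse = ", "), call. = FALSE)
  out <- data.frame(rank = seq_len(k), gene_id = top$gene_id,
                    importance = top$importance,
                    lfc_sign = ifelse(deg_table$logFC[idx] >= 0, 1L, -1L),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("signature_set", "data.frame")
  out
}
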