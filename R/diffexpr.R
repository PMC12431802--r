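#' Per-gene log2 fold change
#'
#' `logFC_g = mean(case) - mean(control)` on log2-scale expression, the limma
#' convention for a two-group comparison.
#'
#' @param es An [expression_study()].
#' @return Named numeric vector, one entry per gene.
#' @export
log_fold_change <- function(es) {
  stopifnot(inherits(es, "expr_study"))
  case <- es$labels == 1L
  rowMeans(es$values[, case, drop = FALSE]) -
    rowMeans(es$values[, !case, drop = FALSE])
}

#' Two-group differential expression statistics
#'
#' Computes per-gene logFC, t-statistic, degrees of freedom, raw two-sided
#' p-value and Benjamini-Hochberg adjusted p-value, sorted by raw p (stable).
#'
#' Methods:
#' \describe{
#'   \item{pooled}{classical two-sample t with pooled variance, df = n - 2.}
#'   \item{welch}{Welch statistic with Satterthwaite df.}
#'   \item{moderated}{empirical-Bayes moderated t: per-gene pooled residual
#'     variances are shrunk toward a prior `s0^2` with prior df `d0`
#'     estimated from the marginal distribution of the variances by the
#'     method of moments on log variances with trigamma inversion; the
#'     statistic uses the shrunken variance and df `d0 + (n - 2)`.}
#' }
#'
#' Genes with zero variance in both groups are uninformative under all three
#' methods: their t is `NA`, p is set to 1, and they are flagged in the
#' `zero_var` column (and thereby excluded by [select_degs()]).
#'
#' @param es An [expression_study()].
#' @param method `"moderated"` (default), `"welch"`, or `"pooled"`.
#' @param prior_df Moderated method only: override the estimated prior df
#'   `d0`. `prior_df = 0` disables shrinkage (moderated reduces exactly to
#'   pooled); `Inf` shrinks fully to the prior variance. `NULL` (default)
#'   estimates `d0` from the data.
#' @return A `deg_table` data frame with columns `gene_id`, `logFC`, `t`,
#'   `df`, `p_raw`, `p_adj`, `zero_var`, sorted by `p_raw` ascending, plus
#'   attributes `method`, `prior_df` (`d0`), and `prior_var` (`s0^2`) for
#'   the moderated method.
#' @export
de_test <- function(es, method = c("moderated", "welch", "pooled"),
                    prior_df = NULL) {
  stopifnot(inherits(es, "expr_study"))
  method <- match.arg(method)
  case <- es$labels == 1L
  n1 <- sum(!case)  # control
  n2 <- sum(case)   # case
  if (n1 < 2L || n2 < 2L)
    stop("degenerate design: need >= 2 samples per group", call. = FALSE)

  x1 <- es$values[, !case, drop = FALSE]
  x2 <- es$values[, case, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  lfc <- m2 - m1
  zero_var <- v1 == 0 & v2 == 0

  d0 <- NA_real_
  s0 <- NA_real_
  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tstat <- lfc / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  } else {
    s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    dg <- n1 + n2 - 2L
    if (method == "pooled") {
      tstat <- lfc / sqrt(s2 * (1 / n1 + 1 / n2))
      df <- rep(dg, length(lfc))
    } else {
      fit <- squeeze_var(s2[!zero_var], dg, prior_df = prior_df)
      d0 <- fit$prior_df
      s0 <- fit$prior_var
      s2_post <- s2
      s2_post[!zero_var] <- fit$var_post
      tstat <- lfc / sqrt(s2_post * (1 / n1 + 1 / n2))
      df <- rep(dg + d0, length(lfc))
    }
  }

  p <- 2 * stats::pt(-abs(tstat), df = df)
  tstat[zero_var] <- NA_real_
  p[zero_var] <- 1

  tab <- data.frame(gene_id = gene_ids(es), logFC = lfc, t = tstat,
                    df = df, p_raw = p, zero_var = zero_var,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab$p_adj <- bh_adjust(tab$p_raw)
  tab <- tab[order(tab$p_raw), c("gene_id", "logFC", "t", "df",
                                 "p_raw", "p_adj", "zero_var")]
  rownames(tab) <- NULL
  attr(tab, "method") <- method
  attr(tab, "prior_df") <- d0
  attr(tab, "prior_var") <- s0
  class(tab) <- c("deg_table", "data.frame")
  tab
}

# Empirical-Bayes variance shrinkage: fit a scaled inverse-chi-square prior
# (s0^2, d0) to the marginal distribution of sample variances s2 with df dg,
# by method of moments on e = log(s2) - digamma(dg/2) + log(dg/2):
#   E[e]   = log(s0^2) + digamma(d0/2) - log(d0/2)
#   Var[e] = trigamma(dg/2) + trigamma(d0/2)
# d0 comes from inverting the trigamma function; if the observed variance of
# e does not exceed trigamma(dg/2), the variances are consistent with a
# single common value and d0 = Inf (full shrinkage).
squeeze_var <- function(s2, dg, prior_df = NULL) {
  if (any(s2 <= 0))
    stop("squeeze_var expects strictly positive variances", call. = FALSE)
  if (!is.null(prior_df) && prior_df == 0)
    return(list(prior_df = 0, prior_var = NA_real_, var_post = s2))
  if (length(s2) < 10L && is.null(prior_df)) {
    warning("fewer than 10 informative genes; falling back to no shrinkage ",
            "(pooled variances)", call. = FALSE)
    return(list(prior_df = 0, prior_var = NA_real_, var_post = s2))
  }
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  if (is.null(prior_df)) {
    evar <- stats::var(e) - trigamma(dg / 2)
    d0 <- if (evar > 0) 2 * trigamma_inverse(evar) else Inf
  } else {
    d0 <- prior_df
  }
  s0 <- if (is.finite(d0)) {
    exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    exp(mean(e))
  }
  var_post <- if (is.finite(d0)) (d0 * s0 + dg * s2) / (d0 + dg) else
    rep(s0, length(s2))
  list(prior_df = d0, prior_var = s0, var_post = var_post)
}

# Solve trigamma(y) = x for y > 0 by Newton iteration on 1/y (monotone,
# nearly linear there); asymptotic starts cover the extremes.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control (delegates to
#' [stats::p.adjust()] after validating the input range).
#'
#' @param p_raw Vector of raw p-values in (0, 1].
#' @return Adjusted p-values, elementwise >= input, clipped to 1.
#' @export
bh_adjust <- function(p_raw) {
  if (any(!is.finite(p_raw)) || any(p_raw <= 0) || any(p_raw > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p_raw, method = "BH")
}

#' Filter a DEG table by p-value and fold-change cut-offs
#'
#' Retains genes with (adjusted or raw) p strictly below `p_threshold` and
#' `|logFC|` strictly above `lfc_threshold`, and assigns a direction
#' (`up`/`down`) from the sign of logFC. Zero-variance-flagged genes never
#' pass (their p is 1).
#'
#' @param tab A `deg_table` from [de_test()].
#' @param p_threshold Default 0.05.
#' @param lfc_threshold Default 1.0.
#' @param use_adjusted Filter on `p_adj` (default, BH) rather than `p_raw`.
#' @return The filtered `deg_table` with an added `direction` column; empty
#'   (with a warning) if no gene passes.
#' @export
select_degs <- function(tab, p_threshold = 0.05, lfc_threshold = 1.0,
                        use_adjusted = TRUE) {
  stopifnot(inherits(tab, "deg_table"))
  if (p_threshold <= 0 || lfc_threshold <= 0)
    stop("thresholds must be positive", call. = FALSE)
  p <- if (use_adjusted) tab$p_adj else tab$p_raw
  keep <- p < p_threshold & abs(tab$logFC) > lfc_threshold
  out <- tab[keep, , drop = FALSE]
  out$direction <- ifelse(out$logFC > 0, "up", "down")
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("no genes pass the DEG filter (p < ", p_threshold,
            ", |logFC| > ", lfc_threshold, ")", call. = FALSE)
  class(out) <- c("deg_table", "data.frame")
  out
}
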