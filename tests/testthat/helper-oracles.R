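# Independent brute-force oracles and small fixture builders used across
# the suite. Each oracle recomputes a quantity by the most literal method
# available (explicit loops, textbook formulas, pair enumeration) with no
# code shared with the implementation it checks.

# Textbook pooled two-sample t, one gene at a time.
oracle_pooled_t <- function(es) {
  case <- es$labels == 1L
  t(vapply(seq_len(nrow(es$values)), function(i) {
    x2 <- es$values[i, case]
    x1 <- es$values[i, !case]
    sp2 <- ((length(x1) - 1) * var(x1) + (length(x2) - 1) * var(x2)) /
      (length(x1) + length(x2) - 2)
    tt <- (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / length(x1) + 1 / length(x2)))
    c(t = tt, p = 2 * pt(-abs(tt), df = length(x1) + length(x2) - 2))
  }, c(t = 0, p = 0)))
}

# Mann-Whitney AUC by exhaustive pair enumeration (ties count one half).
oracle_auc_pairs <- function(scores, labels) {
  case <- scores[labels == 1]
  ctrl <- scores[labels == 0]
  total <- 0
  for (a in case) for (b in ctrl)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(case) * length(ctrl))
}

# OOB error curve by explicit vote counting over the first t trees,
# sample by sample. Ties go to "control", matching the documented policy.
oracle_oob_curve <- function(forest) {
  B <- forest$n_trees
  n <- length(forest$labels)
  out <- data.frame(trees = seq_len(B), error_overall = NA_real_,
                    error_control = NA_real_, error_case = NA_real_)
  for (t in seq_len(B)) {
    pred <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      votes <- c(case = 0L, control = 0L)
      for (j in seq_len(t)) {
        if (forest$inbag[i, j] == 0L) {
          v <- forest$per_tree[i, j]
          votes[v] <- votes[v] + 1L
        }
      }
      if (sum(votes) > 0L)
        pred[i] <- if (votes["case"] > votes["control"]) "case" else "control"
    }
    truth <- as.character(forest$labels)
    rate <- function(sel) {
      have <- sel & !is.na(pred)
      if (!any(have)) NA_real_ else mean(pred[have] != truth[have])
    }
    out$error_overall[t] <- rate(rep(TRUE, n))
    out$error_control[t] <- rate(truth == "control")
    out$error_case[t] <- rate(truth == "case")
  }
  out
}

# Central finite-difference gradient of the ANN loss w.r.t. every
# parameter, flattened in the order (W1, b1, W2, b2).
oracle_fd_gradient <- function(model, X, y, loss, h = 1e-5) {
  get_par <- function(m) c(m$W1, m$b1, m$W2, m$b2)
  set_par <- function(m, v) {
    k <- length(m$W1)
    m$W1 <- matrix(v[seq_len(k)], nrow(m$W1))
    v <- v[-seq_len(k)]
    m$b1 <- v[seq_along(m$b1)]
    v <- v[-seq_along(m$b1)]
    m$W2 <- matrix(v[seq_len(length(m$W2))], 1L)
    m$b2 <- v[length(v)]
    m
  }
  theta <- get_par(model)
  g <- numeric(length(theta))
  loss_at <- function(v)
    sigscoreann:::ann_loss_grad(set_par(model, v), X, y, loss)$value
  for (i in seq_along(theta)) {
    up <- theta; up[i] <- up[i] + h
    dn <- theta; dn[i] <- dn[i] - h
    g[i] <- (loss_at(up) - loss_at(dn)) / (2 * h)
  }
  g
}

# Random small labeled study (continuous values) for property tests.
random_study <- function(n_genes = 8, n_case = 4, n_control = 4, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  m <- matrix(rnorm(n_genes * n, mean = 8, sd = 1.5), n_genes, n,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n))))
  expression_study(m, c(rep(0L, n_control), rep(1L, n_case)))
}

# Arbitrary signature over the first k genes of a study, alternating signs.
random_signature <- function(es, k = min(5L, n_genes(es))) {
  structure(data.frame(rank = seq_len(k),
                       gene_id = gene_ids(es)[seq_len(k)],
                       importance = rev(seq_len(k)) + 0,
                       lfc_sign = rep_len(c(1L, -1L), k),
                       stringsAsFactors = FALSE),
            class = c("signature_set", "data.frame"))
}
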