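test_that("logFC is case mean minus control mean, antisymmetric under label swap", {
  fx <- toy_fixture()
  lfc <- log_fold_change(fx$study)
  expect_equal(lfc, fx$expected$lfc)

  swapped <- expression_study(fx$study$values, 1L - fx$study$labels)
  expect_equal(log_fold_change(swapped), -lfc)
})

test_that("pooled t matches the textbook formula to 1e-12", {
  fx <- toy_fixture()
  tab <- de_test(fx$study, method = "pooled")
  ref <- oracle_pooled_t(fx$study)
  idx <- match(tab$gene_id, gene_ids(fx$study))
  informative <- !tab$zero_var
  expect_equal(tab$t[informative], unname(ref[idx, "t"])[informative],
               tolerance = 1e-12)
  expect_equal(tab$p_raw[informative], unname(ref[idx, "p"])[informative],
               tolerance = 1e-12)

  es <- random_study(n_genes = 40, seed = 8)
  tab <- de_test(es, method = "pooled")
  ref <- oracle_pooled_t(es)[match(tab$gene_id, gene_ids(es)), ]
  expect_equal(tab$t, unname(ref[, "t"]), tolerance = 1e-12)
})

test_that("welch matches t.test and preserves |t| and p under label swap", {
  es <- random_study(n_genes = 15, n_case = 4, n_control = 6, seed = 2)
  tab <- de_test(es, method = "welch")
  case <- es$labels == 1L
  for (g in tab$gene_id[1:5]) {
    ref <- t.test(es$values[g, case], es$values[g, !case])
    row <- tab[tab$gene_id == g, ]
    expect_equal(row$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(row$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(row$p_raw, ref$p.value, tolerance = 1e-12)
  }
  swapped <- de_test(expression_study(es$values, 1L - es$labels),
                     method = "welch")
  m <- match(tab$gene_id, swapped$gene_id)
  expect_equal(abs(tab$t), abs(swapped$t[m]), tolerance = 1e-12)
  expect_equal(tab$p_raw, swapped$p_raw[m], tolerance = 1e-12)
})

test_that("moderated t with no shrinkage (forced d0 = 0) reduces to pooled", {
  es <- random_study(n_genes = 30, seed = 4)
  mod <- de_test(es, method = "moderated", prior_df = 0)
  pool <- de_test(es, method = "pooled")
  m <- match(pool$gene_id, mod$gene_id)
  expect_equal(mod$t[m], pool$t, tolerance = 1e-12)
  expect_equal(mod$p_raw[m], pool$p_raw, tolerance = 1e-12)
})

test_that("identical per-gene variances give full shrinkage to a common variance", {
  # every gene has the same within-group residual pattern, so all sample
  # variances coincide; the prior df goes to Inf and every posterior
  # variance equals the common prior, making moderated t proportional to
  # pooled t with a shared constant
  resid <- c(-1, 0, 1, -1, 0, 1)
  m <- t(sapply(1:20, function(i) i / 3 + resid * 0.8 +
                  c(0, 0, 0, rep(i %% 3, 3))))
  dimnames(m) <- list(sprintf("g%02d", 1:20), sprintf("s%d", 1:6))
  es <- expression_study(m, c(0, 0, 0, 1, 1, 1))
  mod <- de_test(es, method = "moderated")
  pool <- de_test(es, method = "pooled")
  expect_identical(attr(mod, "prior_df"), Inf)
  idx <- match(pool$gene_id, mod$gene_id)
  ratio <- mod$t[idx] / pool$t
  ratio <- ratio[is.finite(ratio)]
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-10)
})

test_that("moderated statistics agree with the limma empirical-Bayes oracle", {
  skip_if_not_installed("limma")
  # heteroscedastic genes (true prior df 4) so the prior df estimate is
  # decidedly finite and both estimators work in their regular regime
  set.seed(13)
  ng <- 400
  sd_g <- 0.5 * sqrt(4 / rchisq(ng, df = 4))
  shift <- c(rep(2, 15), rep(-2, 15), rep(0, ng - 30))
  vals <- matrix(rnorm(ng * 12, mean = 8, sd = sd_g), ng, 12) +
    outer(shift, c(rep(0, 6), rep(1, 6)))
  dimnames(vals) <- list(sprintf("g%03d", 1:ng), sprintf("s%02d", 1:12))
  es <- expression_study(vals, c(rep(0L, 6), rep(1L, 6)))
  tab <- de_test(es, method = "moderated")

  design <- cbind(1, es$labels)
  fit <- limma::eBayes(limma::lmFit(es$values, design))
  idx <- match(tab$gene_id, rownames(es$values))
  expect_equal(tab$logFC, unname(fit$coefficients[idx, 2]), tolerance = 1e-10)
  expect_equal(attr(tab, "prior_df"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(tab, "prior_var"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(tab$t, unname(fit$t[idx, 2]), tolerance = 1e-6)
  expect_equal(tab$p_raw, unname(fit$p.value[idx, 2]), tolerance = 1e-6)
})

test_that("BH adjustment matches the hand-computed step-up and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")

  set.seed(31)
  p <- runif(200)^2
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("DEG filter uses strict inequalities and directions from logFC sign", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    logFC = c(1.0, 1.2, -1.5, 2.0),
                    t = 1:4, df = 4, p_raw = c(0.01, 0.01, 0.002, 0.049),
                    p_adj = c(0.01, 0.01, 0.002, 0.049),
                    zero_var = FALSE)
  class(tab) <- c("deg_table", "data.frame")
  out <- select_degs(tab)
  expect_identical(out$gene_id, c("b", "c", "d"))  # a: |logFC| not > 1
  expect_identical(out$direction, c("up", "down", "up"))

  tab$p_adj <- c(0.01, 0.05, 0.002, 0.049)         # b at the p boundary
  out <- select_degs(tab)
  expect_false("b" %in% out$gene_id)
  expect_warning(empty <- select_degs(tab, p_threshold = 1e-6), "no genes")
  expect_identical(nrow(empty), 0L)
})

test_that("the toy fixture yields exactly its two planted DEGs; zero-variance flagged", {
  fx <- toy_fixture()
  tab <- de_test(fx$study, method = "pooled")
  expect_true(tab$zero_var[tab$gene_id == "flat"])
  expect_equal(tab$p_raw[tab$gene_id == "flat"], 1)
  expect_true(is.na(tab$t[tab$gene_id == "flat"]))
  degs <- select_degs(tab)
  expect_setequal(degs$gene_id, fx$expected$deg_ids)
  expect_identical(degs$direction[degs$gene_id == "up1"], "up")
  expect_identical(degs$direction[degs$gene_id == "dn1"], "down")
})

test_that("DEG tables are sorted by raw p and p_adj dominates p_raw", {
  es <- random_study(n_genes = 60, seed = 17)
  for (method in c("pooled", "welch", "moderated")) {
    tab <- de_test(es, method = method)
    expect_true(!is.unsorted(tab$p_raw))
    expect_true(all(tab$p_adj >= tab$p_raw))
  }
})
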