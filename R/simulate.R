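#' Configuration for a synthetic two-group expression study
#'
#' Defaults emulate the study design the pipeline is built for: a training
#' cohort of 15 case (lesional) vs 15 control (nonlesional) skin samples on
#' log2 microarray intensities, with a planted set of differential genes
#' whose effect size (|logFC| = 2) clears the pipeline's |logFC| > 1 cut-off.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_case,n_control Samples per group (defaults 15 / 15).
#' @param n_de Number of planted differentially expressed genes (default 60).
#' @param frac_up Fraction of planted genes upregulated in case (default 0.5).
#' @param effect_lfc Planted absolute log2 fold change (default 2.0).
#' @param baseline_mean_range Range `(low, high)` of per-gene baseline means
#'   on the log2 scale (default `c(4, 12)`, typical array intensities).
#' @param noise_sd Per-gene residual standard deviation on the log2 scale
#'   (default 0.5).
#' @param seed RNG seed (Mersenne-Twister via [set.seed()]).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L, n_case = 15L, n_control = 15L,
                       n_de = 60L, frac_up = 0.5, effect_lfc = 2.0,
                       baseline_mean_range = c(4, 12), noise_sd = 0.5,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_case = as.integer(n_case),
              n_control = as.integer(n_control), n_de = as.integer(n_de),
              frac_up = frac_up, effect_lfc = effect_lfc,
              baseline_mean_range = as.numeric(baseline_mean_range),
              noise_sd = noise_sd, seed = as.integer(seed))
  with(cfg, {
    if (n_genes < 1L || n_de < 0L || n_de > n_genes)
      stop("config-validation: need 0 <= n_de <= n_genes", call. = FALSE)
    if (n_case < 2L || n_control < 2L)
      stop("config-validation: need >= 2 samples per group", call. = FALSE)
    if (frac_up < 0 || frac_up > 1)
      stop("config-validation: frac_up must be in [0, 1]", call. = FALSE)
    if (n_de > 0L && effect_lfc <= 0)
      stop("config-validation: effect_lfc must be > 0", call. = FALSE)
    if (noise_sd <= 0)
      stop("config-validation: noise_sd must be > 0", call. = FALSE)
    if (length(baseline_mean_range) != 2L ||
        diff(baseline_mean_range) < 0)
      stop("config-validation: baseline_mean_range must be (low, high)",
           call. = FALSE)
  })
  structure(cfg, class = "sim_config")
}

# Gene-level generative parameters (baseline means and true logFCs), drawn
# from the config seed only — shared between paired train/test cohorts.
sim_gene_params <- function(cfg) {
  set.seed(cfg$seed)
  ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  mu <- stats::runif(cfg$n_genes, cfg$baseline_mean_range[1L],
                     cfg$baseline_mean_range[2L])
  true_lfc <- numeric(cfg$n_genes)
  de_idx <- integer(0)
  if (cfg$n_de > 0L) {
    de_idx <- sort(sample.int(cfg$n_genes, cfg$n_de))
    n_up <- round(cfg$frac_up * cfg$n_de)
    signs <- rep(c(1, -1), c(n_up, cfg$n_de - n_up))
    true_lfc[de_idx] <- signs * cfg$effect_lfc
  }
  list(gene_ids = ids, mu = mu, true_lfc = true_lfc, de_idx = de_idx)
}

# One cohort from fixed gene-level parameters; assumes the RNG state is
# already positioned (noise only).
sim_cohort <- function(params, cfg_noise_sd, n_case, n_control, prefix = "") {
  n_genes <- length(params$mu)
  n <- n_control + n_case
  means <- cbind(matrix(params$mu, n_genes, n_control),
                 matrix(params$mu + params$true_lfc, n_genes, n_case))
  values <- means + matrix(stats::rnorm(n_genes * n, sd = cfg_noise_sd),
                           n_genes, n)
  dimnames(values) <- list(
    params$gene_ids,
    c(sprintf("%sctrl_%02d", prefix, seq_len(n_control)),
      sprintf("%scase_%02d", prefix, seq_len(n_case))))
  expression_study(values, c(rep(0L, n_control), rep(1L, n_case)))
}

#' Simulate a two-group expression study with planted differential genes
#'
#' Per gene g, control samples are drawn `Normal(mu_g, noise_sd)` and case
#' samples `Normal(mu_g + true_lfc_g, noise_sd)`, with `mu_g` uniform on
#' `baseline_mean_range` and `true_lfc_g` equal to 0 for null genes and
#' `±effect_lfc` for the planted set. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `study` (an [expression_study()]) and
#'   `truth` (a `ground_truth` list: `de_gene_ids`, per-gene `true_lfc`
#'   named by gene id, and the `config` echoed).
#' @examples
#' sim <- simulate_study(sim_config(n_genes = 200, n_de = 10, seed = 1))
#' sim$study
#' head(sim$truth$de_gene_ids)
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  params <- sim_gene_params(cfg)  # seeds the RNG; noise continues the stream
  study <- sim_cohort(params, cfg$noise_sd, cfg$n_case, cfg$n_control)
  truth <- structure(
    list(de_gene_ids = params$gene_ids[params$de_idx],
         true_lfc = stats::setNames(params$true_lfc, params$gene_ids),
         config = cfg),
    class = "ground_truth")
  list(study = study, truth = truth)
}

#' Simulate paired training and test cohorts
#'
#' The test cohort shares the gene universe and the gene-level parameters
#' (baseline means and true logFCs — the same "disease") with the training
#' cohort but receives fresh noise, mirroring an independent accession used
#' for external validation. Default test design: 5 case vs 5 control.
#'
#' @param cfg_train Training-cohort [sim_config()].
#' @param n_case_test,n_control_test Test-cohort group sizes (defaults 5 / 5).
#' @param seed_test Seed for the test cohort's noise (default
#'   `cfg_train$seed + 1000`).
#' @return A list `train` (study), `truth`, `test` (study).
#' @export
simulate_paired_cohorts <- function(cfg_train, n_case_test = 5L,
                                    n_control_test = 5L,
                                    seed_test = cfg_train$seed + 1000L) {
  stopifnot(inherits(cfg_train, "sim_config"))
  if (n_case_test < 2L || n_control_test < 2L)
    stop("config-validation: need >= 2 test samples per group", call. = FALSE)
  sim <- simulate_study(cfg_train)
  params <- sim_gene_params(cfg_train)
  set.seed(as.integer(seed_test))
  test <- sim_cohort(params, cfg_train$noise_sd, as.integer(n_case_test),
                     as.integer(n_control_test), prefix = "t_")
  list(train = sim$study, truth = sim$truth, test = test)
}

#' Hand-checkable 6-gene, 6-sample fixture
#'
#' A fixed integer-valued log2 matrix (3 case / 3 control) designed so that
#' every pipeline quantity is computable by hand:
#' \describe{
#'   \item{up1}{case \{8,9,10\}, control \{4,5,6\}: logFC +4, clear DEG up.}
#'   \item{dn1}{case \{4,5,6\}, control \{8,9,10\}: logFC -4, clear DEG down.}
#'   \item{flat}{constant 7 everywhere: logFC 0, zero variance, excluded.}
#'   \item{small}{logFC 1/3, fails the |logFC| > 1 cut-off.}
#'   \item{null0}{equal group means: logFC 0.}
#'   \item{noisy}{logFC 2 but within-group variance so large that p fails.}
#' }
#' Only `up1` and `dn1` pass the default DEG filter.
#'
#' @return A list with `study` and `expected` (hand-computed logFC vector and
#'   DEG gene ids).
#' @export
toy_fixture <- function() {
  values <- rbind(
    up1   = c(4, 5, 6, 8, 9, 10),
    dn1   = c(8, 9, 10, 4, 5, 6),
    flat  = c(7, 7, 7, 7, 7, 7),
    small = c(7, 7, 7, 7, 7, 8),
    null0 = c(7, 8, 6, 6, 7, 8),
    noisy = c(4, 7, 4, 10, 4, 7))
  colnames(values) <- c("ctrl_01", "ctrl_02", "ctrl_03",
                        "case_01", "case_02", "case_03")
  study <- expression_study(values, c(0L, 0L, 0L, 1L, 1L, 1L))
  expected <- list(
    lfc = c(up1 = 4, dn1 = -4, flat = 0, small = 1 / 3, null0 = 0, noisy = 2),
    deg_ids = c("up1", "dn1"))
  list(study = study, expected = expected)
}
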