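#' Study settings for the synthetic benchmark experiments
#'
#' The hyperparameter set used by the package's own benchmark runs (tests,
#' acceptance script, vignette): a (32, 32) ReLU selector, (64, 64) ReLU
#' predictors, sparsity weight 0.1, Adam at 3e-4, batch 500, 4000 steps
#' with a 1200-step predictor warm-up. Chosen once for the 11-feature
#' Gaussian benchmarks at their standard scale (20,000 training
#' instances); see the methods vignette for rationale.
#'
#' @param seed Integer training seed.
#' @return A [cfs_hyperparams()] object.
#' @export
bench_hyperparams <- function(seed = 1L) {
  cfs_hyperparams(hidden_selector = c(32L, 32L),
                  hidden_predictors = c(64L, 64L),
                  lambda = 0.1,
                  learning_rate = 3e-4,
                  batch_size = 500L,
                  n_steps = 4000L,
                  n_warmup_steps = 1200L,
                  selection_threshold = 0.5,
                  seed = seed)
}

#' Run one synthetic benchmark experiment end to end
#'
#' Generates the named benchmark, splits it in half, trains the
#' three-network model under [bench_hyperparams()], and scores the held-out
#' half: selection TPR/FDR against the generator's ground truth and
#' AUROC/AUPRC/accuracy of both predictors.
#'
#' @param name Generator name (`"dataset1"`, `"dataset2"`, `"dataset3"`).
#' @param seed Seed for both generation and training.
#' @param n Total sample size before the 50/50 split (default 40000:
#'   20,000 train / 20,000 test).
#' @return List with `model`, `selection` (on the test half), `test`
#'   (the test split), `metrics` (named vector: `tpr_pct`, `fdr_pct`,
#'   `auroc`, `auprc`, `accuracy`, plus `auroc_fact`, `auprc_fact`).
#' @export
run_benchmark <- function(name, seed = 1L, n = 40000L) {
  ds <- generate_dataset(name, n, seed = seed)
  sp <- split_dataset(ds)
  model <- cfs_train(sp$train, bench_hyperparams(seed = seed + 1000L))
  sel <- cfs_select(model, sp$test$features)
  met <- evaluate_selection(sel, sp$test$labels, ds$relevant_features)
  pf <- fact_predict(model, sp$test$features)
  met <- c(met,
           auroc_fact = auroc(pf[, 2], sp$test$labels),
           auprc_fact = auprc(pf[, 2], sp$test$labels))
  list(name = name, seed = seed, model = model, selection = sel,
       test = sp$test, metrics = met)
}
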