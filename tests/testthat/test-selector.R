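test_that("hyperparameter constructor enforces its invariants", {
  expect_error(cfs_hyperparams(lambda = -1), "nonnegative")
  expect_error(cfs_hyperparams(hidden_selector = c(10, 0)), "positive")
  expect_error(cfs_hyperparams(selection_threshold = 1), "inside")
  expect_error(cfs_hyperparams(n_steps = 100, n_warmup_steps = 100), "warmup")
  hp <- cfs_hyperparams(n_steps = 100)
  expect_equal(hp$n_warmup_steps, 20L)
})

test_that("an untrained selector emits probabilities near one half", {
  set.seed(1)
  net <- cfsace:::mlp_init(11, c(8), 11, head = "sigmoid")
  net$W[[2]][] <- 0
  net$b[[2]][] <- 0
  P <- selector_forward(net, matrix(rnorm(33), 3, 11))
  expect_equal(dim(P), c(3, 11))
  expect_true(all(P == 0.5))
  net2 <- cfsace:::mlp_init(11, c(8), 11, head = "sigmoid")
  P2 <- selector_forward(net2, matrix(rnorm(55), 5, 11))
  expect_true(all(P2 > 0 & P2 < 1))
})

test_that("mask sampling follows the factorised Bernoulli policy", {
  expect_equal(sample_mask(rep(1, 5)), rep(1, 5))
  expect_equal(sample_mask(rep(0, 5)), rep(0, 5))
  expect_error(sample_mask(c(0.5, 1.2)), "\\[0, 1\\]")
  # any specific mask under p = 0.5, d = 11 has probability 0.5^11
  p <- rep(0.5, 11)
  expect_equal(mask_probability(p, sample_mask(p)), 0.5^11)
  # mask probabilities sum to one over all 2^d masks
  set.seed(4)
  for (rep in 1:3) {
    d <- sample(4:8, 1)
    probs <- runif(d, 0.05, 0.95)
    S <- all_masks(d)
    tot <- sum(apply(S, 1, function(s) mask_probability(probs, s)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("expected selected count equals the probability sum (Monte Carlo)", {
  set.seed(8)
  probs <- runif(11, 0.05, 0.95)
  draws <- sample_mask(matrix(probs, 1e4, 11, byrow = TRUE))
  counts <- rowSums(draws)
  se <- sqrt(sum(probs * (1 - probs)) / 1e4)
  expect_lt(abs(mean(counts) - sum(probs)), 3 * se)
})

test_that("cross-entropy losses and advantage match hand arithmetic", {
  y0 <- c(1, 0)
  expect_equal(loss_cf(y0, c(1, 0)), 0)
  expect_equal(loss_cf(y0, c(0.5, 0.5)), log(2))
  expect_equal(loss_cf(y0, c(exp(-1), 1 - exp(-1))), 1)
  expect_equal(loss_fact(y0, c(0.5, 0.5)), log(2))
  # identical predictions give zero advantage
  expect_equal(advantage(y0, c(0.7, 0.3), c(0.7, 0.3)), 0)
  # CE_cf = 1.0, CE_fact = 0.3 -> 0.7
  expect_equal(advantage(y0, c(exp(-1), 1 - exp(-1)), c(exp(-0.3), 1 - exp(-0.3))),
               0.7, tolerance = 1e-12)
  # advantage may be negative when the selected subset predicts better
  expect_lt(advantage(y0, c(0.9, 0.1), c(0.6, 0.4)), 0)
})

test_that("selector surrogate has the documented score-function gradient", {
  expect_error(selector_loss(rep(0.5, 3), rep(1, 3), 0.2, lambda = -0.1),
               "nonnegative")
  # d surrogate / d p_i = adv * (s_i - p_i) / (p_i (1 - p_i)) at lambda = 0
  set.seed(5)
  p <- runif(3, 0.2, 0.8)
  s <- c(1, 0, 1)
  adv <- 0.37
  for (j in 1:3) {
    h <- 1e-7
    pp <- p; pp[j] <- pp[j] + h
    pm <- p; pm[j] <- pm[j] - h
    num <- (selector_loss(pp, s, adv, 0) - selector_loss(pm, s, adv, 0)) / (2 * h)
    expect_equal(num, adv * (s[j] - p[j]) / (p[j] * (1 - p[j])),
                 tolerance = 1e-5)
  }
  # with zero advantage and lambda = 0 the surrogate gradient vanishes
  for (j in 1:3) {
    h <- 1e-7
    pp <- p; pp[j] <- pp[j] + h
    pm <- p; pm[j] <- pm[j] - h
    expect_equal((selector_loss(pp, s, 0, 0) - selector_loss(pm, s, 0, 0)) / (2 * h),
                 0, tolerance = 1e-6)
  }
})

test_that("policy gradient matches the exhaustive-enumeration oracle", {
  # d = 3 toy: the expected surrogate gradient must equal the finite
  # difference of the fully enumerated objective E_s[lhat + lambda |s|].
  set.seed(6)
  for (rep in 1:2) {
    sel_net <- cfsace:::mlp_init(3, c(4), 3, head = "sigmoid")
    sel_net$W[[2]] <- matrix(rnorm(12, sd = 0.4), 4, 3)
    x <- rnorm(3)
    w_fix <- rnorm(3)
    lhat <- function(s) sum(w_fix * s) + 0.3 * s[1] * s[2]
    lambda <- 0.15
    ana <- expected_surrogate_grad(sel_net, x, lhat, lambda)
    num <- fd_policy_grad(sel_net, x, lhat, lambda)
    for (l in seq_along(ana$W)) {
      expect_equal(ana$W[[l]], num$W[[l]], tolerance = 1e-6)
      expect_equal(ana$b[[l]], num$b[[l]], tolerance = 1e-6)
    }
  }
})

test_that("counterfactual predictions respect the mask contract", {
  set.seed(9)
  ds <- generate_dataset("dataset1", 400, seed = 2)
  hp <- cfs_hyperparams(hidden_selector = c(8), hidden_predictors = c(16),
                        batch_size = 100, n_steps = 60, n_warmup_steps = 20,
                        learning_rate = 1e-3, seed = 3)
  m <- cfs_train(ds, hp)
  X <- ds$features[1:7, ]
  # full mask: rows sum to one
  P1 <- cf_predict(m, X, rep(1, 11))
  expect_equal(rowSums(P1), rep(1, 7), tolerance = 1e-12)
  # empty mask: prediction cannot depend on the feature values
  P0a <- cf_predict(m, X, rep(0, 11))
  P0b <- cf_predict(m, X * 5 + 1, rep(0, 11))
  expect_equal(P0a, P0b, tolerance = 1e-12)
  expect_equal(max(apply(P0a, 2, function(col) diff(range(col)))), 0,
               tolerance = 1e-12)
  # factual predictor: deterministic, rows sum to one
  F1 <- fact_predict(m, X)
  expect_equal(rowSums(F1), rep(1, 7), tolerance = 1e-12)
  expect_identical(F1, fact_predict(m, X))
  expect_error(cf_predict(m, X[, 1:5], rep(1, 5)), "expects")
})

test_that("training validates inputs and records per-step losses", {
  ds <- generate_dataset("dataset1", 200, seed = 2)
  one_class <- tabular_dataset(ds$features, rep(0L, 200))
  expect_error(cfs_train(one_class, cfs_hyperparams(n_steps = 10)),
               "2 classes")
  bad <- tabular_dataset(ds$features, ds$labels + 1L)
  expect_error(cfs_train(bad, cfs_hyperparams(n_steps = 10)), "coded 0")
  hp <- cfs_hyperparams(hidden_selector = c(8), hidden_predictors = c(8),
                        batch_size = 64, n_steps = 30, n_warmup_steps = 5,
                        learning_rate = 1e-3, seed = 11)
  m <- cfs_train(ds, hp)
  expect_equal(nrow(m$training_history), 30)
  expect_true(all(is.finite(as.matrix(m$training_history))))
  expect_named(m$training_history, c("l1", "l2", "l3"))
  # determinism under a fixed seed
  m2 <- cfs_train(ds, hp)
  expect_equal(m$selector$W, m2$selector$W, tolerance = 1e-15)
  expect_equal(m$training_history, m2$training_history, tolerance = 1e-15)
})

test_that("test-time selection thresholds deterministically, ties up", {
  ds <- generate_dataset("dataset2", 300, seed = 4)
  hp <- cfs_hyperparams(hidden_selector = c(8), hidden_predictors = c(8),
                        batch_size = 64, n_steps = 20, n_warmup_steps = 5,
                        learning_rate = 1e-3, seed = 12)
  m <- cfs_train(ds, hp)
  sel <- cfs_select(m, ds$features[1:20, ])
  expect_equal(sel$mask, (sel$probabilities >= 0.5) * 1)
  expect_equal(rowSums(sel$predictions), rep(1, 20), tolerance = 1e-12)
  # a probability exactly at the threshold counts as selected
  fake <- m
  fake$selector$W <- lapply(fake$selector$W, function(w) w * 0)
  fake$selector$b <- lapply(fake$selector$b, function(b) b * 0)
  sel05 <- cfs_select(fake, ds$features[1:3, ])
  expect_true(all(sel05$probabilities == 0.5))
  expect_true(all(sel05$mask == 1))
})

test_that("a very large sparsity weight collapses the selection", {
  ds <- generate_dataset("dataset2", 1000, seed = 5)
  hp <- cfs_hyperparams(hidden_selector = c(8), hidden_predictors = c(16),
                        lambda = 50, learning_rate = 3e-3, batch_size = 200,
                        n_steps = 400, n_warmup_steps = 50, seed = 13)
  m <- cfs_train(ds, hp)
  sel <- cfs_select(m, ds$features)
  expect_lt(mean(rowSums(sel$mask)), 0.5)
})

test_that("selection tracks signal, not feature index", {
  # dataset1 with its relevant columns overwritten by fresh noise: nothing
  # predicts the label, so no feature should be durably selected
  set.seed(31)
  ds <- generate_dataset("dataset1", 3000, seed = 6)
  ds$features[, 1:2] <- matrix(rnorm(2 * 3000), ncol = 2)
  hp <- cfs_hyperparams(hidden_selector = c(16, 16), hidden_predictors = c(32, 32),
                        learning_rate = 1e-3, batch_size = 250,
                        n_steps = 700, n_warmup_steps = 200, seed = 14)
  m <- cfs_train(ds, hp)
  sel <- cfs_select(m, ds$features)
  tf <- tpr_fdr(sel$mask, 1:2)
  expect_lt(tf[["tpr_pct"]], 50)
  expect_lt(mean(rowSums(sel$mask)), 3)
})

test_that("models and selections round-trip through their text formats", {
  ds <- generate_dataset("dataset1", 300, seed = 7)
  hp <- cfs_hyperparams(hidden_selector = c(8), hidden_predictors = c(8),
                        batch_size = 64, n_steps = 20, n_warmup_steps = 5,
                        learning_rate = 1e-3, seed = 15)
  m <- cfs_train(ds, hp)
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  X <- ds$features[1:10, ]
  expect_equal(selector_forward(m2, X), selector_forward(m, X), tolerance = 1e-12)
  expect_equal(fact_predict(m2, X), fact_predict(m, X), tolerance = 1e-12)
  expect_equal(m2$hyperparams$lambda, m$hyperparams$lambda)
  sp <- tempfile(fileext = ".csv")
  write_selection(cfs_select(m, X), sp)
  tab <- read.csv(sp)
  expect_equal(dim(tab), c(10, 11 + 11 + 2))
})

test_that("trained selection probabilities concentrate on the interacting pair", {
  r <- bench_run_cached("dataset1", bench_seeds()[1])
  probs <- colMeans(r$selection$probabilities)
  expect_gt(min(probs[1:2]), max(probs[3:11]))
})
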