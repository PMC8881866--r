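#' Hyperparameters for the three-network selection model
#'
#' @param hidden_selector Hidden layer sizes of the selection network.
#' @param hidden_predictors Hidden layer sizes of both prediction networks.
#' @param lambda Nonnegative sparsity weight on the expected *fraction* of
#'   selected features (the per-feature penalty is `lambda / d`, so the
#'   value transfers across feature dimensions).
#' @param learning_rate Adam learning rate (shared by all three networks).
#' @param batch_size Mini-batch size.
#' @param n_steps Number of training steps.
#' @param n_warmup_steps Initial steps during which only the two predictors
#'   are updated (masks are still sampled from the selector, which starts
#'   near probability 0.5 everywhere). The policy gradient is informative
#'   only once the counterfactual predictor exploits the features present
#'   in a mask, so updating the selector from the start lets the sparsity
#'   penalty erase features before any reward exists for keeping them.
#'   Default: 20 percent of `n_steps`.
#' @param selection_threshold Deterministic test-time selection threshold in
#'   (0, 1); a probability equal to the threshold counts as selected.
#' @param seed Integer seed controlling initialisation, batching and mask
#'   sampling.
#' @return A `cfs_hyperparams` list.
#' @export
cfs_hyperparams <- function(hidden_selector = c(100L, 100L),
                            hidden_predictors = c(200L, 200L),
                            lambda = 0.1,
                            learning_rate = 1e-4,
                            batch_size = 1000L,
                            n_steps = 10000L,
                            n_warmup_steps = NULL,
                            selection_threshold = 0.5,
                            seed = 1L) {
  if (lambda < 0) stop("lambda must be nonnegative")
  if (any(c(hidden_selector, hidden_predictors) <= 0))
    stop("hidden sizes must be positive")
  if (batch_size <= 0 || n_steps <= 0) stop("batch_size and n_steps must be positive")
  if (selection_threshold <= 0 || selection_threshold >= 1)
    stop("selection_threshold must be strictly inside (0, 1)")
  if (is.null(n_warmup_steps)) n_warmup_steps <- floor(n_steps * 0.2)
  if (n_warmup_steps < 0 || n_warmup_steps >= n_steps)
    stop("n_warmup_steps must be in [0, n_steps)")
  structure(list(hidden_selector = as.integer(hidden_selector),
                 hidden_predictors = as.integer(hidden_predictors),
                 lambda = lambda, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 n_steps = as.integer(n_steps),
                 n_warmup_steps = as.integer(n_warmup_steps),
                 selection_threshold = selection_threshold,
                 seed = as.integer(seed)),
            class = "cfs_hyperparams")
}

#' Selection probabilities for a batch of instances
#'
#' Runs the counterfactual selection network ("actor"): for each instance it
#' returns the per-feature probability of being selected, a sigmoid output
#' strictly inside (0, 1).
#'
#' @param model A `cfs_model` from [cfs_train()], or a bare selector network.
#' @param X Numeric matrix (n x d) or a single instance vector.
#' @return n x d matrix of selection probabilities.
#' @export
selector_forward <- function(model, X) {
  net <- if (inherits(model, "cfs_model")) model$selector else model
  mlp_forward(net, X)
}

#' Sample binary selection masks from per-feature probabilities
#'
#' Draws each mask entry independently as Bernoulli(p_i), so the probability
#' of any particular mask is exactly [mask_probability()].
#'
#' @param probs Matrix (or vector) of probabilities in \[0, 1\].
#' @return Binary matrix of the same shape.
#' @export
sample_mask <- function(probs) {
  vec <- !is.matrix(probs)
  if (vec) probs <- matrix(probs, nrow = 1L)
  if (any(probs < 0 | probs > 1)) stop("selection probabilities must be in [0, 1]")
  m <- (matrix(stats::runif(length(probs)), nrow(probs)) < probs) * 1
  if (vec) drop(m) else m
}

#' Probability of a selection mask under the factorised Bernoulli policy
#'
#' `prod_i p_i^{s_i} (1 - p_i)^{1 - s_i}` per row.
#'
#' @param probs Probability matrix or vector.
#' @param mask Binary matrix or vector of the same shape.
#' @return Numeric vector of mask probabilities (one per row).
#' @export
mask_probability <- function(probs, mask) {
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1L)
  if (!is.matrix(mask)) mask <- matrix(mask, nrow = 1L)
  stopifnot(all(dim(probs) == dim(mask)), all(mask %in% c(0, 1)))
  exp(rowSums(mask * log(probs) + (1 - mask) * log1p(-probs)))
}

# Counterfactual input encoding: masked values concatenated with the mask,
# so the predictor can distinguish "unselected" from "observed zero".
cf_input <- function(X, mask) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (!is.matrix(mask)) mask <- matrix(mask, nrow(X), ncol(X), byrow = TRUE)
  cbind(X * mask, mask)
}

#' Counterfactual prediction from selected features only
#'
#' The counterfactual prediction network sees the masked feature values
#' together with the mask itself (2d inputs) and returns class
#' probabilities. Unselected features influence the output only through the
#' zeroed value and the mask channel.
#'
#' @param model A `cfs_model`.
#' @param X Feature matrix or single-instance vector.
#' @param mask Binary mask, one row per instance (a single row is recycled).
#' @return n x c matrix of class probabilities (rows sum to 1).
#' @export
cf_predict <- function(model, X, mask) {
  mlp_forward(model$cf_predictor, cf_input(X, mask))
}

#' Factual prediction from all features
#'
#' The factual prediction network (the "critic") predicts from the complete
#' feature vector, no mask.
#'
#' @param model A `cfs_model`.
#' @param X Feature matrix or single-instance vector.
#' @return n x c matrix of class probabilities.
#' @export
fact_predict <- function(model, X) {
  mlp_forward(model$fact_predictor, X)
}

# Row-wise cross-entropy of class-probability rows against integer labels
# (0-based). Clamped away from log(0).
cross_entropy <- function(P, y) {
  idx <- cbind(seq_along(y), y + 1L)
  -log(pmax(P[idx], 1e-12))
}

#' Cross-entropy loss of the counterfactual predictor
#'
#' @param y One-hot vector (or matrix of one-hot rows) of true labels.
#' @param p Predicted class-probability vector (or matrix).
#' @return Mean cross-entropy; 0 iff all mass sits on the true class.
#' @export
loss_cf <- function(y, p) {
  if (!is.matrix(y)) y <- matrix(y, nrow = 1L)
  if (!is.matrix(p)) p <- matrix(p, nrow = 1L)
  mean(-rowSums(y * log(pmax(p, 1e-12))))
}

#' Cross-entropy loss of the factual predictor
#'
#' Same form as [loss_cf()]; kept separate because the two losses play
#' different roles in the advantage (their difference drives the selector).
#'
#' @inheritParams loss_cf
#' @return Mean cross-entropy.
#' @export
loss_fact <- function(y, p) loss_cf(y, p)

#' Per-instance advantage: counterfactual minus factual loss
#'
#' The reward signal for the selection network, with both predictors held
#' fixed: `CE_cf - CE_fact`. Negative values mean the selected subset
#' predicts better than the full feature vector.
#'
#' @param y One-hot label matrix (rows).
#' @param p_cf Counterfactual class probabilities.
#' @param p_fact Factual class probabilities.
#' @return Numeric vector, one advantage per instance; may be negative.
#' @export
advantage <- function(y, p_cf, p_fact) {
  if (!is.matrix(y)) y <- matrix(y, nrow = 1L)
  if (!is.matrix(p_cf)) p_cf <- matrix(p_cf, nrow = 1L)
  if (!is.matrix(p_fact)) p_fact <- matrix(p_fact, nrow = 1L)
  ce_cf <- -rowSums(y * log(pmax(p_cf, 1e-12)))
  ce_f <- -rowSums(y * log(pmax(p_fact, 1e-12)))
  ce_cf - ce_f
}

#' Score-function surrogate loss for the selection network
#'
#' Returns the scalar surrogate whose gradient in the selector parameters is
#' the exact gradient of the policy objective
#' `E_s[adv(s)] + lambda * E_s[|s|_0]`: a REINFORCE term with the advantage
#' detached (constant) plus the differentiable expected sparsity
#' `lambda * sum_i p_i` (the exact expectation of the selected-feature count
#' under the factorised Bernoulli policy).
#'
#' @param probs Selection probabilities (rows).
#' @param mask Sampled binary masks (rows).
#' @param adv Per-row advantage values, treated as constants.
#' @param lambda Nonnegative sparsity weight.
#' @return Mean surrogate loss over rows.
#' @export
selector_loss <- function(probs, mask, adv, lambda) {
  if (lambda < 0) stop("lambda must be nonnegative")
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1L)
  if (!is.matrix(mask)) mask <- matrix(mask, nrow = 1L)
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  logpi <- rowSums(mask * log(p) + (1 - mask) * log1p(-p))
  mean(adv * logpi + lambda * rowSums(p))
}

# dL/d(selector pre-activation logits) of the surrogate, averaged over the
# batch: adv * (s - p) from the score-function term (sigmoid derivative
# cancels against d log pi / dp) plus lambda * p(1-p) from expected sparsity.
selector_logit_grad <- function(probs, mask, adv, lambda) {
  (adv * (mask - probs) + lambda * probs * (1 - probs)) / nrow(probs)
}

#' Train the three-network counterfactual selection model
#'
#' Joint mini-batch training: each step samples a batch, draws selection
#' masks from the actor's Bernoulli policy, updates the counterfactual
#' predictor on its cross-entropy (masked input + mask channel), updates the
#' factual predictor on its cross-entropy (full input), then updates the
#' selector by the score-function gradient of the detached advantage
#' (counterfactual minus factual loss) plus the expected-sparsity penalty.
#'
#' @param data A [tabular_dataset()] with at least 2 classes.
#' @param hp A [cfs_hyperparams()] object.
#' @return A `cfs_model` holding the three networks, the hyperparameters and
#'   a `training_history` data frame with per-step losses `l1` (CF
#'   cross-entropy), `l2` (factual cross-entropy) and `l3` (policy objective
#'   estimate: advantage plus expected sparsity).
#' @examples
#' \donttest{
#' ds <- generate_dataset("dataset2", 2000, seed = 1)
#' hp <- cfs_hyperparams(hidden_selector = c(16, 16),
#'                       hidden_predictors = c(32, 32),
#'                       batch_size = 200, n_steps = 200,
#'                       learning_rate = 1e-3)
#' model <- cfs_train(ds, hp)
#' }
#' @export
cfs_train <- function(data, hp = cfs_hyperparams()) {
  X <- data$features
  y <- data$labels
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("training data must contain at least 2 classes")
  if (!identical(classes, seq_along(classes) - 1L))
    stop("labels must be coded 0 ... c-1")
  n <- nrow(X)
  d <- ncol(X)
  c_out <- length(classes)
  Y <- matrix(0, n, c_out)
  Y[cbind(seq_len(n), y + 1L)] <- 1

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(hp$seed)

  sel <- mlp_init(d, hp$hidden_selector, d, head = "sigmoid")
  cf <- mlp_init(2L * d, hp$hidden_predictors, c_out, head = "softmax")
  fc <- mlp_init(d, hp$hidden_predictors, c_out, head = "softmax")
  st_sel <- adam_init(sel)
  st_cf <- adam_init(cf)
  st_fc <- adam_init(fc)

  history <- matrix(NA_real_, hp$n_steps, 3L,
                    dimnames = list(NULL, c("l1", "l2", "l3")))
  nb <- hp$batch_size
  for (step in seq_len(hp$n_steps)) {
    idx <- sample.int(n, nb, replace = nb > n)
    Xb <- X[idx, , drop = FALSE]
    Yb <- Y[idx, , drop = FALSE]

    fw_sel <- mlp_forward(sel, Xb, keep = TRUE)
    P <- pmin(pmax(fw_sel$out, 1e-7), 1 - 1e-7)
    S <- (matrix(stats::runif(nb * d), nb, d) < P) * 1

    # counterfactual predictor update (Adam on its own cross-entropy)
    fw_cf <- mlp_forward(cf, cbind(Xb * S, S), keep = TRUE)
    ce_cf <- -rowSums(Yb * log(pmax(fw_cf$out, 1e-12)))
    g <- mlp_backward(cf, fw_cf, (fw_cf$out - Yb) / nb)
    up <- adam_step(cf, g, st_cf, hp$learning_rate)
    cf <- up$net; st_cf <- up$state

    # factual predictor update
    fw_fc <- mlp_forward(fc, Xb, keep = TRUE)
    ce_f <- -rowSums(Yb * log(pmax(fw_fc$out, 1e-12)))
    g <- mlp_backward(fc, fw_fc, (fw_fc$out - Yb) / nb)
    up <- adam_step(fc, g, st_fc, hp$learning_rate)
    fc <- up$net; st_fc <- up$state

    # selector update after warm-up; advantage is detached (a reward, not a
    # gradient path). The sparsity weight is normalised per feature
    # (lambda * mean_i p_i).
    adv <- ce_cf - ce_f
    if (step > hp$n_warmup_steps) {
      dZ <- selector_logit_grad(P, S, adv, hp$lambda / d)
      g <- mlp_backward(sel, fw_sel, dZ)
      up <- adam_step(sel, g, st_sel, hp$learning_rate)
      sel <- up$net; st_sel <- up$state
    }

    history[step, ] <- c(mean(ce_cf), mean(ce_f),
                         mean(adv) + hp$lambda * mean(P))
    if (!all(is.finite(history[step, ])))
      stop("non-finite loss at step ", step,
           " (l1=", history[step, 1L], ", l2=", history[step, 2L],
           "); lower the learning rate")
  }

  structure(list(selector = sel, cf_predictor = cf, fact_predictor = fc,
                 hyperparams = hp, n_features = d, n_classes = c_out,
                 feature_names = data$feature_names,
                 training_history = as.data.frame(history)),
            class = "cfs_model")
}

#' @export
print.cfs_model <- function(x, ...) {
  cat("cfs_model:", x$n_features, "features,", x$n_classes, "classes\n")
  cat("  selector hidden:", paste(x$hyperparams$hidden_selector, collapse = "/"),
      "| predictors hidden:",
      paste(x$hyperparams$hidden_predictors, collapse = "/"), "\n")
  cat("  lambda:", x$hyperparams$lambda,
      "| steps:", x$hyperparams$n_steps, "\n")
  h <- x$training_history
  cat("  final losses: l1 =", signif(h$l1[nrow(h)], 4),
      " l2 =", signif(h$l2[nrow(h)], 4),
      " l3 =", signif(h$l3[nrow(h)], 4), "\n")
  invisible(x)
}

#' Deterministic instance-wise selection and prediction
#'
#' Test-time behaviour: selection probabilities are thresholded (no
#' sampling) at `selection_threshold`, with a probability exactly equal to
#' the threshold counting as selected, and the counterfactual predictor is
#' applied with the resulting mask.
#'
#' @param model A trained `cfs_model`.
#' @param X Feature matrix or single-instance vector.
#' @param threshold Optional override of the model's selection threshold.
#' @return A `selection_result`: list with `probabilities` (n x d), `mask`
#'   (n x d binary) and `predictions` (n x c, rows sum to 1).
#' @export
cfs_select <- function(model, X, threshold = NULL) {
  if (!inherits(model, "cfs_model")) stop("model must be a cfs_model")
  if (is.null(threshold)) threshold <- model$hyperparams$selection_threshold
  probs <- selector_forward(model, X)
  mask <- (probs >= threshold) * 1
  preds <- cf_predict(model, X, mask)
  structure(list(probabilities = probs, mask = mask, predictions = preds,
                 threshold = threshold),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result:", nrow(x$mask), "instances x", ncol(x$mask),
      "features (threshold", x$threshold, ")\n")
  cat("  mean selected per instance:", signif(mean(rowSums(x$mask)), 4), "\n")
  invisible(x)
}

#' Write a selection result as delimited text
#'
#' One row per instance: the d selection probabilities, the d mask bits and
#' the c class probabilities.
#'
#' @param sel A `selection_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  d <- ncol(sel$mask)
  c_out <- ncol(sel$predictions)
  df <- data.frame(sel$probabilities, sel$mask, sel$predictions)
  names(df) <- c(paste0("prob_x", seq_len(d) - 1L),
                 paste0("mask_x", seq_len(d) - 1L),
                 paste0("p_class", seq_len(c_out) - 1L))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a trained model
#'
#' The model is stored as a single JSON manifest (hyperparameters, training
#' history, layer shapes) with all parameter arrays flattened inside it, so
#' the archive is plain text.
#'
#' @param model A `cfs_model`.
#' @param path File path (conventionally `.json`).
#' @return `path` invisibly for `write_model`; a `cfs_model` for
#'   `read_model`.
#' @export
write_model <- function(model, path) {
  pack_net <- function(net) list(
    sizes = net$sizes, head = net$head,
    W = lapply(net$W, as.vector), b = net$b)
  obj <- list(
    package = "cfsace", format = 1L,
    n_features = model$n_features, n_classes = model$n_classes,
    feature_names = model$feature_names,
    hyperparams = unclass(model$hyperparams),
    selector = pack_net(model$selector),
    cf_predictor = pack_net(model$cf_predictor),
    fact_predictor = pack_net(model$fact_predictor),
    training_history = model$training_history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack_net <- function(p) {
    sizes <- as.integer(p$sizes)
    L <- length(sizes) - 1L
    # equal-length parameter vectors come back simplified into a matrix
    # (one layer per row); renormalise to a list of layers
    as_layers <- function(v) {
      if (is.matrix(v)) lapply(seq_len(nrow(v)), function(r) v[r, ]) else v
    }
    pW <- as_layers(p$W)
    pb <- as_layers(p$b)
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- matrix(pW[[l]], sizes[l], sizes[l + 1L])
      b[[l]] <- as.numeric(pb[[l]])
    }
    structure(list(W = W, b = b, head = p$head, sizes = sizes),
              class = "cfs_mlp")
  }
  hp <- do.call(cfs_hyperparams, obj$hyperparams[names(formals(cfs_hyperparams))])
  structure(list(selector = unpack_net(obj$selector),
                 cf_predictor = unpack_net(obj$cf_predictor),
                 fact_predictor = unpack_net(obj$fact_predictor),
                 hyperparams = hp,
                 n_features = as.integer(obj$n_features),
                 n_classes = as.integer(obj$n_classes),
                 feature_names = obj$feature_names,
                 training_history = as.data.frame(obj$training_history)),
            class = "cfs_model")
}
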