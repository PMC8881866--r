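#' Empirical statistics used for interventions
#'
#' Sample mean, sample covariance and per-feature empirical ranges of a
#' feature matrix. Under the assumption that an intervened input is
#' d-separated from the remaining inputs, these observational moments are
#' used directly as the interventional moments of the non-intervened
#' coordinates.
#'
#' @param X Numeric feature matrix (n x d).
#' @return A `data_stats` list: `mean` (d), `cov` (d x d), `low`, `high`
#'   (per-feature min/max).
#' @export
estimate_stats <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows to estimate a covariance")
  structure(list(mean = colMeans(X), cov = stats::cov(X),
                 low = apply(X, 2L, min), high = apply(X, 2L, max)),
            class = "data_stats")
}

#' Configuration for integrated-gradient smoothing
#'
#' @param n_steps Number of Riemann steps along the straight path (grid
#'   `a = k/n`, `k = 1 ... n`); at least 1.
#' @param ig_baseline Baseline input of the path; `NULL` means the zero
#'   vector.
#' @param hessian Which curvature enters the second-order interventional
#'   term: `"smoothed"` (default) differentiates the path-mean gradient, so
#'   the same saturation resistance that motivates integrated gradients also
#'   applies in second order; `"exact"` differentiates the pointwise
#'   gradient, recovering the textbook Taylor expansion (and the closed
#'   forms for polynomial mechanisms).
#' @return An `ig_config` list.
#' @export
ig_config <- function(n_steps = 50L, ig_baseline = NULL,
                      hessian = c("smoothed", "exact")) {
  if (n_steps < 1L) stop("n_steps must be at least 1")
  structure(list(n_steps = as.integer(n_steps), ig_baseline = ig_baseline,
                 hessian = match.arg(hessian)),
            class = "ig_config")
}

# Normalise a mechanism to a pair of row-vectorised functions:
#   f(X)    -> numeric vector (one scalar output per row)
#   grad(X) -> matrix of input gradients (one row per row of X)
# A cfs_model is read as the counterfactual predictor with a fixed selection
# mask: the mechanism maps feature values to the post-softmax probability of
# `target_class`, the mask channel held constant. A plain function of one
# input vector gets a central-difference gradient.
as_mechanism <- function(model, d = NULL, mask = NULL, target_class = 0L,
                         fd_step = 1e-5) {
  if (inherits(model, "cfs_model")) {
    d <- model$n_features
    if (is.null(mask)) mask <- rep(1, d)
    mask <- as.numeric(mask)
    unit <- as.integer(target_class) + 1L
    if (unit < 1L || unit > model$n_classes) stop("target_class out of range")
    f <- function(X) {
      if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
      cf_predict(model, X, matrix(mask, nrow(X), d, byrow = TRUE))[, unit]
    }
    grad <- function(X) {
      if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
      M <- matrix(mask, nrow(X), d, byrow = TRUE)
      G <- mlp_input_grad(model$cf_predictor, cbind(X * M, M), unit)
      # chain rule through the masked value channel; the mask channel is fixed
      G[, seq_len(d), drop = FALSE] * M
    }
    list(f = f, grad = grad, d = d)
  } else if (is.function(model)) {
    if (is.null(d)) stop("d must be given for a plain-function mechanism")
    f <- function(X) {
      if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
      apply(X, 1L, model)
    }
    grad <- function(X) {
      if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
      h <- rep_len(fd_step, d)
      G <- matrix(0, nrow(X), d)
      for (j in seq_len(d)) {
        Xp <- X; Xp[, j] <- Xp[, j] + h[j]
        Xm <- X; Xm[, j] <- Xm[, j] - h[j]
        G[, j] <- (f(Xp) - f(Xm)) / (2 * h[j])
      }
      G
    }
    list(f = f, grad = grad, d = d)
  } else stop("model must be a cfs_model or a function")
}

ig_path_points <- function(x, baseline, n) {
  a <- seq_len(n) / n
  # rows: baseline + a_k (x - baseline)
  outer(a, x - baseline) + matrix(baseline, n, length(x), byrow = TRUE)
}

#' Mean gradient along the straight path from a baseline to an input
#'
#' Averages the gradient of `F` over the points `x' + (k/n) (x - x')`,
#' `k = 1 ... n`. Because every point on the path contributes, a gradient
#' that is saturated (near zero) at `x` itself can still yield a useful
#' signal.
#'
#' @param F Scalar-valued mechanism: a function of one input vector, or a
#'   `cfs_model` (see [ace_curve()] for how a model is read as a mechanism).
#' @param x Input vector (the path endpoint).
#' @param cfg An [ig_config()].
#' @param ... Passed to the mechanism constructor (`mask`, `target_class`).
#' @return Signed mean-gradient vector of length `d`.
#' @export
path_mean_gradient <- function(F, x, cfg = ig_config(), ...) {
  mech <- if (is.list(F) && !is.null(F$grad)) F else as_mechanism(F, d = length(x), ...)
  baseline <- if (is.null(cfg$ig_baseline)) rep(0, length(x)) else cfg$ig_baseline
  P <- ig_path_points(x, baseline, cfg$n_steps)
  G <- mech$grad(P)
  if (!all(is.finite(G))) stop("non-finite gradient along the integration path")
  colMeans(G)
}

#' Integrated-gradient attribution
#'
#' `(x - x') * path-mean gradient`, a Riemann approximation of the path
#' integral of gradients from the baseline `x'` to `x`. Satisfies the
#' completeness property `sum_i IG_i -> F(x) - F(x')` as `n_steps` grows.
#'
#' @inheritParams path_mean_gradient
#' @return Signed attribution vector of length `d`. Use `abs()` for
#'   magnitude rankings.
#' @export
integrated_gradient <- function(F, x, cfg = ig_config(), ...) {
  baseline <- if (is.null(cfg$ig_baseline)) rep(0, length(x)) else cfg$ig_baseline
  (x - baseline) * path_mean_gradient(F, x, cfg, ...)
}

# Curvature of the mechanism at x: central-difference Jacobian of the
# chosen gradient map (pointwise gradient, or the path-mean gradient as a
# function of the path endpoint), symmetrised.
mechanism_hessian <- function(mech, x, cfg, step) {
  d <- length(x)
  baseline <- if (is.null(cfg$ig_baseline)) rep(0, d) else cfg$ig_baseline
  gr <- if (cfg$hessian == "smoothed") {
    function(Xrows) {
      # stack the paths of all query points into one gradient batch
      n <- cfg$n_steps
      big <- do.call(rbind, lapply(seq_len(nrow(Xrows)), function(r)
        ig_path_points(Xrows[r, ], baseline, n)))
      G <- mech$grad(big)
      t(vapply(seq_len(nrow(Xrows)), function(r)
        colMeans(G[((r - 1L) * n + 1L):(r * n), , drop = FALSE]),
        numeric(d)))
    }
  } else {
    mech$grad
  }
  Xp <- matrix(x, d, d, byrow = TRUE) + diag(step, d)
  Xm <- matrix(x, d, d, byrow = TRUE) - diag(step, d)
  Gp <- gr(Xp)
  Gm <- gr(Xm)
  H <- (Gp - Gm) / (2 * step)  # row j: d grad / d x_j
  (H + t(H)) / 2
}

#' Interventional expectation of a mechanism output under do(x_i = alpha)
#'
#' Second-order Taylor approximation of `E[F | do(x_i = alpha)]` around the
#' interventional mean: `F(mu) + 1/2 Tr(H(mu) Sigma_do)`, where `mu` is the
#' observed feature mean with coordinate `i` replaced by `alpha`, and
#' `Sigma_do` is the observed covariance with row and column `i` zeroed (the
#' intervened coordinate has no variance). The curvature `H` is the Hessian
#' of the (optionally path-smoothed) mechanism; see [ig_config()]. The
#' first-order term vanishes because the expansion point is the
#' interventional mean itself.
#'
#' @param model A trained `cfs_model` or a plain scalar function of a
#'   feature vector.
#' @param i Feature index (1-based column).
#' @param alpha Intervention value assigned to feature `i`.
#' @param stats A [estimate_stats()] object.
#' @param cfg An [ig_config()].
#' @param target_class Class (0-based, matching the labels) whose
#'   probability is the mechanism output; ignored for function mechanisms.
#' @param mask Fixed selection mask for the counterfactual predictor
#'   (default all ones); ignored for function mechanisms.
#' @return Scalar interventional expectation. If the curvature is not
#'   finite, falls back to the zeroth/first-order value `F(mu)` with a
#'   warning.
#' @export
interventional_mean <- function(model, i, alpha, stats, cfg = ig_config(),
                                target_class = 0L, mask = NULL) {
  d <- length(stats$mean)
  if (i < 1L || i > d) stop("feature index out of range")
  mech <- if (is.list(model) && !is.null(model$grad)) model else
    as_mechanism(model, d = d, mask = mask, target_class = target_class)
  mu <- stats$mean
  mu[i] <- alpha
  Sigma <- stats$cov
  Sigma[i, ] <- 0
  Sigma[, i] <- 0
  f_mu <- mech$f(mu)
  step <- pmax(1e-3 * (stats$high - stats$low), 1e-6)
  H <- mechanism_hessian(mech, mu, cfg, step)
  if (!all(is.finite(H))) {
    warning("non-finite curvature at do(x_", i, " = ", signif(alpha, 4),
            "); using first-order value")
    return(f_mu)
  }
  f_mu + 0.5 * sum(H * Sigma)  # Tr(H Sigma), both symmetric
}

#' Baseline expectation of a feature's interventional mean
#'
#' Averages [interventional_mean()] over an even grid of intervention
#' values spanning the feature's observed range (inclusive endpoints).
#'
#' @inheritParams interventional_mean
#' @param n_grid Number of grid points over `[low_i, high_i]`.
#' @return Scalar baseline value.
#' @export
baseline_value <- function(model, i, stats, cfg = ig_config(), n_grid = 50L,
                           target_class = 0L, mask = NULL) {
  grid <- seq(stats$low[i], stats$high[i], length.out = n_grid)
  mean(vapply(grid, function(a)
    interventional_mean(model, i, a, stats, cfg, target_class, mask),
    numeric(1L)))
}

#' Average-causal-effect curve of one feature
#'
#' For each intervention value `alpha` on an even grid over the feature's
#' observed range, the ACE is the interventional expectation
#' `E[F | do(x_i = alpha)]` minus the feature's baseline (the grid average
#' of those expectations). By construction the ACE averages to zero over
#' the grid.
#'
#' @inheritParams baseline_value
#' @return An `ace_curve`: list with `feature_index`, `target_class`,
#'   `alphas`, `interventional_means`, `baseline` and `ace`.
#' @export
ace_curve <- function(model, i, stats, cfg = ig_config(), n_grid = 50L,
                      target_class = 0L, mask = NULL) {
  grid <- seq(stats$low[i], stats$high[i], length.out = n_grid)
  ims <- vapply(grid, function(a)
    interventional_mean(model, i, a, stats, cfg, target_class, mask),
    numeric(1L))
  baseline <- mean(ims)
  structure(list(feature_index = i, target_class = as.integer(target_class),
                 alphas = grid, interventional_means = ims,
                 baseline = baseline, ace = ims - baseline),
            class = "ace_curve")
}

#' @export
print.ace_curve <- function(x, ...) {
  cat("ace_curve: feature", x$feature_index, "-> class", x$target_class,
      "|", length(x$alphas), "grid points\n")
  cat("  baseline:", signif(x$baseline, 4),
      "| max |ACE|:", signif(max(abs(x$ace)), 4), "\n")
  invisible(x)
}

#' ACE curves for every selected feature
#'
#' Aggregates the instance-wise selection into a single mask (a feature is
#' in the report if it is selected for any instance), fixes the
#' counterfactual predictor's mask channel at that aggregate selection, and
#' computes one [ace_curve()] per selected feature. A curve requested for a
#' feature outside the aggregate selection (via `features`) is exactly flat
#' by construction — the masked input is identically zero there, which is
#' the method's statement that an unselected feature has no causal effect
#' through the predictor. Set `force_mask = TRUE` to instead switch such a
#' feature's own mask bit on, probing how the network would respond to its
#' value; note this is an input configuration the predictor may never have
#' seen during training.
#'
#' @param model A trained `cfs_model`.
#' @param selection A `selection_result` from [cfs_select()].
#' @param stats A [estimate_stats()] object (typically of the same data).
#' @param cfg An [ig_config()].
#' @param n_grid Grid size per curve.
#' @param target_class Class (0-based) whose probability is analysed.
#' @param features Optional integer vector of feature columns to analyse
#'   (default: all features in the aggregate selection).
#' @param force_mask If `TRUE`, a requested feature outside the aggregate
#'   selection has its mask bit switched on for its own curve.
#' @return An `ace_report`: named list of `ace_curve`s (names are feature
#'   columns), with the aggregate mask attached as an attribute. Empty
#'   selection gives an empty report with a warning.
#' @export
ace_report <- function(model, selection, stats, cfg = ig_config(),
                       n_grid = 50L, target_class = 0L, features = NULL,
                       force_mask = FALSE) {
  agg <- as.numeric(apply(selection$mask, 2L, max))
  if (is.null(features)) features <- which(agg == 1)
  if (length(features) == 0L) {
    warning("empty selection: no features to analyse")
    out <- structure(list(), class = "ace_report")
    attr(out, "mask") <- agg
    return(out)
  }
  if (any(features < 1L | features > length(agg)))
    stop("feature index out of range")
  curves <- lapply(features, function(i) {
    m <- agg
    if (force_mask) m[i] <- 1
    ace_curve(model, i, stats, cfg, n_grid, target_class, mask = m)
  })
  names(curves) <- as.character(features)
  out <- structure(curves, class = "ace_report")
  attr(out, "mask") <- agg
  out
}

#' @export
print.ace_report <- function(x, ...) {
  cat("ace_report:", length(x), "feature curves\n")
  for (cv in x)
    cat(sprintf("  feature %d: max |ACE| = %.4g\n",
                cv$feature_index, max(abs(cv$ace))))
  invisible(x)
}

#' Write ACE curves as delimited text plus a JSON summary
#'
#' Writes `<path>` as comma-separated rows
#' `feature, alpha, interventional_mean, baseline, ace` and
#' `<path>.json` with the per-feature maximum absolute ACE.
#'
#' @param report An `ace_report` (or list of `ace_curve`s).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ace_report <- function(report, path) {
  rows <- lapply(report, function(cv)
    data.frame(feature = cv$feature_index, alpha = cv$alphas,
               interventional_mean = cv$interventional_means,
               baseline = cv$baseline, ace = cv$ace))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = integer(), alpha = numeric(),
               interventional_mean = numeric(), baseline = numeric(),
               ace = numeric())
  utils::write.csv(df, path, row.names = FALSE)
  summary <- lapply(report, function(cv) max(abs(cv$ace)))
  names(summary) <- vapply(report, function(cv)
    as.character(cv$feature_index), character(1L))
  jsonlite::write_json(summary, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
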