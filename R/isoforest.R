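#' Average unsuccessful-search path length c(n)
#'
#' The standard normalizer for isolation-tree path lengths:
#' `c(n) = 2 H(n-1) - 2 (n-1)/n` with `H(m) = ln(m) + gamma` (Euler-
#' Mascheroni), `c(1) = 0`.
#'
#' @param n Node size(s).
#' @return Numeric vector.
#' @export
avg_path_length <- function(n) {
  gamma_em <- 0.5772156649015329
  ifelse(n <= 1, 0, 2 * (log(n - 1) + gamma_em) - 2 * (n - 1) / n)
}

build_itree_ <- function(X, idx, depth, max_depth) {
  n <- length(idx)
  if (n <= 1 || depth >= max_depth) {
    return(list(leaf = TRUE, size = n))
  }
  # choose a split feature among those with spread at this node
  spreads <- apply(X[idx, , drop = FALSE], 2, function(col) diff(range(col)))
  usable <- which(spreads > 0)
  if (length(usable) == 0) return(list(leaf = TRUE, size = n))
  f <- if (length(usable) == 1) usable else sample(usable, 1)
  lo <- min(X[idx, f]); hi <- max(X[idx, f])
  s <- runif(1, lo, hi)
  left <- idx[X[idx, f] < s]
  right <- idx[X[idx, f] >= s]
  if (length(left) == 0 || length(right) == 0) {
    # runif can return its bounds at floating-point resolution
    return(list(leaf = TRUE, size = n))
  }
  list(leaf = FALSE, feature = f, split = s,
       left = build_itree_(X, left, depth + 1, max_depth),
       right = build_itree_(X, right, depth + 1, max_depth))
}

path_length_ <- function(tree, x, depth = 0) {
  if (tree$leaf) return(depth + avg_path_length(tree$size))
  if (x[tree$feature] < tree$split) {
    path_length_(tree$left, x, depth + 1)
  } else {
    path_length_(tree$right, x, depth + 1)
  }
}

#' Fit an isolation forest
#'
#' Builds an ensemble of random binary isolation trees on subsamples of
#' the data. Each tree recursively splits a uniformly chosen feature at a
#' uniform point between the node's min and max until points are isolated
#' or the height limit `ceiling(log2(subsample))` is reached. Anomalous
#' points are isolated in few splits, so short average path lengths mean
#' high anomaly scores. Fully deterministic given `seed`.
#'
#' @param x Numeric vector (1-D feature, e.g. weekly spending frequency)
#'   or matrix (rows = observations).
#' @param n_trees Number of trees (default 100).
#' @param subsample Per-tree subsample size, default `min(256, n)`;
#'   sampled without replacement.
#' @param seed Integer RNG seed.
#' @return An `fp_isoforest` model: `trees`, `subsample`, `n_trees`,
#'   `seed`, `p` (feature count), `degenerate` (constant input, no
#'   isolating split possible).
#' @export
fit_isolation_forest <- function(x, n_trees = 100,
                                 subsample = NULL, seed = 1L) {
  X <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
  n <- nrow(X)
  if (n < 8) abort("fit_isolation_forest: need at least 8 observations")
  subsample <- subsample %||% min(256L, n)
  if (subsample > n) abort("subsample must be <= number of observations")
  max_depth <- ceiling(log2(subsample))
  degenerate <- all(apply(X, 2, function(col) diff(range(col))) == 0)
  trees <- with_seed_(seed, {
    lapply(seq_len(n_trees), function(t) {
      idx <- sample.int(n, subsample, replace = FALSE)
      build_itree_(X, idx, 0, max_depth)
    })
  })
  structure(list(trees = trees, subsample = subsample, n_trees = n_trees,
                 seed = seed, p = ncol(X), degenerate = degenerate),
            class = "fp_isoforest")
}

#' Anomaly scores from an isolation forest
#'
#' The standard isolation-forest score `s(x) = 2^(-E[h(x)] / c(psi))`,
#' where `E[h(x)]` averages per-tree path lengths (with the `c(size)`
#' adjustment added at unexpanded leaves) and `psi` is the subsample size.
#' Scores lie in (0, 1); higher means more anomalous; 0.5 corresponds to a
#' path length equal to the average unsuccessful-search depth. A
#' degenerate model (constant training data) scores everything 0.5.
#'
#' @param model An `fp_isoforest`.
#' @param x Values to score (vector or matrix matching the model's
#'   feature count).
#' @return Numeric score vector in (0, 1).
#' @export
anomaly_scores <- function(model, x) {
  stopifnot(inherits(model, "fp_isoforest"))
  X <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
  stopifnot(ncol(X) == model$p)
  cn <- avg_path_length(model$subsample)
  if (model$degenerate || cn == 0) return(rep(0.5, nrow(X)))
  Eh <- vapply(seq_len(nrow(X)), function(i) {
    mean(vapply(model$trees, path_length_, numeric(1), x = X[i, ]))
  }, numeric(1))
  2^(-Eh / cn)
}

#' Flag the top-scoring periods as anomalies
#'
#' The contamination parameter is the assumed fraction of anomalous
#' points: exactly `k = floor(contamination * n)` of the highest-scoring
#' points are flagged (ties broken toward the earlier period), and the
#' reported threshold is the `1 - contamination` empirical quantile of
#' the scores.
#'
#' @param scores Numeric anomaly scores.
#' @param contamination Assumed anomaly fraction, in (0, 1).
#' @param periods Optional period identifiers (e.g. `period_start`);
#'   defaults to the score index. Order defines the tie-break.
#' @return An `fp_anomaly` tibble: `period`, `score`, `flagged`; with
#'   attributes `threshold`, `contamination`, `k`.
#' @export
flag_outliers <- function(scores, contamination, periods = NULL) {
  stopifnot(is_scalar_number(contamination),
            contamination > 0, contamination < 1)
  n <- length(scores)
  periods <- periods %||% seq_len(n)
  k <- floor(contamination * n)
  if (k == 0) warn("flag_outliers: contamination * n < 1; no points flagged")
  ord <- order(-scores, seq_len(n))  # score desc, earlier period wins ties
  flagged <- logical(n)
  if (k > 0) flagged[ord[seq_len(k)]] <- TRUE
  out <- tibble(period = periods, score = scores, flagged = flagged)
  structure(out,
            threshold = unname(quantile(scores, 1 - contamination)),
            contamination = contamination, k = k,
            class = c("fp_anomaly", class(out)))
}

#' Detect anomalous spending periods in a feature series
#'
#' Convenience wrapper for the usual workflow: fit an isolation forest on
#' the weekly frequency series (transductively — the same points are
#' fitted and scored), score it, and flag the top `contamination`
#' fraction. Both unusually high and unusually low frequency periods can
#' be flagged, since extremes in either direction are easy to isolate.
#'
#' @param features Feature tibble from [resample_features()] (weekly grain
#'   in the reference analysis).
#' @param contamination Assumed anomaly fraction (default 0.05).
#' @param n_trees,subsample,seed Passed to [fit_isolation_forest()].
#' @param endpoint Column to analyze, default `"frequency"`.
#' @param exclude_partial Drop partial edge periods (when the series has a
#'   `partial` column) before fitting: a truncated first or last period has
#'   an artificially low count and would otherwise be flagged as a trivial
#'   extreme.
#' @return An `fp_anomaly` tibble keyed by `period` = `period_start`, with
#'   the endpoint column carried alongside.
#' @export
detect_anomalies <- function(features, contamination = 0.05, n_trees = 100,
                             subsample = NULL, seed = 1L,
                             endpoint = "frequency",
                             exclude_partial = TRUE) {
  if (exclude_partial && "partial" %in% names(features)) {
    features <- features[!features$partial, , drop = FALSE]
  }
  vals <- features[[endpoint]]
  model <- fit_isolation_forest(vals, n_trees = n_trees,
                                subsample = subsample, seed = seed)
  sc <- anomaly_scores(model, vals)
  out <- flag_outliers(sc, contamination, periods = features$period_start)
  out[[endpoint]] <- vals
  out
}
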