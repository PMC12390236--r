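# Two-step dimensionality reduction: (1) pairwise correlation pruning at
# |r| > 0.97, (2) random-forest importance ranking with a top-60% cut
# followed by greedy forward retention driven by cross-validated R2.

#' Prune highly correlated feature columns
#'
#' Iterates column pairs in canonical (given) order; whenever a pair of
#' still-retained columns has `|Pearson r|` above the threshold, the later
#' column is dropped. Constant columns have undefined correlation, treated
#' as 0, and are retained.
#'
#' @param x numeric matrix (rows = examinations).
#' @param threshold absolute correlation above which a pair is considered
#'   redundant.
#' @return list with `retained` (column names), `pruned_pairs` (data frame
#'   kept/dropped/correlation).
#' @export
prune_correlated <- function(x, threshold = 0.97) {
  stopifnot(nrow(x) >= 2)
  cm <- suppressWarnings(cor(x))
  cm[!is.finite(cm)] <- 0
  p <- ncol(x)
  keep <- rep(TRUE, p)
  kept_v <- character(0); dropped_v <- character(0); rv <- numeric(0)
  for (i in seq_len(p - 1)) {
    if (!keep[i]) next
    off <- which(keep & seq_len(p) > i & abs(cm[i, ]) > threshold)
    if (length(off)) {
      keep[off] <- FALSE
      kept_v <- c(kept_v, rep(colnames(x)[i], length(off)))
      dropped_v <- c(dropped_v, colnames(x)[off])
      rv <- c(rv, cm[i, off])
    }
  }
  list(retained = colnames(x)[keep],
       pruned_pairs = data.frame(kept = kept_v, dropped = dropped_v,
                                 correlation = rv))
}

#' Rank features by random-forest importance and keep the top fraction
#'
#' Impurity importance from a random forest fit on all rows, sorted in
#' descending order; `ceiling(keep_fraction * p)` features are returned.
#' Fewer than 2 input features pass through unchanged.
#'
#' @param x numeric feature matrix.
#' @param y numeric target.
#' @param keep_fraction fraction of features retained after ranking.
#' @param seed integer seed for the forest.
#' @param num_trees number of trees.
#' @return character vector of feature names, most important first.
#' @export
rank_and_cut <- function(x, y, keep_fraction = 0.60, seed = 1L,
                         num_trees = 500) {
  if (ncol(x) < 2) return(colnames(x))
  rf <- ranger::ranger(y = y, x = as.data.frame(x), num.trees = num_trees,
                       importance = "impurity", seed = as.integer(seed),
                       num.threads = 1)
  imp <- sort(rf$variable.importance, decreasing = TRUE)
  head(names(imp), ceiling(keep_fraction * ncol(x)))
}

# Pooled-prediction cross-validated R2 of a model on a feature subset.
cv_score <- function(x, y, features, model_spec, k = 5, seed = 1L) {
  folds <- make_folds(length(y), scheme = cv_scheme("kfold", k = k,
                                                    seed = seed))
  pred <- numeric(length(y))
  for (f in unique(folds)) {
    te <- folds == f
    sc <- fit_scaler(x[!te, features, drop = FALSE])
    xtr <- apply_scaler(x[!te, features, drop = FALSE], sc)
    xte <- apply_scaler(x[te, features, drop = FALSE], sc)
    m <- fit_regressor(xtr, y[!te], model_spec)
    pred[te] <- predict(m, xte)
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Greedy forward feature retention
#'
#' Starting from the most important feature, candidates are added in
#' ranking order and retained only if the cross-validated score strictly
#' improves (by more than `epsilon`). The first-ranked feature is always
#' retained.
#'
#' @param x numeric feature matrix.
#' @param y numeric target.
#' @param ranked character vector of candidate features, most important
#'   first.
#' @param model_spec a [model_spec()] used for scoring.
#' @param k inner cross-validation folds.
#' @param seed seed for the inner folds.
#' @param epsilon minimum improvement counted as progress.
#' @param max_features optional cap on candidates examined.
#' @return list with `retained` (ordered names) and `cv_trace` (data frame
#'   step/feature/score/retained); the trace restricted to retained steps
#'   is strictly increasing.
#' @export
greedy_forward_select <- function(x, y, ranked, model_spec = model_spec("rf"),
                                  k = 5, seed = 1L, epsilon = 0,
                                  max_features = Inf) {
  stopifnot(length(ranked) >= 1)
  ranked <- head(ranked, max_features)
  retained <- ranked[1]
  best <- cv_score(x, y, retained, model_spec, k = k, seed = seed)
  trace <- data.frame(step = 1L, feature = ranked[1], score = best,
                      retained = TRUE)
  for (j in seq_along(ranked)[-1]) {
    cand <- c(retained, ranked[j])
    s <- cv_score(x, y, cand, model_spec, k = k, seed = seed)
    ok <- s > best + epsilon
    trace <- rbind(trace, data.frame(step = j, feature = ranked[j],
                                     score = s, retained = ok))
    if (ok) { retained <- cand; best <- s }
  }
  list(retained = retained, cv_trace = trace)
}

#' Run the full two-step selection on a training table
#'
#' Correlation pruning, importance ranking with the top-60% cut and,
#' optionally, greedy forward retention.
#'
#' @param x numeric feature matrix (training rows only).
#' @param y numeric target.
#' @param threshold correlation pruning threshold.
#' @param keep_fraction top fraction kept after importance ranking.
#' @param greedy run the greedy forward stage (slow for wide tables).
#' @param model_spec scoring model for the greedy stage.
#' @param seed integer seed.
#' @param max_features cap on greedy candidates.
#' @return character vector of selected feature names.
#' @export
select_features <- function(x, y, threshold = 0.97, keep_fraction = 0.60,
                            greedy = FALSE, model_spec = model_spec("rf"),
                            seed = 1L, max_features = Inf) {
  pruned <- prune_correlated(x, threshold)$retained
  ranked <- rank_and_cut(x[, pruned, drop = FALSE], y,
                         keep_fraction = keep_fraction, seed = seed)
  if (!greedy) return(ranked)
  greedy_forward_select(x, y, ranked, model_spec = model_spec,
                        seed = seed, max_features = max_features)$retained
}
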