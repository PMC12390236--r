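# Standard and class-balanced regression metrics for imbalanced ordinal
# targets, plus prediction clipping and permutation feature importance.

#' Regression metrics with class-balanced variants
#'
#' Computes MSE, R-squared, MAE and Pearson's r, then discretizes the true
#' values to their label grid (integers for 0-4 symptom severities, a 0.5
#' grid for the -4..4 treatment-response state), computes the MAE and MSE
#' separately per class, and averages them over the classes present:
#' `bMAE = mean_k(MAE_k)`, `bMSE = mean_k(MSE_k)`. With equal class counts
#' bMAE equals MAE and bMSE equals MSE. Predictions are never discretized.
#'
#' For zero-variance true values R-squared and r are undefined and reported
#' as `NA` with `degenerate = TRUE`.
#'
#' @param pred a `pd_predictions` data frame (or any data frame with
#'   `y_true` and `y_pred`).
#' @param grid spacing of the label grid used for per-class metrics.
#' @return list of class `pd_metrics`: `mse`, `r2`, `mae`, `r`,
#'   `per_class` (data frame class/n/mae/mse), `bmae`, `bmse`, `n_classes`,
#'   `degenerate`.
#' @export
compute_metrics <- function(pred, grid = 1) {
  y <- pred$y_true; p <- pred$y_pred
  stopifnot(length(y) == length(p), length(y) > 0)
  err <- y - p
  mse <- mean(err^2)
  mae <- mean(abs(err))
  degenerate <- var(y) == 0
  r2 <- if (degenerate) NA_real_ else 1 - sum(err^2) / sum((y - mean(y))^2)
  r <- if (degenerate || sd(p) == 0) NA_real_ else cor(y, p)
  cls <- round(y / grid) * grid
  per <- do.call(rbind, lapply(sort(unique(cls)), function(k) {
    sel <- cls == k
    data.frame(class = k, n = sum(sel), mae = mean(abs(err[sel])),
               mse = mean(err[sel]^2))
  }))
  structure(list(mse = mse, r2 = r2, mae = mae, r = r, per_class = per,
                 bmae = mean(per$mae), bmse = mean(per$mse),
                 n_classes = nrow(per), degenerate = degenerate),
            class = "pd_metrics")
}

#' @export
print.pd_metrics <- function(x, ...) {
  cat(sprintf("MSE %.3f | R2 %s | MAE %.3f | r %s | bMAE %.3f | bMSE %.3f (%d classes)\n",
              x$mse, format(round(x$r2, 3)), x$mae, format(round(x$r, 3)),
              x$bmae, x$bmse, x$n_classes))
  invisible(x)
}

#' Clip predictions to the valid target range
#'
#' Post-processing for regression outputs that fall outside the label
#' range: values below/above the bounds are moved to the bounds, interior
#' values and ordering are preserved.
#'
#' @param pred a `pd_predictions` data frame.
#' @param range two-element numeric, e.g. `c(0, 4)` for symptom severities
#'   or `c(-4, 4)` for the treatment-response state.
#' @return the prediction set with clipped `y_pred`.
#' @export
clip_predictions <- function(pred, range = c(0, 4)) {
  pred$y_pred <- pmin(pmax(pred$y_pred, range[1]), range[2])
  pred
}

#' Permutation feature importance
#'
#' Mean decrease in R-squared when each feature column is shuffled,
#' averaged over `n_repeats` permutations; deterministic given `seed`.
#'
#' @param model a fitted `pd_model`.
#' @param x numeric feature matrix (more than one row).
#' @param y numeric target.
#' @param n_repeats number of shuffles per feature.
#' @param seed integer seed.
#' @return named numeric vector of importance scores (one per column),
#'   descending.
#' @export
permutation_importance <- function(model, x, y, n_repeats = 10, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need more than one row for permutation importance")
  r2 <- function(yy, pp) 1 - sum((yy - pp)^2) / sum((yy - mean(yy))^2)
  base <- r2(y, predict(model, x))
  set.seed(as.integer(seed))
  imp <- vapply(seq_len(ncol(x)), function(j) {
    drops <- vapply(seq_len(n_repeats), function(i) {
      xp <- x
      xp[, j] <- xp[sample(nrow(x)), j]
      base - r2(y, predict(model, xp))
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  sort(setNames(imp, colnames(x)), decreasing = TRUE)
}
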