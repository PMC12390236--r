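# The three regressor families: random forest (ranger), gradient-boosted
# trees (xgboost) and an RBF-kernel support vector regressor (e1071). All
# are used with their implementation defaults; features are expected to be
# z-scored by the caller.

#' Specify a regression model
#'
#' @param kind `"rf"` (random forest), `"xgb"` (gradient-boosted trees) or
#'   `"svm"` (RBF support vector regression).
#' @param seed integer seed (tree families; the SVM fit is deterministic).
#' @param ... implementation arguments overriding the defaults
#'   (e.g. `num.trees`, `nrounds`, `cost`).
#' @return a `pd_model_spec`.
#' @export
model_spec <- function(kind = c("rf", "xgb", "svm"), seed = 1L, ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = as.integer(seed), args = list(...)),
            class = "pd_model_spec")
}

#' Fit one regressor
#'
#' @param x numeric feature matrix (no missing values, >= 2 rows).
#' @param y numeric target.
#' @param spec a [model_spec()].
#' @return a `pd_model` with a [predict][predict.pd_model] method.
#' @export
fit_regressor <- function(x, y, spec = model_spec("rf")) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to fit a regressor")
  if (anyNA(x) || anyNA(y)) stop("missing values in model input")
  fit <- switch(spec$kind,
    rf = do.call(ranger::ranger, c(list(
      y = y, x = as.data.frame(x), seed = spec$seed, num.threads = 1),
      spec$args)),
    xgb = {
      set.seed(spec$seed)
      nrounds <- spec$args$nrounds %||% 100
      params <- c(list(objective = "reg:squarederror", nthread = 1,
                       seed = spec$seed),
                  spec$args[setdiff(names(spec$args), "nrounds")])
      xgboost::xgb.train(params = params,
                         data = xgboost::xgb.DMatrix(x, label = y),
                         nrounds = nrounds)
    },
    svm = do.call(e1071::svm, c(list(x = x, y = y, scale = FALSE),
                                spec$args)))
  structure(list(kind = spec$kind, fit = fit, features = colnames(x)),
            class = "pd_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
predict.pd_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features))
    newdata <- newdata[, object$features, drop = FALSE]
  switch(object$kind,
    rf = predict(object$fit, data = as.data.frame(newdata),
                 num.threads = 1)$predictions,
    xgb = predict(object$fit, xgboost::xgb.DMatrix(newdata)),
    svm = as.numeric(predict(object$fit, newdata)))
}

#' Specify a cross-validation scheme
#'
#' @param kind `"kfold"` (shuffled k-fold) or `"loo_patient"`
#'   (leave-one-patient-out: each fold's test set is all examinations of
#'   one patient).
#' @param k number of folds for `"kfold"`.
#' @param seed integer seed for the shuffle.
#' @return a `pd_cv_scheme`.
#' @export
cv_scheme <- function(kind = c("kfold", "loo_patient"), k = 10, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, k = as.integer(k), seed = as.integer(seed)),
            class = "pd_cv_scheme")
}

# Fold assignment vector (one integer per row). For grouped LOO the folds
# are the distinct patients.
make_folds <- function(n, scheme, patient_id = NULL) {
  if (scheme$kind == "kfold") {
    k <- min(scheme$k, n)
    set.seed(scheme$seed)
    sample(rep_len(seq_len(k), n))
  } else {
    if (is.null(patient_id)) stop("leave-one-patient-out requires patient ids")
    as.integer(factor(patient_id, levels = unique(patient_id)))
  }
}

#' Cross-validated out-of-fold predictions
#'
#' Every row is predicted exactly once by a model that never saw it (nor,
#' under `"loo_patient"`, any examination of the same patient).
#' Z-normalization is fitted on each training fold and applied to its test
#' fold; optional feature selection likewise runs inside each training
#' fold.
#'
#' @param x numeric feature matrix.
#' @param y numeric target.
#' @param patient_id patient grouping vector (required for
#'   `"loo_patient"`).
#' @param spec a [model_spec()].
#' @param scheme a [cv_scheme()].
#' @param selection `NULL`, or a list of arguments for [select_features()]
#'   applied within each training fold (e.g.
#'   `list(keep_fraction = 0.6, greedy = FALSE)`).
#' @return a `pd_predictions` data frame with `y_true`, `y_pred`, `fold`
#'   and `row`.
#' @export
cross_validate <- function(x, y, patient_id = NULL, spec = model_spec("rf"),
                           scheme = cv_scheme("kfold"), selection = NULL) {
  x <- as.matrix(x)
  folds <- make_folds(nrow(x), scheme, patient_id)
  pred <- numeric(nrow(x))
  for (f in unique(folds)) {
    te <- folds == f
    xtr <- x[!te, , drop = FALSE]; ytr <- y[!te]
    cols <- colnames(x)
    if (!is.null(selection))
      cols <- do.call(select_features, c(list(x = xtr, y = ytr), selection))
    sc <- fit_scaler(xtr[, cols, drop = FALSE])
    m <- fit_regressor(apply_scaler(xtr[, cols, drop = FALSE], sc), ytr, spec)
    pred[te] <- predict(m, apply_scaler(x[te, cols, drop = FALSE], sc))
  }
  structure(data.frame(y_true = y, y_pred = pred, fold = folds,
                       row = seq_along(y)),
            class = c("pd_predictions", "data.frame"))
}
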