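# Experiment orchestration: run model x validation-scheme grids over data
# scopes (single sensor/exercise, single exercise, single device, all
# data), collect metric reports, and render the standard figures.

#' Column subset of a feature table for a data scope
#'
#' A scope restricts which recording blocks contribute features; metadata
#' columns are always included.
#'
#' @param ft a `pd_feature_table`.
#' @param device,sensor,exercise optional restrictions; `NULL` keeps all.
#' @return character vector of column names.
#' @export
scope_columns <- function(ft, device = NULL, sensor = NULL, exercise = NULL) {
  info <- ft$feature_info
  keep <- info$kind == "meta" |
    ((is.null(device) | info$device %in% device) &
     (is.null(sensor) | info$sensor %in% sensor) &
     (is.null(exercise) | info$exercise %in% exercise) &
     info$kind == "sensor")
  info$name[keep]
}

#' Run an experiment grid
#'
#' One cross-validated run per (scope, target, model, scheme) cell; each
#' cell yields a full metric report row. The best cell per (target, scheme)
#' is flagged by highest R-squared, ties broken by lower bMAE.
#'
#' @param ft a `pd_feature_table`.
#' @param targets label columns to predict (symptoms and/or
#'   treatment-response states).
#' @param scopes named list; each element is a list with optional `device`,
#'   `sensor`, `exercise` restrictions.
#' @param models character vector of model kinds (`"rf"`, `"xgb"`,
#'   `"svm"`).
#' @param schemes named list of [cv_scheme()]s.
#' @param selection optional selection configuration passed to
#'   [cross_validate()].
#' @param seed base seed for model fits.
#' @param keep_predictions also return the per-cell prediction sets.
#' @return data frame of metric rows (and, if requested, an attribute
#'   `predictions`: a list keyed `scope.target.model.scheme`).
#' @export
run_grid <- function(ft, targets = SYMPTOMS,
                     scopes = list(all_data = list()),
                     models = c("rf", "xgb", "svm"),
                     schemes = list(`10F` = cv_scheme("kfold", k = 10),
                                    LOO = cv_scheme("loo_patient")),
                     selection = NULL, seed = 1L,
                     keep_predictions = FALSE) {
  rows <- list(); preds <- list()
  for (sc_name in names(scopes)) {
    cols <- do.call(scope_columns, c(list(ft = ft), scopes[[sc_name]]))
    xs <- ft$features[, cols, drop = FALSE]
    for (target in targets) {
      y <- ft$labels[[target]]
      grid <- if (target %in% TRS_TARGETS) 0.5 else 1
      for (mk in models) for (cv_name in names(schemes)) {
        pr <- cross_validate(xs, y, patient_id = ft$patient_id,
                             spec = model_spec(mk, seed = seed),
                             scheme = schemes[[cv_name]],
                             selection = selection)
        m <- compute_metrics(pr, grid = grid)
        rows[[length(rows) + 1]] <- data.frame(
          scope = sc_name, target = target, model = mk, scheme = cv_name,
          n = nrow(pr), r2 = m$r2, r = m$r, mse = m$mse, mae = m$mae,
          bmae = m$bmae, bmse = m$bmse, n_classes = m$n_classes)
        if (keep_predictions)
          preds[[paste(sc_name, target, mk, cv_name, sep = ".")]] <- pr
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$best <- FALSE
  for (tg in unique(out$target)) for (cv in unique(out$scheme)) {
    sel <- which(out$target == tg & out$scheme == cv)
    if (!length(sel)) next
    ord <- sel[order(-out$r2[sel], out$bmae[sel])]
    out$best[ord[1]] <- TRUE
  }
  if (keep_predictions) attr(out, "predictions") <- preds
  out
}

#' Violin plot of predictions per true severity class
#'
#' One violin per true class with the class-specific MAE annotated;
#' degenerate classes (constant predictions) are drawn as points.
#'
#' @param pred a `pd_predictions` data frame.
#' @param path output image path (e.g. PNG).
#' @param target label used in the title.
#' @param grid label grid spacing.
#' @return list with `path` and the `per_class` MAE table, invisibly.
#' @export
severity_violin_report <- function(pred, path, target = "severity",
                                   grid = 1) {
  m <- compute_metrics(pred, grid = grid)
  df <- data.frame(cls = factor(round(pred$y_true / grid) * grid),
                   y_pred = pred$y_pred)
  spread <- tapply(df$y_pred, df$cls, sd)
  ok <- df$cls %in% names(spread)[!is.na(spread) & spread > 0]
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = cls, y = y_pred)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7)
  if (any(ok))
    gg <- gg + ggplot2::geom_violin(data = df[ok, ], alpha = 0.5,
                                    fill = "steelblue", scale = "width")
  gg <- gg +
    ggplot2::annotate("text", x = seq_len(nrow(m$per_class)),
                      y = max(df$y_pred) + 0.3,
                      label = sprintf("MAE %.2f", m$per_class$mae),
                      size = 2.8) +
    ggplot2::labs(x = "true severity class", y = "predicted severity",
                  title = target)
  ggplot2::ggsave(path, gg, width = 6, height = 4, dpi = 100)
  invisible(list(path = path, per_class = m$per_class))
}

#' Scatter plot of predicted vs true treatment-response state
#'
#' True values on the x-axis, predictions on the y-axis, identity line,
#' both axes spanning -4..4.
#'
#' @param pred a `pd_predictions` data frame.
#' @param path output image path.
#' @param target label used in the title.
#' @return list with `path` and the point count, invisibly.
#' @export
trs_scatter_report <- function(pred, path, target = "treatment-response state") {
  gg <- ggplot2::ggplot(pred, ggplot2::aes(x = y_true,
                                           y = y_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(-4, 4), ylim = c(-4, 4)) +
    ggplot2::labs(x = "true state", y = "predicted state", title = target)
  ggplot2::ggsave(path, gg, width = 5, height = 5, dpi = 100)
  invisible(list(path = path, n = nrow(pred)))
}

#' Paired Wilcoxon signed-rank comparison of two score vectors
#'
#' Thin wrapper over [stats::wilcox.test()] for comparing per-cell
#' R-squared scores of two models or validation schemes.
#'
#' @param a,b equal-length numeric score vectors (paired by grid cell).
#' @return the `htest` result.
#' @export
compare_scores <- function(a, b) {
  stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
}
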