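#' Mean absolute error
#'
#' MAE = (1/n) sum |x_i - y_i|, in the units of the target.
#'
#' @param x real (observed) values.
#' @param y predicted values, same length.
#' @return non-negative scalar.
#' @export
mae <- function(x, y) {
  check_paired(x, y)
  mean(abs(x - y))
}

#' Root-mean-squared error
#'
#' RMSE = sqrt(sum (x_i - y_i)^2 / n). Always >= MAE on the same pairs.
#'
#' @inheritParams mae
#' @return non-negative scalar.
#' @export
rmse <- function(x, y) {
  check_paired(x, y)
  sqrt(mean((x - y)^2))
}

check_paired <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length (", length(x), " vs ", length(y), ")")
  }
  if (length(x) == 0) stop("empty input")
  invisible(NULL)
}

#' Overall error across sub-ranges
#'
#' The study's aggregate: the \emph{arithmetic mean} of the per-sub-range
#' error values (equal-count sub-ranges make this an equal-weight mean, which
#' for MAE coincides with the pooled error; for RMSE it is generally smaller
#' than the pooled RMSE). Degenerate sub-ranges are excluded; if all are
#' excluded the overall error is not estimated (`NA`).
#'
#' @param per_subrange numeric vector of per-sub-range MAE or RMSE values.
#' @param excluded integer indices of degenerate sub-ranges to drop.
#' @return scalar mean, or `NA_real_` when every sub-range is excluded.
#' @export
overall_error <- function(per_subrange, excluded = integer(0)) {
  keep <- setdiff(seq_along(per_subrange), excluded)
  if (length(keep) == 0) return(NA_real_)
  mean(per_subrange[keep])
}

#' Percentage change of a sub-range overall error vs the full-range model
#'
#' 100 * (sub_overall - full_overall) / full_overall; negative values mean the
#' segmented model is more accurate.
#'
#' @param sub_overall overall error of the segmented (k > 1) model.
#' @param full_overall overall error of the corresponding full-range model;
#'   must be positive.
#' @return percentage (not rounded).
#' @export
pct_change <- function(sub_overall, full_overall) {
  if (!is.finite(full_overall) || full_overall <= 0) {
    stop("full-range error must be positive, got ", full_overall)
  }
  100 * (sub_overall - full_overall) / full_overall
}

#' Evaluate a segmented model
#'
#' Routes every case (RVS/FULL by the real target value, PVS by the stage-1
#' prediction), predicts with the routed sub-model, and reports per-sub-range
#' MAE/RMSE over \emph{all} cases landing in each sub-range, plus the overall
#' (mean-of-sub-ranges) aggregates. Degenerate sub-ranges appear with `NA`
#' errors and are excluded from the overall values. Per-split (train, valid,
#' test) errors are reported as supplementary columns when a split assignment
#' is given. Sub-ranges that receive no cases are excluded from the overall
#' aggregates, like degenerate ones.
#'
#' @param model a `segmented_model`.
#' @param table a `case_table` with real target values.
#' @param split optional `split_assignment` aligned with `table` rows.
#' @return an `error_report`: list with `table` (per-sub-range data frame),
#'   `overall_mae`, `overall_rmse`, `k`, `mode`, `excluded`.
#' @export
evaluate <- function(model, table, split = NULL) {
  target <- model$target
  if (!(target %in% names(table))) stop("table lacks target column ", target)
  y <- table[[target]]
  idx <- route_for_evaluation(model, table)
  pred <- predict(model, table)
  deg <- vapply(model$submodels, is_degenerate_marker, logical(1))
  rows <- lapply(seq_len(model$k), function(i) {
    sel <- idx == i
    n_i <- sum(sel)
    if (deg[i] || n_i == 0) {
      data.frame(subrange = i, label = subrange_label(model, i),
                 low = model$ranges[i, "low"], high = model$ranges[i, "high"],
                 n = n_i, mae = NA_real_, rmse = NA_real_)
    } else {
      data.frame(subrange = i, label = subrange_label(model, i),
                 low = model$ranges[i, "low"], high = model$ranges[i, "high"],
                 n = n_i, mae = mae(y[sel], pred[sel]),
                 rmse = rmse(y[sel], pred[sel]))
    }
  })
  tab <- do.call(rbind, rows)
  if (!is.null(split)) {
    for (lab in c("train", "valid", "test")) {
      tab[[paste0("mae_", lab)]] <- vapply(seq_len(model$k), function(i) {
        sel <- idx == i & split == lab
        if (deg[i] || !any(sel)) NA_real_ else mae(y[sel], pred[sel])
      }, numeric(1))
    }
  }
  # degenerate sub-ranges and sub-ranges receiving no cases carry no error
  excluded <- union(which(deg), which(tab$n == 0))
  structure(list(
    table = tab,
    overall_mae = overall_error(tab$mae, excluded),
    overall_rmse = overall_error(tab$rmse, excluded),
    k = model$k, mode = model$mode, target = target, excluded = excluded
  ), class = "error_report")
}

subrange_label <- function(model, i) {
  sprintf("%s-%d/%d", model$mode, i, model$k)
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> %s k = %d, target %s\n", x$mode, x$k, x$target))
  print(transform(x$table, mae = round(mae, 3), rmse = round(rmse, 3),
                  low = signif(low, 4), high = signif(high, 4)),
        row.names = FALSE)
  cat(sprintf(" overall MAE %.4g | overall RMSE %.4g", x$overall_mae,
              x$overall_rmse))
  if (length(x$excluded) > 0) {
    cat(" | excluded sub-ranges:", paste(x$excluded, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Percentage-change comparison table across k
#'
#' Compares each report's overall MAE/RMSE to the k = 1 report of the same
#' mode, mirroring the summary layout of segmented-vs-full-range studies.
#'
#' @param reports list of `error_report`s (must include one with k = 1 per
#'   mode).
#' @return data frame with columns `mode`, `k`, `overall_mae`, `overall_rmse`,
#'   `dmae_pct`, `drmse_pct` (0 for k = 1, rounded to 1 decimal).
#' @export
comparison_table <- function(reports) {
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(mode = r$mode, k = r$k, overall_mae = r$overall_mae,
               overall_rmse = r$overall_rmse)
  }))
  df$dmae_pct <- NA_real_
  df$drmse_pct <- NA_real_
  for (m in unique(df$mode)) {
    base <- df[df$mode == m & df$k == 1, ]
    if (nrow(base) != 1) next
    sel <- df$mode == m
    df$dmae_pct[sel] <- round_half_up(
      pct_change(df$overall_mae[sel], base$overall_mae), 1)
    df$drmse_pct[sel] <- round_half_up(
      pct_change(df$overall_rmse[sel], base$overall_rmse), 1)
  }
  df
}

# Half-up decimal rounding (R's round() is banker's rounding); reports use the
# convention of the printed tables.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Write an error report as CSV or JSON
#'
#' CSV mirrors the printed-table layout (model label, sub-range bounds, n,
#' MAE, overall MAE, RMSE, overall RMSE, with overall values on the first
#' row); JSON holds the full report.
#'
#' @param report an `error_report`.
#' @param path output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_error_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(mode = report$mode, k = report$k, target = report$target,
           overall_mae = report$overall_mae, overall_rmse = report$overall_rmse,
           excluded = report$excluded, table = report$table),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    out <- report$table
    out$overall_mae <- c(report$overall_mae, rep(NA, nrow(out) - 1))
    out$overall_rmse <- c(report$overall_rmse, rep(NA, nrow(out) - 1))
    ord <- c("label", "low", "high", "n", "mae", "overall_mae", "rmse",
             "overall_rmse")
    ord <- c(ord, setdiff(names(out), c(ord, "subrange")))
    utils::write.csv(out[, ord], path, row.names = FALSE, na = "")
  }
  invisible(path)
}
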