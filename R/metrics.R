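# Evaluation metrics for affinity regression, plus the Kd -> pKd transform.

#' Convert a dissociation constant to pKd
#'
#' `pKd = -log10(Kd / 1e9)` with `Kd` in nanomolar, so 1 nM maps to 9 and
#' 1e9 nM (1 M) maps to 0.
#'
#' @param kd Dissociation constant(s) in nM; must be strictly positive.
#' @return pKd value(s).
#' @export
kd_to_pkd <- function(kd) {
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("Kd must be strictly positive and finite (nM)")
  -log10(kd / 1e9)
}

#' Regression metric suite
#'
#' Computes mean squared error, its square root, Pearson and Spearman
#' correlations (mid-ranks for ties), the coefficient of determination
#' relative to the mean model, and the concordance index.
#'
#' Correlation fields (and CI when no pair of true values is strictly
#' ordered) are returned as `NA` with a warning when undefined (constant
#' input), never silently zero.
#'
#' @param y True affinities.
#' @param yhat Predicted affinities.
#' @param ci Include the concordance index (set `FALSE` to skip the O(n log
#'   n) pass when only error metrics are needed).
#' @return Object of class `dta_metric_report`: list with `mse`, `rmse`,
#'   `pearson`, `spearman`, `ci`, `r2`, `n`.
#' @export
regression_metrics <- function(y, yhat, ci = TRUE) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L,
            all(is.finite(y)), all(is.finite(yhat)))
  n <- length(y)
  mse <- mean((y - yhat)^2)
  r2 <- 1 - sum((yhat - y)^2) / sum((mean(y) - y)^2)
  const_y <- stats::sd(y) == 0
  const_yh <- stats::sd(yhat) == 0
  if (const_y || const_yh) {
    warning("correlation undefined for constant input; returning NA")
    pearson <- spearman <- NA_real_
  } else {
    pearson <- stats::cor(y, yhat)
    spearman <- stats::cor(rank(y, ties.method = "average"),
                           rank(yhat, ties.method = "average"))
  }
  civ <- if (ci) concordance_index(y, yhat) else NA_real_
  structure(list(mse = mse, rmse = sqrt(mse), pearson = pearson,
                 spearman = spearman, ci = civ, r2 = r2, n = n),
            class = "dta_metric_report")
}

#' Concordance index
#'
#' Probability that, over all pairs whose true affinities are strictly
#' ordered, the predictions are ordered the same way; tied predictions
#' count 0.5.  The default method delegates the counting to
#' `survival::concordance`; `method = "pairwise"` is the O(n^2) reference
#' that enumerates every strictly ordered pair, and the two must agree
#' exactly.
#'
#' @param y True affinities.
#' @param yhat Predicted affinities.
#' @param method `"fast"` (order statistics) or `"pairwise"` (reference).
#' @return CI in `[0, 1]`, or `NA` (with a warning) when no strictly
#'   ordered true pair exists.
#' @export
concordance_index <- function(y, yhat, method = c("fast", "pairwise")) {
  method <- match.arg(method)
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  if (all(y == y[1L])) {
    warning("concordance undefined: no strictly ordered true pair")
    return(NA_real_)
  }
  if (method == "fast") {
    fit <- survival::concordance(y ~ yhat)
    return(as.numeric(fit$concordance))
  }
  num <- 0; z <- 0L
  n <- length(y)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (y[i] == y[j]) next
      z <- z + 1L
      diff <- (yhat[i] - yhat[j]) * sign(y[i] - y[j])
      num <- num + (if (diff > 0) 1 else if (diff == 0) 0.5 else 0)
    }
  }
  num / z
}

#' @export
print.dta_metric_report <- function(x, ...) {
  cat(sprintf(
    "affinity metrics (n = %d)\n  MSE %.4f | RMSE %.4f | Pearson %.4f | Spearman %.4f | CI %.4f | r2 %.4f\n",
    x$n, x$mse, x$rmse, x$pearson, x$spearman, x$ci, x$r2))
  invisible(x)
}

#' Evaluate a predictions table
#'
#' Reads a predictions TSV (columns `y_true` and `y_pred`, typically with
#' `drug_id` / `protein_id` or a `pair_id`) and returns the metric report;
#' optionally writes it as JSON.
#'
#' @param pred_path Path to the predictions TSV.
#' @param json_out Optional path for a JSON metric report.
#' @return A `dta_metric_report`.
#' @export
evaluate_predictions_file <- function(pred_path, json_out = NULL) {
  df <- utils::read.table(pred_path, header = TRUE, sep = "\t")
  stopifnot(all(c("y_true", "y_pred") %in% names(df)))
  rep <- regression_metrics(df$y_true, df$y_pred)
  if (!is.null(json_out))
    jsonlite::write_json(unclass(rep), json_out, auto_unbox = TRUE,
                         digits = NA)
  rep
}
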