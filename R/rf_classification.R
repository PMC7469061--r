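#' Imbalanced-classification metrics for one test set
#'
#' Computes the metric panel used to evaluate each train/test split:
#' accuracy, Cohen's kappa, the Matthews correlation coefficient (MCC),
#' rank-based AUC, sensitivity (true-positive rate of class 1, mainland)
#' and specificity (true-negative rate of class 0, island).
#'
#' MCC is `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, set to 0
#' (with a message) when the denominator vanishes, e.g. for a constant
#' prediction. Kappa is `(p_o - p_e) / (1 - p_e)`, likewise 0 when
#' `p_e = 1`. AUC is the probability that a random class-1 score exceeds a
#' random class-0 score, ties counting one half — identical to
#' `U / (n1 * n0)` with the midrank U statistic of [mann_whitney_u()].
#'
#' @param y_true Integer/numeric vector of true labels (0/1), both classes
#'   present.
#' @param y_pred Predicted labels (0/1), same length.
#' @param y_score Predicted class-1 probabilities, same length; if `NULL`
#'   the AUC is computed from `y_pred`.
#' @return A one-row tibble: `accuracy`, `kappa`, `mcc`, `auc`,
#'   `sensitivity`, `specificity`.
#' @export
#' @examples
#' compute_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
compute_metrics <- function(y_true, y_pred, y_score = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop_meddiet("y_true and y_pred must have the same length.")
  }
  if (length(unique(y_true)) < 2) {
    stop_meddiet("Both classes must be present in y_true.")
  }
  if (is.null(y_score)) y_score <- as.numeric(y_pred)
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  n <- length(y_true)

  accuracy <- (tp + tn) / n
  sensitivity <- tp / (tp + fn)
  specificity <- tn / (tn + fp)

  p_o <- accuracy
  p_e <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (abs(1 - p_e) < .Machine$double.eps^0.5) 0 else (p_o - p_e) / (1 - p_e)

  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) {
    message("MCC denominator is zero (degenerate confusion matrix); ",
            "returning 0 by convention.")
    0
  } else {
    (tp * tn - fp * fn) / denom
  }

  # midrank AUC: P(score_1 > score_0) + P(score_1 = score_0) / 2
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  r <- rank(y_score)
  auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  tibble::tibble(accuracy = accuracy, kappa = kappa, mcc = mcc, auc = auc,
                 sensitivity = sensitivity, specificity = specificity)
}

cohort_design <- function(cohort, variables = NULL) {
  vars <- variables %||% numeric_variables(cohort)
  x <- as.data.frame(cohort[vars])
  y <- as.integer(cohort$class %||% as.integer(cohort$location == "mainland"))
  list(x = x, y = y, vars = vars)
}

#' One random 75/25 train/test split of the forest classifier
#'
#' Randomly splits the cohort into a 75% training and 25% test partition,
#' fits a probability random forest (500 trees, sqrt(p) candidate
#' variables per split, impurity importance) predicting mainland (class 1)
#' vs island (class 0), and evaluates the metric panel on the held-out
#' test set. Remaining missing predictor cells are imputed with the
#' training-set median. If a partition misses a class the split is redrawn
#' (at most 100 times, count recorded in the `resplits` attribute).
#'
#' @param cohort Analysis table with `class` (or `location`) and numeric
#'   predictors.
#' @param seed Integer seed controlling the split and the forest.
#' @param variables Optional predictor subset (default: all numeric
#'   variables).
#' @param train_fraction Training fraction (default 0.75).
#' @param num_trees,mtry Forest size and candidate variables per split
#'   (default 500 and `floor(sqrt(p))`).
#' @return A list with `metrics` (one-row tibble) and `importances`
#'   (named vector of impurity importances normalized to sum to 1).
#' @export
run_split <- function(cohort, seed, variables = NULL, train_fraction = 0.75,
                      num_trees = 500, mtry = NULL) {
  d <- cohort_design(cohort, variables)
  n <- nrow(d$x)
  if (n < 8) stop_meddiet("At least 8 participants are required for a split.")
  set.seed(seed)
  n_train <- floor(train_fraction * n)
  resplits <- 0
  repeat {
    idx <- sample.int(n, n_train)
    if (length(unique(d$y[idx])) == 2 && length(unique(d$y[-idx])) == 2) break
    resplits <- resplits + 1
    if (resplits > 100) stop_meddiet("Could not draw a split containing both classes.")
  }
  x_train <- d$x[idx, , drop = FALSE]
  x_test <- d$x[-idx, , drop = FALSE]
  # median imputation fitted on the training partition only
  for (nm in names(x_train)) {
    if (anyNA(x_train[[nm]]) || anyNA(x_test[[nm]])) {
      med <- median(x_train[[nm]], na.rm = TRUE)
      if (is.na(med)) med <- 0
      x_train[[nm]][is.na(x_train[[nm]])] <- med
      x_test[[nm]][is.na(x_test[[nm]])] <- med
    }
  }
  fit <- ranger::ranger(
    x = x_train, y = factor(d$y[idx], levels = c(0, 1)),
    num.trees = num_trees,
    mtry = mtry %||% max(1, floor(sqrt(ncol(x_train)))),
    probability = TRUE, importance = "impurity",
    seed = seed, num.threads = 1
  )
  prob1 <- predict(fit, data = x_test, num.threads = 1)$predictions[, "1"]
  y_pred <- as.integer(prob1 >= 0.5)
  metrics <- compute_metrics(d$y[-idx], y_pred, prob1)
  imp <- fit$variable.importance
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
  out <- list(metrics = metrics, importances = imp)
  attr(out, "resplits") <- resplits
  attr(out, "n_test") <- n - n_train
  out
}

#' Repeated random-split evaluation of the island/mainland classifier
#'
#' Repeats [run_split()] `n_repeats` times with a different random 75/25
#' split each time and summarizes every metric as its mean with a 95%
#' confidence interval (mean +/- 1.96 sd / sqrt(R)) over the repeats,
#' together with the per-variable mean normalized importances. Per-repeat
#' seeds are spawned deterministically from `base_seed`.
#'
#' @inheritParams run_split
#' @param n_repeats Number of repeated splits (the study protocol uses
#'   1000), at least 2.
#' @param base_seed Master seed for the repeat sequence.
#' @return An object of class `meddiet_rf_summary`: a list with `metrics`
#'   (tibble `metric`, `mean`, `sd`, `ci_lower`, `ci_upper`),
#'   `importances` (tibble `variable`, `mean_importance`, descending),
#'   `per_repeat` (tibble of per-split metrics), `n_repeats`, `base_seed`,
#'   `variables`.
#' @export
repeat_classification <- function(cohort, n_repeats = 1000, base_seed = 11,
                                  variables = NULL, train_fraction = 0.75,
                                  num_trees = 500, mtry = NULL) {
  if (n_repeats < 2) stop_meddiet("n_repeats must be at least 2.")
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1, n_repeats)
  metrics <- vector("list", n_repeats)
  imp_sum <- NULL
  for (r in seq_len(n_repeats)) {
    res <- run_split(cohort, seed = seeds[r], variables = variables,
                     train_fraction = train_fraction,
                     num_trees = num_trees, mtry = mtry)
    metrics[[r]] <- res$metrics
    imp_sum <- if (is.null(imp_sum)) res$importances else imp_sum + res$importances
  }
  per_repeat <- dplyr::bind_rows(metrics)
  summary_tbl <- tidyr::pivot_longer(per_repeat, dplyr::everything(),
                                     names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop") |>
    dplyr::mutate(ci_lower = .data$mean - 1.96 * .data$sd / sqrt(n_repeats),
                  ci_upper = .data$mean + 1.96 * .data$sd / sqrt(n_repeats))
  imp_mean <- imp_sum / n_repeats
  importances <- tibble::tibble(variable = names(imp_mean),
                                mean_importance = unname(imp_mean)) |>
    dplyr::arrange(dplyr::desc(.data$mean_importance))
  structure(
    list(metrics = summary_tbl, importances = importances,
         per_repeat = per_repeat, n_repeats = n_repeats,
         base_seed = base_seed,
         variables = importances$variable),
    class = "meddiet_rf_summary"
  )
}

#' @export
print.meddiet_rf_summary <- function(x, digits = 3, ...) {
  cat("Random-forest classification over", x$n_repeats,
      "random 75/25 splits (mean +/- 95% CI):\n")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s %.*f +/- %.*f\n", m$metric[i], digits, m$mean[i],
                digits, 1.96 * m$sd[i] / sqrt(x$n_repeats)))
  }
  cat("Top variables by mean importance:\n")
  top <- head(x$importances, 5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-28s %.1f%%\n", top$variable[i], 100 * top$mean_importance[i]))
  }
  invisible(x)
}

#' Select variables by mean forest importance
#'
#' Keeps all and only the variables whose mean normalized importance over
#' the repeated forests reaches the threshold (1% by default), ordered by
#' descending importance.
#'
#' @param summary A `meddiet_rf_summary` from [repeat_classification()].
#' @param threshold Minimum mean importance (fraction; default 0.01).
#' @return Character vector of selected variable names.
#' @export
select_variables <- function(summary, threshold = 0.01) {
  imp <- summary$importances
  sel <- imp$variable[imp$mean_importance >= threshold]
  if (length(sel) == 0) {
    stop_meddiet("No variable reaches mean importance ", threshold,
                 "; lower the threshold.")
  }
  sel
}

#' Re-train the classifier on the selected variables
#'
#' Repeats the full random-split protocol restricted to the selected
#' variable subset. When the summary of the original (all-variable) run is
#' supplied, a paired before/after comparison per metric is attached as
#' the `"comparison"` attribute.
#'
#' @inheritParams repeat_classification
#' @param selected Character vector of variable names (subset of the
#'   cohort's variables).
#' @param original Optional `meddiet_rf_summary` of the full-variable run.
#' @return A `meddiet_rf_summary` for the restricted model.
#' @export
retrain_selected <- function(cohort, selected, n_repeats = 1000,
                             base_seed = 11, original = NULL, ...) {
  missing_vars <- setdiff(selected, names(cohort))
  if (length(missing_vars) > 0) {
    stop_meddiet("Selected variable(s) absent from the cohort: ",
                 paste(missing_vars, collapse = ", "))
  }
  out <- repeat_classification(cohort, n_repeats = n_repeats,
                               base_seed = base_seed, variables = selected, ...)
  if (!is.null(original)) {
    comparison <- dplyr::inner_join(
      dplyr::select(original$metrics, "metric", before = "mean"),
      dplyr::select(out$metrics, "metric", after = "mean"),
      by = "metric"
    )
    comparison$delta <- comparison$after - comparison$before
    attr(out, "comparison") <- comparison
  }
  out
}
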