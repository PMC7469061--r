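#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two samples with midranks for ties. The two-sided
#' p-value is exact (by enumeration of the rank-sum distribution) when the
#' samples are untied and `n1 * n2` does not exceed `exact_limit`;
#' otherwise the normal approximation with tie-corrected variance (and
#' continuity correction) is used. The U statistic is reported for the
#' first sample: `U = #\{x_i > y_j\} + #\{x_i = y_j\} / 2`, so
#' `U(x, y) + U(y, x) = n1 * n2`.
#'
#' @param x,y Numeric samples (NAs dropped); each must retain at least one
#'   observation.
#' @param exact_limit Largest `n1 * n2` for which the exact distribution is
#'   used (default 400).
#' @return A list with elements `U`, `p`, `n1`, `n2`, `exact`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
mann_whitney_u <- function(x, y, exact_limit = 400) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) {
    stop_meddiet("Both samples must contain at least one non-missing value.")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && n1 * n2 <= exact_limit
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = !exact)
  )
  list(U = unname(wt$statistic), p = wt$p.value, n1 = n1, n2 = n2,
       exact = exact)
}

#' Bonferroni-corrected per-test significance level
#'
#' Dividing the overall alpha by the number of tests controls the
#' family-wise error rate of the battery of comparisons.
#'
#' @param alpha Overall significance level in (0, 1).
#' @param m Number of tests, at least 1.
#' @return The corrected per-test level `alpha / m`.
#' @export
#' @examples
#' bonferroni(0.05, 100)   # 5e-04
bonferroni <- function(alpha, m) {
  if (length(m) != 1 || is.na(m) || m < 1 || m != round(m)) {
    stop_meddiet("m must be a positive integer number of tests.")
  }
  if (alpha <= 0 || alpha >= 1) stop_meddiet("alpha must lie in (0, 1).")
  alpha / m
}

#' Compare every variable between the two location groups
#'
#' Runs a two-sided Mann-Whitney U test per variable (island vs mainland),
#' reporting the raw p-value, its display tier on the `*`/`**`/`***`
#' convention, and the Bonferroni gate at `alpha / m` where `m` is the
#' number of variables tested. Missing values are dropped per variable
#' (pairwise omission).
#'
#' @param cohort Analysis table with a binary `location` column and
#'   numeric variables (see [build_analysis_table()]).
#' @param group_var Name of the grouping column (default `"location"`).
#' @param alpha Overall significance level before correction.
#' @param exact_limit Passed to [mann_whitney_u()].
#' @return A tibble sorted by raw p-value: `variable`, `n_island`,
#'   `n_mainland`, `U`, `p_raw`, `tier`, `alpha_corrected`, `significant`.
#' @export
compare_all <- function(cohort, group_var = "location", alpha = 0.05,
                        exact_limit = 400) {
  g <- cohort[[group_var]]
  levels_g <- unique(as.character(g[!is.na(g)]))
  if (length(levels_g) != 2) {
    stop_meddiet("Grouping variable '", group_var,
                 "' must have exactly two observed levels.")
  }
  levels_g <- sort(levels_g)
  vars <- numeric_variables(cohort, exclude = c("participant_id", "class", group_var))
  if (length(vars) == 0) stop_meddiet("No numeric variables to compare.")
  m <- length(vars)
  alpha_corr <- bonferroni(alpha, m)
  rows <- lapply(vars, function(nm) {
    x <- cohort[[nm]][g == levels_g[1]]
    y <- cohort[[nm]][g == levels_g[2]]
    res <- mann_whitney_u(x, y, exact_limit = exact_limit)
    tibble::tibble(variable = nm, n_island = res$n1, n_mainland = res$n2,
                   U = res$U, p_raw = res$p)
  })
  out <- dplyr::bind_rows(rows)
  out$tier <- significance_tier(out$p_raw)
  out$alpha_corrected <- alpha_corr
  out$significant <- out$p_raw <= alpha_corr
  dplyr::arrange(out, .data$p_raw)
}

#' Stratified island-vs-mainland comparison of outcome variables
#'
#' For each level of a binary stratifier (e.g. education high/low), the
#' location groups are compared on each outcome: per-location means and
#' the Mann-Whitney significance tier. Strata in which either location
#' group has fewer than `min_n` members are reported but not tested.
#'
#' @param cohort Analysis table with a `location` column.
#' @param stratifier Name of the binary stratifying variable.
#' @param outcomes Character vector of outcome variable names.
#' @param group_var Name of the location column.
#' @param min_n Minimum per-location group size for testing (default 5).
#' @return A tibble with one row per (stratum level, location, outcome):
#'   `stratifier`, `stratum`, `outcome`, `location`, `n`, `mean`, `p_raw`,
#'   `tier`, `tested`.
#' @export
stratified_compare <- function(cohort, stratifier, outcomes,
                               group_var = "location", min_n = 5) {
  s <- cohort[[stratifier]]
  lv <- sort(unique(s[!is.na(s)]), decreasing = TRUE)
  if (length(lv) != 2) {
    stop_meddiet("Stratifier '", stratifier, "' must be binary.")
  }
  g <- as.character(cohort[[group_var]])
  locs <- sort(unique(g))
  rows <- list()
  for (v in lv) {
    in_stratum <- !is.na(s) & s == v
    for (oc in outcomes) {
      xs <- lapply(locs, function(l) {
        val <- cohort[[oc]][in_stratum & g == l]
        val[!is.na(val)]
      })
      tested <- all(vapply(xs, length, integer(1)) >= min_n)
      p <- if (tested) mann_whitney_u(xs[[1]], xs[[2]])$p else NA_real_
      for (k in seq_along(locs)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          stratifier = stratifier, stratum = v, outcome = oc,
          location = locs[k], n = length(xs[[k]]),
          mean = if (length(xs[[k]]) > 0) mean(xs[[k]]) else NA_real_,
          p_raw = p, tier = significance_tier(p), tested = tested
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' PCA loadings of scaled cumulative food-group frequencies
#'
#' Standardizes each variable (zero mean, unit variance) and performs a
#' principal component analysis, returning the loadings and the
#' explained-variance ratios. The sign of each component is fixed so that
#' its largest-magnitude loading is positive, making the output
#' deterministic.
#'
#' @param cumulative A cumulative frequency table (a `participant_id`
#'   column is ignored); at least 2 variables and 3 participants.
#' @param n_components Number of components retained in the `loadings`
#'   tibble (default 2, for the PC1/PC2 loadings plot).
#' @return A list of class `meddiet_pca`: `loadings` (tibble `variable`,
#'   `PC1`, `PC2`, ...), `explained_variance_ratio` (full vector),
#'   `center`, `scale`.
#' @export
pca_loadings <- function(cumulative, n_components = 2) {
  x <- cumulative[numeric_variables(cumulative)]
  if (ncol(x) < 2 || nrow(x) < 3) {
    stop_meddiet("PCA needs at least 2 variables and 3 participants.")
  }
  sds <- vapply(x, sd, numeric(1))
  if (any(sds == 0 | is.na(sds))) {
    stop_meddiet("Zero-variance variable(s) must be filtered before PCA: ",
                 paste(names(x)[sds == 0 | is.na(sds)], collapse = ", "))
  }
  fit <- prcomp(as.matrix(x), center = TRUE, scale. = TRUE)
  rot <- fit$rotation
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  k <- min(n_components, ncol(rot))
  loadings <- tibble::as_tibble(rot[, seq_len(k), drop = FALSE])
  loadings <- dplyr::bind_cols(tibble::tibble(variable = rownames(rot)), loadings)
  structure(
    list(loadings = loadings,
         explained_variance_ratio = fit$sdev^2 / sum(fit$sdev^2),
         rotation = rot, center = fit$center, scale = fit$scale),
    class = "meddiet_pca"
  )
}

#' @export
print.meddiet_pca <- function(x, ...) {
  evr <- x$explained_variance_ratio
  cat("PCA of", nrow(x$loadings), "variables; PC1/PC2 explain",
      sprintf("%.1f%% / %.1f%%", 100 * evr[1], 100 * evr[2]),
      "of the variance\n")
  invisible(x)
}
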