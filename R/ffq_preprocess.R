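#' Convert a raw FFQ frequency to a per-day frequency
#'
#' Raw questionnaire responses report how many times an item is consumed
#' per day, week or month. The analysis works on daily frequencies:
#' a response of "2 times per week" becomes `2/7`, "3 times per month"
#' becomes `3/30` under the default 30-day-month convention.
#'
#' The conversion is linear in `frequency` and monotone within a period.
#'
#' @param frequency Non-negative numeric vector of reported counts.
#' @param period Character vector (recycled) with values `"day"`, `"week"`
#'   or `"month"`.
#' @param days_per_month Days per month used for the monthly conversion;
#'   30 by default, 30.44 (the mean calendar month) is also in common use.
#' @return Numeric vector of per-day frequencies.
#' @export
#' @examples
#' normalize_frequency(2, "week")      # 2/7
#' normalize_frequency(3, "month")     # 0.1
normalize_frequency <- function(frequency, period, days_per_month = 30) {
  if (any(frequency < 0, na.rm = TRUE)) {
    stop_meddiet("Frequencies must be non-negative.")
  }
  divisor <- c(day = 1, week = 7, month = days_per_month)
  bad <- setdiff(unique(period), names(divisor))
  if (length(bad) > 0) {
    stop_meddiet("Unknown reporting period token(s): ",
                 paste0("'", bad, "'", collapse = ", "),
                 ". Expected one of 'day', 'week', 'month'.")
  }
  unname(frequency / divisor[period])
}

#' Build the participants-by-items daily frequency table
#'
#' Converts a long FFQ table (one row per participant and item, with a
#' reported `frequency`, its `period` and an optional `portion_multiplier`)
#' into a wide table of per-day serving frequencies. Items a participant
#' did not report are 0.
#'
#' @param ffq Long tibble with columns `participant_id`, `item_id`,
#'   `frequency`, `period`, and optionally `portion_multiplier`.
#' @param days_per_month See [normalize_frequency()].
#' @return A tibble with `participant_id` and one numeric column per item.
#' @export
daily_frequencies <- function(ffq, days_per_month = 30) {
  if (anyDuplicated(ffq[c("participant_id", "item_id")]) > 0) {
    stop_meddiet("Duplicate (participant_id, item_id) rows in the FFQ table.")
  }
  pm <- ffq$portion_multiplier %||% rep(1, nrow(ffq))
  if (is.null(ffq$portion_multiplier)) ffq$portion_multiplier <- pm
  if (any(ffq$portion_multiplier <= 0)) {
    stop_meddiet("portion_multiplier must be positive.")
  }
  ffq$daily <- normalize_frequency(ffq$frequency, ffq$period, days_per_month) *
    ffq$portion_multiplier
  ffq |>
    dplyr::select("participant_id", "item_id", "daily") |>
    tidyr::pivot_wider(names_from = "item_id", values_from = "daily",
                       values_fill = 0) |>
    dplyr::arrange(.data$participant_id)
}

#' Cumulative food-group frequencies
#'
#' Sums per-day item frequencies into food-group ("similar answer")
#' cumulative frequencies per participant, e.g. all white-meat items into
#' one `white_meat` variable. Total mass is conserved: for each
#' participant the group values sum to the sum of the grouped items'
#' daily frequencies.
#'
#' @param daily Wide daily frequency table from [daily_frequencies()].
#' @param grouping Tibble with columns `item_id` and `group`
#'   ([default_item_groups()] by default). Items mapped to `NA` are
#'   ungrouped.
#' @param keep_items How to treat item-level columns in the output:
#'   `"all"` (default) keeps every item column next to the group sums —
#'   the layout of the study's ~105-variable analysis table;
#'   `"ungrouped"` keeps only items that belong to no group;
#'   `"none"` returns group sums only.
#' @return A tibble with `participant_id`, one column per group, and item
#'   columns per `keep_items`.
#' @export
cumulative_group_frequencies <- function(daily,
                                         grouping = default_item_groups(),
                                         keep_items = c("all", "ungrouped", "none")) {
  keep_items <- match.arg(keep_items)
  if (anyDuplicated(grouping$item_id[!is.na(grouping$group)]) > 0) {
    dup <- grouping$item_id[duplicated(grouping$item_id) & !is.na(grouping$group)]
    stop_meddiet("Item(s) mapped to more than one group: ",
                 paste(unique(dup), collapse = ", "))
  }
  grouping <- grouping[!is.na(grouping$group), , drop = FALSE]
  missing_items <- setdiff(grouping$item_id, names(daily))
  if (length(missing_items) > 0) {
    stop_meddiet("Grouped item(s) absent from the daily table: ",
                 paste(missing_items, collapse = ", "))
  }
  out <- tibble::tibble(participant_id = daily$participant_id)
  for (g in unique(grouping$group)) {
    members <- grouping$item_id[grouping$group == g]
    out[[g]] <- rowSums(as.matrix(daily[, members, drop = FALSE]))
  }
  item_cols <- setdiff(names(daily), "participant_id")
  keep <- switch(keep_items,
                 all = item_cols,
                 ungrouped = setdiff(item_cols, grouping$item_id),
                 none = character(0))
  dplyr::bind_cols(out, daily[keep])
}

#' Filter uninformative variables
#'
#' Removes variables that carry no usable information for the group
#' comparison: variables with more than `missing_threshold` missing cells,
#' constant variables, variables with variance below `var_threshold`
#' (on the daily-frequency scale), and — scanning columns left to right —
#' the later member of any pair with absolute Spearman correlation above
#' `corr_threshold`. The scan order makes the result deterministic and
#' the operation idempotent. A removal log (one row per dropped variable
#' with the reason) is attached as the `"removal_log"` attribute.
#'
#' `participant_id`, `location` and `class` columns are never touched.
#'
#' @param table A wide analysis table (one row per participant).
#' @param var_threshold Minimum variance to keep a variable.
#' @param corr_threshold Maximum tolerated absolute Spearman correlation
#'   between two retained variables, in (0, 1].
#' @param missing_threshold Maximum tolerated fraction of missing cells.
#' @return The filtered table with attribute `removal_log`.
#' @export
filter_variables <- function(table, var_threshold = 1e-4,
                             corr_threshold = 0.95,
                             missing_threshold = 0.2) {
  if (corr_threshold <= 0 || corr_threshold > 1) {
    stop_meddiet("corr_threshold must lie in (0, 1].")
  }
  vars <- numeric_variables(table)
  log <- list()
  drop <- character(0)

  for (nm in vars) {
    x <- table[[nm]]
    frac_na <- mean(is.na(x))
    if (frac_na > missing_threshold) {
      log[[nm]] <- c(nm, "missing", sprintf("%.1f%% missing", 100 * frac_na))
      drop <- c(drop, nm)
      next
    }
    xx <- x[!is.na(x)]
    if (length(unique(xx)) <= 1) {
      log[[nm]] <- c(nm, "constant", "single repeated value")
      drop <- c(drop, nm)
      next
    }
    if (var(xx) < var_threshold) {
      log[[nm]] <- c(nm, "low_variance", sprintf("variance %.2e", var(xx)))
      drop <- c(drop, nm)
    }
  }
  vars <- setdiff(vars, drop)

  # greedy left-to-right scan: drop the later-ordered member of any
  # too-correlated pair
  if (length(vars) > 1) {
    rho <- suppressWarnings(
      cor(as.matrix(table[vars]), method = "spearman", use = "pairwise.complete.obs")
    )
    kept <- vars[1]
    for (nm in vars[-1]) {
      r <- abs(rho[nm, kept])
      if (any(r > corr_threshold, na.rm = TRUE)) {
        partner <- kept[which.max(r)]
        log[[nm]] <- c(nm, "high_correlation",
                       sprintf("|rho| = %.3f with %s", max(r, na.rm = TRUE), partner))
        drop <- c(drop, nm)
      } else {
        kept <- c(kept, nm)
      }
    }
    vars <- kept
  }

  keep_cols <- names(table)[names(table) %in%
                              c("participant_id", "location", "class", vars)]
  out <- table[keep_cols]
  if (length(numeric_variables(out)) == 0) {
    stop_meddiet("No variables survive filtering; relax the thresholds.")
  }
  removal_log <- if (length(log) > 0) {
    tibble::tibble(
      variable = unname(vapply(log, `[`, character(1), 1)),
      reason = unname(vapply(log, `[`, character(1), 2)),
      detail = unname(vapply(log, `[`, character(1), 3))
    )
  } else {
    tibble::tibble(variable = character(0), reason = character(0),
                   detail = character(0))
  }
  attr(out, "removal_log") <- removal_log
  out
}

#' Join scores, cumulative frequencies and socio-demographics into one table
#'
#' Inner join on `participant_id`. By default any participant present in
#' one input but not another is an error (reporting the orphan ids); a
#' positive `orphan_tolerance` allows up to that fraction of orphan ids,
#' which are then dropped.
#'
#' @param scores Per-participant score table (e.g. from [score_mdss()] and
#'   [score_mds_preg()], totals only or with flags).
#' @param cumulative Cumulative frequency table.
#' @param sociodemo Socio-demographic table.
#' @param labels Tibble with `participant_id`, `location` and `class`.
#' @param orphan_tolerance Tolerated fraction of non-shared participant
#'   ids, default 0.
#' @return A cohort analysis table: `participant_id`, `location`, `class`,
#'   then all variable columns, with a `var_meta` attribute classifying
#'   each variable as `score`, `nutrition` or `lifestyle`.
#' @export
assemble_cohort <- function(scores, cumulative, sociodemo, labels,
                            orphan_tolerance = 0) {
  inputs <- list(scores = scores, cumulative = cumulative,
                 sociodemo = sociodemo, labels = labels)
  ids <- lapply(inputs, function(x) unique(x$participant_id))
  shared <- Reduce(intersect, ids)
  all_ids <- Reduce(union, ids)
  orphans <- setdiff(all_ids, shared)
  if (length(orphans) > orphan_tolerance * length(all_ids)) {
    stop_meddiet("Participant ids do not align across inputs; ",
                 length(orphans), " orphan id(s): ",
                 paste(head(orphans, 5), collapse = ", "),
                 if (length(orphans) > 5) ", ..." else "")
  }
  sociodemo <- sociodemo[setdiff(names(sociodemo), c("location", "class"))]
  out <- labels[labels$participant_id %in% shared, ] |>
    dplyr::inner_join(scores, by = "participant_id") |>
    dplyr::inner_join(cumulative, by = "participant_id") |>
    dplyr::inner_join(sociodemo, by = "participant_id")
  kind <- c(
    setNames(rep("score", length(setdiff(names(scores), "participant_id"))),
             setdiff(names(scores), "participant_id")),
    setNames(rep("nutrition", length(setdiff(names(cumulative), "participant_id"))),
             setdiff(names(cumulative), "participant_id")),
    setNames(rep("lifestyle", length(setdiff(names(sociodemo), "participant_id"))),
             setdiff(names(sociodemo), "participant_id"))
  )
  attr(out, "var_meta") <- tibble::tibble(variable = names(kind), kind = unname(kind))
  out
}

#' Build the full analysis table from a cohort
#'
#' Convenience wrapper running the preprocessing chain on a (synthetic or
#' read-in) cohort: daily frequencies, cumulative group frequencies, both
#' diet scores, join, and uninformative-variable filtering.
#'
#' @param cohort A `meddiet_cohort` (or a list with elements `ffq`,
#'   `sociodemo`, `labels`).
#' @param score_config Scoring configuration, see [default_score_config()].
#' @param composition Fat composition table for the MUFA:SFA component.
#' @param grouping Item-to-group map for cumulative frequencies.
#' @param keep_items Passed to [cumulative_group_frequencies()].
#' @param days_per_month Days per month for the frequency conversion.
#' @param filter Logical; apply [filter_variables()] (default `TRUE`).
#' @param ... Passed on to [filter_variables()].
#' @return The filtered cohort analysis table (see [assemble_cohort()]).
#' @export
build_analysis_table <- function(cohort,
                                 score_config = default_score_config(),
                                 composition = default_composition(),
                                 grouping = default_item_groups(),
                                 keep_items = "all",
                                 days_per_month = 30,
                                 filter = TRUE, ...) {
  daily <- daily_frequencies(cohort$ffq, days_per_month = days_per_month)
  cumulative <- cumulative_group_frequencies(daily, grouping, keep_items = keep_items)
  mdss <- score_mdss(daily, score_config)
  mdspreg <- score_mds_preg(daily, composition, score_config)
  scores <- tibble::tibble(
    participant_id = mdss$participant_id,
    mdss_total = mdss$mdss_total,
    mdspreg_total = mdspreg$mdspreg_total
  )
  out <- assemble_cohort(scores, cumulative, cohort$sociodemo, cohort$labels)
  if (filter) {
    meta <- attr(out, "var_meta")
    out2 <- filter_variables(out, ...)
    attr(out2, "var_meta") <- meta[meta$variable %in% names(out2), , drop = FALSE]
    out <- out2
  }
  out
}
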