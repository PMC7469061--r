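#' Convert a per-day frequency into servings per reference period
#'
#' Score criteria are stated per main meal, per day or per week. A daily
#' frequency `f` corresponds to `f` servings/day, `7 f` servings/week and
#' `f / main_meals_per_day` servings/main meal.
#'
#' @param daily_frequency Non-negative numeric vector of servings per day.
#' @param reference_period `"main_meal"`, `"day"` or `"week"`.
#' @param main_meals_per_day Positive integer; number of main meals a day
#'   (default 3).
#' @return Servings per reference period.
#' @export
#' @examples
#' servings_in_period(0.5, "week")       # 3.5 servings/week
#' servings_in_period(3, "main_meal")    # 1 per main meal
servings_in_period <- function(daily_frequency, reference_period,
                               main_meals_per_day = 3) {
  if (main_meals_per_day <= 0) {
    stop_meddiet("main_meals_per_day must be positive.")
  }
  switch(reference_period,
         day = daily_frequency,
         week = 7 * daily_frequency,
         main_meal = daily_frequency / main_meals_per_day,
         stop_meddiet("Unknown reference period '", reference_period, "'."))
}

# evaluate one serving rule; bounds are inclusive unless the rule is
# printed strict (e.g. red meat "< 2 servings/week"), with a small
# tolerance so that 7 * (2/7) counts as exactly 2
rule_met <- function(value, rule) {
  switch(rule$direction,
    within_range = value >= rule$min - .tol & value <= rule$max + .tol,
    at_least = if (isTRUE(rule$strict)) value > rule$min + .tol else value >= rule$min - .tol,
    at_most = if (isTRUE(rule$strict)) value < rule$max - .tol else value <= rule$max + .tol,
    stop_meddiet("Unknown rule direction '", rule$direction, "'.")
  )
}

#' Read, write and validate scoring configurations
#'
#' The scoring configuration holds the MDSS category table (member items,
#' serving rules, points, the fermented-beverage switch and the two
#' adherence cut-offs) and the MDS-preg component definitions with their
#' adherence bands. `default_score_config()` loads the configuration
#' shipped with the package; the YAML round trip is lossless.
#'
#' @param path Path to a YAML scoring configuration.
#' @param config A score configuration list.
#' @return `read_score_config()` and `default_score_config()` return a
#'   validated configuration list of class `meddiet_score_config`.
#' @export
read_score_config <- function(path) {
  config <- yaml::read_yaml(path)
  config <- structure(config, class = "meddiet_score_config")
  validate_score_config(config)
  config
}

#' @rdname read_score_config
#' @export
write_score_config <- function(config, path) {
  writeLines(yaml::as.yaml(unclass(config), precision = 15), path)
  invisible(path)
}

#' @rdname read_score_config
#' @export
default_score_config <- function() {
  read_score_config(system.file("extdata", "mdss_default.yaml",
                                package = "meddietr", mustWork = TRUE))
}

#' @rdname read_score_config
#' @export
validate_score_config <- function(config) {
  cats <- config$mdss$categories
  nm <- vapply(cats, `[[`, character(1), "name")
  if (anyDuplicated(nm) > 0) stop_meddiet("Duplicate MDSS category names.")
  for (cc in cats) {
    if (cc$points > 0 && length(cc$items) == 0) {
      stop_meddiet("MDSS category '", cc$name,
                   "' awards points but has no mapped items.")
    }
    if (!cc$direction %in% c("within_range", "at_least", "at_most")) {
      stop_meddiet("MDSS category '", cc$name, "': unknown direction.")
    }
    if (!cc$points %in% 1:3) {
      stop_meddiet("MDSS category '", cc$name, "': points must be 1, 2 or 3.")
    }
  }
  max_pts <- mdss_max_points(config)
  cutoff <- mdss_cutoff(config)
  if (cutoff <= 0 || cutoff >= max_pts) {
    stop_meddiet("MDSS cut-off (", cutoff, ") must lie strictly inside (0, ",
                 max_pts, ").")
  }
  comp <- config$mds_preg$components
  if (length(comp) != 9) {
    stop_meddiet("MDS-preg expects exactly 9 components, got ", length(comp), ".")
  }
  if (!config$mds_preg$zero_sfa %in% c("unmet", "error")) {
    stop_meddiet("mds_preg$zero_sfa must be 'unmet' or 'error'.")
  }
  invisible(config)
}

active_mdss_categories <- function(config) {
  Filter(function(cc) config$include_fermented || !isTRUE(cc$fermented),
         config$mdss$categories)
}

#' Attainable MDSS maximum and the adherence cut-off in force
#'
#' With the fermented-beverage category excluded the default configuration
#' attains at most 23 points (cut-off 12.5); with it included, 24 points
#' (cut-off 13.5).
#'
#' @param config A score configuration.
#' @return A single number.
#' @export
mdss_max_points <- function(config) {
  sum(vapply(active_mdss_categories(config), `[[`, numeric(1), "points"))
}

#' @rdname mdss_max_points
#' @export
mdss_cutoff <- function(config) {
  if (config$include_fermented) config$mdss$cutoff_included else config$mdss$cutoff_excluded
}

category_period_servings <- function(daily, rule, main_meals_per_day) {
  members <- intersect(rule$items, names(daily))
  if (length(members) == 0) {
    stop_meddiet("Category/component '", rule$name,
                 "' has no mapped items in the daily frequency table.")
  }
  daily_sum <- rowSums(as.matrix(daily[, members, drop = FALSE]))
  servings_in_period(daily_sum, rule$period, main_meals_per_day)
}

#' Score the Mediterranean Diet Serving Score (MDSS)
#'
#' Awards each food category its 1-3 points when the participant's serving
#' frequency satisfies the category's rule (e.g. fresh fruit 1-2
#' servings/main meal for 3 points; red meat strictly fewer than 2
#' servings/week for 1 point). No negative points are assigned. With the
#' default configuration the attainable maximum is 23 points and a total
#' of at least 12.5 counts as adherent; setting `include_fermented: true`
#' restores the original 24-point score with cut-off 13.5.
#'
#' @param daily Wide per-day frequency table from [daily_frequencies()]
#'   (column `participant_id` plus one column per item).
#' @param config Score configuration, see [default_score_config()].
#' @return A tibble with `participant_id`, one logical `met_<category>`
#'   column per active category, `mdss_total` and `mdss_adherent`.
#' @export
score_mdss <- function(daily, config = default_score_config()) {
  validate_score_config(config)
  cats <- active_mdss_categories(config)
  out <- tibble::tibble(participant_id = daily$participant_id)
  total <- numeric(nrow(daily))
  for (cc in cats) {
    value <- category_period_servings(daily, cc, config$main_meals_per_day)
    met <- rule_met(value, cc)
    out[[paste0("met_", cc$name)]] <- met
    total <- total + met * cc$points
  }
  out$mdss_total <- as.integer(total)
  out$mdss_adherent <- total >= mdss_cutoff(config)
  out
}

#' MUFA:SFA intake ratio
#'
#' Ratio of total monounsaturated to total saturated fatty acid intake,
#' each computed as the composition-weighted sum of daily serving
#' frequencies over the items covered by the composition table.
#'
#' @param daily Wide per-day frequency table.
#' @param composition Tibble `item_id`, `mufa_g`, `sfa_g` (grams per
#'   serving); see [default_composition()].
#' @return Numeric vector; `NA` where total SFA intake is zero.
#' @export
mufa_sfa_ratio <- function(daily, composition = default_composition()) {
  if (is.null(composition)) {
    stop_meddiet("MUFA:SFA ratio component: no fat composition table supplied. ",
                 "Pass a table with columns item_id, mufa_g, sfa_g ",
                 "(see default_composition()).")
  }
  members <- intersect(composition$item_id, names(daily))
  if (length(members) == 0) {
    stop_meddiet("MUFA:SFA ratio component: the composition table covers ",
                 "none of the items in the daily frequency table.")
  }
  comp <- composition[match(members, composition$item_id), ]
  m <- as.matrix(daily[, members, drop = FALSE])
  mufa <- as.numeric(m %*% comp$mufa_g)
  sfa <- as.numeric(m %*% comp$sfa_g)
  ifelse(sfa > 0, mufa / sfa, NA_real_)
}

#' Score the Mediterranean Diet Score for pregnant women (MDS-preg)
#'
#' Nine binary components, each worth one point: vegetables, fruits and
#' whole-grain products at 3 or more servings/day; fish, dairy products
#' and nuts at 2 or more servings/day; legumes strictly over 1.5
#' servings/week; a MUFA:SFA intake ratio strictly above 1.6; and red plus
#' processed meat strictly below 4.5 servings/week. Totals of 0-3, 4-6 and
#' 7-9 map to low, moderate and high adherence.
#'
#' A record with zero saturated-fat intake has no defined ratio; by default
#' (`zero_sfa: "unmet"`) the ratio component is scored as not met with a
#' warning, or it can be configured to raise an error.
#'
#' @inheritParams score_mdss
#' @param composition Fat composition table for the ratio component.
#' @return A tibble with `participant_id`, one logical `met_<component>`
#'   column per component, `mdspreg_total` and `mdspreg_band`.
#' @export
score_mds_preg <- function(daily, composition = default_composition(),
                           config = default_score_config()) {
  validate_score_config(config)
  out <- tibble::tibble(participant_id = daily$participant_id)
  total <- numeric(nrow(daily))
  for (cc in config$mds_preg$components) {
    if (isTRUE(cc$ratio)) {
      ratio <- mufa_sfa_ratio(daily, composition)
      if (anyNA(ratio)) {
        if (config$mds_preg$zero_sfa == "error") {
          stop_meddiet("MUFA:SFA ratio component: ", sum(is.na(ratio)),
                       " record(s) with zero saturated-fat intake.")
        }
        warning(sum(is.na(ratio)),
                " record(s) with zero saturated-fat intake; MUFA:SFA ratio ",
                "component scored as not met.", call. = FALSE)
      }
      met <- !is.na(ratio) & rule_met(ratio, cc)
    } else {
      value <- category_period_servings(daily, cc, config$main_meals_per_day)
      met <- rule_met(value, cc)
    }
    out[[paste0("met_", cc$name)]] <- met
    total <- total + met
  }
  out$mdspreg_total <- as.integer(total)
  out$mdspreg_band <- classify_mds_preg(out$mdspreg_total,
                                        low_max = config$mds_preg$low_max,
                                        moderate_max = config$mds_preg$moderate_max)
  out
}

#' Map an MDS-preg total to its adherence band
#'
#' @param total Integer vector of MDS-preg totals in 0-9.
#' @param low_max Largest total still classed low (default 3).
#' @param moderate_max Largest total still classed moderate (default 6).
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
#' @examples
#' classify_mds_preg(c(0, 3, 4, 6, 7, 9))
classify_mds_preg <- function(total, low_max = 3, moderate_max = 6) {
  if (any(total < 0 | total > 9 | total != round(total), na.rm = TRUE)) {
    stop_meddiet("MDS-preg totals must be integers in 0-9.")
  }
  factor(ifelse(total <= low_max, "low",
                ifelse(total <= moderate_max, "moderate", "high")),
         levels = c("low", "moderate", "high"))
}

#' Reference dietary records for score validation
#'
#' Constructs a one-row daily frequency table that either satisfies or
#' violates every active MDSS category of a configuration, derived purely
#' from the serving rules: a satisfied within-range rule is set to the
#' mid-point of its range, an at-least rule to its bound (just above it if
#' strict), an at-most rule to zero; violations use zero for at-least
#' rules and one serving above the bound otherwise. Each category's target
#' is placed on its first member item.
#'
#' Because the MDSS categories partition disjoint item sets, the
#' "satisfy" record attains the configuration's maximum total and the
#' "violate" record scores zero.
#'
#' @param config Score configuration.
#' @param type `"satisfy"` or `"violate"`.
#' @return A one-row daily frequency tibble covering all catalogue items.
#' @export
#' @examples
#' rec <- mdss_reference_record()
#' score_mdss(rec)$mdss_total   # the attainable maximum, 23 by default
mdss_reference_record <- function(config = default_score_config(),
                                  type = c("satisfy", "violate")) {
  type <- match.arg(type)
  items <- unique(unlist(lapply(config$mdss$categories, `[[`, "items")))
  daily <- tibble::as_tibble(setNames(as.list(rep(0, length(items))), items))
  daily <- dplyr::bind_cols(tibble::tibble(participant_id = "reference"), daily)
  mm <- config$main_meals_per_day
  to_daily <- function(v, period) {
    switch(period, day = v, week = v / 7, main_meal = v * mm)
  }
  for (cc in active_mdss_categories(config)) {
    target <- if (type == "satisfy") {
      switch(cc$direction,
             within_range = (cc$min + cc$max) / 2,
             at_least = if (isTRUE(cc$strict)) cc$min + 1 else cc$min,
             at_most = 0)
    } else {
      switch(cc$direction,
             within_range = cc$max + 1,
             at_least = 0,
             at_most = cc$max + 1)
    }
    daily[[cc$items[1]]] <- to_daily(target, cc$period)
  }
  daily
}
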