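# Shared fixture builders. Everything is generated in code; no stored data.

# one-row daily table with every scored item at zero
blank_record <- function(config = default_score_config(), id = "r") {
  items <- unique(unlist(c(
    lapply(config$mdss$categories, `[[`, "items"),
    lapply(config$mds_preg$components, `[[`, "items")
  )))
  rec <- tibble::as_tibble(setNames(as.list(rep(0, length(items))), items))
  dplyr::bind_cols(tibble::tibble(participant_id = id), rec)
}

# set one MDSS category of a record to its satisfying / violating target,
# mirroring the construction in mdss_reference_record()
set_category <- function(rec, name, config = default_score_config(),
                         type = "satisfy") {
  cc <- Filter(function(x) x$name == name, config$mdss$categories)[[1]]
  mm <- config$main_meals_per_day
  target <- if (type == "satisfy") {
    switch(cc$direction,
           within_range = (cc$min + cc$max) / 2,
           at_least = if (isTRUE(cc$strict)) cc$min + 1 else cc$min,
           at_most = 0)
  } else {
    switch(cc$direction, within_range = cc$max + 1, at_least = 0,
           at_most = cc$max + 1)
  }
  rec[[cc$items[1]]] <- switch(cc$period, day = target, week = target / 7,
                               main_meal = target * mm)
  rec
}

# a small cohort configuration for fast simulation tests
small_cohort_config <- function(n_total = 40, effect_scale = 0,
                                missing_rate = 0, n_items = 4) {
  cfg <- default_cohort_config(n_total = n_total, island_fraction = 0.5,
                               effect_scale = effect_scale,
                               missing_rate = missing_rate)
  cfg$ffq_items <- cfg$ffq_items[seq_len(n_items), ]
  cfg
}

# random daily record over the scored items (integer counts over random
# reporting periods, so realistic tie-prone values like 3/7 appear)
random_daily_record <- function(config, id) {
  rec <- blank_record(config, id)
  items <- setdiff(names(rec), "participant_id")
  divisor <- sample(c(1, 7, 30), length(items), replace = TRUE,
                    prob = c(0.3, 0.5, 0.2))
  counts <- rpois(length(items), 2) * rbinom(length(items), 1, 0.7)
  rec[items] <- as.list(counts / divisor)
  rec
}
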