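#' FFQ item catalogue
#'
#' The catalogue of food-frequency-questionnaire items used by the default
#' configurations. Each row is one FFQ item with
#'
#' * `cumulative_group` — the "similar answers" group whose member daily
#'   frequencies are summed into a cumulative frequency (`NA` for items
#'   that stay on their own),
#' * `mdss_category` — the Mediterranean Diet Serving Score category the
#'   item counts toward (`NA` when the item is outside the score),
#' * `mdspreg_component` — the MDS-preg component the item counts toward,
#' * generator parameters for the synthetic cohort: `base_mean` (servings
#'   per day at the cohort midpoint), `delta` (log-scale island-minus-
#'   mainland difference; positive means islanders consume more) and
#'   `zero_prob` (zero-inflation probability of never consuming the item),
#' * `mufa_g` / `sfa_g` — synthetic monounsaturated and saturated fat grams
#'   per serving used by the default fat-quality composition table.
#'
#' The fat composition values are synthetic, order-of-magnitude values for
#' testing; real analyses should supply a composition table from a nutrient
#' database via the `composition` argument of [score_mds_preg()].
#'
#' @return A tibble with one row per FFQ item.
#' @export
ffq_item_catalogue <- function() {
  tibble::tribble(
    ~item_id,            ~cumulative_group, ~mdss_category, ~mdspreg_component,   ~base_mean, ~delta, ~zero_prob, ~mufa_g, ~sfa_g,
    # fresh fruit (mainland somewhat higher)
    "apple",             "fruit",           "fresh_fruit",  "fruits",             0.80, -0.15, 0.05, 0.0, 0.0,
    "citrus_fruit",      "fruit",           "fresh_fruit",  "fruits",             0.50, -0.15, 0.10, 0.0, 0.0,
    "banana",            "fruit",           "fresh_fruit",  "fruits",             0.45, -0.15, 0.10, 0.1, 0.1,
    "seasonal_fruit",    "fruit",           "fresh_fruit",  "fruits",             0.70, -0.15, 0.05, 0.0, 0.0,
    "dried_fruit",       NA,                NA,             "fruits",             0.10, -0.10, 0.40, 0.3, 0.1,
    # vegetables (similar between groups)
    "veg_main_dish",     "vegetables",      "vegetables",   "vegetables",         0.55,  0.00, 0.05, 0.1, 0.1,
    "veg_side_dish",     "vegetables",      "vegetables",   "vegetables",         0.50,  0.00, 0.05, 0.1, 0.1,
    "fresh_vegetables",  "vegetables",      "vegetables",   "vegetables",         0.70,  0.00, 0.05, 0.1, 0.0,
    "frozen_vegetables", "vegetables",      "vegetables",   "vegetables",         0.20, -0.05, 0.25, 0.1, 0.0,
    "veg_stew",          "vegetables",      "vegetables",   "vegetables",         0.30,  0.05, 0.15, 0.2, 0.2,
    # breads and cereals (healthy bread higher on the islands)
    "wheat_bread",       "healthy_bread",   "cereals",      "whole_grains",       0.30,  0.25, 0.25, 0.3, 0.2,
    "black_bread",       "healthy_bread",   "cereals",      "whole_grains",       0.15,  0.25, 0.35, 0.3, 0.2,
    "wholewheat_bread",  "healthy_bread",   "cereals",      "whole_grains",       0.15,  0.25, 0.35, 0.3, 0.2,
    "rye_bread",         "healthy_bread",   "cereals",      "whole_grains",       0.10,  0.25, 0.45, 0.3, 0.2,
    "corn_bread",        "healthy_bread",   "cereals",      "whole_grains",       0.06,  0.25, 0.55, 0.3, 0.2,
    "multigrain_bread",  "healthy_bread",   "cereals",      "whole_grains",       0.12,  0.25, 0.40, 0.3, 0.2,
    "white_bread",       "unhealthy_bread", "cereals",      NA,                   0.90,  0.10, 0.10, 0.3, 0.3,
    "toast",             "unhealthy_bread", "cereals",      NA,                   0.40,  0.05, 0.30, 0.4, 0.4,
    "rice",              NA,                "cereals",      NA,                   0.18,  0.00, 0.15, 0.1, 0.1,
    "pasta",             NA,                "cereals",      NA,                   0.28, -0.05, 0.10, 0.3, 0.2,
    "unsweetened_muesli","healthy_muesli",  "cereals",      "whole_grains",       0.12, -0.30, 0.45, 0.8, 0.4,
    "oatmeal",           "healthy_muesli",  "cereals",      "whole_grains",       0.10, -0.30, 0.50, 0.8, 0.4,
    "cornflakes",        "healthy_muesli",  "cereals",      "whole_grains",       0.08, -0.30, 0.50, 0.2, 0.2,
    "sweetened_muesli",  "unhealthy_muesli","cereals",      NA,                   0.06, -0.10, 0.55, 0.8, 0.8,
    "choco_balls",       "unhealthy_muesli","cereals",      NA,                   0.04, -0.10, 0.65, 0.8, 1.2,
    # potatoes
    "mashed_potatoes",   "potatoes",        "potatoes",     NA,                   0.15,  0.05, 0.20, 0.3, 0.6,
    "baked_potatoes",    "potatoes",        "potatoes",     NA,                   0.15,  0.05, 0.20, 0.3, 0.3,
    "french_fries",      "potatoes",        "potatoes",     NA,                   0.10,  0.00, 0.30, 2.0, 1.5,
    # olive oil
    "olive_oil",         NA,                "olive_oil",    NA,                   3.00,  0.10, 0.05, 10.0, 1.9,
    # nuts (mainland higher)
    "nuts_mixed",        "nuts",            "nuts",         "nuts",               0.16, -0.25, 0.35, 6.0, 1.2,
    "walnuts",           "nuts",            "nuts",         "nuts",               0.10, -0.25, 0.40, 2.5, 0.9,
    "almonds",           "nuts",            "nuts",         "nuts",               0.06, -0.25, 0.50, 6.5, 0.8,
    # dairy
    "highfat_milk",      "dairy",           "dairy_products","dairy",             0.30,  0.05, 0.25, 0.8, 2.0,
    "avgfat_milk",       "dairy",           "dairy_products","dairy",             0.50,  0.00, 0.15, 0.5, 1.2,
    "lowfat_milk",       "dairy",           "dairy_products","dairy",             0.20, -0.10, 0.40, 0.2, 0.4,
    "highfat_yogurt",    "dairy",           "dairy_products","dairy",             0.30,  0.05, 0.25, 0.8, 2.0,
    "lowfat_yogurt",     "dairy",           "dairy_products","dairy",             0.20, -0.10, 0.40, 0.2, 0.4,
    "fruit_yogurt",      "dairy",           "dairy_products","dairy",             0.20,  0.00, 0.35, 0.6, 1.5,
    "kefir",             "dairy",           "dairy_products","dairy",             0.10,  0.00, 0.50, 0.6, 1.5,
    # legumes (islanders somewhat higher)
    "beans",             "beans_lentils",   "legumes",      "legumes",            0.15,  0.10, 0.20, 0.2, 0.1,
    "lentils",           "beans_lentils",   "legumes",      "legumes",            0.08,  0.10, 0.35, 0.2, 0.1,
    # eggs
    "eggs",              NA,                "eggs",         NA,                   0.35,  0.05, 0.10, 2.0, 1.6,
    # fish (mainland higher)
    "blue_fish",         "fish",            "fish",         "fish",               0.10, -0.20, 0.25, 2.5, 1.2,
    "white_fish",        "fish",            "fish",         "fish",               0.12, -0.20, 0.25, 1.0, 0.6,
    "shellfish",         "fish",            "fish",         "fish",               0.04, -0.15, 0.60, 0.2, 0.2,
    "squid_octopus",     "fish",            "fish",         "fish",               0.04, -0.10, 0.60, 0.3, 0.3,
    "crabs",             "fish",            "fish",         "fish",               0.02, -0.10, 0.75, 0.2, 0.2,
    # white meat (mainland higher)
    "poultry",           "white_meat",      "white_meat",   NA,                   0.25, -0.15, 0.10, 3.0, 1.5,
    "turkey",            "white_meat",      "white_meat",   NA,                   0.10, -0.15, 0.35, 2.5, 1.2,
    # red meat (islanders higher)
    "beef_veal",         "red_meat",        "red_meat",     "red_processed_meat", 0.20,  0.10, 0.10, 3.5, 3.5,
    "pork",              "red_meat",        "red_meat",     "red_processed_meat", 0.20,  0.10, 0.10, 4.0, 3.5,
    "lamb",              "red_meat",        "red_meat",     "red_processed_meat", 0.08,  0.15, 0.40, 4.0, 4.5,
    "venison",           "red_meat",        "red_meat",     "red_processed_meat", 0.01,  0.10, 0.80, 1.5, 1.5,
    "sausages",          "meat_products",   "red_meat",     "red_processed_meat", 0.15,  0.10, 0.20, 5.0, 5.5,
    "hotdogs",           "meat_products",   "red_meat",     "red_processed_meat", 0.08,  0.10, 0.35, 5.0, 5.5,
    # sweets
    "pudding",           "sweets",          "sweets",       NA,                   0.08,  0.00, 0.45, 0.5, 1.5,
    "ice_cream",         "sweets",          "sweets",       NA,                   0.15,  0.00, 0.25, 1.5, 3.0,
    "sweet_pastries",    "sweets",          "sweets",       NA,                   0.25,  0.05, 0.15, 2.0, 3.0,
    "cookies",           "sweets",          "sweets",       NA,                   0.30,  0.05, 0.15, 2.0, 3.5,
    "pancakes",          "sweets",          "sweets",       NA,                   0.10,  0.00, 0.35, 1.5, 2.0,
    "chocolate",         "sweets",          "sweets",       NA,                   0.40,  0.00, 0.10, 3.0, 6.0,
    "candies",           "sweets",          "sweets",       NA,                   0.15,  0.05, 0.30, 0.2, 0.5,
    "chocolate_cake",    "sweets",          "sweets",       NA,                   0.12,  0.00, 0.30, 2.0, 3.5,
    # sweetened drinks (islanders slightly higher)
    "cola",              "sweetened_drinks","sweets",       NA,                   0.15,  0.15, 0.35, 0.0, 0.0,
    "soft_drinks",       "sweetened_drinks","sweets",       NA,                   0.15,  0.15, 0.35, 0.0, 0.0,
    "energy_drinks",     "sweetened_drinks","sweets",       NA,                   0.02,  0.10, 0.80, 0.0, 0.0,
    # other lifestyle-relevant items
    "fast_food",         NA,                NA,             NA,                   0.16,  0.05, 0.20, 2.5, 3.5,
    "snacks",            NA,                NA,             NA,                   0.14, -0.20, 0.25, 3.0, 2.5,
    "dressing",          NA,                NA,             NA,                   0.18,  0.30, 0.30, 4.0, 1.5,
    "sugar",             NA,                NA,             NA,                   7.00,  0.00, 0.05, 0.0, 0.0,
    "tea",               NA,                NA,             NA,                   4.00,  0.05, 0.10, 0.0, 0.0,
    "coffee",            NA,                NA,             NA,                   1.50,  0.00, 0.15, 0.0, 0.0,
    "water",             NA,                NA,             NA,                   6.00, -0.10, 0.02, 0.0, 0.0,
    "juice",             NA,                NA,             NA,                   0.40,  0.00, 0.20, 0.0, 0.0,
    # fermented beverages: essentially absent in a pregnancy cohort
    "wine",              NA,                "fermented_beverages", NA,            0.010, 0.00, 0.90, 0.0, 0.0,
    "beer",              NA,                "fermented_beverages", NA,            0.010, 0.00, 0.90, 0.0, 0.0,
    "spirits",           NA,                "fermented_beverages", NA,            0.003, 0.00, 0.95, 0.0, 0.0
  )
}

#' Default item-to-group map for cumulative frequencies
#'
#' Returns the mapping from FFQ items to "similar answer" groups whose
#' daily frequencies are summed by [cumulative_group_frequencies()].
#' Items with no group (`NA`) stay as individual variables.
#'
#' @return A tibble with columns `item_id` and `group`.
#' @export
default_item_groups <- function() {
  cat <- ffq_item_catalogue()
  tibble::tibble(item_id = cat$item_id, group = cat$cumulative_group)
}

#' Default synthetic fat composition table
#'
#' A synthetic per-serving monounsaturated (MUFA) and saturated (SFA)
#' fatty-acid composition table covering the catalogue items, used by the
#' MUFA:SFA ratio component of [score_mds_preg()] when no nutrient-database
#' table is supplied. Values are plausible but synthetic; substitute a real
#' composition table for substantive analyses.
#'
#' @return A tibble with columns `item_id`, `mufa_g`, `sfa_g`.
#' @export
default_composition <- function() {
  cat <- ffq_item_catalogue()
  tibble::tibble(item_id = cat$item_id, mufa_g = cat$mufa_g, sfa_g = cat$sfa_g)
}
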