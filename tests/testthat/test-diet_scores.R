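# Independent straight-line reimplementation of the two scores, used as an
# oracle. Deliberately transcribes each serving rule as explicit arithmetic,
# with values rounded to 9 decimals before comparison (the same numeric
# convention the engine's 1e-9 tolerance encodes).
oracle_mdss <- function(rec, mm = 3, include_fermented = FALSE) {
  g <- function(items) sum(unlist(rec[items]))
  r9 <- function(x) round(x, 9)
  total <- 0
  v <- r9(g(c("apple", "citrus_fruit", "banana", "seasonal_fruit")) / mm)
  if (v >= 1 && v <= 2) total <- total + 3                     # fresh fruit
  v <- r9(g(c("veg_main_dish", "veg_side_dish", "fresh_vegetables",
              "frozen_vegetables", "veg_stew")) / mm)
  if (v >= 2) total <- total + 3                               # vegetables
  v <- r9(g(c("wheat_bread", "black_bread", "wholewheat_bread", "rye_bread",
              "corn_bread", "multigrain_bread", "white_bread", "toast",
              "rice", "pasta", "unsweetened_muesli", "oatmeal", "cornflakes",
              "sweetened_muesli", "choco_balls")) / mm)
  if (v >= 1 && v <= 2) total <- total + 3                     # cereals
  v <- r9(7 * g(c("mashed_potatoes", "baked_potatoes", "french_fries")))
  if (v <= 3) total <- total + 1                               # potatoes
  v <- r9(g("olive_oil") / mm)
  if (v >= 1) total <- total + 3                               # olive oil
  v <- r9(g(c("nuts_mixed", "walnuts", "almonds")))
  if (v >= 1 && v <= 2) total <- total + 2                     # nuts
  v <- r9(7 * g(c("highfat_milk", "avgfat_milk", "lowfat_milk",
                  "highfat_yogurt", "lowfat_yogurt", "fruit_yogurt", "kefir")))
  if (v == 2) total <- total + 2                               # dairy
  v <- r9(7 * g(c("beans", "lentils")))
  if (v >= 2) total <- total + 1                               # legumes
  v <- r9(7 * g("eggs"))
  if (v >= 2 && v <= 4) total <- total + 1                     # eggs
  v <- r9(7 * g(c("blue_fish", "white_fish", "shellfish", "squid_octopus",
                  "crabs")))
  if (v >= 2) total <- total + 1                               # fish
  v <- r9(7 * g(c("poultry", "turkey")))
  if (v == 2) total <- total + 1                               # white meat
  v <- r9(7 * g(c("beef_veal", "pork", "lamb", "venison", "sausages",
                  "hotdogs")))
  if (v < 2) total <- total + 1                                # red meat, strict
  v <- r9(7 * g(c("pudding", "ice_cream", "sweet_pastries", "cookies",
                  "pancakes", "chocolate", "candies", "chocolate_cake",
                  "cola", "soft_drinks", "energy_drinks")))
  if (v <= 2) total <- total + 1                               # sweets
  if (include_fermented) {
    v <- r9(g(c("wine", "beer", "spirits")))
    if (v >= 1 && v <= 2) total <- total + 1                   # fermented
  }
  total
}

oracle_mds_preg <- function(rec, composition) {
  g <- function(items) sum(unlist(rec[items]))
  r9 <- function(x) round(x, 9)
  total <- 0
  if (r9(g(c("veg_main_dish", "veg_side_dish", "fresh_vegetables",
             "frozen_vegetables", "veg_stew"))) >= 3) total <- total + 1
  if (r9(g(c("apple", "citrus_fruit", "banana", "seasonal_fruit",
             "dried_fruit"))) >= 3) total <- total + 1
  if (r9(g(c("wheat_bread", "black_bread", "wholewheat_bread", "rye_bread",
             "corn_bread", "multigrain_bread", "unsweetened_muesli",
             "oatmeal", "cornflakes"))) >= 3) total <- total + 1
  if (r9(g(c("blue_fish", "white_fish", "shellfish", "squid_octopus",
             "crabs"))) >= 2) total <- total + 1
  if (r9(g(c("highfat_milk", "avgfat_milk", "lowfat_milk", "highfat_yogurt",
             "lowfat_yogurt", "fruit_yogurt", "kefir"))) >= 2) total <- total + 1
  if (r9(g(c("nuts_mixed", "walnuts", "almonds"))) >= 2) total <- total + 1
  if (r9(7 * g(c("beans", "lentils"))) > 1.5) total <- total + 1
  mufa <- sfa <- 0
  for (i in seq_len(nrow(composition))) {
    it <- composition$item_id[i]
    if (!is.null(rec[[it]])) {
      mufa <- mufa + rec[[it]] * composition$mufa_g[i]
      sfa <- sfa + rec[[it]] * composition$sfa_g[i]
    }
  }
  if (sfa > 0 && r9(mufa / sfa) > 1.6) total <- total + 1
  if (r9(7 * g(c("beef_veal", "pork", "lamb", "venison", "sausages",
                 "hotdogs"))) < 4.5) total <- total + 1
  total
}

test_that("servings_in_period converts daily frequencies to each reference period", {
  expect_equal(servings_in_period(0.5, "week"), 3.5)
  expect_equal(servings_in_period(3, "main_meal", main_meals_per_day = 3), 1)
  expect_equal(servings_in_period(0, "day"), 0)
  expect_equal(servings_in_period(0, "week"), 0)
  expect_equal(servings_in_period(0, "main_meal"), 0)
  expect_error(servings_in_period(1, "main_meal", main_meals_per_day = 0),
               "positive")
  expect_error(servings_in_period(1, "year"), "period")
})

test_that("an all-criteria record attains the 23-point adapted maximum and the
           24-point original maximum", {
  cfg <- default_score_config()
  expect_equal(mdss_max_points(cfg), 23)
  res <- score_mdss(mdss_reference_record(cfg), cfg)
  expect_equal(res$mdss_total, 23L)
  expect_true(res$mdss_adherent)

  cfg24 <- cfg
  cfg24$include_fermented <- TRUE
  expect_equal(mdss_max_points(cfg24), 24)
  expect_equal(mdss_cutoff(cfg24), 13.5)
  res24 <- score_mdss(mdss_reference_record(cfg24), cfg24)
  expect_equal(res24$mdss_total, 24L)
  expect_true(res24$mdss_adherent)
})

test_that("a record meeting no category scores zero and is not adherent", {
  cfg <- default_score_config()
  res <- score_mdss(mdss_reference_record(cfg, type = "violate"), cfg)
  expect_equal(res$mdss_total, 0L)
  expect_false(res$mdss_adherent)
})

test_that("the adherence cut-off separates totals of 12 and 13", {
  cfg <- default_score_config()
  rec12 <- mdss_reference_record(cfg, type = "violate")
  for (nm in c("fresh_fruit", "vegetables", "cereals", "olive_oil")) {
    rec12 <- set_category(rec12, nm, cfg)   # 4 x 3 points
  }
  res12 <- score_mdss(rec12, cfg)
  expect_equal(res12$mdss_total, 12L)
  expect_false(res12$mdss_adherent)

  rec13 <- set_category(rec12, "potatoes", cfg)   # + 1 point
  res13 <- score_mdss(rec13, cfg)
  expect_equal(res13$mdss_total, 13L)
  expect_true(res13$mdss_adherent)
})

test_that("a record satisfying only vegetables and eggs scores their 3 + 1 points", {
  cfg <- default_score_config()
  rec <- mdss_reference_record(cfg, type = "violate")
  rec <- set_category(rec, "vegetables", cfg)
  rec <- set_category(rec, "eggs", cfg)
  res <- score_mdss(rec, cfg)
  expect_equal(res$mdss_total, 4L)
  expect_true(res$met_vegetables)
  expect_true(res$met_eggs)
})

test_that("MDS-preg scores hand-built fixtures over the nine components", {
  cfg <- default_score_config()
  comp <- default_composition()

  all_met <- blank_record(cfg)
  all_met$veg_main_dish <- 3      # >= 3/day
  all_met$apple <- 3              # >= 3/day
  all_met$wheat_bread <- 3        # whole grains >= 3/day
  all_met$blue_fish <- 2          # >= 2/day
  all_met$highfat_milk <- 2       # >= 2/day
  all_met$nuts_mixed <- 2         # >= 2/day (also drives MUFA:SFA above 1.6)
  all_met$beans <- 0.25           # 1.75/week > 1.5
  res <- score_mds_preg(all_met, comp, cfg)
  expect_equal(res$mdspreg_total, 9L)
  expect_equal(as.character(res$mdspreg_band), "high")

  none_met <- blank_record(cfg)
  none_met$beef_veal <- 5 / 7     # 5/week >= 4.5 fails the meat criterion too
  res0 <- suppressWarnings(score_mds_preg(none_met, comp, cfg))
  expect_equal(res0$mdspreg_total, 0L)
  expect_equal(as.character(res0$mdspreg_band), "low")

  only_meat <- blank_record(cfg)
  only_meat$beef_veal <- 4 / 7    # 4/week < 4.5: the single point
  res1 <- suppressWarnings(score_mds_preg(only_meat, comp, cfg))
  expect_equal(res1$mdspreg_total, 1L)
  expect_true(res1$met_red_processed_meat)
})

test_that("printed-strict thresholds are strict at their boundaries", {
  cfg <- default_score_config()
  comp <- default_composition()
  rec <- blank_record(cfg)
  rec$beans <- 1.5 / 7            # exactly 1.5/week: 'over 1.5' not met
  rec$beef_veal <- 4.5 / 7        # exactly 4.5/week: 'lower than 4.5' not met
  rec$veg_main_dish <- 3          # exactly 3/day: '3 or more' met (inclusive)
  res <- suppressWarnings(score_mds_preg(rec, comp, cfg))
  expect_false(res$met_legumes)
  expect_false(res$met_red_processed_meat)
  expect_true(res$met_vegetables)

  # red meat < 2/week (MDSS) is strict as printed
  rec2 <- mdss_reference_record(cfg)
  rec2$beef_veal <- 2 / 7
  expect_false(score_mdss(rec2, cfg)$met_red_meat)
})

test_that("the MUFA:SFA ratio is the composition-weighted intake ratio", {
  comp <- tibble::tibble(item_id = c("a", "b"), mufa_g = c(8, 2),
                         sfa_g = c(4, 4))
  one <- tibble::tibble(participant_id = "r", a = 0.7, b = 0)
  expect_equal(mufa_sfa_ratio(one, comp), 2)        # frequency cancels
  two <- tibble::tibble(participant_id = "r", a = 0.3, b = 0.3)
  expect_equal(mufa_sfa_ratio(two, tibble::tibble(item_id = c("a", "b"),
                                                  mufa_g = c(10, 2),
                                                  sfa_g = c(5, 4))), 12 / 9)
  zero <- tibble::tibble(participant_id = "r", a = 0, b = 0)
  expect_true(is.na(mufa_sfa_ratio(zero, comp)))
  expect_error(mufa_sfa_ratio(one, NULL), "composition")
  expect_error(mufa_sfa_ratio(tibble::tibble(participant_id = "r", zz = 1),
                              comp), "covers")
})

test_that("a ratio of exactly 1.6 does not meet the exceed criterion", {
  cfg <- default_score_config()
  comp <- tibble::tibble(item_id = "olive_oil", mufa_g = 1.6, sfa_g = 1)
  rec <- blank_record(cfg)
  rec$olive_oil <- 1
  res <- score_mds_preg(rec, comp, cfg)
  expect_false(res$met_mufa_sfa_ratio)
  comp$mufa_g <- 1.601
  expect_true(score_mds_preg(rec, comp, cfg)$met_mufa_sfa_ratio)
})

test_that("MDS-preg band mapping follows the 0-3 / 4-6 / 7-9 boundaries", {
  expect_equal(as.character(classify_mds_preg(c(0, 3, 4, 6, 7, 9))),
               c("low", "low", "moderate", "moderate", "high", "high"))
  expect_error(classify_mds_preg(10), "0-9")
  expect_error(classify_mds_preg(-1), "0-9")
})

test_that("adding servings never lowers an at-least score and red meat never
           raises either score", {
  cfg <- default_score_config()
  comp <- default_composition()
  withr::with_seed(99, {
    for (i in 1:25) {
      rec <- random_daily_record(cfg, "r")
      up <- rec
      up$blue_fish <- up$blue_fish + runif(1, 0, 2)   # at_least category (fish)
      expect_gte(score_mdss(up, cfg)$mdss_total, score_mdss(rec, cfg)$mdss_total)

      meat <- rec
      meat$pork <- meat$pork + runif(1, 0, 3)
      expect_lte(score_mdss(meat, cfg)$mdss_total, score_mdss(rec, cfg)$mdss_total)
      expect_lte(
        suppressWarnings(score_mds_preg(meat, comp, cfg)$mdspreg_total),
        suppressWarnings(score_mds_preg(rec, comp, cfg)$mdspreg_total)
      )
    }
  })
})

test_that("both engines agree with the straight-line oracle on random records", {
  cfg <- default_score_config()
  cfg24 <- cfg; cfg24$include_fermented <- TRUE
  comp <- default_composition()
  withr::with_seed(123, {
    for (i in 1:500) {
      rec <- random_daily_record(cfg, paste0("r", i))
      expect_equal(score_mdss(rec, cfg)$mdss_total, oracle_mdss(rec))
      expect_equal(score_mdss(rec, cfg24)$mdss_total,
                   oracle_mdss(rec, include_fermented = TRUE))
      expect_equal(
        suppressWarnings(score_mds_preg(rec, comp, cfg)$mdspreg_total),
        oracle_mds_preg(rec, comp)
      )
    }
  })
})

test_that("score bounds hold on random records", {
  cfg <- default_score_config()
  comp <- default_composition()
  withr::with_seed(321, {
    for (i in 1:50) {
      rec <- random_daily_record(cfg, "r")
      s1 <- score_mdss(rec, cfg)$mdss_total
      s2 <- suppressWarnings(score_mds_preg(rec, comp, cfg)$mdspreg_total)
      expect_true(s1 >= 0 && s1 <= 23)
      expect_true(s2 >= 0 && s2 <= 9)
    }
  })
})

test_that("a score configuration round-trips through YAML with identical scoring", {
  cfg <- default_score_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_score_config(cfg, path)
  cfg2 <- read_score_config(path)
  withr::with_seed(55, {
    recs <- dplyr::bind_rows(lapply(1:20, function(i)
      random_daily_record(cfg, paste0("r", i))))
  })
  expect_equal(score_mdss(recs, cfg2), score_mdss(recs, cfg))
  expect_equal(suppressWarnings(score_mds_preg(recs, config = cfg2)),
               suppressWarnings(score_mds_preg(recs, config = cfg)))
})

test_that("invalid score configurations are rejected", {
  cfg <- default_score_config()
  bad <- cfg
  bad$mdss$categories[[1]]$items <- list()
  expect_error(validate_score_config(bad), "no mapped items")
  bad2 <- cfg
  bad2$mdss$cutoff_excluded <- 30
  expect_error(validate_score_config(bad2), "cut-off")
  bad3 <- cfg
  bad3$mds_preg$components <- bad3$mds_preg$components[1:5]
  expect_error(validate_score_config(bad3), "9 components")
})
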