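# Default scoring configuration.
#
# mdss: the 14 food categories of the Mediterranean Diet Serving Score with
# their serving rules (reference period: main_meal / day / week), points
# (1-3) and member FFQ items. The fermented-beverage category is excluded
# by default (include_fermented: false), giving an attainable maximum of 23
# points with an adherence cut-off of 12.5; including it restores the
# original 24-point score with a cut-off of 13.5.
#
# mds_preg: the nine binary components of the Mediterranean Diet Score for
# pregnant women, thresholds read literally ("3 or more" inclusive,
# "over 1.5" / "exceed 1.6" / "lower than 4.5" strict), with low (0-3),
# moderate (4-6) and high (7-9) adherence bands.
main_meals_per_day: 3
include_fermented: false
mdss:
  cutoff_excluded: 12.5
  cutoff_included: 13.5
  categories:
  - name: fresh_fruit
    points: 3
    direction: within_range
    min: 1.0
    max: 2.0
    period: main_meal
    strict: false
    fermented: false
    items: [apple, citrus_fruit, banana, seasonal_fruit]
  - name: vegetables
    points: 3
    direction: at_least
    min: 2.0
    period: main_meal
    strict: false
    fermented: false
    items: [veg_main_dish, veg_side_dish, fresh_vegetables, frozen_vegetables, veg_stew]
  - name: cereals
    points: 3
    direction: within_range
    min: 1.0
    max: 2.0
    period: main_meal
    strict: false
    fermented: false
    items: [wheat_bread, black_bread, wholewheat_bread, rye_bread, corn_bread,
            multigrain_bread, white_bread, toast, rice, pasta,
            unsweetened_muesli, oatmeal, cornflakes, sweetened_muesli, choco_balls]
  - name: potatoes
    points: 1
    direction: at_most
    max: 3.0
    period: week
    strict: false
    fermented: false
    items: [mashed_potatoes, baked_potatoes, french_fries]
  - name: olive_oil
    points: 3
    direction: at_least
    min: 1.0
    period: main_meal
    strict: false
    fermented: false
    items: [olive_oil]
  - name: nuts
    points: 2
    direction: within_range
    min: 1.0
    max: 2.0
    period: day
    strict: false
    fermented: false
    items: [nuts_mixed, walnuts, almonds]
  - name: dairy_products
    points: 2
    direction: within_range
    min: 2.0
    max: 2.0
    period: week
    strict: false
    fermented: false
    items: [highfat_milk, avgfat_milk, lowfat_milk, highfat_yogurt,
            lowfat_yogurt, fruit_yogurt, kefir]
  - name: legumes
    points: 1
    direction: at_least
    min: 2.0
    period: week
    strict: false
    fermented: false
    items: [beans, lentils]
  - name: eggs
    points: 1
    direction: within_range
    min: 2.0
    max: 4.0
    period: week
    strict: false
    fermented: false
    items: [eggs]
  - name: fish
    points: 1
    direction: at_least
    min: 2.0
    period: week
    strict: false
    fermented: false
    items: [blue_fish, white_fish, shellfish, squid_octopus, crabs]
  - name: white_meat
    points: 1
    direction: within_range
    min: 2.0
    max: 2.0
    period: week
    strict: false
    fermented: false
    items: [poultry, turkey]
  - name: red_meat
    points: 1
    direction: at_most
    max: 2.0
    period: week
    strict: true
    fermented: false
    items: [beef_veal, pork, lamb, venison, sausages, hotdogs]
  - name: sweets
    points: 1
    direction: at_most
    max: 2.0
    period: week
    strict: false
    fermented: false
    items: [pudding, ice_cream, sweet_pastries, cookies, pancakes, chocolate,
            candies, chocolate_cake, cola, soft_drinks, energy_drinks]
  - name: fermented_beverages
    points: 1
    direction: within_range
    min: 1.0
    max: 2.0
    period: day
    strict: false
    fermented: true
    items: [wine, beer, spirits]
mds_preg:
  low_max: 3
  moderate_max: 6
  zero_sfa: unmet
  components:
  - name: vegetables
    direction: at_least
    min: 3.0
    period: day
    strict: false
    ratio: false
    items: [veg_main_dish, veg_side_dish, fresh_vegetables, frozen_vegetables, veg_stew]
  - name: fruits
    direction: at_least
    min: 3.0
    period: day
    strict: false
    ratio: false
    items: [apple, citrus_fruit, banana, seasonal_fruit, dried_fruit]
  - name: whole_grains
    direction: at_least
    min: 3.0
    period: day
    strict: false
    ratio: false
    items: [wheat_bread, black_bread, wholewheat_bread, rye_bread, corn_bread,
            multigrain_bread, unsweetened_muesli, oatmeal, cornflakes]
  - name: fish
    direction: at_least
    min: 2.0
    period: day
    strict: false
    ratio: false
    items: [blue_fish, white_fish, shellfish, squid_octopus, crabs]
  - name: dairy
    direction: at_least
    min: 2.0
    period: day
    strict: false
    ratio: false
    items: [highfat_milk, avgfat_milk, lowfat_milk, highfat_yogurt,
            lowfat_yogurt, fruit_yogurt, kefir]
  - name: nuts
    direction: at_least
    min: 2.0
    period: day
    strict: false
    ratio: false
    items: [nuts_mixed, walnuts, almonds]
  - name: legumes
    direction: at_least
    min: 1.5
    period: week
    strict: true
    ratio: false
    items: [beans, lentils]
  - name: mufa_sfa_ratio
    direction: at_least
    min: 1.6
    period: none
    strict: true
    ratio: true
    items: []
  - name: red_processed_meat
    direction: at_most
    max: 4.5
    period: week
    strict: true
    ratio: false
    items: [beef_veal, pork, lamb, venison, sausages, hotdogs]
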