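test_that("frequency normalization follows the day/week/month conversion", {
  expect_identical(normalize_frequency(2, "week"), 2 / 7)
  expect_identical(normalize_frequency(1, "day"), 1)
  expect_equal(normalize_frequency(3, "month"), 0.1)
  expect_equal(normalize_frequency(3, "month", days_per_month = 30.44),
               3 / 30.44)
  expect_error(normalize_frequency(2, "fortnight"), "fortnight")
  expect_error(normalize_frequency(-1, "day"), "non-negative")
})

test_that("normalization is linear and monotone within a period", {
  withr::with_seed(1, {
    f <- runif(50, 0, 20)
    a <- runif(50, 0, 5)
    for (p in c("day", "week", "month")) {
      expect_equal(normalize_frequency(a * f, p), a * normalize_frequency(f, p))
      ord <- order(f)
      expect_true(!is.unsorted(normalize_frequency(f, p)[ord]))
    }
  })
})

test_that("daily_frequencies widens the long FFQ with zero fill and portions", {
  ffq <- tibble::tibble(
    participant_id = c("a", "a", "b"),
    item_id = c("fish", "bread", "fish"),
    frequency = c(2, 7, 3),
    period = c("week", "day", "month"),
    portion_multiplier = c(1, 1, 2)
  )
  wide <- daily_frequencies(ffq)
  expect_equal(wide$fish, c(2 / 7, 2 * 3 / 30))
  expect_equal(wide$bread, c(7, 0))
  dup <- dplyr::bind_rows(ffq, ffq[1, ])
  expect_error(daily_frequencies(dup), "Duplicate")
})

test_that("cumulative group frequencies sum members and conserve mass", {
  daily <- tibble::tibble(participant_id = c("a", "b"),
                          poultry = c(0.2, 0.5), turkey = c(0.1, 0),
                          fish = c(0.3, 0.4))
  grouping <- tibble::tibble(item_id = c("poultry", "turkey", "fish"),
                             group = c("white_meat", "white_meat", NA))
  cum <- cumulative_group_frequencies(daily, grouping, keep_items = "ungrouped")
  expect_equal(cum$white_meat, c(0.3, 0.5))
  expect_named(cum, c("participant_id", "white_meat", "fish"))

  # all members zero => the group is zero
  daily0 <- daily; daily0$poultry <- 0; daily0$turkey <- 0
  expect_equal(cumulative_group_frequencies(daily0, grouping,
                                            keep_items = "none")$white_meat,
               c(0, 0))

  # conflicting map is a config error
  bad <- dplyr::bind_rows(grouping,
                          tibble::tibble(item_id = "poultry", group = "meat"))
  expect_error(cumulative_group_frequencies(daily, bad), "more than one group")
})

test_that("cumulative frequencies match a brute-force recomputation and are
           permutation invariant", {
  withr::with_seed(42, {
    n <- 5; p <- 12
    items <- sprintf("it%02d", seq_len(p))
    daily <- tibble::as_tibble(matrix(round(runif(n * p), 3), n,
                                      dimnames = list(NULL, items)))
    daily <- dplyr::bind_cols(
      tibble::tibble(participant_id = sprintf("P%d", 1:n)), daily)
    grouping <- tibble::tibble(item_id = items,
                               group = rep(c("g1", "g2", "g3", "g4"), each = 3))
    cum <- cumulative_group_frequencies(daily, grouping, keep_items = "none")
    # independent recomputation, cell by cell
    for (g in c("g1", "g2", "g3", "g4")) {
      members <- grouping$item_id[grouping$group == g]
      manual <- vapply(seq_len(n),
                       function(i) sum(vapply(members, function(m) daily[[m]][i],
                                              numeric(1))),
                       numeric(1))
      expect_equal(cum[[g]], manual)
    }
    # mass conservation
    expect_equal(rowSums(as.matrix(cum[-1])), rowSums(as.matrix(daily[items])))
    # permutation invariance in item order
    perm <- sample(p)
    daily2 <- dplyr::bind_cols(daily[1], daily[items[perm]])
    cum2 <- cumulative_group_frequencies(daily2, grouping[sample(p), ],
                                         keep_items = "none")
    expect_equal(cum[sort(names(cum))], cum2[sort(names(cum2))])
  })
})

test_that("variable filtering removes constant, low-variance, missing and
           duplicated columns with a removal log", {
  withr::with_seed(7, {
    n <- 60
    tab <- tibble::tibble(
      participant_id = sprintf("P%d", 1:n),
      location = factor(rep(c("island", "mainland"), n / 2)),
      keepme = rnorm(n),
      konst = rep(3, n),
      tiny_var = rnorm(n, sd = 1e-4),
      holey = ifelse(runif(n) < 0.5, NA, rnorm(n))
    )
    tab$dupe <- tab$keepme  # identical copy, later in column order
    out <- filter_variables(tab)
    expect_setequal(numeric_variables(out), "keepme")
    log <- attr(out, "removal_log")
    expect_setequal(log$variable, c("konst", "tiny_var", "holey", "dupe"))
    expect_equal(log$reason[log$variable == "konst"], "constant")
    expect_equal(log$reason[log$variable == "dupe"], "high_correlation")
    expect_equal(log$reason[log$variable == "holey"], "missing")
  })
})

test_that("correlation filtering equals a brute-force greedy scan and is
           idempotent", {
  withr::with_seed(11, {
    n <- 80
    base <- matrix(rnorm(n * 4), n, 4)
    x <- cbind(base,
               base[, 1] + rnorm(n, sd = 0.05),   # near-duplicate of v1
               base[, 2] + rnorm(n, sd = 0.02),   # near-duplicate of v2
               base[, 1] - base[, 2] + rnorm(n),
               matrix(rnorm(n * 3), n, 3))
    colnames(x) <- sprintf("v%02d", 1:10)
    tab <- dplyr::bind_cols(tibble::tibble(participant_id = sprintf("P%d", 1:n)),
                            tibble::as_tibble(x))
    thr <- 0.95
    out <- filter_variables(tab, corr_threshold = thr)

    # brute-force oracle: walk columns left to right over the full
    # Spearman matrix, keeping a column only if it is not too correlated
    # with any previously kept column
    rho <- abs(cor(x, method = "spearman"))
    kept <- 1
    for (j in 2:10) {
      if (all(rho[j, kept] <= thr)) kept <- c(kept, j)
    }
    expect_identical(numeric_variables(out), colnames(x)[kept])

    # idempotence
    again <- filter_variables(out, corr_threshold = thr)
    expect_identical(names(again), names(out))
    expect_equal(nrow(attr(again, "removal_log")), 0)
  })
})

test_that("cohort assembly inner-joins on participant id and reports orphans", {
  ids <- c("a", "b", "c")
  scores <- tibble::tibble(participant_id = ids, mdss_total = 1:3)
  cum <- tibble::tibble(participant_id = ids, fish = c(0.1, 0.2, 0.3))
  sd_tab <- tibble::tibble(participant_id = ids, education = c(1, 0, 1))
  labels <- tibble::tibble(participant_id = ids,
                           location = factor(c("island", "island", "mainland")),
                           class = c(0L, 0L, 1L))
  out <- assemble_cohort(scores, cum, sd_tab, labels)
  expect_equal(nrow(out), 3)
  expect_setequal(names(out), c("participant_id", "location", "class",
                                "mdss_total", "fish", "education"))
  expect_setequal(attr(out, "var_meta")$variable,
                  c("mdss_total", "fish", "education"))

  scores2 <- scores; scores2$participant_id <- c("x", "y", "z")
  expect_error(assemble_cohort(scores2, cum, sd_tab, labels), "orphan")
})

test_that("the default synthetic cohort assembles to the study-sized table", {
  cohort <- generate_cohort(default_cohort_config(), seed = 5)
  tab <- build_analysis_table(cohort)
  p <- length(numeric_variables(tab))
  # generator config implies 104 variables (77 items + 16 groups +
  # 9 lifestyle + 2 scores); a couple may fall to the filters
  expect_gte(p, 98)
  expect_lte(p, 104)
  expect_equal(nrow(tab), 266)
})
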