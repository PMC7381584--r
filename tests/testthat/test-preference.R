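test_that("proportional_abundance normalises over the observed plant set", {
  expect_equal(proportional_abundance(c(A = 60, B = 20, C = 20)),
               c(A = 0.6, B = 0.2, C = 0.2))
  expect_equal(proportional_abundance(c(A = 7)), c(A = 1))
  expect_equal(proportional_abundance(c(A = 0, B = 10)), c(A = 0, B = 1))
  expect_error(proportional_abundance(c(A = 0, B = 0)), "all abundances")
})

test_that("build_site_week_matrix applies the scaling modes", {
  rates <- rbind(honey_bee = c(A = 0.1, B = 0),
                 wild = c(A = 0.2, B = 0.1))
  shares <- c(A = 0.5, B = 0.5)
  m <- build_site_week_matrix(rates, shares)
  expect_equal(m$entries,
               rbind(honey_bee = c(A = 0.05, B = 0),
                     wild = c(A = 0.1, B = 0.05)))
  expect_false(m$one_dimensional)
  expect_equal(m$row_sums, rowSums(m$entries), tolerance = 1e-9)

  m_none <- build_site_week_matrix(rates, shares, "none")
  expect_equal(m_none$entries, rates)

  m_div <- build_site_week_matrix(rates, shares, "divide")
  expect_equal(m_div$entries, rates / 0.5)
  expect_warning(
    build_site_week_matrix(rates, c(A = 1, B = 0), "divide"),
    "zero abundance share")

  # all-zero honey-bee row triggers the one-dimensional wild-only path
  rates0 <- rbind(honey_bee = c(A = 0, B = 0), wild = c(A = 0.2, B = 0.1))
  m1 <- build_site_week_matrix(rates0, shares)
  expect_true(m1$one_dimensional)
  expect_equal(rownames(m1$entries), "wild")
})

test_that("preference is observed minus null mean; forced cases are zero", {
  rates <- rbind(honey_bee = c(A = 0.1, B = 0.02),
                 wild = c(A = 0.2, B = 0.3))
  m <- build_site_week_matrix(rates, c(A = 0.5, B = 0.5))
  res <- preference_indices(m, n_replicates = 500, seed = 12,
                            site = "S1", week = 3)
  expect_equal(res$preference, res$observed - res$expected)
  expect_equal(nrow(res), 4L)
  # a single plant leaves the null forced: preference exactly 0
  one <- build_site_week_matrix(
    rbind(honey_bee = c(A = 0.1), wild = c(A = 0.2)), c(A = 1))
  res1 <- preference_indices(one, n_replicates = 100, seed = 1)
  expect_equal(res1$preference, c(0, 0), tolerance = 1e-9)
  expect_equal(res1$mc_se, c(0, 0), tolerance = 1e-9)
})

test_that("preferences within a site-week sum to ~0 (shared marginals)", {
  set.seed(21)
  rates <- rbind(honey_bee = runif(5, 0, 0.1), wild = runif(5, 0, 0.3))
  colnames(rates) <- paste0("P", 1:5)
  shares <- proportional_abundance(setNames(runif(5, 1, 50),
                                            colnames(rates)))
  m <- build_site_week_matrix(rates, shares)
  res <- preference_indices(m, n_replicates = 400, seed = 5)
  expect_lt(abs(sum(res$preference)), 10 / 1e4)
})

test_that("identical seed and inputs give identical preference results", {
  d <- small_dataset(seed = 3, n_weeks = 4L)
  p1 <- site_week_preferences(d$obs, d$abundance, n_replicates = 100,
                              master_seed = 17)
  p2 <- site_week_preferences(d$obs, d$abundance, n_replicates = 100,
                              master_seed = 17)
  expect_identical(p1, p2)
  p3 <- site_week_preferences(d$obs, d$abundance, n_replicates = 100,
                              master_seed = 18)
  expect_false(identical(p1$preference, p3$preference))
})

test_that("aggregate_species_preference averages and ranks per type", {
  res <- data.frame(site = "S", week = c(1, 2, 1),
                    plant_id = c("A", "A", "B"),
                    pollinator_type = "wild",
                    preference = c(0.10, 0.12, 0.05))
  agg <- aggregate_species_preference(res)
  expect_equal(agg$mean_preference[agg$plant_id == "A"], 0.11)
  expect_equal(agg$mean_preference[agg$plant_id == "B"], 0.05)
  expect_equal(agg$rank[agg$plant_id == "A"], 1)
  expect_equal(agg$n_site_weeks[agg$plant_id == "A"], 2)
})

test_that("data generated by the null itself yields near-zero preference", {
  # draw the observed matrix from the fixed-margins null, then measure its
  # preference against a fresh ensemble: mean over cells ~ 0
  set.seed(31)
  rs <- c(0.2, 0.45)
  cs <- c(0.25, 0.15, 0.25)
  obs <- sample_decimal_table(rs, cs, g = 1e4)
  dimnames(obs) <- list(c("honey_bee", "wild"), paste0("P", 1:3))
  swm <- structure(list(entries = obs, row_sums = rowSums(obs),
                        col_sums = colSums(obs), scaling_mode = "none",
                        one_dimensional = FALSE, raw_rates = obs),
                   class = "site_week_matrix")
  res <- preference_indices(swm, n_replicates = 2000, seed = 77)
  pooled_se <- sqrt(sum(res$mc_se^2)) / nrow(res)
  expect_lt(abs(mean(res$preference)), 3 * pooled_se + 1e-6)
})

test_that("preference_model reports interaction and main-effect LRTs", {
  d <- small_dataset(seed = 6, n_weeks = 8L)
  prefs <- site_week_preferences(d$obs, d$abundance, n_replicates = 100,
                                 master_seed = 2)
  pm <- preference_model(prefs, d$plants)
  expect_setequal(pm$lrt$term, c("native_status:pollinator_type",
                                 "native_status", "pollinator_type"))
  expect_true(all(pm$lrt$p >= 0 & pm$lrt$p <= 1))
  expect_true(all(pm$lrt$chisq >= 0))
  expect_equal(nrow(pm$group_means), 4L)

  only_wild <- prefs[prefs$pollinator_type == "wild", ]
  expect_error(preference_model(only_wild, d$plants), "single level")
})
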