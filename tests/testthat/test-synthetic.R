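test_that("generation is deterministic under a fixed master seed", {
  a <- generate_dataset(default_generator_config(n_weeks = 3L), seed = 17)
  b <- generate_dataset(default_generator_config(n_weeks = 3L), seed = 17)
  for (nm in c("plants", "observations", "stems", "netting", "pollen")) {
    expect_identical(a[[nm]], b[[nm]])
  }
  c2 <- generate_dataset(default_generator_config(n_weeks = 3L), seed = 18)
  expect_false(identical(a$observations, c2$observations))
})

test_that("degenerate abundance spread collapses to exp(mu)", {
  com <- generate_community(default_generator_config(abundance_sdlog = 0),
                            seed = 1)
  expect_true(all(abs(com$truth$abundance - exp(3)) < 1e-9))
})

test_that("status split matches the binomial expectation", {
  n_intro <- vapply(1:20, function(s) {
    sum(generate_community(seed = s)$plants$native_status == "introduced")
  }, numeric(1))
  expect_lt(abs(mean(n_intro) - 30), 3 * sqrt(54 * (30 / 54) * (24 / 54) / 20))
})

test_that("flat generator recovers the base rate by the law of large numbers", {
  cfg <- default_generator_config(
    n_sites = 5L, n_weeks = 25L, pref_weight_sdlog = 0,
    beta = matrix(0, 2, 2, dimnames = list(c("honey_bee", "wild"),
                                           c("native", "introduced"))))
  com <- generate_community(cfg, seed = 3)
  obs <- filter_visits(generate_observations(com, cfg, seed = 3))
  rate_w <- visitation_rate(obs$wild_visits, obs$floral_units, obs$minutes)
  mc_se <- sd(rate_w) / sqrt(length(rate_w))
  expect_lt(abs(mean(rate_w) - 0.05), 3 * mc_se)
})

test_that("large theta approaches the Poisson variance-mean relation", {
  cfg <- default_generator_config(
    theta = 1e6, pref_weight_sdlog = 0, abundance_sdlog = 0,
    beta = matrix(0, 2, 2, dimnames = list(c("honey_bee", "wild"),
                                           c("native", "introduced"))),
    floral_units_extra_mean = 0)  # constant exposure -> iid counts
  com <- generate_community(cfg, seed = 4)
  obs <- filter_visits(generate_observations(com, cfg, seed = 4))
  x <- obs$wild_visits
  # var/mean ~ 1 + mu/theta ~ 1; allow sampling noise on ~216 draws
  expect_lt(abs(var(x) / mean(x) - 1), 0.35)
})

test_that("zero exposure is rejected", {
  cfg <- default_generator_config(minutes = 0)
  com <- generate_community(cfg, seed = 1)
  expect_error(generate_observations(com, cfg, seed = 1), "exposure")
})

test_that("generated bundles validate with zero rejected rows", {
  d <- generate_dataset(default_generator_config(n_weeks = 4L), seed = 23)
  expect_equal(nrow(d$validation), 0L)
  expect_length(d$unknown_plants, 0L)
})

test_that("pollen generator respects the Beta-binomial construction", {
  d <- generate_pollen(default_generator_config(), seed = 2)
  expect_true(all(d$total_grains == 300))
  expect_true(all(d$knapweed_grains >= 0 & d$knapweed_grains <= 300))
  # degenerate share at zero -> all-zero counts
  cfg0 <- default_generator_config(pollen_beta = list(bee_bread = c(0, 1)))
  expect_true(all(generate_pollen(cfg0, seed = 3)$knapweed_grains == 0))
  # mean percent across many apiaries ~ a / (a + b)
  cfgm <- default_generator_config(
    n_apiaries = 400L, pollen_beta = list(bee_bread = c(1, 19)))
  dm <- generate_pollen(cfgm, seed = 4)
  pct <- 100 * dm$knapweed_grains / dm$total_grains
  expect_lt(abs(mean(pct) - 5), 3 * sd(pct) / sqrt(length(pct)))
})

test_that("netting with a single-taxon pool has zero diversity", {
  cfg <- default_generator_config(n_taxa = 1L, n_weeks = 3L)
  com <- generate_community(cfg, seed = 5)
  net <- generate_netting(com, cfg, seed = 5)
  dt <- diversity_table(net)
  expect_true(all(dt$shannon == 0))
  expect_true(all(dt$richness <= 1))
})

test_that("high-concentration uniform communities approach ln(k)", {
  cfg <- default_generator_config(n_taxa = 5L, dirichlet_conc = 5000,
                                  netting_specimen_mean = 400,
                                  n_weeks = 2L, netting_per_siteweek = 3L)
  com <- generate_community(cfg, seed = 6)
  net <- generate_netting(com, cfg, seed = 6)
  dt <- diversity_table(net)
  expect_lt(max(abs(dt$shannon - log(5))), 0.05)
})

test_that("unknown generator fields are rejected", {
  expect_error(default_generator_config(nonsense = 1), "unknown generator")
})
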