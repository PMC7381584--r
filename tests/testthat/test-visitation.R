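test_that("visitation_rate divides by exposure and rejects zero exposure", {
  expect_equal(visitation_rate(9, 30, 15), 0.02)
  expect_equal(visitation_rate(0, 30, 15), 0)
  expect_error(visitation_rate(1, 30, 0), "exposure")
  expect_error(visitation_rate(1, 0, 15), "exposure")
})

test_that("likelihood_ratio_test handles identity, nesting, and df", {
  d <- small_dataset(seed = 2, n_weeks = 6L)
  long <- build_rate_table(d$obs, d$abundance, d$plants)
  full <- fit_rate_model(long, mode = "robust", abundance_transform = "log")
  same <- likelihood_ratio_test(full, full)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  red <- fit_rate_model(long,
                        fixed = ~ (abund_x + native_status +
                                     pollinator_type)^2,
                        mode = "robust", abundance_transform = "log")
  lrt <- likelihood_ratio_test(full, red)
  expect_equal(lrt$df, 1L)
  expect_gte(lrt$chisq, 0)
  expect_error(likelihood_ratio_test(red, full), "not nested")
})

test_that("doubling all exposures shifts only the intercept by -log 2", {
  d <- small_dataset(seed = 2, n_weeks = 6L)
  long <- build_rate_table(d$obs, d$abundance, d$plants)
  f1 <- fit_rate_model(long, mode = "robust", abundance_transform = "log")
  long2 <- long
  long2$minutes <- long2$minutes * 2
  f2 <- fit_rate_model(long2, mode = "robust", abundance_transform = "log")
  delta <- f2$coefficients - f1$coefficients
  expect_equal(unname(delta["(Intercept)"]), -log(2), tolerance = 1e-6)
  expect_lt(max(abs(delta[names(delta) != "(Intercept)"])), 1e-6)
})

test_that("NB fit approaches the Poisson fit as dispersion grows", {
  # Poisson-generated counts make glm.nb drive theta large; coefficients
  # must agree with the plain Poisson GLM
  set.seed(14)
  n <- 300
  df <- data.frame(x = rnorm(n), off = log(runif(n, 50, 400)))
  df$y <- rpois(n, exp(-3 + 0.4 * df$x + df$off))
  nb <- suppressWarnings(MASS::glm.nb(y ~ x + offset(off), data = df))
  po <- stats::glm(y ~ x + offset(off), family = poisson, data = df)
  expect_lt(max(abs(coef(nb) - coef(po))), 1e-3)
})

test_that("a constant factor raises a design-rank error", {
  d <- small_dataset(seed = 2, n_weeks = 6L)
  long <- build_rate_table(d$obs, d$abundance, d$plants)
  long$pollinator_type <- "honey_bee"
  expect_error(fit_rate_model(long, mode = "robust"), "rank deficient")
})

test_that("abundance_slopes recovers equal slopes when interactions vanish", {
  # hand-built fit object: only the common abundance slope is nonzero
  d <- small_dataset(seed = 2, n_weeks = 6L)
  long <- build_rate_table(d$obs, d$abundance, d$plants)
  long$abund_x <- log(long$abundance)
  long$native_status <- factor(long$native_status)
  long$pollinator_type <- factor(long$pollinator_type)
  X <- model.matrix(~ abund_x * native_status * pollinator_type, long)
  beta <- setNames(rep(0, ncol(X)), colnames(X))
  beta["abund_x"] <- -0.2
  fit <- structure(list(coefficients = beta, vcov = diag(ncol(X)) * 1e-4,
                        fixed = ~ abund_x * native_status * pollinator_type,
                        data = long, converged = TRUE, wald_df = Inf,
                        mode = "robust"),
                   class = "rate_model_fit")
  sl <- abundance_slopes(fit)
  expect_equal(sl$slopes$estimate, rep(-0.2, 4), tolerance = 1e-12)
  expect_equal(sl$slope_differences$estimate, c(0, 0), tolerance = 1e-12)
  # with no slope difference, the status main effect at mean abundance is
  # reported for both pollinator types
  expect_equal(nrow(sl$status_at_mean), 2L)
})

test_that("adjust_tukey matches the unadjusted test for one contrast and
           is more conservative for several", {
  expect_equal(adjust_tukey(2, matrix(1)), 2 * pnorm(-2), tolerance = 1e-9)
  V <- diag(3)
  p_adj <- adjust_tukey(c(2, 0.5, 1), V)
  expect_gt(p_adj[1], 2 * pnorm(-2))
  expect_true(all(p_adj >= 0 & p_adj <= 1))
  # perfectly correlated contrasts need no correction
  V1 <- matrix(1, 2, 2)
  expect_equal(adjust_tukey(c(2, 2), V1 + diag(1e-10, 2))[1],
               2 * pnorm(-2), tolerance = 1e-3)
})

test_that("knapweed_contrast needs knapweed rows and returns 6 pairwise
           comparisons of the four means", {
  d <- small_dataset(seed = 5, n_weeks = 8L)
  long <- build_rate_table(d$obs, d$abundance, d$plants)
  expect_error(knapweed_contrast(long, knapweed_ids = "NOPE"),
               "no knapweed rows")
  kc <- knapweed_contrast(long, knapweed_ids = c("P01", "P02", "P03"),
                          mode = "robust")
  expect_equal(nrow(kc$means), 4L)
  expect_equal(nrow(kc$pairwise), 6L)
  expect_true(all(kc$means$rate > 0))
  expect_true(all(kc$pairwise$p_adj >= 0 & kc$pairwise$p_adj <= 1))
  expect_equal(kc$interaction_lrt$df, 1L)
})

test_that("planted knapweed excess is detected for honey bees only", {
  # honey bees visit the knapweed species ~13x more; wild pollinators are
  # indifferent (flat abundance response so no systematic wild contrast)
  b0 <- matrix(0, 2, 2, dimnames = list(c("honey_bee", "wild"),
                                        c("native", "introduced")))
  cfg <- default_generator_config(n_weeks = 15L, plants_per_siteweek = 8L,
                                  abundance_sdlog = 0.3,
                                  pref_weight_sdlog = 0.1, beta = b0)
  detect <- vapply(1:8, function(s) {
    d <- generate_dataset(cfg, seed = s)
    w <- d$truth$weights
    w["honey_bee", "P05"] <- w["honey_bee", "P05"] * 13
    com <- list(plants = d$plants, truth = modifyList(d$truth,
                                                      list(weights = w)))
    com$truth$abundance <- d$truth$abundance
    obs <- filter_visits(generate_observations(com, cfg, seed = s + 100))
    long <- build_rate_table(obs, d$truth_abundance, d$plants)
    kc <- knapweed_contrast(long, knapweed_ids = "P05", mode = "robust")
    hb <- grepl("honey_bee/knapweed - honey_bee/coflowering",
                kc$pairwise$label) |
      grepl("honey_bee/coflowering - honey_bee/knapweed",
            kc$pairwise$label)
    wd <- grepl("wild/knapweed - wild/coflowering", kc$pairwise$label) |
      grepl("wild/coflowering - wild/knapweed", kc$pairwise$label)
    c(kc$pairwise$p_adj[hb] < 0.05, kc$pairwise$p_adj[wd] > 0.05)
  }, logical(2))
  expect_gte(mean(detect[1, ]), 0.75)  # honey-bee contrast fires
  expect_gte(mean(detect[2, ]), 0.75)  # wild contrast stays null
})
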