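#' @name acceptance
#' @title Desk-scale validation batteries
#' @description
#' Self-contained checks that exercise the pipeline's statistical engine at
#' desk scale: the table-sampler distributional oracle, marginal
#' conservation, null calibration and planted-preference recovery of the
#' preference index, rate-model exponent recovery, and exact closed forms.
#' Each returns the measured quantities; the test suite asserts thresholds
#' on them and `scripts/acceptance.R` reports them.
NULL

# all ordered compositions of n into exactly k positive parts
.compositions <- function(n, k) {
  if (k > n) return(list())
  if (k == 1L) return(list(n))
  out <- list()
  for (first in seq_len(n - k + 1L)) {
    for (rest in .compositions(n - first, k - 1L)) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}

#' Sampler oracle: empirical table frequencies vs. enumerated pmf
#'
#' For every ordered pair of positive marginal vectors (up to 3 parts each)
#' with grand total at most `max_total`, draws `n_draws` tables and compares
#' the empirical distribution over tables with the enumerated multiple-
#' hypergeometric pmf by total-variation distance.
#'
#' @param n_draws draws per marginal pair (default 2e5).
#' @param max_total largest grand total (default 6).
#' @param seed RNG seed.
#' @return List: `n_pairs`, `max_tvd`, `mean_tvd`, and `tvd` (per pair).
#' @export
ac_sampler_oracle <- function(n_draws = 2e5, max_total = 6, seed = 1L) {
  set.seed(seed)
  tvds <- numeric()
  for (N in seq_len(max_total)) {
    margins <- unlist(lapply(1:3, function(k) .compositions(N, k)),
                      recursive = FALSE)
    for (rs in margins) for (cs in margins) {
      tabs <- enumerate_tables(rs, cs)
      pmf <- vapply(tabs, table_probability, numeric(1))
      base <- (N + 1)
      key_of <- function(m) sum(m * base^(seq_along(m) - 1))
      keys <- vapply(tabs, key_of, numeric(1))
      draws <- patefield_cpp(as.integer(rs), as.integer(cs),
                             as.integer(n_draws))
      m <- matrix(draws, length(rs) * length(cs), n_draws)
      dkeys <- as.numeric(crossprod(base^(seq_len(nrow(m)) - 1), m))
      emp <- tabulate(match(dkeys, keys), nbins = length(keys)) / n_draws
      tvds <- c(tvds, 0.5 * sum(abs(emp - pmf)))
    }
  }
  list(n_pairs = length(tvds), max_tvd = max(tvds), mean_tvd = mean(tvds),
       tvd = tvds)
}

#' Conservation battery for the decimal sampler and preference zero-sums
#'
#' Draws `n` decimal null replicates at granularity `g` for a realistic
#' continuous-marginal matrix and measures the worst marginal deviation;
#' also computes within-site-week preference sums for a generated dataset.
#'
#' @param n replicates (default 1e4).
#' @param g granularity (default 1e4).
#' @param seed RNG seed.
#' @return List: `max_marginal_dev` (worst |replicate margin - target|),
#'   `tolerance` (1/g), `max_pref_sum` (worst within-site-week preference
#'   sum), `pref_sum_bound` (dim/g for the widest site-week).
#' @export
ac_conservation <- function(n = 1e4, g = 1e4, seed = 1L) {
  set.seed(derive_seed(seed, "conservation"))
  rows <- c(0.137, 0.261)
  cols <- c(0.05, 0.121, 0.019, 0.208)
  reps <- sample_decimal_table(rows, cols, g = g, n = n)
  dev_r <- apply(reps, 3, function(m) max(abs(rowSums(m) - rows)))
  dev_c <- apply(reps, 3, function(m) max(abs(colSums(m) - cols)))
  # preference zero-sums on a generated community
  d <- generate_dataset(default_generator_config(n_weeks = 6L),
                        seed = derive_seed(seed, "cons-data"))
  ex <- exclude_status_both(d$plants, observations = d$observations)
  obs <- filter_visits(ex$observations)
  prefs <- site_week_preferences(obs, d$truth_abundance,
                                 n_replicates = 200L, g = g,
                                 master_seed = seed)
  two_d <- prefs[!prefs$one_dimensional, , drop = FALSE]
  sums <- tapply(two_d$preference,
                 interaction(two_d$site, two_d$week, drop = TRUE), sum)
  dims <- tapply(seq_len(nrow(two_d)),
                 interaction(two_d$site, two_d$week, drop = TRUE), length)
  list(max_marginal_dev = max(dev_r, dev_c), tolerance = 1 / g,
       max_pref_sum = max(abs(sums)), pref_sum_bound = max(dims) / g)
}

#' Null calibration of species mean preferences
#'
#' Generates a 100-site-week community with no planted preference (uniform
#' weights, flat abundance response) and computes, per species and
#' pollinator type, the mean preference and its Monte-Carlo standard error
#' over site-weeks.
#'
#' @param n_null null replicates per site-week (default 1000).
#' @param seed RNG seed.
#' @return List: `grand_z` (grand mean / its SE), `coverage3se` (fraction
#'   of species x type means within 3 MC SE of 0), `max_abs_z`, `n_combos`.
#' @export
ac_null_calibration <- function(n_null = 1000L, seed = 1L) {
  b0 <- matrix(0, 2, 2, dimnames = list(c("honey_bee", "wild"),
                                        c("native", "introduced")))
  cfg <- default_generator_config(n_sites = 4L, n_weeks = 25L,
                                  pref_weight_sdlog = 0, beta = b0)
  d <- generate_dataset(cfg, seed = derive_seed(seed, "nullcal"))
  ex <- exclude_status_both(d$plants, observations = d$observations)
  obs <- filter_visits(ex$observations)
  prefs <- site_week_preferences(obs, d$truth_abundance,
                                 n_replicates = n_null,
                                 master_seed = derive_seed(seed, "nullcal2"))
  agg <- aggregate_species_preference(prefs)
  se <- aggregate(preference ~ plant_id + pollinator_type, prefs,
                  FUN = function(x) sd(x) / sqrt(length(x)))
  m <- merge(agg, se, by = c("plant_id", "pollinator_type"))
  z <- abs(m$mean_preference) / m$preference
  z <- z[is.finite(z)]
  grand_se <- sd(prefs$preference) / sqrt(nrow(prefs))
  list(grand_z = mean(prefs$preference) / grand_se,
       coverage3se = mean(z <= 3), max_abs_z = max(z),
       n_combos = length(z))
}

#' Planted-preference recovery across seeds
#'
#' A uniform community (equal abundances and weights, flat abundance
#' response) with one species' wild visitation mass doubled; counts how
#' often that species is top-ranked by mean wild preference. The design
#' (6 sites x 25 weeks, 8 plants per site visit) gives each of the 54
#' species about 22 site-weeks, the replication a recovery experiment
#' needs for rank identification against 53 competitors.
#'
#' @param n_seeds number of generator seeds (default 100).
#' @param n_null null replicates (default 1000).
#' @param seed base RNG seed.
#' @return List: `recovery_rate`, `n_seeds`.
#' @export
ac_recovery <- function(n_seeds = 100L, n_null = 1000L, seed = 1L) {
  b0 <- matrix(0, 2, 2, dimnames = list(c("honey_bee", "wild"),
                                        c("native", "introduced")))
  cfg <- default_generator_config(
    n_sites = 6L, n_weeks = 25L, plants_per_siteweek = 8L,
    abundance_sdlog = 0, pref_weight_sdlog = 0, beta = b0,
    boost_species = "P07", boost_factor = 2)
  hits <- vapply(seq_len(n_seeds), function(i) {
    s <- derive_seed(seed, paste0("recovery", i))
    d <- generate_dataset(cfg, seed = s)
    ex <- exclude_status_both(d$plants, observations = d$observations)
    obs <- filter_visits(ex$observations)
    prefs <- site_week_preferences(obs, d$truth_abundance,
                                   n_replicates = n_null, master_seed = s)
    agg <- aggregate_species_preference(prefs)
    w <- agg[agg$pollinator_type == "wild", ]
    w$plant_id[which.max(w$mean_preference)] == "P07"
  }, logical(1))
  list(recovery_rate = mean(hits), n_seeds = n_seeds)
}

#' Rate-model exponent recovery and null calibration across seeds
#'
#' At the default paper-scale design (~432 period-rows), fits the NB offset
#' model (robust mode, log-abundance covariate so the slope estimates the
#' planted exponent) across seeds and measures: sign recovery of the
#' planted exponents (honey bee 0 within noise; wild negative), detection
#' of the wild introduced-vs-native slope difference, and — under a fully
#' null generator — the rejection rate of the four slope tests.
#'
#' @param n_seeds seeds per arm (default 100).
#' @param seed base RNG seed.
#' @return List: `detection_rate`, `sign_recovery_rate`,
#'   `null_rejection_rate`, `n_seeds`.
#' @export
ac_rate_recovery <- function(n_seeds = 100L, seed = 1L) {
  run_one <- function(s, beta = NULL) {
    args <- list()
    if (!is.null(beta)) args$beta <- beta
    d <- generate_dataset(do.call(default_generator_config, args), seed = s)
    ex <- exclude_status_both(d$plants, observations = d$observations)
    obs <- filter_visits(ex$observations)
    long <- build_rate_table(obs, d$truth_abundance, ex$plants)
    fit <- fit_rate_model(long, mode = "robust",
                          abundance_transform = "log")
    sl <- abundance_slopes(fit)
    wild <- sl$slopes$pollinator_type == "wild"
    c(detect = sl$slope_differences$p_adj[
        sl$slope_differences$pollinator_type == "wild"] < 0.05,
      sign = all(sl$slopes$estimate[wild] < 0),
      rej = sum(sl$slopes$p_adj < 0.05))
  }
  alt <- t(vapply(seq_len(n_seeds), function(i) {
    run_one(derive_seed(seed, paste0("rate-alt", i)))
  }, numeric(3)))
  b0 <- matrix(0, 2, 2, dimnames = list(c("honey_bee", "wild"),
                                        c("native", "introduced")))
  null <- t(vapply(seq_len(n_seeds), function(i) {
    run_one(derive_seed(seed, paste0("rate-null", i)), beta = b0)
  }, numeric(3)))
  list(detection_rate = mean(alt[, "detect"]),
       sign_recovery_rate = mean(alt[, "sign"]),
       null_rejection_rate = sum(null[, "rej"]) / (4 * n_seeds),
       n_seeds = n_seeds)
}

#' Exact closed forms: Shannon cases and NB offset equivariance
#'
#' @param seed RNG seed for the equivariance dataset.
#' @return List: `shannon_uniform_err`, `shannon_single_err` (absolute
#'   errors of the closed-form cases), `offset_equivariance_err` (max
#'   absolute coefficient drift after doubling all exposures, intercept
#'   compared after adding back log 2).
#' @export
ac_closed_forms <- function(seed = 1L) {
  sh_u <- abs(shannon(rep(1, 4)) - log(4))
  sh_s <- abs(shannon(c(10)) - 0)
  d <- generate_dataset(default_generator_config(n_weeks = 6L),
                        seed = derive_seed(seed, "offset"))
  ex <- exclude_status_both(d$plants, observations = d$observations)
  obs <- filter_visits(ex$observations)
  long <- build_rate_table(obs, d$truth_abundance, ex$plants)
  f1 <- fit_rate_model(long, mode = "robust", abundance_transform = "log")
  long2 <- long
  long2$minutes <- long2$minutes * 2
  f2 <- fit_rate_model(long2, mode = "robust", abundance_transform = "log")
  delta <- f2$coefficients - f1$coefficients
  delta["(Intercept)"] <- delta["(Intercept)"] + log(2)
  list(shannon_uniform_err = sh_u, shannon_single_err = sh_s,
       offset_equivariance_err = max(abs(delta)))
}
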