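#' Default synthetic-community generator configuration
#'
#' The defaults mirror the scale of the motivating field study: 3 sites
#' surveyed for 18 weeks, 54 plant species of which 30/54 are introduced,
#' about 4 observation periods per site-week (~216 total, two pollinator
#' rows each), 15-minute periods watching at least 10 floral units,
#' log-normal floral abundances, overdispersed NB2 visit counts, planted
#' abundance exponents (honey bee 0, wild-native -0.15, wild-introduced
#' -0.35 on the log-abundance scale), Dirichlet-multinomial netting
#' communities, and 300-grain Beta-binomial pollen counts from 22 apiaries.
#'
#' @param ... overrides for any default field.
#' @return Named list of generator parameters.
#' @export
default_generator_config <- function(...) {
  cfg <- list(
    n_sites = 3L,
    n_weeks = 18L,
    n_plants = 54L,
    prop_introduced = 30 / 54,
    abundance_meanlog = 3,
    abundance_sdlog = 1.5,
    units_per_stem_meanlog = 1.2,
    units_per_stem_sdlog = 0.6,
    plants_per_siteweek = 4L,
    floral_units_min = 10L,
    floral_units_extra_mean = 20,
    minutes = 15,
    base_rate = c(honey_bee = 0.02, wild = 0.05),
    # abundance exponents beta[type, status] on the log-abundance scale
    beta = matrix(c(0, 0, -0.15, -0.35), nrow = 2, byrow = TRUE,
                  dimnames = list(c("honey_bee", "wild"),
                                  c("native", "introduced"))),
    pref_weight_sdlog = 0.2,
    boost_species = NULL,   # plant id whose weights are multiplied...
    boost_factor = 1,       # ...by this factor (planted preference)
    boost_type = "wild",    # which pollinator type gets the boost
                            # ("wild", "honey_bee", or "both"); the paired
                            # fixed-margins null is invariant to a boost
                            # shared by both types, so a planted preference
                            # must be type-differential to be recoverable
    theta = 5,
    netting_per_siteweek = 6L,
    netting_specimen_mean = 6,
    n_taxa = 40L,
    dirichlet_conc = 0.3,
    n_apiaries = 22L,
    pollen_rounds = 2L,
    pollen_beta = list(bee_bread = c(0.3, 5), nectar = c(0.5, 25)),
    pollen_grains = 300L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) pn_stop("unknown generator field(s): ",
                               paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$theta > 0, cfg$abundance_sdlog >= 0,
            cfg$prop_introduced >= 0, cfg$prop_introduced <= 1)
  cfg
}

.rdirichlet <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[1] <- 1
  x / sum(x)
}

#' Generate a synthetic plant community with known truth
#'
#' Statuses are Bernoulli(prop_introduced); per site x species abundances
#' are log-normal; species preference weights per pollinator type are
#' log-normal (optionally boosted for one planted species). Also emits
#' stem-count and floral-units-per-stem tables consistent with the drawn
#' abundances so the quadrat pipeline can be exercised end to end.
#'
#' @param config list from [default_generator_config()].
#' @param seed integer seed.
#' @return List: `plants`, `abundance` (site x species truth abundances in
#'   [floral_abundance()] layout), `stems`, `floral_units`, `truth`.
#' @export
generate_community <- function(config = default_generator_config(),
                               seed = 1L) {
  set.seed(derive_seed(seed, "community"))
  P <- config$n_plants
  plant_ids <- sprintf("P%02d", seq_len(P))
  status <- ifelse(runif(P) < config$prop_introduced, "introduced", "native")
  plants <- data.frame(plant_id = plant_ids,
                       name = paste("Species", plant_ids),
                       native_status = status)
  sites <- sprintf("S%d", seq_len(config$n_sites))
  A <- matrix(rlnorm(config$n_sites * P, config$abundance_meanlog,
                     config$abundance_sdlog),
              nrow = config$n_sites,
              dimnames = list(sites, plant_ids))
  u <- rlnorm(P, config$units_per_stem_meanlog, config$units_per_stem_sdlog)
  names(u) <- plant_ids
  # preference weights per species x pollinator type
  w <- matrix(rlnorm(2 * P, 0, config$pref_weight_sdlog), nrow = 2,
              dimnames = list(c("honey_bee", "wild"), plant_ids))
  if (!is.null(config$boost_species)) {
    rows <- if (config$boost_type == "both") c("honey_bee", "wild")
            else config$boost_type
    w[rows, config$boost_species] <- w[rows, config$boost_species] *
      config$boost_factor
  }
  abundance <- expand.grid(site = sites, plant_id = plant_ids,
                           stringsAsFactors = FALSE)
  abundance$mean_stems <- A[cbind(abundance$site, abundance$plant_id)] /
    u[abundance$plant_id]
  abundance$mean_floral_units_per_stem <- u[abundance$plant_id]
  abundance$abundance <- A[cbind(abundance$site, abundance$plant_id)]
  abundance$n_weeks_observed <- config$n_weeks
  abundance$n_stem_measurements <- 7L
  # quadrat stem counts: 3 zones per site-week, Poisson around mean_stems
  grid <- expand.grid(site = sites, week = seq_len(config$n_weeks),
                      zone = 1:3, plant_id = plant_ids,
                      stringsAsFactors = FALSE)
  lam <- abundance$mean_stems[match(paste(grid$site, grid$plant_id),
                                    paste(abundance$site,
                                          abundance$plant_id))]
  grid$stems <- rpois(nrow(grid), lam)
  stems <- grid[order(grid$site, grid$week, grid$zone, grid$plant_id), ]
  floral_units <- do.call(rbind, lapply(plant_ids, function(p) {
    data.frame(site = sample(sites, 7, replace = TRUE),
               date = sprintf("2017-%02d-01", sample(5:9, 7, TRUE)),
               plant_id = p, stem_id = seq_len(7),
               floral_units_on_stem = rpois(7, u[p]))
  }))
  truth <- list(abundance = A, units_per_stem = u, statuses =
                  setNames(status, plant_ids), weights = w,
                beta = config$beta, theta = config$theta,
                base_rate = config$base_rate)
  list(plants = plants, abundance = abundance, stems = stems,
       floral_units = floral_units, truth = truth)
}

#' Generate timed observation periods with NB2 visit counts
#'
#' For each site-week a random subset of plants is watched; honey-bee and
#' wild counts are drawn NB2 with mean
#' `exposure * base_rate[type] * w[species, type] * abundance^beta[type, status]`.
#' Wild visits are split across the fly / other-bee-wasp / butterfly-moth
#' recording groups, and nuisance ant, true-bug, and outside-flower counts
#' are added so the load-time filters have work to do.
#'
#' @param community result of [generate_community()].
#' @param config generator config.
#' @param seed integer seed.
#' @return Observations data frame in the raw CSV schema.
#' @export
generate_observations <- function(community,
                                  config = default_generator_config(),
                                  seed = 1L) {
  set.seed(derive_seed(seed, "observations"))
  if (config$minutes <= 0 || config$floral_units_min < 1) {
    pn_stop("exposure must be positive: minutes > 0, floral_units >= 1")
  }
  truth <- community$truth
  sites <- rownames(truth$abundance)
  plant_ids <- colnames(truth$abundance)
  rows <- list()
  oid <- 0L
  for (s in sites) for (wk in seq_len(config$n_weeks)) {
    k <- min(config$plants_per_siteweek, length(plant_ids))
    watched <- sample(plant_ids, k)
    for (p in watched) {
      oid <- oid + 1L
      fu <- config$floral_units_min +
        rpois(1, config$floral_units_extra_mean)
      expo <- fu * config$minutes
      ab <- truth$abundance[s, p]
      st <- truth$statuses[p]
      mu <- vapply(c("honey_bee", "wild"), function(tp) {
        m <- expo * truth$base_rate[tp] * truth$weights[tp, p] *
          ab^truth$beta[tp, st]
        if (!is.finite(m) || m > 1e7) pn_stop("visit mean overflow")
        m
      }, numeric(1))
      hb <- rnbinom(1, size = truth$theta, mu = mu["honey_bee"])
      wild <- rnbinom(1, size = truth$theta, mu = mu["wild"])
      split3 <- as.integer(rmultinom(1, wild, c(0.5, 0.35, 0.15)))
      rows[[oid]] <- data.frame(
        obs_id = sprintf("OBS%04d", oid), site = s, week = wk,
        zone = sample(1:9, 1), plant_id = p, floral_units = fu,
        minutes = config$minutes,
        visits_honey_bee = hb,
        visits_other_bee_wasp = split3[1],
        visits_fly = split3[2],
        visits_butterfly_moth = split3[3],
        visits_ant = rpois(1, 0.5),
        visits_true_bug = rpois(1, 0.2),
        outside_honey_bee = rpois(1, 0.1),
        outside_other_bee_wasp = rpois(1, 0.2),
        outside_fly = rpois(1, 0.3),
        outside_butterfly_moth = 0L,
        outside_ant = rpois(1, 0.2),
        outside_true_bug = 0L)
    }
  }
  obs <- do.call(rbind, rows)
  rownames(obs) <- NULL
  obs
}

#' Generate netting periods with Dirichlet-multinomial bee communities
#'
#' Per period the specimen total is Poisson and taxa are drawn from a
#' Dirichlet-multinomial over the taxon pool, giving realistic overdispersed
#' uneven communities whose expected Shannon diversity follows from the
#' concentration parameter.
#'
#' @inheritParams generate_observations
#' @return Netting data frame in the raw CSV schema (specimens as
#'   ";"-separated labels).
#' @export
generate_netting <- function(community, config = default_generator_config(),
                             seed = 1L) {
  set.seed(derive_seed(seed, "netting"))
  sites <- rownames(community$truth$abundance)
  plant_ids <- colnames(community$truth$abundance)
  taxa <- sprintf("taxon_%02d", seq_len(config$n_taxa))
  rows <- list()
  nid <- 0L
  for (s in sites) for (wk in seq_len(config$n_weeks)) {
    for (r in seq_len(config$netting_per_siteweek)) {
      nid <- nid + 1L
      n <- rpois(1, config$netting_specimen_mean)
      probs <- .rdirichlet(rep(config$dirichlet_conc, config$n_taxa))
      specimens <- if (n > 0) {
        paste(sample(taxa, n, replace = TRUE, prob = probs), collapse = ";")
      } else ""
      rows[[nid]] <- data.frame(
        netting_id = sprintf("NET%04d", nid), site = s, week = wk,
        zone = sample(1:9, 1), plant_id = sample(plant_ids, 1),
        minutes = 15, specimens = specimens)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate apiary pollen counts
#'
#' Per apiary and matrix a knapweed share is drawn from the configured Beta
#' distribution, and each sampling round counts
#' `Binomial(pollen_grains, share)` knapweed grains out of the fixed total.
#'
#' @param config generator config.
#' @param seed integer seed.
#' @return Pollen data frame in the raw CSV schema.
#' @export
generate_pollen <- function(config = default_generator_config(), seed = 1L) {
  set.seed(derive_seed(seed, "pollen"))
  rows <- list()
  i <- 0L
  for (ap in sprintf("A%02d", seq_len(config$n_apiaries))) {
    for (mx in names(config$pollen_beta)) {
      ab <- config$pollen_beta[[mx]]
      share <- if (ab[1] == 0) 0 else stats::rbeta(1, ab[1], ab[2])
      for (rd in seq_len(config$pollen_rounds)) {
        i <- i + 1L
        rows[[i]] <- data.frame(
          apiary_id = ap, round = rd, matrix = mx,
          knapweed_grains = rbinom(1, config$pollen_grains, share),
          total_grains = config$pollen_grains)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a full synthetic dataset with ground truth
#'
#' Runs all generators under named substreams of one master seed and
#' validates the bundle through the same path as files read from disk.
#'
#' @param config generator config.
#' @param seed master seed.
#' @return `pollinet_tables` bundle with an extra `truth` element.
#' @export
generate_dataset <- function(config = default_generator_config(),
                             seed = 1L) {
  com <- generate_community(config, seed)
  obs <- generate_observations(com, config, seed)
  net <- generate_netting(com, config, seed)
  pol <- generate_pollen(config, seed)
  bundle <- suppressWarnings(validate_tables(list(
    plants = com$plants, observations = obs, stems = com$stems,
    floral_units = com$floral_units, netting = net, pollen = pol)))
  bundle$truth <- com$truth
  bundle$truth_abundance <- com$abundance
  bundle
}
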