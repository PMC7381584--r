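#' Proportional floral abundance of the plants observed in a site-week
#'
#' @param abundances named non-negative vector (names = plant ids) of floral
#'   abundances for the plant set observed that site-week.
#' @return Named shares summing to 1 over the observed plant set.
#' @export
proportional_abundance <- function(abundances) {
  stopifnot(all(abundances >= 0))
  total <- sum(abundances)
  if (total <= 0) pn_stop("all abundances are zero; shares undefined")
  abundances / total
}

#' Build the pollinator-type x plant visitation matrix for one site-week
#'
#' Entries are visitation rates scaled by the proportional floral abundance
#' of each plant observed that site-week. The default (`multiply`) weights
#' each rate by the plant's share of the floral market; `divide` instead
#' expresses rate per unit of share; `none` leaves raw rates. When every
#' honey-bee rate is zero the honey-bee row is dropped and the matrix is
#' flagged one-dimensional (the null model then randomizes the wild row
#' only, and no honey-bee preference is computed for that site-week).
#'
#' @param rates numeric matrix, rows = pollinator types (`honey_bee`,
#'   `wild`), columns = plant ids observed that site-week.
#' @param shares named share vector from [proportional_abundance()], one
#'   entry per column of `rates`.
#' @param scaling_mode `"multiply"` (default), `"divide"`, or `"none"`.
#' @return An object of class `site_week_matrix`: list with `entries`,
#'   `row_sums`, `col_sums`, `scaling_mode`, `one_dimensional`, `raw_rates`.
#' @export
build_site_week_matrix <- function(rates,
                                   shares,
                                   scaling_mode = c("multiply", "divide",
                                                    "none")) {
  scaling_mode <- match.arg(scaling_mode)
  stopifnot(is.matrix(rates), !is.null(colnames(rates)),
            !is.null(rownames(rates)), all(rates >= 0))
  shares <- shares[colnames(rates)]
  stopifnot(!anyNA(shares))
  raw <- rates
  ent <- switch(scaling_mode,
    multiply = sweep(rates, 2L, shares, `*`),
    divide = {
      drop_cols <- shares == 0
      if (any(drop_cols)) {
        pn_warn("divide scaling: dropping ", sum(drop_cols),
                " plant(s) with zero abundance share")
        rates <- rates[, !drop_cols, drop = FALSE]
        raw <- raw[, !drop_cols, drop = FALSE]
        shares <- shares[!drop_cols]
      }
      sweep(rates, 2L, shares, `/`)
    },
    none = rates
  )
  one_dim <- FALSE
  if ("honey_bee" %in% rownames(ent) && sum(ent["honey_bee", ]) == 0) {
    ent <- ent[setdiff(rownames(ent), "honey_bee"), , drop = FALSE]
    raw <- raw[rownames(ent), , drop = FALSE]
    one_dim <- TRUE
  }
  if (nrow(ent) == 1L) one_dim <- TRUE
  structure(list(entries = ent,
                 row_sums = rowSums(ent),
                 col_sums = colSums(ent),
                 scaling_mode = scaling_mode,
                 one_dimensional = one_dim,
                 raw_rates = raw),
            class = "site_week_matrix")
}

#' Sample integer contingency tables with fixed marginal totals
#'
#' Sequential conditional (Patefield-style) sampling from the multiple
#' hypergeometric distribution: the conditional law of a table of
#' independent cells given both margins. Implemented in compiled code; uses
#' R's RNG, so results are reproducible under [set.seed()].
#'
#' @param row_sums,col_sums non-negative integer marginal totals with equal
#'   sums.
#' @param n number of replicate tables.
#' @return For `n = 1` an integer matrix; otherwise an integer array of
#'   dimension `c(length(row_sums), length(col_sums), n)`.
#' @export
sample_integer_table <- function(row_sums, col_sums, n = 1L) {
  row_sums <- as.integer(round(row_sums))
  col_sums <- as.integer(round(col_sums))
  if (sum(row_sums) != sum(col_sums)) {
    pn_stop("row and column totals must have equal sums")
  }
  out <- patefield_cpp(row_sums, col_sums, as.integer(n))
  if (n == 1L) {
    matrix(out, length(row_sums), length(col_sums))
  } else {
    out
  }
}

#' Sample null tables for continuous (decimal) marginal totals
#'
#' The continuous marginals are multiplied by the granularity `g`, rounded
#' to integers by largest-remainder apportionment so that both grand totals
#' match exactly, sampled with the integer core, and divided by `g`. Row and
#' column sums of every replicate match the continuous targets to within
#' `1/g` per margin entry. If a nonzero marginal would round to zero, `g`
#' escalates tenfold (up to `g_max`) before failing.
#'
#' @param row_sums,col_sums non-negative real marginal totals;
#'   `|sum(rows) - sum(cols)|` must be below `tol * max(1, grand total)`.
#' @param g granularity (default `1e4`), `>= 100`.
#' @param n replicates.
#' @param tol relative tolerance on the grand-total match.
#' @param g_max escalation cap.
#' @return Matrix (`n = 1`) or r-by-c-by-n array of non-negative reals.
#' @export
sample_decimal_table <- function(row_sums, col_sums, g = 1e4, n = 1L,
                                 tol = 1e-6, g_max = 1e8) {
  stopifnot(g >= 100, all(row_sums >= 0), all(col_sums >= 0))
  gt <- sum(row_sums)
  if (abs(gt - sum(col_sums)) > tol * max(1, gt)) {
    pn_stop("row and column totals disagree beyond tolerance")
  }
  repeat {
    total_int <- round(gt * g)
    ri <- largest_remainder_round(row_sums * g, total_int)
    ci <- largest_remainder_round(col_sums * g, total_int)
    bad <- (ri == 0 & row_sums > 0) | FALSE
    badc <- (ci == 0 & col_sums > 0)
    if (!any(bad) && !any(badc)) break
    if (g * 10 > g_max) {
      pn_stop("marginal rounds to zero at maximum granularity ", g_max)
    }
    g <- g * 10
  }
  out <- patefield_cpp(ri, ci, as.integer(n)) / g
  if (n == 1L) {
    matrix(out, length(row_sums), length(col_sums))
  } else {
    array(out, c(length(row_sums), length(col_sums), n))
  }
}

#' One-dimensional null: redistribute a single row total over cells
#'
#' With a single pollinator row the column constraints must be dropped
#' (otherwise the table is fully determined); the discretized total is
#' allocated over cells by an equal-probability multinomial and rescaled.
#'
#' @param total non-negative row total.
#' @param n_cells number of plants.
#' @param g granularity.
#' @param n replicates.
#' @return Matrix `n_cells x n` of non-negative reals, each column summing
#'   to `total` within `1/g`.
#' @export
sample_one_dim <- function(total, n_cells, g = 1e4, n = 1L) {
  stopifnot(total >= 0)
  if (n_cells < 1) pn_stop("n_cells must be >= 1")
  ti <- round(total * g)
  if (ti == 0) return(matrix(0, n_cells, n))
  rmultinom(n, ti, rep(1 / n_cells, n_cells)) / g
}

#' Null ensemble for a site-week matrix
#'
#' Draws `n_replicates` null matrices conserving the observed marginal
#' totals (full Patefield path), or redistributing the single row total
#' (one-dimensional path), and summarises each cell's null distribution.
#'
#' @param swm a [build_site_week_matrix()] object.
#' @param n_replicates number of null matrices (default 1000).
#' @param g discretization granularity.
#' @param seed optional integer seed applied before sampling.
#' @return List with `mean`, `sd` (matrices like `swm$entries`),
#'   `n_replicates`, `g`, `seed`, and `replicates` (3-d array).
#' @export
null_ensemble <- function(swm, n_replicates = 1000L, g = 1e4, seed = NULL) {
  stopifnot(inherits(swm, "site_week_matrix"))
  if (!is.null(seed)) set.seed(seed)
  ent <- swm$entries
  r <- nrow(ent); s <- ncol(ent)
  if (swm$one_dimensional) {
    reps <- array(0, c(r, s, n_replicates))
    wild_rows <- seq_len(r)
    for (i in wild_rows) {
      reps[i, , ] <- sample_one_dim(sum(ent[i, ]), s, g = g, n = n_replicates)
    }
  } else {
    reps <- sample_decimal_table(rowSums(ent), colSums(ent), g = g,
                                 n = n_replicates)
    reps <- array(reps, c(r, s, n_replicates))
  }
  m <- apply(reps, c(1, 2), mean)
  sdev <- apply(reps, c(1, 2), sd)
  dimnames(m) <- dimnames(sdev) <- dimnames(ent)
  list(mean = m, sd = sdev, n_replicates = n_replicates, g = g, seed = seed,
       replicates = reps)
}

#' Preference indices for one site-week
#'
#' Preference = observed scaled visitation rate minus the mean rate expected
#' under the marginal-total-conserving null model. Positive values indicate
#' preference, negative values avoidance. For one-dimensional site-weeks
#' (honey bees absent) only wild preferences are returned.
#'
#' @inheritParams null_ensemble
#' @param site,week identifiers copied into the result.
#' @return Data frame: site, week, plant_id, pollinator_type, observed
#'   (scaled), raw_rate, expected (null mean), preference, mc_se.
#' @export
preference_indices <- function(swm, n_replicates = 1000L, g = 1e4,
                               seed = NULL, site = NA, week = NA) {
  ens <- null_ensemble(swm, n_replicates = n_replicates, g = g, seed = seed)
  ent <- swm$entries
  grid <- expand.grid(pollinator_type = rownames(ent),
                      plant_id = colnames(ent),
                      stringsAsFactors = FALSE)
  data.frame(
    site = site, week = week,
    plant_id = grid$plant_id,
    pollinator_type = grid$pollinator_type,
    observed = ent[cbind(grid$pollinator_type, grid$plant_id)],
    raw_rate = swm$raw_rates[cbind(grid$pollinator_type, grid$plant_id)],
    expected = ens$mean[cbind(grid$pollinator_type, grid$plant_id)],
    preference = ent[cbind(grid$pollinator_type, grid$plant_id)] -
      ens$mean[cbind(grid$pollinator_type, grid$plant_id)],
    mc_se = ens$sd[cbind(grid$pollinator_type, grid$plant_id)] /
      sqrt(n_replicates),
    one_dimensional = swm$one_dimensional,
    scaling_mode = swm$scaling_mode,
    row.names = NULL
  )
}

#' Site-week preference indices for a whole visitation data set
#'
#' Builds one scaled matrix per site-week from per-period visitation rates
#' and site-level abundances, then computes null-model preferences. Rates
#' for a plant observed more than once in a site-week are averaged first.
#' Each site-week gets its own RNG substream derived from the master seed,
#' so evaluation order does not change results.
#'
#' @param obs filtered observations (see [filter_visits()]) with columns
#'   site, week, plant_id, floral_units, minutes, honey_bee_visits,
#'   wild_visits.
#' @param abundance table from [floral_abundance()].
#' @param scaling_mode passed to [build_site_week_matrix()].
#' @param n_replicates,g null-model controls.
#' @param master_seed integer master seed.
#' @return Data frame of per site-week per plant per pollinator-type
#'   preferences (see [preference_indices()]).
#' @export
site_week_preferences <- function(obs, abundance,
                                  scaling_mode = c("multiply", "divide",
                                                   "none"),
                                  n_replicates = 1000L, g = 1e4,
                                  master_seed = 1L) {
  scaling_mode <- match.arg(scaling_mode)
  obs$hb_rate <- visitation_rate(obs$honey_bee_visits, obs$floral_units,
                                 obs$minutes)
  obs$wild_rate <- visitation_rate(obs$wild_visits, obs$floral_units,
                                   obs$minutes)
  keys <- unique(obs[, c("site", "week")])
  out <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    s <- keys$site[k]; w <- keys$week[k]
    sub <- obs[obs$site == s & obs$week == w, , drop = FALSE]
    hb <- tapply(sub$hb_rate, sub$plant_id, mean)
    wd <- tapply(sub$wild_rate, sub$plant_id, mean)
    plants <- names(hb)
    rates <- rbind(honey_bee = as.numeric(hb), wild = as.numeric(wd))
    colnames(rates) <- plants
    ab <- abundance$abundance[abundance$site == s][
      match(plants, abundance$plant_id[abundance$site == s])]
    names(ab) <- plants
    if (anyNA(ab)) {
      pn_warn("site ", s, " week ", w, ": no abundance for ",
              paste(plants[is.na(ab)], collapse = ", "), "; plants dropped")
      keep <- !is.na(ab)
      if (!any(keep)) next
      rates <- rates[, keep, drop = FALSE]
      ab <- ab[keep]
    }
    if (sum(ab) <= 0) next
    shares <- proportional_abundance(ab)
    swm <- build_site_week_matrix(rates, shares, scaling_mode)
    out[[k]] <- preference_indices(
      swm, n_replicates = n_replicates, g = g,
      seed = derive_seed(master_seed, paste("null", s, w, sep = "/")),
      site = s, week = w)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average preference per plant species and pollinator type
#'
#' Unweighted mean over site-weeks (use `weight_by_n = TRUE` to weight by
#' site-week counts of observation, which here equal one per site-week), and
#' a descending preference ranking within each pollinator type.
#'
#' @param results data frame from [site_week_preferences()].
#' @param weight_by_n reserved toggle; the default (FALSE) matches the
#'   plain average.
#' @return Data frame: plant_id, pollinator_type, mean_preference,
#'   n_site_weeks, rank (1 = most preferred).
#' @export
aggregate_species_preference <- function(results, weight_by_n = FALSE) {
  agg <- aggregate(preference ~ plant_id + pollinator_type, data = results,
                   FUN = mean)
  names(agg)[names(agg) == "preference"] <- "mean_preference"
  n <- aggregate(preference ~ plant_id + pollinator_type, data = results,
                 FUN = length)
  agg$n_site_weeks <- n$preference
  agg <- agg[order(agg$pollinator_type, -agg$mean_preference), ]
  agg$rank <- ave(-agg$mean_preference, agg$pollinator_type,
                  FUN = function(x) rank(x, ties.method = "first"))
  rownames(agg) <- NULL
  agg
}

#' Linear mixed model for preference
#'
#' Models preference as native status x pollinator type with random
#' intercepts for the observation pairing (site-week-plant), site, week, and
#' plant species, and reports likelihood-ratio tests (ML refits) for the
#' interaction and, from the additive model, both main effects.
#'
#' @param results data frame from [site_week_preferences()].
#' @param plants plant table with plant_id, native_status.
#' @return List with `fit` (lmerMod), `lrt` (data frame: term, chisq, df,
#'   p), `group_means` (status x type means with SE).
#' @export
preference_model <- function(results, plants) {
  df <- merge(results, plants[, c("plant_id", "native_status")],
              by = "plant_id")
  df <- df[df$native_status %in% c("native", "introduced"), , drop = FALSE]
  for (v in c("native_status", "pollinator_type")) {
    df[[v]] <- factor(df[[v]])
    if (nlevels(df[[v]]) < 2) {
      pn_stop("factor '", v, "' has a single level; model is degenerate")
    }
  }
  df$pair_id <- interaction(df$site, df$week, df$plant_id, drop = TRUE)
  df$site <- factor(df$site); df$week <- factor(df$week)
  df$plant_id <- factor(df$plant_id)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  full <- lme4::lmer(preference ~ native_status * pollinator_type +
                       (1 | pair_id) + (1 | site) + (1 | week) +
                       (1 | plant_id),
                     data = df, REML = FALSE, control = ctrl)
  add <- update(full, . ~ . - native_status:pollinator_type)
  no_status <- update(add, . ~ . - native_status)
  no_type <- update(add, . ~ . - pollinator_type)
  lrt <- rbind(
    likelihood_ratio_test(full, add, label = "native_status:pollinator_type"),
    likelihood_ratio_test(add, no_status, label = "native_status"),
    likelihood_ratio_test(add, no_type, label = "pollinator_type")
  )
  gm <- aggregate(preference ~ native_status + pollinator_type, data = df,
                  FUN = function(x) c(mean = mean(x),
                                      se = sd(x) / sqrt(length(x))))
  gm <- do.call(data.frame, gm)
  names(gm)[3:4] <- c("mean", "se")
  list(fit = full, lrt = lrt, group_means = gm)
}
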