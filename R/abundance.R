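#' Mean weekly stem count for one species at one site
#'
#' Weekly value = mean stems per 100 m^2 over the quadrats surveyed that week
#' (a species missing from a surveyed quadrat counts as 0 for that quadrat).
#' The site-level estimate averages weekly values over the contiguous span
#' from the first to the last week the species was seen flowering there;
#' weeks inside the span with no quadrat survey contribute nothing.
#'
#' @param stems stems table (site, week, zone, plant_id, stems).
#' @param site,plant_id which series to summarise.
#' @param span_zeros `"skip"` (default) drops in-span weeks whose recorded
#'   weekly mean is exactly 0; `"include"` keeps them as true zeros.
#' @return Scalar stems per 100 m^2 per week, or `NA_real_` (signals the
#'   fallback path) when the species was never recorded flowering there.
#' @export
mean_weekly_stems <- function(stems, site, plant_id,
                              span_zeros = c("skip", "include")) {
  span_zeros <- match.arg(span_zeros)
  # quadrats surveyed that site-week (any species recorded => surveyed)
  surveyed <- unique(stems[stems$site == site, c("week", "zone")])
  sp <- stems[stems$site == site & stems$plant_id == plant_id, , drop = FALSE]
  if (nrow(sp) == 0L || all(sp$stems == 0)) return(NA_real_)
  weeks <- sort(unique(surveyed$week))
  weekly <- vapply(weeks, function(w) {
    zones <- surveyed$zone[surveyed$week == w]
    counts <- sp$stems[sp$week == w][match(zones, sp$zone[sp$week == w])]
    counts[is.na(counts)] <- 0
    mean(counts)
  }, numeric(1))
  pos <- which(weekly > 0)
  span <- weeks >= weeks[min(pos)] & weeks <= weeks[max(pos)]
  vals <- weekly[span]
  if (span_zeros == "skip") vals <- vals[vals > 0]
  mean(vals)
}

#' Mean floral units per stem for one species, pooled study-wide
#'
#' One value per species for the whole study area: the arithmetic mean over
#' all per-stem measurements, pooled across sites and both measurement
#' campaigns (they arrive in one table).
#'
#' @param floral_units floral-unit table (plant_id, floral_units_on_stem).
#' @param plant_id species code.
#' @return Scalar mean floral units per stem, or `NA_real_` when the species
#'   was never measured (signals the fallback path).
#' @export
mean_floral_units_per_stem <- function(floral_units, plant_id) {
  x <- floral_units$floral_units_on_stem[floral_units$plant_id == plant_id]
  if (length(x) == 0L) return(NA_real_)
  mean(x)
}

#' Site-specific floral abundance table
#'
#' Floral abundance (floral units per 100 m^2 per week) for every site x
#' species combination: mean weekly stem count at the site multiplied by the
#' study-wide mean floral units per stem of the species.
#'
#' When one component is missing the fallback ladder (config
#' `abundance.fallback = TRUE`) substitutes the species-level mean of the
#' same component across other sites, else the smallest positive value
#' observed study-wide; with fallback off, the species is dropped at that
#' site with a warning.
#'
#' @param stems stems table.
#' @param floral_units floral-unit table.
#' @param sites,plant_ids optional restriction; defaults to all observed.
#' @param fallback logical, see Details.
#' @param span_zeros passed to [mean_weekly_stems()].
#' @return Data frame with columns site, plant_id, mean_stems,
#'   mean_floral_units_per_stem, abundance, n_weeks_observed,
#'   n_stem_measurements.
#' @export
floral_abundance <- function(stems, floral_units,
                             sites = sort(unique(stems$site)),
                             plant_ids = sort(unique(stems$plant_id)),
                             fallback = TRUE,
                             span_zeros = c("skip", "include")) {
  span_zeros <- match.arg(span_zeros)
  units <- setNames(
    vapply(plant_ids, function(p) mean_floral_units_per_stem(floral_units, p),
           numeric(1)), plant_ids)
  min_pos_units <- suppressWarnings(min(units[units > 0], na.rm = TRUE))
  grid <- expand.grid(site = sites, plant_id = plant_ids,
                      stringsAsFactors = FALSE)
  grid$mean_stems <- mapply(function(s, p) {
    mean_weekly_stems(stems, s, p, span_zeros = span_zeros)
  }, grid$site, grid$plant_id)
  if (fallback) {
    for (p in plant_ids) {
      idx <- grid$plant_id == p
      if (any(is.na(grid$mean_stems[idx])) && any(!is.na(grid$mean_stems[idx]))) {
        grid$mean_stems[idx & is.na(grid$mean_stems)] <-
          mean(grid$mean_stems[idx], na.rm = TRUE)
      }
    }
    min_pos_stems <- suppressWarnings(min(grid$mean_stems[grid$mean_stems > 0],
                                          na.rm = TRUE))
    if (is.finite(min_pos_stems)) {
      grid$mean_stems[is.na(grid$mean_stems)] <- min_pos_stems
    }
    if (is.finite(min_pos_units)) units[is.na(units)] <- min_pos_units
  }
  grid$mean_floral_units_per_stem <- units[grid$plant_id]
  grid$abundance <- grid$mean_stems * grid$mean_floral_units_per_stem
  grid$n_weeks_observed <- mapply(function(s, p) {
    length(unique(stems$week[stems$site == s & stems$plant_id == p &
                               stems$stems > 0]))
  }, grid$site, grid$plant_id)
  grid$n_stem_measurements <- vapply(grid$plant_id, function(p) {
    sum(floral_units$plant_id == p)
  }, integer(1))
  dropped <- is.na(grid$abundance)
  if (any(dropped)) {
    pn_warn(sum(dropped), " site x species abundance value(s) undefined; ",
            "dropped (fallback = ", fallback, ")")
    grid <- grid[!dropped, , drop = FALSE]
  }
  rownames(grid) <- NULL
  grid
}
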