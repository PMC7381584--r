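#' Visitor groups recorded during timed floral observation
#'
#' Field observers distinguish at least these six visitor groups. Ants and
#' true bugs are excluded from analysis (unlikely to be foraging), and all
#' remaining non-honey-bee groups are pooled as "wild pollinators".
#'
#' @format Character vector of group codes.
#' @export
VISITOR_GROUPS <- c("honey_bee", "other_bee_wasp", "fly", "butterfly_moth",
                    "ant", "true_bug")

#' Default wild-pollinator groups (all non-honey-bee groups minus the
#' excluded ants and true bugs). Wasps travel inside `other_bee_wasp`;
#' drop that group here to exclude them.
#' @export
WILD_GROUPS <- c("other_bee_wasp", "fly", "butterfly_moth")

# column contracts for the six input CSVs -----------------------------------

.schemas <- list(
  plants = list(required = c("plant_id", "name", "native_status")),
  observations = list(required = c("obs_id", "site", "week", "zone",
                                   "plant_id", "floral_units", "minutes",
                                   paste0("visits_", VISITOR_GROUPS),
                                   paste0("outside_", VISITOR_GROUPS))),
  stems = list(required = c("site", "week", "zone", "plant_id", "stems")),
  floral_units = list(required = c("site", "date", "plant_id", "stem_id",
                                   "floral_units_on_stem")),
  netting = list(required = c("netting_id", "site", "week", "zone",
                              "plant_id", "minutes", "specimens")),
  pollen = list(required = c("apiary_id", "round", "matrix",
                             "knapweed_grains", "total_grains"))
)

.is_count <- function(x) is.finite(x) & x >= 0 & x == floor(x)

# per-table row validators: return character reason or NA (row OK)
.row_checks <- list(
  plants = function(df) {
    ifelse(!df$native_status %in% c("native", "introduced", "excluded"),
           "native_status must be native/introduced/excluded", NA_character_)
  },
  observations = function(df) {
    counts <- df[, c(paste0("visits_", VISITOR_GROUPS),
                     paste0("outside_", VISITOR_GROUPS)), drop = FALSE]
    bad_counts <- !apply(counts, 1L, function(r) all(.is_count(r)))
    reason <- rep(NA_character_, nrow(df))
    reason[bad_counts] <- "visit counts must be non-negative integers"
    reason[!(df$floral_units >= 1 & .is_count(df$floral_units))] <-
      "floral_units must be an integer >= 1"
    reason[!(is.finite(df$minutes) & df$minutes > 0)] <- "minutes must be > 0"
    reason
  },
  stems = function(df) {
    ifelse(!.is_count(df$stems), "stems must be a non-negative count",
           NA_character_)
  },
  floral_units = function(df) {
    ifelse(!(is.finite(df$floral_units_on_stem) &
               df$floral_units_on_stem >= 0),
           "floral_units_on_stem must be >= 0", NA_character_)
  },
  netting = function(df) {
    ifelse(!(is.finite(df$minutes) & df$minutes > 0), "minutes must be > 0",
           NA_character_)
  },
  pollen = function(df) {
    reason <- rep(NA_character_, nrow(df))
    reason[!(.is_count(df$knapweed_grains) & .is_count(df$total_grains) &
               df$knapweed_grains <= df$total_grains)] <-
      "need 0 <= knapweed_grains <= total_grains"
    reason[is.na(reason) & df$total_grains != 300] <-
      NA_character_ # totals != 300 are accepted; flagged below with a warning
    reason[!df$matrix %in% c("bee_bread", "nectar")] <-
      "matrix must be bee_bread or nectar"
    reason
  }
)

#' Read and validate the analysis input tables
#'
#' Reads any subset of the six input CSVs (`plants`, `observations`, `stems`,
#' `floral_units`, `netting`, `pollen`), enforces the column contracts, and
#' applies row-level invariant checks. A missing required column is a hard
#' error; a row breaching an invariant is rejected and logged in the
#' validation report; unknown extra columns are kept with a warning.
#'
#' @param paths named list/vector of file paths; names must be table names.
#' @param soft_floral_units warn (not reject) when an observation period has
#'   fewer than this many floral units (field protocol aims for >= 10).
#' @return A list of class `pollinet_tables`: one data frame per supplied
#'   table, plus a `validation` data frame (table, row, reason) of rejected
#'   rows and `unknown_plants`, plant ids referenced but absent from the
#'   plant table.
#' @export
read_tables <- function(paths, soft_floral_units = 10) {
  stopifnot(!is.null(names(paths)), all(nzchar(names(paths))))
  unknown <- setdiff(names(paths), names(.schemas))
  if (length(unknown)) pn_stop("unknown table name(s): ",
                               paste(unknown, collapse = ", "))
  out <- list()
  rejects <- list()
  for (nm in names(paths)) {
    df <- read.csv(paths[[nm]], stringsAsFactors = FALSE)
    out[[nm]] <- df
  }
  bundle <- validate_tables(out, soft_floral_units = soft_floral_units)
  bundle
}

#' Validate an in-memory table bundle
#'
#' Same contract as [read_tables()] but starting from data frames, so
#' generated datasets share one validation path with files on disk.
#'
#' @param tables named list of data frames.
#' @inheritParams read_tables
#' @return A `pollinet_tables` list; see [read_tables()].
#' @export
validate_tables <- function(tables, soft_floral_units = 10) {
  out <- list()
  rejects <- list()
  for (nm in names(tables)) {
    schema <- .schemas[[nm]]
    if (is.null(schema)) pn_stop("unknown table name: ", nm)
    df <- as.data.frame(tables[[nm]])
    missing <- setdiff(schema$required, names(df))
    if (length(missing)) {
      pn_stop("table '", nm, "' is missing required column(s): ",
              paste(missing, collapse = ", "))
    }
    extra <- setdiff(names(df), schema$required)
    if (length(extra)) {
      pn_warn("table '", nm, "': ignoring unknown column(s): ",
              paste(extra, collapse = ", "))
    }
    reason <- .row_checks[[nm]](df)
    if (any(!is.na(reason))) {
      bad <- which(!is.na(reason))
      rejects[[nm]] <- data.frame(table = nm, row = bad,
                                  reason = reason[bad])
      df <- df[-bad, , drop = FALSE]
    }
    if (nm == "observations" && any(df$floral_units < soft_floral_units)) {
      pn_warn(sum(df$floral_units < soft_floral_units),
              " observation period(s) watched fewer than ",
              soft_floral_units, " floral units")
    }
    if (nm == "pollen" && any(df$total_grains != 300)) {
      pn_warn(sum(df$total_grains != 300),
              " pollen sample(s) with total_grains != 300 accepted with flag")
    }
    rownames(df) <- NULL
    out[[nm]] <- df
  }
  out$validation <- if (length(rejects)) {
    do.call(rbind, c(rejects, list(make.row.names = FALSE)))
  } else {
    data.frame(table = character(), row = integer(), reason = character())
  }
  if (!is.null(out$plants)) {
    ref <- unique(unlist(lapply(
      c("observations", "stems", "floral_units", "netting"),
      function(t) out[[t]]$plant_id
    )))
    out$unknown_plants <- setdiff(ref, out$plants$plant_id)
  } else {
    out$unknown_plants <- character()
  }
  class(out) <- c("pollinet_tables", "list")
  out
}

#' Write a validated bundle back to CSV files
#'
#' @param bundle a `pollinet_tables` list.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of files written.
#' @export
write_tables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nms <- intersect(names(.schemas), names(bundle))
  files <- setNames(file.path(dir, paste0(nms, ".csv")), nms)
  for (nm in nms) write.csv(bundle[[nm]], files[[nm]], row.names = FALSE)
  invisible(files)
}

#' Collapse per-group visit counts to the canonical honey-bee / wild pair
#'
#' Ants and true bugs are dropped, visits recorded outside the flower are
#' excluded for every group (those columns are simply not counted), and all
#' remaining non-honey-bee groups are summed as wild pollinators. Applied
#' once at load so every downstream model sees one (honey_bee, wild) pair
#' per observation period.
#'
#' @param obs observations data frame (validated).
#' @param wild_groups visitor groups pooled as "wild"; defaults to
#'   [WILD_GROUPS] (wasps included via `other_bee_wasp`).
#' @return `obs` with the per-group columns replaced by `honey_bee_visits`
#'   and `wild_visits`.
#' @export
filter_visits <- function(obs, wild_groups = WILD_GROUPS) {
  if (all(c("honey_bee_visits", "wild_visits") %in% names(obs)) &&
      !any(paste0("visits_", VISITOR_GROUPS) %in% names(obs))) {
    return(obs) # already filtered: idempotent
  }
  stopifnot(all(paste0("visits_", wild_groups) %in% names(obs)))
  keep_cols <- setdiff(names(obs), c(paste0("visits_", VISITOR_GROUPS),
                                     paste0("outside_", VISITOR_GROUPS)))
  res <- obs[, keep_cols, drop = FALSE]
  res$honey_bee_visits <- as.integer(obs$visits_honey_bee)
  wild <- obs[, paste0("visits_", wild_groups), drop = FALSE]
  res$wild_visits <- as.integer(round(rowSums(wild)))
  res
}

#' Drop plants whose native status is neither native nor introduced
#'
#' Species coded `excluded` (e.g. a USDA status of "both") are removed from
#' the plant table and every referencing record.
#'
#' @param plants plant table with `plant_id` and `native_status`.
#' @param ... data frames with a `plant_id` column to filter alongside.
#' @return list with `plants` and each filtered table, plus `n_removed`,
#'   the count of dropped records per table.
#' @export
exclude_status_both <- function(plants, ...) {
  dots <- list(...)
  drop_ids <- plants$plant_id[plants$native_status == "excluded"]
  out <- list(plants = plants[!plants$plant_id %in% drop_ids, , drop = FALSE])
  n_removed <- c(plants = length(drop_ids))
  for (nm in names(dots)) {
    df <- dots[[nm]]
    hit <- df$plant_id %in% drop_ids
    n_removed[nm] <- sum(hit)
    out[[nm]] <- df[!hit, , drop = FALSE]
    if (nrow(out[[nm]]) == 0L && nrow(df) > 0L) {
      pn_warn("all rows of '", nm, "' referenced excluded plants")
    }
  }
  out$n_removed <- n_removed
  out
}
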