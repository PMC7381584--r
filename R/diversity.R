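#' Shannon diversity index (natural log)
#'
#' `H = -sum(p_i * log(p_i))` over taxa with positive counts, in nats.
#' Empty and single-taxon samples return 0.
#'
#' @param counts non-negative taxon counts (named or not).
#' @return Shannon H in nats.
#' @export
shannon <- function(counts) {
  stopifnot(all(counts >= 0))
  x <- counts[counts > 0]
  if (length(x) <= 1L) return(0)
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Taxon richness: number of taxa with positive count
#'
#' Morphotype labels count as distinct taxa.
#'
#' @param counts non-negative taxon counts.
#' @return Integer count.
#' @export
richness <- function(counts) {
  sum(counts > 0)
}

#' Per-netting-period diversity table
#'
#' Specimen lists (semicolon-separated taxon labels, case-normalised) are
#' tabulated per netting period; empty periods are retained with H = 0,
#' S = 0 unless `drop_empty`.
#'
#' @param netting netting table with `netting_id`, `site`, `week`,
#'   `plant_id`, `specimens` (";"-separated labels, possibly empty).
#' @param drop_empty drop periods without specimens.
#' @param synonyms optional named character vector mapping raw labels to
#'   canonical taxa; unmatched labels are kept as their own morphotaxa.
#' @return Data frame: netting_id, site, week, plant_id, shannon, richness,
#'   n_specimens.
#' @export
diversity_table <- function(netting, drop_empty = FALSE, synonyms = NULL) {
  res <- netting[, c("netting_id", "site", "week", "plant_id")]
  stats <- lapply(netting$specimens, function(s) {
    labs <- trimws(strsplit(ifelse(is.na(s), "", s), ";")[[1]])
    labs <- tolower(labs[nzchar(labs)])
    if (!is.null(synonyms)) {
      hit <- labs %in% names(synonyms)
      labs[hit] <- synonyms[labs[hit]]
    }
    counts <- table(labs)
    c(shannon(as.numeric(counts)), richness(as.numeric(counts)),
      sum(counts))
  })
  m <- do.call(rbind, stats)
  res$shannon <- m[, 1]
  res$richness <- as.integer(m[, 2])
  res$n_specimens <- as.integer(m[, 3])
  if (drop_empty) res <- res[res$n_specimens > 0, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Mixed models for bee diversity and richness
#'
#' Shannon diversity is modelled with a linear mixed model and richness with
#' a Poisson generalized linear mixed model, each as native status x floral
#' abundance with random intercepts for site, week, and plant species.
#' Likelihood-ratio tests (ML refits) are reported for native status, floral
#' abundance, and their interaction, for both responses.
#'
#' @param div table from [diversity_table()].
#' @param abundance table from [floral_abundance()].
#' @param plants plant table with native_status.
#' @param abundance_transform transform applied to abundance before
#'   modelling (default identity).
#' @return List: `shannon_fit`, `richness_fit`, `lrt` (response, term,
#'   chisq, df, p — six rows).
#' @export
diversity_models <- function(div, abundance, plants,
                             abundance_transform = "identity") {
  key <- paste(div$site, div$plant_id)
  akey <- paste(abundance$site, abundance$plant_id)
  div$abundance <- abundance$abundance[match(key, akey)]
  div$native_status <- plants$native_status[match(div$plant_id,
                                                  plants$plant_id)]
  div <- div[!is.na(div$abundance) &
               div$native_status %in% c("native", "introduced"), ,
             drop = FALSE]
  div$abund_x <- .transform_abundance(div$abundance, abundance_transform)
  div$native_status <- factor(div$native_status)
  if (nlevels(div$native_status) < 2) {
    pn_stop("native_status constant; diversity model degenerate")
  }
  for (v in c("site", "week", "plant_id")) div[[v]] <- factor(div[[v]])
  ctrl_l <- lme4::lmerControl(check.conv.singular = "ignore",
                              calc.derivs = FALSE)
  ctrl_g <- lme4::glmerControl(check.conv.singular = "ignore",
                               calc.derivs = FALSE)
  re <- "(1 | site) + (1 | week) + (1 | plant_id)"
  fits <- list()
  lrt <- list()
  for (resp in c("shannon", "richness")) {
    f_full <- as.formula(paste(resp, "~ native_status * abund_x +", re))
    f_add <- as.formula(paste(resp, "~ native_status + abund_x +", re))
    f_nost <- as.formula(paste(resp, "~ abund_x +", re))
    f_noab <- as.formula(paste(resp, "~ native_status +", re))
    fitter <- if (resp == "shannon") {
      function(f) lme4::lmer(f, data = div, REML = FALSE, control = ctrl_l)
    } else {
      function(f) lme4::glmer(f, data = div, family = stats::poisson(),
                              control = ctrl_g)
    }
    full <- suppressWarnings(fitter(f_full))
    add <- suppressWarnings(fitter(f_add))
    nost <- suppressWarnings(fitter(f_nost))
    noab <- suppressWarnings(fitter(f_noab))
    fits[[resp]] <- full
    lrt[[resp]] <- rbind(
      cbind(response = resp,
            likelihood_ratio_test(add, nost, label = "native_status")),
      cbind(response = resp,
            likelihood_ratio_test(add, noab, label = "abundance")),
      cbind(response = resp,
            likelihood_ratio_test(full, add,
                                  label = "native_status:abundance")))
  }
  list(shannon_fit = fits$shannon, richness_fit = fits$richness,
       lrt = do.call(rbind, c(lrt, list(make.row.names = FALSE))))
}
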