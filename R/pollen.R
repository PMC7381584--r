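#' Percent knapweed pollen in a 300-grain count
#'
#' @param knapweed_grains knapweed grains counted.
#' @param total_grains total grains counted (normally 300).
#' @return `100 * knapweed_grains / total_grains`, vectorised.
#' @export
percent_knapweed <- function(knapweed_grains, total_grains) {
  if (any(total_grains <= 0)) pn_stop("total_grains must be > 0")
  stopifnot(all(knapweed_grains >= 0), all(knapweed_grains <= total_grains))
  100 * knapweed_grains / total_grains
}

#' Apiary-level and across-apiary knapweed pollen summaries
#'
#' Per apiary and matrix (bee bread or nectar): the mean percent knapweed
#' over sampling rounds and whether any round contained knapweed. Across
#' apiaries (per matrix): median, min, max of the apiary means and the
#' fraction of apiaries with any knapweed — the median is of apiary means,
#' never of pooled raw samples.
#'
#' @param pollen validated pollen table (apiary_id, round, matrix,
#'   knapweed_grains, total_grains).
#' @return List with `by_apiary` (apiary_id, matrix, mean_percent, n_rounds,
#'   contains_knapweed) and `across` (matrix, median_percent, min_percent,
#'   max_percent, n_apiaries, n_with_knapweed, fraction_with_knapweed).
#' @export
apiary_summaries <- function(pollen) {
  pollen$percent <- percent_knapweed(pollen$knapweed_grains,
                                     pollen$total_grains)
  by_ap <- aggregate(percent ~ apiary_id + matrix, data = pollen, FUN = mean)
  names(by_ap)[names(by_ap) == "percent"] <- "mean_percent"
  n_rounds <- aggregate(percent ~ apiary_id + matrix, data = pollen,
                        FUN = length)
  by_ap$n_rounds <- n_rounds$percent
  any_pos <- aggregate(knapweed_grains ~ apiary_id + matrix, data = pollen,
                       FUN = function(x) any(x > 0))
  by_ap$contains_knapweed <- any_pos$knapweed_grains
  across <- do.call(rbind, lapply(split(by_ap, by_ap$matrix), function(d) {
    data.frame(matrix = d$matrix[1],
               median_percent = median(d$mean_percent),
               min_percent = min(d$mean_percent),
               max_percent = max(d$mean_percent),
               n_apiaries = nrow(d),
               n_with_knapweed = sum(d$contains_knapweed),
               fraction_with_knapweed = mean(d$contains_knapweed))
  }))
  rownames(by_ap) <- rownames(across) <- NULL
  list(by_apiary = by_ap, across = across)
}
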