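# pollinet

Community-wide analysis of how honey bees (*Apis mellifera*) and wild
pollinators use introduced versus native flowering plants: who visits
what, how visitation responds to floral abundance, and which plants are
*preferred* — visited more than expected given their availability.

The package is aimed at pollination ecologists with timed
floral-visitation surveys (visit counts per observation period, by
visitor group), quadrat stem counts, bee netting records, and apiary
pollen counts. Every stage also runs on a built-in synthetic-data
generator with known ground truth, so the full pipeline is testable with
no downloads.

## What it computes

* **Floral abundance** per site × species (floral units / 100 m² /
  week): mean weekly stem count × study-wide mean floral units per stem.
* **Visitation-rate models**: visits per floral unit per minute via a
  log-link negative-binomial (NB2) regression with
  `log(floral units × minutes)` exposure offset; fixed effects abundance
  × native status × pollinator type; random intercepts for observation
  period, site, week, plant species (`lme4` mixed mode, or a documented
  cluster-robust approximation). Likelihood-ratio tests, per-group
  abundance slopes, Tukey (max-|t|) adjusted contrasts, and a
  knapweed-vs-coflowering case study.
* **Null-model preference index** — the core. Site-week visitation
  matrices (pollinator type × plant, rates scaled by proportional floral
  abundance) are compared against 1000 null matrices that conserve both
  marginal-total vectors, drawn by an own Patefield-style sampler from
  the multiple hypergeometric law

  $$P(T) \;=\; \frac{\prod_i r_i!\,\prod_j c_j!}{N!\,\prod_{ij} n_{ij}!},$$

  extended to continuous entries by granularity-`g` discretization with
  largest-remainder rounding, and to the one-row degenerate case
  (site-weeks without honey bees) by uniform multinomial
  redistribution. Preference = observed − null mean; positive values
  indicate preference, negative avoidance.
* **Bee diversity**: Shannon index (nats) and richness per netting
  period, with the corresponding mixed models.
* **Apiary pollen summaries**: percent knapweed of 300-grain counts,
  apiary means over rounds, across-apiary median/range and the fraction
  of apiaries containing knapweed.

## Worked example

```r
library(pollinet)

# synthetic community at field scale: 3 sites, 54 species, ~120 periods
d   <- generate_dataset(default_generator_config(n_weeks = 10L), seed = 42)
ex  <- exclude_status_both(d$plants, observations = d$observations,
                           stems = d$stems, netting = d$netting)
obs <- filter_visits(ex$observations)          # ants/bugs/outside excluded
ab  <- floral_abundance(ex$stems, d$floral_units)

prefs <- site_week_preferences(obs, ab, n_replicates = 1000,
                               master_seed = 42)
head(aggregate_species_preference(prefs)[
  aggregate_species_preference(prefs)$pollinator_type == "wild", ], 3)
#>  plant_id pollinator_type mean_preference n_site_weeks rank
#>       P27            wild     0.004066579            3    1
#>       P19            wild     0.003321224            1    2
#>       P47            wild     0.003079733            1    3

long <- build_rate_table(obs, ab, ex$plants)
fit  <- fit_rate_model(long, mode = "robust", abundance_transform = "log")
abundance_slopes(fit)$slopes[, c("label", "estimate", "se", "p_adj")]
#>                 label estimate     se    p_adj
#>  introduced:honey_bee   0.0291 0.0319 3.67e-01
#>      native:honey_bee   0.1673 0.1109 1.38e-01
#>       introduced:wild  -0.3531 0.0777 3.75e-05
#>           native:wild  -0.1484 0.0998 1.43e-01
```

The mean preference column is on the abundance-scaled rate scale
(observed − expected visits per floral unit per minute after scaling);
positive means the species drew more wild-pollinator visitation than the
fixed-margins null predicts from its availability. The slope table shows
the generator's planted structure recovered: honey-bee visitation flat in
log abundance, wild visitation declining, more steeply on introduced
plants (planted exponents 0, 0, −0.35, −0.15).

A pipeline run over every stage, with artifacts and provenance JSON:

```r
run_stage("report", read_run_config(), out = "results/")
```

or from the shell via the bundled CLI:

```sh
Rscript inst/cli/pollinet report --seed 17 --out results/
```

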