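# tiny in-code fixtures shared across test files

obs_fixture <- function() {
  data.frame(
    obs_id = c("O1", "O2", "O3"),
    site = "S1", week = c(1L, 1L, 2L), zone = 1L,
    plant_id = c("A", "B", "A"),
    floral_units = c(30L, 12L, 20L), minutes = 15,
    visits_honey_bee = c(2L, 0L, 4L),
    visits_other_bee_wasp = c(1L, 2L, 0L),
    visits_fly = c(3L, 0L, 1L),
    visits_butterfly_moth = 0L,
    visits_ant = c(5L, 0L, 0L),
    visits_true_bug = c(1L, 0L, 0L),
    outside_honey_bee = 0L,
    outside_other_bee_wasp = 0L,
    outside_fly = c(1L, 0L, 0L),
    outside_butterfly_moth = 0L,
    outside_ant = 0L,
    outside_true_bug = 0L)
}

plants_fixture <- function() {
  data.frame(plant_id = c("A", "B", "C"),
             name = c("Alpha", "Beta", "Gamma"),
             native_status = c("introduced", "native", "excluded"))
}

write_obs_csv <- function(df = obs_fixture()) {
  p <- tempfile(fileext = ".csv")
  write.csv(df, p, row.names = FALSE)
  p
}

# small analysis-ready dataset for model-level tests
small_dataset <- function(seed = 2, n_weeks = 8L, ...) {
  d <- generate_dataset(default_generator_config(n_weeks = n_weeks, ...),
                        seed = seed)
  ex <- exclude_status_both(d$plants, observations = d$observations,
                            stems = d$stems, netting = d$netting)
  list(bundle = d, plants = ex$plants,
       obs = filter_visits(ex$observations),
       stems = ex$stems, netting = ex$netting,
       abundance = d$truth_abundance)
}
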