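# Shared small fixtures, built once per test run.

# mixed-mating desk population: 126 relationship entities
small_mixed_pop <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cfg <- sim_config(n_years = 3, queens_per_year = 20, n_dams = 4,
                        daughters_per_dam = 5, n_stations = 2,
                        dpq_per_station = 8, p_controlled = 0.5,
                        apiary_size = 4, trait = bee_traits()[["T2"]],
                        seed = 11)
      val <<- simulate_population(cfg)
    }
    val
  }
})

# controlled desk population used by the REML tests (300 records)
small_ctrl_pop <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cfg <- sim_config(n_years = 5, queens_per_year = 60, n_dams = 6,
                        daughters_per_dam = 10, n_stations = 2,
                        dpq_per_station = 8, p_controlled = 1,
                        apiary_size = 10, trait = bee_traits()[["T7"]],
                        seed = 77)
      val <<- simulate_population(cfg, keep_drones = FALSE)
    }
    val
  }
})

# hand-built pedigree with exactly computable relationships:
# two base queens; Q1 mated to 12 drones all produced by Q2; her worker
# group W1; a daughter queen Q3 (dam Q1, father a drone of Q2)
toy_pedigree <- function() {
  data.frame(
    id = c("Q1", "Q2", "P1", "W1", "Q3"),
    kind = c("queen", "queen", "sire_group", "worker_group", "queen"),
    dam_id = c(NA, NA, NA, "Q1", "Q1"),
    sire_group_id = c(NA, NA, NA, "P1", "P1"),
    father_dam_id = c(NA, NA, NA, NA, "Q2"),
    drone_dam_ids = c(NA, NA, paste(rep("Q2", 12), collapse = ";"), NA, NA),
    year = c(1L, 1L, 1L, 1L, 2L),
    stringsAsFactors = FALSE)
}
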